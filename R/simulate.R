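#' Simulation configuration
#'
#' Assembles the parameter set the synthetic-data generators run under.
#' Defaults emulate the statistical structure of a mammalian RRBS study at
#' desk scale: a CpG-depleted background with MspI sites about every kb,
#' CpG-island blocks, a bimodal promoter CpG-content mixture whose equal
#' weights/sds put the density crossover at 4 percent, a bimodal methylome
#' (a high mode near 0.8 and a hypomethylated mode near promoters), low
#' non-CpG methylation, negative-binomial coverage, a small bisulfite
#' conversion-failure rate matching ~99.6 percent conversion, and a planted
#' two-condition differential plan.
#'
#' @param seed Integer seed; every generator derives its streams from it.
#' @param n_chroms,chrom_length Genome shape (default 2 x 400 kb).
#' @param gene_count Total genes placed (default 40).
#' @param gc_background Background GC fraction (default 0.42).
#' @param cpg_retention Fraction of background CG dinucleotides kept, the
#'   CpG depletion typical of mammalian genomes (default 0.25).
#' @param ccgg_rate Planted MspI sites per bp on top of the background
#'   (default 5e-4).
#' @param n_cgi,cgi_len_range CpG-island blocks per genome and their length
#'   range in bp.
#' @param cgi_gc,cgi_oe GC fraction and observed/expected CpG of planted
#'   islands.
#' @param promoter_mix Two-component promoter CpG-content mixture on the
#'   percent scale: list with `weight`, `mean`, `sd` (length-2 each).
#' @param hcp_threshold Generative content threshold separating the classes
#'   (4 percent, the crossover of the default mixture).
#' @param high_mean High methylation mode (default 0.8).
#' @param dip_hcp,dip_lcp TSS dip depths in logit units for HCP and LCP
#'   genes (defaults 4 and 1).
#' @param dip_width Gaussian dip width in bp (default 1000).
#' @param density_coupling Logit-scale coupling of methylation to local gene
#'   density (default 0.5); 0 disables it.
#' @param density_window Window for the local gene-density covariate in bp.
#' @param level_concentration Beta concentration of per-site biological
#'   noise around the mean level (`Inf` = none).
#' @param rep_dispersion Between-replicate beta-binomial dispersion; the
#'   default 0 gives the pure binomial count model, with the knob exposed
#'   for calibration studies.
#' @param coverage_mean,coverage_size Negative-binomial read depth per
#'   strand record has mean `coverage_mean / 2` and size `coverage_size`.
#' @param conversion_failure Probability an unmethylated C escapes
#'   conversion and reads as methylated (default 0.004).
#' @param noncpg_level True non-CpG methylation level (default 0.01).
#' @param noncpg_fraction Fraction of non-CpG cytosines that receive
#'   coverage records (default 0.02).
#' @param diff_n_regions,diff_width,diff_delta Differential plan: number of
#'   planted regions, their width in bp, and the level shift added in
#'   condition B (default -0.5, hypomethylation in B).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_length = 400000L,
                       gene_count = 40L,
                       gc_background = 0.42, cpg_retention = 0.25,
                       ccgg_rate = 5e-4,
                       n_cgi = 30L, cgi_len_range = c(300L, 700L),
                       cgi_gc = 0.65, cgi_oe = 0.85,
                       promoter_mix = list(weight = c(0.5, 0.5),
                                           mean = c(2, 6),
                                           sd = c(0.8, 0.8)),
                       hcp_threshold = 4.0,
                       high_mean = 0.8,
                       dip_hcp = 4, dip_lcp = 1, dip_width = 1000,
                       density_coupling = 0.5, density_window = 50000,
                       level_concentration = 50,
                       rep_dispersion = 0,
                       coverage_mean = 15, coverage_size = 4,
                       conversion_failure = 0.004,
                       noncpg_level = 0.01, noncpg_fraction = 0.02,
                       diff_n_regions = 30L, diff_width = 400L,
                       diff_delta = -0.5) {
  cfg <- as.list(environment())
  stopifnot(cfg$cpg_retention >= 0, cfg$cpg_retention <= 1,
            cfg$conversion_failure >= 0, cfg$conversion_failure <= 1,
            cfg$noncpg_level >= 0, cfg$noncpg_level <= 1,
            cfg$chrom_length > 0, cfg$coverage_mean > 0)
  structure(cfg, class = "sim_config")
}

# assemble a block of given length with an exact count of planted CG
# dinucleotides; filler bases drawn with the given GC probability and
# accidental CG pairs broken so the planted count is exact
.cg_block <- function(len, n_cg, gc_filler = 0.5) {
  n_cg <- max(0L, min(n_cg, floor(len / 2)))
  n_fill <- len - 2L * n_cg
  units <- c(rep("CG", n_cg),
             sample(c("A", "C", "G", "T"), n_fill, replace = TRUE,
                    prob = c((1 - gc_filler) / 2, gc_filler / 2,
                             gc_filler / 2, (1 - gc_filler) / 2)))
  units <- sample(units)
  planted <- units == "CG"
  base <- strsplit(paste(units, collapse = ""), "", fixed = TRUE)[[1L]]
  # 0-based start of each unit and of each planted CG
  unit_start <- cumsum(c(0L, nchar(units)[-length(units)]))
  planted_start <- unit_start[planted]
  cg_at <- which(base[-length(base)] == "C" & base[-1L] == "G") - 1L
  accidental <- setdiff(cg_at, planted_start)
  if (length(accidental) > 0L) base[accidental + 2L] <- "T"
  if (base[len] == "C" && !(len - 2L) %in% planted_start) base[len] <- "T"
  base
}

#' Simulate a genome with genes, promoters and CpG islands
#'
#' Builds a CpG-depleted background, plants MspI (CCGG) sites, places
#' non-overlapping genes with exon/intron structure at a density that
#' declines along each chromosome, overwrites each 1-kb promoter window
#' with a block whose CpG content is drawn from the configured two-normal
#' mixture, and inserts CG-rich island blocks away from promoters. Truth
#' tables record every planted promoter content and island span.
#'
#' @param config `sim_config`.
#' @return List: `genome` (named `DNAStringSet`), `genes` (gene-model
#'   table), `truth` (list with `promoters` data frame of planted contents
#'   and HCP labels, and `cgis` data frame of planted island spans).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  L <- config$chrom_length
  up_guard <- 6000L  # keep flanks and promoter windows inside the chromosome
  slot <- 12000L
  chrom_names <- paste0("chr", seq_len(config$n_chroms))
  per_chrom <- diff(round(seq(0, config$gene_count,
                              length.out = config$n_chroms + 1L)))
  seqs <- list()
  gene_rows <- list()
  prom_truth <- list()
  cgi_truth <- list()
  gid <- 0L
  for (ci in seq_len(config$n_chroms)) {
    ch <- chrom_names[ci]
    gc <- config$gc_background
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    # CpG depletion: break a fraction of background CG dinucleotides
    cg_at <- which(base[-L] == "C" & base[-1L] == "G")
    drop <- cg_at[stats::runif(length(cg_at)) > config$cpg_retention]
    if (length(drop) > 0L) {
      base[drop + 1L] <- sample(c("A", "T"), length(drop), replace = TRUE)
    }
    # planted MspI sites
    n_ccgg <- stats::rpois(1L, config$ccgg_rate * L)
    if (n_ccgg > 0L) {
      at <- sample.int(L - 4L, n_ccgg)  # 1-based start
      for (k in at) base[k:(k + 3L)] <- c("C", "C", "G", "G")
    }
    # gene placement: declining density along the chromosome
    n_slots <- floor((L - 2L * up_guard) / slot)
    n_genes <- min(per_chrom[ci], n_slots)
    w <- 1 + 4 * (1 - seq_len(n_slots) / n_slots)
    slots <- sort(sample.int(n_slots, n_genes, prob = w))
    for (s in slots) {
      gid <- gid + 1L
      slot_start <- up_guard + (s - 1L) * slot
      span <- sample(2000:5000, 1L)
      start <- slot_start + sample.int(slot - span - 1000L, 1L)
      strand <- sample(c("+", "-"), 1L)
      n_ex <- sample(3:5, 1L)
      ex_w <- sample(150:400, n_ex, replace = TRUE)
      gap_total <- span - sum(ex_w)
      if (gap_total < n_ex - 1L) { ex_w <- rep(150L, n_ex); gap_total <- span - sum(ex_w) }
      cuts <- sort(stats::runif(n_ex - 2L))
      in_w <- round(diff(c(0, cuts, 1)) * gap_total)
      in_w[n_ex - 1L] <- gap_total - sum(in_w[-(n_ex - 1L)])
      in_w <- pmax(in_w, 0L)
      ex_start <- start + cumsum(c(0L, ex_w[-n_ex] + in_w))
      ex <- cbind(start = as.integer(ex_start),
                  end = as.integer(ex_start + ex_w))
      ex[n_ex, 2] <- start + span  # last exon closes the span exactly
      tss <- if (strand == "+") start else start + span
      tes <- if (strand == "+") start + span else start
      gene_rows[[gid]] <- list(gene_id = sprintf("g%03d", gid), chrom = ch,
                               strand = strand, tss = tss, tes = tes,
                               exons = ex)
      # planted promoter CpG content
      comp <- sample(1:2, 1L, prob = config$promoter_mix$weight)
      content <- stats::rnorm(1L, config$promoter_mix$mean[comp],
                              config$promoter_mix$sd[comp])
      content <- min(max(content, 0.2), 45)
      n_cg <- round(content * 10)  # CG starts in the 1000-bp window
      block <- .cg_block(1000L, n_cg, gc_filler = 0.5)
      base[(tss - 500L + 1L):(tss + 500L)] <- block
      prom_truth[[gid]] <- data.frame(
        gene_id = sprintf("g%03d", gid), chrom = ch, tss = tss,
        content = n_cg / 10, component = comp,
        hcp = n_cg / 10 > config$hcp_threshold, stringsAsFactors = FALSE)
    }
    seqs[[ch]] <- base
  }
  genes <- .assemble_rows(gene_rows)
  # CpG-island blocks away from promoters and from each other
  prom <- do.call(rbind, prom_truth)
  for (k in seq_len(config$n_cgi)) {
    ch <- sample(chrom_names, 1L)
    len <- sample(config$cgi_len_range[1]:config$cgi_len_range[2], 1L)
    for (try in 1:50) {
      at <- sample.int(L - len - 1000L, 1L) + 500L  # 1-based start
      near_prom <- any(prom$chrom == ch &
                         abs(prom$tss - at) < 2000L + len)
      near_cgi <- length(cgi_truth) > 0L && any(vapply(cgi_truth, function(d) {
        d$chrom == ch && abs(d$start - (at - 1L)) < 2L * len + 500L
      }, TRUE))
      if (!near_prom && !near_cgi) break
    }
    n_cg <- round(len * (config$cgi_gc / 2)^2 * config$cgi_oe)
    gc_fill <- (config$cgi_gc * len - 2 * n_cg) / (len - 2 * n_cg)
    block <- .cg_block(len, n_cg, gc_filler = max(min(gc_fill, 0.95), 0.05))
    seqs[[ch]][at:(at + len - 1L)] <- block
    cgi_truth[[k]] <- data.frame(chrom = ch, start = at - 1L,
                                 end = at - 1L + len, stringsAsFactors = FALSE)
  }
  genome <- Biostrings::DNAStringSet(
    vapply(seqs, function(b) paste(b, collapse = ""), ""))
  names(genome) <- chrom_names
  cgis <- do.call(rbind, cgi_truth)
  if (!is.null(cgis)) cgis <- cgis[order(cgis$chrom, cgis$start), , drop = FALSE]
  list(genome = genome, genes = genes,
       truth = list(promoters = prom, cgis = cgis))
}

.assemble_rows <- function(rows) {
  gene_model_table(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    tss = vapply(rows, function(r) as.integer(r$tss), 1L),
    tes = vapply(rows, function(r) as.integer(r$tes), 1L),
    exons = lapply(rows, `[[`, "exons"))
}

#' Simulate the true methylome of a synthetic genome
#'
#' Per-CpG mean level is `plogis(logit(high_mean) - density_coupling * z -
#' dip * exp(-d^2 / (2 dip_width^2)))` where z is the standardized local
#' gene density and d the distance to the nearest TSS; the dip depth is
#' `dip_hcp` for genes whose planted promoter content exceeds the HCP
#' threshold and `dip_lcp` otherwise. Per-site beta noise with the
#' configured concentration is added around the mean. Non-CpG cytosines
#' receive the configured low level; a configured fraction of them is
#' retained for coverage simulation.
#'
#' @param sim Output of [simulate_genome()].
#' @param config `sim_config`.
#' @return List: `cpg` (data frame `chrom`, `pos` (forward duplex C),
#'   `mu` (noise-free mean), `true_level`), `noncpg` (data frame `chrom`,
#'   `pos`, `strand`, `context`, `true_level`).
#' @export
simulate_methylome <- function(sim, config) {
  set.seed(config$seed + 1L)
  genome <- sim$genome
  genes <- sim$genes
  hcp_ids <- sim$truth$promoters$gene_id[sim$truth$promoters$hcp]
  base_logit <- stats::qlogis(config$high_mean)
  cpg_list <- list(); noncpg_list <- list()
  dens_all <- list()
  for (ch in names(genome)) {
    pos <- cg_positions(genome[[ch]])
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) > 0L) {
      tss <- sort(g$tss)
      near <- findInterval(pos, tss)
      d_lo <- ifelse(near > 0L, pos - tss[pmax(near, 1L)], Inf)
      d_hi <- ifelse(near < length(tss), tss[pmin(near + 1L, length(tss))] - pos, Inf)
      d <- pmin(abs(d_lo), abs(d_hi))
      nearest_tss <- ifelse(abs(d_lo) <= abs(d_hi),
                            tss[pmax(near, 1L)],
                            tss[pmin(near + 1L, length(tss))])
      ord_ids <- g$gene_id[order(g$tss)]
      nearest_id <- ord_ids[match(nearest_tss, tss)]
      dip <- ifelse(nearest_id %in% hcp_ids, config$dip_hcp, config$dip_lcp)
      # local gene density: TSS count within density_window of each CpG
      half <- config$density_window / 2
      dens <- findInterval(pos + half, tss) - findInterval(pos - half, tss)
    } else {
      d <- rep(Inf, length(pos)); dip <- 0; dens <- rep(0, length(pos))
    }
    dens_all[[ch]] <- dens
    cpg_list[[ch]] <- data.frame(
      chrom = ch, pos = pos, d = d, dip = dip, dens = dens,
      stringsAsFactors = FALSE)
    # non-CpG cytosines (both strands)
    s <- as.character(genome[[ch]])
    b <- strsplit(s, "", fixed = TRUE)[[1L]]
    Lc <- length(b)
    fwd_c <- which(b == "C")
    fwd_c <- fwd_c[b[pmin(fwd_c + 1L, Lc)] != "G" | fwd_c == Lc]
    rev_c <- which(b == "G")
    rev_c <- rev_c[b[pmax(rev_c - 1L, 1L)] != "C" | rev_c == 1L]
    take_f <- fwd_c[stats::runif(length(fwd_c)) < config$noncpg_fraction]
    take_r <- rev_c[stats::runif(length(rev_c)) < config$noncpg_fraction]
    nc <- data.frame(chrom = ch,
                     pos = c(take_f, take_r) - 1L,
                     strand = rep(c("+", "-"), c(length(take_f), length(take_r))),
                     stringsAsFactors = FALSE)
    if (nrow(nc) > 0L) {
      nc$context <- classify_context(genome, nc$chrom, nc$pos, nc$strand)
      nc <- nc[!is.na(nc$context) & nc$context != "CpG", , drop = FALSE]
      nc$true_level <- config$noncpg_level
    }
    noncpg_list[[ch]] <- nc
  }
  cpg <- do.call(rbind, cpg_list)
  z <- if (stats::sd(cpg$dens) > 0) as.numeric(scale(cpg$dens)) else 0
  logit_mu <- base_logit - config$density_coupling * z -
    cpg$dip * exp(-cpg$d^2 / (2 * config$dip_width^2))
  mu <- stats::plogis(logit_mu)
  conc <- config$level_concentration
  lv <- if (is.finite(conc)) {
    stats::rbeta(length(mu), mu * conc, (1 - mu) * conc)
  } else mu
  out_cpg <- data.frame(chrom = cpg$chrom, pos = cpg$pos, mu = mu,
                        true_level = pmin(pmax(lv, 1e-4), 1 - 1e-4),
                        stringsAsFactors = FALSE)
  noncpg <- do.call(rbind, noncpg_list)
  rownames(out_cpg) <- rownames(noncpg) <- NULL
  list(cpg = out_cpg, noncpg = noncpg)
}

#' Simulate bisulfite count records from a true methylome
#'
#' Each CpG duplex yields a + strand record at the forward C and a - strand
#' record at the partner position, each with independent negative-binomial
#' depth (mean `coverage_mean / 2`, size `coverage_size`); non-CpG sites
#' yield single-strand records. Replicates share the true levels; per
#' replicate and site, the realized level is a beta draw around the truth
#' with dispersion `rep_dispersion`. Conversion failure inflates the
#' observed methylated probability to `beta + (1 - beta) * f`. Zero-depth
#' records are not emitted (coverage files list covered sites only).
#'
#' @param methylome Output of [simulate_methylome()] (or a compatible list
#'   with `cpg` and optional `noncpg` data frames carrying `true_level`).
#' @param config `sim_config`.
#' @param n_replicates Number of replicates (default 1).
#' @param seed Base seed for the count streams (default
#'   `config$seed + 100`); replicate r uses `seed + r`.
#' @return List of count-record data frames ([read_coverage()] schema), one
#'   per replicate.
#' @export
simulate_counts <- function(methylome, config, n_replicates = 1L,
                            seed = config$seed + 100L) {
  reps <- vector("list", n_replicates)
  f <- config$conversion_failure
  phi <- config$rep_dispersion
  mu_strand <- config$coverage_mean / 2
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r)
    cpg <- methylome$cpg
    n <- nrow(cpg)
    lv <- cpg$true_level
    if (phi > 0) {
      ab <- 1 / phi - 1
      lv <- stats::rbeta(n, lv * ab, (1 - lv) * ab)
      lv <- pmin(pmax(lv, 0), 1)
    }
    p_obs <- lv + (1 - lv) * f
    dp <- stats::rnbinom(n, mu = mu_strand, size = config$coverage_size)
    dm <- stats::rnbinom(n, mu = mu_strand, size = config$coverage_size)
    mp <- stats::rbinom(n, dp, p_obs)
    mm <- stats::rbinom(n, dm, p_obs)
    cpg_rec <- data.frame(
      chrom = rep(cpg$chrom, 2L),
      pos = c(cpg$pos, cpg$pos + 1L),
      strand = rep(c("+", "-"), each = n),
      meth = c(mp, mm), unmeth = c(dp - mp, dm - mm),
      context = "CpG", stringsAsFactors = FALSE)
    cpg_rec <- cpg_rec[cpg_rec$meth + cpg_rec$unmeth > 0L, , drop = FALSE]
    out <- cpg_rec
    nc <- methylome$noncpg
    if (!is.null(nc) && nrow(nc) > 0L) {
      k <- nrow(nc)
      p_nc <- nc$true_level + (1 - nc$true_level) * f
      dn <- stats::rnbinom(k, mu = mu_strand, size = config$coverage_size)
      mn <- stats::rbinom(k, dn, p_nc)
      nc_rec <- data.frame(chrom = nc$chrom, pos = nc$pos,
                           strand = nc$strand, meth = mn,
                           unmeth = dn - mn, context = nc$context,
                           stringsAsFactors = FALSE)
      out <- rbind(out, nc_rec[nc_rec$meth + nc_rec$unmeth > 0L, , drop = FALSE])
    }
    out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    reps[[r]] <- out
  }
  reps
}

#' Simulate a two-condition methylome with planted differential regions
#'
#' Condition A is the simulated methylome; condition B adds `diff_delta`
#' (clamped to [0.01, 0.99]) to every CpG inside `diff_n_regions` planted
#' regions of width `diff_width`. Regions are chosen disjoint, with at
#' least 5 CpGs and a mean condition-A level of at least 0.6 so the planted
#' shift survives clamping.
#'
#' @param config `sim_config`.
#' @param sim,methylome Optional pre-built genome and methylome (rebuilt
#'   from `config` when missing).
#' @return List: `sim`, `methylome_a`, `methylome_b`, `counts_a`,
#'   `counts_b` (single-replicate count data frames) and `truth_regions`
#'   (data frame `chrom`, `start`, `end`, `n_cpgs`, `delta`).
#' @export
simulate_two_conditions <- function(config, sim = NULL, methylome = NULL) {
  if (config$diff_delta == 0 && config$diff_n_regions > 0L) {
    warning("diff_delta = 0: planted regions are undetectable")
  }
  if (is.null(sim)) sim <- simulate_genome(config)
  if (is.null(methylome)) methylome <- simulate_methylome(sim, config)
  set.seed(config$seed + 7L)
  cpg <- methylome$cpg
  width <- config$diff_width
  chosen <- list()
  in_region <- rep(FALSE, nrow(cpg))
  attempts <- 0L
  while (length(chosen) < config$diff_n_regions && attempts < 400L * config$diff_n_regions) {
    attempts <- attempts + 1L
    i <- sample.int(nrow(cpg), 1L)
    ch <- cpg$chrom[i]; a <- cpg$pos[i]; b <- a + width
    inside <- which(cpg$chrom == ch & cpg$pos >= a & cpg$pos < b)
    if (length(inside) < 5L) next
    if (mean(cpg$true_level[inside]) < 0.6) next
    overlap <- any(vapply(chosen, function(r) {
      r$chrom == ch && a < r$end + width && b > r$start - width
    }, TRUE))
    if (overlap) next
    chosen[[length(chosen) + 1L]] <- list(chrom = ch, start = a, end = b,
                                          n_cpgs = length(inside))
    in_region[inside] <- TRUE
  }
  meth_b <- methylome
  meth_b$cpg$true_level[in_region] <-
    pmin(pmax(meth_b$cpg$true_level[in_region] + config$diff_delta, 0.01), 0.99)
  counts_a <- simulate_counts(methylome, config, 1L, seed = config$seed + 200L)[[1L]]
  counts_b <- simulate_counts(meth_b, config, 1L, seed = config$seed + 300L)[[1L]]
  truth <- do.call(rbind, lapply(chosen, as.data.frame))
  if (!is.null(truth)) {
    truth$delta <- config$diff_delta
    truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
  }
  list(sim = sim, methylome_a = methylome, methylome_b = meth_b,
       counts_a = counts_a, counts_b = counts_b, truth_regions = truth)
}
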