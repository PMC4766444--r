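#' Run the full synthetic-study pipeline
#'
#' Executes the stages in dependency order on a simulated study: genome
#' simulation, in-silico digestion and RR-genome statistics, methylation
#' calling with QC, TSS/metagene profiles, promoter classification, and
#' two-condition differential methylation. Writes every table under
#' `out_dir` and a JSON manifest with the seed, the resolved configuration,
#' per-stage record counts and an md5 checksum of every output file.
#' Re-running with the same configuration reproduces identical checksums.
#'
#' @param config `sim_config`.
#' @param out_dir Output directory (created if missing).
#' @param n_replicates Replicates for the single-condition arm (default 3).
#' @param stages Character subset of
#'   `c("simulate", "digest", "call", "profile", "classify", "diff")`;
#'   stages always run in dependency order.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, n_replicates = 3L,
                         stages = c("simulate", "digest", "call",
                                    "profile", "classify", "diff")) {
  allowed <- c("simulate", "digest", "call", "profile", "classify", "diff")
  if (!all(stages %in% allowed)) {
    stop("unknown stage: ", paste(setdiff(stages, allowed), collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  counts <- list()
  res <- list()
  say <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

  say("simulate: genome + methylome + counts (seed ", config$seed, ")")
  sim <- simulate_genome(config)
  meth <- simulate_methylome(sim, config)
  reps <- simulate_counts(meth, config, n_replicates)
  res$sim <- sim; res$methylome <- meth; res$replicates <- reps
  if ("simulate" %in% stages) {
    fa <- file.path(out_dir, "genome.fa")
    Biostrings::writeXStringSet(sim$genome, fa)
    outputs <- c(outputs, fa)
    for (r in seq_along(reps)) {
      p <- file.path(out_dir, sprintf("rep%d.cov.tsv", r))
      write_coverage(reps[[r]], p)
      outputs <- c(outputs, p)
    }
    tp <- file.path(out_dir, "truth_promoters.tsv")
    write_tsv(sim$truth$promoters, tp)
    outputs <- c(outputs, tp)
    counts$simulate <- list(n_cpg_duplexes = nrow(meth$cpg),
                            n_noncpg_sites = nrow(meth$noncpg))
  }

  chrom_len <- genome_lengths(sim$genome)
  features <- build_feature_set(sim$genes, chrom_len)
  if ("digest" %in% stages) {
    say("digest: MspI fragments and RR statistics")
    frags <- digest_genome(sim$genome)
    rr <- size_select(frags)
    gsum <- summarize_digest(frags, sim$genome, features)
    rsum <- summarize_rr(rr, sim$genome, features)
    folds <- enrichment_folds(gsum, rsum)
    cap <- capture_fractions(gsum, rsum)
    res$digest <- list(fragments = frags, rr = rr, genome_summary = gsum,
                       rr_summary = rsum, folds = folds, capture = cap)
    fb <- file.path(out_dir, "rr_fragments.bed")
    write_bed(rr$fragments[, c("chrom", "start", "end")], fb)
    st <- file.path(out_dir, "rr_summary.tsv")
    write_tsv(data.frame(
      quantity = c("segments_genome", "segments_rr", "segments_per_mb_genome",
                   "segments_per_mb_rr", "cpgs_per_mb_genome",
                   "cpgs_per_mb_rr", "segment_fold", "cpg_fold",
                   paste0("capture_", names(cap))),
      value = c(gsum$segment_count, rsum$segment_count, gsum$segments_per_mb,
                rsum$segments_per_mb, gsum$cpgs_per_mb, rsum$cpgs_per_mb,
                folds$segment_fold, folds$cpg_fold, unname(cap))), st)
    outputs <- c(outputs, fb, st)
    counts$digest <- list(n_fragments = nrow(frags), n_selected = rr$n_fragments)
  }

  say("call: strand combining, depth filter, QC")
  called <- lapply(reps, function(r) {
    call_levels(filter_depth(combine_strands(r)))
  })
  qc <- lapply(reps, conversion_rate)
  res$called <- called; res$qc <- qc
  if ("call" %in% stages) {
    for (r in seq_along(called)) {
      p <- file.path(out_dir, sprintf("rep%d.meth.tsv", r))
      write_tsv(called[[r]], p)
      outputs <- c(outputs, p)
    }
    counts$call <- list(sites_per_replicate = vapply(called, nrow, 1L),
                        conversion_rates = vapply(qc, `[[`, 1, "rate"))
  }

  rep1_cpg <- called[[1]][called[[1]]$context == "CpG", ]
  if ("profile" %in% stages) {
    say("profile: TSS, metagene, windows, CGIs")
    tssm <- tss_profile(rep1_cpg, sim$genes, value = "methylation")
    tssc <- tss_profile(sim$genome, sim$genes, value = "cpg_content")
    mg <- metagene_profile(rep1_cpg, sim$genes)
    wm <- window_methylation(rep1_cpg, sim$genes, chrom_len, window = 50000)
    cgis <- cgi_scan(sim$genome)
    cfm <- cgi_feature_methylation(cgis, features, rep1_cpg)
    res$profiles <- list(tss_meth = tssm, tss_cpg = tssc, metagene = mg,
                         windows = wm, cgis = cgis, cgi_features = cfm)
    for (nm in c("tss_meth", "tss_cpg", "metagene", "windows")) {
      p <- file.path(out_dir, paste0(nm, ".tsv"))
      write_tsv(res$profiles[[nm]], p)
      outputs <- c(outputs, p)
    }
    pb <- file.path(out_dir, "cgis.bed")
    write_bed(cgis, pb)
    outputs <- c(outputs, pb)
    counts$profile <- list(n_cgis = nrow(cgis))
  }

  if ("classify" %in% stages) {
    say("classify: promoter CpG content, mixture fit, crossover")
    contents <- promoter_cpg_content(sim$genome, sim$genes)
    fit <- fit_two_normal_mixture(contents$content, seed = config$seed)
    thr <- crossover(fit)
    classes <- classify_promoters(contents, thr)
    res$promoters <- list(contents = contents, fit = fit,
                          crossover = thr, classes = classes)
    p <- file.path(out_dir, "promoter_classes.tsv")
    write_tsv(classes, p)
    fj <- file.path(out_dir, "mixture_fit.json")
    jsonlite::write_json(list(weight = fit$weight, mean = fit$mean,
                              sd = fit$sd, log_likelihood = fit$log_likelihood,
                              n_iterations = fit$n_iterations,
                              converged = fit$converged, crossover = thr),
                         fj, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, p, fj)
    counts$classify <- list(n_hcp = sum(classes$class == "HCP"),
                            n_lcp = sum(classes$class == "LCP"),
                            crossover = thr)
  }

  if ("diff" %in% stages) {
    say("diff: two-condition DMC/DMR calling")
    two <- simulate_two_conditions(config, sim = sim, methylome = meth)
    sa <- combine_strands(two$counts_a)
    sb <- combine_strands(two$counts_b)
    sites <- shared_sites(sa, sb)
    disp <- estimate_dispersion(sites)
    dm <- call_dmcs(sites, disp)
    dmrs <- merge_dmrs(dm$dmcs)
    ann <- if (nrow(dm$dmcs) > 0) annotate_features(dm$dmcs, features) else NULL
    res$diff <- list(truth = two$truth_regions, sites = sites,
                     dmcs = dm$dmcs, tests = dm$tests, dmrs = dmrs,
                     annotation = ann)
    pd <- file.path(out_dir, "dmc.tsv")
    write_tsv(dm$dmcs[, setdiff(names(dm$dmcs), "is_dmc")], pd)
    pr <- file.path(out_dir, "dmr.bed")
    write_bed(dmrs, pr)
    pt <- file.path(out_dir, "truth_dmr.bed")
    write_bed(two$truth_regions, pt)
    outputs <- c(outputs, pd, pr, pt)
    counts$diff <- list(n_shared = nrow(sites), n_dmcs = nrow(dm$dmcs),
                        n_dmrs = nrow(dmrs))
  }

  manifest <- list(
    tool = paste0("rrbsim ", as.character(utils::packageVersion("rrbsim"))),
    seed = config$seed,
    config = unclass(config),
    stages = stages,
    counts = counts,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) list(path = p,
                                      md5 = unname(tools::md5sum(p)))))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say("done: ", length(outputs), " outputs + manifest")
  invisible(list(results = res, manifest = manifest))
}
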