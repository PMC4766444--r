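#' TSS-anchored profile of methylation or CpG content
#'
#' Bins the `flank` bp on either side of every TSS into `bin`-bp bins
#' (200 bins with the defaults). Offsets are strand-aware signed distances
#' from the TSS (negative = upstream); bin index = floor((offset + flank) /
#' bin). For `value = "methylation"` each bin averages the levels of the CpG
#' records falling in it, pooled across genes; for `value = "cpg_content"`
#' each bin reports 100 x CG starts per bp of its genomic span, averaged
#' over genes whose span is fully inside the chromosome.
#'
#' @param x Filtered methylation records (with `level`) for
#'   `value = "methylation"`, or a named `DNAStringSet` genome for
#'   `value = "cpg_content"`.
#' @param genes Gene-model table.
#' @param flank Flank size in bp (default 5000); must be a multiple of `bin`.
#' @param bin Bin width in bp (default 50).
#' @param value `"methylation"` or `"cpg_content"`.
#' @return Data frame `bin_index` (0-based), `offset_mid` (bp from TSS at
#'   the bin midpoint), `mean_value` (`NA` for empty bins), `n_observations`.
#' @export
tss_profile <- function(x, genes, flank = 5000L, bin = 50L,
                        value = c("methylation", "cpg_content")) {
  value <- match.arg(value)
  if (flank %% bin != 0L) stop("flank must be a multiple of bin")
  n_bins <- as.integer(2L * flank / bin)
  if (value == "methylation") {
    records <- x
    if (!"level" %in% names(records)) records <- call_levels(records)
    sums <- numeric(n_bins); ns <- integer(n_bins)
    for (ch in unique(genes$chrom)) {
      g <- genes[genes$chrom == ch, , drop = FALSE]
      r <- records[records$chrom == ch & records$context == "CpG", , drop = FALSE]
      if (nrow(r) == 0L) next
      for (i in seq_len(nrow(g))) {
        off <- if (g$strand[i] == "+") r$pos - g$tss[i] else g$tss[i] - r$pos
        keep <- off >= -flank & off < flank
        if (!any(keep)) next
        bi <- floor((off[keep] + flank) / bin) + 1L
        sums <- sums + .bin_sum(r$level[keep], bi, n_bins)
        ns <- ns + tabulate(bi, nbins = n_bins)
      }
    }
    mean_value <- ifelse(ns > 0L, sums / ns, NA_real_)
    n_obs <- ns
  } else {
    genome <- x
    mat <- matrix(NA_real_, nrow = nrow(genes), ncol = n_bins)
    for (ch in unique(genes$chrom)) {
      cg <- cg_positions(genome[[ch]])
      L <- length(genome[[ch]])
      gi <- which(genes$chrom == ch)
      for (i in gi) {
        tss <- genes$tss[i]
        if (tss - flank < 0L || tss + flank > L) next  # clipped span skipped
        off <- if (genes$strand[i] == "+") cg - tss else tss - cg
        keep <- off >= -flank & off < flank
        bi <- floor((off[keep] + flank) / bin) + 1L
        mat[i, ] <- 100 * tabulate(bi, nbins = n_bins) / bin
      }
    }
    n_obs <- colSums(!is.na(mat))
    mean_value <- colMeans(mat, na.rm = TRUE)
    mean_value[n_obs == 0L] <- NA_real_
  }
  data.frame(bin_index = seq_len(n_bins) - 1L,
             offset_mid = -flank + (seq_len(n_bins) - 0.5) * bin,
             mean_value = mean_value, n_observations = n_obs)
}

.bin_sum <- function(values, bins, n_bins) {
  out <- numeric(n_bins)
  agg <- rowsum(values, bins)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Metagene methylation profile
#'
#' Concatenated profile over up5k (20 bins of 250 bp), exon (40 bins over
#' each gene's exonic bp joined 5' to 3' into one virtual axis), intron
#' (40 bins over the non-exonic gene-body bp), and down2k (20 bins of
#' 100 bp). Orientation is strand-aware; observations are pooled across
#' genes per bin. Genes without introns simply contribute nothing to the
#' intron bins.
#'
#' @param records Filtered CpG records with levels.
#' @param genes Gene-model table.
#' @param n_flank_bins Bins for each flank (default 20).
#' @param n_body_bins Bins for each of the exon and intron axes (default 40).
#' @param up,down Flank sizes in bp (5000 and 2000).
#' @return Data frame `region_label`, `bin_index` (0-based within region),
#'   `n_bins`, `mean_value`, `n_observations`.
#' @export
metagene_profile <- function(records, genes, n_flank_bins = 20L,
                             n_body_bins = 40L, up = 5000L, down = 2000L) {
  if (!"level" %in% names(records)) records <- call_levels(records)
  records <- records[records$context == "CpG", , drop = FALSE]
  regions <- c("up5k", "exon", "intron", "down2k")
  nb <- c(up5k = n_flank_bins, exon = n_body_bins,
          intron = n_body_bins, down2k = n_flank_bins)
  sums <- lapply(nb, function(k) numeric(k))
  ns <- lapply(nb, function(k) integer(k))
  add <- function(region, virt, axis_len, lev) {
    k <- nb[[region]]
    bi <- pmin(floor(virt * k / axis_len), k - 1) + 1L
    sums[[region]] <<- sums[[region]] + .bin_sum(lev, bi, k)
    ns[[region]] <<- ns[[region]] + tabulate(bi, nbins = k)
  }
  for (ch in unique(genes$chrom)) {
    r <- records[records$chrom == ch, , drop = FALSE]
    if (nrow(r) == 0L) next
    g <- genes[genes$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      plus <- g$strand[i] == "+"
      tss <- g$tss[i]; tes <- g$tes[i]
      ex <- g$exons[[i]]
      # up5k: fixed-length axis upstream of the TSS
      off <- if (plus) r$pos - (tss - up) else (tss + up) - r$pos - 1L
      keep <- off >= 0L & off < up
      if (any(keep)) add("up5k", off[keep], up, r$level[keep])
      # down2k: fixed-length axis downstream of the TES
      off <- if (plus) r$pos - tes else tes - r$pos - 1L
      keep <- off >= 0L & off < down
      if (any(keep)) add("down2k", off[keep], down, r$level[keep])
      # exon axis: exonic bp concatenated 5'->3'
      widths <- ex[, 2] - ex[, 1]
      cum <- c(0L, cumsum(widths))
      E <- cum[length(cum)]
      if (E > 0L) {
        idx <- findInterval(r$pos, ex[, 1])
        inside <- idx > 0L & r$pos < ex[pmax(idx, 1L), 2]
        if (any(inside)) {
          v5 <- cum[idx[inside]] + (r$pos[inside] - ex[idx[inside], 1])
          virt <- if (plus) v5 else E - 1L - v5
          add("exon", virt, E, r$level[inside])
        }
      }
      # intron axis: non-exonic gene-body bp concatenated 5'->3'
      lo <- min(tss, tes); hi <- max(tss, tes)
      body <- IRanges::setdiff(IRanges::IRanges(start = lo + 1L, end = hi),
                               IRanges::IRanges(start = ex[, 1] + 1L,
                                                end = ex[, 2]))
      if (length(body) > 0L) {
        ist <- BiocGenerics::start(body) - 1L
        ien <- BiocGenerics::end(body)
        iw <- ien - ist
        icum <- c(0L, cumsum(iw))
        I <- icum[length(icum)]
        idx <- findInterval(r$pos, ist)
        inside <- idx > 0L & r$pos < ien[pmax(idx, 1L)]
        if (any(inside)) {
          v5 <- icum[idx[inside]] + (r$pos[inside] - ist[idx[inside]])
          virt <- if (plus) v5 else I - 1L - v5
          add("intron", virt, I, r$level[inside])
        }
      }
    }
  }
  do.call(rbind, lapply(regions, function(rg) {
    k <- nb[[rg]]
    data.frame(region_label = rg, bin_index = seq_len(k) - 1L, n_bins = k,
               mean_value = ifelse(ns[[rg]] > 0L, sums[[rg]] / ns[[rg]],
                                   NA_real_),
               n_observations = ns[[rg]], stringsAsFactors = FALSE)
  }))
}

#' Mean methylation and gene density in fixed windows
#'
#' @param records Filtered CpG records with levels.
#' @param genes Gene-model table (density = TSS count per window).
#' @param chrom_lengths Named chromosome lengths.
#' @param window Window size in bp (default 1 Mb).
#' @return Data frame `chrom`, `win`, `start`, `end`, `mean_level` (`NA` for
#'   windows without covered sites), `n_sites`, `gene_count`.
#' @export
window_methylation <- function(records, genes, chrom_lengths, window = 1e6) {
  if (!"level" %in% names(records)) records <- call_levels(records)
  records <- records[records$context == "CpG", , drop = FALSE]
  dens <- window_density(data.frame(chrom = genes$chrom, pos = genes$tss),
                         chrom_lengths, window)
  out <- lapply(names(chrom_lengths), function(ch) {
    d <- dens[dens$chrom == ch, , drop = FALSE]
    r <- records[records$chrom == ch, , drop = FALSE]
    n_win <- nrow(d)
    sums <- numeric(n_win); cnt <- integer(n_win)
    if (nrow(r) > 0L) {
      bi <- floor(r$pos / window) + 1L
      sums <- .bin_sum(r$level, bi, n_win)
      cnt <- tabulate(bi, nbins = n_win)
    }
    data.frame(chrom = ch, win = d$win, start = d$start, end = d$end,
               mean_level = ifelse(cnt > 0L, sums / cnt, NA_real_),
               n_sites = cnt, gene_count = d$count, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# per-window GC fraction and forward CG counts for a set of candidate spans
.span_stats <- function(gc_cum, cg_cum, start, end) {
  len <- end - start
  gc <- (gc_cum[end + 1L] - gc_cum[start + 1L]) / len
  obs <- cg_cum[end + 1L] - cg_cum[start + 1L]  # CG starts with C in span
  exp_cg <- len * (gc / 2)^2
  oe <- ifelse(exp_cg > 0, obs / exp_cg, 0)
  list(gc = gc, obs = obs, oe = oe)
}

#' Scan a genome for CpG islands
#'
#' CpG islands are regions longer than `min_len` bp with GC fraction above
#' `min_gc` and observed/expected CpG ratio above `min_oe`, where the
#' expected CpG count of a span of length L is `L * (gc/2)^2` and the
#' observed count is the number of forward-strand CG starts in the span.
#' The scanner slides a `min_len`-bp window in 1-bp steps, merges
#' overlapping or adjacent passing windows, re-tests each merged span, and
#' trims failing spans by one bp from both ends until they pass or shrink
#' to `min_len`.
#'
#' @param genome Named `DNAStringSet`.
#' @param min_len Minimum length, exclusive (default 200).
#' @param min_gc Minimum GC fraction, exclusive (default 0.5).
#' @param min_oe Minimum observed/expected ratio, exclusive (default 0.6).
#' @return Data frame `chrom`, `start`, `end`, `gc_fraction`,
#'   `obs_exp_ratio`; every emitted interval satisfies all three
#'   thresholds.
#' @export
cgi_scan <- function(genome, min_len = 200L, min_gc = 0.5, min_oe = 0.6) {
  out <- lapply(names(genome), function(ch) {
    s <- as.character(genome[[ch]])
    L <- nchar(s)
    if (L < min_len) return(NULL)
    base <- strsplit(s, "", fixed = TRUE)[[1L]]
    is_gc <- as.integer(base %in% c("G", "C"))
    gc_cum <- c(0L, cumsum(is_gc))
    is_cg_start <- as.integer(base[-L] == "C" & base[-1L] == "G")
    cg_cum <- c(0L, cumsum(c(is_cg_start, 0L)))
    starts <- 0:(L - min_len)
    st <- .span_stats(gc_cum, cg_cum, starts, starts + min_len)
    pass <- st$gc > min_gc & st$oe > min_oe
    if (!any(pass)) return(NULL)
    merged <- IRanges::reduce(IRanges::IRanges(start = starts[pass] + 1L,
                                               width = min_len))
    rows <- lapply(seq_along(merged), function(k) {
      a <- BiocGenerics::start(merged)[k] - 1L
      b <- BiocGenerics::end(merged)[k]
      repeat {
        stt <- .span_stats(gc_cum, cg_cum, a, b)
        ok <- (b - a) > min_len && stt$gc > min_gc && stt$oe > min_oe
        if (ok) {
          return(data.frame(chrom = ch, start = a, end = b,
                            gc_fraction = stt$gc, obs_exp_ratio = stt$oe,
                            stringsAsFactors = FALSE))
        }
        if ((b - a) <= min_len) return(NULL)
        a <- a + 1L; b <- b - 1L
      }
    })
    do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), gc_fraction = numeric(),
                      obs_exp_ratio = numeric(), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' CGI methylation by genomic feature
#'
#' Each CGI is assigned to the feature class containing its midpoint; its
#' methylation is the mean level of the covered CpG records inside it. CGIs
#' without covered CpGs count toward the class totals but contribute no
#' level.
#'
#' @param cgis CGI data frame ([cgi_scan()]).
#' @param features `feature_set`.
#' @param records Filtered CpG records with levels.
#' @return List: `counts` (named per-feature CGI counts) and `levels`
#'   (data frame `chrom`, `start`, `end`, `feature`, `mean_level`,
#'   `n_sites`).
#' @export
cgi_feature_methylation <- function(cgis, features, records) {
  if (!"level" %in% names(records)) records <- call_levels(records)
  records <- records[records$context == "CpG", , drop = FALSE]
  mid <- floor((cgis$start + cgis$end) / 2)
  feat <- assign_feature(features, cgis$chrom, mid)
  mean_level <- rep(NA_real_, nrow(cgis))
  n_sites <- integer(nrow(cgis))
  for (ch in unique(cgis$chrom)) {
    ci <- which(cgis$chrom == ch)
    r <- records[records$chrom == ch, , drop = FALSE]
    if (nrow(r) == 0L) next
    for (k in ci) {
      inside <- r$pos >= cgis$start[k] & r$pos < cgis$end[k]
      n_sites[k] <- sum(inside)
      if (n_sites[k] > 0L) mean_level[k] <- mean(r$level[inside])
    }
  }
  lv <- c("up5k", "exon", "intron", "down2k", "intergenic")
  counts <- table(factor(feat, levels = lv))
  list(counts = stats::setNames(as.integer(counts), lv),
       levels = data.frame(chrom = cgis$chrom, start = cgis$start,
                           end = cgis$end, feature = feat,
                           mean_level = mean_level, n_sites = n_sites,
                           stringsAsFactors = FALSE))
}
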