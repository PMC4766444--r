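#' Sites shared by two samples at sufficient depth
#'
#' Intersects the duplex-keyed CpG sites of two combined record sets,
#' keeping sites where both samples have `total >= min_depth`.
#'
#' @param records_a,records_b Combined CpG records ([combine_strands()]).
#' @param min_depth Minimum total reads in each sample (inclusive,
#'   default 5).
#' @return Data frame `chrom`, `pos`, `meth_a`, `total_a`, `meth_b`,
#'   `total_b`, `level_a`, `level_b`.
#' @export
shared_sites <- function(records_a, records_b, min_depth = 5L) {
  a <- filter_depth(records_a[records_a$context == "CpG", , drop = FALSE],
                    min_depth)
  b <- filter_depth(records_b[records_b$context == "CpG", , drop = FALSE],
                    min_depth)
  ka <- paste(a$chrom, a$pos, sep = ":")
  kb <- paste(b$chrom, b$pos, sep = ":")
  common <- intersect(ka, kb)
  if (length(common) == 0L) stop("no shared sites between samples")
  ia <- match(common, ka); ib <- match(common, kb)
  out <- data.frame(chrom = a$chrom[ia], pos = a$pos[ia],
                    meth_a = a$meth[ia], total_a = a$total[ia],
                    meth_b = b$meth[ib], total_b = b$total[ib],
                    stringsAsFactors = FALSE)
  out$level_a <- out$meth_a / out$total_a
  out$level_b <- out$meth_b / out$total_b
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# paired-contrast method-of-moments dispersion for one window of shared
# sites. The per-site difference d_j = p_aj - p_bj cancels the real
# methylation level of the site, which both samples share, leaving only
# read-sampling noise with variance
#   beta_j (1 - beta_j) [ (1 + (n_aj - 1) phi) / n_aj
#                       + (1 + (n_bj - 1) phi) / n_bj ].
# The scale of the contrasts is taken from successive differences of
# position-adjacent sites (the von Neumann estimator,
# mean(diff(d)^2) / 2): any locally constant shift between the conditions
# cancels in every pair except the one spanning a shift boundary, so a
# differential region does not masquerade as dispersion, while the second
# moment (unlike a robust scale) stays unbiased under the heavy-tailed
# contrasts a truly overdispersed null produces. Sites are assumed
# position-ordered. Returns NA when the window has < 3 sites or no level
# information.
.window_dispersion <- function(m_a, n_a, m_b, n_b) {
  k <- length(m_a)
  if (k < 3L) return(NA_real_)
  d <- m_a / n_a - m_b / n_b
  pbar <- (m_a + m_b) / (n_a + n_b)
  v <- pbar * (1 - pbar)
  den <- mean(v * ((n_a - 1) / n_a + (n_b - 1) / n_b))
  if (den <= 0) return(NA_real_)
  s2 <- mean(diff(d)^2) / 2
  (s2 - mean(v * (1 / n_a + 1 / n_b))) / den
}

#' Estimate local beta-binomial dispersion with shrinkage
#'
#' For every shared site, a covariance-adjusted method-of-moments
#' dispersion is computed from the paired counts of the sites within a
#' centered window and shrunk toward the genome-wide median of the window
#' estimates with a weight proportional to the prior strength over the
#' local observation count. The adjustment subtracts the between-sample
#' covariance of the window's level estimates, i.e. the site-to-site
#' methylation variation both samples share, so neither real methylation
#' structure nor a condition-wide level shift masquerades as read-level
#' dispersion. Isolated sites fall back to the genome-wide value.
#' Estimates are clamped to `[1e-6, 0.99]`.
#'
#' @param sites Paired sites from [shared_sites()] (at least 50).
#' @param window Window width in bp (default 500; sites within
#'   `window / 2` of the focal position are pooled).
#' @param prior_strength Pseudo-observations backing the genome-wide prior
#'   (default 10).
#' @return List of class `dispersion_model`: `phi` (per-site vector aligned
#'   with `sites`), `phi_global`, `window`, `prior_strength`.
#' @export
estimate_dispersion <- function(sites, window = 500L, prior_strength = 10) {
  if (nrow(sites) < 50L) stop("need at least 50 shared sites")
  half <- window / 2
  n_sites <- nrow(sites)
  phi_local <- rep(NA_real_, n_sites)
  k_local <- integer(n_sites)
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    pos <- sites$pos[idx]
    lo <- findInterval(pos - half, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + half, pos)
    for (j in seq_along(idx)) {
      nb <- idx[lo[j]:hi[j]]
      phi_local[idx[j]] <- .window_dispersion(sites$meth_a[nb], sites$total_a[nb],
                                              sites$meth_b[nb], sites$total_b[nb])
      k_local[idx[j]] <- length(nb) * 2L
    }
  }
  have <- !is.na(phi_local)
  if (!any(have)) stop("too few sites per window to estimate dispersion")
  target <- max(stats::median(pmax(phi_local[have], 0)), 0)
  phi <- ifelse(have,
                (k_local * pmax(phi_local, 0) + prior_strength * target) /
                  (k_local + prior_strength),
                target)
  phi <- pmin(pmax(phi, 1e-6), 0.99)
  structure(list(phi = phi, phi_global = target,
                 window = window, prior_strength = prior_strength),
            class = "dispersion_model")
}

#' Beta-binomial Wald test for a difference in methylation
#'
#' For counts (m, n) in each sample with dispersion phi, the level estimate
#' is `m / n` with variance `b(1-b)(1 + (n-1) phi) / n`, where `b(1-b)` is
#' floored at `1 / (n+1)^2` so boundary proportions keep a positive
#' variance. The statistic is the difference over the square root of the
#' summed variances; p is the two-sided standard-normal tail. With phi = 0
#' this is the classic two-proportion Wald test.
#'
#' @param m_a,n_a,m_b,n_b Methylated and total counts (vectorized).
#' @param phi Dispersion(s), recycled.
#' @return Data frame `delta` (level_a - level_b), `stat`, `p`.
#' @export
wald_test <- function(m_a, n_a, m_b, n_b, phi = 0) {
  if (any(n_a <= 0) || any(n_b <= 0)) stop("totals must be positive")
  ba <- m_a / n_a; bb <- m_b / n_b
  va <- pmax(ba * (1 - ba), 1 / (n_a + 1)^2) * (1 + (n_a - 1) * phi) / n_a
  vb <- pmax(bb * (1 - bb), 1 / (n_b + 1)^2) * (1 + (n_b - 1) * phi) / n_b
  stat <- (ba - bb) / sqrt(va + vb)
  data.frame(delta = ba - bb, stat = stat,
             p = 2 * stats::pnorm(-abs(stat)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, `q_(i) = min_{j >= i} p_(j) m / j` capped at 1,
#' mapped back to the input order.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially methylated cytosines
#'
#' Tests every shared site with the beta-binomial Wald test, adjusts all
#' p-values by Benjamini-Hochberg (the family is all shared sites, never a
#' delta-prefiltered subset), and calls a DMC where `|delta| > delta_min`
#' (strict) and `q < q_max`.
#'
#' @param sites Paired sites ([shared_sites()]).
#' @param dispersion `dispersion_model`, a numeric phi vector, or a scalar
#'   (default 0 = binomial).
#' @param delta_min Minimum absolute level difference, exclusive
#'   (default 0.20).
#' @param q_max FDR threshold, exclusive (default 0.01).
#' @return List: `tests` (all sites with `delta`, `stat`, `p`, `q`,
#'   `is_dmc`) and `dmcs` (called subset with `direction`
#'   `hyper_in_a`/`hypo_in_a`).
#' @export
call_dmcs <- function(sites, dispersion = 0, delta_min = 0.20, q_max = 0.01) {
  phi <- if (inherits(dispersion, "dispersion_model")) dispersion$phi
         else dispersion
  wt <- wald_test(sites$meth_a, sites$total_a, sites$meth_b, sites$total_b,
                  phi)
  tests <- cbind(sites, wt)
  tests$q <- bh_adjust(tests$p)
  tests$is_dmc <- abs(tests$delta) > delta_min & tests$q < q_max
  dmcs <- tests[tests$is_dmc, , drop = FALSE]
  dmcs$direction <- ifelse(dmcs$delta > 0, "hyper_in_a", "hypo_in_a")
  rownames(dmcs) <- NULL
  list(tests = tests, dmcs = dmcs)
}

#' Merge DMCs into differentially methylated regions
#'
#' Greedy scan per chromosome: consecutive same-direction DMCs with an
#' inter-site gap of at most `max_gap` bp merge into a run; runs with at
#' least `min_cpgs` members become DMRs. A direction flip splits the run.
#' The region end covers the last CG duplex (`last pos + 2`).
#'
#' @param dmcs DMC data frame (sorted by chrom, pos; as from
#'   [call_dmcs()]`$dmcs`).
#' @param max_gap Maximum gap between member DMCs in bp (default 300).
#' @param min_cpgs Minimum member DMCs (default 3).
#' @return Data frame `chrom`, `start`, `end`, `length`, `n_cpgs`,
#'   `direction`, `mean_level_a`, `mean_level_b`, `mean_delta`.
#' @export
merge_dmrs <- function(dmcs, max_gap = 300L, min_cpgs = 3L) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer(),
                      n_cpgs = integer(), direction = character(),
                      mean_level_a = numeric(), mean_level_b = numeric(),
                      mean_delta = numeric(), stringsAsFactors = FALSE)
  if (nrow(dmcs) == 0L) return(empty)
  dmcs <- dmcs[order(dmcs$chrom, dmcs$pos), , drop = FALSE]
  new_run <- c(TRUE, dmcs$chrom[-1L] != dmcs$chrom[-nrow(dmcs)] |
                 dmcs$direction[-1L] != dmcs$direction[-nrow(dmcs)] |
                 diff(dmcs$pos) > max_gap)
  run_id <- cumsum(new_run)
  rows <- lapply(split(seq_len(nrow(dmcs)), run_id), function(i) {
    if (length(i) < min_cpgs) return(NULL)
    d <- dmcs[i, , drop = FALSE]
    data.frame(chrom = d$chrom[1L], start = min(d$pos),
               end = max(d$pos) + 2L,
               length = max(d$pos) + 2L - min(d$pos),
               n_cpgs = nrow(d), direction = d$direction[1L],
               mean_level_a = mean(d$level_a),
               mean_level_b = mean(d$level_b),
               mean_delta = mean(d$delta), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) return(empty)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Feature annotation of DMCs or DMRs
#'
#' DMCs are assigned by position, DMRs by midpoint; the per-class fractions
#' sum to one.
#'
#' @param items Data frame with `chrom` and either `pos` (sites) or
#'   `start`/`end` (regions).
#' @param features `feature_set`.
#' @return List: `fractions` (named per-feature proportions) and `labels`
#'   (per-item feature).
#' @export
annotate_features <- function(items, features) {
  if (nrow(items) == 0L) stop("no items to annotate")
  pos <- if ("pos" %in% names(items)) items$pos
         else floor((items$start + items$end) / 2)
  lab <- assign_feature(features, items$chrom, pos)
  lv <- c("up5k", "exon", "intron", "down2k", "intergenic")
  frac <- table(factor(lab, levels = lv)) / length(lab)
  list(fractions = stats::setNames(as.numeric(frac), lv), labels = lab)
}
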