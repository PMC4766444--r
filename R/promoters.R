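#' Promoter CpG content around TSSs
#'
#' The CpG content of a promoter is 100 x (forward-strand CG starts in the
#' window from `upstream` bp before to `downstream` bp after the TSS) /
#' (window length in bp). Windows are clipped at chromosome ends; N bases
#' are excluded from the denominator. Genes whose window shrinks to zero bp
#' are skipped with a warning.
#'
#' @param genome Named `DNAStringSet`.
#' @param genes Gene-model table.
#' @param upstream,downstream Window half-sizes in bp (defaults 500/500,
#'   i.e. the 1-kb window around the TSS).
#' @return Data frame `gene_id`, `content` (percent).
#' @export
promoter_cpg_content <- function(genome, genes, upstream = 500L,
                                 downstream = 500L) {
  content <- rep(NA_real_, nrow(genes))
  for (ch in unique(genes$chrom)) {
    s <- as.character(genome[[ch]])
    L <- nchar(s)
    base <- strsplit(s, "", fixed = TRUE)[[1L]]
    not_n <- cumsum(c(0L, as.integer(base != "N")))
    cg <- c(0L, cumsum(c(as.integer(base[-L] == "C" & base[-1L] == "G"), 0L)))
    for (i in which(genes$chrom == ch)) {
      tss <- genes$tss[i]
      a <- max(0L, tss - upstream)
      b <- min(L, tss + downstream)
      len <- not_n[b + 1L] - not_n[a + 1L]   # non-N bp in window
      if (len == 0L) {
        warning("zero-length promoter window for ", genes$gene_id[i])
        next
      }
      content[i] <- 100 * (cg[b + 1L] - cg[a + 1L]) / len
    }
  }
  data.frame(gene_id = genes$gene_id, content = content,
             stringsAsFactors = FALSE)
}

#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Initialization places the component means at the 25th and 75th
#' percentiles with the pooled standard deviation and equal weights;
#' iteration stops when the log-likelihood improves by less than `tol` or
#' after `max_iter` iterations. A degenerate component (sd collapsing to 0)
#' triggers a restart from a perturbed initialization, up to 5 times.
#' Components are reported ordered by mean.
#'
#' @param values Numeric vector, at least 20 non-constant values.
#' @param seed Seed for restart perturbations (default 1).
#' @param max_iter,tol EM stopping rule (defaults 500 and 1e-8).
#' @return List of class `mixture_fit`: `weight`, `mean`, `sd` (length-2,
#'   ordered by mean), `log_likelihood`, `loglik_trace`, `n_iterations`,
#'   `converged`.
#' @export
fit_two_normal_mixture <- function(values, seed = 1L, max_iter = 500L,
                                   tol = 1e-8) {
  values <- values[!is.na(values)]
  if (length(values) < 20L) stop("need at least 20 values")
  if (stats::sd(values) == 0) stop("constant values: mixture undefined")
  rng <- .local_rng(seed)
  for (attempt in 0:5) {
    q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
    s0 <- stats::sd(values)
    if (attempt > 0) {         # perturbed restart
      q <- q + rng$rnorm(2L, 0, s0 / 4)
      s0 <- s0 * rng$runif(1L, 0.5, 1.5)
    }
    fit <- .em_two_normal(values, mu = sort(q), sd = c(s0, s0),
                          w = c(0.5, 0.5), max_iter = max_iter, tol = tol)
    if (!is.null(fit)) {
      ord <- order(fit$mean)
      fit$mean <- fit$mean[ord]; fit$sd <- fit$sd[ord]
      fit$weight <- fit$weight[ord]
      class(fit) <- "mixture_fit"
      return(fit)
    }
  }
  stop("mixture fit degenerate after 5 restarts")
}

.em_two_normal <- function(x, mu, sd, w, max_iter, tol) {
  n <- length(x)
  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sd[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sd[2])
    tot <- d1 + d2
    if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      return(list(weight = w, mean = mu, sd = sd, log_likelihood = ll,
                  loglik_trace = trace, n_iterations = it, converged = TRUE))
    }
    ll_old <- ll
    g1 <- d1 / tot
    n1 <- sum(g1); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) return(NULL)
    mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
    sd <- sqrt(c(sum(g1 * (x - mu[1])^2) / n1,
                 sum((1 - g1) * (x - mu[2])^2) / n2))
    if (any(sd < 1e-8) || any(!is.finite(sd))) return(NULL)
    w <- c(n1, n2) / n
  }
  list(weight = w, mean = mu, sd = sd, log_likelihood = ll_old,
       loglik_trace = trace, n_iterations = max_iter, converged = FALSE)
}

# private RNG stream that does not disturb the global .Random.seed
.local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  })
  draw <- function(fun, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fun(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
  list(rnorm = function(...) draw(stats::rnorm, ...),
       runif = function(...) draw(stats::runif, ...))
}

#' Crossover point of a two-component mixture
#'
#' The smallest x in `(mean_1, mean_2)` where the weighted component
#' densities are equal, found by bisection to `tol`. For equal weights and
#' equal sds this is the midpoint of the means.
#'
#' @param fit `mixture_fit` from [fit_two_normal_mixture()].
#' @param tol Bisection tolerance (default 1e-6).
#' @return Crossover value (same units as the fitted values).
#' @export
crossover <- function(fit, tol = 1e-6) {
  if (!fit$converged) stop("mixture fit did not converge")
  m1 <- fit$mean[1]; m2 <- fit$mean[2]
  if (!(m1 < m2)) stop("components must have distinct ordered means")
  f <- function(x) {
    fit$weight[1] * stats::dnorm(x, m1, fit$sd[1]) -
      fit$weight[2] * stats::dnorm(x, m2, fit$sd[2])
  }
  # locate the first sign change on a fine grid, then bisect
  grid <- seq(m1, m2, length.out = 1024L)
  fg <- f(grid)
  sgn <- which(fg[-length(fg)] > 0 & fg[-1L] <= 0)
  if (length(sgn) == 0L) {
    stop("no density crossover inside (mean_1, mean_2); ",
         "set a manual threshold")
  }
  lo <- grid[sgn[1L]]; hi <- grid[sgn[1L] + 1L]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Classify promoters as high- or low-CpG-content
#'
#' Content strictly above the threshold is HCP; content at or below it is
#' LCP (ties go to the low class).
#'
#' @param contents Data frame from [promoter_cpg_content()] (or a numeric
#'   vector of contents).
#' @param threshold Percent CpG content cutoff (e.g. the fitted crossover).
#' @return The input with a `class` column (`"HCP"`/`"LCP"`), or a character
#'   vector if a bare numeric was given.
#' @export
classify_promoters <- function(contents, threshold) {
  if (threshold <= 0) stop("threshold must be positive")
  if (is.numeric(contents)) {
    return(ifelse(contents > threshold, "HCP", "LCP"))
  }
  contents$class <- ifelse(contents$content > threshold, "HCP", "LCP")
  contents
}

#' Metagene profiles per promoter class
#'
#' @param records Filtered CpG records with levels.
#' @param genes Gene-model table.
#' @param labels Data frame `gene_id`, `class` ([classify_promoters()]).
#' @param ... Passed to [metagene_profile()].
#' @return Named list of metagene profiles, one per class present; an empty
#'   class yields a warning and no profile.
#' @export
class_metagene <- function(records, genes, labels, ...) {
  out <- list()
  for (cl in c("HCP", "LCP")) {
    ids <- labels$gene_id[labels$class == cl]
    g <- genes[genes$gene_id %in% ids, , drop = FALSE]
    if (nrow(g) == 0L) {
      warning("no genes in class ", cl)
      next
    }
    out[[cl]] <- metagene_profile(records, g, ...)
  }
  out
}
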