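test_that("shared sites intersect depth-passing CpG duplexes", {
  a <- combine_strands(toy_records("c1", c(10L, 20L, 30L),
                                   meth = c(3L, 2L, 4L), unmeth = c(2L, 2L, 4L)))
  b <- combine_strands(toy_records("c1", c(20L, 30L, 40L),
                                   meth = c(1L, 5L, 2L), unmeth = c(4L, 3L, 6L)))
  s <- shared_sites(a, b, min_depth = 5L)
  # site 10 is A-only; site 20 fails depth in A (total 4); sites kept: 30
  expect_identical(s$pos, 30L)
  expect_equal(s$level_a, 0.5)
  expect_lte(nrow(s), min(nrow(a), nrow(b)))
  # both exactly at depth 5 are included (inclusive threshold)
  a5 <- combine_strands(toy_records("c1", 50L, 3L, 2L))
  b5 <- combine_strands(toy_records("c1", 50L, 1L, 4L))
  expect_identical(nrow(shared_sites(a5, b5)), 1L)
  expect_error(shared_sites(a5, combine_strands(toy_records("c1", 60L, 3L, 3L))),
               "no shared sites")
})

test_that("the Wald statistic matches its closed form and reduces to two proportions", {
  w <- wald_test(5, 10, 5, 10, 0)
  expect_equal(w$stat, 0)
  expect_equal(w$p, 1)
  # boundary proportions with the variance floor
  w2 <- wald_test(50, 50, 0, 50, 0)
  v <- (1 / 51^2) / 50
  expect_equal(w2$stat, 1 / sqrt(2 * v))
  expect_equal(w2$p, 2 * pnorm(-abs(w2$stat)))
  expect_lt(w2$p, 1e-6)
  # phi = 0 equals the classic two-proportion Wald statistic
  w3 <- wald_test(12, 40, 30, 45, 0)
  p1 <- 12 / 40; p2 <- 30 / 45
  classic <- (p1 - p2) / sqrt(p1 * (1 - p1) / 40 + p2 * (1 - p2) / 45)
  expect_equal(w3$stat, classic)
  # dispersion widens the variance, shrinking the statistic
  expect_lt(abs(wald_test(12, 40, 30, 45, 0.2)$stat), abs(w3$stat))
  expect_error(wald_test(1, 0, 1, 5), "positive")
})

test_that("BH adjustment matches the literal step-up and p.adjust", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(41)
  p <- runif(200)^2
  q <- bh_adjust(p)
  expect_equal(q, naive_bh(p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DMC calling applies strict delta and FDR thresholds", {
  # a site at exactly delta = 0.20 is never a DMC
  sites <- data.frame(chrom = "c1", pos = c(10L, 20L),
                      meth_a = c(40L, 45L), total_a = c(50L, 50L),
                      meth_b = c(30L, 5L), total_b = c(50L, 50L))
  sites$level_a <- sites$meth_a / sites$total_a
  sites$level_b <- sites$meth_b / sites$total_b
  out <- call_dmcs(sites, 0)
  expect_equal(out$tests$delta[1], 0.20)
  expect_false(out$tests$is_dmc[1])
  expect_true(out$tests$is_dmc[2])
  expect_identical(out$dmcs$direction, "hyper_in_a")
})

test_that("swapping the samples is an exact symmetry", {
  set.seed(42)
  n <- 500
  sites <- data.frame(chrom = "c1", pos = sort(sample.int(1e5, n)),
                      meth_a = rbinom(n, 30, 0.7), total_a = 30L,
                      meth_b = rbinom(n, 30, 0.7), total_b = 30L)
  sites$level_a <- sites$meth_a / sites$total_a
  sites$level_b <- sites$meth_b / sites$total_b
  swapped <- sites
  names(swapped)[3:8] <- c("meth_b", "total_b", "meth_a", "total_a",
                           "level_b", "level_a")
  d1 <- call_dmcs(sites, 0.05)
  d2 <- call_dmcs(swapped, 0.05)
  expect_equal(d2$tests$delta, -d1$tests$delta)
  expect_equal(d2$tests$stat, -d1$tests$stat)
  expect_equal(d2$tests$p, d1$tests$p)
  expect_equal(d2$tests$q, d1$tests$q)
  expect_identical(d2$tests$is_dmc, d1$tests$is_dmc)
  if (nrow(d1$dmcs) > 0) {
    expect_identical(d2$dmcs$direction,
                     ifelse(d1$dmcs$direction == "hyper_in_a",
                            "hypo_in_a", "hyper_in_a"))
  }
})

test_that("dispersion estimation recovers truth and falls back when isolated", {
  mk_sites <- function(n, depth, beta, phi, seed) {
    set.seed(seed)
    pos <- sort(sample.int(n * 50L, n))
    draw <- function() {
      lv <- if (phi > 0) rbeta(n, beta * (1 / phi - 1), (1 - beta) * (1 / phi - 1)) else rep(beta, n)
      rbinom(n, depth, lv)
    }
    s <- data.frame(chrom = "c1", pos = pos,
                    meth_a = draw(), total_a = depth,
                    meth_b = draw(), total_b = depth)
    s$level_a <- s$meth_a / s$total_a
    s$level_b <- s$meth_b / s$total_b
    s
  }
  # pure binomial counts: the estimate collapses to the clamp floor
  d0 <- estimate_dispersion(mk_sites(2000, 30, 0.5, 0, 51))
  expect_lt(mean(d0$phi), 0.01)
  # phi = 0.1 recovered within 0.03 at 2000 sites x depth 30
  d1 <- estimate_dispersion(mk_sites(2000, 30, 0.5, 0.1, 52))
  expect_lt(abs(mean(d1$phi) - 0.1), 0.03)
  expect_lt(abs(d1$phi_global - 0.1), 0.03)
  # an isolated site takes the genome-wide value
  s <- mk_sites(100, 30, 0.5, 0.1, 53)
  s$pos[100] <- s$pos[99] + 100000L
  d2 <- estimate_dispersion(s)
  expect_equal(d2$phi[100], max(min(d2$phi_global, 0.99), 1e-6))
  expect_error(estimate_dispersion(s[1:10, ]), "at least 50")
})

test_that("a planted level shift does not masquerade as dispersion", {
  set.seed(54)
  n <- 2000; depth <- 30L
  pos <- sort(sample.int(60000, n))
  beta_a <- rep(0.8, n)
  beta_b <- ifelse(pos > 20000 & pos < 24000, 0.3, 0.8)  # planted block
  s <- data.frame(chrom = "c1", pos = pos,
                  meth_a = rbinom(n, depth, beta_a), total_a = depth,
                  meth_b = rbinom(n, depth, beta_b), total_b = depth)
  s$level_a <- s$meth_a / s$total_a
  s$level_b <- s$meth_b / s$total_b
  d <- estimate_dispersion(s)
  inside <- s$pos > 20500 & s$pos < 23500
  expect_lt(mean(d$phi[inside]), 0.02)
})

test_that("DMR merging respects gaps, direction and the member minimum", {
  dmc <- function(pos, dir) {
    data.frame(chrom = "c1", pos = pos, level_a = 0.8, level_b = 0.3,
               delta = ifelse(dir == "hyper_in_a", 0.5, -0.5),
               direction = dir, stringsAsFactors = FALSE)
  }
  d <- dmc(c(100L, 200L, 300L), "hyper_in_a")
  r <- merge_dmrs(d)
  expect_identical(nrow(r), 1L)
  expect_identical(r$n_cpgs, 3L)
  expect_identical(r$start, 100L)
  expect_identical(r$end, 302L)  # covers the last CG duplex
  expect_identical(r$length, 202L)
  # a gap beyond max_gap splits the run
  d2 <- dmc(c(100L, 200L, 600L, 700L, 800L), "hyper_in_a")
  expect_identical(nrow(merge_dmrs(d2, max_gap = 300L, min_cpgs = 3L)), 1L)
  # direction flip splits the run
  d3 <- rbind(dmc(c(100L, 200L, 300L), "hyper_in_a"),
              dmc(c(400L, 500L, 600L), "hypo_in_a"))
  r3 <- merge_dmrs(d3)
  expect_identical(nrow(r3), 2L)
  expect_identical(r3$direction, c("hyper_in_a", "hypo_in_a"))
  # two DMCs never reach the three-member minimum
  expect_identical(nrow(merge_dmrs(dmc(c(100L, 150L), "hyper_in_a"))), 0L)
  # every member of a DMR is a DMC and no DMC is in two DMRs
  expect_identical(sum(r3$n_cpgs), nrow(d3))
})

test_that("feature annotation fractions partition the items", {
  g <- toy_gene(start = 1000L, end = 2000L)
  fs <- build_feature_set(g, c(c1 = 10000L))
  items <- data.frame(chrom = "c1", pos = c(1500L, 5000L, 9000L))
  ann <- annotate_features(items, fs)
  expect_equal(sum(ann$fractions), 1)
  expect_equal(ann$fractions[["exon"]], 1 / 3)
  expect_equal(ann$fractions[["intergenic"]], 2 / 3)
  # regions annotate by midpoint
  reg <- data.frame(chrom = "c1", start = 1400L, end = 1600L)
  expect_identical(annotate_features(reg, fs)$labels, "exon")
  expect_error(annotate_features(data.frame(chrom = "cX", pos = 1L), fs),
               "unknown chromosome")
})
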