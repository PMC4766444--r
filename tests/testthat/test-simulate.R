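# a small configuration keeps the generator tests quick
small_cfg <- function(seed = 5L, ...) {
  args <- list(seed = seed, n_chroms = 1L, chrom_length = 150000L,
               gene_count = 10L, n_cgi = 8L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("the generators are deterministic under a fixed seed", {
  cfg <- small_cfg()
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$truth, s2$truth)
  m1 <- simulate_methylome(s1, cfg)
  m2 <- simulate_methylome(s2, cfg)
  expect_identical(m1, m2)
  expect_identical(simulate_counts(m1, cfg, 2), simulate_counts(m2, cfg, 2))
  # a different seed changes the genome
  s3 <- simulate_genome(small_cfg(seed = 6L))
  expect_false(identical(as.character(s1$genome), as.character(s3$genome)))
})

test_that("simulated genomes validate and honour the configured structure", {
  cfg <- small_cfg()
  sim <- simulate_genome(cfg)
  expect_identical(unname(genome_lengths(sim$genome)), cfg$chrom_length)
  expect_true(all(Biostrings::letterFrequency(sim$genome, "ACGT")[, 1] ==
                    Biostrings::width(sim$genome)))
  expect_identical(nrow(sim$genes), 10L)
  # gene models pass their own validator (constructed through it)
  expect_s3_class(sim$genes, "gene_models")
  # zero genes -> pure background, no annotation
  cfg0 <- small_cfg(gene_count = 0L, n_cgi = 0L)
  sim0 <- simulate_genome(cfg0)
  expect_identical(nrow(sim0$genes), 0L)
})

test_that("planted promoter contents are recovered from the sequence", {
  cfg <- small_cfg()
  sim <- simulate_genome(cfg)
  pc <- promoter_cpg_content(sim$genome, sim$genes)
  truth <- sim$truth$promoters[match(pc$gene_id, sim$truth$promoters$gene_id), ]
  expect_lt(max(abs(pc$content - truth$content)), 0.2)
})

test_that("planted CpG islands qualify when re-measured", {
  cfg <- small_cfg()
  sim <- simulate_genome(cfg)
  s <- as.character(sim$genome[[1]])
  cg <- sim$truth$cgis
  for (i in seq_len(nrow(cg))) {
    span <- substr(s, cg$start[i] + 1L, cg$end[i])
    b <- strsplit(span, "", fixed = TRUE)[[1]]
    gc <- mean(b %in% c("G", "C"))
    obs <- sum(b[-length(b)] == "C" & b[-1] == "G")
    expect_gt(gc, 0.5)
    expect_gt(obs / (nchar(span) * (gc / 2)^2), 0.6)
  }
})

test_that("the methylome is bimodal with a TSS dip and low non-CpG levels", {
  cfg <- small_cfg()
  sim <- simulate_genome(cfg)
  meth <- simulate_methylome(sim, cfg)
  lv <- meth$cpg$true_level
  h <- hist(lv, breaks = seq(0, 1, 0.1), plot = FALSE)$counts
  # modes in [0, 0.1] and (0.7, 1.0]
  expect_gt(sum(h[1]), 0.03 * length(lv))
  expect_gt(sum(h[8:10]), 0.5 * length(lv))
  expect_lt(sum(h[4:6]), sum(h[8:10]))
  expect_true(all(meth$noncpg$true_level == cfg$noncpg_level))
  # mean level near HCP TSSs is far below the distal mean
  hcp <- sim$truth$promoters[sim$truth$promoters$hcp, ]
  near <- rep(FALSE, nrow(meth$cpg))
  for (t in hcp$tss) near <- near | abs(meth$cpg$pos - t) < 500
  expect_lt(mean(lv[near]), 0.3)
  expect_gt(mean(lv[!near]), 0.6)
  # coupling 0 and dip 0 produce an i.i.d. high-mode field
  cfg_flat <- small_cfg(density_coupling = 0, dip_hcp = 0, dip_lcp = 0,
                        level_concentration = Inf)
  m_flat <- simulate_methylome(simulate_genome(cfg_flat), cfg_flat)
  expect_true(all(abs(m_flat$cpg$true_level - cfg_flat$high_mean) < 1e-6))
})

test_that("counts converge to the true level and carry the conversion bias", {
  grid <- seq(100L, by = 60L, length.out = 1500L)
  methylome <- list(
    cpg = data.frame(chrom = "c1", pos = grid, mu = 0.7, true_level = 0.7),
    noncpg = data.frame(chrom = "c1", pos = grid + 20L, strand = "+",
                        context = "CHH", true_level = 0))
  f <- 0.02
  cfg <- sim_config(seed = 9, coverage_mean = 200, conversion_failure = f)
  rec <- simulate_counts(methylome, cfg, 1)[[1]]
  called <- call_levels(filter_depth(combine_strands(rec)))
  cpg <- called[called$context == "CpG", ]
  expected <- 0.7 + 0.3 * f
  expect_lt(abs(mean(cpg$level) - expected), 0.005)
  # at f = 0 the observed level converges to beta
  cfg0 <- sim_config(seed = 9, coverage_mean = 200, conversion_failure = 0)
  rec0 <- simulate_counts(methylome, cfg0, 1)[[1]]
  cpg0 <- call_levels(filter_depth(combine_strands(rec0)))
  expect_lt(abs(mean(cpg0$level[cpg0$context == "CpG"]) - 0.7), 0.005)
  # conversion rate recovers 1 - f from the non-CpG records
  cr <- conversion_rate(rec)
  expect_lt(abs(cr$rate - (1 - f)), 3 * sqrt(f * (1 - f) / cr$total_nonCpG))
})

test_that("replicate correlation rises with coverage", {
  cfg_lo <- small_cfg(coverage_mean = 5)
  sim <- simulate_genome(cfg_lo)
  meth <- simulate_methylome(sim, cfg_lo)
  r_of <- function(cfg) {
    reps <- simulate_counts(meth, cfg, 2)
    called <- lapply(reps, function(r) {
      x <- call_levels(filter_depth(combine_strands(r)))
      x[x$context == "CpG", ]
    })
    replicate_correlation(called[[1]], called[[2]])$r
  }
  expect_gt(r_of(small_cfg(coverage_mean = 50)), r_of(cfg_lo))
})

test_that("two-condition truth regions are disjoint and planted as stated", {
  cfg <- small_cfg(diff_n_regions = 10L)
  two <- simulate_two_conditions(cfg)
  tr <- two$truth_regions
  expect_gt(nrow(tr), 0L)
  o <- order(tr$chrom, tr$start)
  same <- tr$chrom[o][-1] == tr$chrom[o][-nrow(tr)]
  expect_true(all(!same | tr$start[o][-1] >= tr$end[o][-nrow(tr)]))
  # inside the regions condition B shifts by delta (up to clamping)
  a <- two$methylome_a$cpg; b <- two$methylome_b$cpg
  for (i in seq_len(nrow(tr))) {
    j <- a$chrom == tr$chrom[i] & a$pos >= tr$start[i] & a$pos < tr$end[i]
    expect_true(all(abs(b$true_level[j] -
                          pmin(pmax(a$true_level[j] + cfg$diff_delta, 0.01), 0.99))
                    < 1e-12))
  }
  # outside they are identical
  out <- rep(TRUE, nrow(a))
  for (i in seq_len(nrow(tr))) {
    out <- out & !(a$chrom == tr$chrom[i] & a$pos >= tr$start[i] & a$pos < tr$end[i])
  }
  expect_identical(a$true_level[out], b$true_level[out])
  expect_warning(simulate_two_conditions(small_cfg(diff_delta = 0)),
                 "undetectable")
})
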