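test_that("cut sites fall one bp into each CCGG motif", {
  expect_identical(find_cut_sites("AACCGGTTTTCCGGAA"), c(3L, 11L))
  expect_identical(find_cut_sites("AAAA"), integer(0))
  expect_identical(find_cut_sites("CCGGCCGG"), c(1L, 5L))
})

test_that("digestion partitions each N-free block and flags terminal pieces", {
  fr <- digest("AACCGGTTTTCCGGAA", "c1")
  expect_identical(fr$start, c(0L, 3L, 11L))
  expect_identical(fr$end, c(3L, 11L, 16L))
  expect_identical(fr$terminal, c(TRUE, FALSE, TRUE))
  # the internal fragment reads CGG...C, so it carries a CpG at offset 0
  expect_identical(count_cpgs_two_strand("CGGTTTTC"), 2L)

  # 0 or 1 cut -> no internal fragments
  expect_true(all(digest("AACCGGTT")$terminal))
  expect_true(all(digest("AATTAATT")$terminal))

  # N runs split the sequence into independently digested blocks
  s <- "CCGGAANNAACCGGTTCCGGAA"
  fr <- digest(s, "c1")
  expect_true(all(fr$start >= 0 & fr$end <= nchar(s)))
  expect_identical(fr[!fr$terminal, ]$start, 11L)  # only block 2 has two cuts
  expect_identical(fr[!fr$terminal, ]$end, 17L)
  # digestion reconstructs each block exactly: no overlap, no gap inside blocks
  expect_identical(sum(fr$length), nchar(s) - 2L)  # minus the NN run
})

test_that("fragment boundaries match a naive scan on random sequences", {
  set.seed(42)
  for (i in 1:25) {
    s <- random_seq(3000)
    if (i %% 5 == 0) {  # plant an N run
      substr(s, 1200, 1210) <- strrep("N", 11)
    }
    expect_identical(digest(s, "c1"), naive_digest(s, "c1"),
                     info = paste("sequence", i))
  }
})

test_that("internal fragments always start with CGG, end with C, and hold a CpG", {
  set.seed(7)
  for (i in 1:10) {
    s <- random_seq(5000)
    fr <- digest(s, "c1")
    int <- fr[!fr$terminal, , drop = FALSE]
    for (j in seq_len(nrow(int))) {
      frag <- substr(s, int$start[j] + 1L, int$end[j])
      expect_identical(substr(frag, 1, 3), "CGG")
      expect_identical(substr(frag, nchar(frag), nchar(frag)), "C")
      expect_gte(count_cpgs_two_strand(frag), 2L)
    }
  }
})

test_that("size selection keeps inclusive bounds and drops terminal pieces", {
  fr <- data.frame(chrom = "c1", start = c(0, 100, 300, 500, 800, 1100),
                   end = c(100, 174, 410, 650, 1020, 1321),
                   length = c(100, 74, 110, 150, 220, 221),
                   terminal = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  rr <- size_select(fr, 110, 220)
  expect_identical(rr$fragments$length, c(110, 150, 220))
  expect_identical(rr$n_fragments, 3L)
  expect_error(size_select(fr, 220, 110), "min_len")
  # empty selection yields zero totals
  expect_identical(size_select(fr, 5000, 6000)$total_length_bp, 0)
})

test_that("widening the size window never shrinks the RR genome", {
  set.seed(11)
  s <- random_seq(20000)
  fr <- digest(s, "c1")
  prev <- size_select(fr, 110, 220)
  for (w in list(c(100, 250), c(80, 300), c(40, 400))) {
    cur <- size_select(fr, w[1], w[2])
    expect_gte(cur$n_fragments, prev$n_fragments)
    expect_gte(cur$total_length_bp, prev$total_length_bp)
    prev <- cur
  }
})

test_that("two-strand CpG counting doubles forward CG starts within bounds", {
  expect_identical(count_cpgs_two_strand("ACGT"), 2L)
  expect_identical(count_cpgs_two_strand("AATT"), 0L)
  # C inside, G outside the interval end: still counted
  expect_identical(count_cpgs_two_strand("ACG", 0L, 2L), 2L)
  expect_identical(count_cpgs_two_strand("ACG", 0L, 1L), 0L)
  expect_error(count_cpgs_two_strand("ACG", 0L, 9L), "bounds")
  set.seed(5)
  for (i in 1:10) {
    s <- random_seq(800)
    expect_identical(count_cpgs_two_strand(s), 2L * naive_cg_count(s))
  }
})

test_that("feature partition tiles the genome with the stated precedence", {
  g <- toy_gene(start = 1000L, end = 2000L)
  fs <- build_feature_set(g, c(c1 = 10000L))
  expect_identical(fs$feature, c("up5k", "exon", "down2k", "intergenic"))
  expect_identical(fs$start, c(0L, 1000L, 2000L, 4000L))
  expect_identical(fs$end, c(1000L, 2000L, 4000L, 10000L))
  # minus strand: up5k sits right of the gene span
  gm <- toy_gene(strand = "-", start = 1000L, end = 2000L)
  fsm <- build_feature_set(gm, c(c1 = 10000L))
  up <- fsm[fsm$feature == "up5k", ]
  expect_identical(c(up$start, up$end), c(2000L, 7000L))
  # exon wins over a neighbouring gene's flank
  g2 <- gene_model_table(
    gene_id = c("a", "b"), chrom = "c1", strand = "+",
    tss = c(1000L, 2500L), tes = c(2000L, 3500L),
    exons = list(cbind(start = 1000L, end = 2000L),
                 cbind(start = 2500L, end = 3500L)))
  fs2 <- build_feature_set(g2, c(c1 = 10000L))
  expect_identical(assign_feature(fs2, "c1", 1500L), "exon")
  expect_identical(assign_feature(fs2, "c1", 2250L), "up5k")  # b's flank
  expect_error(build_feature_set(toy_gene(end = 20000L,
                                          exons = cbind(start = 1000L, end = 20000L)),
                                 c(c1 = 10000L)),
               "chromosome bounds")
})

test_that("summaries recompute densities and conserve feature CpG counts", {
  genome <- toy_genome(c1 = paste0(strrep("AT", 500),
                                   "CCGG", strrep("ACGT", 40), "CCGG",
                                   strrep("TA", 500)))
  g <- toy_gene(start = 1000L, end = 1100L,
                exons = cbind(start = 1000L, end = 1100L))
  fs <- build_feature_set(g, genome_lengths(genome))
  fr <- digest_genome(genome)
  gsum <- summarize_digest(fr, genome, fs)
  expect_identical(sum(gsum$feature_cpgs), gsum$total_cpgs)
  expect_equal(gsum$segments_per_mb,
               gsum$segment_count / gsum$genome_size_mb)
  rr <- size_select(fr, 1, 10000)
  rsum <- summarize_rr(rr, genome, fs)
  expect_identical(sum(rsum$feature_cpgs), rsum$total_cpgs)
  # selecting everything internal keeps every internal-fragment CpG
  expect_lte(rsum$total_cpgs, gsum$total_cpgs)
  expect_error(genome_summary(10, 0, 5), "size")
})

test_that("enrichment folds and capture fractions behave on identity", {
  s <- genome_summary(100, 2, 4000, c(up5k = 1000, exon = 3000))
  f <- enrichment_folds(s, s)
  expect_equal(f$segment_fold, 1.0)
  expect_equal(f$cpg_fold, 1.0)
  cap <- capture_fractions(s, s)
  expect_equal(unname(cap[c("up5k", "exon", "overall")]), c(100, 100, 100))
  z <- genome_summary(100, 2, 4000, c(up5k = 0, exon = 4000))
  expect_true(is.na(capture_fractions(z, z)[["up5k"]]))
})

test_that("window densities keep partial windows and conserve totals", {
  pos <- data.frame(chrom = "c1", pos = c(0, 5e5, 999999, 1.2e6, 2.4e6))
  wd <- window_density(pos, c(c1 = 2.5e6), window = 1e6)
  expect_identical(nrow(wd), 3L)
  expect_identical(wd$count, c(3L, 1L, 1L))
  expect_identical(wd$end[3], 2.5e6)
  expect_identical(sum(wd$count), nrow(pos))
})

test_that("track correlation matches the direct formula and rejects constants", {
  set.seed(9)
  a <- rnorm(50); b <- rnorm(50)
  tc <- track_correlation(a, b)
  r_direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(tc$r, r_direct, tolerance = 1e-12)
  expect_equal(track_correlation(a, a)$r, 1.0)
  expect_equal(track_correlation(a, -a)$r, -1.0)
  expect_error(track_correlation(rep(1, 10), rnorm(10)), "variance")
})

test_that("read capture covers fragment ends and region coverage integrates", {
  fr <- data.frame(chrom = "c1", start = c(0L, 1000L), end = c(150L, 1300L),
                   length = c(150L, 300L), terminal = FALSE)
  cov100 <- simulate_read_capture(fr, read_len = 100)
  # 150-bp fragment fully covered by PE100
  expect_true(any(cov100$start == 0 & cov100$end == 150))
  cov50 <- simulate_read_capture(fr, read_len = 50)
  # 300-bp fragment with PE50: middle 200 bp uncovered
  mid <- cov50[cov50$start >= 1000 & cov50$end <= 1300, ]
  expect_identical(nrow(mid), 2L)
  expect_identical(mid$end[1] - mid$start[1], 50L)
  expect_error(simulate_read_capture(fr, read_len = 0), "read_len")

  rc <- region_coverage(cov50, data.frame(chrom = "c1",
                                          start = c(1050L, 5000L),
                                          end = c(1250L, 5100L)))
  expect_equal(rc$fraction_bp, 0)  # middle of the long fragment + far region
  rc2 <- region_coverage(cov100, data.frame(chrom = "c1", start = 0L, end = 150L))
  expect_equal(rc2$fraction_bp, 1)
  expect_equal(rc2$fraction_regions_hit, 1)
})
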