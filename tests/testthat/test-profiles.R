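test_that("TSS profile bins strand-aware offsets and averages levels", {
  g <- toy_gene(start = 10000L, end = 12000L,
                exons = cbind(start = 10000L, end = 12000L))
  rec <- call_levels(combine_strands(
    toy_records("c1", c(10024L, 9976L, 5200L), meth = c(8L, 2L, 5L),
                unmeth = c(2L, 8L, 5L))))
  tp <- tss_profile(rec, g, flank = 5000L, bin = 50L)
  expect_identical(nrow(tp), 200L)
  # offset +24 -> bin 100
  expect_equal(tp$mean_value[tp$bin_index == 100], 0.8)
  # offset -24 -> bin 99
  expect_equal(tp$mean_value[tp$bin_index == 99], 0.2)
  # position at TSS - 4800 -> bin 4
  expect_equal(tp$mean_value[tp$bin_index == 4], 0.5)
  expect_identical(sum(tp$n_observations), 3L)
  # minus strand flips the offsets
  gm <- toy_gene(strand = "-", start = 8000L, end = 10000L)
  tpm <- tss_profile(rec, gm, flank = 5000L, bin = 50L)
  expect_equal(tpm$mean_value[tpm$bin_index == 100], 0.2)  # 9976 -> +24
  expect_error(tss_profile(rec, g, flank = 5001L), "multiple")
  # a constant field stays constant in every occupied bin
  set.seed(1)
  pos <- sort(sample(seq(5000L, 15000L, 2L), 400))
  flat <- call_levels(combine_strands(toy_records("c1", pos, 5L, 5L)))
  tpf <- tss_profile(flat, g)
  expect_true(all(abs(tpf$mean_value[tpf$n_observations > 0] - 0.5) < 1e-12))
})

test_that("TSS CpG-content profile measures CG starts per bin span", {
  # 10 kb of AT with one CG planted every 10 bp in [9975, 10025)
  base <- rep(c("A", "T"), 10000)
  for (p in seq(9975L, 10020L, 10L)) base[c(p + 1L, p + 2L)] <- c("C", "G")
  g <- toy_genome(c1 = paste(base, collapse = ""))
  gene <- toy_gene(chrom = "c1", start = 10000L, end = 12000L,
                   exons = cbind(start = 10000L, end = 12000L))
  tc <- tss_profile(g, gene, value = "cpg_content")
  # bins 99 and 100 hold the planted CGs: 100 * count / 50
  expect_equal(tc$mean_value[tc$bin_index == 99], 100 * 3 / 50)
  expect_equal(tc$mean_value[tc$bin_index == 100], 100 * 2 / 50)
  expect_equal(tc$mean_value[tc$bin_index == 0], 0)
})

test_that("metagene profile integrates exon and intron axes strand-aware", {
  # one gene: exons [1000,1400) and [1600,2000), intron [1400,1600)
  g <- gene_model_table("g1", "c1", "+", 1000L, 2000L,
                        list(cbind(start = c(1000L, 1600L),
                                   end = c(1400L, 2000L))))
  # uniform 0.5 everywhere -> all occupied exon bins 0.5
  set.seed(2)
  pos <- seq(980L, 2020L, 2L)
  rec <- call_levels(combine_strands(toy_records("c1", pos, 5L, 5L)))
  mg <- metagene_profile(rec, g)
  ex <- mg[mg$region_label == "exon", ]
  expect_true(all(abs(ex$mean_value[ex$n_observations > 0] - 0.5) < 1e-12))
  # conservation: exonic observations equal exonic records
  n_exonic <- sum((pos >= 1000 & pos < 1400) | (pos >= 1600 & pos < 2000))
  expect_identical(sum(ex$n_observations), n_exonic)
  n_intronic <- sum(pos >= 1400 & pos < 1600)
  expect_identical(sum(mg$n_observations[mg$region_label == "intron"]),
                   n_intronic)

  # virtual position arithmetic: exonic CpG at virtual 399/800 of an
  # 800-bp exon axis lands in bin floor(399 * 40 / 800) = 19
  one <- call_levels(combine_strands(toy_records("c1", 1399L, 9L, 1L)))
  mg1 <- metagene_profile(one, g)
  ex1 <- mg1[mg1$region_label == "exon", ]
  expect_identical(ex1$n_observations[ex1$bin_index == 19], 1L)
  # on the minus strand the same genomic position maps to the mirrored bin
  gm <- gene_model_table("g1", "c1", "-", 2000L, 1000L,
                         list(cbind(start = c(1000L, 1600L),
                                    end = c(1400L, 2000L))))
  mgm <- metagene_profile(one, gm)
  exm <- mgm[mgm$region_label == "exon", ]
  expect_identical(exm$n_observations[exm$bin_index == 40 - 1 - 19], 1L)
  # a single-exon gene contributes nothing to intron bins
  g0 <- toy_gene()
  mg0 <- metagene_profile(rec, g0)
  expect_identical(sum(mg0$n_observations[mg0$region_label == "intron"]), 0L)
})

test_that("windowed methylation averages sites and counts TSS per window", {
  g <- gene_model_table(c("a", "b"), "c1", "+", c(100L, 1500L),
                        c(600L, 1900L),
                        exons = list(cbind(start = 100L, end = 600L),
                                     cbind(start = 1500L, end = 1900L)))
  rec <- call_levels(combine_strands(
    toy_records("c1", c(10L, 20L, 1200L), meth = c(2L, 4L, 5L),
                unmeth = c(8L, 6L, 5L))))
  wm <- window_methylation(rec, g, c(c1 = 2500L), window = 1000L)
  expect_identical(nrow(wm), 3L)
  expect_equal(wm$mean_level[1], 0.3)   # (0.2 + 0.4) / 2
  expect_equal(wm$mean_level[2], 0.5)
  expect_true(is.na(wm$mean_level[3]))
  expect_identical(wm$gene_count, c(1L, 1L, 0L))
})

test_that("the CGI scanner finds closed-form islands and audits its thresholds", {
  s <- paste0(strrep("AT", 200), strrep("CG", 150), strrep("TA", 200))
  cg <- cgi_scan(toy_genome(c1 = s))
  expect_identical(nrow(cg), 1L)
  # the 300-bp CG repeat: gc 1.0, obs/exp 2.0 at its core
  expect_gt(cg$gc_fraction, 0.5)
  expect_gt(cg$obs_exp_ratio, 0.6)
  expect_gt(cg$end - cg$start, 200)
  expect_true(cg$start <= 400 && cg$end >= 700)
  expect_identical(nrow(cgi_scan(toy_genome(c1 = strrep("AT", 300)))), 0L)
  # short chromosome -> empty result
  expect_identical(nrow(cgi_scan(toy_genome(c1 = "ACGT"))), 0L)
})

test_that("scanner output matches the brute-force enumeration on planted blocks", {
  set.seed(13)
  for (i in 1:8) {
    block <- paste(sample(c("C", "G", "CG", "A", "T"), 180, replace = TRUE,
                          prob = c(0.25, 0.25, 0.3, 0.1, 0.1)), collapse = "")
    s <- paste0(random_seq(600), block, random_seq(600))
    got <- cgi_scan(toy_genome(c1 = s))
    want <- naive_cgi(s)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(got$start, want$start, info = paste("seq", i))
      expect_identical(got$end, want$end, info = paste("seq", i))
      expect_equal(got$gc_fraction, want$gc, tolerance = 1e-12)
      expect_equal(got$obs_exp_ratio, want$oe, tolerance = 1e-12)
    }
  }
})

test_that("CGI feature methylation assigns by midpoint and partitions counts", {
  g <- toy_gene(start = 1000L, end = 2000L)
  fs <- build_feature_set(g, c(c1 = 10000L))
  cgis <- data.frame(chrom = "c1", start = c(1100L, 5000L),
                     end = c(1500L, 5400L))
  rec <- call_levels(combine_strands(
    toy_records("c1", c(1200L, 1210L, 5100L), meth = c(1L, 1L, 9L),
                unmeth = c(9L, 9L, 1L))))
  cfm <- cgi_feature_methylation(cgis, fs, rec)
  expect_identical(sum(cfm$counts), 2L)
  expect_identical(cfm$counts[["exon"]], 1L)
  expect_identical(cfm$counts[["intergenic"]], 1L)
  expect_equal(cfm$levels$mean_level[1], 0.1)
  expect_equal(cfm$levels$mean_level[2], 0.9)
  # a CGI without covered CpGs keeps its count but contributes no level
  cgis2 <- rbind(cgis, data.frame(chrom = "c1", start = 8000L, end = 8300L))
  cfm2 <- cgi_feature_methylation(cgis2, fs, rec)
  expect_identical(sum(cfm2$counts), 3L)
  expect_true(is.na(cfm2$levels$mean_level[3]))
})
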