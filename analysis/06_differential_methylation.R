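#!/usr/bin/env Rscript
# Stage 6: two-condition differential methylation: planted-region study,
# beta-binomial Wald tests with windowed dispersion, BH correction, DMC
# thresholds (|delta| > 0.20, q < 0.01), DMR merging and feature annotation.

suppressPackageStartupMessages(library(rrbsim))

out <- "results/diff"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 20160225L, coverage_mean = 30)
two <- simulate_two_conditions(cfg)
write_coverage(two$counts_a, file.path(out, "condition_a.cov.tsv"))
write_coverage(two$counts_b, file.path(out, "condition_b.cov.tsv"))
write_bed(two$truth_regions, file.path(out, "truth_regions.bed"))

sites <- shared_sites(combine_strands(two$counts_a),
                      combine_strands(two$counts_b), min_depth = 5L)
cat(sprintf("Shared CpG sites at depth >= 5 in both conditions: %d.\n",
            nrow(sites)))
cat(sprintf("Mean level: condition A %.3f, condition B %.3f.\n",
            mean(sites$level_a), mean(sites$level_b)))

disp <- estimate_dispersion(sites)
cat(sprintf("Dispersion: genome-wide %.4f, per-site mean %.4f.\n",
            disp$phi_global, mean(disp$phi)))

dm <- call_dmcs(sites, disp, delta_min = 0.20, q_max = 0.01)
dmrs <- merge_dmrs(dm$dmcs, max_gap = 300L, min_cpgs = 3L)
n_hyper <- sum(dm$dmcs$direction == "hyper_in_a")
cat(sprintf("DMCs: %d of %d sites (%d hyper in A, %d hypo in A).\n",
            nrow(dm$dmcs), nrow(sites), n_hyper, nrow(dm$dmcs) - n_hyper))
cat(sprintf("DMRs: %d; mean length %.0f bp; mean CpGs per DMR %.1f.\n",
            nrow(dmrs), mean(dmrs$length), mean(dmrs$n_cpgs)))

tr <- two$truth_regions
recovered <- vapply(seq_len(nrow(tr)), function(i) {
  any(dm$dmcs$chrom == tr$chrom[i] & dm$dmcs$pos >= tr$start[i] &
        dm$dmcs$pos < tr$end[i])
}, TRUE)
cat(sprintf("Planted regions recovered by >= 1 DMC: %d / %d (%.0f%%).\n",
            sum(recovered), nrow(tr), 100 * mean(recovered)))

genes_flat <- read_tsv("results/study/genes.tsv")
genes <- gene_model_table(
  gene_id = genes_flat$gene_id, chrom = genes_flat$chrom,
  strand = genes_flat$strand, tss = genes_flat$tss, tes = genes_flat$tes,
  exons = lapply(strsplit(genes_flat$exons, ","), function(p) {
    m <- do.call(rbind, strsplit(p, "-"))
    cbind(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
  }))
genome <- read_fasta("results/study/genome.fa")
features <- build_feature_set(genes, genome_lengths(genome))
if (nrow(dm$dmcs) > 0) {
  ann <- annotate_features(dm$dmcs, features)
  cat("DMC distribution over features (%):\n")
  print(round(100 * ann$fractions, 2))
}
if (nrow(dmrs) > 0) {
  ann_r <- annotate_features(dmrs, features)
  cat("DMR distribution over features (%):\n")
  print(round(100 * ann_r$fractions, 2))
}

write_tsv(dm$tests[, setdiff(names(dm$tests), "is_dmc")],
          file.path(out, "all_tests.tsv"))
write_tsv(dm$dmcs[, setdiff(names(dm$dmcs), "is_dmc")],
          file.path(out, "dmc.tsv"))
write_bed(dmrs, file.path(out, "dmr.bed"))
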