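#!/usr/bin/env Rscript
# Stage 5: promoter CpG content around TSSs (-500..+500 bp), the
# two-component Gaussian mixture fit, the HCP/LCP crossover, and the
# class-wise metagene profiles.

suppressPackageStartupMessages(library(rrbsim))

study <- "results/study"
out <- "results/promoters"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- read_fasta(file.path(study, "genome.fa"))
genes_flat <- read_tsv(file.path(study, "genes.tsv"))
genes <- gene_model_table(
  gene_id = genes_flat$gene_id, chrom = genes_flat$chrom,
  strand = genes_flat$strand, tss = genes_flat$tss, tes = genes_flat$tes,
  exons = lapply(strsplit(genes_flat$exons, ","), function(p) {
    m <- do.call(rbind, strsplit(p, "-"))
    cbind(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
  }))
rec <- read_tsv("results/calling/rep1.meth.tsv")
cpg <- rec[rec$context == "CpG", ]

contents <- promoter_cpg_content(genome, genes)
fit <- fit_two_normal_mixture(contents$content, seed = 1L)
thr <- crossover(fit)
classes <- classify_promoters(contents, thr)

cat(sprintf("Mixture fit (%d promoters, %d EM iterations):\n",
            nrow(contents), fit$n_iterations))
cat(sprintf("  component 1: weight %.2f, mean %.2f%%, sd %.2f\n",
            fit$weight[1], fit$mean[1], fit$sd[1]))
cat(sprintf("  component 2: weight %.2f, mean %.2f%%, sd %.2f\n",
            fit$weight[2], fit$mean[2], fit$sd[2]))
cat(sprintf("Crossover: %.2f%% CpG content -> %d HCP, %d LCP.\n",
            thr, sum(classes$class == "HCP"), sum(classes$class == "LCP")))

# recovered classes against the generative truth
truth <- read_tsv(file.path(study, "truth_promoters.tsv"))
agree <- mean((classes$class == "HCP") ==
                truth$hcp[match(classes$gene_id, truth$gene_id)])
cat(sprintf("Agreement with planted classes: %.1f%%.\n", 100 * agree))

profiles <- class_metagene(cpg, genes, classes)
tss_bins <- function(p) {
  up <- p[p$region_label == "up5k", ]
  mean(up$mean_value[up$bin_index >= 18], na.rm = TRUE)  # last 500 bp before TSS
}
cat(sprintf("Mean level in the 500 bp before the TSS: HCP %.3f vs LCP %.3f.\n",
            tss_bins(profiles$HCP), tss_bins(profiles$LCP)))

write_tsv(classes, file.path(out, "promoter_classes.tsv"))
jsonlite::write_json(list(weight = fit$weight, mean = fit$mean, sd = fit$sd,
                          log_likelihood = fit$log_likelihood,
                          n_iterations = fit$n_iterations,
                          converged = fit$converged, crossover = thr),
                     file.path(out, "mixture_fit.json"),
                     auto_unbox = TRUE, digits = NA)
for (cl in names(profiles)) {
  write_tsv(profiles[[cl]], file.path(out, sprintf("metagene_%s.tsv", cl)))
}
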