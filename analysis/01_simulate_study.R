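#!/usr/bin/env Rscript
# Stage 1: generate the synthetic RRBS study all later stages analyse.
# Writes the genome (FASTA), three replicate coverage files, the truth
# tables, and the resolved configuration under results/study/.

suppressPackageStartupMessages(library(rrbsim))

cfg <- sim_config(seed = 20160225L)
out <- "results/study"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_genome(cfg)
meth <- simulate_methylome(sim, cfg)
reps <- simulate_counts(meth, cfg, n_replicates = 3L)

Biostrings::writeXStringSet(sim$genome, file.path(out, "genome.fa"))
for (r in seq_along(reps)) {
  write_coverage(reps[[r]], file.path(out, sprintf("rep%d.cov.tsv", r)))
}
write_tsv(sim$truth$promoters, file.path(out, "truth_promoters.tsv"))
write_bed(sim$truth$cgis, file.path(out, "truth_cgis.bed"))
write_tsv(meth$cpg, file.path(out, "truth_methylome.tsv"))
genes_flat <- sim$genes[, c("gene_id", "chrom", "strand", "tss", "tes")]
genes_flat$exons <- vapply(sim$genes$exons, function(e) {
  paste(paste(e[, 1], e[, 2], sep = "-"), collapse = ",")
}, "")
write_tsv(genes_flat, file.path(out, "genes.tsv"))
jsonlite::write_json(unclass(cfg), file.path(out, "config.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf(
  "Simulated %d chromosomes x %d bp, %d genes (%d HCP promoters), %d CpG duplexes.\n",
  cfg$n_chroms, cfg$chrom_length, nrow(sim$genes),
  sum(sim$truth$promoters$hcp), nrow(meth$cpg)))
cat(sprintf("Replicate coverage files: %s\n",
            paste(sprintf("rep%d.cov.tsv", seq_along(reps)), collapse = ", ")))
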