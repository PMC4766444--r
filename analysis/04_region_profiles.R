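#!/usr/bin/env Rscript
# Stage 4: regional methylation structure of replicate 1: TSS-anchored
# CpG-content and methylation profiles, the whole-gene metagene, windowed
# methylation vs gene density, CpG-island discovery and CGI methylation by
# genomic feature.

suppressPackageStartupMessages(library(rrbsim))

study <- "results/study"
out <- "results/profiles"
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
chrom_len <- genome_lengths(genome)
rec <- read_tsv("results/calling/rep1.meth.tsv")
cpg <- rec[rec$context == "CpG", ]

tss_meth <- tss_profile(cpg, genes, value = "methylation")
tss_cpg <- tss_profile(genome, genes, value = "cpg_content")
min_bin <- tss_meth$bin_index[which.min(tss_meth$mean_value)]
max_cpg_bin <- tss_cpg$bin_index[which.max(tss_cpg$mean_value)]
cat(sprintf("TSS profile: methylation minimum at bin %d (offset %+d bp), CpG content maximum at bin %d.\n",
            min_bin, as.integer(tss_meth$offset_mid[min_bin + 1L]), max_cpg_bin))
ok <- complete.cases(tss_meth$mean_value, tss_cpg$mean_value)
cat(sprintf("Methylation vs CpG content across the 200 bins: r = %.2f.\n",
            track_correlation(tss_meth$mean_value[ok], tss_cpg$mean_value[ok])$r))

mg <- metagene_profile(cpg, genes)
by_region <- tapply(mg$mean_value, mg$region_label, mean, na.rm = TRUE)
cat("Metagene mean level by region:\n")
print(round(by_region[c("up5k", "exon", "intron", "down2k")], 3))

wm <- window_methylation(cpg, genes, chrom_len, window = 50000)
okw <- !is.na(wm$mean_level)
wc <- track_correlation(wm$mean_level[okw], wm$gene_count[okw])
cat(sprintf("50-kb windows: methylation vs gene density r = %.2f (p = %.2e) over %d windows.\n",
            wc$r, wc$p, sum(okw)))

cgis <- cgi_scan(genome)
cfm <- cgi_feature_methylation(cgis, build_feature_set(genes, chrom_len), cpg)
cat(sprintf("CGI scan: %d islands (median length %d bp).\n",
            nrow(cgis), as.integer(median(cgis$end - cgis$start))))
cat("CGI counts and median methylation by feature:\n")
med <- tapply(cfm$levels$mean_level, cfm$levels$feature, median, na.rm = TRUE)
for (f in names(cfm$counts)) {
  cat(sprintf("  %-10s n = %2d  median level = %s\n", f, cfm$counts[[f]],
              ifelse(f %in% names(med), sprintf("%.3f", med[[f]]), "NA")))
}

write_tsv(tss_meth, file.path(out, "tss_methylation.tsv"))
write_tsv(tss_cpg, file.path(out, "tss_cpg_content.tsv"))
write_tsv(mg, file.path(out, "metagene.tsv"))
write_tsv(wm, file.path(out, "window_methylation.tsv"))
write_bed(cgis, file.path(out, "cgis.bed"))
write_tsv(cfm$levels, file.path(out, "cgi_feature_methylation.tsv"))
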