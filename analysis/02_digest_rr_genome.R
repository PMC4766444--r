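#!/usr/bin/env Rscript
# Stage 2: MspI digestion of the study genome, 110-220 bp size selection,
# and the digest-table statistics: densities, enrichment folds, feature
# capture, windowed density correlation, and simulated read capture of
# promoters at PE50 vs PE100.

suppressPackageStartupMessages(library(rrbsim))

study <- "results/study"
out <- "results/digest"
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

frags <- digest_genome(genome)
rr <- size_select(frags, 110, 220)
features <- build_feature_set(genes, chrom_len)
gsum <- summarize_digest(frags, genome, features)
rsum <- summarize_rr(rr, genome, features)
folds <- enrichment_folds(gsum, rsum)
cap <- capture_fractions(gsum, rsum)

cat(sprintf("Genome: %d internal segments (%.2f/Mb), %d CpGs (%.2f/Mb).\n",
            gsum$segment_count, gsum$segments_per_mb, gsum$total_cpgs,
            gsum$cpgs_per_mb))
cat(sprintf("RR genome: %d fragments, %.3f Mb (%.2f%% of the genome), %.2f segments/Mb.\n",
            rsum$segment_count, rsum$genome_size_mb,
            100 * rsum$genome_size_mb / gsum$genome_size_mb,
            rsum$segments_per_mb))
cat(sprintf("Enrichment folds: segments %.2f, CpGs %.2f.\n",
            folds$segment_fold, folds$cpg_fold))
cat("CpG capture by feature (%):\n")
print(round(cap, 2))

# modal fragment length of the raw internal-fragment histogram
internal <- frags[!frags$terminal, ]
mode_len <- as.integer(names(which.max(table(internal$length))))
cat(sprintf("Modal internal fragment length: %d bp.\n", mode_len))

# 50-kb windowed CpG density: RR genome tracks the genome
cg_all <- do.call(rbind, lapply(names(genome), function(ch) {
  data.frame(chrom = ch, pos = cg_positions(genome[[ch]]))
}))
rr_cg <- do.call(rbind, lapply(names(genome), function(ch) {
  cg <- cg_all[cg_all$chrom == ch, ]
  f <- rr$fragments[rr$fragments$chrom == ch, ]
  if (nrow(f) == 0L) return(cg[0, ])
  k <- findInterval(cg$pos, f$start)
  cg[k > 0L & cg$pos < f$end[pmax(k, 1L)], ]
}))
wd_g <- window_density(cg_all, chrom_len, window = 50000)
wd_r <- window_density(rr_cg, chrom_len, window = 50000)
tc <- track_correlation(wd_g$count, wd_r$count)
cat(sprintf("Windowed CpG density, RR vs genome: Pearson r = %.2f (p = %.2e).\n",
            tc$r, tc$p))

# read capture of promoter windows under the two paired-end strategies
prom <- data.frame(chrom = genes$chrom,
                   start = pmax(ifelse(genes$strand == "+",
                                       genes$tss - 2000L, genes$tss),
                                0),
                   end = ifelse(genes$strand == "+", genes$tss,
                                genes$tss + 2000L))
prom <- prom[order(prom$chrom, prom$start), ]
for (rl in c(50L, 100L)) {
  cov <- simulate_read_capture(rr, read_len = rl)
  rc <- region_coverage(cov, prom)
  cat(sprintf("PE%d: %.1f%% of promoter bp covered, %.1f%% of promoters hit.\n",
              rl, 100 * rc$fraction_bp, 100 * rc$fraction_regions_hit))
}

write_bed(rr$fragments[, c("chrom", "start", "end")],
          file.path(out, "rr_fragments.bed"))
write_tsv(data.frame(quantity = c("segments_per_mb_genome", "segments_per_mb_rr",
                                  "cpgs_per_mb_genome", "cpgs_per_mb_rr",
                                  "segment_fold", "cpg_fold", "modal_fragment_bp",
                                  paste0("capture_pct_", names(cap))),
                     value = c(gsum$segments_per_mb, rsum$segments_per_mb,
                               gsum$cpgs_per_mb, rsum$cpgs_per_mb,
                               folds$segment_fold, folds$cpg_fold, mode_len,
                               unname(cap))),
          file.path(out, "rr_summary.tsv"))
write_tsv(features, file.path(out, "features.tsv"))
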