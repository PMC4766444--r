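# rrbsim

In-silico RRBS design and reduced-representation methylome analysis in R.

Reduced representation bisulfite sequencing (RRBS) reads the methylation
state of a genome at single-base resolution while sequencing only a few
percent of it: MspI (C|CGG) digestion followed by size selection yields a
CpG-enriched *reduced representation (RR) genome*, and because every
internal MspI fragment starts `CGG` and ends `C`, every fragment carries at
least one CpG. rrbsim implements the computational workflow around that
idea for anyone designing or analysing an RRBS experiment — typically on a
genome without a well-trodden methylation literature, where the design
statistics and the methylome description both have to be computed from
scratch:

- **Design** — in-silico digestion, size selection (110–220 bp default),
  and the design statistics: segments/Mb, CpGs/Mb, RR-genome enrichment
  folds, per-feature CpG capture fractions (up5k / exon / intron / down2k /
  intergenic), windowed density correlations, and paired-end read-capture
  coverage of promoters and CpG islands.
- **Calling** — per-cytosine methylation levels `beta = C / (C + T)` from
  Bismark-style coverage files, with duplex strand combining, an inclusive
  five-read depth filter, bisulfite conversion-rate QC from non-CpG
  cytosines, context-level histograms, and replicate concordance.
- **Profiles** — 200-bin TSS-anchored methylation and CpG-content
  profiles, whole-gene metagene profiles (20 | 40 | 40 | 20 bins over
  up5k | exon | intron | down2k), windowed methylation vs gene density,
  CpG-island discovery (length > 200 bp, GC > 0.5, obs/exp CpG > 0.6),
  and CGI methylation by genomic feature.
- **Promoter classes** — CpG content of the ±500 bp TSS window, a
  two-component Gaussian mixture fit by EM, the density crossover
  (≈4% for a bimodal mammalian promoter set), and HCP/LCP classification.
- **Differential methylation** — a beta-binomial Wald test with windowed
  paired-contrast dispersion estimation, Benjamini–Hochberg correction,
  DMCs at |Δβ| > 0.20 and q < 0.01, and greedy DMR merging.
- **Synthetic data** — generators for genomes, gene models and bisulfite
  counts with planted, recoverable structure (bimodal methylome, TSS dip,
  promoter content mixture, gene-density coupling, conversion failure,
  planted differential regions), so the whole pipeline is testable without
  any downloads.

## Worked example

```r
library(rrbsim)

# design statistics from published digest-table counts
g <- genome_summary(segment_count = 2366953, genome_size_mb = 2808.53,
                    total_cpgs = 60920863)
r <- genome_summary(segment_count = 281216, genome_size_mb = 45.25,
                    total_cpgs = 3714426)
folds <- enrichment_folds(g, r)
cat(sprintf("segments/Mb: genome %.2f, RR %.2f (%.2f-fold)\n",
            g$segments_per_mb, r$segments_per_mb, folds$segment_fold))
cat(sprintf("CpGs/Mb:     genome %.2f, RR %.2f (%.2f-fold)\n",
            g$cpgs_per_mb, r$cpgs_per_mb, folds$cpg_fold))

# a small end-to-end synthetic study
cfg <- sim_config(seed = 1)
sim <- simulate_genome(cfg)
meth <- simulate_methylome(sim, cfg)
counts <- simulate_counts(meth, cfg, n_replicates = 2)

rr <- size_select(digest_genome(sim$genome), 110, 220)
cat(sprintf("RR genome: %d fragments, %d bp\n", rr$n_fragments, rr$total_length_bp))

called <- lapply(counts, function(x) call_levels(filter_depth(combine_strands(x))))
qc <- conversion_rate(counts[[1]])
cat(sprintf("conversion rate: %.2f%%\n", 100 * qc$rate))
cpg <- lapply(called, function(x) x[x$context == "CpG", ])
cat(sprintf("replicate r: %.3f\n", replicate_correlation(cpg[[1]], cpg[[2]])$r))

fit <- fit_two_normal_mixture(promoter_cpg_content(sim$genome, sim$genes)$content)
cat(sprintf("promoter mixture means: %.2f%% / %.2f%%, crossover %.2f%%\n",
            fit$mean[1], fit$mean[2], crossover(fit)))
```

prints

```
segments/Mb: genome 842.77, RR 6214.72 (7.37-fold)
CpGs/Mb:     genome 21691.37, RR 82086.76 (3.78-fold)
RR genome: 102 fragments, 16931 bp
conversion rate: 98.50%
replicate r: 0.814
promoter mixture means: 2.21% / 5.81%, crossover 4.09%
```

The first block is pure design arithmetic: an RR genome built from
110–220 bp MspI fragments concentrates digestion segments 7.37-fold and
CpGs 3.78-fold relative to the source genome. The second block runs the
synthetic study at its default scale (two 400-kb chromosomes, 40 genes):
the RR genome covers ~2% of the genome, the conversion-rate QC reads
98.5% (the generator plants 1% true non-CpG methylation on top of a 0.4%
conversion-failure rate, and the QC statistic deliberately conflates the
two), replicates agree at r ≈ 0.81 at ~15× coverage, and the promoter
CpG-content mixture crosses over at ≈4%, separating high- from low-CpG
promoters.

## The analysis workflow

`analysis/` holds the numbered study scripts, each a thin driver over the
package that prints its findings and writes tables under `results/`:

```sh
Rscript analysis/01_simulate_study.R          # genome + 3 replicate count files
Rscript analysis/02_digest_rr_genome.R        # RR genome + design statistics
Rscript analysis/03_methylation_calling.R     # calls, QC, replicate concordance
Rscript analysis/04_region_profiles.R         # TSS/metagene/window/CGI profiles
Rscript analysis/05_promoter_classes.R        # mixture fit, crossover, HCP/LCP
Rscript analysis/06_differential_methylation.R# DMCs, DMRs, feature annotation
```

`run_pipeline()` chains the same stages programmatically and writes a JSON
manifest with the seed, the resolved configuration and an md5 checksum of
every output, so a rerun with the same configuration is verifiably
identical. The methods vignette (`vignettes/rrbsim-methods.Rmd`) documents
the models, parameter choices and limitations.

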