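---
title: "Models and methods in rrbsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in rrbsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rrbsim)
```

rrbsim implements the computational side of a reduced representation
bisulfite sequencing (RRBS) study: the in-silico restriction design that
decides what an RRBS library will see, the per-cytosine methylation calls
made from bisulfite counts, the regional summaries that describe a
methylome, and the detection of differential methylation between two
samples. This vignette explains the models behind each stage, the
parameters that matter, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## Coordinates and formats

All internal coordinates are 0-based and half-open. BED and bedGraph are
native to this convention; GTF (1-based, closed) is converted at the parse
boundary (`start0 = start1 - 1`, `end0 = end1`), and Bismark-style coverage
files (1-based positions) likewise. A CpG site is identified by the
forward-strand C of the CG duplex after strand combining. Chromosome names
match exactly; nothing aliases `chr1` to `1`, because silent aliasing hides
data errors. N bases never participate in motif matching: a CCGG cannot
contain one, runs of N split chromosomes into independently digested
blocks, and any N in a context-deciding di- or trinucleotide makes that
cytosine unclassifiable.

## In-silico MspI digestion and the RR genome

MspI recognizes CCGG and cuts after the first C. `find_cut_sites()` places
a cut at `p + 1` for a motif at 0-based `p`; both strands are treated at
the same duplex coordinate, because the 2-nt overhang and its fill-in do
not change the genomic span of a fragment. Fragments are the pieces
between consecutive cuts; pieces touching a chromosome end or an N run are
flagged *terminal* and excluded from the RR genome, since a real RRBS
insert needs an MspI end on both sides for adapter ligation. Every
internal fragment begins `CGG...` and ends `...C`, so it contains at least
one CpG — the structural reason RRBS enriches CpGs.

Size selection keeps fragments with lengths in a closed interval,
110–220 bp by default; the bounds are read as inclusive. Summaries report
segment and CpG densities per Mb, where a genome's size includes N runs
(the without-N size is reported alongside, since assembly conventions
differ) and an RR genome's size is the summed length of its selected
fragments. CpGs are counted on two strands: twice the number of
forward-strand CG starts whose C lies in the interval. Enrichment folds
divide RR densities by genome densities; capture fractions divide RR CpG
counts by genome CpG counts per feature.

The five-feature partition (up5k = 5 kb upstream of the TSS, exon, intron,
down2k = 2 kb downstream of the TES, intergenic) resolves overlaps with
the precedence exon > intron > up5k > down2k > intergenic — transcribed
sequence is the most specific annotation — and tiles each chromosome
exactly, so per-feature counts always sum to totals. Read capture is
modelled geometrically: a paired-end read of length R covers
`[start, start + R)` and `[end - R, end)` of each fragment, so fragments
no longer than 2R are fully covered.

## Methylation calling

The level of a cytosine is methylated reads over total reads. For CpGs the
counts of the two duplex strands (forward C at p, reverse C at p + 1) are
summed first and the `>= 5` read filter is applied to the combined total:
filtering per strand would discard duplex evidence asymmetrically. The
filter is inclusive ("at least five reads"). The conversion rate is the
fraction of non-CpG (CHG + CHH) read observations called unmethylated;
it assumes true non-CpG methylation is negligible, so when the simulator
plants a non-zero non-CpG level the QC rate is expectedly below `1 - f`
(the observed non-CpG methylated probability is `lvl + (1 - lvl) f` for
conversion-failure rate f). Level histograms use ten 10-point bins with
the top bin closed (`[90,100]`) so fully methylated sites are counted
once. Replicate concordance is a Pearson correlation over the levels at
the intersection of filtered sites.

## Regional profiles

TSS profiles bin the 5 kb on either side of every TSS into 50-bp bins
(200 bins); the offset is the strand-aware signed distance, negative
upstream, and bin means pool observations across genes rather than
averaging per-gene means — pooling is stable when per-gene coverage is
sparse, which is the norm for RRBS. The metagene concatenates each gene's
exonic bp into one 40-bin virtual axis and, independently, all non-exonic
gene-body bp into another 40 bins, with fixed 20-bin axes for the 5-kb
upstream and 2-kb downstream flanks; the intron axis is defined as all
non-exonic gene-body sequence so the two body axes are disjoint and
jointly cover the gene. Out-of-range observations are dropped, never
clipped, and empty bins are reported missing rather than zero.

CpG islands follow the Gardiner-Garden-style definition: length > 200 bp,
GC fraction > 0.5, observed/expected CpG > 0.6, with expected CpGs of a
span of length L equal to `L (gc/2)^2`. The scanner slides a 200-bp window
in 1-bp steps, merges overlapping or adjacent passing windows, re-tests
each merged span and trims failing spans by one bp from both ends until
they pass or shrink to 200 bp. Thresholds are parameters, so externally
produced CGI intervals can be substituted. Gene density per window is the
count of TSSs in the window — unambiguous for genes crossing window
borders.

## Promoter classes

Promoter CpG content is 100 × (CG starts in the ±500 bp window around the
TSS) / (non-N window bp). This "CG starts per bp" reading — not C+G
fraction, not observed/expected — is the definition under which a bimodal
mammalian promoter distribution crosses over near 4% for a 1-kb window.
The two-component Gaussian mixture is fit by EM: initialization at the
25th/75th percentiles with the pooled SD and equal weights, convergence
when the log-likelihood gains less than 1e-8, at most 500 iterations, up
to 5 perturbed restarts if a component degenerates (SD below 1e-8), and
components reported ordered by mean. The log-likelihood trace is retained
so monotonicity is assertable. The crossover is the smallest root of
`w1 φ(x; m1, s1) = w2 φ(x; m2, s2)` inside `(m1, m2)`, located on a
1024-point grid and refined by bisection to 1e-6. Classification is
strict: content above the threshold is HCP, ties go to LCP as the
conservative boundary default.

## Differential methylation

Two samples are compared at the CpG sites where both pass the depth
filter. The test is a beta-binomial Wald test: with counts (m, n) per
sample and dispersion φ, the level estimate `b = m/n` has variance
`b(1-b)(1 + (n-1)φ)/n`, with `b(1-b)` floored at `1/(n+1)^2` so boundary
proportions keep positive variance; the statistic divides the level
difference by the root of the summed variances and p-values are two-sided
normal tails. With φ = 0 this is the classic two-proportion Wald test.
All shared sites form the Benjamini–Hochberg family — pre-filtering by
effect size before testing would invalidate the FDR — and a DMC requires
both `|delta| > 0.20` (strict) and `q < 0.01`. DMRs merge consecutive
same-direction DMCs with gaps of at most 300 bp into runs of at least 3,
the region end extending 2 bp past the last DMC to cover its duplex; both
merging parameters are exposed because no canonical rule exists.

The dispersion model deserves its own paragraph, because the obvious
estimator is wrong in an instructive way. With one library per condition,
a windowed method of moments that pools both samples' counts under a
common-level assumption confounds three things: read-sampling dispersion
(what the Wald variance needs), real site-to-site methylation structure
(shared by the samples, hence irrelevant to their difference), and the
condition difference itself — so genuinely differential regions inflate
their own variance estimate and mask themselves. `estimate_dispersion()`
therefore works on the paired contrasts `d_j = p_aj - p_bj`, in which the
shared site effects cancel exactly, and measures their scale by the von
Neumann successive-difference estimator `mean(diff(d)^2)/2` within a
500-bp window: a locally constant level shift cancels in every adjacent
pair except the one spanning a region boundary, while the plain second
moment remains unbiased under the heavy-tailed contrasts a truly
overdispersed null produces (robust scales such as the MAD underestimate
there and break FDR calibration). The window estimates are shrunk toward
their genome-wide median with a prior strength of 10 pseudo-observations;
isolated sites fall back to the median, and estimates are clamped to
`[1e-6, 0.99]`. This is a deliberately simple stand-in for the smoothing
and empirical-Bayes machinery of dedicated packages, not a
re-implementation of any of them.

## The synthetic-data generator

The generator exists so every stage is testable without downloads. It
emulates, with planted and therefore recoverable structure: a CpG-depleted
background (background CG dinucleotides retained with probability 0.25
over a 42% GC base composition), MspI sites at about one per kb, CG-rich
island blocks (GC 0.65, observed/expected 0.85, 300–700 bp), promoters
whose CpG content is drawn from an equal-weight two-normal mixture with
means 2% and 6% and SDs 0.8 — the configuration whose density crossover
sits at 4% — written into the ±500 bp TSS window with an exact planted CG
count, and genes with exon/intron structure placed at a density that
declines along each chromosome. The methylome sets each CpG's mean level
to `plogis(logit(0.8) - 0.5 z - dip · exp(-d^2 / 2w^2))` with z the
standardized local gene density, d the distance to the nearest TSS,
w = 1000 bp, and a dip of 4 logit units at high-CpG promoters versus 1 at
low-CpG promoters, then adds per-site beta noise with concentration 50.
Counts are binomial given the level, with negative-binomial per-strand
depths (mean 7.5 per strand, size 4, i.e. ~15 per duplex), a bisulfite
conversion-failure rate of 0.004 (the ~99.6% conversion regime typical of
a well-run library) applied as unconverted-C-read-as-methylated, and 1%
true non-CpG methylation on a 2% sample of non-CpG cytosines. A
between-replicate beta-binomial dispersion knob exists for calibration
studies but defaults to 0, which is the count model the analysis assumes.
The two-condition plan adds a -0.5 level shift (clamped to [0.01, 0.99])
inside 30 disjoint 400-bp regions chosen to contain at least 5 CpGs at a
mean level of at least 0.6, so the planted shift survives clamping.

Default problem sizes are two 400-kb chromosomes with 40 genes (~11,000
CpG duplexes); the FDR-calibration studies use two 800-kb chromosomes to
exceed 20,000 shared sites, and profile-recovery studies switch off the
density coupling and the level noise and use a uniform dip so the planted
level function is known in closed form at every distance. These sizes are
the package's chosen study scale: large enough for every planted property
to be recovered well above sampling noise, small enough that the full
suite and the acceptance script run in minutes.

What passing tests do and do not show: the generator plants i.i.d.
negative-binomial coverage, independent sites, exact bisulfite chemistry,
and clean annotation. Real RRBS data add M-bias along reads, PCR
duplicates, SNPs under C positions, mapping bias in CpG-dense regions,
incomplete and transcript-ambiguous annotation, and fragment-length-
dependent coverage — none of which are modelled. Recovery of planted
structure therefore validates the arithmetic and the statistical
machinery, not robustness to those artefacts; the upstream hygiene
(trimming, alignment, deduplication) is explicitly out of scope, and the
pipeline consumes count files, not reads.

## Known limitations

The digest model treats the enzyme as ideal (complete digestion, no star
activity) and ignores the CG fill-in bases at fragment ends. The Wald test
is asymptotic; at depth 5 its p-values are discrete and conservative
behaviour relies on the BH step-up. Dispersion is weakly identifiable with
one library per condition — the windowed estimator bounds it usefully but
cannot distinguish a genuinely hypervariable window from a short
differential region narrower than the window. The EM fit assumes exactly
two promoter classes; genomes without promoter bimodality (sheep, cow)
would need a manual threshold, for which `classify_promoters()` accepts
any cutoff. DMR counts depend on the exposed merging parameters and are
reported descriptively rather than asserted against any external truth.
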