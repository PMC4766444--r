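#' Find MspI cut sites in a sequence
#'
#' MspI cuts C|CGG: for every occurrence of the motif `CCGG` at 0-based
#' position p, the cut falls between the first C and the CGG, i.e. at
#' coordinate p + 1. The motif contains no N, so sites never span ambiguity
#' runs. All occurrences are reported, including book-ended ones.
#'
#' @param seq A `DNAString`, single-element `DNAStringSet`, or character
#'   scalar (normalized uppercase).
#' @param motif Recognition motif (default `"CCGG"`).
#' @param cut_offset Cut position within the motif (default 1 for C|CGG).
#' @return Sorted integer vector of 0-based cut coordinates.
#' @export
find_cut_sites <- function(seq, motif = "CCGG", cut_offset = 1L) {
  seq <- .as_dnastring(seq)
  m <- Biostrings::matchPattern(motif, seq)
  # matchPattern starts are 1-based: 0-based motif pos p = start - 1,
  # cut coordinate = p + cut_offset = start - 1 + cut_offset
  sort(BiocGenerics::start(m) - 1L + as.integer(cut_offset))
}

.as_dnastring <- function(seq) {
  if (is.character(seq)) return(Biostrings::DNAString(seq))
  if (methods::is(seq, "DNAStringSet")) {
    if (length(seq) != 1L) stop("expected a single sequence")
    return(seq[[1L]])
  }
  seq
}

#' Digest one chromosome in silico
#'
#' Fragments are the pieces between consecutive cut coordinates. Runs of one
#' or more N split the chromosome into blocks that are digested
#' independently; pieces touching a block edge (chromosome end or N run)
#' rather than two cut sites are flagged `terminal`. Every non-terminal
#' fragment starts with `CGG` and ends with `C`, hence contains at least one
#' CpG.
#'
#' @param seq Sequence (as in [find_cut_sites()]).
#' @param chrom Chromosome name attached to the output.
#' @inheritParams find_cut_sites
#' @return Data frame `chrom`, `start`, `end` (0-based half-open), `length`,
#'   `terminal`, sorted by `start`.
#' @export
digest <- function(seq, chrom = "chr", motif = "CCGG", cut_offset = 1L) {
  seq <- .as_dnastring(seq)
  len <- length(seq)
  if (len == 0L) return(.empty_fragments())
  cuts <- find_cut_sites(seq, motif, cut_offset)
  # N runs delimit independently digested blocks
  nruns <- Biostrings::matchPattern("N", seq, max.mismatch = 0)
  n_pos <- BiocGenerics::start(nruns) - 1L
  if (length(n_pos) > 0L) {
    r <- IRanges::reduce(IRanges::IRanges(start = n_pos + 1L, width = 1L))
    block_bounds <- cbind(c(0L, BiocGenerics::end(r)),
                          c(BiocGenerics::start(r) - 1L, len))
  } else {
    block_bounds <- cbind(0L, len)
  }
  out <- vector("list", nrow(block_bounds))
  for (b in seq_len(nrow(block_bounds))) {
    b0 <- block_bounds[b, 1]; b1 <- block_bounds[b, 2]
    if (b1 <= b0) next
    bc <- cuts[cuts > b0 & cuts < b1]
    bounds <- c(b0, bc, b1)
    st <- bounds[-length(bounds)]
    en <- bounds[-1L]
    keep <- en > st
    st <- st[keep]; en <- en[keep]
    terminal <- st == b0 | en == b1   # touches block edge, not two cuts
    out[[b]] <- data.frame(chrom = chrom, start = st, end = en,
                           length = en - st, terminal = terminal,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) return(.empty_fragments())
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

.empty_fragments <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             length = integer(), terminal = logical(), stringsAsFactors = FALSE)
}

#' Digest a whole genome
#'
#' @param genome Named `DNAStringSet`.
#' @inheritParams find_cut_sites
#' @return Fragment data frame over all chromosomes (see [digest()]).
#' @export
digest_genome <- function(genome, motif = "CCGG", cut_offset = 1L) {
  frags <- lapply(names(genome), function(ch) {
    digest(genome[[ch]], chrom = ch, motif = motif, cut_offset = cut_offset)
  })
  out <- do.call(rbind, frags)
  rownames(out) <- NULL
  out
}

#' Size-select fragments into a reduced-representation genome
#'
#' Keeps non-terminal fragments whose length lies in `[min_len, max_len]`
#' (bounds inclusive); terminal fragments lack a second MspI end and are
#' excluded, as in a real RRBS library.
#'
#' @param fragments Fragment data frame from [digest_genome()].
#' @param min_len,max_len Inclusive size-selection bounds in bp
#'   (default 110-220).
#' @return Object of class `rr_genome`: list with `fragments`, `min_len`,
#'   `max_len`, `n_fragments`, `total_length_bp`.
#' @export
size_select <- function(fragments, min_len = 110L, max_len = 220L) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  keep <- !fragments$terminal &
    fragments$length >= min_len & fragments$length <= max_len
  sel <- fragments[keep, , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(fragments = sel, min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 n_fragments = nrow(sel),
                 total_length_bp = sum(sel$length)),
            class = "rr_genome")
}

#' Forward-strand CG dinucleotide positions
#'
#' @param seq Sequence (as in [find_cut_sites()]).
#' @return 0-based positions of the C of each CG occurrence.
#' @export
cg_positions <- function(seq) {
  seq <- .as_dnastring(seq)
  BiocGenerics::start(Biostrings::matchPattern("CG", seq)) - 1L
}

#' Count CpGs on two strands within an interval
#'
#' Counts forward-strand CG dinucleotides whose C lies inside
#' `[start, end)` and doubles the count (each CG duplex carries a cytosine
#' on both strands). A CG straddling the interval end is counted iff its C
#' is inside.
#'
#' @param seq Sequence.
#' @param start,end 0-based half-open interval; defaults to the whole
#'   sequence.
#' @return Integer two-strand CpG count.
#' @export
count_cpgs_two_strand <- function(seq, start = 0L, end = NULL) {
  seq <- .as_dnastring(seq)
  if (is.null(end)) end <- length(seq)
  if (start < 0L || end > length(seq) || start > end) {
    stop("interval out of sequence bounds")
  }
  cg <- cg_positions(seq)
  2L * sum(cg >= start & cg < end)
}

#' Build the five-feature genomic partition
#'
#' Partitions each chromosome into up5k (5 kb upstream of the TSS,
#' strand-aware), exon, intron, down2k (2 kb downstream of the TES) and
#' intergenic, with overlaps resolved by precedence
#' exon > intron > up5k > down2k > intergenic. Flanks are truncated at
#' chromosome ends; the result tiles the genome exactly.
#'
#' @param genes Gene-model table ([read_gene_models()]).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param up,down Flank sizes in bp (defaults 5000 and 2000).
#' @return Data frame `chrom`, `start`, `end`, `feature`, sorted; class
#'   `feature_set` with `chrom_lengths` attribute.
#' @export
build_feature_set <- function(genes, chrom_lengths, up = 5000L, down = 2000L) {
  if (any(!genes$chrom %in% names(chrom_lengths))) {
    stop("gene on unknown chromosome")
  }
  span_lo <- pmin(genes$tss, genes$tes)
  span_hi <- pmax(genes$tss, genes$tes)
  if (any(span_lo < 0) || any(span_hi > chrom_lengths[genes$chrom])) {
    stop("gene beyond chromosome bounds")
  }
  res <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    clip <- function(s, e) {
      s <- pmax(s, 0); e <- pmin(e, L)
      IRanges::reduce(IRanges::IRanges(start = s[e > s] + 1L, end = e[e > s]))
    }
    if (nrow(g) == 0L) {
      ex <- IRanges::IRanges(); intr <- IRanges::IRanges()
      u5 <- IRanges::IRanges(); d2 <- IRanges::IRanges()
    } else {
      ex_mat <- do.call(rbind, g$exons)
      ex <- clip(ex_mat[, 1], ex_mat[, 2])
      lo <- pmin(g$tss, g$tes); hi <- pmax(g$tss, g$tes)
      body <- clip(lo, hi)
      intr <- IRanges::setdiff(body, ex)
      plus <- g$strand == "+"
      u5 <- clip(ifelse(plus, g$tss - up, g$tss),
                 ifelse(plus, g$tss, g$tss + up))
      d2 <- clip(ifelse(plus, g$tes, g$tes - down),
                 ifelse(plus, g$tes + down, g$tes))
      # precedence: exon > intron > up5k > down2k > intergenic
      u5 <- IRanges::setdiff(u5, IRanges::union(ex, intr))
      d2 <- IRanges::setdiff(d2, IRanges::reduce(c(ex, intr, u5)))
    }
    whole <- IRanges::IRanges(start = 1L, end = L)
    inter <- IRanges::setdiff(whole, IRanges::reduce(c(ex, intr, u5, d2)))
    part <- list(up5k = u5, exon = ex, intron = intr, down2k = d2,
                 intergenic = inter)
    do.call(rbind, lapply(names(part), function(f) {
      ir <- part[[f]]
      if (length(ir) == 0L) return(NULL)
      data.frame(chrom = ch, start = BiocGenerics::start(ir) - 1L,
                 end = BiocGenerics::end(ir), feature = f,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, chrom_lengths = chrom_lengths,
            class = c("feature_set", "data.frame"))
}

#' Assign positions to features of a partition
#'
#' @param features `feature_set` from [build_feature_set()].
#' @param chrom,pos Parallel vectors of chromosome names and 0-based
#'   positions.
#' @return Character vector of feature labels.
#' @export
assign_feature <- function(features, chrom, pos) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    f <- features[features$chrom == ch, , drop = FALSE]
    if (nrow(f) == 0L) stop("position on unknown chromosome: ", ch)
    i <- chrom == ch
    idx <- findInterval(pos[i], f$start)
    if (any(idx == 0L) || any(pos[i] >= f$end[idx])) {
      stop("position outside the feature partition on ", ch)
    }
    out[i] <- f$feature[idx]
  }
  out
}

#' Summary statistics of a digested genome or RR genome
#'
#' Computes the segment and CpG densities reported for restriction-digest
#' design work: segment count, size in Mb, segments/Mb, two-strand CpG
#' total, CpGs/Mb, and per-feature CpG counts when a feature partition is
#' supplied. Densities recompute from the raw counts
#' (`segments_per_mb = segment_count / genome_size_mb`).
#'
#' @param segment_count Number of digested segments.
#' @param genome_size_mb Size in Mb (total assembled bp / 1e6 for a genome;
#'   summed selected-fragment bp / 1e6 for an RR genome).
#' @param total_cpgs Two-strand CpG count.
#' @param feature_cpgs Optional named vector of per-feature CpG counts.
#' @return List of class `genome_summary`.
#' @export
genome_summary <- function(segment_count, genome_size_mb, total_cpgs,
                           feature_cpgs = NULL) {
  if (genome_size_mb <= 0) stop("empty genome: size must be positive")
  structure(list(segment_count = segment_count,
                 genome_size_mb = genome_size_mb,
                 segments_per_mb = segment_count / genome_size_mb,
                 total_cpgs = total_cpgs,
                 cpgs_per_mb = total_cpgs / genome_size_mb,
                 feature_cpgs = feature_cpgs),
            class = "genome_summary")
}

#' Summarize a whole-genome digestion
#'
#' Segment count is the number of internal (two-cut) fragments; genome size
#' includes N runs (both conventions are standard; the without-N size is
#' returned alongside).
#'
#' @param fragments Fragment data frame from [digest_genome()].
#' @param genome Named `DNAStringSet`.
#' @param features Optional `feature_set` for per-feature CpG counts.
#' @return `genome_summary`; also carries `genome_size_mb_no_n`.
#' @export
summarize_digest <- function(fragments, genome, features = NULL) {
  size_bp <- sum(as.numeric(Biostrings::width(genome)))
  if (size_bp == 0) stop("empty genome")
  n_bp <- sum(Biostrings::letterFrequency(genome, letters = "N")[, 1])
  cg_by_chrom <- lapply(names(genome), function(ch) {
    data.frame(chrom = ch, pos = cg_positions(genome[[ch]]),
               stringsAsFactors = FALSE)
  })
  cg <- do.call(rbind, cg_by_chrom)
  total_cpgs <- 2L * nrow(cg)
  feature_cpgs <- NULL
  if (!is.null(features)) {
    lab <- assign_feature(features, cg$chrom, cg$pos)
    feature_cpgs <- 2L * table(factor(
      lab, levels = c("up5k", "exon", "intron", "down2k", "intergenic")))
    feature_cpgs <- stats::setNames(as.integer(feature_cpgs),
                                    names(feature_cpgs))
  }
  s <- genome_summary(segment_count = sum(!fragments$terminal),
                      genome_size_mb = size_bp / 1e6,
                      total_cpgs = total_cpgs,
                      feature_cpgs = feature_cpgs)
  s$genome_size_mb_no_n <- (size_bp - n_bp) / 1e6
  s
}

#' Summarize an RR genome
#'
#' Size is the summed length of the selected fragments; CpGs are counted
#' within the fragments only.
#'
#' @param rr `rr_genome` from [size_select()].
#' @param genome Named `DNAStringSet`.
#' @param features Optional `feature_set`.
#' @return `genome_summary`.
#' @export
summarize_rr <- function(rr, genome, features = NULL) {
  if (rr$total_length_bp == 0) {
    return(genome_summary(0L, .Machine$double.eps, 0L))
  }
  frag <- rr$fragments
  cg_list <- lapply(names(genome), function(ch) {
    f <- frag[frag$chrom == ch, , drop = FALSE]
    if (nrow(f) == 0L) return(NULL)
    cg <- cg_positions(genome[[ch]])
    idx <- findInterval(cg, f$start)
    inside <- idx > 0L & cg < f$end[pmax(idx, 1L)]
    data.frame(chrom = ch, pos = cg[inside], stringsAsFactors = FALSE)
  })
  cg <- do.call(rbind, cg_list[!vapply(cg_list, is.null, TRUE)])
  total_cpgs <- if (is.null(cg)) 0L else 2L * nrow(cg)
  feature_cpgs <- NULL
  if (!is.null(features) && !is.null(cg)) {
    lab <- assign_feature(features, cg$chrom, cg$pos)
    feature_cpgs <- 2L * table(factor(
      lab, levels = c("up5k", "exon", "intron", "down2k", "intergenic")))
    feature_cpgs <- stats::setNames(as.integer(feature_cpgs),
                                    names(feature_cpgs))
  }
  genome_summary(segment_count = rr$n_fragments,
                 genome_size_mb = rr$total_length_bp / 1e6,
                 total_cpgs = total_cpgs,
                 feature_cpgs = feature_cpgs)
}

#' Enrichment folds of an RR genome over its source genome
#'
#' @param genome_summary,rr_summary `genome_summary` objects for the full
#'   genome and the RR genome.
#' @return List with `segment_fold` and `cpg_fold` (RR density / genome
#'   density).
#' @export
enrichment_folds <- function(genome_summary, rr_summary) {
  if (genome_summary$segments_per_mb == 0 || genome_summary$cpgs_per_mb == 0) {
    stop("zero density in genome summary")
  }
  list(segment_fold = rr_summary$segments_per_mb / genome_summary$segments_per_mb,
       cpg_fold = rr_summary$cpgs_per_mb / genome_summary$cpgs_per_mb)
}

#' Per-feature CpG capture fractions of an RR genome
#'
#' @inheritParams enrichment_folds
#' @return Named numeric vector of percentages (one per feature plus
#'   `overall`); a feature with zero genome CpGs is reported `NA`.
#' @export
capture_fractions <- function(genome_summary, rr_summary) {
  g <- genome_summary$feature_cpgs
  r <- rr_summary$feature_cpgs
  out <- c()
  if (!is.null(g) && !is.null(r)) {
    out <- 100 * ifelse(g > 0, r[names(g)] / g, NA_real_)
    names(out) <- names(g)
  }
  c(out, overall = 100 * rr_summary$total_cpgs / genome_summary$total_cpgs)
}

#' Count positions in fixed genomic windows
#'
#' Left-aligned non-overlapping windows; the last partial window is kept.
#'
#' @param positions Data frame with `chrom`, `pos` (0-based).
#' @param chrom_lengths Named chromosome lengths.
#' @param window Window size in bp (default 1 Mb).
#' @return Data frame `chrom`, `win`, `start`, `end`, `count` covering every
#'   window of every chromosome (zero counts included).
#' @export
window_density <- function(positions, chrom_lengths, window = 1e6) {
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    n_win <- max(1L, as.integer(ceiling(L / window)))
    p <- positions$pos[positions$chrom == ch]
    idx <- floor(p / window)
    cnt <- tabulate(idx + 1L, nbins = n_win)
    data.frame(chrom = ch, win = seq_len(n_win) - 1L,
               start = (seq_len(n_win) - 1L) * window,
               end = pmin(seq_len(n_win) * window, L),
               count = cnt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two aligned window tracks
#'
#' @param track_a,track_b Equal-length numeric vectors.
#' @return List with `r` and two-sided `p` (t transform, n - 2 df).
#' @export
track_correlation <- function(track_a, track_b) {
  if (length(track_a) != length(track_b)) stop("tracks must align")
  if (stats::sd(track_a) == 0 || stats::sd(track_b) == 0) {
    stop("zero variance track: correlation undefined")
  }
  ct <- stats::cor.test(track_a, track_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Simulate paired-end read capture over RR fragments
#'
#' Each fragment is read from both ends: covered bases are
#' `[start, start + read_len)` and `[end - read_len, end)` clipped to the
#' fragment, so fragments no longer than twice the read length are fully
#' covered.
#'
#' @param rr `rr_genome` (or a fragment data frame).
#' @param read_len Read length in bp (50 or 100 in practice).
#' @param paired Capture both ends (default) or only the 5' end.
#' @return Data frame of reduced covered intervals `chrom`, `start`, `end`.
#' @export
simulate_read_capture <- function(rr, read_len = 100L, paired = TRUE) {
  if (read_len <= 0) stop("read_len must be positive")
  frag <- if (inherits(rr, "rr_genome")) rr$fragments else rr
  if (nrow(frag) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  left <- data.frame(chrom = frag$chrom, start = frag$start,
                     end = pmin(frag$start + read_len, frag$end))
  iv <- left
  if (paired) {
    right <- data.frame(chrom = frag$chrom,
                        start = pmax(frag$end - read_len, frag$start),
                        end = frag$end)
    iv <- rbind(left, right)
  }
  out <- lapply(unique(iv$chrom), function(ch) {
    v <- iv[iv$chrom == ch, , drop = FALSE]
    r <- IRanges::reduce(IRanges::IRanges(start = v$start + 1L, end = v$end))
    data.frame(chrom = ch, start = BiocGenerics::start(r) - 1L,
               end = BiocGenerics::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Coverage of regions by captured intervals
#'
#' @param covered Covered intervals (`chrom`, `start`, `end`).
#' @param regions Regions of interest (`chrom`, `start`, `end`).
#' @return List: `fraction_bp` (fraction of total region bp overlapped) and
#'   `fraction_regions_hit` (fraction of regions with >= 1 covered bp).
#' @export
region_coverage <- function(covered, regions) {
  if (nrow(regions) == 0L) stop("no regions supplied")
  total_bp <- sum(as.numeric(regions$end - regions$start))
  hit_bp <- 0
  hit_regions <- logical(nrow(regions))
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    rr <- IRanges::IRanges(start = regions$start[ri] + 1L,
                           end = regions$end[ri])
    cv <- covered[covered$chrom == ch, , drop = FALSE]
    if (nrow(cv) == 0L) next
    ci <- IRanges::reduce(IRanges::IRanges(start = cv$start + 1L,
                                           end = cv$end))
    ov <- IRanges::findOverlaps(rr, ci)
    hit_regions[ri[unique(S4Vectors::queryHits(ov))]] <- TRUE
    if (length(ov) > 0L) {
      q <- rr[S4Vectors::queryHits(ov)]
      s <- ci[S4Vectors::subjectHits(ov)]
      inter_w <- pmin(BiocGenerics::end(q), BiocGenerics::end(s)) -
        pmax(BiocGenerics::start(q), BiocGenerics::start(s)) + 1L
      hit_bp <- hit_bp + sum(as.numeric(inter_w))
    }
  }
  list(fraction_bp = hit_bp / total_bp,
       fraction_regions_hit = mean(hit_regions))
}
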