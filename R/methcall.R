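#' Classify the context of a cytosine
#'
#' On the + strand the two bases following the C decide the context:
#' `CG*` is CpG, `CHG` is CHG, `CHH` is CHH (H = A, C or T). On the - strand
#' the same rule applies to the reverse complement. Any N inside the
#' deciding di-/trinucleotide makes the site unclassifiable (`NA`).
#'
#' @param genome Named `DNAStringSet`.
#' @param chrom,pos,strand Parallel vectors: chromosome, 0-based position of
#'   the cytosine on its strand, and strand.
#' @return Character vector in `{"CpG","CHG","CHH", NA}`.
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  n <- length(pos)
  out <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    s <- as.character(genome[[ch]])
    L <- nchar(s)
    i <- which(chrom == ch)
    base_here <- substring(s, pos[i] + 1L, pos[i] + 1L)
    fwd <- strand[i] == "+"
    if (any(fwd & base_here != "C") || any(!fwd & base_here != "G")) {
      stop("base at a classified position is not a cytosine on its strand")
    }
    b1 <- ifelse(fwd, pos[i] + 1L, pos[i] - 1L)  # next base 0-based
    b2 <- ifelse(fwd, pos[i] + 2L, pos[i] - 2L)
    nb1 <- ifelse(b1 >= 0L & b1 < L, substring(s, b1 + 1L, b1 + 1L), "N")
    nb2 <- ifelse(b2 >= 0L & b2 < L, substring(s, b2 + 1L, b2 + 1L), "N")
    # on the - strand the duplex partner of G is C read 3'->5'
    g1 <- ifelse(fwd, "G", "C")
    ctx <- ifelse(nb1 == "N", NA_character_,
           ifelse(nb1 == g1, "CpG",
           ifelse(nb2 == "N", NA_character_,
           ifelse(nb2 == g1, "CHG", "CHH"))))
    out[i] <- ctx
  }
  out
}

#' Combine strand counts at CpG duplexes
#'
#' Counts at the + strand C (position p) and at its - strand partner
#' (position p + 1) of the same CG duplex are summed into one record keyed
#' by the forward C position. A minus-strand CpG record without a partner
#' is remapped to pos - 1. Non-CpG records pass through unchanged.
#' Read mass is conserved.
#'
#' @param records Count-record data frame ([read_coverage()]).
#' @return Data frame `chrom`, `pos`, `meth`, `unmeth`, `total`, `context`;
#'   CpG records are strand-combined and duplex-keyed.
#' @export
combine_strands <- function(records) {
  cpg <- records[records$context == "CpG", , drop = FALSE]
  rest <- records[records$context != "CpG", , drop = FALSE]
  if (nrow(cpg) > 0L) {
    key_pos <- ifelse(cpg$strand == "+", cpg$pos, cpg$pos - 1L)
    agg <- stats::aggregate(cbind(meth, unmeth) ~ chrom + key_pos,
                            data = cbind(cpg, key_pos = key_pos), FUN = sum)
    cpg_out <- data.frame(chrom = agg$chrom, pos = agg$key_pos,
                          meth = agg$meth, unmeth = agg$unmeth,
                          context = "CpG", stringsAsFactors = FALSE)
  } else {
    cpg_out <- data.frame(chrom = character(), pos = integer(),
                          meth = integer(), unmeth = integer(),
                          context = character(), stringsAsFactors = FALSE)
  }
  rest_out <- data.frame(chrom = rest$chrom, pos = rest$pos,
                         meth = rest$meth, unmeth = rest$unmeth,
                         context = rest$context, stringsAsFactors = FALSE)
  out <- rbind(cpg_out, rest_out)
  out$total <- out$meth + out$unmeth
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter sites by read depth
#'
#' Keeps records with `total >= min_depth` ("at least five reads" with the
#' default). Applied after strand combining so duplex evidence is pooled
#' first.
#'
#' @param records Combined records ([combine_strands()]).
#' @param min_depth Minimum total reads, inclusive (default 5).
#' @return Subset of `records`, counts unmodified.
#' @export
filter_depth <- function(records, min_depth = 5L) {
  if (min_depth < 1L) stop("min_depth must be >= 1")
  records[records$total >= min_depth, , drop = FALSE]
}

#' Methylation level of a site
#'
#' The level is the methylated read count divided by the total read count.
#'
#' @param meth,total Counts (vectorized); requires `total > 0` and
#'   `0 <= meth <= total`.
#' @return Fraction in `[0, 1]`.
#' @export
methylation_level <- function(meth, total) {
  if (any(total <= 0)) stop("methylation level undefined at zero depth")
  if (any(meth < 0) || any(meth > total)) stop("meth must lie in [0, total]")
  meth / total
}

#' Add methylation levels to filtered records
#'
#' @param records Combined, depth-filtered records.
#' @return Records with a `level` column.
#' @export
call_levels <- function(records) {
  records$level <- methylation_level(records$meth, records$total)
  records
}

#' Bisulfite conversion rate from non-CpG cytosines
#'
#' Converted cytosines are the unmethylated calls in CHG and CHH context
#' (assuming true non-CpG methylation is negligible); the rate is converted
#' reads over all non-CpG reads.
#'
#' @param records Count records retaining context labels (combined or raw).
#' @return List `converted_nonCpG`, `total_nonCpG`, `rate`.
#' @export
conversion_rate <- function(records) {
  noncpg <- records[records$context %in% c("CHG", "CHH"), , drop = FALSE]
  if (nrow(noncpg) == 0L) stop("no non-CpG records: conversion rate undefined")
  total <- sum(noncpg$meth) + sum(noncpg$unmeth)
  if (total == 0) stop("no non-CpG read observations")
  converted <- sum(noncpg$unmeth)
  list(converted_nonCpG = converted, total_nonCpG = total,
       rate = converted / total)
}

#' Sites shared by replicates
#'
#' @param ... Two or more depth-filtered record sets.
#' @return List: `common` (data frame of chrom/pos keys present in all
#'   sets), `pairwise` (matrix of pairwise intersection sizes), `sizes`
#'   (per-set site counts).
#' @export
intersect_replicates <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !is.data.frame(sets[[1L]])) {
    sets <- sets[[1L]]
  }
  keys <- lapply(sets, function(r) paste(r$chrom, r$pos, sep = ":"))
  common_keys <- Reduce(intersect, keys)
  k <- length(sets)
  pw <- matrix(NA_integer_, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    pw[i, j] <- length(intersect(keys[[i]], keys[[j]]))
  }
  first <- sets[[1L]]
  sel <- match(common_keys, keys[[1L]])
  list(common = data.frame(chrom = first$chrom[sel], pos = first$pos[sel],
                           stringsAsFactors = FALSE),
       pairwise = pw,
       sizes = lengths(keys))
}

#' Histogram of methylation levels per context
#'
#' Ten bins of 10 percentage points, `[0,10) ... [80,90) [90,100]`; the top
#' bin is closed so fully methylated sites are counted once.
#'
#' @param records Filtered records with `level`.
#' @return Data frame `context`, `bin` (label), `count`; per-context counts
#'   sum to the record count.
#' @export
level_histogram <- function(records) {
  if (!"level" %in% names(records)) records <- call_levels(records)
  bin <- pmin(floor(records$level * 10), 9)
  labels <- c(paste0("[", seq(0, 80, 10), ",", seq(10, 90, 10), ")"),
              "[90,100]")
  tab <- table(context = records$context,
               bin = factor(labels[bin + 1L], levels = labels))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("context", "bin", "count")
  out
}

#' Replicate correlation of CpG methylation levels
#'
#' Pearson correlation over the per-site levels at the sites shared by two
#' filtered replicates.
#'
#' @param rec_a,rec_b Combined, depth-filtered record sets with levels.
#' @return List `r`, `p`, `n_common`.
#' @export
replicate_correlation <- function(rec_a, rec_b) {
  if (!"level" %in% names(rec_a)) rec_a <- call_levels(rec_a)
  if (!"level" %in% names(rec_b)) rec_b <- call_levels(rec_b)
  ka <- paste(rec_a$chrom, rec_a$pos, sep = ":")
  kb <- paste(rec_b$chrom, rec_b$pos, sep = ":")
  common <- intersect(ka, kb)
  if (length(common) < 3L) stop("need at least 3 common sites")
  a <- rec_a$level[match(common, ka)]
  b <- rec_b$level[match(common, kb)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant levels: correlation undefined")
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_common = length(common))
}
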