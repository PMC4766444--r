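#' Read a genome FASTA file
#'
#' Reads a (multi-)FASTA file into a named [Biostrings::DNAStringSet].
#' Sequence names are taken from the header up to the first whitespace,
#' lowercase bases are uppercased, and only the characters A, C, G, T and N
#' are accepted; any other IUPAC code is a format error.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`, one element per record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  bad <- Biostrings::letterFrequency(seqs, letters = "ACGTN")
  illegal <- which(bad[, 1] != Biostrings::width(seqs))
  if (length(illegal) > 0L) {
    stop("illegal character in FASTA record '", names(seqs)[illegal[1]],
         "' (line ", .fasta_bad_line(path), "): only A,C,G,T,N allowed")
  }
  if (anyDuplicated(names(seqs))) stop("duplicate sequence names in ", path)
  seqs
}

# first line of a FASTA file containing a disallowed sequence character
.fasta_bad_line <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seq_lines <- which(!startsWith(lines, ">") & nzchar(lines))
  bad <- grepl("[^ACGTNacgtn]", lines[seq_lines])
  if (any(bad)) seq_lines[which(bad)[1]] else NA_integer_
}

#' Chromosome lengths of a genome
#'
#' @param genome A named `DNAStringSet` as returned by [read_fasta()].
#' @return Named integer vector of sequence lengths in bp.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Read gene models from GTF or BED12
#'
#' Internal coordinates are 0-based, half-open everywhere. GTF (1-based,
#' closed) exon rows are converted at the boundary: `start0 = start1 - 1`,
#' `end0 = end1`. BED12 is taken as-is. The TSS is the 5' end with respect
#' to strand, so a minus-strand gene has `tss > tes` in genomic coordinates.
#'
#' @param path Path to the annotation file.
#' @param dialect `"gtf"` or `"bed12"`.
#' @return A gene-model data frame with columns `gene_id`, `chrom`, `strand`,
#'   `tss`, `tes` and a list column `exons` of two-column matrices
#'   (0-based half-open intervals, sorted, non-overlapping).
#' @export
read_gene_models <- function(path, dialect = c("gtf", "bed12")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "gtf") .read_gtf(path) else .read_bed12(path)
}

.read_gtf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 9L)) stop("malformed GTF line ", which(n_col < 9L)[1])
  feat <- vapply(fields, `[`, "", 3L)
  keep <- feat == "exon"
  if (!any(keep)) stop("no exon features in GTF: ", path)
  fields <- fields[keep]
  chrom <- vapply(fields, `[`, "", 1L)
  start1 <- as.integer(vapply(fields, `[`, "", 4L))
  end1 <- as.integer(vapply(fields, `[`, "", 5L))
  strand <- vapply(fields, `[`, "", 7L)
  attrs <- vapply(fields, `[`, "", 9L)
  m <- regmatches(attrs, regexpr('gene_id "[^"]+"', attrs))
  if (length(m) != length(attrs)) stop("GTF exon without gene_id attribute")
  gene_id <- sub('gene_id "([^"]+)"', "\\1", m)
  # 1-based closed -> 0-based half-open
  start0 <- start1 - 1L
  end0 <- end1
  .assemble_gene_models(gene_id, chrom, strand, start0, end0)
}

.assemble_gene_models <- function(gene_id, chrom, strand, start0, end0) {
  if (!all(strand %in% c("+", "-"))) {
    stop("unknown strand: ", paste(unique(setdiff(strand, c("+", "-"))), collapse = ","))
  }
  ids <- unique(gene_id)
  rows <- lapply(ids, function(g) {
    i <- which(gene_id == g)
    if (length(unique(chrom[i])) > 1L || length(unique(strand[i])) > 1L) {
      stop("gene ", g, " spans multiple chromosomes or strands")
    }
    ord <- order(start0[i])
    ex <- cbind(start = start0[i][ord], end = end0[i][ord])
    if (any(ex[, 1] >= ex[, 2])) stop("empty exon in gene ", g)
    if (nrow(ex) > 1L && any(ex[-1L, 1] < ex[-nrow(ex), 2])) {
      stop("overlapping exons in gene ", g)
    }
    span <- c(min(ex[, 1]), max(ex[, 2]))
    st <- strand[i][1]
    list(gene_id = g, chrom = chrom[i][1], strand = st,
         tss = if (st == "+") span[1] else span[2],
         tes = if (st == "+") span[2] else span[1],
         exons = ex)
  })
  gene_model_table(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    tss = vapply(rows, function(r) as.integer(r$tss), 1L),
    tes = vapply(rows, function(r) as.integer(r$tes), 1L),
    exons = lapply(rows, `[[`, "exons")
  )
}

.read_bed12 <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 12L) stop("BED12 requires 12 columns, got ", ncol(tab))
  strand <- tab[[6]]
  if (!all(strand %in% c("+", "-"))) stop("unknown strand in BED12")
  exon_list <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    sizes <- as.integer(strsplit(sub(",$", "", tab[i, 11]), ",")[[1]])
    offs <- as.integer(strsplit(sub(",$", "", tab[i, 12]), ",")[[1]])
    if (length(sizes) != tab[i, 10] || length(offs) != tab[i, 10]) {
      stop("BED12 block count mismatch on line ", i)
    }
    st <- tab[i, 2] + offs
    ex <- cbind(start = st, end = st + sizes)
    if (any(ex[, 2] > tab[i, 3]) || any(ex[, 1] < tab[i, 2])) {
      stop("exon outside transcript bounds on line ", i)
    }
    exon_list[[i]] <- ex
  }
  gene_model_table(
    gene_id = as.character(tab[[4]]),
    chrom = as.character(tab[[1]]),
    strand = strand,
    tss = ifelse(strand == "+", tab[[2]], tab[[3]]),
    tes = ifelse(strand == "+", tab[[3]], tab[[2]]),
    exons = exon_list
  )
}

#' Construct a gene-model table
#'
#' Low-level constructor shared by the readers and the genome simulator.
#' Coordinates are 0-based half-open; for minus-strand genes `tss > tes`.
#'
#' @param gene_id,chrom,strand,tss,tes Per-gene vectors.
#' @param exons List of two-column matrices (`start`, `end`), sorted and
#'   non-overlapping, all within the gene span.
#' @return Validated gene-model data frame.
#' @export
gene_model_table <- function(gene_id, chrom, strand, tss, tes, exons) {
  df <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   tss = as.integer(tss), tes = as.integer(tes),
                   stringsAsFactors = FALSE)
  df$exons <- exons
  for (i in seq_len(nrow(df))) {
    lo <- min(df$tss[i], df$tes[i]); hi <- max(df$tss[i], df$tes[i])
    ex <- df$exons[[i]]
    if (any(ex[, 1] < lo) || any(ex[, 2] > hi)) {
      stop("exon outside gene span for ", df$gene_id[i])
    }
    if (df$strand[i] == "-" && df$tss[i] <= df$tes[i]) {
      stop("minus-strand gene must have tss > tes: ", df$gene_id[i])
    }
  }
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Read a Bismark-style cytosine coverage file
#'
#' Expects a TSV with columns chrom, 1-based position, strand, methylated
#' read count, unmethylated read count, context (`CpG`, `CHG`, `CHH`).
#' Positions are converted to the internal 0-based convention. No depth
#' filtering happens at parse time.
#'
#' @param path Path to the coverage TSV (no header).
#' @return Data frame with columns `chrom`, `pos` (0-based), `strand`,
#'   `meth`, `unmeth`, `context`.
#' @export
read_coverage <- function(path) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "pos1", "strand",
                                         "meth", "unmeth", "context"))
  if (!all(tab$strand %in% c("+", "-"))) stop("unknown strand token in ", path)
  if (!all(tab$context %in% c("CpG", "CHG", "CHH"))) {
    stop("unknown context token in ", path)
  }
  if (any(tab$meth < 0) || any(tab$unmeth < 0)) {
    stop("negative read counts in ", path)
  }
  if (any(tab$pos1 < 1)) stop("positions must be 1-based and positive in ", path)
  data.frame(chrom = tab$chrom, pos = as.integer(tab$pos1 - 1L),
             strand = tab$strand, meth = as.integer(tab$meth),
             unmeth = as.integer(tab$unmeth), context = tab$context,
             stringsAsFactors = FALSE)
}

#' Write a Bismark-style coverage file
#'
#' Inverse of [read_coverage()]: emits 1-based positions, tab-separated,
#' no header.
#'
#' @param records Count-record data frame (internal 0-based `pos`).
#' @param path Output path.
#' @export
write_coverage <- function(records, path) {
  out <- data.frame(records$chrom, records$pos + 1L, records$strand,
                    records$meth, records$unmeth, records$context)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write intervals as BED
#'
#' @param intervals Data frame with at least `chrom`, `start`, `end`
#'   (0-based half-open); any further columns are appended in order.
#' @param path Output path.
#' @param sorted Require input sorted by (chrom, start); error if violated.
#' @export
write_bed <- function(intervals, path, sorted = TRUE) {
  if (nrow(intervals) > 0 && sorted) {
    o <- order(intervals$chrom, intervals$start)
    if (!identical(o, seq_len(nrow(intervals)))) {
      stop("intervals must be sorted by (chrom, start) for BED output")
    }
  }
  extra <- setdiff(names(intervals), c("chrom", "start", "end"))
  out <- intervals[, c("chrom", "start", "end", extra), drop = FALSE]
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.6f", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a bedGraph track
#'
#' @param values Data frame with `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @export
write_bedgraph <- function(values, path) {
  out <- data.frame(values$chrom, values$start, values$end,
                    sprintf("%.6f", values$value))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a summary table as TSV
#'
#' Header row included; doubles rendered with fixed 6-decimal precision so
#' outputs diff reproducibly.
#'
#' @param table Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(table, path) {
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.6f", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
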