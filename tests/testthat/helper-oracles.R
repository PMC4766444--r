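# Independent brute-force oracles and tiny fixture builders used across the
# suite. These deliberately share no code with the package internals: the
# digest oracle scans character vectors position by position, the CGI
# oracle tests every window by direct counting, and the BH oracle applies
# the step-up formula literally.

random_seq <- function(n, prob = c(0.3, 0.2, 0.2, 0.3)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# naive digestion: split on N runs, scan each block for the motif at every
# offset, cut one bp in, collect pieces
naive_digest <- function(s, chrom = "chr") {
  out <- list()
  # block boundaries around N runs
  n_at <- gregexpr("N+", s)[[1]]
  if (n_at[1] == -1) {
    blocks <- data.frame(start = 0L, end = nchar(s))
  } else {
    bs <- c(0L, n_at + attr(n_at, "match.length") - 1L)
    be <- c(n_at - 1L, nchar(s))
    blocks <- data.frame(start = bs, end = be)[bs < be, , drop = FALSE]
  }
  for (bi in seq_len(nrow(blocks))) {
    b0 <- blocks$start[bi]; b1 <- blocks$end[bi]
    cuts <- integer(0)
    for (p in b0:(b1 - 4L)) {           # 0-based motif start
      if (b1 - b0 < 4L) break
      if (substr(s, p + 1L, p + 4L) == "CCGG") cuts <- c(cuts, p + 1L)
    }
    bounds <- c(b0, cuts, b1)
    for (j in seq_len(length(bounds) - 1L)) {
      st <- bounds[j]; en <- bounds[j + 1L]
      if (en > st) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = st, end = en, length = en - st,
          terminal = (st == b0 || en == b1), stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, out)
  df[order(df$start), , drop = FALSE]
}

# forward-strand CG count by direct character comparison
naive_cg_count <- function(s, start = 0L, end = nchar(s)) {
  b <- strsplit(s, "", fixed = TRUE)[[1L]]
  cnt <- 0L
  for (p in seq_len(nchar(s) - 1L)) {   # 1-based C position
    if (b[p] == "C" && b[p + 1L] == "G" && (p - 1L) >= start && (p - 1L) < end) {
      cnt <- cnt + 1L
    }
  }
  cnt
}

# brute-force CGI regions: test every 200-bp window directly, paint the bp
# covered by passing windows, take maximal runs, then re-test/trim each run
# by direct counting
naive_cgi <- function(s, min_len = 200L, min_gc = 0.5, min_oe = 0.6) {
  b <- strsplit(s, "", fixed = TRUE)[[1L]]
  L <- length(b)
  if (L < min_len) return(NULL)
  measure <- function(a, e) {           # 0-based half-open
    seg <- b[(a + 1L):e]
    gc <- mean(seg %in% c("G", "C"))
    obs <- sum(seg[-length(seg)] == "C" & seg[-1L] == "G")
    oe <- if (gc > 0) obs / ((e - a) * (gc / 2)^2) else 0
    c(gc = gc, oe = oe)
  }
  painted <- rep(FALSE, L)
  for (a in 0:(L - min_len)) {
    st <- measure(a, a + min_len)
    if (st["gc"] > min_gc && st["oe"] > min_oe) {
      painted[(a + 1L):(a + min_len)] <- TRUE
    }
  }
  if (!any(painted)) return(NULL)
  r <- rle(painted)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (k in which(r$values)) {
    a <- starts[k] - 1L; e <- ends[k]
    repeat {
      st <- measure(a, e)
      if ((e - a) > min_len && st["gc"] > min_gc && st["oe"] > min_oe) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = a, end = e, gc = st[["gc"]], oe = st[["oe"]])
        break
      }
      if ((e - a) <= min_len) break
      a <- a + 1L; e <- e - 1L
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

# literal Benjamini-Hochberg step-up
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# one-gene model on one chromosome, for hand-constructed cases
toy_gene <- function(gene_id = "g1", chrom = "c1", strand = "+",
                     start = 1000L, end = 2000L,
                     exons = cbind(start = start, end = end)) {
  gene_model_table(gene_id = gene_id, chrom = chrom, strand = strand,
                   tss = if (strand == "+") start else end,
                   tes = if (strand == "+") end else start,
                   exons = list(exons))
}

# count records straight from vectors
toy_records <- function(chrom, pos, meth, unmeth, context = "CpG",
                        strand = "+") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             meth = as.integer(meth), unmeth = as.integer(unmeth),
             context = context, stringsAsFactors = FALSE)
}

# a small deterministic genome as a DNAStringSet
toy_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}
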