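# Independent brute-force oracles used to validate the scanning algorithms.

# Position-wise six-frame ORF oracle: for every ATG, walk forward codon by
# codon to the next stop and backward to the previous breaker, and keep the
# ATG only if it is the first one in its stop-to-stop segment. Codons
# containing N break segments and cannot start or terminate an ORF.
orf_oracle_strand <- function(seq, circular, min_aa) {
  L <- nchar(seq)
  s <- if (circular) strrep(seq, 3L) else seq
  ns <- nchar(s)
  if (ns < 3L) return(NULL)
  cod <- substring(s, 1:(ns - 2L), 3:ns)
  is_stop <- cod %in% c("TAA", "TAG", "TGA")
  has_n <- grepl("N", cod, fixed = TRUE)
  is_atg <- cod == "ATG"
  out <- list()
  wrap <- function(p) if (circular) ((p - 1L) %% L) + 1L else p
  for (p in which(is_atg)) {
    # circular: use the middle copy so both walks always have context
    if (circular && (p <= L || p > 2L * L)) next
    # forward: find the terminating stop
    q <- p + 3L
    ok <- FALSE
    while (TRUE) {
      if (q + 2L > ns) break
      if (circular && (q - p) >= L) break     # span would exceed the circle
      if (has_n[q]) break
      if (is_stop[q]) { ok <- TRUE; break }
      q <- q + 3L
    }
    if (!ok) next
    aa <- (q - p) %/% 3L
    if (aa < min_aa) next
    # backward: previous breaker, and no earlier ATG in the segment
    r <- p - 3L
    first <- TRUE
    steps <- 0L
    found_boundary <- !circular  # linear: sequence start is a boundary
    while (r >= 1L) {
      if (is_stop[r] || has_n[r]) { found_boundary <- TRUE; break }
      if (is_atg[r]) { first <- FALSE; break }
      r <- r - 3L
      steps <- steps + 1L
      if (circular && steps * 3L > L) break
    }
    if (!first || !found_boundary) next
    out[[length(out) + 1L]] <- c(start = wrap(p), end = wrap(q + 2L),
                                 aa = aa)
  }
  out
}

orf_oracle <- function(genome, min_aa) {
  g <- if (inherits(genome, "circular_seq")) genome else
    circular_seq(genome)
  L <- g$length
  plus <- orf_oracle_strand(g$seq, g$circular, min_aa)
  minus <- orf_oracle_strand(revcomp(g$seq), g$circular, min_aa)
  rows <- character(0)
  for (o in plus) {
    rows <- c(rows, paste(o["start"], o["end"], "+", o["aa"]))
  }
  for (o in minus) {
    rows <- c(rows, paste(L - o["end"] + 1L, L - o["start"] + 1L, "-",
                          o["aa"]))
  }
  sort(unique(rows))
}

orf_table_key <- function(orfs) {
  sort(paste(orfs$start, orfs$end, orfs$strand, orfs$aa_count))
}

# O(n^2) longest-common-extension repeat oracle for small linear toys:
# returns TRUE iff the sequence contains two disjoint occurrences of a
# substring of at least k bp, in direct or inverted orientation.
has_repeat_oracle <- function(seq, k) {
  a <- strsplit(seq, "")[[1]]
  n <- length(a)
  lce <- function(b) {
    # M[i, j] = longest common extension of a[i..] and b[j..]
    M <- matrix(0L, n + 1L, n + 1L)
    for (i in n:1) {
      M[i, 1:n] <- ifelse(a[i] == b, M[i + 1L, 2:(n + 1L)] + 1L, 0L)
    }
    M[1:n, 1:n, drop = FALSE]
  }
  Md <- lce(a)
  hit <- which(Md >= k, arr.ind = TRUE)
  if (any(hit[, 1] != hit[, 2])) return(TRUE)
  rc <- rev(chartr("ACGT", "TGCA", a))
  Mi <- lce(rc)
  hit <- which(Mi >= k, arr.ind = TRUE)
  for (r in seq_len(nrow(hit))) {
    i <- hit[r, 1]; j <- hit[r, 2]; l <- Mi[i, j]
    gj <- n - j - l + 2L           # genome start of the inverted image
    if ((i + l - 1L < gj) || (gj + l - 1L < i)) return(TRUE)
  }
  FALSE
}
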