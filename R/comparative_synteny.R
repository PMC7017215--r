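circ_kmers <- function(seq, k, circular) {
  L <- nchar(seq)
  if (circular) {
    s <- paste0(seq, substr(seq, 1L, k - 1L))
    n <- L
  } else {
    s <- seq
    n <- L - k + 1L
    if (n < 1L) return(character(0))
  }
  substring(s, seq_len(n), seq_len(n) + k - 1L)
}

revcomp_vec <- function(kmers) {
  if (length(kmers) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
}

# group matched k-mer position pairs into maximal co-diagonal runs
runs_from_pairs <- function(i, j, inverted = FALSE) {
  if (length(i) == 0L) {
    return(tibble::tibble(i0 = integer(0), i1 = integer(0),
                          j0 = integer(0), j1 = integer(0)))
  }
  diag <- if (inverted) i + j else j - i
  ord <- order(diag, i)
  i <- i[ord]; j <- j[ord]; diag <- diag[ord]
  new_run <- c(TRUE, diff(i) != 1L | diff(diag) != 0L)
  run_id <- cumsum(new_run)
  tibble::tibble(
    i0 = tapply(i, run_id, min), i1 = tapply(i, run_id, max),
    j0 = tapply(j, run_id, min), j1 = tapply(j, run_id, max)
  )
}

#' Find unique exact match anchors between two genomes
#'
#' Reports maximal exact matches of at least `min_len` bp whose sequence
#' occurs exactly once in each genome (counting both strands), on both
#' orientations and wrap-aware on circular genomes. These play the role of
#' MUM-style anchors for syntenic-block chaining.
#'
#' @param genome_a,genome_b [circular_seq()] objects or character scalars.
#' @param min_len Minimum anchor length, bp.
#' @return Tibble with `start_a`, `end_a`, `start_b`, `end_b` (1-based
#'   inclusive, leftmost plus-strand coordinates; `end < start` marks an
#'   origin wrap), `length` and `orientation` (`"forward"`/`"inverted"`),
#'   sorted by `start_a`.
#' @export
find_anchors <- function(genome_a, genome_b, min_len = 100) {
  ga <- as_circseq(genome_a); gb <- as_circseq(genome_b)
  k <- as.integer(min_len)
  La <- ga$length; Lb <- gb$length
  ka <- circ_kmers(ga$seq, k, ga$circular)
  kb <- circ_kmers(gb$seq, k, gb$circular)
  rb <- revcomp(gb$seq)
  kbr <- circ_kmers(rb, k, gb$circular)
  # a k-mer is unique in a genome when it occurs once counting both strands:
  # occurrences(kmer) + occurrences(revcomp(kmer)) == 1 on the fwd strand
  cnt_b_fwd <- table(kb)
  cnt_in_b <- function(x) {
    f <- cnt_b_fwd[x]; f[is.na(f)] <- 0L
    r <- cnt_b_fwd[revcomp_vec(x)]; r[is.na(r)] <- 0L
    as.integer(f) + as.integer(r)
  }
  cnt_a_fwd <- table(ka)
  cnt_in_a <- function(x) {
    f <- cnt_a_fwd[x]; f[is.na(f)] <- 0L
    r <- cnt_a_fwd[revcomp_vec(x)]; r[is.na(r)] <- 0L
    as.integer(f) + as.integer(r)
  }
  uniq_a <- cnt_in_a(ka) == 1L
  idx_a <- which(uniq_a)
  if (length(idx_a) == 0L) return(empty_anchors())
  sel_ka <- ka[idx_a]
  keep <- cnt_in_b(sel_ka) == 1L
  idx_a <- idx_a[keep]
  sel_ka <- sel_ka[keep]
  if (length(idx_a) == 0L) return(empty_anchors())
  mf <- match(sel_ka, kb)
  mr <- match(sel_ka, kbr)
  fwd <- runs_from_pairs(idx_a[!is.na(mf)], mf[!is.na(mf)])
  inv_rc <- runs_from_pairs(idx_a[!is.na(mr)], mr[!is.na(mr)])
  anchors <- list()
  if (nrow(fwd)) {
    anchors[[1]] <- tibble::tibble(
      start_a = as.integer(fwd$i0), end_a = as.integer(fwd$i1 + k - 1L),
      start_b = as.integer(fwd$j0), end_b = as.integer(fwd$j1 + k - 1L),
      length = as.integer(fwd$i1 - fwd$i0 + k),
      orientation = "forward")
  }
  if (nrow(inv_rc)) {
    # run coordinates on revcomp(B); map back to plus strand of B
    anchors[[2]] <- tibble::tibble(
      start_a = as.integer(inv_rc$i0), end_a = as.integer(inv_rc$i1 + k - 1L),
      start_b = as.integer(Lb - (inv_rc$j1 + k - 1L) + 1L),
      end_b = as.integer(Lb - inv_rc$j0 + 1L),
      length = as.integer(inv_rc$i1 - inv_rc$i0 + k),
      orientation = "inverted")
  }
  out <- dplyr::bind_rows(anchors)
  if (nrow(out) == 0L) return(empty_anchors())
  out <- merge_wrap_anchors(out, La, Lb, k)
  out$start_a <- ((out$start_a - 1L) %% La) + 1L
  out$end_a <- ((out$end_a - 1L) %% La) + 1L
  out$start_b <- ((out$start_b - 1L) %% Lb) + 1L
  out$end_b <- ((out$end_b - 1L) %% Lb) + 1L
  dplyr::arrange(out, .data$start_a)
}

empty_anchors <- function() {
  tibble::tibble(start_a = integer(0), end_a = integer(0),
                 start_b = integer(0), end_b = integer(0),
                 length = integer(0), orientation = character(0))
}

# Join anchor runs that continue across the circular origin of genome A.
# Coordinates here are un-modded: a run over k-mer positions [i0, i1]
# (i1 <= La) spans nucleotides [i0, i1 + k - 1]; the two nucleotide
# intervals of adjoining runs overlap by k - 1 bases.
merge_wrap_anchors <- function(anchors, La, Lb, k) {
  nxt <- function(j, L) (((j - 1L) %% L) %% L) + 1L
  repeat {
    merged <- FALSE
    tails <- which(anchors$end_a - k + 1L == La)
    heads <- which(anchors$start_a == 1L)
    for (ti in tails) {
      for (hi in heads) {
        if (ti == hi) next
        if (anchors$orientation[ti] != anchors$orientation[hi]) next
        if (anchors$orientation[ti] == "forward") {
          j_t <- ((anchors$end_b[ti] - k) %% Lb) + 1L  # tail's last k-mer
          cont <- (j_t %% Lb) + 1L == anchors$start_b[hi]
        } else {
          bot_t <- ((anchors$start_b[ti] - 1L) %% Lb) + 1L
          top_h <- ((anchors$end_b[hi] - k) %% Lb) + 1L
          cont <- ((bot_t - 2L) %% Lb) + 1L == top_h
        }
        if (!cont) next
        new_len <- anchors$length[ti] + anchors$length[hi] - k + 1L
        anchors$length[ti] <- new_len
        anchors$end_a[ti] <- anchors$start_a[ti] + new_len - 1L
        if (anchors$orientation[ti] == "forward") {
          anchors$end_b[ti] <- anchors$start_b[ti] + new_len - 1L
        } else {
          anchors$start_b[ti] <- anchors$end_b[ti] - new_len + 1L
        }
        anchors <- anchors[-hi, , drop = FALSE]
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  # a full-circle match caps at the genome length
  cap <- min(La, Lb)
  over <- which(anchors$length > cap)
  for (i in over) {
    anchors$length[i] <- cap
    anchors$end_a[i] <- anchors$start_a[i] + cap - 1L
    if (anchors$orientation[i] == "forward") {
      anchors$end_b[i] <- anchors$start_b[i] + cap - 1L
    } else {
      anchors$start_b[i] <- anchors$end_b[i] - cap + 1L
    }
  }
  anchors
}

#' Chain anchors into syntenic blocks
#'
#' Co-oriented anchors with consistent diagonal offsets (within `diag_tol`
#' bp, absorbing small indels) and inter-anchor gaps of at most `max_gap` bp
#' are chained greedily in genome-A order; chains spanning less than
#' `min_block` bp are discarded, and among conflicting overlapping chains
#' the longer wins.
#'
#' @param anchors Tibble from [find_anchors()].
#' @param len_a,len_b Genome lengths.
#' @param max_gap Maximum gap between chained anchors, bp.
#' @param min_block Minimum block span, bp.
#' @param diag_tol Maximum drift of the diagonal offset within a chain, bp.
#' @param max_overlap Maximum overlap allowed between chained anchors, bp
#'   (same-diagonal anchors may overlap by up to the anchor seed length
#'   around short duplicated stretches).
#' @return Tibble of blocks: `block_id`, `start_a`, `end_a`, `start_b`,
#'   `end_b`, `orientation`, `anchors` (count), `matched_bp`, `identity`,
#'   plus a list-column `members` holding each block's anchors.
#' @export
chain_blocks <- function(anchors, len_a, len_b, max_gap = 2000,
                         min_block = 500, diag_tol = 30,
                         max_overlap = 100) {
  if (nrow(anchors) == 0L) return(empty_blocks())
  a <- dplyr::arrange(anchors, .data$start_a)
  n <- nrow(a)
  chain_id <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (i == 1L) { cur <- 1L; chain_id[i] <- cur; next }
    p <- i - 1L
    same <- a$orientation[i] == a$orientation[p]
    gap_a <- a$start_a[i] - a$end_a[p] - 1L
    if (a$orientation[i] == "forward") {
      gap_b <- a$start_b[i] - a$end_b[p] - 1L
    } else {
      gap_b <- a$start_b[p] - a$end_b[i] - 1L
    }
    ok <- same && gap_a >= -max_overlap && gap_a <= max_gap &&
      gap_b >= -max_overlap && gap_b <= max_gap &&
      abs(gap_a - gap_b) <= diag_tol
    if (ok) chain_id[i] <- cur else { cur <- cur + 1L; chain_id[i] <- cur }
  }
  blocks <- lapply(split(seq_len(n), chain_id), function(idx) {
    m <- a[idx, , drop = FALSE]   # already in genome-A order
    fwd <- m$orientation[1] == "forward"
    tibble::tibble(
      start_a = m$start_a[1], end_a = m$end_a[nrow(m)],
      start_b = if (fwd) m$start_b[1] else m$start_b[nrow(m)],
      end_b = if (fwd) m$end_b[nrow(m)] else m$end_b[1],
      orientation = m$orientation[1],
      anchors = nrow(m),
      matched_bp = sum(m$length),
      members = list(m)
    )
  })
  blocks <- dplyr::bind_rows(blocks)
  # join first and last chain across the circular origin of genome A
  if (nrow(blocks) > 1L) {
    f <- 1L; l <- nrow(blocks)
    gap_a <- (blocks$start_a[f] - blocks$end_a[l] - 1L) %% len_a
    same <- blocks$orientation[f] == blocks$orientation[l]
    if (blocks$orientation[f] == "forward") {
      gap_b <- (blocks$start_b[f] - blocks$end_b[l] - 1L) %% len_b
    } else {
      gap_b <- (blocks$start_b[l] - blocks$end_b[f] - 1L) %% len_b
    }
    if (same && gap_a <= max_gap && gap_b <= max_gap &&
        abs(gap_a - gap_b) <= diag_tol) {
      blocks$start_a[f] <- blocks$start_a[l]
      if (blocks$orientation[f] == "forward") {
        blocks$start_b[f] <- blocks$start_b[l]
      } else {
        blocks$end_b[f] <- blocks$end_b[l]
      }
      blocks$anchors[f] <- blocks$anchors[f] + blocks$anchors[l]
      blocks$matched_bp[f] <- blocks$matched_bp[f] + blocks$matched_bp[l]
      blocks$members[[f]] <- dplyr::bind_rows(blocks$members[[l]],
                                              blocks$members[[f]])
      blocks <- blocks[-l, , drop = FALSE]
    }
  }
  blocks$span_a <- interval_span(blocks$start_a, blocks$end_a, len_a)
  blocks$span_b <- interval_span(blocks$start_b, blocks$end_b, len_b)
  blocks <- dplyr::filter(blocks, .data$span_a >= min_block)
  if (nrow(blocks) == 0L) return(empty_blocks())
  blocks$identity <- pmin(1, blocks$matched_bp / blocks$span_a)
  blocks <- dplyr::arrange(blocks, .data$start_a)
  blocks$block_id <- seq_len(nrow(blocks))
  dplyr::relocate(blocks, "block_id")
}

empty_blocks <- function() {
  tibble::tibble(block_id = integer(0), start_a = integer(0),
                 end_a = integer(0), start_b = integer(0),
                 end_b = integer(0), orientation = character(0),
                 anchors = integer(0), matched_bp = integer(0),
                 members = list(), span_a = integer(0), span_b = integer(0),
                 identity = numeric(0))
}

# complement of a set of (possibly wrapping) intervals on a circle
circle_complement <- function(starts, ends, len) {
  if (length(starts) == 0L) {
    return(tibble::tibble(start = 1L, end = len))
  }
  covered <- rep(FALSE, len)
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i]
    if (e >= s) covered[s:e] <- TRUE else covered[c(s:len, 1:e)] <- TRUE
  }
  free <- which(!covered)
  if (length(free) == 0L) {
    return(tibble::tibble(start = integer(0), end = integer(0)))
  }
  runs <- split(free, cumsum(c(1L, diff(free) != 1L)))
  out <- tibble::tibble(
    start = unname(vapply(runs, min, integer(1))),
    end = unname(vapply(runs, max, integer(1)))
  )
  # join the run touching position `len` with the run touching position 1
  if (nrow(out) > 1L && out$start[1] == 1L && out$end[nrow(out)] == len) {
    out$start[1] <- out$start[nrow(out)]
    out <- out[-nrow(out), , drop = FALSE]
  }
  out
}

#' Regions of one genome not covered by any syntenic block
#'
#' @param genome_len Genome length.
#' @param blocks Block tibble from [chain_blocks()].
#' @param which `"a"` or `"b"`: which genome's coordinates to use.
#' @param min_unique_len Minimum reported region length, bp.
#' @return Tibble `start`, `end`, `length` (1-based inclusive, wrap-aware).
#' @export
unique_regions <- function(genome_len, blocks, which = "a",
                           min_unique_len = 200) {
  s <- if (which == "a") blocks$start_a else blocks$start_b
  e <- if (which == "a") blocks$end_a else blocks$end_b
  comp <- circle_complement(s, e, genome_len)
  comp$length <- interval_span(comp$start, comp$end, genome_len)
  dplyr::filter(comp, .data$length >= min_unique_len)
}

longest_increasing_subsequence <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  best <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (x[j] < x[i] && best[j] + 1L > best[i]) {
        best[i] <- best[j] + 1L
        prev[i] <- j
      }
    }
  }
  i <- which.max(best)
  out <- integer(0)
  while (i > 0L) { out <- c(i, out); i <- prev[i] }
  out
}

#' Classify each syntenic block's rearrangement type
#'
#' Blocks are ordered along genome A; after a circular rotation that aligns
#' the largest block between the two genomes (flipping the frame when that
#' block is inverted), blocks on the longest order-preserving backbone are
#' collinear (forward) or inversions (inverted in place), and the rest are
#' translocations or translocation + inversion.
#'
#' @param blocks Block tibble from [chain_blocks()].
#' @return The tibble with a `class` column, plus a `summary` attribute of
#'   per-class counts.
#' @export
classify_rearrangements <- function(blocks) {
  n <- nrow(blocks)
  if (n == 0L) {
    attr(blocks, "summary") <- c(collinear = 0L, inversion = 0L,
                                 translocation = 0L,
                                 `translocation+inversion` = 0L)
    return(blocks)
  }
  b <- dplyr::arrange(blocks, .data$start_a)
  ranks <- rank(b$start_b, ties.method = "first")
  big <- which.max(b$span_a)
  flip <- b$orientation[big] == "inverted"
  eff_orient <- b$orientation
  if (flip) {
    ranks <- n + 1L - ranks
    eff_orient <- ifelse(b$orientation == "inverted", "forward", "inverted")
  }
  # rotate A order so the largest block comes first, and B ranks so its
  # rank is 1
  ord <- c(big:n, seq_len(big - 1L))
  r <- ((ranks[ord] - ranks[big]) %% n) + 1L
  lis <- longest_increasing_subsequence(r)
  in_backbone <- rep(FALSE, n)
  in_backbone[ord[lis]] <- TRUE
  cls <- character(n)
  for (i in seq_len(n)) {
    fwd <- eff_orient[i] == "forward"
    cls[i] <- if (in_backbone[i] && fwd) "collinear"
      else if (in_backbone[i]) "inversion"
      else if (fwd) "translocation"
      else "translocation+inversion"
  }
  b$class <- cls
  out <- b[match(blocks$block_id, b$block_id), , drop = FALSE]
  attr(out, "summary") <- c(
    collinear = sum(cls == "collinear"),
    inversion = sum(cls == "inversion"),
    translocation = sum(cls == "translocation"),
    `translocation+inversion` = sum(cls == "translocation+inversion")
  )
  out
}

is_homopolymer_context <- function(genome, pos, len = 5L) {
  g <- as_circseq(genome)
  L <- g$length
  s <- ((pos - 3L - 1L) %% L) + 1L
  e <- ((pos + 3L - 1L) %% L) + 1L
  ctx <- extract_subseq(g, s, e)
  any(vapply(c("A", "T", "G", "C"), function(b) {
    grepl(strrep(b, len), ctx, fixed = TRUE)
  }, logical(1)))
}

#' Call variants between two genomes within syntenic blocks
#'
#' Inter-anchor gaps inside each block are inspected: equal-length gaps are
#' compared base by base (substitutions), unequal-length gaps are aligned
#' globally (match +1, mismatch -1, gap -2) yielding substitutions and
#' indels. Inverted blocks are compared in the genome-A reading frame.
#' Variants falling inside annotated CDS features are mapped to CDS
#' coordinates and classified with [classify_effect()]. Indels flanked by a
#' homopolymer 5-mer are marked, reflecting their usual sequencing-bias
#' origin in mitogenome comparisons.
#'
#' @param blocks Block tibble from [chain_blocks()] (with `members`).
#' @param genome_a,genome_b The two genomes.
#' @param annotations Annotation tibble for the reference genome.
#' @param annotation_genome `"a"` or `"b"`: which genome the annotations
#'   (and hence `ref`/`cds_pos`/`effect`) refer to.
#' @return Tibble: `pos_a`, `pos_b`, `ref`, `alt`, `type`
#'   (`snp`/`insertion`/`deletion`), `gene_id`, `cds_pos`, `effect`,
#'   `homopolymer`.
#' @export
call_variants <- function(blocks, genome_a, genome_b, annotations = NULL,
                          annotation_genome = "b") {
  ga <- as_circseq(genome_a); gb <- as_circseq(genome_b)
  rows <- list()
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1)
  for (bi in seq_len(nrow(blocks))) {
    m <- blocks$members[[bi]]
    m <- dplyr::arrange(m, .data$start_a)
    inv <- blocks$orientation[bi] == "inverted"
    if (nrow(m) < 2L) next
    for (i in seq_len(nrow(m) - 1L)) {
      a_s <- m$end_a[i] + 1L; a_e <- m$start_a[i + 1L] - 1L
      if (a_e < a_s) next
      if (inv) {
        b_s <- m$end_b[i + 1L] + 1L; b_e <- m$start_b[i] - 1L
      } else {
        b_s <- m$end_b[i] + 1L; b_e <- m$start_b[i + 1L] - 1L
      }
      seq_a <- substr(ga$seq, a_s, a_e)
      len_b_gap <- b_e - b_s + 1L
      seq_b <- if (len_b_gap >= 1L) {
        x <- substr(gb$seq, b_s, b_e)
        if (inv) revcomp(x) else x
      } else ""
      la <- nchar(seq_a); lb <- nchar(seq_b)
      if (la > 0L && lb == 0L) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          pos_a = a_s, pos_b = if (inv) b_s else b_s - 1L,
          ref = seq_a, alt = "-", type = "deletion", inverted = inv)
      } else if (la == 0L && lb > 0L) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          pos_a = a_s - 1L, pos_b = b_s,
          ref = "-", alt = if (inv) revcomp(seq_b) else seq_b,
          type = "insertion", inverted = inv)
      } else if (la == lb && la > 0L) {
        ca <- strsplit(seq_a, "")[[1]]; cb <- strsplit(seq_b, "")[[1]]
        for (p in which(ca != cb)) {
          pos_a <- a_s + p - 1L
          pos_b <- if (inv) b_e - p + 1L else b_s + p - 1L
          # alleles are reported on each genome's plus strand
          rows[[length(rows) + 1L]] <- tibble::tibble(
            pos_a = pos_a, pos_b = pos_b, ref = ca[p],
            alt = if (inv) comp_base(cb[p]) else cb[p],
            type = "snp", inverted = inv)
        }
      } else {
        aln <- Biostrings::pairwiseAlignment(
          pattern = seq_a, subject = seq_b, type = "global",
          substitutionMatrix = submat, gapOpening = 0, gapExtension = 2)
        pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
        pb <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
        ia <- a_s - 1L
        ib0 <- 0L  # offset within seq_b (A-frame orientation)
        col <- 1L
        while (col <= length(pa)) {
          if (pa[col] != "-" && pb[col] != "-") {
            ia <- ia + 1L; ib0 <- ib0 + 1L
            if (pa[col] != pb[col]) {
              rows[[length(rows) + 1L]] <- tibble::tibble(
                pos_a = ia,
                pos_b = if (inv) b_e - ib0 + 1L else b_s + ib0 - 1L,
                ref = pa[col], alt = pb[col], type = "snp")
            }
            col <- col + 1L
          } else if (pb[col] == "-") {
            # deletion in B relative to A
            del <- character(0)
            while (col <= length(pa) && pb[col] == "-") {
              ia <- ia + 1L; del <- c(del, pa[col]); col <- col + 1L
            }
            rows[[length(rows) + 1L]] <- tibble::tibble(
              pos_a = ia - length(del) + 1L,
              pos_b = if (inv) b_e - ib0 + 1L else b_s + ib0 - 1L,
              ref = paste(del, collapse = ""), alt = "-",
              type = "deletion", inverted = inv)
          } else {
            ins <- character(0)
            while (col <= length(pa) && pa[col] == "-") {
              ib0 <- ib0 + 1L; ins <- c(ins, pb[col]); col <- col + 1L
            }
            ins_seq <- paste(ins, collapse = "")
            rows[[length(rows) + 1L]] <- tibble::tibble(
              pos_a = ia,
              pos_b = if (inv) b_e - ib0 + 1L else b_s + ib0 - 1L,
              ref = "-", alt = if (inv) revcomp(ins_seq) else ins_seq,
              type = "insertion", inverted = inv)
          }
        }
      }
    }
  }
  vars <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(pos_a = integer(0), pos_b = integer(0),
                   ref = character(0), alt = character(0),
                   type = character(0), inverted = logical(0))
  }
  vars$gene_id <- NA_character_
  vars$cds_pos <- NA_integer_
  vars$effect <- NA_character_
  vars$homopolymer <- FALSE
  if (nrow(vars) == 0L) return(vars)
  ref_genome <- if (annotation_genome == "a") ga else gb
  ref_pos <- if (annotation_genome == "a") vars$pos_a else vars$pos_b
  ref_allele <- if (annotation_genome == "a") vars$ref else vars$alt
  # the other genome's allele, expressed in the annotated genome's
  # plus-strand frame (inverted blocks flip the strand of homology)
  alt_allele <- if (annotation_genome == "a") vars$alt else vars$ref
  flip <- vars$inverted & vars$type == "snp"
  alt_allele[flip] <- vapply(alt_allele[flip], comp_base, character(1),
                             USE.NAMES = FALSE)
  for (v in seq_len(nrow(vars))) {
    if (vars$type[v] != "snp") {
      indel_len <- max(nchar(vars$ref[v]), nchar(vars$alt[v]))
      vars$homopolymer[v] <- is_homopolymer_context(ga, vars$pos_a[v])
      vars$effect[v] <- if (indel_len %% 3L != 0L) "frameshift"
        else "inframe_indel"
      next
    }
    if (is.null(annotations) || nrow(annotations) == 0L) {
      vars$effect[v] <- "intergenic"
      next
    }
    cds <- annotations[annotations$feature == "CDS", , drop = FALSE]
    hit <- which(point_in_interval(ref_pos[v], cds$start, cds$end,
                                   ref_genome$length))
    if (length(hit) == 0L) {
      vars$effect[v] <- "intergenic"
      next
    }
    hit <- hit[1]
    gstrand <- cds$strand[hit]
    if (gstrand == "+") {
      cpos <- ref_pos[v] - cds$start[hit] + 1L
      r <- ref_allele[v]; aalt <- alt_allele[v]
    } else {
      cpos <- cds$end[hit] - ref_pos[v] + 1L
      r <- revcomp(ref_allele[v]); aalt <- revcomp(alt_allele[v])
    }
    gene_cds <- extract_subseq(ref_genome, cds$start[hit], cds$end[hit],
                               gstrand)
    vars$gene_id[v] <- cds$gene_id[hit]
    vars$cds_pos[v] <- as.integer(cpos)
    vars$effect[v] <- classify_effect(gene_cds, cpos, r, aalt)
  }
  vars
}

#' Classify the coding effect of a variant inside a CDS
#'
#' Substitutes the alternate base at the given CDS position, translates the
#' affected codon with the standard genetic code, and reports
#' `"synonymous"` or an amino-acid change written `"X-Y"` (reference
#' residue, then alternate). Indel alleles (`ref`/`alt` of different
#' lengths, `-` for absence) are classified as `"frameshift"` when the
#' length difference is not a multiple of 3, otherwise `"inframe_indel"`.
#'
#' @param gene_cds CDS nucleotide sequence (length divisible by 3), read
#'   5' to 3'.
#' @param cds_pos 1-based position from the start codon.
#' @param ref,alt Reference and alternate alleles on the CDS strand.
#' @return Effect string.
#' @export
classify_effect <- function(gene_cds, cds_pos, ref, alt) {
  if (identical(ref, alt)) stop("ref and alt alleles are identical",
                                call. = FALSE)
  ref_len <- if (ref == "-") 0L else nchar(ref)
  alt_len <- if (alt == "-") 0L else nchar(alt)
  if (ref_len != alt_len) {
    return(if (abs(ref_len - alt_len) %% 3L != 0L) "frameshift"
           else "inframe_indel")
  }
  if (nchar(gene_cds) %% 3L != 0L) {
    stop("gene_cds length is not divisible by 3", call. = FALSE)
  }
  if (cds_pos < 1L || cds_pos + ref_len - 1L > nchar(gene_cds)) {
    stop("cds_pos outside the CDS", call. = FALSE)
  }
  if (substr(gene_cds, cds_pos, cds_pos + ref_len - 1L) != ref) {
    stop(sprintf("reference allele mismatch at CDS position %d", cds_pos),
         call. = FALSE)
  }
  mutated <- paste0(substr(gene_cds, 1L, cds_pos - 1L), alt,
                    substr(gene_cds, cds_pos + ref_len,
                           nchar(gene_cds)))
  codon_i <- (cds_pos - 1L) %/% 3L
  cstart <- codon_i * 3L + 1L
  ref_codon <- substr(gene_cds, cstart, cstart + 2L)
  alt_codon <- substr(mutated, cstart, cstart + 2L)
  aa_ref <- unname(Biostrings::GENETIC_CODE[ref_codon])
  aa_alt <- unname(Biostrings::GENETIC_CODE[alt_codon])
  if (identical(aa_ref, aa_alt)) "synonymous" else paste0(aa_ref, "-", aa_alt)
}

#' Full synteny decomposition of two circular genomes
#'
#' Convenience wrapper: anchors, blocks, rearrangement classes and unique
#' regions for both genomes.
#'
#' @inheritParams find_anchors
#' @inheritParams chain_blocks
#' @inheritParams unique_regions
#' @return List with `anchors`, `blocks` (classified), `unique_a`,
#'   `unique_b`, `len_a`, `len_b`.
#' @export
synteny_decompose <- function(genome_a, genome_b, min_len = 100,
                              max_gap = 2000, min_block = 500,
                              diag_tol = 30, min_unique_len = 200) {
  ga <- as_circseq(genome_a); gb <- as_circseq(genome_b)
  anchors <- find_anchors(ga, gb, min_len = min_len)
  blocks <- chain_blocks(anchors, ga$length, gb$length, max_gap = max_gap,
                         min_block = min_block, diag_tol = diag_tol,
                         max_overlap = max(min_len, diag_tol))
  blocks <- classify_rearrangements(blocks)
  list(
    anchors = anchors,
    blocks = blocks,
    unique_a = unique_regions(ga$length, blocks, "a", min_unique_len),
    unique_b = unique_regions(gb$length, blocks, "b", min_unique_len),
    len_a = ga$length, len_b = gb$length
  )
}
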