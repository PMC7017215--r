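#' Find exact repeat families in a genome
#'
#' Detects maximal exact repeats of at least `min_len` bp with two or more
#' copies, in direct and inverted orientation, wrap-aware on circular
#' genomes. Copies carrying identical (up to strand) sequence are grouped
#' into families; short families are named `R1`, `R2`, ... by descending
#' unit length and families longer than 1 kb are reported as large repeats,
#' following the usual presentation of plant mitogenome repeat tables.
#'
#' @param genome A [circular_seq()] or character scalar.
#' @param min_len Minimum repeat unit length, bp.
#' @return Tibble with one row per copy: `family_id`, `unit_length`,
#'   `size_class` (`"large"` > 1000 bp, else `"short"`), `copy`, `start`,
#'   `end`, `strand`.
#' @export
find_repeats <- function(genome, min_len = 80) {
  g <- as_circseq(genome)
  L <- g$length
  k <- as.integer(min_len)
  empty <- tibble::tibble(family_id = character(0), unit_length = integer(0),
                          size_class = character(0), copy = integer(0),
                          start = integer(0), end = integer(0),
                          strand = character(0))
  if (L < k) return(empty)
  km <- circ_kmers(g$seq, k, g$circular)
  n <- length(km)
  rc <- revcomp_vec(km)
  cnt <- table(km)
  tot <- as.integer(cnt[km])
  rc_cnt <- cnt[rc]
  rc_cnt[is.na(rc_cnt)] <- 0L
  tot <- tot + as.integer(rc_cnt)
  multi <- which(tot >= 2L & !(km == rc & tot <= 2L))
  if (length(multi) == 0L) return(empty)
  by_kmer <- split(multi, km[multi])
  pairs_d <- list(); pairs_i <- list()
  for (i in multi) {
    same <- by_kmer[[km[i]]]
    js <- same[same > i]
    if (length(js)) pairs_d[[length(pairs_d) + 1L]] <-
        cbind(i = rep(i, length(js)), j = js)
    opp <- by_kmer[[rc[i]]]
    if (!is.null(opp)) {
      js2 <- opp[opp >= i & opp != i]
      if (km[i] == rc[i]) js2 <- opp[opp > i]
      if (length(js2)) pairs_i[[length(pairs_i) + 1L]] <-
          cbind(i = rep(i, length(js2)), j = js2)
    }
  }
  fam_rows <- list()
  add_pairs <- function(mat, inverted) {
    if (is.null(mat) || nrow(mat) == 0L) return(invisible())
    runs <- runs_from_pairs(mat[, "i"], mat[, "j"], inverted = inverted)
    for (r in seq_len(nrow(runs))) {
      i0 <- runs$i0[r]; i1 <- runs$i1[r]
      len <- as.integer(i1 - i0 + k)
      j_start <- runs$j0[r]
      j_end <- runs$j0[r] + len - 1L
      fam_rows[[length(fam_rows) + 1L]] <<- tibble::tibble(
        s1 = as.integer(i0), e1 = as.integer(i0 + len - 1L),
        s2 = as.integer(j_start), e2 = as.integer(j_end),
        len = len, inverted = inverted)
    }
  }
  add_pairs(do.call(rbind, pairs_d), FALSE)
  add_pairs(do.call(rbind, pairs_i), TRUE)
  if (length(fam_rows) == 0L) return(empty)
  pr <- dplyr::bind_rows(fam_rows)
  # group maximal match pairs into families by canonical unit sequence
  pr$seq1 <- vapply(seq_len(nrow(pr)), function(i) {
    extract_subseq(g, ((pr$s1[i] - 1L) %% L) + 1L,
                   ((pr$e1[i] - 1L) %% L) + 1L)
  }, character(1))
  pr$canon <- vapply(pr$seq1, function(s) min(s, revcomp(s)), character(1),
                     USE.NAMES = FALSE)
  fams <- split(pr, pr$canon)
  fam_list <- lapply(fams, function(f) {
    cps <- list()
    for (i in seq_len(nrow(f))) {
      cps[[length(cps) + 1L]] <- c(f$s1[i], f$e1[i], 0L)
      cps[[length(cps) + 1L]] <- c(f$s2[i], f$e2[i],
                                   if (f$inverted[i]) 1L else 0L)
    }
    m <- unique(do.call(rbind, cps))
    tibble::tibble(
      unit_length = f$len[1],
      start = as.integer(((m[, 1] - 1L) %% L) + 1L),
      end = as.integer(((m[, 2] - 1L) %% L) + 1L),
      strand = ifelse(m[, 3] == 1L, "-", "+")
    )
  })
  # drop a family whose copies are all contained in a longer family's copies
  unit_lens <- vapply(fam_list, function(f) f$unit_length[1], integer(1))
  ord <- order(-unit_lens)
  fam_list <- fam_list[ord]
  contained <- rep(FALSE, length(fam_list))
  within_copy <- function(f, s, e) {
    any(f$start <= s & f$end >= e)
  }
  for (i in seq_along(fam_list)) {
    if (i == 1L) next
    f <- fam_list[[i]]
    for (j in seq_len(i - 1L)) {
      if (contained[j]) next
      if (all(vapply(seq_len(nrow(f)), function(r) {
        within_copy(fam_list[[j]], f$start[r], f$end[r])
      }, logical(1)))) {
        contained[i] <- TRUE
        break
      }
    }
  }
  fam_list <- fam_list[!contained]
  lens <- vapply(fam_list, function(f) f$unit_length[1], integer(1))
  large <- lens > 1000L
  ids <- character(length(fam_list))
  ids[large] <- if (sum(large) == 1L) "Large repeat" else
    paste0("Large repeat ", seq_len(sum(large)))
  ids[!large] <- paste0("R", seq_len(sum(!large)))
  out <- dplyr::bind_rows(lapply(seq_along(fam_list), function(i) {
    f <- fam_list[[i]]
    f <- dplyr::arrange(f, .data$start)
    tibble::tibble(family_id = ids[i], unit_length = f$unit_length,
                   size_class = if (large[i]) "large" else "short",
                   copy = seq_len(nrow(f)), start = f$start, end = f$end,
                   strand = f$strand)
  }))
  out
}

#' Associate repeat copies with syntenic-block junctions
#'
#' A repeat copy hits a junction when its interval comes within `tolerance`
#' bp (circular distance) of a block boundary on the repeats' genome.
#'
#' @param repeats Tibble from [find_repeats()].
#' @param blocks Block tibble from [chain_blocks()].
#' @param genome_len Length of the repeats' genome.
#' @param tolerance Distance tolerance, bp.
#' @param which `"a"` or `"b"`: which block coordinates lie on the repeats'
#'   genome.
#' @return The repeat tibble with `junction_hits` (list of boundary labels)
#'   and logical `at_junction` per copy.
#' @export
associate_junctions <- function(repeats, blocks, genome_len,
                                tolerance = 200, which = "a") {
  s <- if (which == "a") blocks$start_a else blocks$start_b
  e <- if (which == "a") blocks$end_a else blocks$end_b
  bounds <- tibble::tibble(
    pos = c(s, e),
    label = c(paste0("block", blocks$block_id, ":start"),
              paste0("block", blocks$block_id, ":end"))
  )
  repeats$junction_hits <- vector("list", nrow(repeats))
  repeats$at_junction <- FALSE
  for (i in seq_len(nrow(repeats))) {
    rs <- repeats$start[i]; re <- repeats$end[i]
    inside <- point_in_interval(bounds$pos, rs, re, genome_len)
    d <- pmin(circular_distance(bounds$pos, rs, genome_len),
              circular_distance(bounds$pos, re, genome_len))
    d[inside] <- 0L
    hit <- which(d <= tolerance)
    repeats$junction_hits[[i]] <- bounds$label[hit]
    repeats$at_junction[i] <- length(hit) > 0L
  }
  repeats
}

## ---- signed-circle algebra -------------------------------------------

seg_name <- function(x) sub("^-", "", x)
seg_flip <- function(x) ifelse(grepl("^-", x), sub("^-", "", x),
                               paste0("-", x))

rotate_vec <- function(x, i) {
  n <- length(x)
  if (n == 0L || i == 1L) return(x)
  c(x[i:n], x[seq_len(i - 1L)])
}

reflect_circle <- function(x) rev(seg_flip(x))

#' Canonical form of a signed block circle
#'
#' Circles are identified up to rotation and reflection (a flipped circle is
#' the same double-stranded molecule); the canonical form is the
#' lexicographically minimal rotation over both representations.
#'
#' @param x Character vector of signed segment labels (e.g.
#'   `c("1", "R", "-3")`).
#' @return Canonical character vector.
#' @export
canonical_circle <- function(x) {
  n <- length(x)
  if (n == 0L) return(x)
  cands <- c(lapply(seq_len(n), function(i) rotate_vec(x, i)),
             lapply(seq_len(n), function(i) rotate_vec(reflect_circle(x), i)))
  keys <- vapply(cands, paste, character(1), collapse = "\r")
  cands[[which.min(rank(keys, ties.method = "min"))]]
}

circle_key <- function(x) paste(canonical_circle(x), collapse = ",")
state_key <- function(circles) {
  paste(sort(vapply(circles, circle_key, character(1))), collapse = " | ")
}

copies_of <- function(circle, family) which(seg_name(circle) == family)

#' Apply one repeat-mediated recombination event
#'
#' Given a set of circles (each an ordered signed segment vector) and a
#' repeat family, enumerates every possible single crossover between two
#' copies of the family: two copies in direct relative orientation on one
#' circle cause fission into two circles (each retaining one copy), two
#' copies in inverted orientation on one circle invert the intervening
#' segment, and copies on two different circles fuse them.
#'
#' @param circles List of signed segment vectors.
#' @param family Segment label of the repeat family.
#' @return List of outcome states; each outcome is the full list of circles
#'   after one event. Empty when the family cannot recombine.
#' @export
recombine <- function(circles, family) {
  if (!is.list(circles)) circles <- list(circles)
  counts <- vapply(circles, function(cc) length(copies_of(cc, family)),
                   integer(1))
  if (sum(counts) < 2L) {
    stop("repeat family '", family,
         "' has fewer than two copies on the input circles", call. = FALSE)
  }
  outcomes <- list()
  add <- function(new_circles) {
    outcomes[[length(outcomes) + 1L]] <<- new_circles
  }
  # intramolecular events
  for (ci in seq_along(circles)) {
    circ <- circles[[ci]]
    cp <- copies_of(circ, family)
    if (length(cp) >= 2L) {
      for (pq in utils::combn(cp, 2L, simplify = FALSE)) {
        v <- rotate_vec(circ, pq[1])
        q <- pq[2] - pq[1] + 1L
        s1 <- !grepl("^-", v[1]); s2 <- !grepl("^-", v[q])
        rest <- circles[-ci]
        if (s1 == s2) {
          c1 <- v[seq_len(q - 1L)]
          c2 <- v[q:length(v)]
          add(c(rest, list(c1, c2)))
        } else {
          a <- if (q > 2L) v[2:(q - 1L)] else character(0)
          b <- if (q < length(v)) v[(q + 1L):length(v)] else character(0)
          inv <- c(v[1], rev(seg_flip(a)), v[q], b)
          add(c(rest, list(inv)))
        }
      }
    }
  }
  # intermolecular fusions
  if (length(circles) >= 2L) {
    idx <- utils::combn(seq_along(circles), 2L, simplify = FALSE)
    for (ij in idx) {
      c1 <- circles[[ij[1]]]; c2 <- circles[[ij[2]]]
      cp1 <- copies_of(c1, family); cp2 <- copies_of(c2, family)
      for (p in cp1) for (q in cp2) {
        u <- rotate_vec(c1, p)
        w <- rotate_vec(c2, q)
        if (grepl("^-", u[1]) != grepl("^-", w[1])) {
          w <- rotate_vec(reflect_circle(w), length(w))
        }
        add(c(circles[-ij], list(c(u, w))))
      }
    }
  }
  outcomes
}

#' Enumerate genome isomers reachable by repeat-mediated recombination
#'
#' Breadth-first closure of [recombine()] over all multi-copy repeat
#' families, deduplicating circles up to rotation and reflection. Master
#' circles are the distinct single-circle configurations; subgenomic
#' circles are the distinct circles occurring in multi-circle
#' configurations.
#'
#' @param master Signed segment vector (or list of them) for the starting
#'   configuration.
#' @param families Repeat family labels; by default every segment label
#'   with two or more copies across the starting circles.
#' @param max_states Safety cap on the number of explored configurations.
#' @return List with `states` (all reachable configurations, as lists of
#'   canonical circles), `isomers` (distinct single-circle configurations),
#'   `subcircles` (distinct circles from multi-circle configurations) and
#'   `paths` (the event path reaching each state).
#' @export
enumerate_isomers <- function(master, families = NULL, max_states = 1000) {
  state0 <- if (is.list(master)) master else list(master)
  all_segs <- unlist(state0)
  if (is.null(families)) {
    nm <- seg_name(all_segs)
    families <- unique(nm[duplicated(nm)])
  }
  seen <- new.env(parent = emptyenv())
  queue <- list(list(state = state0, path = character(0)))
  assign(state_key(state0), TRUE, envir = seen)
  states <- list(state0)
  paths <- list(character(0))
  while (length(queue) > 0L) {
    item <- queue[[1]]
    queue <- queue[-1]
    for (fam in families) {
      counts <- vapply(item$state, function(cc) {
        length(copies_of(cc, fam))
      }, integer(1))
      if (sum(counts) < 2L) next
      outs <- recombine(item$state, fam)
      for (o in outs) {
        o_can <- lapply(o, canonical_circle)
        key <- state_key(o_can)
        if (!exists(key, envir = seen)) {
          if (length(states) >= max_states) {
            stop("isomer closure exceeded max_states = ", max_states,
                 call. = FALSE)
          }
          assign(key, TRUE, envir = seen)
          states[[length(states) + 1L]] <- o_can
          p <- c(item$path, fam)
          paths[[length(paths) + 1L]] <- p
          queue[[length(queue) + 1L]] <- list(state = o_can, path = p)
        }
      }
    }
  }
  singles <- states[vapply(states, length, integer(1)) == 1L]
  iso_keys <- unique(vapply(singles, function(s) circle_key(s[[1]]),
                            character(1)))
  multi <- states[vapply(states, length, integer(1)) > 1L]
  sub_keys <- unique(unlist(lapply(multi, function(s) {
    vapply(s, circle_key, character(1))
  })))
  list(
    states = states,
    paths = paths,
    isomers = lapply(singles, function(s) s[[1]])[
      !duplicated(vapply(singles, function(s) circle_key(s[[1]]),
                         character(1)))],
    subcircles = sub_keys
  )
}

#' Assemble the nucleotide sequence of a signed block circle
#'
#' @param circle Signed segment vector.
#' @param seg_seqs Named character vector of segment sequences (unsigned
#'   labels).
#' @return Character scalar: the circle sequence starting at the first
#'   segment.
#' @export
circle_sequence <- function(circle, seg_seqs) {
  paste(vapply(circle, function(s) {
    base <- seg_seqs[[seg_name(s)]]
    if (grepl("^-", s)) revcomp(base) else base
  }, character(1)), collapse = "")
}

#' Build junction-spanning probe sequences for a circle
#'
#' For each junction between consecutive segments of the circle, extracts
#' the junction point plus `flank` bp of context on both sides (wrapping
#' the circle as needed).
#'
#' @param circle Signed segment vector.
#' @param seg_seqs Named segment sequences.
#' @param circle_id Identifier used in junction names.
#' @param flank Context on each side of the junction, bp.
#' @return Tibble: `junction_id`, `probe`, `junction_offset` (the probe
#'   position after which the junction point lies).
#' @export
make_junction_probes <- function(circle, seg_seqs, circle_id = "MC",
                                 flank = 1000) {
  seqs <- vapply(circle, function(s) {
    base <- seg_seqs[[seg_name(s)]]
    if (grepl("^-", s)) revcomp(base) else base
  }, character(1))
  full <- paste(seqs, collapse = "")
  L <- nchar(full)
  ends <- cumsum(nchar(seqs))
  n <- length(circle)
  probes <- vapply(seq_len(n), function(i) {
    j <- ends[i]  # junction after segment i
    s <- ((j - flank) %% L) + 1L
    e <- (j %% L) + flank
    e <- ((e - 1L) %% L) + 1L
    extract_subseq(circular_seq(full, circular = TRUE), s, e)
  }, character(1))
  ids <- vapply(seq_len(n), function(i) {
    nxt <- if (i == n) 1L else i + 1L
    sprintf("%s(%s+%s)", circle_id, seg_name(circle[i]),
            seg_name(circle[nxt]))
  }, character(1))
  tibble::tibble(junction_id = ids, probe = probes,
                 junction_offset = as.integer(flank))
}

#' Count long reads supporting each junction assay
#'
#' A read supports a junction when it contains the junction-spanning core
#' (the junction point plus `min_flank` bp each side, taken from the probe)
#' on either strand with at most `max_mismatch` mismatches. Reads matching
#' more than one assay are counted as ambiguous and excluded from per-assay
#' counts.
#'
#' @param reads Character vector of read sequences (or a tibble with a
#'   `seq` column).
#' @param assays Tibble from [make_junction_probes()].
#' @param min_flank Required exact context on each side of the junction
#'   point, bp.
#' @param max_mismatch Mismatches tolerated in the core match.
#' @return Tibble: `junction_id`, `supporting_reads`, `fraction`; the
#'   number of ambiguous reads is attached as the `ambiguous` attribute.
#' @export
junction_support <- function(reads, assays, min_flank = 50,
                             max_mismatch = 0) {
  if (is.data.frame(reads)) reads <- reads$seq
  n_assay <- nrow(assays)
  counts <- integer(n_assay)
  if (length(reads) == 0L) {
    out <- tibble::tibble(junction_id = assays$junction_id,
                          supporting_reads = counts, fraction = NA_real_)
    attr(out, "ambiguous") <- 0L
    return(out)
  }
  rset <- Biostrings::DNAStringSet(reads)
  hits <- matrix(FALSE, nrow = length(reads), ncol = n_assay)
  for (ai in seq_len(n_assay)) {
    off <- assays$junction_offset[ai]
    core <- substr(assays$probe[ai], off - min_flank + 1L, off + min_flank)
    if (nchar(core) < 2L * min_flank) next
    h1 <- Biostrings::vcountPattern(core, rset,
                                    max.mismatch = max_mismatch) > 0L
    h2 <- Biostrings::vcountPattern(revcomp(core), rset,
                                    max.mismatch = max_mismatch) > 0L
    hits[, ai] <- h1 | h2
  }
  n_hit <- rowSums(hits)
  ambiguous <- sum(n_hit > 1L)
  ok <- n_hit == 1L
  counts <- colSums(hits[ok, , drop = FALSE])
  total <- sum(counts)
  out <- tibble::tibble(
    junction_id = assays$junction_id,
    supporting_reads = as.integer(counts),
    fraction = if (total > 0L) counts / total else NA_real_
  )
  attr(out, "ambiguous") <- as.integer(ambiguous)
  out
}

#' Five-block master-circle toy with two repeat families
#'
#' A compact signed-circle arrangement of five sequence blocks and two
#' repeat families (R with three copies, S with three copies, including
#' inverted tandem copies) whose recombination closure contains exactly
#' three master-circle isomers and four subgenomic circles — the
#' configuration reported for CMS-type radish mitogenomes, where two
#' master circles interconvert through a third via paired subgenomic
#' circles.
#'
#' @return Signed segment vector suitable for [enumerate_isomers()].
#' @export
toy_master_circle <- function() {
  c("5", "4", "3", "2", "S", "-R", "R", "1", "-S", "S", "-R")
}
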