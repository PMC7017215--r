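#' @importFrom dplyr %>%
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Kyte-Doolittle hydropathy scale
#' @keywords internal
KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  paste(aa[-length(aa)][aa[-length(aa)] != "*"], collapse = "")
}

# Scan one strand of a (possibly circular) sequence for stop-to-stop ORFs.
# Returns 5'->3' coordinates on the scanned strand. A codon containing N is
# treated as non-coding: it breaks the reading but cannot terminate an ORF.
scan_strand_orfs <- function(seq, circular, min_aa) {
  L <- nchar(seq)
  s <- if (circular) strrep(seq, 3L) else seq
  res <- vector("list", 3L)
  for (f in 0:2) {
    pos <- seq.int(f + 1L, nchar(s) - 2L, by = 3L)
    if (length(pos) == 0L) next
    codons <- substring(s, pos, pos + 2L)
    is_stop <- codons %in% STOP_CODONS
    has_n <- grepl("N", codons, fixed = TRUE)
    brk <- which(is_stop | has_n)
    atg <- which(codons == "ATG")
    if (length(brk) == 0L || length(atg) == 0L) next
    seg <- findInterval(atg, brk)            # segment index of each ATG
    first_atg <- tapply(atg, seg, min)
    seg_id <- as.integer(names(first_atg))
    first_atg <- unname(first_atg)
    if (circular) {
      # on a circle the preceding in-frame stop must have been observed
      keep <- seg_id >= 1L
      first_atg <- first_atg[keep]
      seg_id <- seg_id[keep]
    }
    # terminating breaker must exist and be a true stop codon
    has_term <- (seg_id + 1L) <= length(brk)
    first_atg <- first_atg[has_term]
    seg_id <- seg_id[has_term]
    if (length(first_atg) == 0L) next
    term <- brk[seg_id + 1L]
    stop_ok <- is_stop[term]
    first_atg <- first_atg[stop_ok]
    term <- term[stop_ok]
    if (length(first_atg) == 0L) next
    aa_count <- term - first_atg
    keep2 <- aa_count >= min_aa
    first_atg <- first_atg[keep2]
    term <- term[keep2]
    aa_count <- aa_count[keep2]
    if (length(first_atg) == 0L) next
    nt_start <- pos[first_atg]
    nt_end <- pos[term] + 2L
    if (circular) {
      win <- nt_start > L & nt_start <= 2L * L
      span_ok <- (nt_end - nt_start + 1L) <= L
      sel <- win & span_ok
    } else {
      sel <- rep(TRUE, length(nt_start))
    }
    if (!any(sel)) next
    res[[f + 1L]] <- lapply(which(sel), function(i) {
      cod <- codons[first_atg[i]:term[i]]
      g_start <- ((nt_start[i] - 1L) %% L) + 1L
      g_end <- ((nt_end[i] - 1L) %% L) + 1L
      list(start = g_start, end = g_end, aa_count = aa_count[i],
           frame = f, nt = paste(cod, collapse = ""),
           protein = paste(Biostrings::GENETIC_CODE[cod[-length(cod)]],
                           collapse = ""))
    })
  }
  do.call(c, res)
}

#' Discover open reading frames on both strands of a genome
#'
#' Scans all six reading frames; on circular sequences frames continue
#' across the origin. Within each stop-to-stop segment of a frame, the ORF
#' runs from the first `ATG` after the preceding stop to the next in-frame
#' stop (one ORF per segment). On a linear sequence, segments lacking a
#' terminating stop are dropped. Codons containing `N` are treated as
#' non-coding breaks that cannot serve as start or stop.
#'
#' @param genome A [circular_seq()] or character scalar.
#' @param min_aa Minimum number of encoded amino acids (the stop codon is
#'   not counted); the published screen used 70.
#' @return A tibble sorted by `start` with columns `start`, `end`, `strand`,
#'   `frame`, `aa_count`, `nt` (coding sequence including the stop codon)
#'   and `protein`. Intervals are 1-based inclusive; `end < start` marks an
#'   origin-wrapping ORF. For minus-strand ORFs the interval is given in
#'   plus-strand coordinates, so `extract_subseq(genome, start, end, "-")`
#'   recovers the coding sequence.
#' @export
find_orfs <- function(genome, min_aa = 70) {
  g <- as_circseq(genome)
  L <- g$length
  plus <- scan_strand_orfs(g$seq, g$circular, min_aa)
  rc <- revcomp(g$seq)
  minus <- scan_strand_orfs(rc, g$circular, min_aa)
  rows <- list()
  if (length(plus)) {
    rows <- c(rows, lapply(plus, function(o) {
      tibble::tibble(start = o$start, end = o$end, strand = "+",
                     frame = o$frame, aa_count = o$aa_count, nt = o$nt,
                     protein = o$protein)
    }))
  }
  if (length(minus)) {
    rows <- c(rows, lapply(minus, function(o) {
      tibble::tibble(start = L - o$end + 1L, end = L - o$start + 1L,
                     strand = "-", frame = o$frame, aa_count = o$aa_count,
                     nt = o$nt, protein = o$protein)
    }))
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          strand = character(0), frame = integer(0),
                          aa_count = integer(0), nt = character(0),
                          protein = character(0)))
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::distinct(out, .data$start, .data$end, .data$strand,
                         .keep_all = TRUE)
  dplyr::arrange(out, .data$start, .data$end, .data$strand)
}

# bijective base-26 suffix: 1 -> a, 26 -> z, 27 -> aa, 28 -> ab, ...
orf_suffix <- function(i) {
  out <- character(length(i))
  for (k in seq_along(i)) {
    n <- i[k]
    s <- ""
    while (n > 0L) {
      r <- (n - 1L) %% 26L
      s <- paste0(letters[r + 1L], s)
      n <- (n - 1L) %/% 26L
    }
    out[k] <- s
  }
  out
}

#' Name ORFs by encoded amino-acid count
#'
#' Names follow the `orf<aa_count><letter>` convention: ORFs sharing an
#' amino-acid count receive suffixes `a`, `b`, ... in ascending start-position
#' order (continuing `aa`, `ab`, ... beyond `z`).
#'
#' @param orfs Tibble from [find_orfs()].
#' @return The tibble with a `name` column prepended.
#' @export
name_orfs <- function(orfs) {
  if (nrow(orfs) == 0L) {
    return(dplyr::mutate(orfs, name = character(0), .before = 1L))
  }
  orfs %>%
    dplyr::arrange(.data$start, .data$end) %>%
    dplyr::group_by(.data$aa_count) %>%
    dplyr::mutate(name = paste0("orf", .data$aa_count,
                                orf_suffix(dplyr::row_number()))) %>%
    dplyr::ungroup() %>%
    dplyr::relocate("name")
}

point_in_interval <- function(p, start, end, len) {
  ifelse(end >= start, p >= start & p <= end, p >= start | p <= end)
}

interval_midpoint <- function(start, end, len) {
  span <- interval_span(start, end, len)
  ((start - 1L + (span - 1L) %/% 2L) %% len) + 1L
}

#' Flag ORFs absent from a comparison genome
#'
#' An ORF is `unique` when its full nucleotide sequence has no exact match
#' in the other genome on either strand (wrap-aware). When unique regions
#' from [unique_regions()] are supplied, `in_unique_region` marks ORFs whose
#' midpoint falls inside one.
#'
#' @param orfs Tibble from [find_orfs()] / [name_orfs()].
#' @param genome_b The comparison genome.
#' @param uregions Optional tibble of unique regions (`start`, `end`) on the
#'   ORFs' own genome.
#' @return The tibble with logical columns `unique` and `in_unique_region`.
#' @export
classify_unique <- function(orfs, genome_b, uregions = NULL) {
  gb <- as_circseq(genome_b)
  subj <- if (gb$circular) strrep(gb$seq, 2L) else gb$seq
  subj_rc <- revcomp(subj)
  found <- vapply(orfs$nt, function(p) {
    grepl(p, subj, fixed = TRUE) || grepl(p, subj_rc, fixed = TRUE)
  }, logical(1), USE.NAMES = FALSE)
  orfs$unique <- !found
  if (!is.null(uregions) && nrow(uregions) > 0L) {
    gl <- attr(orfs, "genome_length")
    orfs$in_unique_region <- vapply(seq_len(nrow(orfs)), function(i) {
      L <- if (is.null(gl)) max(orfs$end, uregions$end) else gl
      mid <- interval_midpoint(orfs$start[i], orfs$end[i], L)
      any(point_in_interval(mid, uregions$start, uregions$end, L))
    }, logical(1))
  } else {
    orfs$in_unique_region <- FALSE
  }
  orfs
}

#' Decompose an ORF into known-gene and novel segments
#'
#' Aligns the ORF nucleotide sequence locally (match +1, mismatch -1, gap -2)
#' against each library CDS and its reverse complement, greedily taking the
#' best-scoring non-overlapping matches with identity at or above
#' `min_identity` over at least `min_match` bp. Uncovered stretches of at
#' least `min_novel` bp are reported as novel. The ORF is chimeric when it
#' has at least one match segment and at least one novel segment — the
#' classic signature of CMS-associated ORFs.
#'
#' @param orf_nt ORF nucleotide sequence (character scalar).
#' @param library Tibble with columns `gene_id` and `cds`.
#' @param min_identity Minimum alignment identity (matches / alignment
#'   columns).
#' @param min_match Minimum matched length on the ORF, bp.
#' @param min_novel Minimum reported novel-segment length, bp.
#' @return A list with `chimeric_segments` (tibble: `source_gene`,
#'   `orf_start`, `orf_end`, `identity`, `gene_strand`), `novel_segments`
#'   (tibble: `orf_start`, `orf_end`) and logical `chimeric`.
#' @export
detect_chimera <- function(orf_nt, library, min_identity = 0.9,
                           min_match = 60, min_novel = 100) {
  stopifnot(nrow(library) > 0L)
  n <- nchar(orf_nt)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1)
  free <- tibble::tibble(start = 1L, end = n)
  segs <- list()
  targets <- dplyr::bind_rows(
    tibble::tibble(gene_id = library$gene_id, cds = library$cds,
                   gene_strand = "+"),
    tibble::tibble(gene_id = library$gene_id,
                   cds = vapply(library$cds, revcomp, character(1),
                                USE.NAMES = FALSE),
                   gene_strand = "-")
  )
  repeat {
    best <- NULL
    for (fi in seq_len(nrow(free))) {
      fs <- free$start[fi]; fe <- free$end[fi]
      if (fe - fs + 1L < min_match) next
      sub <- substr(orf_nt, fs, fe)
      for (ti in seq_len(nrow(targets))) {
        aln <- Biostrings::pairwiseAlignment(
          pattern = sub, subject = targets$cds[ti], type = "local",
          substitutionMatrix = submat, gapOpening = 0, gapExtension = 2)
        pr <- Biostrings::pattern(aln)
        width <- Biostrings::nchar(aln)   # alignment columns
        mlen <- IRanges::width(pr@range)
        if (mlen < min_match) next
        ident <- Biostrings::nmatch(aln) / width
        if (ident < min_identity) next
        sc <- Biostrings::score(aln)
        if (is.null(best) || sc > best$score) {
          best <- list(score = sc, gene_id = targets$gene_id[ti],
                       gene_strand = targets$gene_strand[ti],
                       start = fs + IRanges::start(pr@range) - 1L,
                       end = fs + IRanges::end(pr@range) - 1L,
                       identity = ident)
        }
      }
    }
    if (is.null(best)) break
    segs[[length(segs) + 1L]] <- tibble::tibble(
      source_gene = best$gene_id, orf_start = best$start,
      orf_end = best$end, identity = best$identity,
      gene_strand = best$gene_strand)
    # carve the matched interval out of the free set
    new_free <- list()
    for (fi in seq_len(nrow(free))) {
      fs <- free$start[fi]; fe <- free$end[fi]
      if (best$end < fs || best$start > fe) {
        new_free[[length(new_free) + 1L]] <- c(fs, fe)
      } else {
        if (best$start > fs) {
          new_free[[length(new_free) + 1L]] <- c(fs, best$start - 1L)
        }
        if (best$end < fe) {
          new_free[[length(new_free) + 1L]] <- c(best$end + 1L, fe)
        }
      }
    }
    free <- if (length(new_free)) {
      tibble::tibble(start = vapply(new_free, `[`, integer(1), 1L),
                     end = vapply(new_free, `[`, integer(1), 2L))
    } else {
      tibble::tibble(start = integer(0), end = integer(0))
    }
    if (nrow(free) == 0L) break
  }
  chim <- if (length(segs)) dplyr::bind_rows(segs) else {
    tibble::tibble(source_gene = character(0), orf_start = integer(0),
                   orf_end = integer(0), identity = numeric(0),
                   gene_strand = character(0))
  }
  chim <- dplyr::arrange(chim, .data$orf_start)
  novel <- dplyr::filter(free, .data$end - .data$start + 1L >= min_novel)
  novel <- tibble::tibble(orf_start = novel$start, orf_end = novel$end)
  list(chimeric_segments = chim, novel_segments = novel,
       chimeric = nrow(chim) > 0L && nrow(novel) > 0L)
}

#' Predict transmembrane segments by Kyte-Doolittle hydropathy
#'
#' Computes window-mean hydropathy over a sliding window and reports maximal
#' runs of window centers whose mean exceeds the threshold, expanded to the
#' full window span; overlapping runs are merged. This is a hydropathy
#' heuristic, not an HMM-based topology predictor.
#'
#' @param protein Amino-acid string (one-letter codes). Unknown letters get
#'   hydropathy 0 with a warning.
#' @param window Window size in residues (odd).
#' @param threshold Window-mean hydropathy a transmembrane segment must
#'   exceed.
#' @return Tibble of amino-acid intervals (`start`, `end`) on the protein.
#' @export
predict_tm <- function(protein, window = 19, threshold = 1.6) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  empty <- tibble::tibble(start = integer(0), end = integer(0))
  if (length(aa) < window) return(empty)
  h <- KD_SCALE[aa]
  if (anyNA(h)) {
    warning("unknown residue letter(s) treated as hydropathy 0: ",
            paste(unique(aa[is.na(h)]), collapse = ", "))
    h[is.na(h)] <- 0
  }
  means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
  centers <- which(!is.na(means) & means > threshold)
  if (length(centers) == 0L) return(empty)
  half <- (window - 1L) %/% 2L
  runs <- split(centers, cumsum(c(1L, diff(centers) != 1L)))
  segs <- tibble::tibble(
    start = vapply(runs, min, integer(1)) - half,
    end = vapply(runs, max, integer(1)) + half
  )
  # merge window-expanded runs that overlap
  segs <- dplyr::arrange(segs, .data$start)
  merged <- list(c(segs$start[1], segs$end[1]))
  for (i in seq_len(nrow(segs))[-1]) {
    last <- merged[[length(merged)]]
    if (segs$start[i] <= last[2] + 1L) {
      merged[[length(merged)]] <- c(last[1], max(last[2], segs$end[i]))
    } else {
      merged[[length(merged) + 1L]] <- c(segs$start[i], segs$end[i])
    }
  }
  tibble::tibble(start = vapply(merged, `[`, numeric(1), 1L),
                 end = vapply(merged, `[`, numeric(1), 2L))
}

#' Flag ORFs adjacent to annotated mitochondrial genes
#'
#' For each ORF, finds the nearest annotated feature within `max_distance`
#' bp of circular gap distance (0 for overlap) and records the gene, the
#' distance and the side relative to the ORF's strand.
#'
#' @param orfs ORF tibble.
#' @param annotations Annotation tibble (`gene_id`, `start`, `end`).
#' @param genome_len Genome length in bp.
#' @param max_distance Maximum gap, bp.
#' @return The tibble with `adjacent_gene`, `adjacent_distance`,
#'   `adjacent_side` columns (`NA` when no gene is within range).
#' @export
flag_adjacency <- function(orfs, annotations, genome_len,
                           max_distance = 1000) {
  L <- genome_len
  orfs$adjacent_gene <- NA_character_
  orfs$adjacent_distance <- NA_integer_
  orfs$adjacent_side <- NA_character_
  if (nrow(annotations) == 0L || nrow(orfs) == 0L) return(orfs)
  for (i in seq_len(nrow(orfs))) {
    os <- orfs$start[i]; oe <- orfs$end[i]
    # gap after the ORF's right end going forward to each gene start,
    # and before its left end going backward from each gene end
    d_after <- (annotations$start - oe - 1L) %% L
    d_before <- (os - annotations$end - 1L) %% L
    overlap <- point_in_interval(annotations$start, os, oe, L) |
      point_in_interval(annotations$end, os, oe, L) |
      point_in_interval(os, annotations$start, annotations$end, L)
    d <- pmin(d_after, d_before)
    d[overlap] <- 0L
    j <- which.min(d)
    if (d[j] <= max_distance) {
      side_fwd <- if (overlap[j]) "overlap"
        else if (d_after[j] <= d_before[j]) "downstream" else "upstream"
      if (orfs$strand[i] == "-" && side_fwd != "overlap") {
        side_fwd <- if (side_fwd == "downstream") "upstream" else "downstream"
      }
      orfs$adjacent_gene[i] <- annotations$gene_id[j]
      orfs$adjacent_distance[i] <- as.integer(d[j])
      orfs$adjacent_side[i] <- side_fwd
    }
  }
  orfs
}

#' Select CMS candidate ORFs
#'
#' Candidates are the unique ORFs that either encode at least one
#' transmembrane segment or lie within range of a known mitochondrial gene;
#' chimeric candidates are additionally marked.
#'
#' @param orfs ORF tibble with `unique`, `n_tm`, `adjacent_gene` and
#'   `chimeric` columns filled in.
#' @return The candidate subset of the tibble.
#' @export
select_candidates <- function(orfs) {
  dplyr::filter(orfs, .data$unique &
                  (.data$n_tm > 0L | !is.na(.data$adjacent_gene)))
}

#' Run the full ORF screen on one genome against a comparison genome
#'
#' Discovers and names ORFs, flags uniqueness against `other`, screens
#' unique ORFs for chimerism against a known-gene library, predicts
#' transmembrane segments, flags gene adjacency and selects candidates.
#'
#' @param genome Genome to screen (the CMS mitogenome in the published
#'   design).
#' @param other Comparison genome (the normal mitogenome).
#' @param annotations Annotations of `genome` (for adjacency).
#' @param gene_library Known-gene library tibble (`gene_id`, `cds`); when
#'   `NULL`, derived from `annotations` CDS features on `genome`.
#' @param uregions Optional unique-region tibble from [unique_regions()].
#' @param min_aa Minimum ORF length in amino acids.
#' @param min_identity,min_match,min_novel Chimera-detection thresholds; see
#'   [detect_chimera()].
#' @param tm_window,tm_threshold Hydropathy parameters; see [predict_tm()].
#' @param max_distance Adjacency threshold, bp.
#' @return ORF tibble with all screening columns; candidates are the rows
#'   with `candidate == TRUE`.
#' @export
screen_orfs <- function(genome, other, annotations = NULL,
                        gene_library = NULL, uregions = NULL, min_aa = 70,
                        min_identity = 0.9, min_match = 60, min_novel = 100,
                        tm_window = 19, tm_threshold = 1.6,
                        max_distance = 1000) {
  g <- as_circseq(genome)
  orfs <- find_orfs(g, min_aa = min_aa)
  attr(orfs, "genome_length") <- g$length
  orfs <- name_orfs(orfs)
  attr(orfs, "genome_length") <- g$length
  orfs <- classify_unique(orfs, other, uregions = uregions)
  if (is.null(gene_library) && !is.null(annotations)) {
    cds_rows <- annotations[annotations$feature == "CDS", , drop = FALSE]
    gene_library <- tibble::tibble(
      gene_id = cds_rows$gene_id,
      cds = vapply(seq_len(nrow(cds_rows)), function(i) {
        extract_subseq(g, cds_rows$start[i], cds_rows$end[i],
                       cds_rows$strand[i])
      }, character(1))
    )
  }
  n <- nrow(orfs)
  orfs$tm_segments <- vector("list", n)
  orfs$n_tm <- 0L
  orfs$chimeric <- FALSE
  orfs$chimeric_segments <- vector("list", n)
  orfs$novel_segments <- vector("list", n)
  for (i in seq_len(n)) {
    tm <- predict_tm(orfs$protein[i], window = tm_window,
                     threshold = tm_threshold)
    orfs$tm_segments[[i]] <- tm
    orfs$n_tm[i] <- nrow(tm)
    if (orfs$unique[i] && !is.null(gene_library) &&
        nrow(gene_library) > 0L) {
      coding <- substr(orfs$nt[i], 1L, nchar(orfs$nt[i]) - 3L)
      ch <- detect_chimera(coding, gene_library,
                           min_identity = min_identity,
                           min_match = min_match, min_novel = min_novel)
      orfs$chimeric[i] <- ch$chimeric
      orfs$chimeric_segments[[i]] <- ch$chimeric_segments
      orfs$novel_segments[[i]] <- ch$novel_segments
    }
  }
  if (!is.null(annotations)) {
    orfs <- flag_adjacency(orfs, annotations, genome_len = g$length,
                           max_distance = max_distance)
  } else {
    orfs$adjacent_gene <- NA_character_
    orfs$adjacent_distance <- NA_integer_
    orfs$adjacent_side <- NA_character_
  }
  orfs$candidate <- orfs$unique &
    (orfs$n_tm > 0L | !is.na(orfs$adjacent_gene))
  attr(orfs, "genome_length") <- g$length
  orfs
}
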