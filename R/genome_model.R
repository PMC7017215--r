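#' Create a circular (or linear) nucleotide sequence object
#'
#' A light container for a single mitogenome-scale DNA sequence with 1-based
#' inclusive coordinates and origin-wrapping access. Plant mitochondrial
#' genomes are conventionally represented as a single circular molecule, so
#' circularity is the default.
#'
#' @param seq Character scalar, DNA sequence. Lowercase is uppercased and
#'   `U` is mapped to `T`; after mapping, only `A`, `C`, `G`, `T`, `N` are
#'   accepted.
#' @param id Sequence identifier.
#' @param circular Logical; is the molecule circular?
#' @return An object of class `circular_seq` with fields `id`, `seq`,
#'   `circular` and `length`.
#' @export
circular_seq <- function(seq, id = "seq", circular = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- chartr("u", "t", seq)
  seq <- toupper(seq)
  seq <- chartr("U", "T", seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop(sprintf("non-IUPAC character '%s' at position %d in sequence '%s'",
                 substr(seq, bad, bad), bad, id), call. = FALSE)
  }
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence", call. = FALSE)
  structure(
    list(id = id, seq = seq, circular = isTRUE(circular), length = n),
    class = "circular_seq"
  )
}

#' @export
print.circular_seq <- function(x, ...) {
  cat(sprintf("<circular_seq> %s: %s bp (%s)\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' @export
length.circular_seq <- function(x) x$length

as_circseq <- function(x, circular = TRUE) {
  if (inherits(x, "circular_seq")) x else circular_seq(x, circular = circular)
}

#' Read genome sequences from a FASTA file
#'
#' Sequences are uppercased and `U` is mapped to `T`. Circularity is taken
#' from a `circular=true` / `circular=false` token in the FASTA header when
#' present, otherwise from the `circular` argument.
#'
#' @param path FASTA file path.
#' @param circular Default circularity for records whose header carries no
#'   `circular=` token.
#' @return A named list of [circular_seq()] objects in file order.
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  out <- lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    id <- sub("\\s.*$", "", header)
    circ <- circular
    if (grepl("circular=true", header, ignore.case = TRUE)) circ <- TRUE
    if (grepl("circular=false", header, ignore.case = TRUE)) circ <- FALSE
    circular_seq(as.character(set[[i]]), id = id, circular = circ)
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Write genome sequences to a FASTA file
#'
#' Headers carry a `circular=true|false` token so that circularity
#' round-trips through [read_genome_fasta()].
#'
#' @param genomes A `circular_seq` or list of them.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "circular_seq")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, character(1), "seq"))
  names(set) <- vapply(genomes, function(g) {
    sprintf("%s circular=%s", g$id, tolower(as.character(g$circular)))
  }, character(1))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' GC content of a genome
#'
#' @param genome A [circular_seq()] or character scalar.
#' @return Percent GC, computed as 100 (G + C) / (A + C + G + T); `N` bases
#'   are excluded from the denominator. An all-`N` sequence is an error.
#' @export
gc_content <- function(genome) {
  g <- as_circseq(genome)
  counts <- base_counts(g$seq)
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0L) {
    stop("GC content undefined: sequence contains no A/C/G/T bases",
         call. = FALSE)
  }
  100 * sum(counts[c("G", "C")]) / denom
}

base_counts <- function(seq) {
  tab <- table(strsplit(seq, "", fixed = TRUE)[[1]])
  out <- c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Length of a 1-based inclusive interval, possibly wrapping the origin
#'
#' On a circle, an interval with `end < start` wraps through the origin and
#' spans `length - start + 1 + end` bases.
#'
#' @param start,end 1-based inclusive coordinates.
#' @param len Total genome length (needed only for wrapping intervals).
#' @export
interval_span <- function(start, end, len) {
  ifelse(end >= start, end - start + 1L, len - start + 1L + end)
}

#' Circular distance between two positions
#'
#' @param p,q Positions (1-based).
#' @param len Genome length.
#' @return `min(|p - q|, len - |p - q|)`.
#' @export
circular_distance <- function(p, q, len) {
  d <- abs(p - q)
  pmin(d, len - d)
}

#' Extract a subsequence, wrapping the circular origin when needed
#'
#' @param genome A [circular_seq()] or character scalar.
#' @param start,end 1-based inclusive coordinates. `end < start` requests an
#'   origin-wrapping extraction, which is an error on a linear sequence.
#' @param strand `"+"` returns the forward sequence, `"-"` its reverse
#'   complement.
#' @return Character scalar.
#' @export
extract_subseq <- function(genome, start, end, strand = "+") {
  g <- as_circseq(genome)
  L <- g$length
  if (start < 1L || start > L || end < 1L || end > L) {
    stop(sprintf("interval %d-%d outside [1, %d]", start, end, L),
         call. = FALSE)
  }
  if (end >= start) {
    s <- substr(g$seq, start, end)
  } else {
    if (!g$circular) {
      stop("origin-wrapping interval requested on a linear sequence",
           call. = FALSE)
    }
    s <- paste0(substr(g$seq, start, L), substr(g$seq, 1L, end))
  }
  if (strand == "-") s <- revcomp(s)
  s
}

#' Reverse complement of a DNA string
#' @param seq Character scalar over A/C/G/T/N.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Rotate a circular sequence so that position `offset + 1` becomes position 1
#'
#' @param genome A [circular_seq()].
#' @param offset Number of bases moved from the front to the back.
#' @export
rotate_genome <- function(genome, offset) {
  g <- as_circseq(genome)
  if (!g$circular) stop("cannot rotate a linear sequence", call. = FALSE)
  offset <- ((offset %% g$length) + g$length) %% g$length
  if (offset == 0) return(g)
  circular_seq(paste0(substr(g$seq, offset + 1L, g$length),
                      substr(g$seq, 1L, offset)),
               id = g$id, circular = TRUE)
}

#' Read gene annotations from a GFF3 file
#'
#' Only `CDS`, `tRNA` and `rRNA` features are retained. The
#' `Is_circular=true` attribute on the `region` line is honored and returned
#' as the `is_circular` attribute of the result.
#'
#' @param path GFF3 file path.
#' @return A tibble with columns `gene_id`, `start`, `end`, `strand`,
#'   `feature`, `product`.
#' @export
read_annotations <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- as.data.frame(gr)
  is_circ <- FALSE
  reg <- meta$type %in% c("region", "chromosome")
  if (any(reg) && "Is_circular" %in% names(meta)) {
    v <- meta$Is_circular[reg]
    is_circ <- any(tolower(as.character(v)) == "true", na.rm = TRUE)
  }
  keep <- meta$type %in% c("CDS", "tRNA", "rRNA")
  meta <- meta[keep, , drop = FALSE]
  ids <- if ("ID" %in% names(meta)) as.character(meta$ID) else NA_character_
  prod <- if ("product" %in% names(meta)) as.character(meta$product) else NA_character_
  out <- tibble::tibble(
    gene_id = ids,
    start = as.integer(meta$start),
    end = as.integer(meta$end),
    strand = as.character(meta$strand),
    feature = as.character(meta$type),
    product = prod
  )
  attr(out, "is_circular") <- is_circ
  out
}

#' Write gene annotations to a GFF3 file
#'
#' Emits a `region` line carrying `Is_circular=true` for circular genomes,
#' followed by one row per feature.
#'
#' @param annotations Tibble as returned by [read_annotations()].
#' @param path Output path.
#' @param seqid Sequence identifier the features belong to.
#' @param seqlen Genome length in bp.
#' @param circular Logical; written as the `Is_circular` region attribute.
#' @export
write_annotations <- function(annotations, path, seqid, seqlen,
                              circular = TRUE) {
  header <- c("##gff-version 3",
              sprintf("##sequence-region %s 1 %d", seqid, seqlen))
  region <- sprintf("%s\tmitoscreen\tregion\t1\t%d\t.\t+\t.\tID=%s;Is_circular=%s",
                    seqid, seqlen, seqid, tolower(as.character(circular)))
  rows <- sprintf(
    "%s\tmitoscreen\t%s\t%d\t%d\t.\t%s\t%s\tID=%s;product=%s",
    seqid, annotations$feature, annotations$start, annotations$end,
    annotations$strand, ifelse(annotations$feature == "CDS", "0", "."),
    annotations$gene_id,
    ifelse(is.na(annotations$product), annotations$gene_id,
           annotations$product)
  )
  writeLines(c(header, region, rows), path)
  invisible(path)
}

#' Basic genome statistics
#'
#' @param genome A [circular_seq()].
#' @param annotations Annotation tibble (see [read_annotations()]); may be
#'   empty.
#' @return A one-row tibble: `id`, `length`, `gc_percent` (2 decimals),
#'   `n_cds`, `n_trna`, `n_rrna`.
#' @export
genome_stats <- function(genome, annotations = NULL) {
  g <- as_circseq(genome)
  if (is.null(annotations)) {
    annotations <- tibble::tibble(feature = character(0))
  }
  tibble::tibble(
    id = g$id,
    length = g$length,
    gc_percent = round(gc_content(g), 2),
    n_cds = sum(annotations$feature == "CDS"),
    n_trna = sum(annotations$feature == "tRNA"),
    n_rrna = sum(annotations$feature == "rRNA")
  )
}
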