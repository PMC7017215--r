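ALL_CODONS <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                c("T", "C", "A", "G")), 1, paste,
                    collapse = "")
SENSE_CODONS <- setdiff(ALL_CODONS, c("TAA", "TAG", "TGA"))
HYDRO_CODONS <- c("CTT", "CTC", "CTA", "CTG", "ATT", "ATC", "ATA",
                  "GTT", "GTC", "GTA", "GTG")  # Leu / Ile / Val

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

#' Simulation parameters for a synthetic mitogenome pair
#'
#' Defaults emulate the structure reported for a CMS/normal radish
#' mitogenome comparison at roughly half scale: 18 syntenic blocks, 11
#' unique regions, 33 protein-coding genes, nine short repeat families with
#' the published unit lengths, a large (>1 kb) two-copy repeat, 14 SNPs in
#' 7 conserved genes, and one planted chimeric ORF built from a 128-bp
#' known-gene fragment plus a 1261-bp novel transmembrane-encoding segment
#' (128 + 1261 = 1389 = 3 x 463 coding positions).
#'
#' @param genome_length Approximate normal-genome length, bp.
#' @param n_blocks Number of syntenic blocks.
#' @param n_unique_regions Number of unique regions inserted into the CMS
#'   genome.
#' @param n_genes Number of protein-coding genes.
#' @param n_trna,n_rrna Numbers of tRNA / rRNA features.
#' @param short_repeat_lengths Unit lengths (bp) of the short repeat
#'   families, in decreasing order.
#' @param large_repeat_length Unit length (bp) of the large repeat
#'   (must exceed 1000).
#' @param n_snps_in_genes Total SNPs planted inside conserved genes.
#' @param n_snp_genes Number of genes carrying those SNPs.
#' @param chimera_known_fragment Length (bp) of the known-gene 5' fragment
#'   of the chimeric ORF.
#' @param chimera_novel Length (bp) of its novel segment.
#' @param permutation Optional explicit block permutation for the CMS
#'   genome; by default a seeded random permutation with no two blocks kept
#'   in their original adjacency.
#' @param inversions Optional explicit logical vector (one per permuted
#'   block); by default each block is inverted with probability 0.35.
#' @param seed Random seed; all generator randomness derives from it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(genome_length = 120000, n_blocks = 18,
                       n_unique_regions = 11, n_genes = 33, n_trna = 17,
                       n_rrna = 3,
                       short_repeat_lengths = c(508L, 307L, 232L, 152L,
                                                147L, 141L, 98L, 87L, 81L),
                       large_repeat_length = 2000,
                       n_snps_in_genes = 14, n_snp_genes = 7,
                       chimera_known_fragment = 128, chimera_novel = 1261,
                       permutation = NULL, inversions = NULL, seed = 1) {
  p <- list(genome_length = genome_length, n_blocks = n_blocks,
            n_unique_regions = n_unique_regions, n_genes = n_genes,
            n_trna = n_trna, n_rrna = n_rrna,
            short_repeat_lengths = as.integer(short_repeat_lengths),
            large_repeat_length = as.integer(large_repeat_length),
            n_snps_in_genes = n_snps_in_genes, n_snp_genes = n_snp_genes,
            chimera_known_fragment = as.integer(chimera_known_fragment),
            chimera_novel = as.integer(chimera_novel),
            permutation = permutation, inversions = inversions, seed = seed)
  if ((p$chimera_known_fragment + p$chimera_novel) %% 3L != 0L) {
    stop("chimera fragment lengths must sum to a multiple of 3",
         call. = FALSE)
  }
  if (p$large_repeat_length <= 1000L) {
    stop("large_repeat_length must exceed 1000 bp", call. = FALSE)
  }
  if (any(p$short_repeat_lengths < 80L | p$short_repeat_lengths > 999L)) {
    stop("short repeat lengths must lie in [80, 999] bp", call. = FALSE)
  }
  class(p) <- "sim_params"
  p
}

# a permutation is "breaking" when no two blocks keep their original
# circular adjacency in the same relative orientation
is_breaking_permutation <- function(perm, inv) {
  n <- length(perm)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (!inv[i] && !inv[j] && perm[j] == (perm[i] %% n) + 1L) return(FALSE)
    if (inv[i] && inv[j] && perm[i] == (perm[j] %% n) + 1L) return(FALSE)
  }
  TRUE
}

build_chimera_coding <- function(donor_cds, known_len, novel_len,
                                 max_try = 200) {
  total_codons <- (known_len + novel_len) %/% 3L
  donor_tail <- substring(donor_cds,
                          seq(known_len + 1L, nchar(donor_cds)),
                          seq(known_len + 1L, nchar(donor_cds)))
  horizon <- length(donor_tail)
  hydro_from <- total_codons - 60L
  hydro_codon_idx <- hydro_from:(hydro_from + 24L)
  for (attempt in seq_len(max_try)) {
    coding <- substr(donor_cds, 1L, known_len)
    score <- 0
    ok <- TRUE
    ci <- known_len %/% 3L + 1L  # codon index being completed/started
    while (nchar(coding) < known_len + novel_len) {
      cstart <- (ci - 1L) * 3L + 1L
      fill_from <- max(nchar(coding) + 1L, cstart)
      pool <- if (ci %in% hydro_codon_idx) HYDRO_CODONS else SENSE_CODONS
      placed <- FALSE
      for (tr in seq_len(200L)) {
        cod <- if (fill_from > cstart) {
          paste0(substr(coding, cstart, fill_from - 1L),
                 substr(sample(pool, 1L), fill_from - cstart + 1L, 3L))
        } else sample(pool, 1L)
        if (cod %in% c("TAA", "TAG", "TGA")) next
        new_bases <- substring(cod, fill_from - cstart + 1L, 3L)
        nb <- strsplit(new_bases, "")[[1]]
        s <- score
        good <- TRUE
        for (bi in seq_along(nb)) {
          p_novel <- nchar(coding) + bi - known_len
          if (p_novel >= 1L && p_novel <= horizon) {
            s <- s + if (nb[bi] == donor_tail[p_novel]) 1 else -1
            if (s > -1) { good <- FALSE; break }
          }
        }
        if (!good) next
        coding <- paste0(substr(coding, 1L, cstart - 1L), cod)
        coding <- substr(coding, 1L, min(nchar(coding),
                                         known_len + novel_len))
        score <- s
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
      ci <- ci + 1L
    }
    if (!ok) next
    # confirm the local aligner recovers exactly the planted boundary
    det <- detect_chimera(paste0(coding, "TAA"),
                          tibble::tibble(gene_id = "donor",
                                         cds = donor_cds),
                          min_identity = 0.9, min_match = 60,
                          min_novel = 100)
    cs <- det$chimeric_segments
    if (nrow(cs) == 1L && cs$orf_start == 1L && cs$orf_end == known_len) {
      return(paste0(coding, "TAA"))
    }
  }
  stop("failed to construct a chimeric ORF with a sharp boundary",
       call. = FALSE)
}

#' Generate a (normal, CMS) synthetic circular mitogenome pair
#'
#' Builds a normal genome as a sequence of syntenic blocks carrying random
#' ATG...stop gene models, then derives the CMS genome by permuting and
#' inverting the blocks, inserting unique regions (hosting planted repeat
#' copies, a large repeat and one chimeric transmembrane ORF) and short
#' sub-threshold spacers at every rearrangement junction, and injecting
#' SNPs into conserved genes. All planted features are recorded in a
#' ground-truth manifest. Junction-flanking bases are chosen so that exact
#' matches terminate precisely at block boundaries, making planted
#' coordinates recoverable exactly.
#'
#' @param params A [sim_params()] list.
#' @return A `mito_sim` list: `normal`, `cms` ([circular_seq()]),
#'   `normal_annotations`, `cms_annotations`, and `truth` (manifest list
#'   with `blocks`, `unique_regions`, `fillers`, `repeats`, `snps`,
#'   `chimera`, `genes`).
#' @export
generate_pair <- function(params = sim_params()) {
  p <- params
  set.seed(p$seed)
  n <- p$n_blocks
  nfam <- length(p$short_repeat_lengths)

  ## ---- features assigned round-robin to blocks -----------------------
  feats <- tibble::tibble(
    gene_id = c(sprintf("gene%02d", seq_len(p$n_genes)),
                sprintf("trn%02d", seq_len(p$n_trna)),
                sprintf("rrn%d", seq_len(p$n_rrna))),
    feature = c(rep("CDS", p$n_genes), rep("tRNA", p$n_trna),
                rep("rRNA", p$n_rrna))
  )
  feats <- feats[sample(nrow(feats)), ]
  feats$block <- rep_len(seq_len(n), nrow(feats))
  feats$strand <- sample(c("+", "-"), nrow(feats), replace = TRUE)
  feats$seq <- vapply(seq_len(nrow(feats)), function(i) {
    switch(feats$feature[i],
           CDS = paste(c("ATG", sample(SENSE_CODONS,
                                       sample(100:500, 1L) - 1L,
                                       replace = TRUE),
                         sample(c("TAA", "TAG", "TGA"), 1L)),
                       collapse = ""),
           tRNA = rand_dna(sample(70:90, 1L)),
           rRNA = rand_dna(sample(500:1500, 1L)))
  }, character(1))

  ## ---- normal genome blocks ------------------------------------------
  margin <- 250L
  target <- pmax(3000L,
                 round(p$genome_length / n *
                         stats::runif(n, 0.8, 1.2)))
  block_seqs <- character(n)
  gene_rows <- list()
  for (b in seq_len(n)) {
    fb <- feats[feats$block == b, , drop = FALSE]
    flens <- nchar(fb$seq)
    need <- 2L * margin + sum(flens) + 80L * max(0L, nrow(fb) - 1L)
    blen <- max(target[b], need + 400L)
    extra <- blen - need
    gaps <- as.integer(round(extra * c(stats::runif(nrow(fb) + 1L))))
    gaps <- gaps * 0L
    if (nrow(fb) >= 0L) {
      w <- stats::runif(nrow(fb) + 1L)
      gaps <- floor(extra * w / sum(w))
    }
    gaps[1] <- gaps[1] + (extra - sum(gaps))
    pieces <- character(0)
    pos <- 0L
    pieces <- c(pieces, rand_dna(margin + gaps[1]))
    pos <- margin + gaps[1]
    for (fi in seq_len(nrow(fb))) {
      fseq <- if (fb$strand[fi] == "+") fb$seq[fi] else revcomp(fb$seq[fi])
      gene_rows[[length(gene_rows) + 1L]] <- tibble::tibble(
        gene_id = fb$gene_id[fi], feature = fb$feature[fi],
        strand = fb$strand[fi], block = b,
        local_start = pos + 1L, local_end = pos + nchar(fseq),
        cds = fb$seq[fi])
      pieces <- c(pieces, fseq)
      pos <- pos + nchar(fseq)
      gap_after <- if (fi < nrow(fb)) 80L + gaps[fi + 1L] else
        margin + gaps[fi + 1L]
      pieces <- c(pieces, rand_dna(gap_after))
      pos <- pos + gap_after
    }
    if (nrow(fb) == 0L) {
      pieces <- c(pieces, rand_dna(blen - margin - gaps[1]))
    }
    block_seqs[b] <- paste(pieces, collapse = "")
  }
  block_len <- nchar(block_seqs)
  n_start <- cumsum(c(1L, block_len[-n]))
  n_end <- n_start + block_len - 1L
  normal_seq <- paste(block_seqs, collapse = "")
  genes <- dplyr::bind_rows(gene_rows)
  genes$start <- n_start[genes$block] + genes$local_start - 1L
  genes$end <- n_start[genes$block] + genes$local_end - 1L

  ## ---- rearrangement plan --------------------------------------------
  perm <- p$permutation
  inv <- p$inversions
  if (is.null(perm)) {
    repeat {
      perm <- sample(n)
      inv <- stats::runif(n) < 0.35
      if (is_breaking_permutation(perm, inv)) break
    }
  } else if (is.null(inv)) {
    inv <- rep(FALSE, n)
  }
  identity_plan <- identical(perm, seq_len(n)) && !any(inv)

  ## ---- planted elements ----------------------------------------------
  fam_units <- vapply(p$short_repeat_lengths, rand_dna, character(1))
  large_unit <- rand_dna(p$large_repeat_length)
  donor_pool <- genes[genes$feature == "CDS" & genes$strand == "+" &
                        nchar(genes$cds) >= p$chimera_known_fragment +
                        200L, , drop = FALSE]
  donor <- donor_pool[sample(nrow(donor_pool), 1L), ]
  chimera_seq <- build_chimera_coding(donor$cds, p$chimera_known_fragment,
                                      p$chimera_novel)

  ## ---- filler plans ---------------------------------------------------
  n_u <- p$n_unique_regions
  filler_plan <- vector("list", n)
  u_slots <- if (identity_plan || n_u == 0L) integer(0) else
    sort(sample(n, n_u))
  elements <- list()  # each: list(kind, label, seq, place)
  if (n_u > 0L) {
    elements <- c(
      list(list(kind = "chimera", label = "chimera",
                seq = paste0("TAA", chimera_seq), place = "interior")),
      if (n_u >= 3L) list(
        list(kind = "large", label = "Large repeat", copy = 1L,
             seq = large_unit, place = "interior"),
        list(kind = "large", label = "Large repeat", copy = 2L,
             seq = large_unit, place = "interior"))
    )
    n_edge_fams <- min(5L, nfam)
    for (f in seq_len(nfam)) {
      for (cp in 1:2) {
        place <- if (f <= n_edge_fams && (cp == 1L || f <= 2L)) "edge"
          else "interior"
        elements <- c(elements, list(list(
          kind = "repeat", label = paste0("fam", f), copy = cp,
          seq = fam_units[f], place = place)))
      }
    }
  }
  edge_elems <- Filter(function(e) e$place == "edge", elements)
  int_elems <- Filter(function(e) e$place == "interior", elements)
  if (n_u > 0L && length(edge_elems) > 2L * n_u) {
    stop("infeasible packing: too many junction repeats for the requested ",
         "number of unique regions", call. = FALSE)
  }
  region_edge <- vector("list", n_u)   # per region: start/end edge elems
  region_int <- vector("list", n_u)
  if (n_u > 0L) {
    for (i in seq_along(edge_elems)) {
      r <- ((i - 1L) %% n_u) + 1L
      side <- if (i <= n_u) "start" else "end"
      region_edge[[r]][[side]] <- edge_elems[[i]]
    }
    for (i in seq_along(int_elems)) {
      r <- ((i - 1L) %% n_u) + 1L
      region_int[[r]] <- c(region_int[[r]], list(int_elems[[i]]))
    }
  }

  ## ---- assemble CMS ----------------------------------------------------
  cms_pieces <- character(0)
  pos <- 0L
  cms_block <- tibble::tibble(block_id = integer(0), start = integer(0),
                              end = integer(0), orientation = character(0))
  fillers <- list()
  planted <- list()   # planted element coordinates on CMS
  u_idx <- 0L
  for (i in seq_len(n)) {
    b <- perm[i]
    bseq <- if (inv[i]) revcomp(block_seqs[b]) else block_seqs[b]
    cms_pieces <- c(cms_pieces, bseq)
    cms_block <- dplyr::bind_rows(cms_block, tibble::tibble(
      block_id = b, start = pos + 1L, end = pos + nchar(bseq),
      orientation = if (inv[i]) "inverted" else "forward"))
    pos <- pos + nchar(bseq)
    if (identity_plan && n_u == 0L) next
    is_unique <- i %in% u_slots
    if (is_unique) {
      u_idx <- which(u_slots == i)
      parts <- character(0)
      local <- 0L
      elems_here <- list()
      se <- region_edge[[u_idx]]$start
      if (!is.null(se)) {
        g <- sample(20:120, 1L)
        parts <- c(parts, rand_dna(g)); local <- local + g
        elems_here <- c(elems_here, list(c(list(local_start = local + 1L),
                                           se)))
        parts <- c(parts, se$seq); local <- local + nchar(se$seq)
      } else {
        g <- sample(320:500, 1L)
        parts <- c(parts, rand_dna(g)); local <- local + g
      }
      for (el in region_int[[u_idx]]) {
        g <- sample(180:400, 1L)
        parts <- c(parts, rand_dna(g)); local <- local + g
        elems_here <- c(elems_here, list(c(list(local_start = local + 1L),
                                           el)))
        parts <- c(parts, el$seq); local <- local + nchar(el$seq)
      }
      ee <- region_edge[[u_idx]]$end
      if (!is.null(ee)) {
        g <- sample(180:400, 1L)
        parts <- c(parts, rand_dna(g)); local <- local + g
        elems_here <- c(elems_here, list(c(list(local_start = local + 1L),
                                           ee)))
        parts <- c(parts, ee$seq); local <- local + nchar(ee$seq)
        g <- sample(20:120, 1L)
        parts <- c(parts, rand_dna(g)); local <- local + g
      } else {
        g <- sample(320:500, 1L)
        parts <- c(parts, rand_dna(g)); local <- local + g
      }
      fseq <- paste(parts, collapse = "")
      ftype <- "unique"
    } else {
      fseq <- rand_dna(sample(60:150, 1L))
      ftype <- "spacer"
      elems_here <- list()
    }
    # sharpen the junction: the filler's first/last base must differ from
    # the base that continues the flanking blocks' match in the normal
    # genome, so anchors end exactly at block boundaries
    L_n <- nchar(normal_seq)
    bp_prev <- perm[i]
    x <- if (!inv[i]) {
      substr(normal_seq, (n_end[bp_prev] %% L_n) + 1L,
             (n_end[bp_prev] %% L_n) + 1L)
    } else {
      comp_base(substr(normal_seq, ((n_start[bp_prev] - 2L) %% L_n) + 1L,
                       ((n_start[bp_prev] - 2L) %% L_n) + 1L))
    }
    jn <- if (i == n) 1L else i + 1L
    bp_next <- perm[jn]
    y <- if (!inv[jn]) {
      substr(normal_seq, ((n_start[bp_next] - 2L) %% L_n) + 1L,
             ((n_start[bp_next] - 2L) %% L_n) + 1L)
    } else {
      comp_base(substr(normal_seq, (n_end[bp_next] %% L_n) + 1L,
                       (n_end[bp_next] %% L_n) + 1L))
    }
    b1 <- sample(setdiff(c("A", "C", "G", "T"), x), 1L)
    substr(fseq, 1L, 1L) <- b1
    b2 <- sample(setdiff(c("A", "C", "G", "T"), y), 1L)
    substr(fseq, nchar(fseq), nchar(fseq)) <- b2
    fillers[[length(fillers) + 1L]] <- tibble::tibble(
      slot = i, type = ftype, start = pos + 1L, end = pos + nchar(fseq),
      length = nchar(fseq))
    for (el in elems_here) {
      planted[[length(planted) + 1L]] <- tibble::tibble(
        kind = el$kind, label = el$label,
        copy = if (!is.null(el$copy)) el$copy else NA_integer_,
        start = pos + el$local_start,
        end = pos + el$local_start + nchar(el$seq) - 1L,
        at_junction = el$place == "edge", slot = i)
    }
    cms_pieces <- c(cms_pieces, fseq)
    pos <- pos + nchar(fseq)
  }
  cms_seq <- paste(cms_pieces, collapse = "")

  ## ---- SNPs in conserved genes ----------------------------------------
  cds_genes <- genes[genes$feature == "CDS" &
                       genes$gene_id != donor$gene_id, , drop = FALSE]
  snp_genes <- cds_genes[sample(nrow(cds_genes),
                                min(p$n_snp_genes, nrow(cds_genes))), ]
  snp_rows <- list()
  if (p$n_snps_in_genes > 0L && nrow(snp_genes) > 0L) {
    alloc <- rep(seq_len(nrow(snp_genes)),
                 length.out = p$n_snps_in_genes)
    for (gi in seq_len(nrow(snp_genes))) {
      gene <- snp_genes[gi, ]
      k_snp <- sum(alloc == gi)
      cds_len <- nchar(gene$cds)
      poss <- sample(4:(cds_len - 3L), k_snp)
      for (cp in poss) {
        ref_cds <- substr(gene$cds, cp, cp)
        repeat {
          alt_cds <- sample(setdiff(c("A", "C", "G", "T"), ref_cds), 1L)
          mut <- gene$cds
          substr(mut, cp, cp) <- alt_cds
          ci <- (cp - 1L) %/% 3L
          ref_codon <- substr(gene$cds, ci * 3L + 1L, ci * 3L + 3L)
          alt_codon <- substr(mut, ci * 3L + 1L, ci * 3L + 3L)
          if (unname(Biostrings::GENETIC_CODE[alt_codon]) != "*") break
        }
        aa_ref <- unname(Biostrings::GENETIC_CODE[ref_codon])
        aa_alt <- unname(Biostrings::GENETIC_CODE[alt_codon])
        effect <- if (aa_ref == aa_alt) "synonymous"
          else paste0(aa_ref, "-", aa_alt)
        pos_n <- if (gene$strand == "+") gene$start + cp - 1L
          else gene$end - cp + 1L
        brow <- cms_block[cms_block$block_id == gene$block, ]
        off <- pos_n - n_start[gene$block]
        pos_c <- if (brow$orientation == "forward") brow$start + off
          else brow$end - off
        base_plus_n <- if (gene$strand == "+") alt_cds else
          comp_base(alt_cds)
        base_c <- if (brow$orientation == "forward") base_plus_n else
          comp_base(base_plus_n)
        substr(cms_seq, pos_c, pos_c) <- base_c
        snp_rows[[length(snp_rows) + 1L]] <- tibble::tibble(
          gene_id = gene$gene_id, cds_pos = cp, ref = ref_cds,
          alt = alt_cds, effect = effect, pos_normal = pos_n,
          pos_cms = pos_c)
      }
    }
  }
  snps <- if (length(snp_rows)) dplyr::bind_rows(snp_rows) else
    tibble::tibble(gene_id = character(0), cds_pos = integer(0),
                   ref = character(0), alt = character(0),
                   effect = character(0), pos_normal = integer(0),
                   pos_cms = integer(0))

  ## ---- annotations ----------------------------------------------------
  normal_ann <- tibble::tibble(
    gene_id = genes$gene_id, start = genes$start, end = genes$end,
    strand = genes$strand, feature = genes$feature,
    product = genes$gene_id)
  cms_ann <- normal_ann
  for (i in seq_len(nrow(cms_ann))) {
    b <- genes$block[i]
    brow <- cms_block[cms_block$block_id == b, ]
    off_s <- genes$start[i] - n_start[b]
    off_e <- genes$end[i] - n_start[b]
    if (brow$orientation == "forward") {
      cms_ann$start[i] <- brow$start + off_s
      cms_ann$end[i] <- brow$start + off_e
    } else {
      cms_ann$start[i] <- brow$end - off_e
      cms_ann$end[i] <- brow$end - off_s
      cms_ann$strand[i] <- if (genes$strand[i] == "+") "-" else "+"
    }
  }

  ## ---- manifest -------------------------------------------------------
  planted_tbl <- if (length(planted)) dplyr::bind_rows(planted) else
    tibble::tibble(kind = character(0), label = character(0),
                   copy = integer(0), start = integer(0), end = integer(0),
                   at_junction = logical(0), slot = integer(0))
  filler_tbl <- if (length(fillers)) dplyr::bind_rows(fillers) else
    tibble::tibble(slot = integer(0), type = character(0),
                   start = integer(0), end = integer(0),
                   length = integer(0))
  chim_row <- planted_tbl[planted_tbl$kind == "chimera", , drop = FALSE]
  chimera_truth <- NULL
  if (nrow(chim_row) == 1L) {
    # the cassette starts with an in-frame TAA; the ORF begins 3 bp later
    chimera_truth <- list(
      start = chim_row$start + 3L,
      end = chim_row$end,
      strand = "+",
      aa_count = (p$chimera_known_fragment + p$chimera_novel) %/% 3L,
      donor_gene = donor$gene_id,
      known_fragment = c(1L, p$chimera_known_fragment),
      novel = c(p$chimera_known_fragment + 1L,
                p$chimera_known_fragment + p$chimera_novel),
      nt = chimera_seq)
  }
  rep_tbl <- planted_tbl[planted_tbl$kind %in% c("repeat", "large"), ,
                         drop = FALSE]
  rep_tbl$unit_length <- rep_tbl$end - rep_tbl$start + 1L
  truth <- list(
    params = p,
    permutation = perm,
    inversions = inv,
    blocks = tibble::tibble(
      block_id = cms_block$block_id,
      normal_start = n_start[cms_block$block_id],
      normal_end = n_end[cms_block$block_id],
      cms_start = cms_block$start, cms_end = cms_block$end,
      orientation = cms_block$orientation),
    fillers = filler_tbl,
    unique_regions = filler_tbl[filler_tbl$type == "unique", , drop = FALSE],
    repeats = rep_tbl,
    snps = snps,
    chimera = chimera_truth,
    genes = genes[, c("gene_id", "feature", "strand", "block", "start",
                      "end")]
  )
  structure(list(
    normal = circular_seq(normal_seq, id = "normal_mito", circular = TRUE),
    cms = circular_seq(cms_seq, id = "cms_mito", circular = TRUE),
    normal_annotations = normal_ann,
    cms_annotations = cms_ann,
    truth = truth
  ), class = "mito_sim")
}

#' Simulate a synthetic mitogenome pair (alias with explicit seed)
#'
#' @param seed Random seed.
#' @param ... Passed to [sim_params()].
#' @export
simulate_mito_pair <- function(seed = 1, ...) {
  generate_pair(sim_params(seed = seed, ...))
}

#' Simulate long reads from a mixture of circular isomers
#'
#' Each read is drawn from a circle chosen by its mixture fraction, starts
#' uniformly on the circle (wrapping the origin), lies on a random strand,
#' and carries independent substitution errors.
#'
#' @param circles Named character vector (or list) of circle sequences.
#' @param mixture Named numeric vector of fractions summing to 1.
#' @param read_length Read length, bp (must not exceed any sampled
#'   circle's length).
#' @param error_rate Per-base substitution error rate.
#' @param n_reads Number of reads.
#' @param seed Random seed.
#' @return Tibble: `read_id`, `circle`, `start`, `strand`, `seq`.
#' @export
generate_long_reads <- function(circles, mixture, read_length = 8000,
                                error_rate = 0, n_reads = 1000, seed = 1) {
  set.seed(seed)
  circles <- as.list(circles)
  if (abs(sum(mixture) - 1) > 1e-8) {
    stop("mixture fractions must sum to 1", call. = FALSE)
  }
  if (!all(names(mixture) %in% names(circles))) {
    stop("mixture names must match circle names", call. = FALSE)
  }
  lens <- vapply(circles[names(mixture)], nchar, integer(1))
  if (any(read_length > lens)) {
    stop("read_length exceeds a circle length", call. = FALSE)
  }
  if (n_reads == 0L) {
    return(tibble::tibble(read_id = character(0), circle = character(0),
                          start = integer(0), strand = character(0),
                          seq = character(0)))
  }
  which_circle <- sample(names(mixture), n_reads, replace = TRUE,
                         prob = mixture)
  out <- vector("list", n_reads)
  bases <- c("A", "C", "G", "T")
  for (r in seq_len(n_reads)) {
    cname <- which_circle[r]
    cs <- circles[[cname]]
    L <- nchar(cs)
    st <- sample.int(L, 1L)
    en <- ((st + read_length - 2L) %% L) + 1L
    sq <- extract_subseq(circular_seq(cs, circular = TRUE), st, en)
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") sq <- revcomp(sq)
    if (error_rate > 0) {
      nerr <- stats::rbinom(1L, read_length, error_rate)
      if (nerr > 0L) {
        at <- sample.int(read_length, nerr)
        for (a in at) {
          old <- substr(sq, a, a)
          substr(sq, a, a) <- sample(setdiff(bases, old), 1L)
        }
      }
    }
    out[[r]] <- tibble::tibble(read_id = sprintf("read%05d", r),
                               circle = cname, start = st,
                               strand = strand, seq = sq)
  }
  dplyr::bind_rows(out)
}

#' Write simulated reads to a FASTQ file
#'
#' @param reads Tibble from [generate_long_reads()].
#' @param path Output path.
#' @export
write_reads_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    writeLines(c(paste0("@", reads$read_id[i]), reads$seq[i], "+",
                 strrep("I", nchar(reads$seq[i]))), con)
  }
  invisible(path)
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Generates `Ct_target = ct_ref_mean - log2(fold) + offset + noise` and
#' `Ct_reference = ct_ref_mean + noise` per replicate, so that [ddct()] on
#' a noise-free table recovers the planted fold changes exactly (relative
#' to the calibrator group, whose fold should be 1).
#'
#' @param true_fold_changes Named numeric vector of fold changes per group
#'   (calibrator group should have fold 1).
#' @param ct_ref_mean Mean reference-gene Ct.
#' @param noise_sd Gaussian noise SD added independently to every Ct.
#' @param replicates Technical replicates per sample.
#' @param offset Constant target-vs-reference Ct offset.
#' @param seed Random seed.
#' @return Ct tibble in the format expected by [ddct()], with the planted
#'   folds attached as attribute `true_fold_changes`.
#' @export
generate_ct_table <- function(true_fold_changes, ct_ref_mean = 20,
                              noise_sd = 0, replicates = 3, offset = 2,
                              seed = 1) {
  set.seed(seed)
  if (any(true_fold_changes <= 0)) {
    stop("fold changes must be positive", call. = FALSE)
  }
  if (replicates < 1L) stop("need at least one replicate", call. = FALSE)
  rows <- list()
  for (g in names(true_fold_changes)) {
    for (r in seq_len(replicates)) {
      ct_ref <- ct_ref_mean + stats::rnorm(1L, 0, noise_sd)
      ct_tgt <- ct_ref_mean - log2(true_fold_changes[[g]]) + offset +
        stats::rnorm(1L, 0, noise_sd)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = paste0(g, "_s1"), group = g,
        gene = c("reference", "target"), replicate = r,
        ct = c(ct_ref, ct_tgt))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "true_fold_changes") <- true_fold_changes
  out
}

#' Write a simulated pair to disk (FASTA + GFF3 + JSON manifest)
#'
#' @param sim A `mito_sim` object from [generate_pair()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
save_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    normal_fasta = file.path(outdir, "normal.fasta"),
    cms_fasta = file.path(outdir, "cms.fasta"),
    normal_gff = file.path(outdir, "normal.gff3"),
    cms_gff = file.path(outdir, "cms.gff3"),
    manifest = file.path(outdir, "truth_manifest.json")
  )
  write_genome_fasta(sim$normal, paths["normal_fasta"])
  write_genome_fasta(sim$cms, paths["cms_fasta"])
  write_annotations(sim$normal_annotations, paths["normal_gff"],
                    seqid = sim$normal$id, seqlen = sim$normal$length)
  write_annotations(sim$cms_annotations, paths["cms_gff"],
                    seqid = sim$cms$id, seqlen = sim$cms$length)
  truth <- sim$truth
  truth$params$permutation <- NULL
  truth$params <- unclass(truth$params)
  jsonlite::write_json(truth, paths["manifest"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
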