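#' Default pipeline configuration
#'
#' All thresholds used anywhere in the screen, with their module defaults.
#'
#' @param ... Named overrides of individual thresholds.
#' @return A named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    min_aa = 70,
    anchor_min_len = 100,
    max_gap = 2000,
    min_block = 500,
    diag_tol = 30,
    min_unique_len = 200,
    repeat_min_len = 80,
    junction_tolerance = 200,
    tm_window = 19,
    tm_threshold = 1.6,
    chimera_min_identity = 0.9,
    chimera_min_match = 60,
    chimera_min_novel = 100,
    adjacency_max_distance = 1000,
    isomer_max_states = 500,
    seed = 1
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full comparative screen of a CMS genome against a normal genome
#'
#' Executes synteny decomposition, the ORF screen, repeat detection with
#' junction association, variant calling inside conserved genes, and
#' repeat-mediated isomer enumeration, and optionally writes a report
#' bundle to a directory.
#'
#' @param cms,normal The two genomes ([circular_seq()] or FASTA paths).
#' @param cms_annotations,normal_annotations Annotation tibbles (or GFF3
#'   paths). The normal annotations provide the known-gene library for
#'   chimera detection and the reference frame for variant effects.
#' @param config Configuration list from [default_config()].
#' @param outdir Optional output directory for TSV/BED/JSON reports.
#' @return A `mito_screen` object: list with `blocks`, `unique_regions`,
#'   `orfs`, `candidates`, `repeats`, `variants`, `isomers`, `summary`,
#'   `config`.
#' @export
run_screen <- function(cms, normal, cms_annotations = NULL,
                       normal_annotations = NULL,
                       config = default_config(), outdir = NULL) {
  if (is.character(cms) && length(cms) == 1L && file.exists(cms)) {
    cms <- read_genome_fasta(cms)[[1]]
  }
  if (is.character(normal) && length(normal) == 1L &&
      file.exists(normal)) {
    normal <- read_genome_fasta(normal)[[1]]
  }
  if (is.character(cms_annotations)) {
    cms_annotations <- read_annotations(cms_annotations)
  }
  if (is.character(normal_annotations)) {
    normal_annotations <- read_annotations(normal_annotations)
  }
  cms <- as_circseq(cms); normal <- as_circseq(normal)

  syn <- synteny_decompose(cms, normal,
                           min_len = config$anchor_min_len,
                           max_gap = config$max_gap,
                           min_block = config$min_block,
                           diag_tol = config$diag_tol,
                           min_unique_len = config$min_unique_len)

  gene_library <- NULL
  if (!is.null(normal_annotations)) {
    cds <- normal_annotations[normal_annotations$feature == "CDS", ,
                              drop = FALSE]
    if (nrow(cds)) {
      gene_library <- tibble::tibble(
        gene_id = cds$gene_id,
        cds = vapply(seq_len(nrow(cds)), function(i) {
          extract_subseq(normal, cds$start[i], cds$end[i], cds$strand[i])
        }, character(1)))
    }
  }
  orfs <- screen_orfs(cms, normal, annotations = cms_annotations,
                      gene_library = gene_library,
                      uregions = syn$unique_a, min_aa = config$min_aa,
                      min_identity = config$chimera_min_identity,
                      min_match = config$chimera_min_match,
                      min_novel = config$chimera_min_novel,
                      tm_window = config$tm_window,
                      tm_threshold = config$tm_threshold,
                      max_distance = config$adjacency_max_distance)
  candidates <- select_candidates(orfs)

  repeats <- find_repeats(cms, min_len = config$repeat_min_len)
  if (nrow(repeats)) {
    repeats <- associate_junctions(repeats, syn$blocks, cms$length,
                                   tolerance = config$junction_tolerance,
                                   which = "a")
  } else {
    repeats$junction_hits <- list()
    repeats$at_junction <- logical(0)
  }

  variants <- call_variants(syn$blocks, cms, normal,
                            annotations = normal_annotations,
                            annotation_genome = "b")

  isomers <- tryCatch(
    isomer_closure_from_screen(syn$blocks, repeats, cms$length,
                               max_states = config$isomer_max_states),
    error = function(e) NULL)

  summary <- list(
    cms_stats = genome_stats(cms, cms_annotations),
    normal_stats = genome_stats(normal, normal_annotations),
    n_blocks = nrow(syn$blocks),
    n_unique_regions = nrow(syn$unique_a),
    rearrangement_classes = as.list(attr(syn$blocks, "summary")),
    n_orfs = nrow(orfs),
    n_unique_orfs = sum(orfs$unique),
    n_unique_orfs_in_unique_region = sum(orfs$unique &
                                           orfs$in_unique_region),
    n_candidates = nrow(candidates),
    candidate_names = candidates$name,
    n_repeat_families = length(unique(repeats$family_id)),
    n_short_repeat_families =
      length(unique(repeats$family_id[repeats$size_class == "short"])),
    n_junction_repeat_families =
      length(unique(repeats$family_id[repeats$at_junction])),
    n_variants = nrow(variants),
    n_master_circle_isomers = if (is.null(isomers)) NA_integer_ else
      length(isomers$isomers),
    n_subgenomic_circles = if (is.null(isomers)) NA_integer_ else
      length(isomers$subcircles)
  )

  res <- structure(list(
    blocks = syn$blocks, unique_regions = syn$unique_a,
    unique_regions_b = syn$unique_b, orfs = orfs, candidates = candidates,
    repeats = repeats, variants = variants, isomers = isomers,
    summary = summary, config = config,
    len_a = cms$length, len_b = normal$length
  ), class = "mito_screen")
  if (!is.null(outdir)) write_screen_reports(res, outdir)
  res
}

# block-level circle model of the CMS genome: blocks in genome order with
# junction repeat elements (families with >= 2 junction copies) between
# them
isomer_closure_from_screen <- function(blocks, repeats, genome_len,
                                       max_states = 500) {
  if (nrow(blocks) == 0L) return(NULL)
  b <- dplyr::arrange(blocks, .data$start_a)
  segs <- character(0)
  eligible <- character(0)
  if (nrow(repeats)) {
    fam_j <- repeats %>%
      dplyr::group_by(.data$family_id) %>%
      dplyr::summarise(nj = sum(.data$at_junction), .groups = "drop")
    eligible <- fam_j$family_id[fam_j$nj >= 2L]
  }
  for (i in seq_len(nrow(b))) {
    segs <- c(segs, paste0("B", b$block_id[i]))
    gap_s <- b$end_a[i] + 1L
    gap_e <- if (i < nrow(b)) b$start_a[i + 1L] - 1L else
      b$start_a[1L] - 1L + genome_len
    if (gap_e < gap_s) next
    shifted <- ifelse(repeats$start < gap_s,
                      repeats$start + genome_len, repeats$start)
    in_gap <- repeats[repeats$family_id %in% eligible &
                        repeats$at_junction &
                        shifted >= gap_s & shifted <= gap_e, ,
                      drop = FALSE]
    in_gap <- dplyr::arrange(in_gap, .data$start)
    for (r in seq_len(nrow(in_gap))) {
      lab <- gsub("[^A-Za-z0-9]", "", in_gap$family_id[r])
      segs <- c(segs, if (in_gap$strand[r] == "-") paste0("-", lab)
                else lab)
    }
  }
  nm <- seg_name(segs)
  fams <- unique(nm[duplicated(nm)])
  fams <- setdiff(fams, paste0("B", b$block_id))
  if (length(fams) == 0L) {
    return(list(states = list(list(canonical_circle(segs))),
                isomers = list(canonical_circle(segs)),
                subcircles = character(0), master = segs))
  }
  out <- enumerate_isomers(segs, families = fams, max_states = max_states)
  out$master <- segs
  out
}

#' Write the report bundle of a screen
#'
#' Emits `blocks.tsv`, `unique_regions.bed` (0-based half-open),
#' `orfs.tsv`, `candidates.tsv`, `repeats.tsv`, `variants.tsv`,
#' `isomers.json`, `summary.json` and the resolved `config.yaml`.
#'
#' @param res A `mito_screen` object.
#' @param outdir Output directory.
#' @export
write_screen_reports <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  bl <- res$blocks
  bl$members <- NULL
  readr::write_tsv(bl, file.path(outdir, "blocks.tsv"))
  # BED: 0-based half-open; wrapped intervals split at the origin
  ur <- res$unique_regions
  bed <- list()
  for (i in seq_len(nrow(ur))) {
    if (ur$end[i] >= ur$start[i]) {
      bed[[length(bed) + 1L]] <- tibble::tibble(
        chrom = "cms", start = ur$start[i] - 1L, end = ur$end[i],
        name = sprintf("unique_%d", i))
    } else {
      bed[[length(bed) + 1L]] <- tibble::tibble(
        chrom = "cms", start = c(ur$start[i] - 1L, 0L),
        end = c(res$len_a, ur$end[i]),
        name = sprintf("unique_%d", i))
    }
  }
  bed <- if (length(bed)) dplyr::bind_rows(bed) else
    tibble::tibble(chrom = character(0), start = integer(0),
                   end = integer(0), name = character(0))
  readr::write_tsv(bed, file.path(outdir, "unique_regions.bed"),
                   col_names = FALSE)
  flatten_orfs <- function(o) {
    o$tm_segments <- vapply(o$tm_segments, function(x) {
      if (is.null(x) || nrow(x) == 0L) "" else
        paste(sprintf("%d-%d", x$start, x$end), collapse = ";")
    }, character(1))
    o$chimeric_segments <- vapply(o$chimeric_segments, function(x) {
      if (is.null(x) || nrow(x) == 0L) "" else
        paste(sprintf("%s:%d-%d", x$source_gene, x$orf_start, x$orf_end),
              collapse = ";")
    }, character(1))
    o$novel_segments <- vapply(o$novel_segments, function(x) {
      if (is.null(x) || nrow(x) == 0L) "" else
        paste(sprintf("%d-%d", x$orf_start, x$orf_end), collapse = ";")
    }, character(1))
    o$nt <- NULL
    o$protein <- NULL
    o
  }
  readr::write_tsv(flatten_orfs(res$orfs), file.path(outdir, "orfs.tsv"))
  readr::write_tsv(flatten_orfs(res$candidates),
                   file.path(outdir, "candidates.tsv"))
  reps <- res$repeats
  if (!is.null(reps$junction_hits)) {
    reps$junction_hits <- vapply(reps$junction_hits, paste,
                                 character(1), collapse = ";")
  }
  readr::write_tsv(reps, file.path(outdir, "repeats.tsv"))
  readr::write_tsv(res$variants, file.path(outdir, "variants.tsv"))
  if (!is.null(res$isomers)) {
    iso <- list(
      master = res$isomers$master,
      isomers = lapply(res$isomers$isomers, as.character),
      subcircles = res$isomers$subcircles
    )
    jsonlite::write_json(iso, file.path(outdir, "isomers.json"),
                         auto_unbox = FALSE)
  }
  jsonlite::write_json(res$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(res$config, file.path(outdir, "config.yaml"))
  invisible(outdir)
}

#' @export
print.mito_screen <- function(x, ...) {
  s <- x$summary
  cat("<mito_screen>\n")
  cat(sprintf("  genomes: %s bp (screened) vs %s bp\n",
              format(x$len_a, big.mark = ","),
              format(x$len_b, big.mark = ",")))
  cat(sprintf("  syntenic blocks: %d; unique regions: %d\n",
              s$n_blocks, s$n_unique_regions))
  cat(sprintf("  ORFs: %d (%d unique); candidates: %d\n",
              s$n_orfs, s$n_unique_orfs, s$n_candidates))
  if (length(s$candidate_names)) {
    cat("  candidates:", paste(s$candidate_names, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Candidate table of a screen, broom-style
#'
#' @param x A `mito_screen` object.
#' @param ... Unused.
#' @return Tibble of candidate ORFs with their screening flags.
#' @method tidy mito_screen
#' @export
tidy.mito_screen <- function(x, ...) {
  dplyr::select(x$candidates, "name", "start", "end", "strand",
                "aa_count", "unique", "in_unique_region", "chimeric",
                "n_tm", "adjacent_gene", "adjacent_distance")
}

#' One-row summary of a screen, broom-style
#'
#' @param x A `mito_screen` object.
#' @param ... Unused.
#' @method glance mito_screen
#' @export
glance.mito_screen <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_blocks = s$n_blocks, n_unique_regions = s$n_unique_regions,
    n_orfs = s$n_orfs, n_unique_orfs = s$n_unique_orfs,
    n_candidates = s$n_candidates,
    n_short_repeat_families = s$n_short_repeat_families,
    n_junction_repeat_families = s$n_junction_repeat_families,
    n_variants = s$n_variants,
    n_master_circle_isomers = s$n_master_circle_isomers,
    n_subgenomic_circles = s$n_subgenomic_circles
  )
}

#' Synteny diagram of a screen
#'
#' Draws the two genomes as horizontal bars with ribbons connecting
#' syntenic blocks, colored by rearrangement class.
#'
#' @param x A `mito_screen` object (or classified block tibble with
#'   `len_a`/`len_b` attributes).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_synteny <- function(x, ...) {
  blocks <- if (inherits(x, "mito_screen")) x$blocks else x
  ribbon <- dplyr::bind_rows(lapply(seq_len(nrow(blocks)), function(i) {
    tibble::tibble(
      block_id = blocks$block_id[i],
      class = blocks$class[i],
      xa = c(blocks$start_a[i], blocks$end_a[i]),
      xb = if (blocks$orientation[i] == "forward") {
        c(blocks$start_b[i], blocks$end_b[i])
      } else {
        c(blocks$end_b[i], blocks$start_b[i])
      })
  }))
  ggplot2::ggplot(ribbon) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$xa, xend = .data$xb,
                                       y = 1, yend = 0,
                                       colour = .data$class),
                          alpha = 0.6) +
    ggplot2::scale_y_continuous(breaks = c(0, 1),
                                labels = c("normal", "screened")) +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = "class") +
    ggplot2::theme_minimal()
}

#' Autoplot method for screen results
#' @param object A `mito_screen` object.
#' @param ... Unused.
#' @method autoplot mito_screen
#' @export
autoplot.mito_screen <- function(object, ...) plot_synteny(object, ...)

#' Bar plot of relative expression with error bars
#'
#' @param expr Tibble from [ddct()].
#' @return A ggplot object.
#' @export
plot_expression <- function(expr) {
  ggplot2::ggplot(expr, ggplot2::aes(x = .data$group,
                                     y = .data$rel_expr)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rel_expr - .data$se,
                                        ymax = .data$rel_expr + .data$se),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = expression(2^{-Delta*Delta*Ct})) +
    ggplot2::theme_minimal()
}
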