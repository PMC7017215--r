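#' Relative expression by the 2^-ddCt method
#'
#' For each sample, dCt is the mean target Ct minus the mean reference Ct
#' across replicates; ddCt subtracts the mean dCt of the calibrator group;
#' relative expression is `2^-ddCt`. Standard errors are propagated from
#' replicate variation (SE of a difference of replicate means, then the
#' delta method for the exponentiation).
#'
#' @param ct_table Tibble with columns `sample_id`, `group`, `gene`
#'   (`"target"` or `"reference"`), `replicate`, `ct`.
#' @param calibrator_group Group whose mean dCt serves as calibrator.
#' @return Tibble per group: `group`, `n_samples`, `dct`, `ddct`,
#'   `rel_expr`, `se` (delta-method SE of `rel_expr`).
#' @export
ddct <- function(ct_table, calibrator_group) {
  stopifnot(all(c("sample_id", "group", "gene", "replicate", "ct") %in%
                  names(ct_table)))
  if (!calibrator_group %in% ct_table$group) {
    stop("calibrator group '", calibrator_group,
         "' not present in the Ct table", call. = FALSE)
  }
  per_sample <- ct_table %>%
    dplyr::group_by(.data$sample_id, .data$group, .data$gene) %>%
    dplyr::summarise(mean_ct = mean(.data$ct),
                     var_ct = stats::var(.data$ct),
                     n = dplyr::n(), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "gene",
                       values_from = c("mean_ct", "var_ct", "n"))
  if (!all(c("mean_ct_target", "mean_ct_reference") %in%
           names(per_sample)) ||
      anyNA(per_sample$mean_ct_target) ||
      anyNA(per_sample$mean_ct_reference)) {
    stop("every sample needs both target and reference gene measurements",
         call. = FALSE)
  }
  per_sample <- per_sample %>%
    dplyr::mutate(
      dct = .data$mean_ct_target - .data$mean_ct_reference,
      var_dct = dplyr::coalesce(.data$var_ct_target, 0) /
        .data$n_target +
        dplyr::coalesce(.data$var_ct_reference, 0) / .data$n_reference
    )
  cal <- dplyr::filter(per_sample, .data$group == calibrator_group)
  cal_mean <- mean(cal$dct)
  cal_var <- sum(cal$var_dct) / nrow(cal)^2
  per_sample %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(
      n_samples = dplyr::n(),
      dct = mean(.data$dct),
      var_dct_grp = sum(.data$var_dct) / dplyr::n()^2,
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      ddct = .data$dct - cal_mean,
      rel_expr = 2^(-.data$ddct),
      se = log(2) * .data$rel_expr *
        sqrt(.data$var_dct_grp + cal_var)
    ) %>%
    dplyr::select("group", "n_samples", "dct", "ddct", "rel_expr", "se")
}

#' Tabulate marker presence across accessions
#'
#' @param presence_table Tibble with columns `accession`, `species`,
#'   `present` (logical or 0/1).
#' @return List with `per_species` (tibble: `species`, `total`,
#'   `positive`) and `overall` (tibble: `total`, `positive`,
#'   `percent` to 2 decimals).
#' @export
tabulate_marker <- function(presence_table) {
  stopifnot(all(c("accession", "species", "present") %in%
                  names(presence_table)))
  per <- presence_table %>%
    dplyr::group_by(.data$species) %>%
    dplyr::summarise(total = dplyr::n(),
                     positive = sum(as.logical(.data$present)),
                     .groups = "drop")
  total <- nrow(presence_table)
  pos <- sum(as.logical(presence_table$present))
  list(
    per_species = per,
    overall = tibble::tibble(
      total = total, positive = pos,
      percent = round(100 * pos / total, 2)
    )
  )
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Ties are broken
#' deterministically by taxon label order; negative branch lengths are
#' clamped to zero with the deficit moved to the sister edge.
#'
#' @param dm Symmetric numeric matrix with zero diagonal and taxa labels as
#'   dimnames, or an object coercible via `as.matrix()`.
#' @return An [ape::phylo] object (unrooted); the sum of branch lengths is
#'   attached as attribute `branch_length_sum`.
#' @export
nj_tree <- function(dm) {
  d <- as.matrix(dm)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  rownames(d) <- colnames(d) <- labels
  frag <- stats::setNames(as.list(labels), labels)
  active <- labels
  total_len <- 0
  fmt <- function(x) sprintf("%.15g", x)
  while (length(active) > 3L) {
    m <- length(active)
    dd <- d[active, active, drop = FALSE]
    rs <- rowSums(dd)
    q <- (m - 2) * dd - outer(rs, rs, `+`)
    diag(q) <- Inf
    minq <- min(q)
    cand <- which(q - minq <= 1e-12 * max(1, abs(minq)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ord <- order(rownames(dd)[cand[, 1]], rownames(dd)[cand[, 2]])
    i <- cand[ord[1], 1]; j <- cand[ord[1], 2]
    li <- active[i]; lj <- active[j]
    vi <- 0.5 * dd[i, j] + (rs[i] - rs[j]) / (2 * (m - 2))
    vj <- dd[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_lab <- paste0(".n", length(frag) + 1L)
    frag[[new_lab]] <- sprintf("(%s:%s,%s:%s)", frag[[li]], fmt(vi),
                               frag[[lj]], fmt(vj))
    total_len <- total_len + vi + vj
    others <- setdiff(active, c(li, lj))
    dnew <- 0.5 * (d[li, others] + d[lj, others] - d[li, lj])
    d <- rbind(cbind(d, 0), 0)
    rownames(d)[nrow(d)] <- colnames(d)[ncol(d)] <- new_lab
    d[new_lab, others] <- dnew
    d[others, new_lab] <- dnew
    active <- c(others, new_lab)
  }
  # closed-form star resolution of the last three lineages
  a <- active[1]; b <- active[2]; cc <- active[3]
  la <- (d[a, b] + d[a, cc] - d[b, cc]) / 2
  lb <- (d[a, b] + d[b, cc] - d[a, cc]) / 2
  lc <- (d[a, cc] + d[b, cc] - d[a, b]) / 2
  lens <- pmax(c(la, lb, lc), 0)
  total_len <- total_len + sum(lens)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[[a]], fmt(lens[1]),
                 frag[[b]], fmt(lens[2]), frag[[cc]], fmt(lens[3]))
  tr <- ape::read.tree(text = nwk)
  attr(tr, "branch_length_sum") <- total_len
  tr
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' `d = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q))` with `P` the transition and
#' `Q` the transversion fraction over gap-free aligned columns.
#'
#' @param aligned_a,aligned_b Equal-length aligned sequences (gaps `-`
#'   allowed; gapped or ambiguous columns are dropped).
#' @return Distance (substitutions per site).
#' @export
k2p_distance <- function(aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b)) {
    stop("aligned sequences have unequal length", call. = FALSE)
  }
  a <- strsplit(toupper(aligned_a), "")[[1]]
  b <- strsplit(toupper(aligned_b), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L) stop("no comparable columns", call. = FALSE)
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    stop("K2P distance saturated (log argument <= 0)", call. = FALSE)
  }
  -0.5 * log(arg1 * sqrt(arg2))
}
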