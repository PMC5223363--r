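#' Downsample age groups to a common size
#'
#' Randomly selects, without replacement, the smallest group's size from each
#' larger group, so all groups are matched in size (e.g. groups of 543/238/106
#' become 106/106/106, total 318). Selection is reproducible from `rng_seed`;
#' already-equal groups are returned with identical membership.
#'
#' @param cohort A cohort tibble with an `age_group` column.
#' @param rng_seed Integer seed.
#' @return The reduced cohort (original row order preserved), with a
#'   `selection_log` attribute (tibble: `age_group`, `n_before`, `n_after`).
#' @export
matched_subsample <- function(cohort, rng_seed = 1L) {
  stopifnot("age_group" %in% names(cohort))
  groups <- unique(as.character(cohort$age_group))
  if (length(groups) < 2L) stop("need at least 2 age groups")
  sizes <- table(as.character(cohort$age_group))
  if (any(sizes == 0L)) stop("empty age group")
  n_min <- min(sizes)
  keep <- with_seed(derive_seed(rng_seed, "matched_subsample"), {
    unlist(lapply(groups, function(g) {
      idx <- which(as.character(cohort$age_group) == g)
      if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
    }))
  })
  keep <- sort(keep)
  out <- cohort[keep, , drop = FALSE]
  log <- tibble::tibble(age_group = groups,
                        n_before = as.integer(sizes[groups]),
                        n_after = n_min)
  attr(out, "selection_log") <- log
  for (a in c("thickness", "ledger", "config")) {
    if (!is.null(attr(cohort, a))) attr(out, a) <- attr(cohort, a)
  }
  if (!is.null(attr(cohort, "thickness"))) {
    th <- attr(cohort, "thickness")
    attr(out, "thickness") <- th[th$subject_id %in% out$subject_id, ]
  }
  out
}

# stack per-subject connectivity matrices into a subjects x pairs matrix
stack_edges <- function(matrices, atlas) {
  pairs <- node_pair_table(atlas)
  idx <- cbind(pairs$i, pairs$j)
  out <- t(vapply(matrices, function(m) m[idx], numeric(nrow(pairs))))
  rownames(out) <- names(matrices)
  attr(out, "pairs") <- pairs
  out
}

#' Per-age-group mean connectivity matrices
#'
#' Per node pair and age group: mean Fisher z, SD, and the number of subjects
#' with a non-missing value (missing pairs are excluded pairwise).
#'
#' @param matrices Named list of `connectivity_matrix` objects (names =
#'   subject ids).
#' @param cohort Cohort tibble with `subject_id` and `age_group`.
#' @param atlas The `roi_atlas`.
#' @return Tibble: pair columns (`i`, `j`, `node_a`, `node_b`, `network_a`,
#'   `network_b`, `within`) plus `age_group`, `mean_z`, `sd_z`, `n`.
#' @export
group_mean_matrices <- function(matrices, cohort, atlas) {
  edges <- stack_edges(matrices[cohort$subject_id], atlas)
  pairs <- attr(edges, "pairs")
  groups <- unique(as.character(cohort$age_group))
  purrr::map_dfr(groups, function(g) {
    sub <- edges[as.character(cohort$age_group) == g, , drop = FALSE]
    if (nrow(sub) < 2L) stop("need >= 2 subjects per group (", g, ")")
    n_ok <- colSums(!is.na(sub))
    dplyr::mutate(pairs, age_group = g,
                  mean_z = colMeans(sub, na.rm = TRUE),
                  sd_z = apply(sub, 2L, stats::sd, na.rm = TRUE),
                  n = n_ok)
  })
}

# vectorised Welch two-sample t over columns; returns list(t, df, p)
welch_t_cols <- function(a, b) {
  na <- colSums(!is.na(a)); nb <- colSums(!is.na(b))
  ma <- colMeans(a, na.rm = TRUE); mb <- colMeans(b, na.rm = TRUE)
  va <- apply(a, 2L, stats::var, na.rm = TRUE)
  vb <- apply(b, 2L, stats::var, na.rm = TRUE)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(delta = ma - mb, t = t, df = df, p = p, na = na, nb = nb,
       va = va, vb = vb)
}

#' Age-group difference matrix with FDR correction
#'
#' For every node pair, compares the two groups' subject Fisher-z values with
#' a Welch two-sample t test (difference reported as earlier group minus
#' later group, e.g. "Y-M" = mean(young) - mean(middle)), then corrects the
#' p values jointly across all pairs in the matrix. The default correction is
#' Benjamini-Yekutieli, valid under arbitrary dependence between pairs;
#' Benjamini-Hochberg is available via `fdr_method = "BH"`. Pairs with
#' degenerate variance in both groups are marked untestable and excluded from
#' the correction family (recorded in the `untestable` attribute).
#'
#' @param matrices Named list of `connectivity_matrix` objects.
#' @param cohort Cohort tibble (`subject_id`, `age_group`).
#' @param group_a Earlier group label (difference = A - B).
#' @param group_b Later group label.
#' @param atlas The `roi_atlas`.
#' @param alpha FDR level (default 0.05).
#' @param fdr_method `"BY"` (default) or `"BH"`.
#' @return Tibble of class `difference_matrix`: pair columns plus `delta_z`,
#'   `t`, `df`, `p`, `q`, `significant`; attributes `alpha`, `fdr_method`,
#'   `groups`, `untestable` (pair count excluded).
#' @export
difference_matrix_test <- function(matrices, cohort, group_a, group_b, atlas,
                                   alpha = 0.05,
                                   fdr_method = c("BY", "BH")) {
  fdr_method <- match.arg(fdr_method)
  ga <- as.character(cohort$age_group) == group_a
  gb <- as.character(cohort$age_group) == group_b
  if (sum(ga) < 2L || sum(gb) < 2L) stop("need >= 2 subjects per group")
  edges <- stack_edges(matrices[cohort$subject_id], atlas)
  pairs <- attr(edges, "pairs")
  w <- welch_t_cols(edges[ga, , drop = FALSE], edges[gb, , drop = FALSE])
  untestable <- !is.finite(w$t)
  p <- w$p
  q <- rep(NA_real_, length(p))
  q[!untestable] <- stats::p.adjust(p[!untestable], method = fdr_method)
  out <- dplyr::mutate(pairs, delta_z = w$delta, t = w$t, df = w$df,
                       p = p, q = q,
                       significant = !untestable & q <= alpha)
  attr(out, "alpha") <- alpha
  attr(out, "fdr_method") <- fdr_method
  attr(out, "groups") <- c(group_a, group_b)
  attr(out, "untestable") <- sum(untestable)
  class(out) <- c("difference_matrix", class(out))
  out
}

#' Voxelwise two-sample t map with permutation family-wise-error control
#'
#' Computes a Welch t statistic per voxel and controls family-wise error by
#' group-label permutation of the maximum |t| over voxels: significant voxels
#' are those whose observed |t| exceeds the (1 - alpha) quantile of the
#' permutation max-|t| null.
#'
#' @param maps Subjects x voxels matrix (e.g. flattened seed z maps on a
#'   common grid).
#' @param groups Character/factor vector of length `nrow(maps)` with two
#'   levels.
#' @param n_perm Number of label permutations (>= 1000 recommended; < 100
#'   triggers a warning).
#' @param alpha Family-wise error level.
#' @param rng_seed Integer seed for the permutations.
#' @return List: `t` (voxel t values), `threshold`, `mask` (logical),
#'   `null_max_t` (permutation distribution).
#' @export
voxelwise_group_ttest <- function(maps, groups, n_perm = 1000, alpha = 0.05,
                                  rng_seed = 1L) {
  stopifnot(is.matrix(maps), nrow(maps) == length(groups))
  groups <- as.character(groups)
  lev <- unique(groups)
  stopifnot(length(lev) == 2L)
  if (any(table(groups) < 2L)) stop("need >= 2 subjects per group")
  if (n_perm < 100) warning("n_perm < 100 gives an unstable null")
  tstat <- function(lab) {
    w <- welch_t_cols(maps[lab == lev[1L], , drop = FALSE],
                      maps[lab == lev[2L], , drop = FALSE])
    t <- w$t
    t[!is.finite(t)] <- 0
    t
  }
  t_obs <- tstat(groups)
  null_max <- with_seed(derive_seed(rng_seed, "maxt"), {
    vapply(seq_len(n_perm), function(b) max(abs(tstat(sample(groups)))),
           numeric(1L))
  })
  thr <- stats::quantile(null_max, 1 - alpha, names = FALSE, type = 8)
  list(t = t_obs, threshold = thr, mask = abs(t_obs) > thr,
       null_max_t = null_max)
}
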