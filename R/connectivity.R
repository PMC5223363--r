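#' Extract mean ROI time series from a preprocessed run
#'
#' Each node's series is the unweighted mean, per frame, over the voxels
#' whose centres fall inside its sphere.
#'
#' @param run A `bold_run` (preprocessed).
#' @param atlas An `roi_atlas`.
#' @param radius_override Optional single radius in mm replacing every node's
#'   own radius (e.g. 4 mm spheres for peak-based box plots).
#' @return Matrix frames x nodes, columns named by node id, with attribute
#'   `atlas_hash`.
#' @export
extract_roi_timeseries <- function(run, atlas, radius_override = NULL) {
  stopifnot(inherits(run, "bold_run"), inherits(atlas, "roi_atlas"))
  dims <- dim(run)[1:3]
  nt <- run_n_frames(run)
  dat <- matrix(unclass_bold(run), prod(dims), nt)
  out <- matrix(NA_real_, nt, nrow(atlas),
                dimnames = list(NULL, atlas$node_id))
  empty <- character(0)
  for (k in seq_len(nrow(atlas))) {
    r <- radius_override %||% atlas$radius_mm[k]
    idx <- voxels_in_sphere(dims, run_affine(run),
                            c(atlas$x[k], atlas$y[k], atlas$z[k]), r)
    if (length(idx) == 0L) {
      empty <- c(empty, atlas$node_id[k])
    } else {
      out[, k] <- colMeans(dat[idx, , drop = FALSE])
    }
  }
  if (length(empty) > 0L) {
    stop("empty ROI sphere(s) on grid ", paste(dims, collapse = "x"),
         " (voxel ", paste(sqrt(colSums(run_affine(run)[1:3, 1:3]^2)),
                           collapse = "x"), " mm): ",
         paste(empty, collapse = ", "))
  }
  attr(out, "atlas_hash") <- atlas_hash(atlas)
  out
}

#' Pairwise Pearson correlation of node time series
#'
#' @param series Frames x nodes matrix (>= 4 frames).
#' @return Symmetric correlation matrix with unit diagonal. A zero-variance
#'   series propagates `NA` through its row/column, with a warning.
#' @export
pairwise_correlation <- function(series) {
  stopifnot(is.matrix(series))
  if (nrow(series) < 4L) stop("need at least 4 frames")
  sds <- apply(series, 2L, stats::sd)
  degenerate <- which(sds == 0 | !is.finite(sds))
  if (length(degenerate) > 0L) {
    warning("zero-variance series: ",
            paste(colnames(series)[degenerate], collapse = ", "),
            "; their correlations are set to NA")
    series[, degenerate] <- NA_real_
  }
  r <- suppressWarnings(stats::cor(series, use = "everything"))
  diag(r) <- 1
  r
}

#' Fisher r-to-z transform
#'
#' z(r) = 0.5 ln((1 + r) / (1 - r)); odd and strictly increasing on (-1, 1).
#'
#' @param r Correlation value(s) with |r| < 1 (`NA` passes through).
#' @return z value(s), same shape as `r`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    stop("|r| must be < 1 (exclude the matrix diagonal before transforming)")
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Per-subject Fisher-z connectivity matrix
#'
#' Correlates all node pairs and applies the Fisher transform; the diagonal
#' is excluded (set to `NA`).
#'
#' @param series Frames x nodes matrix from [extract_roi_timeseries()] (or
#'   any node series matrix).
#' @param atlas The `roi_atlas` fixing node order.
#' @return Symmetric node x node matrix of class `connectivity_matrix` with
#'   `NA` diagonal and an `atlas_hash` attribute.
#' @export
subject_connectivity <- function(series, atlas) {
  stopifnot(inherits(atlas, "roi_atlas"))
  if (!is.null(colnames(series)) &&
      !identical(colnames(series), atlas$node_id)) {
    stop("series columns do not match atlas node order")
  }
  r <- pairwise_correlation(series)
  diag(r) <- NA_real_
  z <- fisher_z(r)
  dimnames(z) <- list(atlas$node_id, atlas$node_id)
  structure(z, atlas_hash = atlas_hash(atlas),
            class = c("connectivity_matrix", "matrix", "array"))
}

#' Tidy edge list of a connectivity matrix
#'
#' @param z_matrix A `connectivity_matrix`.
#' @param atlas The matching `roi_atlas`.
#' @return Tibble: `node_a`, `node_b`, `network_a`, `network_b`, `within`,
#'   `z`, `r`.
#' @export
connectivity_edges <- function(z_matrix, atlas) {
  pairs <- node_pair_table(atlas)
  z <- z_matrix[cbind(pairs$i, pairs$j)]
  dplyr::mutate(pairs, z = z, r = tanh(z))[
    , c("node_a", "node_b", "network_a", "network_b", "within", "z", "r")]
}

#' Per-network mean connectivity of one subject
#'
#' Arithmetic mean of Fisher-z values over each network's within-network node
#' pairs; signed values are kept, so anticorrelated pairs lower the mean.
#'
#' @param z_matrix A `connectivity_matrix`.
#' @param atlas The matching `roi_atlas`.
#' @return Tibble: `network`, `n_pairs`, `mean_z` (one row per network, in
#'   atlas network order).
#' @export
subject_network_summary <- function(z_matrix, atlas) {
  stopifnot(inherits(atlas, "roi_atlas"))
  h <- attr(z_matrix, "atlas_hash")
  if (!is.null(h) && !identical(h, atlas_hash(atlas))) {
    stop("connectivity matrix was computed under a different atlas")
  }
  pairs <- node_pair_table(atlas)
  within <- pairs[pairs$within, ]
  z <- z_matrix[cbind(within$i, within$j)]
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(network = within$network_a, z = z),
                    .data$network),
    n_pairs = dplyr::n(), mean_z = mean(.data$z), .groups = "drop")
  nets <- atlas_networks(atlas)$network
  agg[match(nets, agg$network), , drop = FALSE]
}

#' Seed-to-voxel correlation map
#'
#' Correlates one seed time course with every brain-mask voxel's time course;
#' the Fisher-z map clamps |r| at 1 - 1e-7 so seed voxels (r = 1) stay
#' finite.
#'
#' @param run A preprocessed `bold_run`.
#' @param seed_series Numeric vector, one value per frame.
#' @param brain_mask 3-D logical array (`NULL` = all voxels).
#' @return List with 3-D arrays `r` and `z` (`NA` outside the mask).
#' @export
seed_correlation_map <- function(run, seed_series, brain_mask = NULL) {
  stopifnot(inherits(run, "bold_run"))
  nt <- run_n_frames(run)
  stopifnot(length(seed_series) == nt)
  dims <- dim(run)[1:3]
  dat <- matrix(unclass_bold(run), prod(dims), nt)
  idx <- if (is.null(brain_mask)) seq_len(nrow(dat)) else
    which(as.vector(brain_mask))
  x <- dat[idx, , drop = FALSE]
  xc <- x - rowMeans(x)
  s <- seed_series - mean(seed_series)
  num <- as.vector(xc %*% s)
  den <- sqrt(rowSums(xc^2) * sum(s^2))
  r <- ifelse(den > 0, num / den, NA_real_)
  rmap <- array(NA_real_, dims)
  rmap[idx] <- r
  zmap <- array(NA_real_, dims)
  zmap[idx] <- fisher_z(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
  list(r = rmap, z = zmap)
}
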