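#' Read an ROI table
#'
#' Tab-separated, header `name network x y z radius_mm` (radius optional).
#'
#' @param path File path.
#' @return Tibble with one row per region.
#' @export
read_roi_table <- function(path) {
  if (!file.exists(path)) stop("ROI table not found: ", path)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a rigid-body motion trace
#'
#' Whitespace-separated, six columns per frame: three translations in mm then
#' three rotations in radians.
#'
#' @param path File path.
#' @return Numeric matrix frames x 6 with columns `trans_x..rot_z`.
#' @export
read_motion <- function(path) {
  if (!file.exists(path)) stop("motion file not found: ", path)
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L) {
    stop("motion trace must have exactly 6 columns (got ", ncol(m), "): ", path)
  }
  storage.mode(m) <- "double"
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

#' Write a motion trace
#' @param motion Frames x 6 matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motion <- function(motion, path) {
  stopifnot(is.matrix(motion), ncol(motion) == 6L)
  utils::write.table(motion, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a subject metadata table
#'
#' Tab-separated with at least `subject_id`, `age`, `age_group`, `gender`,
#' `center`, `tr`, `n_frames`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read / write a BOLD run as NIfTI-1
#'
#' The voxel-to-MNI affine is preserved exactly; `read_bold` returns a
#' `bold_run` (4-D array plus `affine` and `tr` attributes).
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return `read_bold`: a `bold_run`; `write_bold`: `path`, invisibly.
#' @export
read_bold <- function(path) {
  if (!file.exists(path)) stop("BOLD file not found: ", path)
  img <- RNifti::readNifti(path)
  dat <- array(as.numeric(img), dim = dim(img))
  if (length(dim(dat)) == 3L) dim(dat) <- c(dim(dat), 1L)
  hdr <- RNifti::niftiHeader(img)
  tr <- as.numeric(hdr$pixdim[5L])
  aff <- RNifti::xform(img)
  attributes(aff) <- list(dim = dim(aff))
  bold_run(dat, affine = aff, tr = tr)
}

#' @rdname read_bold
#' @param run A `bold_run`.
#' @export
write_bold <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  img <- RNifti::asNifti(unclass_bold(run))
  aff <- run_affine(run)
  vox <- sqrt(colSums(aff[1:3, 1:3]^2))
  img <- RNifti::`pixdim<-`(img, c(vox, run_tr(run)))
  img <- RNifti::`sform<-`(img, structure(aff, code = 4L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a data frame as TSV (tab separated, UTF-8, `.` decimal, header row)
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Write a connectivity matrix as TSV and as a flat edge list
#'
#' The matrix file carries node ids as header and row names; the edge list has
#' columns `node_a node_b r z`.
#'
#' @param z_matrix Symmetric Fisher-z matrix with node-id dimnames.
#' @param path Output path for the matrix TSV.
#' @param edge_path Optional output path for the edge list.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(z_matrix, path, edge_path = NULL) {
  df <- data.frame(node_id = rownames(z_matrix), z_matrix,
                   check.names = FALSE)
  readr::write_tsv(df, path, progress = FALSE)
  if (!is.null(edge_path)) {
    n <- nrow(z_matrix)
    idx <- which(upper.tri(z_matrix), arr.ind = TRUE)
    edges <- tibble::tibble(
      node_a = rownames(z_matrix)[idx[, 1L]],
      node_b = colnames(z_matrix)[idx[, 2L]],
      z = z_matrix[idx],
      r = tanh(z_matrix[idx])
    )[, c("node_a", "node_b", "r", "z")]
    readr::write_tsv(edges, edge_path, progress = FALSE)
  }
  invisible(path)
}
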