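#' BOLD run container
#'
#' A 4-D lattice (x, y, z, t) of BOLD intensities on an MNI-aligned grid,
#' carrying its voxel-to-MNI-mm affine and repetition time.
#'
#' @param data 4-D numeric array.
#' @param affine 4x4 invertible voxel-to-mm map (0-based voxel indices).
#' @param tr Repetition time in seconds.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, affine, tr) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  if (!all(is.finite(data))) stop("BOLD data contains non-finite values")
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (abs(det(affine)) < 1e-12) stop("affine is not invertible")
  stopifnot(is.numeric(tr), length(tr) == 1L, tr > 0)
  structure(data, affine = affine, tr = tr, class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x)
  cat("<bold_run> ", paste(d[1:3], collapse = "x"), " voxels, ", d[4L],
      " frames, TR ", attr(x, "tr"), " s\n", sep = "")
  invisible(x)
}

#' Accessors for `bold_run`
#' @param run A `bold_run`.
#' @return The affine matrix, TR (s), frame count, or bare array.
#' @export
run_affine <- function(run) attr(run, "affine")

#' @rdname run_affine
#' @export
run_tr <- function(run) attr(run, "tr")

#' @rdname run_affine
#' @export
run_n_frames <- function(run) dim(run)[4L]

#' @rdname run_affine
#' @export
unclass_bold <- function(run) {
  x <- run
  attributes(x) <- list(dim = dim(run))
  x
}

# rebuild a bold_run with new data but same geometry
rewrap_bold <- function(data, template) {
  bold_run(data, affine = run_affine(template), tr = run_tr(template))
}

#' Define an MNI-aligned sampling grid
#'
#' The default grid is 4 mm isotropic, 46 x 55 x 46 voxels, covering the MNI
#' bounding box x -90..90, y -126..90, z -72..108 mm. A 2 mm grid (or any
#' other isotropic spacing) is available through `voxel_mm`.
#'
#' @param voxel_mm Isotropic voxel size in mm (> 0).
#' @param dims Optional integer triplet; derived from `voxel_mm` if missing.
#' @return List with `dims`, `voxel_mm` and the 4x4 `affine` (0-based voxel
#'   index to MNI mm).
#' @export
mni_grid <- function(voxel_mm = 4, dims = NULL) {
  stopifnot(voxel_mm > 0)
  lo <- c(-90, -126, -72)
  hi <- c(90, 90, 108)
  if (is.null(dims)) dims <- floor((hi - lo) / voxel_mm) + 1L
  dims <- as.integer(dims)
  affine <- diag(c(rep(voxel_mm, 3L), 1))
  affine[1:3, 4L] <- lo
  list(dims = dims, voxel_mm = voxel_mm, affine = affine)
}

# n x 3 matrix of voxel-centre MNI coordinates, column-major voxel order
voxel_coords_mm <- function(dims, affine) {
  ijk <- as.matrix(expand.grid(i = 0:(dims[1L] - 1L), j = 0:(dims[2L] - 1L),
                               k = 0:(dims[3L] - 1L)))
  sweep(ijk %*% t(affine[1:3, 1:3]), 2L, affine[1:3, 4L], "+")
}

#' Linear voxel indices inside a sphere
#'
#' A voxel belongs to the sphere iff its centre (mapped to MNI mm through the
#' affine) lies within `radius_mm` of `center_mm` — deterministic and
#' independent of grid conventions.
#'
#' @param dims Grid dimensions (3 integers).
#' @param affine 4x4 voxel-to-mm map.
#' @param center_mm Length-3 MNI coordinate.
#' @param radius_mm Sphere radius in mm.
#' @return Integer vector of linear (column-major) voxel indices.
#' @export
voxels_in_sphere <- function(dims, affine, center_mm, radius_mm) {
  coords <- voxel_coords_mm(dims, affine)
  d2 <- (coords[, 1L] - center_mm[1L])^2 + (coords[, 2L] - center_mm[2L])^2 +
    (coords[, 3L] - center_mm[3L])^2
  which(d2 <= radius_mm^2)
}

#' Procedural tissue masks on a grid
#'
#' Brain: an ellipsoid (centre (0, -10, 10) mm, semi-axes 82 x 95 x 78 mm)
#' large enough to contain all standard ROI spheres. Lateral-ventricle and
#' deep-white-matter compartments are interior boxes, disjoint from each other
#' and from every standard ROI sphere.
#'
#' @param grid A grid from [mni_grid()].
#' @return List of 3-D logical arrays `brain`, `ventricle`, `deep_wm`.
#' @export
make_tissue_masks <- function(grid) {
  dims <- grid$dims
  co <- voxel_coords_mm(dims, grid$affine)
  x <- co[, 1L]; y <- co[, 2L]; z <- co[, 3L]
  brain <- ((x / 82)^2 + ((y + 10) / 95)^2 + ((z - 10) / 78)^2) <= 1
  ventricle <- abs(x) <= 12 & y >= -44 & y <= -12 & z >= 4 & z <= 28
  deep_wm <- abs(x) >= 26 & abs(x) <= 36 & y >= -42 & y <= -26 &
    z >= 16 & z <= 32
  ventricle <- ventricle & brain
  deep_wm <- deep_wm & brain & !ventricle
  shape <- function(v) array(v, dim = dims)
  masks <- list(brain = shape(brain), ventricle = shape(ventricle),
                deep_wm = shape(deep_wm))
  if (!any(masks$ventricle) || !any(masks$deep_wm) || !any(masks$brain)) {
    stop("tissue mask empty on this grid; use a finer grid")
  }
  masks
}
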