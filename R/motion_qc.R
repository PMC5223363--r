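#' Framewise displacement
#'
#' FD[t] = sum of absolute backward differences of the six rigid-body
#' parameters, with the three rotations converted from radians to mm as arc
#' length at `head_radius_mm`; FD of the first frame is 0.
#'
#' @param motion Frames x 6 matrix (translations mm, rotations rad).
#' @param head_radius_mm Sphere radius for rotation-to-mm conversion
#'   (default 50 mm).
#' @return Numeric vector of per-frame FD in mm.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  stopifnot(is.matrix(motion), ncol(motion) == 6L)
  if (nrow(motion) < 2L) stop("need at least 2 frames")
  if (any(abs(motion[, 4:6]) > pi)) {
    warning("rotation parameters exceed pi radians; check units")
  }
  d <- apply(motion, 2L, function(v) c(0, diff(v)))
  d[, 4:6] <- d[, 4:6] * head_radius_mm
  rowSums(abs(d))
}

#' DVARS: RMS of the temporal derivative of the BOLD signal
#'
#' DVARS[t] = sqrt(mean over brain-mask voxels of (x[t] - x[t-1])^2), with
#' DVARS of the first frame defined as 0.
#'
#' @param run A `bold_run`.
#' @param brain_mask 3-D logical array.
#' @return Numeric vector of per-frame DVARS in signal units.
#' @export
dvars <- function(run, brain_mask) {
  stopifnot(inherits(run, "bold_run"))
  idx <- which(as.vector(brain_mask))
  if (length(idx) == 0L) stop("empty mask: brain")
  nt <- run_n_frames(run)
  dat <- matrix(unclass_bold(run), prod(dim(run)[1:3]), nt)[idx, , drop = FALSE]
  d <- dat[, -1L, drop = FALSE] - dat[, -nt, drop = FALSE]
  c(0, sqrt(colMeans(d^2)))
}

#' Standardize DVARS against its predicted null value
#'
#' Divides DVARS by sqrt(mean over voxels of the robust per-voxel lag-1
#' difference variance), where each voxel's difference SD is estimated as
#' IQR(diff(x)) / 1.349. A temporally white run therefore yields values near
#' 1, and the result is invariant to rescaling the intensities.
#'
#' @param dvars_series Output of [dvars()].
#' @param run The same `bold_run`.
#' @param brain_mask The same mask.
#' @return Unitless per-frame series; all zeros (with a warning) if the
#'   predicted null value is zero (temporally constant data).
#' @export
standardize_dvars <- function(dvars_series, run, brain_mask) {
  stopifnot(inherits(run, "bold_run"))
  nt <- run_n_frames(run)
  if (nt < 3L) stop("need at least 3 frames")
  idx <- which(as.vector(brain_mask))
  dat <- matrix(unclass_bold(run), prod(dim(run)[1:3]), nt)[idx, , drop = FALSE]
  d <- dat[, -1L, drop = FALSE] - dat[, -nt, drop = FALSE]
  iqr <- apply(d, 1L, stats::IQR, type = 7)
  pred <- sqrt(mean((iqr / 1.349)^2))
  if (pred == 0) {
    warning("predicted null DVARS is zero (temporally constant data)")
    return(rep(0, length(dvars_series)))
  }
  dvars_series / pred
}

#' Compute per-subject motion QC metrics
#'
#' @param run A `bold_run`.
#' @param motion Frames x 6 motion matrix.
#' @param brain_mask 3-D logical array.
#' @param head_radius_mm Rotation-to-mm radius (default 50 mm).
#' @return List of class `qc_metrics`: `fd_series`, `dvars_series`,
#'   `dvars_std_series`, `mean_fd`, `mean_dvars_std` (means over frames
#'   2..T, i.e. excluding the zero-defined first frame).
#' @export
qc_metrics <- function(run, motion, brain_mask, head_radius_mm = 50) {
  fd <- framewise_displacement(motion, head_radius_mm)
  dv <- dvars(run, brain_mask)
  dvs <- standardize_dvars(dv, run, brain_mask)
  structure(list(
    fd_series = fd, dvars_series = dv, dvars_std_series = dvs,
    mean_fd = mean(fd[-1L]), mean_dvars_std = mean(dvs[-1L])
  ), class = "qc_metrics")
}

#' Screen subjects on motion QC bounds
#'
#' Pass iff mean FD is strictly below `fd_max_mm` and mean standardized DVARS
#' lies within the closed `dvars_std_range`. Default bounds are the screening
#' values of the retained sample: FD below 0.5 mm and standardized DVARS in
#' [0.7, 1.5]. Screening flags subjects; it does not drop them.
#'
#' @param metrics A `qc_metrics`, or a data frame with `mean_fd` and
#'   `mean_dvars_std` columns.
#' @param fd_max_mm Exclusive upper bound on mean FD (mm).
#' @param dvars_std_range Closed range for mean standardized DVARS.
#' @return Tibble with `mean_fd`, `mean_dvars_std`, `pass_flag`, `reason`
#'   (machine-readable, `"ok"` or `;`-joined failure codes).
#' @export
qc_screen <- function(metrics, fd_max_mm = 0.5, dvars_std_range = c(0.7, 1.5)) {
  if (inherits(metrics, "qc_metrics")) {
    tab <- tibble::tibble(mean_fd = metrics$mean_fd,
                          mean_dvars_std = metrics$mean_dvars_std)
  } else {
    tab <- tibble::as_tibble(metrics)
  }
  fd_ok <- tab$mean_fd < fd_max_mm
  dv_ok <- tab$mean_dvars_std >= dvars_std_range[1L] &
    tab$mean_dvars_std <= dvars_std_range[2L]
  reason <- purrr::map2_chr(fd_ok, dv_ok, function(f, d) {
    codes <- c(if (!f) "mean_fd_exceeds_max",
               if (!d) "mean_dvars_std_out_of_range")
    if (length(codes) == 0L) "ok" else paste(codes, collapse = ";")
  })
  dplyr::mutate(tab, pass_flag = fd_ok & dv_ok, reason = reason)
}
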