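#' Preprocessing configuration
#'
#' @param lowpass_hz Low-pass cutoff in Hz (default 0.08; must stay below the
#'   Nyquist frequency 1/(2 TR) of each run).
#' @param smooth_fwhm_mm Gaussian smoothing kernel full width at half
#'   maximum, mm (default 4; 0 disables smoothing).
#' @param gsr Include the global (whole-brain mean) signal among the nuisance
#'   regressors (default `TRUE`).
#' @param include_derivatives Include backward-difference first derivatives
#'   of every nuisance waveform (default `TRUE`).
#' @param filter_regressors Apply the same detrend/low-pass to the nuisance
#'   columns before regression (default `TRUE`), preventing the regression
#'   from reintroducing variance at filtered-out frequencies.
#' @param smooth_first Smooth before temporal filtering (default `TRUE`).
#' @return List of class `preprocess_config`.
#' @export
preprocess_config <- function(lowpass_hz = 0.08, smooth_fwhm_mm = 4,
                              gsr = TRUE, include_derivatives = TRUE,
                              filter_regressors = TRUE, smooth_first = TRUE) {
  stopifnot(lowpass_hz > 0, smooth_fwhm_mm >= 0)
  structure(list(lowpass_hz = lowpass_hz, smooth_fwhm_mm = smooth_fwhm_mm,
                 gsr = isTRUE(gsr),
                 include_derivatives = isTRUE(include_derivatives),
                 filter_regressors = isTRUE(filter_regressors),
                 smooth_first = isTRUE(smooth_first)),
            class = "preprocess_config")
}

#' Detrend and low-pass filter time series
#'
#' Removes the constant offset and least-squares linear trend, then applies a
#' zero-phase hard low-pass in the FFT domain retaining frequencies strictly
#' below `cutoff_hz`, and re-removes any residual offset/trend so the output
#' has exactly zero mean and zero least-squares linear trend.
#'
#' @param x Numeric vector or matrix (frames in rows, one series per column).
#' @param tr Repetition time, seconds.
#' @param cutoff_hz Cutoff frequency, Hz; must be below Nyquist = 1/(2 TR).
#' @return Filtered series, same shape as `x`.
#' @export
detrend_lowpass <- function(x, tr, cutoff_hz = 0.08) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  if (n < 8L) stop("need at least 8 frames")
  nyquist <- 1 / (2 * tr)
  if (cutoff_hz >= nyquist) {
    stop("cutoff ", cutoff_hz, " Hz is not below the Nyquist frequency ",
         signif(nyquist, 4), " Hz implied by TR = ", tr, " s")
  }
  tt <- seq_len(n)
  detrend <- function(m) {
    fit <- stats::lm.fit(cbind(1, tt), m)
    m - cbind(1, tt) %*% fit$coefficients
  }
  y <- detrend(x)
  f <- (seq_len(n) - 1L) / (n * tr)
  f <- pmin(f, 1 / tr - f)
  keep <- f < cutoff_hz - 1e-12
  yf <- stats::mvfft(y)
  yf[!keep, ] <- 0
  y <- Re(stats::mvfft(yf, inverse = TRUE)) / n
  y <- detrend(y)
  if (vec) y[, 1L] else y
}

# band matrix for 1-D Gaussian convolution with truncated, renormalized
# kernel at the boundaries (rows sum to 1 exactly)
gauss_band_matrix <- function(n, sigma_vox) {
  if (sigma_vox == 0) return(diag(1, n))
  half <- max(1L, ceiling(3 * sigma_vox))
  offs <- -half:half
  w <- exp(-offs^2 / (2 * sigma_vox^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1L & j <= n
    K[i, j[ok]] <- w[ok] / sum(w[ok])
  }
  K
}

#' Spatially smooth a BOLD run with a Gaussian kernel
#'
#' Per-frame separable 3-D Gaussian convolution with per-axis sigma =
#' FWHM / (2 sqrt(2 ln 2)) scaled by that axis's voxel size (anisotropic
#' voxels are handled per axis). At volume boundaries the kernel is truncated
#' and renormalized, so a constant volume is reproduced exactly.
#'
#' @param run A `bold_run`.
#' @param fwhm_mm Kernel full width at half maximum in mm (0 = identity).
#' @return Smoothed `bold_run`.
#' @export
gaussian_smooth <- function(run, fwhm_mm = 4) {
  stopifnot(inherits(run, "bold_run"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(run)
  dims <- dim(run)[1:3]
  nt <- dim(run)[4L]
  vox <- sqrt(colSums(run_affine(run)[1:3, 1:3]^2))
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / vox
  dat <- unclass_bold(run)
  # axis 1
  K1 <- gauss_band_matrix(dims[1L], sigma_vox[1L])
  dim(dat) <- c(dims[1L], prod(dims[2:3]) * nt)
  dat <- K1 %*% dat
  dim(dat) <- c(dims, nt)
  # axis 2
  K2 <- gauss_band_matrix(dims[2L], sigma_vox[2L])
  dat <- aperm(dat, c(2L, 1L, 3L, 4L))
  dim(dat) <- c(dims[2L], dims[1L] * dims[3L] * nt)
  dat <- K2 %*% dat
  dim(dat) <- c(dims[2L], dims[1L], dims[3L], nt)
  dat <- aperm(dat, c(2L, 1L, 3L, 4L))
  # axis 3
  K3 <- gauss_band_matrix(dims[3L], sigma_vox[3L])
  dat <- aperm(dat, c(3L, 1L, 2L, 4L))
  dim(dat) <- c(dims[3L], dims[1L] * dims[2L] * nt)
  dat <- K3 %*% dat
  dim(dat) <- c(dims[3L], dims[1L], dims[2L], nt)
  dat <- aperm(dat, c(2L, 3L, 1L, 4L))
  rewrap_bold(dat, run)
}

#' Assemble the nuisance regression design
#'
#' Columns: constant, linear trend, six rigid-body motion parameters, the
#' global (whole-brain mean) signal when `config$gsr`, the lateral-ventricle
#' mean signal, the deep-white-matter mean signal, and the
#' backward-difference first derivative of each waveform (d[1] = 0). All
#' columns except the constant are mean-centred. With derivatives this gives
#' 20 columns with GSR and 18 without.
#'
#' @param motion Frames x 6 motion matrix.
#' @param run A `bold_run` (for the mask-average signals).
#' @param masks Tissue masks (`brain`, `ventricle`, `deep_wm`).
#' @param config A [preprocess_config()].
#' @return Numeric matrix (frames x columns) with named columns and
#'   attributes `rank` and `gsr`. A degenerate (rank-deficient) design
#'   triggers a warning.
#' @export
assemble_nuisance <- function(motion, run, masks, config = preprocess_config()) {
  stopifnot(inherits(run, "bold_run"), is.matrix(motion), ncol(motion) == 6L)
  nt <- run_n_frames(run)
  if (nrow(motion) != nt) stop("motion trace and run frame counts differ")
  dat <- unclass_bold(run)
  dim(dat) <- c(prod(dim(run)[1:3]), nt)
  mask_mean <- function(mask, label) {
    idx <- which(as.vector(mask))
    if (length(idx) == 0L) stop("empty mask: ", label)
    colMeans(dat[idx, , drop = FALSE])
  }
  base <- motion
  colnames(base) <- c("trans_x", "trans_y", "trans_z",
                      "rot_x", "rot_y", "rot_z")
  if (config$gsr) base <- cbind(base, global = mask_mean(masks$brain, "brain"))
  base <- cbind(base,
                ventricle = mask_mean(masks$ventricle, "ventricle"),
                deep_wm = mask_mean(masks$deep_wm, "deep_wm"))
  if (config$include_derivatives) {
    deriv <- apply(base, 2L, function(v) c(0, diff(v)))
    colnames(deriv) <- paste0("d_", colnames(base))
    base <- cbind(base, deriv)
  }
  base <- scale(base, center = TRUE, scale = FALSE)
  design <- cbind(constant = rep(1, nt),
                  linear = seq_len(nt) - mean(seq_len(nt)),
                  base)
  rk <- qr(design)$rank
  if (rk < ncol(design)) {
    warning("degenerate nuisance design: rank ", rk, " < ", ncol(design),
            " columns")
  }
  attr(design, "rank") <- rk
  attr(design, "gsr") <- config$gsr
  design
}

#' Regress nuisance variance out of a BOLD run
#'
#' Per-voxel ordinary least squares against the design; returns residuals
#' orthogonal to every retained design column. Rank-deficient designs are
#' reduced by pivoted QR elimination; dropped columns are recorded in the
#' `dropped_columns` attribute of the result.
#'
#' @param run A `bold_run` (or a frames x series matrix).
#' @param design Design matrix from [assemble_nuisance()].
#' @return Residual `bold_run` (or matrix), with attribute
#'   `dropped_columns`.
#' @export
regress_out <- function(run, design) {
  is_run <- inherits(run, "bold_run")
  if (is_run) {
    nt <- run_n_frames(run)
    Y <- t(matrix(unclass_bold(run), prod(dim(run)[1:3]), nt))
  } else {
    Y <- if (is.null(dim(run))) matrix(run, ncol = 1L) else run
    nt <- nrow(Y)
  }
  if (nrow(design) != nt) stop("design and run frame counts differ")
  qrd <- qr(design)
  rk <- qrd$rank
  if (nt <= rk) stop("frames (", nt, ") must exceed design rank (", rk, ")")
  keep <- qrd$pivot[seq_len(rk)]
  dropped <- colnames(design)[qrd$pivot[-seq_len(rk)]]
  X <- design[, keep, drop = FALSE]
  qx <- qr(X)
  res <- Y - X %*% qr.coef(qx, Y)
  if (is_run) {
    out <- rewrap_bold(array(t(res), dim = dim(run)), run)
  } else {
    out <- if (is.null(dim(run))) res[, 1L] else res
  }
  attr(out, "dropped_columns") <- dropped
  out
}

#' Run the full preprocessing chain on one subject
#'
#' Fixed stage order: spatial smoothing, then detrend/low-pass, then nuisance
#' regression; the nuisance columns are extracted from the smoothed run and
#' (by default) passed through the identical detrend/low-pass before the
#' regression. The order and design properties are recorded in the `log`
#' attribute. Toggling `config$gsr` changes only the design, never the
#' filtering.
#'
#' @param run A `bold_run`.
#' @param motion Frames x 6 motion matrix.
#' @param masks Tissue masks.
#' @param config A [preprocess_config()].
#' @return Residual `bold_run` with a `log` attribute (list: `order`,
#'   `design_rank`, `dropped_columns`, `gsr`).
#' @export
preprocess_run <- function(run, motion, masks, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  smoothed <- if (config$smooth_first) {
    gaussian_smooth(run, config$smooth_fwhm_mm)
  } else {
    run
  }
  filtered <- rewrap_bold(
    array(t(detrend_lowpass(
      t(matrix(unclass_bold(smoothed), prod(dim(smoothed)[1:3]),
               run_n_frames(smoothed))),
      tr = run_tr(run), cutoff_hz = config$lowpass_hz)),
      dim = dim(run)), run)
  if (!config$smooth_first) {
    filtered <- gaussian_smooth(filtered, config$smooth_fwhm_mm)
  }
  design <- assemble_nuisance(motion, smoothed, masks, config)
  if (config$filter_regressors) {
    body <- design[, -1L, drop = FALSE] # constant column must not be filtered
    body <- detrend_lowpass(body, tr = run_tr(run),
                            cutoff_hz = config$lowpass_hz)
    design2 <- cbind(constant = design[, 1L], body)
    # filtering annihilates the linear column; rebuild the design without
    # numerically-zero columns, keeping names
    norms <- sqrt(colSums(design2^2))
    design2 <- design2[, norms > 1e-10 * max(norms), drop = FALSE]
    design <- design2
  }
  out <- regress_out(filtered, design)
  attr(out, "log") <- list(
    order = c(if (config$smooth_first) "smooth" else NULL,
              "detrend_lowpass",
              if (!config$smooth_first) "smooth" else NULL,
              "nuisance_regression"),
    design_rank = qr(design)$rank,
    dropped_columns = attr(out, "dropped_columns"),
    gsr = config$gsr
  )
  out
}
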