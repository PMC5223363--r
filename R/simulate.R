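# Band-limited unit-variance noise: white Gaussian series hard low-passed in
# the FFT domain below `cutoff_hz`, then rescaled to unit SD per column. Used
# for latent network signals and for global/ventricle/WM drifts so that the
# pipeline's 0.08 Hz low-pass preserves the planted structure (all latent
# power sits below the cutoff).
band_limited_noise <- function(n_frames, n_series, tr, cutoff_hz = 0.08) {
  z <- matrix(stats::rnorm(n_frames * n_series), n_frames, n_series)
  f <- (seq_len(n_frames) - 1L) / (n_frames * tr)
  f <- pmin(f, 1 / tr - f)
  keep <- f < cutoff_hz
  keep[1L] <- FALSE # drop DC; series are fluctuations around zero
  zf <- stats::mvfft(z)
  zf[!keep, ] <- 0
  x <- Re(stats::mvfft(zf, inverse = TRUE)) / n_frames
  sds <- apply(x, 2L, stats::sd)
  sds[sds == 0] <- 1
  sweep(x, 2L, sds, "/")
}

#' Simulate latent ROI time series with a planted correlation structure
#'
#' Draws `n_frames` samples of a zero-mean multivariate normal whose
#' correlation matrix equals `target_corr`. By default the series are
#' band-limited below 0.08 Hz (low-frequency-dominated, as resting BOLD
#' fluctuations are); `band_limited = FALSE` yields temporally white series,
#' for which the Fisher-z null sampling theory (SD 1/sqrt(T-3)) holds
#' exactly.
#'
#' @param n_frames Number of time points (>= 16).
#' @param tr Repetition time, seconds.
#' @param target_corr Positive semi-definite correlation matrix (one node per
#'   column).
#' @param rng_seed Integer seed.
#' @param band_limited Low-pass the latent series below `cutoff_hz`?
#' @param cutoff_hz Band limit in Hz.
#' @param noise_sd SD of white measurement noise added per series.
#' @return Matrix `n_frames` x `ncol(target_corr)`; column names are taken
#'   from `target_corr`.
#' @export
simulate_roi_series <- function(n_frames, tr, target_corr, rng_seed,
                                band_limited = TRUE, cutoff_hz = 0.08,
                                noise_sd = 0) {
  k <- ncol(target_corr)
  ev <- eigen(target_corr, symmetric = TRUE)
  if (min(ev$values) < -1e-8) stop("target correlation matrix is not PSD")
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k) %*% t(ev$vectors)
  with_seed(rng_seed, {
    z <- if (band_limited) {
      band_limited_noise(n_frames, k, tr, cutoff_hz)
    } else {
      matrix(stats::rnorm(n_frames * k), n_frames, k)
    }
    x <- z %*% rt
    if (noise_sd > 0) x <- x + matrix(stats::rnorm(n_frames * k, 0, noise_sd),
                                      n_frames, k)
    colnames(x) <- colnames(target_corr)
    x
  })
}

#' Simulate a smooth head-motion trace
#'
#' A smoothed Gaussian random walk: three translations (mm) with per-frame
#' step SD `motion_scale` and three rotations (rad) with step SD
#' `motion_scale / head_radius`; steps are smoothed with a 5-frame moving
#' average before integration. `motion_scale = 0` gives an identically zero
#' trace.
#'
#' @param n_frames Number of frames.
#' @param motion_scale mm-scale of motion steps.
#' @param rng_seed Integer seed.
#' @param head_radius_mm Radius used to express rotation steps on the mm
#'   scale (default 50 mm).
#' @return Matrix `n_frames` x 6 (`trans_x..rot_z`).
#' @export
simulate_motion_trace <- function(n_frames, motion_scale, rng_seed,
                                  head_radius_mm = 50) {
  cols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (motion_scale == 0) {
    m <- matrix(0, n_frames, 6L)
    colnames(m) <- cols
    return(m)
  }
  with_seed(rng_seed, {
    sds <- c(rep(motion_scale, 3L), rep(motion_scale / head_radius_mm, 3L))
    steps <- sapply(sds, function(s) stats::rnorm(n_frames, 0, s))
    sm <- apply(steps, 2L, function(v) {
      as.numeric(stats::filter(v, rep(1 / 5, 5L), sides = 2L, circular = TRUE))
    })
    m <- apply(sm, 2L, cumsum)
    colnames(m) <- cols
    m
  })
}

# Map each in-sphere voxel to exactly one node: nearest sphere centre among
# the spheres containing it (ties broken by node order). Returns a list of
# integer vectors of linear voxel indices, one per node.
assign_sphere_voxels <- function(atlas, dims, affine, radius_override = NULL) {
  coords <- voxel_coords_mm(dims, affine)
  n_nodes <- nrow(atlas)
  best_d2 <- rep(Inf, nrow(coords))
  best_node <- rep(NA_integer_, nrow(coords))
  for (k in seq_len(n_nodes)) {
    r <- radius_override %||% atlas$radius_mm[k]
    d2 <- (coords[, 1L] - atlas$x[k])^2 + (coords[, 2L] - atlas$y[k])^2 +
      (coords[, 3L] - atlas$z[k])^2
    hit <- d2 <= r^2 & d2 < best_d2
    best_d2[hit] <- d2[hit]
    best_node[hit] <- k
  }
  out <- lapply(seq_len(n_nodes), function(k) which(best_node == k))
  empty <- which(lengths(out) == 0L)
  if (length(empty) > 0L) {
    stop("empty ROI sphere(s) on grid ", paste(dims, collapse = "x"), ": ",
         paste(atlas$node_id[empty], collapse = ", "))
  }
  out
}

#' Simulate one subject's BOLD run and motion trace
#'
#' ROI-sphere voxels receive the subject's age-group latent network signals
#' (drawn from a multivariate normal whose correlation matrix is the effect
#' ledger's target for that group) plus white voxel noise; all brain voxels
#' share a global fluctuation; ventricle and deep-white-matter compartments
#' receive their own slow drift components; non-brain voxels are pure noise.
#' All structured components are band-limited below 0.08 Hz so that the
#' pipeline's low-pass filter preserves the planted structure. The motion
#' trace is a smooth random walk scaled by `motion_scale` and does not
#' displace the simulated volumes (realignment is out of scope; motion enters
#' downstream as nuisance regressors and QC covariates).
#'
#' @param subject One-row slice of a [generate_cohort()] tibble (or any list
#'   with `age_group`, `tr`, `n_frames`, `subject_id`).
#' @param atlas An `roi_atlas`.
#' @param masks Tissue masks from [make_tissue_masks()].
#' @param ledger An [effect_ledger()].
#' @param grid Grid from [mni_grid()] (must match `masks`).
#' @param rng_seed Integer seed for this subject.
#' @param noise_sd White voxel-noise SD.
#' @param global_amp Amplitude of the shared global fluctuation.
#' @param motion_scale mm-scale of simulated motion.
#' @param baseline Mean intensity added to brain voxels.
#' @return List with `run` (a `bold_run`) and `motion` (frames x 6 matrix).
#' @export
simulate_subject_bold <- function(subject, atlas, masks, ledger, grid,
                                  rng_seed, noise_sd = 1, global_amp = 0.5,
                                  motion_scale = 0.05, baseline = 1000) {
  group <- as.character(subject$age_group)
  target <- ledger$targets[[group]]
  if (is.null(target)) stop("no ledger target for age group '", group, "'")
  n_frames <- subject$n_frames
  tr <- subject$tr
  dims <- grid$dims
  nvox <- prod(dims)

  sphere_vox <- assign_sphere_voxels(atlas, dims, grid$affine)
  brain_idx <- which(as.vector(masks$brain))
  out_of_brain <- setdiff(unlist(sphere_vox), brain_idx)
  if (length(out_of_brain) > 0L) {
    stop("ROI spheres extend outside the brain mask on this grid")
  }

  latent <- simulate_roi_series(n_frames, tr, target,
                                rng_seed = derive_seed(rng_seed, "latent"))
  with_seed(derive_seed(rng_seed, "voxels"), {
    dat <- matrix(stats::rnorm(nvox * n_frames, 0, noise_sd), nvox, n_frames)
    glob <- band_limited_noise(n_frames, 1L, tr)[, 1L]
    vent <- band_limited_noise(n_frames, 1L, tr)[, 1L]
    wm <- band_limited_noise(n_frames, 1L, tr)[, 1L]
    dat[brain_idx, ] <- dat[brain_idx, ] +
      rep(global_amp * glob, each = length(brain_idx)) + baseline
    vent_idx <- which(as.vector(masks$ventricle))
    wm_idx <- which(as.vector(masks$deep_wm))
    dat[vent_idx, ] <- dat[vent_idx, ] + rep(vent, each = length(vent_idx))
    dat[wm_idx, ] <- dat[wm_idx, ] + rep(wm, each = length(wm_idx))
    for (k in seq_along(sphere_vox)) {
      dat[sphere_vox[[k]], ] <- dat[sphere_vox[[k]], ] +
        rep(latent[, k], each = length(sphere_vox[[k]]))
    }
  })
  run <- bold_run(array(dat, dim = c(dims, n_frames)), affine = grid$affine,
                  tr = tr)
  motion <- simulate_motion_trace(n_frames, motion_scale,
                                  rng_seed = derive_seed(rng_seed, "motion"))
  list(run = run, motion = motion)
}

#' Simulate a cohort's connectivity matrices via the latent ROI path
#'
#' Generates each subject's latent ROI series directly (identical in law to
#' the sphere-voxel signals that [simulate_subject_bold()] plants, without the
#' voxel lattice) and returns per-subject Fisher-z connectivity matrices.
#' This is the fast path for cohort-scale statistical experiments; a test
#' verifies it agrees with the full voxel route.
#'
#' @param cohort A [generate_cohort()] tibble.
#' @param atlas The `roi_atlas` the cohort's ledger was built on.
#' @param band_limited Low-pass the latent series (default `TRUE`).
#' @param noise_sd Per-series white noise SD (default 0).
#' @param rng_seed Master seed; per-subject seeds are derived from it.
#' @return Named list of Fisher-z `connectivity_matrix` objects, one per
#'   subject, in cohort row order.
#' @export
simulate_cohort_connectivity <- function(cohort, atlas, band_limited = TRUE,
                                         noise_sd = 0,
                                         rng_seed = cohort_config_of(cohort)$rng_seed) {
  ledger <- cohort_ledger(cohort)
  stopifnot(!is.null(ledger))
  mats <- purrr::map(seq_len(nrow(cohort)), function(s) {
    target <- ledger$targets[[as.character(cohort$age_group[s])]]
    x <- simulate_roi_series(cohort$n_frames[s], cohort$tr[s], target,
                             rng_seed = derive_seed(rng_seed, "roi", s),
                             band_limited = band_limited, noise_sd = noise_sd)
    subject_connectivity(x, atlas)
  })
  stats::setNames(mats, cohort$subject_id)
}
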