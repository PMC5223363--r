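test_that("detrend/low-pass removes offsets, trends and stopband power", {
  tr <- 2.5
  n <- 120
  t_s <- (seq_len(n) - 1) * tr
  # stopband: 0.1 Hz sinusoid attenuated to <= 1% RMS
  hi <- sin(2 * pi * 0.1 * t_s)
  out <- detrend_lowpass(hi, tr, 0.08)
  expect_lte(sqrt(mean(out^2)), 0.01 * sqrt(mean(hi^2)))
  # passband: 0.02 Hz sinusoid preserved >= 95% of its detrended RMS
  lo <- sin(2 * pi * 0.02 * t_s)
  lo_dt <- stats::residuals(stats::lm(lo ~ t_s))
  out_lo <- detrend_lowpass(lo, tr, 0.08)
  expect_gte(sqrt(mean(out_lo^2)), 0.95 * sqrt(mean(lo_dt^2)))
  # constant input maps to zero; output always has zero mean and trend
  expect_equal(detrend_lowpass(rep(7, n), tr, 0.08), rep(0, n))
  mixed <- 3 + 0.05 * t_s + lo + hi
  out_m <- detrend_lowpass(mixed, tr, 0.08)
  expect_lt(abs(mean(out_m)), 1e-10)
  expect_lt(abs(stats::coef(stats::lm(out_m ~ t_s))[2]), 1e-10)
  # cutoff at or above Nyquist is rejected naming the TR
  expect_error(detrend_lowpass(lo, tr, 0.2), "Nyquist")
  expect_error(detrend_lowpass(lo[1:4], tr, 0.08), "8 frames")
})

test_that("Gaussian smoothing matches the closed-form kernel and conserves mass", {
  dims <- c(15L, 15L, 15L)
  nvox <- prod(dims)
  # unit impulse at the grid centre, 4 mm voxels, 8 mm FWHM
  dat <- matrix(0, nvox, 1)
  centre <- c(8L, 8L, 8L)
  lin <- centre[1] + (centre[2] - 1L) * dims[1] +
    (centre[3] - 1L) * dims[1] * dims[2]
  dat[lin, 1] <- 1
  run <- matrix_bold(dat, dims, voxel_mm = 4)
  sm <- gaussian_smooth(run, 8)
  # oracle: separable normalized kernel sampled on the grid
  sigma_vox <- (8 / (2 * sqrt(2 * log(2)))) / 4
  offs <- -ceiling(3 * sigma_vox):ceiling(3 * sigma_vox)
  w <- exp(-offs^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  expect_equal(sm[centre[1], centre[2], centre[3], 1],
               w[offs == 0]^3, tolerance = 1e-12)
  # mass conserved away from the boundary
  expect_equal(sum(sm[, , , 1]), 1, tolerance = 1e-3)
  # fwhm = 0 is the identity; a constant volume is exactly unchanged
  expect_identical(unclass_bold(gaussian_smooth(run, 0)), unclass_bold(run))
  const <- matrix_bold(matrix(3, nvox, 2), dims, voxel_mm = 4)
  expect_equal(unclass_bold(gaussian_smooth(const, 6)), unclass_bold(const),
               tolerance = 1e-12)
})

test_that("nuisance design has the documented column structure", {
  dims <- c(10L, 12L, 10L)
  g <- mni_grid(6, dims = dims)
  # build masks valid on this small grid by hand
  brain <- array(TRUE, dims)
  vent <- array(FALSE, dims)
  vent[5:6, 6:7, 5:6] <- TRUE
  wm <- array(FALSE, dims)
  wm[2:3, 2:3, 2:3] <- TRUE
  masks <- list(brain = brain, ventricle = vent, deep_wm = wm)
  nt <- 40L
  set.seed(1)
  run <- bold_run(array(rnorm(prod(dims) * nt), c(dims, nt)),
                  affine = g$affine, tr = 2.5)
  motion <- simulate_motion_trace(nt, 0.1, rng_seed = 4)
  d_on <- assemble_nuisance(motion, run, masks, preprocess_config(gsr = TRUE))
  d_off <- assemble_nuisance(motion, run, masks, preprocess_config(gsr = FALSE))
  expect_equal(ncol(d_on), 20L)
  expect_equal(ncol(d_off), 18L)
  expect_true("global" %in% colnames(d_on))
  expect_false("global" %in% colnames(d_off))
  # derivatives are backward differences with d[1] = 0
  expect_equal(d_on[, "d_trans_x"],
               c(0, diff(motion[, 1])) - mean(c(0, diff(motion[, 1]))))
  # all columns except the constant are mean-centred
  expect_true(all(abs(colMeans(d_on[, -1])) < 1e-12))
  # degenerate inputs: zero motion + constant volumes leave only the
  # constant and linear columns informative
  run_const <- bold_run(array(5, c(dims, nt)), affine = g$affine, tr = 2.5)
  motion0 <- matrix(0, nt, 6L)
  expect_warning(
    d_deg <- assemble_nuisance(motion0, run_const, masks, preprocess_config()),
    "degenerate")
  expect_equal(attr(d_deg, "rank"), 2L)
  # empty mask is rejected by name
  masks_bad <- masks
  masks_bad$ventricle <- array(FALSE, dims)
  expect_error(assemble_nuisance(motion, run, masks_bad, preprocess_config()),
               "ventricle")
})

test_that("nuisance regression orthogonalises, is idempotent, and GSR removes a planted global", {
  nt <- 120L
  tr <- 2.5
  set.seed(7)
  g_sig <- as.vector(simulate_roi_series(nt, tr, diag(1, 1), rng_seed = 8))
  net <- as.vector(simulate_roi_series(nt, tr, diag(1, 1), rng_seed = 9))
  net <- unname(stats::residuals(stats::lm(net ~ g_sig))) # exact construction
  y <- net + 0.8 * g_sig
  base <- cbind(constant = rep(1, nt), linear = scale(seq_len(nt), TRUE, FALSE))
  with_g <- cbind(base, global = g_sig - mean(g_sig))
  res_on <- regress_out(y, with_g)
  expect_lt(abs(sum(res_on * g_sig)) / sqrt(sum(g_sig^2) * sum(res_on^2)), 1e-8)
  res_off <- regress_out(y, base)
  expect_gt(abs(stats::cor(res_off, g_sig)), 0.5)
  # residuals orthogonal to every design column
  for (k in seq_len(ncol(with_g))) {
    expect_lt(abs(sum(res_on * with_g[, k])),
              1e-8 * sqrt(sum(with_g[, k]^2)) * sqrt(sum(res_on^2)) + 1e-12)
  }
  # a series equal to a design column is annihilated
  expect_lt(max(abs(regress_out(g_sig, with_g))), 1e-10)
  # a series orthogonal to all columns is only centred
  ortho <- sin(2 * pi * 10 * seq_len(nt) / nt)
  ortho <- unname(stats::residuals(stats::lm(ortho ~ with_g - 1)))
  expect_equal(regress_out(ortho, with_g), ortho, tolerance = 1e-10,
               ignore_attr = TRUE)
  # idempotence
  twice <- regress_out(res_on, with_g)
  expect_lt(sqrt(mean((twice - res_on)^2)), 1e-10)
  # rank-deficient designs drop columns and report them
  dup <- cbind(with_g, global2 = with_g[, "global"])
  res_dup <- regress_out(y, dup)
  expect_length(attr(res_dup, "dropped_columns"), 1L)
  expect_true(attr(res_dup, "dropped_columns") %in% c("global", "global2"))
  expect_equal(unname(res_dup), unname(res_on), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(regress_out(y[1:3], with_g[1:3, ]), "exceed")
})

test_that("preprocessing order is fixed and GSR toggles only the design", {
  atlas <- std_atlas()
  cfg <- one_site_config(2, rng_seed = 11, grid = mni_grid(6), frames = 100L,
                         noise_sd = 0.5)
  coh <- generate_cohort(cfg, atlas)
  masks <- make_tissue_masks(cfg$grid)
  sim <- simulate_subject_bold(coh[1, ], atlas, masks, cohort_ledger(coh),
                               cfg$grid, rng_seed = 13, noise_sd = 0.5,
                               global_amp = 0.8, motion_scale = 0.05)
  on <- preprocess_run(sim$run, sim$motion, masks, preprocess_config(gsr = TRUE))
  off <- preprocess_run(sim$run, sim$motion, masks,
                        preprocess_config(gsr = FALSE))
  expect_equal(attr(on, "log")$order,
               c("smooth", "detrend_lowpass", "nuisance_regression"))
  expect_true(attr(on, "log")$gsr)
  expect_false(attr(off, "log")$gsr)
  # with a shared global component, removing GSR raises mean connectivity
  z_on <- subject_connectivity(extract_roi_timeseries(on, atlas), atlas)
  z_off <- subject_connectivity(extract_roi_timeseries(off, atlas), atlas)
  expect_gt(mean(z_off[upper.tri(z_off)]), mean(z_on[upper.tri(z_on)]))
})
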