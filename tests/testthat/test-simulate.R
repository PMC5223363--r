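test_that("latent ROI series recover planted correlations at long runs", {
  atlas <- std_atlas()
  cfg <- one_site_config(2, rng_seed = 3)
  led <- effect_ledger(cfg, atlas)
  for (g in c("young", "old")) {
    x <- simulate_roi_series(6000, 2.5, led$targets[[g]], rng_seed = 100 + nchar(g))
    r <- stats::cor(x)
    idx <- upper.tri(r)
    err <- abs(r[idx] - led$targets[[g]][idx])
    expect_gt(mean(err <= 0.05), 0.95)
  }
})

test_that("null latent series follow the Fisher sampling law on white noise", {
  # SD of Fisher z over a null cohort approximately 1/sqrt(T - 3); this is a
  # property of temporally white series (band-limiting widens it)
  atlas <- std_atlas()
  frames <- 120
  target <- diag(1, nrow(atlas))
  dimnames(target) <- list(atlas$node_id, atlas$node_id)
  zs <- sapply(1:200, function(s) {
    x <- simulate_roi_series(frames, 2.5, target, rng_seed = s,
                             band_limited = FALSE)
    m <- subject_connectivity(x, atlas)
    m[upper.tri(m)]
  })
  expect_lt(abs(stats::sd(as.vector(zs)) - 1 / sqrt(frames - 3)) *
              sqrt(frames - 3), 0.10)
  expect_lt(abs(mean(zs)), 0.005)
})

test_that("latent signals are low-frequency dominated", {
  x <- simulate_roi_series(240, 2.5, diag(1, 3), rng_seed = 1,
                           band_limited = TRUE)
  for (k in 1:3) {
    sp <- Mod(stats::fft(x[, k]))^2
    f <- (seq_len(240) - 1) / (240 * 2.5)
    f <- pmin(f, 1 / 2.5 - f)
    expect_gte(sum(sp[f < 0.08]) / sum(sp), 0.8)
  }
})

test_that("motion traces scale with motion_scale and vanish at zero", {
  m0 <- simulate_motion_trace(100, 0, rng_seed = 1)
  expect_true(all(m0 == 0))
  scales <- c(0.02, 0.1, 0.3, 0.6)
  mean_fd <- sapply(scales, function(s) {
    mean(sapply(1:8, function(k) {
      fd <- framewise_displacement(simulate_motion_trace(120, s, rng_seed = k))
      mean(fd[-1])
    }))
  })
  expect_true(all(diff(mean_fd) > 0))
  # QC rejection frequency is monotone in motion scale
  pass_rate <- sapply(scales, function(s) {
    mean(sapply(1:8, function(k) {
      fd <- framewise_displacement(simulate_motion_trace(120, s, rng_seed = k))
      qc_screen(tibble::tibble(mean_fd = mean(fd[-1]),
                               mean_dvars_std = 1))$pass_flag
    }))
  })
  expect_true(all(diff(pass_rate) <= 0))
  expect_gt(pass_rate[1], pass_rate[length(pass_rate)])
})

test_that("voxel-level simulation carries the planted structure", {
  atlas <- std_atlas()
  cfg <- one_site_config(2, rng_seed = 5, grid = mni_grid(6), frames = 200L,
                         noise_sd = 0.2, motion_scale = 0.02)
  coh <- generate_cohort(cfg, atlas)
  masks <- make_tissue_masks(cfg$grid)
  sim <- simulate_subject_bold(coh[1, ], atlas, masks, cohort_ledger(coh),
                               cfg$grid, rng_seed = 17, noise_sd = 0.2,
                               motion_scale = 0.02)
  expect_s3_class(sim$run, "bold_run")
  expect_equal(dim(sim$run)[4], 200L)
  expect_true(all(is.finite(sim$run)))
  # extracted sphere means correlate strongly within planted networks
  series <- extract_roi_timeseries(sim$run, atlas)
  r <- pairwise_correlation(series)
  g <- as.character(coh$age_group[1])
  target <- cohort_ledger(coh)$targets[[g]]
  dmn <- which(atlas$network == "DMN")
  expect_gt(mean(r[dmn, dmn][upper.tri(r[dmn, dmn])]),
            mean(target[dmn, dmn][upper.tri(target[dmn, dmn])]) - 0.15)
  # determinism: same seed, same voxels
  sim2 <- simulate_subject_bold(coh[1, ], atlas, masks, cohort_ledger(coh),
                                cfg$grid, rng_seed = 17, noise_sd = 0.2,
                                motion_scale = 0.02)
  expect_identical(unclass_bold(sim$run), unclass_bold(sim2$run))
  expect_identical(sim$motion, sim2$motion)
})

test_that("the ROI fast path matches the voxel route in distribution", {
  # same subject, same planted targets: mean within-DMN z from the two
  # routes agrees to sampling accuracy over a long run
  atlas <- std_atlas()
  cfg <- one_site_config(2, rng_seed = 5, grid = mni_grid(6), frames = 400L,
                         noise_sd = 0, motion_scale = 0)
  coh <- generate_cohort(cfg, atlas)
  masks <- make_tissue_masks(cfg$grid)
  sim <- simulate_subject_bold(coh[1, ], atlas, masks, cohort_ledger(coh),
                               cfg$grid, rng_seed = 23, noise_sd = 0,
                               global_amp = 0, motion_scale = 0)
  series <- extract_roi_timeseries(sim$run, atlas)
  z_vox <- subject_connectivity(series, atlas)
  z_roi <- simulate_cohort_connectivity(coh[1, ], atlas, rng_seed = 23)[[1]]
  s_vox <- subject_network_summary(z_vox, atlas)
  s_roi <- subject_network_summary(z_roi, atlas)
  expect_equal(s_vox$mean_z, s_roi$mean_z, tolerance = 0.25)
  g <- as.character(coh$age_group[1])
  target <- cohort_ledger(coh)$targets[[g]]
  for (net in unique(atlas$network)) {
    idx <- which(atlas$network == net)
    t_z <- mean(fisher_z(target[idx, idx][upper.tri(target[idx, idx])]))
    expect_lt(abs(s_vox$mean_z[s_vox$network == net] - t_z), 0.2)
  }
})

test_that("global regressor is unrelated to planted contrasts without a global component", {
  atlas <- std_atlas()
  cfg <- one_site_config(2, rng_seed = 2, grid = mni_grid(6), frames = 200L,
                         noise_sd = 0.5, motion_scale = 0)
  coh <- generate_cohort(cfg, atlas)
  masks <- make_tissue_masks(cfg$grid)
  sim <- simulate_subject_bold(coh[1, ], atlas, masks, cohort_ledger(coh),
                               cfg$grid, rng_seed = 31, noise_sd = 0.5,
                               global_amp = 0, motion_scale = 0)
  dat <- matrix(unclass_bold(sim$run), prod(dim(sim$run)[1:3]),
                dim(sim$run)[4])
  global <- colMeans(dat[which(as.vector(masks$brain)), ])
  series <- extract_roi_timeseries(sim$run, atlas)
  # between-network contrast of mean signals (the planted quantity of
  # interest downstream) is uncorrelated with the global regressor
  dmn <- rowMeans(series[, atlas$network == "DMN"])
  mn <- rowMeans(series[, atlas$network == "MN"])
  expect_lt(abs(stats::cor(global, dmn - mn)), 0.15)
})
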