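# independent step-up FDR oracle (hand-rolled; the implementation uses
# p.adjust)
stepup_fdr <- function(p, q_level, dependent) {
  m <- length(p)
  ord <- order(p)
  cm <- if (dependent) sum(1 / seq_len(m)) else 1
  thresh <- seq_len(m) * q_level / (m * cm)
  passed <- which(p[ord] <= thresh)
  if (length(passed) == 0L) return(logical(m))
  k <- max(passed)
  out <- logical(m)
  out[ord[seq_len(k)]] <- TRUE
  out
}

test_that("group mean matrices aggregate per pair with missing-value bookkeeping", {
  atlas <- toy_atlas()
  set.seed(1)
  mk <- function(seed) {
    x <- simulate_roi_series(60, 2.5, diag(1, 5), rng_seed = seed)
    colnames(x) <- atlas$node_id
    subject_connectivity(x, atlas)
  }
  mats <- list(s1 = mk(1), s2 = mk(1), s3 = mk(3), s4 = mk(4))
  coh <- tibble::tibble(subject_id = names(mats),
                        age_group = c("young", "young", "old", "old"))
  gm <- group_mean_matrices(mats, coh, atlas)
  y <- gm[gm$age_group == "young", ]
  # two identical subjects: mean equals either, SD 0
  expect_equal(y$mean_z, mats$s1[cbind(y$i, y$j)])
  expect_true(all(y$sd_z == 0))
  expect_true(all(y$n == 2L))
  # a missing pair reduces that pair's n only
  mats$s3[1, 2] <- mats$s3[2, 1] <- NA
  gm2 <- group_mean_matrices(mats, coh, atlas)
  o <- gm2[gm2$age_group == "old", ]
  expect_equal(o$n[o$i == 1 & o$j == 2], 1L)
  expect_true(all(o$n[!(o$i == 1 & o$j == 2)] == 2L))
})

test_that("difference matrices use Welch t and a brute-force-checked FDR step-up", {
  # Welch t cross-checked against stats::t.test on a toy cohort
  atlas <- toy_atlas()
  mk <- function(seed, shift = 0) {
    x <- simulate_roi_series(80, 2.5, diag(1, 5), rng_seed = seed)
    x[, 1] <- x[, 1] + shift * x[, 2]
    colnames(x) <- atlas$node_id
    subject_connectivity(x, atlas)
  }
  mats <- c(lapply(1:8, mk, shift = 0.8), lapply(9:16, mk, shift = 0))
  names(mats) <- sprintf("s%02d", 1:16)
  coh <- tibble::tibble(subject_id = names(mats),
                        age_group = rep(c("young", "middle"), each = 8L))
  d <- difference_matrix_test(mats, coh, "young", "middle", atlas,
                              fdr_method = "BH")
  za <- sapply(mats[1:8], function(m) m[1, 2])
  zb <- sapply(mats[9:16], function(m) m[1, 2])
  tt <- stats::t.test(za, zb)
  row <- d[d$i == 1 & d$j == 2, ]
  expect_equal(row$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(row$p, tt$p.value, tolerance = 1e-12)
  expect_equal(row$delta_z, mean(za) - mean(zb), tolerance = 1e-12)
  # q values match the hand-rolled BH step-up decision
  expect_equal(d$significant, stepup_fdr(d$p, 0.05, dependent = FALSE))
  d_by <- difference_matrix_test(mats, coh, "young", "middle", atlas,
                                 fdr_method = "BY")
  expect_equal(d_by$significant, stepup_fdr(d_by$p, 0.05, dependent = TRUE))
  # BY never flags a pair BH does not
  expect_true(all(!d_by$significant | d$significant))
  # identical groups: zero differences, nothing flagged
  same <- c(mats[1:8], stats::setNames(mats[1:8], sprintf("t%02d", 1:8)))
  coh_same <- tibble::tibble(subject_id = names(same),
                             age_group = rep(c("young", "middle"), each = 8L))
  d0 <- difference_matrix_test(same, coh_same, "young", "middle", atlas)
  expect_true(all(d0$delta_z == 0))
  expect_true(all(!d0$significant))
})

test_that("toy p-vector: BY flags the signal and BH is never smaller", {
  p <- c(0.001, 0.2, 0.35, 0.5, 0.6, 0.7, 0.8, 0.85, 0.9, 0.95)
  bh <- stepup_fdr(p, 0.05, dependent = FALSE)
  by <- stepup_fdr(p, 0.05, dependent = TRUE)
  expect_identical(which(by), 1L)
  expect_true(all(which(by) %in% which(bh)))
  # and p.adjust (used by the implementation) agrees with the oracle
  expect_identical(unname(stats::p.adjust(p, "BH") <= 0.05), bh)
  expect_identical(unname(stats::p.adjust(p, "BY") <= 0.05), by)
})

test_that("planted within-DMN decline concentrates flags in the DMN block", {
  atlas <- std_atlas()
  cfg <- one_site_config(20, rng_seed = 77,
                         planted_effects = dmn_decline_effects())
  coh <- generate_cohort(cfg, atlas)
  mats <- simulate_cohort_connectivity(coh, atlas)
  d_ym <- difference_matrix_test(mats, coh, "young", "middle", atlas,
                                 fdr_method = "BH")
  flagged <- d_ym[d_ym$significant, ]
  expect_gt(nrow(flagged), 0L)
  expect_gt(mean(flagged$network_a == "DMN" & flagged$network_b == "DMN"),
            0.8)
  d_mo <- difference_matrix_test(mats, coh, "middle", "old", atlas,
                                 fdr_method = "BH")
  expect_lt(mean(d_mo$significant), 0.05)
})

test_that("flagged-pair count grows with the planted effect size", {
  atlas <- std_atlas()
  count_flags <- function(dz, seed) {
    eff <- dmn_decline_effects(z_young = 0.35 + dz, z_later = 0.35)
    cfg <- one_site_config(20, rng_seed = seed, planted_effects = eff)
    coh <- generate_cohort(cfg, atlas)
    mats <- simulate_cohort_connectivity(coh, atlas)
    sum(difference_matrix_test(mats, coh, "young", "middle", atlas,
                               fdr_method = "BH")$significant)
  }
  sizes <- c(0, 0.2, 0.45)
  counts <- sapply(sizes, function(dz)
    mean(sapply(c(11, 12, 13), function(s) count_flags(dz, s))))
  expect_true(all(diff(counts) > 0))
})

test_that("permutation max-t controls family-wise error and finds planted blocks", {
  set.seed(42)
  n_vox <- 400L
  # null: two groups from the same distribution
  maps0 <- matrix(rnorm(40 * n_vox), 40L)
  grp <- rep(c("a", "b"), each = 20L)
  out0 <- voxelwise_group_ttest(maps0, grp, n_perm = 300, rng_seed = 5)
  expect_lt(mean(out0$mask), 0.01)
  # identical groups (same subjects in both): empty mask
  same <- rbind(maps0[1:20, ], maps0[1:20, ])
  out_same <- voxelwise_group_ttest(same, grp, n_perm = 200, rng_seed = 5)
  expect_equal(sum(out_same$mask), 0L)
  # planted 1-SD difference in a contiguous block is mostly recovered
  maps1 <- matrix(rnorm(80 * n_vox), 80L)
  grp2 <- rep(c("a", "b"), each = 40L)
  block <- 1:50
  maps1[grp2 == "a", block] <- maps1[grp2 == "a", block] + 1
  out1 <- voxelwise_group_ttest(maps1, grp2, n_perm = 500, rng_seed = 6)
  expect_gt(mean(out1$mask[block]), 0.5)
  expect_lt(mean(out1$mask[-block]), 0.01)
  expect_warning(voxelwise_group_ttest(maps0, grp, n_perm = 50, rng_seed = 1),
                 "unstable")
})
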