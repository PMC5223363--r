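# shared fixtures, built in code at test time

std_atlas <- function() build_roi_atlas(default_roi_table())

# tiny two-network atlas for geometry-free unit tests
toy_atlas <- function() {
  build_roi_atlas(tibble::tibble(
    name = c("A1", "A2", "A3", "B1", "B2"),
    network = c("netA", "netA", "netA", "netB", "netB"),
    x = c(-20, 20, 0, -40, 40), y = c(0, 0, 20, -40, -40),
    z = c(10, 10, 30, 20, 20), radius_mm = 6
  ))
}

# single-site cohort config: every subject 120 frames at TR 2.5 s
one_site_config <- function(n_per_group, rng_seed = 1L, frames = 120L,
                            planted_effects = default_planted_effects(),
                            ...) {
  cohort_config(
    n_per_group = n_per_group,
    centers = tibble::tibble(center = "siteA", tr = 2.5, n_frames = frames),
    planted_effects = planted_effects, rng_seed = rng_seed, ...)
}

# planted effects table with every network at the same r in every group
flat_effects <- function(r = 0) {
  eff <- default_planted_effects()
  eff$r <- r
  eff
}

# effects with a single young->middle decline inside one network
dmn_decline_effects <- function(z_young = 0.55, z_later = 0.35,
                                r_other = 0.3) {
  eff <- flat_effects(r_other)
  eff$r[eff$network == "DMN"] <- ifelse(
    eff$age_group[eff$network == "DMN"] == "young",
    tanh(z_young), tanh(z_later))
  eff
}

# compact grid centred on the toy atlas coordinates
toy_grid <- function() {
  dims <- c(21L, 21L, 9L)
  affine <- diag(c(6, 6, 6, 1))
  affine[1:3, 4] <- c(-60, -60, 0)
  list(dims = dims, voxel_mm = 6, affine = affine)
}

# small bold run filled from a voxels x frames matrix on an arbitrary grid
matrix_bold <- function(dat_vox_by_t, dims, voxel_mm = 4, tr = 2.5) {
  g <- mni_grid(voxel_mm, dims = dims)
  bold_run(array(dat_vox_by_t, dim = c(dims, ncol(dat_vox_by_t))),
           affine = g$affine, tr = tr)
}

# true cell means reproducing the qualitative lifespan pattern:
# cognitive networks drop 0.15 from young to middle then plateau;
# MN rises 0.1 into middle age then drops 0.1
pattern_cell_means <- function() {
  nets <- c("DMN", "SN", "DAN", "FPCN", "AN", "VN", "MN")
  base <- c(DMN = .5, SN = .45, DAN = .45, FPCN = .4, AN = .4, VN = .45,
            MN = .35)
  ym <- c(DMN = .15, SN = .15, DAN = .15, FPCN = .15, AN = 0, VN = 0,
          MN = -0.1)
  mo <- c(DMN = 0, SN = 0, DAN = 0, FPCN = 0, AN = 0, VN = 0, MN = 0.1)
  cm <- tidyr::expand_grid(network = nets,
                           age_group = c("young", "middle", "old"))
  cm$mean <- ifelse(cm$age_group == "young", base[cm$network],
                    ifelse(cm$age_group == "middle",
                           base[cm$network] - ym[cm$network],
                           base[cm$network] - ym[cm$network] -
                             mo[cm$network]))
  cm
}
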