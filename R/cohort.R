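#' Default multi-center description for the synthetic cohort
#'
#' Four sites spanning the TR range 2-3 s and frame counts typical of public
#' resting-state repositories; the first (largest-site-like) entry is 120
#' frames at TR 2.5 s.
#'
#' @return Tibble with `center`, `tr` (s), `n_frames`.
#' @export
default_centers <- function() {
  tibble::tibble(
    center = c("siteA", "siteB", "siteC", "siteD"),
    tr = c(2.5, 2.0, 3.0, 2.0),
    n_frames = c(120L, 175L, 119L, 150L)
  )
}

#' Default planted within-network correlations by age group
#'
#' Encodes the lifespan pattern the pipeline is designed to detect: high-order
#' cognitive networks (DMN, SN, DAN, FPCN) decline between young and middle
#' adulthood and then plateau (DMN slightly rebounds), auditory and visual
#' networks decline across both transitions, and the motor network rises into
#' middle age before declining.
#'
#' @return Tibble with `network`, `age_group`, `r` (target within-network
#'   correlation of every node pair in that network).
#' @export
default_planted_effects <- function() {
  grid <- tidyr::expand_grid(
    network = c("DMN", "SN", "DAN", "FPCN", "AN", "VN", "MN"),
    age_group = c("young", "middle", "old")
  )
  vals <- rbind(
    DMN  = c(0.55, 0.40, 0.43),
    SN   = c(0.50, 0.38, 0.36),
    DAN  = c(0.50, 0.40, 0.38),
    FPCN = c(0.45, 0.37, 0.36),
    AN   = c(0.45, 0.38, 0.30),
    VN   = c(0.50, 0.42, 0.34),
    MN   = c(0.40, 0.48, 0.38)
  )
  grid$r <- vals[cbind(match(grid$network, rownames(vals)),
                       match(grid$age_group, c("young", "middle", "old")))]
  grid
}

#' Age-group labels and bounds
#' @return Tibble with `age_group`, `lower`, `upper` (years, inclusive).
#' @export
age_group_bounds <- function() {
  tibble::tibble(
    age_group = c("young", "middle", "old"),
    lower = c(21, 41, 61),
    upper = c(40, 60, 85)
  )
}

#' Configuration of the synthetic multi-center cohort
#'
#' @param n_per_group Subjects per age group (>= 2).
#' @param group_bounds Tibble as from [age_group_bounds()]: disjoint, ordered
#'   age intervals in years.
#' @param centers Tibble as from [default_centers()].
#' @param grid Sampling grid from [mni_grid()].
#' @param noise_sd Thermal (voxel) noise SD in signal units.
#' @param global_amp Amplitude of the shared global fluctuation.
#' @param motion_scale mm-scale of simulated head motion (0 = still).
#' @param planted_effects Tibble `network`, `age_group`, `r`: target
#'   within-network correlation per age group.
#' @param inter_network_effects Optional tibble `network_a`, `network_b`,
#'   `age_group`, `r`: target correlation planted between every node pair of
#'   the two networks.
#' @param rng_seed Integer master seed.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 106L,
                          group_bounds = age_group_bounds(),
                          centers = default_centers(),
                          grid = mni_grid(4),
                          noise_sd = 1,
                          global_amp = 0.5,
                          motion_scale = 0.05,
                          planted_effects = default_planted_effects(),
                          inter_network_effects = NULL,
                          rng_seed = 1L) {
  stopifnot(is.numeric(n_per_group), length(n_per_group) == 1L)
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  stopifnot(all(c("age_group", "lower", "upper") %in% names(group_bounds)))
  if (any(diff(group_bounds$lower) <= 0) ||
      any(group_bounds$upper < group_bounds$lower) ||
      any(utils::head(group_bounds$upper, -1) >=
            utils::tail(group_bounds$lower, -1))) {
    stop("group bounds must be disjoint and ordered")
  }
  stopifnot(all(c("center", "tr", "n_frames") %in% names(centers)))
  if (any(centers$n_frames < 16)) stop("frames must be >= 16")
  if (any(centers$tr <= 0)) stop("tr must be positive")
  if (grid$voxel_mm <= 0) stop("voxel size must be positive")
  if (noise_sd < 0 || motion_scale < 0) stop("noise_sd and motion_scale must be >= 0")
  stopifnot(all(c("network", "age_group", "r") %in% names(planted_effects)))
  if (any(abs(planted_effects$r) >= 1)) {
    stop("target correlations must lie in (-1, 1)")
  }
  if (!is.null(inter_network_effects)) {
    stopifnot(all(c("network_a", "network_b", "age_group", "r") %in%
                    names(inter_network_effects)))
    if (any(abs(inter_network_effects$r) >= 1)) {
      stop("target correlations must lie in (-1, 1)")
    }
  }
  structure(list(
    n_per_group = as.integer(n_per_group), group_bounds = group_bounds,
    centers = centers, grid = grid, noise_sd = noise_sd,
    global_amp = global_amp, motion_scale = motion_scale,
    planted_effects = planted_effects,
    inter_network_effects = inter_network_effects,
    rng_seed = as.integer(rng_seed)
  ), class = "cohort_config")
}

#' Ground-truth effect ledger: target node-pair correlation per age group
#'
#' Expands the planted within-network (and optional between-network) targets
#' into one full node x node correlation matrix per age group, in canonical
#' atlas node order. Every planted value is recorded so downstream tests can
#' score recovery. Each matrix must be positive semi-definite; a failing
#' matrix is rejected naming the offending block unless `psd_repair = TRUE`,
#' in which case it is projected to the nearest PSD matrix by eigenvalue
#' clipping (off by default).
#'
#' @param config A `cohort_config`.
#' @param atlas An `roi_atlas`.
#' @param psd_repair Repair non-PSD targets instead of rejecting (default
#'   `FALSE`).
#' @return List of class `effect_ledger`: `targets` (named list of matrices,
#'   one per age group), `planted` (tibble of every planted entry),
#'   `atlas_hash`.
#' @export
effect_ledger <- function(config, atlas, psd_repair = FALSE) {
  stopifnot(inherits(config, "cohort_config"), inherits(atlas, "roi_atlas"))
  groups <- config$group_bounds$age_group
  n <- nrow(atlas)
  targets <- list()
  for (g in groups) {
    m <- diag(1, n)
    dimnames(m) <- list(atlas$node_id, atlas$node_id)
    eff <- dplyr::filter(config$planted_effects, .data$age_group == g)
    for (k in seq_len(nrow(eff))) {
      idx <- which(atlas$network == eff$network[k])
      if (length(idx) >= 2L) {
        m[idx, idx] <- eff$r[k]
        diag(m)[idx] <- 1
      }
    }
    inter <- config$inter_network_effects
    if (!is.null(inter)) {
      inter_g <- dplyr::filter(inter, .data$age_group == g)
      for (k in seq_len(nrow(inter_g))) {
        ia <- which(atlas$network == inter_g$network_a[k])
        ib <- which(atlas$network == inter_g$network_b[k])
        m[ia, ib] <- inter_g$r[k]
        m[ib, ia] <- inter_g$r[k]
      }
    }
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      if (!psd_repair) {
        bad <- unique(config$planted_effects$network)
        stop("target correlation matrix for age group '", g,
             "' is not positive semi-definite (min eigenvalue ",
             signif(min(ev), 3), "); involved networks: ",
             paste(bad, collapse = ", "),
             ". Set psd_repair = TRUE to project to the nearest PSD matrix.")
      }
      m <- nearest_psd_corr(m)
    }
    targets[[g]] <- m
  }
  planted <- config$planted_effects
  structure(list(targets = targets, planted = planted,
                 atlas_hash = atlas_hash(atlas)),
            class = "effect_ledger")
}

# project a symmetric matrix to the nearest PSD correlation matrix
# (eigenvalue clipping followed by unit-diagonal rescaling)
nearest_psd_corr <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, 1e-10)
  out <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  dimnames(out) <- dimnames(m)
  (out + t(out)) / 2
}

#' Generate the metadata table of a synthetic cohort
#'
#' Draws exactly `n_per_group` subjects per age group, assigns centers
#' round-robin (so each age group is balanced across centers), samples ages
#' uniformly inside the group bounds, alternates gender, and attaches a
#' per-subject, per-network cortical-thickness table with mild age-related
#' thinning. Fully reproducible from `config$rng_seed`.
#'
#' @param config A `cohort_config`.
#' @param atlas An `roi_atlas` (used for the thickness table's network list
#'   and the effect ledger).
#' @return Tibble of class `cohort` with one row per subject (`subject_id`,
#'   `age`, `age_group`, `gender`, `center`, `tr`, `n_frames`, `mean_fd`,
#'   `mean_dvars_std` initialised to `NA`), carrying attributes `thickness`
#'   (long tibble subject x network, mm), `ledger` (the [effect_ledger()])
#'   and `config`.
#' @export
generate_cohort <- function(config, atlas = build_roi_atlas(default_roi_table())) {
  stopifnot(inherits(config, "cohort_config"))
  ledger <- effect_ledger(config, atlas)
  groups <- config$group_bounds
  n <- config$n_per_group
  with_seed(derive_seed(config$rng_seed, "cohort"), {
    rows <- purrr::map(seq_len(nrow(groups)), function(gi) {
      g <- groups$age_group[gi]
      ctr_idx <- ((seq_len(n) - 1L) %% nrow(config$centers)) + 1L
      tibble::tibble(
        subject_id = sprintf("sub-%s-%03d", g, seq_len(n)),
        age = stats::runif(n, groups$lower[gi], groups$upper[gi]),
        age_group = g,
        gender = rep_len(c("F", "M"), n),
        center = config$centers$center[ctr_idx],
        tr = config$centers$tr[ctr_idx],
        n_frames = config$centers$n_frames[ctr_idx]
      )
    })
    cohort <- dplyr::bind_rows(rows)
    cohort$age_group <- factor(cohort$age_group, levels = groups$age_group)
    cohort$mean_fd <- NA_real_
    cohort$mean_dvars_std <- NA_real_
    nets <- unique(atlas$network)
    thickness <- tidyr::expand_grid(subject_id = cohort$subject_id,
                                    network = nets)
    age_of <- stats::setNames(cohort$age, cohort$subject_id)
    base <- stats::setNames(stats::runif(length(nets), 2.4, 2.9), nets)
    thickness$thickness_mm <- pmin(pmax(
      base[thickness$network] -
        0.004 * (age_of[thickness$subject_id] - 21) +
        stats::rnorm(nrow(thickness), 0, 0.05), 1.05), 4.95)
    structure(cohort, thickness = thickness, ledger = ledger, config = config,
              class = c("cohort", class(tibble::tibble())))
  })
}

#' Accessors for cohort attributes
#' @param cohort A `cohort` tibble from [generate_cohort()].
#' @return The thickness tibble, effect ledger, or config.
#' @export
cohort_thickness <- function(cohort) attr(cohort, "thickness")

#' @rdname cohort_thickness
#' @export
cohort_ledger <- function(cohort) attr(cohort, "ledger")

#' @rdname cohort_thickness
#' @export
cohort_config_of <- function(cohort) attr(cohort, "config")
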