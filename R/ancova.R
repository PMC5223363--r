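#' Assemble the long-format ANCOVA table
#'
#' One row per subject per network: the subject's mean within-network Fisher
#' z (the response), age group, gender, center, motion covariates and
#' per-network cortical thickness.
#'
#' @param cohort Cohort tibble with `subject_id`, `age_group`, `gender`,
#'   `center`, `mean_fd`, `mean_dvars_std` (QC covariates filled in).
#' @param matrices Named list of `connectivity_matrix` objects.
#' @param atlas The `roi_atlas`.
#' @param thickness Optional long tibble `subject_id`, `network`,
#'   `thickness_mm`; defaults to the cohort's attached thickness table.
#' @return Tibble with columns `subject_id`, `center`, `age_group`, `gender`,
#'   `network`, `mean_fd`, `mean_dvars_std`, `thickness_mm`, `mean_z` (7 rows
#'   per subject for the standard atlas).
#' @export
build_ancova_table <- function(cohort, matrices, atlas,
                               thickness = cohort_thickness(cohort)) {
  summaries <- purrr::map_dfr(cohort$subject_id, function(sid) {
    s <- subject_network_summary(matrices[[sid]], atlas)
    dplyr::mutate(s, subject_id = sid)
  })
  tab <- dplyr::left_join(
    summaries,
    dplyr::select(cohort, dplyr::all_of(c("subject_id", "center", "age_group",
                                          "gender", "mean_fd",
                                          "mean_dvars_std"))),
    by = "subject_id")
  if (!is.null(thickness)) {
    tab <- dplyr::left_join(tab, thickness, by = c("subject_id", "network"))
  } else {
    tab$thickness_mm <- NA_real_
  }
  dplyr::select(tab, dplyr::all_of(c(
    "subject_id", "center", "age_group", "gender", "network",
    "mean_fd", "mean_dvars_std", "thickness_mm")), mean_z = "mean_z")
}

#' Simulate an ANCOVA table directly from the mixed model
#'
#' Generates connectivity scores from the model
#' `mean_z = cell_mean(network, age group) + gender effect + center effect +
#' subject effect + covariate effects + residual`, with independent
#' zero-mean Gaussian center and subject random effects (variance-components
#' structure) and balanced assignment of each age group across centers. Used
#' for parameter-recovery and operating-characteristic experiments.
#'
#' @param n_per_group Subjects per age group.
#' @param n_centers Number of centers (balanced across groups).
#' @param cell_means Tibble `network`, `age_group`, `mean`: true cell means
#'   on the Fisher-z scale. Defaults to a flat 0.3 for the seven standard
#'   networks.
#' @param gender_effect Additive shift for male subjects.
#' @param var_center,var_subject,var_resid Variance components.
#' @param beta_fd,beta_dvars,beta_thickness Covariate slopes.
#' @param rng_seed Integer seed.
#' @return Tibble in [build_ancova_table()] format, with a `truth` attribute
#'   recording every generating parameter.
#' @export
simulate_ancova_cohort <- function(n_per_group = 106L, n_centers = 10L,
                                   cell_means = NULL, gender_effect = 0,
                                   var_center = 0.01, var_subject = 0.02,
                                   var_resid = 0.01,
                                   beta_fd = 0, beta_dvars = 0,
                                   beta_thickness = 0, rng_seed = 1L) {
  groups <- c("young", "middle", "old")
  networks <- c("DMN", "SN", "DAN", "FPCN", "AN", "VN", "MN")
  if (is.null(cell_means)) {
    cell_means <- tidyr::expand_grid(network = networks, age_group = groups)
    cell_means$mean <- 0.3
  }
  stopifnot(all(c("network", "age_group", "mean") %in% names(cell_means)))
  networks <- unique(cell_means$network)
  with_seed(rng_seed, {
    subjects <- tidyr::expand_grid(age_group = groups,
                                   k = seq_len(n_per_group))
    subjects$subject_id <- sprintf("sim-%s-%03d", subjects$age_group,
                                   subjects$k)
    subjects$center <- sprintf("c%02d", ((subjects$k - 1L) %% n_centers) + 1L)
    subjects$gender <- rep_len(c("F", "M"), nrow(subjects))
    subjects$mean_fd <- abs(stats::rnorm(nrow(subjects), 0.15, 0.05))
    subjects$mean_dvars_std <- stats::rnorm(nrow(subjects), 1, 0.05)
    u_center <- stats::setNames(
      stats::rnorm(n_centers, 0, sqrt(var_center)),
      sprintf("c%02d", seq_len(n_centers)))
    u_subject <- stats::setNames(
      stats::rnorm(nrow(subjects), 0, sqrt(var_subject)),
      subjects$subject_id)
    tab <- tidyr::expand_grid(subject_id = subjects$subject_id,
                              network = networks)
    tab <- dplyr::left_join(tab, subjects, by = "subject_id")
    tab <- dplyr::left_join(tab, cell_means,
                            by = c("network", "age_group"))
    tab$thickness_mm <- stats::rnorm(nrow(tab), 2.5, 0.15)
    tab$mean_z <- tab$mean +
      gender_effect * (tab$gender == "M") +
      u_center[tab$center] + u_subject[tab$subject_id] +
      beta_fd * tab$mean_fd + beta_dvars * tab$mean_dvars_std +
      beta_thickness * tab$thickness_mm +
      stats::rnorm(nrow(tab), 0, sqrt(var_resid))
    tab$age_group <- factor(tab$age_group, levels = groups)
    out <- dplyr::select(tab, dplyr::all_of(c(
      "subject_id", "center", "age_group", "gender", "network",
      "mean_fd", "mean_dvars_std", "thickness_mm", "mean_z")))
    attr(out, "truth") <- list(cell_means = cell_means,
                               gender_effect = gender_effect,
                               var_center = var_center,
                               var_subject = var_subject,
                               var_resid = var_resid,
                               beta = c(fd = beta_fd, dvars = beta_dvars,
                                        thickness = beta_thickness))
    out
  })
}

#' Fit the mixed-model ANCOVA of network connectivity
#'
#' Model: `mean_z ~ network * age_group * gender + mean_fd + mean_dvars_std +
#' thickness_mm + (1 | center) + (1 | subject_id)`, fit by REML with a
#' variance-components random-effects structure (independent center and
#' subject intercepts, distinct variances; subjects are nested in age group,
#' gender and center by their unique ids). Fixed terms are tested with
#' type-III F tests; least-squares means per network x age-group cell average
#' the gender factor with equal weights and hold covariates at their sample
#' means.
#'
#' @param table ANCOVA table from [build_ancova_table()] or
#'   [simulate_ancova_cohort()].
#' @param ddf Denominator-degrees-of-freedom method: `"satterthwaite"`
#'   (default) or `"asymptotic"` (large-sample Wald; fast, for simulation
#'   studies).
#' @param include_covariates Include FD, DVARS and thickness covariates
#'   (default `TRUE`).
#' @return Object of class `connlife_ancova`: list with `model` (the lmer
#'   fit), `anova` (tibble: `effect`, `num_df`, `den_df`, `f`, `p`),
#'   `lsmeans` (tibble: `network`, `age_group`, `estimate`, `se`),
#'   `lsm_vcov`, `lsm_fixef_l` (LSM rows in fixed-effect space), `varcomp`,
#'   `singular`, `ddf`.
#' @export
fit_mixed_ancova <- function(table,
                             ddf = c("satterthwaite", "asymptotic"),
                             include_covariates = TRUE) {
  ddf <- match.arg(ddf)
  needed <- c("subject_id", "center", "age_group", "gender", "network",
              "mean_z")
  stopifnot(all(needed %in% names(table)))
  dat <- tibble::as_tibble(table)
  dat$network <- factor(dat$network, levels = unique(dat$network))
  if (!is.factor(dat$age_group)) {
    dat$age_group <- factor(dat$age_group, levels = unique(dat$age_group))
  }
  dat$gender <- factor(dat$gender)
  dat$center <- factor(dat$center)
  if (length(levels(dat$center)) < 2L) stop("need >= 2 centers")
  covs <- intersect(c("mean_fd", "mean_dvars_std", "thickness_mm"),
                    names(dat))
  if (!include_covariates) covs <- character(0)
  covs <- covs[vapply(covs, function(v) !anyNA(dat[[v]]), logical(1L))]
  rhs <- paste(c("network * age_group * gender", covs,
                 "(1 | center)", "(1 | subject_id)"), collapse = " + ")
  form <- stats::as.formula(paste("mean_z ~", rhs))
  ctr <- list(network = "contr.sum", age_group = "contr.sum",
              gender = "contr.sum")
  fit <- lmerTest::lmer(form, data = dat, REML = TRUE, contrasts = ctr,
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore",
                          calc.derivs = FALSE))
  singular <- lme4::isSingular(fit, tol = 1e-5)

  an <- if (ddf == "satterthwaite") {
    a <- as.data.frame(stats::anova(fit, type = 3, ddf = "Satterthwaite"))
    tibble::tibble(effect = rownames(a), num_df = a$NumDF, den_df = a$DenDF,
                   f = a$`F value`, p = a$`Pr(>F)`)
  } else {
    wald_type3(fit)
  }

  lsm <- lsmeans_cells(fit, dat, covs)
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- tibble::tibble(component = vc$grp, variance = vc$vcov,
                            sd = vc$sdcor)

  structure(list(model = fit, anova = an, lsmeans = lsm$table,
                 lsm_vcov = lsm$vcov, lsm_fixef_l = lsm$L,
                 varcomp = varcomp, singular = singular, ddf = ddf,
                 data = dat, covariates = covs),
            class = "connlife_ancova")
}

# large-sample type-III Wald F tests (valid under the sum-to-zero coding
# used by fit_mixed_ancova)
wald_type3 <- function(fit) {
  b <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  asgn <- attr(stats::model.matrix(fit), "assign")
  labels <- attr(stats::terms(fit), "term.labels")
  labels <- labels[!grepl("\\|", labels)]
  rows <- purrr::map_dfr(seq_along(labels), function(k) {
    idx <- which(asgn == k)
    bk <- b[idx]
    W <- as.numeric(t(bk) %*% solve(V[idx, idx, drop = FALSE]) %*% bk)
    q <- length(idx)
    tibble::tibble(effect = labels[k], num_df = q, den_df = Inf,
                   f = W / q, p = stats::pchisq(W, q, lower.tail = FALSE))
  })
  rows
}

# least-squares means of the network x age-group cells: equal-weight average
# over gender, covariates at their sample means
lsmeans_cells <- function(fit, dat, covs) {
  networks <- levels(dat$network)
  groups <- levels(dat$age_group)
  genders <- levels(dat$gender)
  grid <- tidyr::expand_grid(network = networks, age_group = groups,
                             gender = genders)
  grid$network <- factor(grid$network, levels = networks)
  grid$age_group <- factor(grid$age_group, levels = groups)
  grid$gender <- factor(grid$gender, levels = genders)
  for (v in covs) grid[[v]] <- mean(dat[[v]])
  tt <- stats::delete.response(stats::terms(fit))
  X <- stats::model.matrix(tt, grid,
                           contrasts.arg = attr(stats::model.matrix(fit),
                                                "contrasts"))
  cell <- paste(grid$network, grid$age_group, sep = "|")
  cells <- unique(cell)
  L <- t(vapply(cells, function(cl) colMeans(X[cell == cl, , drop = FALSE]),
                numeric(ncol(X))))
  est <- as.vector(L %*% lme4::fixef(fit))
  V <- L %*% as.matrix(stats::vcov(fit)) %*% t(L)
  parts <- do.call(rbind, strsplit(cells, "|", fixed = TRUE))
  tab <- tibble::tibble(network = parts[, 1L], age_group = parts[, 2L],
                        estimate = est, se = unname(sqrt(pmax(diag(V), 0))))
  rownames(L) <- cells
  dimnames(V) <- list(cells, cells)
  list(table = tab, vcov = V, L = L)
}

#' Pre-planned contrasts of lifespan connectivity transitions
#'
#' Two families built from the fitted least-squares means. Family 1, one
#' contrast per network k: `C1(k) = LSM(young, k) - 2 LSM(middle, k) +
#' LSM(old, k)` — the young-to-middle transition against the middle-to-old
#' transition. Family 2, one contrast per (cognitive network c, sensorimotor
#' network s): `C2(c, s) = C1(c) - C1(s)`. Each contrast is tested with its
#' model-based SE; multiplicity within each family is corrected by
#' Monte-Carlo max-|t| over the family's estimated contrast correlation
#' (`n_draws` multivariate-normal draws), so the adjusted p value is
#' `P(max |t| >= observed |t|)` under the joint null.
#'
#' @param result A `connlife_ancova` fit.
#' @param n_draws Monte-Carlo draws for the max-|t| null (default 1e5).
#' @param rng_seed Integer seed for the draws.
#' @param alpha Significance level on adjusted p values.
#' @param network_classes Named map network -> class
#'   (`"cognitive"`/`"sensorimotor"`); family 2 pairs every cognitive with
#'   every sensorimotor network.
#' @return Tibble: `family`, `contrast`, `estimate`, `se`, `df`, `t`,
#'   `p_raw`, `p_adj`, `significant`. Non-estimable contrasts are returned
#'   with `NA` statistics and excluded from the max-|t| family.
#' @export
preplanned_contrasts <- function(result, n_draws = 1e5, rng_seed = 1L,
                                 alpha = 0.05,
                                 network_classes = .network_class_map) {
  stopifnot(inherits(result, "connlife_ancova"))
  lsm <- result$lsmeans
  groups <- unique(lsm$age_group)
  if (length(groups) != 3L) stop("contrasts require exactly 3 age groups")
  networks <- unique(lsm$network)
  cellname <- paste(lsm$network, lsm$age_group, sep = "|")
  k_cells <- nrow(lsm)

  c1_row <- function(net) {
    v <- numeric(k_cells)
    v[cellname == paste(net, groups[1L], sep = "|")] <- 1
    v[cellname == paste(net, groups[2L], sep = "|")] <- -2
    v[cellname == paste(net, groups[3L], sep = "|")] <- 1
    v
  }
  C1 <- t(vapply(networks, c1_row, numeric(k_cells)))
  rownames(C1) <- networks

  cls <- network_classes[networks]
  cog <- networks[!is.na(cls) & cls == "cognitive"]
  sm <- networks[!is.na(cls) & cls == "sensorimotor"]
  pairs2 <- tidyr::expand_grid(c = cog, s = sm)
  C2 <- t(apply(pairs2, 1L, function(p) C1[p[["c"]], ] - C1[p[["s"]], ]))
  rownames(C2) <- paste(pairs2$c, "vs", pairs2$s)

  test_family <- function(C, family, seed_tag) {
    est <- as.vector(C %*% lsm$estimate)
    Vc <- C %*% result$lsm_vcov %*% t(C)
    se <- unname(sqrt(pmax(diag(Vc), 0)))
    estimable <- is.finite(est) & se > 0
    tval <- ifelse(estimable, est / se, NA_real_)
    df <- rep(Inf, nrow(C))
    if (result$ddf == "satterthwaite") {
      Lfix <- C %*% result$lsm_fixef_l
      for (i in which(estimable)) {
        ct <- try(lmerTest::contest(result$model, Lfix[i, ], joint = FALSE),
                  silent = TRUE)
        if (!inherits(ct, "try-error")) df[i] <- ct$df[1L]
      }
    }
    p_raw <- 2 * stats::pt(-abs(tval), df)
    idx <- which(estimable)
    p_adj <- rep(NA_real_, nrow(C))
    if (length(idx) > 0L) {
      R <- stats::cov2cor(Vc[idx, idx, drop = FALSE])
      Rt <- chol(nearest_psd_corr(R))
      maxabs <- with_seed(derive_seed(rng_seed, "contrast_sim", seed_tag), {
        Z <- matrix(stats::rnorm(n_draws * length(idx)), n_draws) %*% Rt
        do.call(pmax, as.data.frame(abs(Z)))
      })
      p_adj[idx] <- vapply(tval[idx], function(t0) {
        (sum(maxabs >= abs(t0)) + 1) / (n_draws + 1)
      }, numeric(1L))
      p_adj[idx] <- pmax(p_adj[idx], p_raw[idx])
    }
    tibble::tibble(family = family, contrast = rownames(C), estimate = est,
                   se = se, df = df, t = tval, p_raw = p_raw, p_adj = p_adj,
                   significant = !is.na(p_adj) & p_adj <= alpha)
  }

  dplyr::bind_rows(
    test_family(C1, "within_network", "c1"),
    if (nrow(C2) > 0L) test_family(C2, "cognitive_vs_sensorimotor", "c2")
  )
}

#' @export
print.connlife_ancova <- function(x, ...) {
  cat("<connlife_ancova> mixed-model ANCOVA of network connectivity\n")
  cat("  observations:", nrow(x$data), " subjects:",
      length(unique(x$data$subject_id)), " centers:",
      length(unique(x$data$center)), "\n")
  if (x$singular) cat("  note: singular fit (a variance component at 0)\n")
  print(x$anova)
  invisible(x)
}

#' Tidy an ANCOVA fit
#'
#' @param x A `connlife_ancova`.
#' @param effects One of `"anova"` (fixed-effect F table, default),
#'   `"lsmeans"`, `"varcomp"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.connlife_ancova <- function(x, effects = c("anova", "lsmeans",
                                                "varcomp"), ...) {
  effects <- match.arg(effects)
  switch(effects, anova = x$anova, lsmeans = x$lsmeans,
         varcomp = x$varcomp)
}

#' One-row summary of an ANCOVA fit
#' @param x A `connlife_ancova`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.connlife_ancova <- function(x, ...) {
  tibble::tibble(
    nobs = nrow(x$data),
    n_subjects = length(unique(x$data$subject_id)),
    n_centers = length(unique(x$data$center)),
    sigma = stats::sigma(x$model),
    REMLcrit = as.numeric(lme4::REMLcrit(x$model)),
    singular = x$singular
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
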