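#' Run the end-to-end synthetic pipeline
#'
#' Fixed stage order: simulate -> preprocess (GSR per `gsr`) -> motion QC ->
#' connectivity -> matched subsampling -> group statistics (difference
#' matrices with FDR, mixed ANCOVA with pre-planned contrasts) -> report.
#' Every stage's outputs are written as TSV (and optionally NIfTI) before the
#' next stage starts, and a JSON run manifest records the configuration,
#' per-stage seeds, package version and stage timings, so a run is exactly
#' reproducible from its manifest.
#'
#' Intended for desk-scale synthetic experiments; cohort-scale statistical
#' studies should use [simulate_cohort_connectivity()] directly.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [cohort_config()]; its `rng_seed` seeds every stage
#'   through named sub-streams.
#' @param atlas An `roi_atlas`.
#' @param gsr Apply global-signal regression (default `TRUE`).
#' @param enforce_qc Drop subjects failing [qc_screen()] instead of only
#'   flagging them (default `FALSE`).
#' @param write_volumes Also write per-subject BOLD NIfTI volumes (default
#'   `FALSE`; they are large).
#' @param fdr_method FDR procedure for the difference matrices.
#' @return Invisibly, a list with the cohort, QC table, connectivity
#'   matrices, difference matrices, ANCOVA fit, contrasts and the manifest.
#' @export
run_pipeline <- function(out_dir, config, atlas = build_roi_atlas(default_roi_table()),
                         gsr = TRUE, enforce_qc = FALSE,
                         write_volumes = FALSE,
                         fdr_method = c("BY", "BH")) {
  fdr_method <- match.arg(fdr_method)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage, prev) {
    now <- proc.time()[["elapsed"]]
    timings[[stage]] <<- now - prev
    now
  }
  seed <- config$rng_seed

  # stage 1: simulate cohort metadata and volumes
  cohort <- generate_cohort(config, atlas)
  write_tsv_table(dplyr::select(cohort, -dplyr::any_of(character(0))),
                  file.path(out_dir, "metadata.tsv"))
  write_tsv_table(cohort_thickness(cohort),
                  file.path(out_dir, "thickness.tsv"))
  write_tsv_table(config$planted_effects,
                  file.path(out_dir, "planted_effects.tsv"))
  masks <- make_tissue_masks(config$grid)
  tprev <- tick("simulate_metadata", t0)

  pconfig <- preprocess_config(gsr = gsr)
  matrices <- list()
  qc_rows <- list()
  for (s in seq_len(nrow(cohort))) {
    subj <- cohort[s, ]
    sim <- simulate_subject_bold(
      subj, atlas, masks, cohort_ledger(cohort), config$grid,
      rng_seed = derive_seed(seed, "subject", s),
      noise_sd = config$noise_sd, global_amp = config$global_amp,
      motion_scale = config$motion_scale)
    write_motion(sim$motion,
                 file.path(out_dir, paste0(subj$subject_id, "_motion.tsv")))
    if (write_volumes) {
      write_bold(sim$run,
                 file.path(out_dir, paste0(subj$subject_id, "_bold.nii.gz")))
    }
    clean <- preprocess_run(sim$run, sim$motion, masks, pconfig)
    qc <- qc_metrics(sim$run, sim$motion, masks$brain)
    qc_rows[[s]] <- tibble::tibble(subject_id = subj$subject_id,
                                   mean_fd = qc$mean_fd,
                                   mean_dvars_std = qc$mean_dvars_std)
    series <- extract_roi_timeseries(clean, atlas)
    zmat <- subject_connectivity(series, atlas)
    matrices[[subj$subject_id]] <- zmat
    write_connectivity(zmat,
                       file.path(out_dir, paste0(subj$subject_id, "_z.tsv")))
  }
  tprev <- tick("preprocess_qc_connectivity", tprev)

  qc_tab <- qc_screen(dplyr::bind_rows(qc_rows))
  write_tsv_table(qc_tab, file.path(out_dir, "qc_report.tsv"))
  cohort$mean_fd <- qc_tab$mean_fd[match(cohort$subject_id,
                                         qc_tab$subject_id)]
  cohort$mean_dvars_std <- qc_tab$mean_dvars_std[match(cohort$subject_id,
                                                       qc_tab$subject_id)]
  if (enforce_qc) {
    keep_ids <- qc_tab$subject_id[qc_tab$pass_flag]
    cohort <- cohort[cohort$subject_id %in% keep_ids, , drop = FALSE]
    matrices <- matrices[cohort$subject_id]
  }
  tprev <- tick("qc_screen", tprev)

  matched <- matched_subsample(cohort, rng_seed = derive_seed(seed, "match"))
  write_tsv_table(attr(matched, "selection_log"),
                  file.path(out_dir, "subsample_log.tsv"))
  groups <- levels(droplevels(factor(matched$age_group)))
  gm <- group_mean_matrices(matrices[matched$subject_id], matched, atlas)
  write_tsv_table(gm, file.path(out_dir, "group_matrices.tsv"))
  diffs <- list()
  for (k in seq_len(length(groups) - 1L)) {
    d <- difference_matrix_test(matrices, matched, groups[k], groups[k + 1L],
                                atlas, fdr_method = fdr_method)
    nm <- paste0(groups[k], "_vs_", groups[k + 1L])
    diffs[[nm]] <- d
    write_tsv_table(tibble::as_tibble(d),
                    file.path(out_dir, paste0("diff_", nm, ".tsv")))
  }
  tprev <- tick("group_matrices", tprev)

  tab <- build_ancova_table(matched, matrices, atlas)
  fit <- fit_mixed_ancova(tab)
  contrasts <- preplanned_contrasts(fit,
                                    rng_seed = derive_seed(seed, "contrast"))
  write_tsv_table(tidy(fit), file.path(out_dir, "ancova_summary.tsv"))
  write_tsv_table(tidy(fit, "lsmeans"), file.path(out_dir, "lsmeans.tsv"))
  write_tsv_table(contrasts, file.path(out_dir, "contrasts.tsv"))
  tprev <- tick("ancova", tprev)

  results <- list(cohort = cohort, qc = qc_tab, matrices = matrices,
                  matched = matched, group_means = gm, differences = diffs,
                  ancova = fit, contrasts = contrasts)
  report <- render_report(results)
  writeLines(report, file.path(out_dir, "report.txt"))

  manifest <- list(
    package = "connlife",
    version = as.character(utils::packageVersion("connlife")),
    master_seed = seed,
    stage_seeds = list(
      cohort = derive_seed(seed, "cohort"),
      subjects = vapply(seq_len(nrow(cohort)),
                        function(s) derive_seed(seed, "subject", s),
                        numeric(1L)),
      match = derive_seed(seed, "match"),
      contrast = derive_seed(seed, "contrast")
    ),
    gsr = gsr, enforce_qc = enforce_qc, fdr_method = fdr_method,
    n_per_group = config$n_per_group,
    centers = config$centers,
    grid = list(dims = config$grid$dims, voxel_mm = config$grid$voxel_mm),
    noise_sd = config$noise_sd, motion_scale = config$motion_scale,
    atlas_hash = atlas_hash(atlas),
    timings_s = timings,
    output_digests = file_digests(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

# content fingerprints of every regular file in a directory
file_digests <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE))
  files <- files[files != "manifest.json"]
  vals <- vapply(files, function(f) {
    rlang::hash(readBin(file.path(dir, f), "raw",
                        n = file.info(file.path(dir, f))$size))
  }, character(1L))
  as.list(vals)
}

#' Render a plain-text summary report
#'
#' Per-network least-squares means with SE, group mean matrices, difference
#' matrices with significance dots, and the QC summary. Deterministic given
#' its inputs: regenerating from the same results yields a byte-identical
#' file.
#'
#' @param results The list returned by [run_pipeline()] (fields `qc`,
#'   `group_means`, `differences`, `ancova`, `contrasts`).
#' @return Character vector of report lines.
#' @export
render_report <- function(results) {
  fmt <- function(x) formatC(x, digits = 3, format = "f")
  lines <- c("connlife run report", strrep("=", 60))
  qc <- results$qc
  lines <- c(lines, "",
             sprintf("QC: %d subjects, %d pass, %d flagged", nrow(qc),
                     sum(qc$pass_flag), sum(!qc$pass_flag)),
             sprintf("  mean FD %s mm, mean standardized DVARS %s",
                     fmt(mean(qc$mean_fd)), fmt(mean(qc$mean_dvars_std))))
  lsm <- results$ancova$lsmeans
  lines <- c(lines, "", "Least-squares means z(r) +/- SE:")
  for (net in unique(lsm$network)) {
    sub <- lsm[lsm$network == net, ]
    lines <- c(lines, sprintf("  %-5s %s", net,
                              paste(sprintf("%s=%s+/-%s", sub$age_group,
                                            fmt(sub$estimate), fmt(sub$se)),
                                    collapse = "  ")))
  }
  lines <- c(lines, "", "Pre-planned contrasts (adjusted p):")
  ct <- results$contrasts
  for (i in seq_len(nrow(ct))) {
    lines <- c(lines, sprintf("  %-28s est=%s  p_adj=%s%s", ct$contrast[i],
                              fmt(ct$estimate[i]), fmt(ct$p_adj[i]),
                              if (isTRUE(ct$significant[i])) " *" else ""))
  }
  for (nm in names(results$differences)) {
    d <- results$differences[[nm]]
    nsig <- sum(d$significant, na.rm = TRUE)
    lines <- c(lines, "",
               sprintf("Difference matrix %s: %d of %d pairs significant (%s, FDR %.2f)",
                       nm, nsig, nrow(d), attr(d, "fdr_method"),
                       attr(d, "alpha")))
    sig <- d[which(d$significant), , drop = FALSE]
    if (nrow(sig) > 0L) {
      show <- utils::head(sig[order(-abs(sig$delta_z)), ], 10L)
      lines <- c(lines, sprintf("  . %s -- %s  dz=%s", show$node_a,
                                show$node_b, fmt(show$delta_z)))
    }
  }
  lines
}
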