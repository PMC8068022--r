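#' Run the full analysis pipeline on a directory of recordings
#'
#' Reads every `*.csv` + sidecar recording in `input_dir` (or takes a list of
#' `pressure_recording`s directly), then for each task: preprocess (median
#' filter, saturation masking, force conversion), synchronize, scale to the
#' reference subject, discard outliers, compute mean curves and CGF. Study
#' level outputs (correlation matrices, peak table, duration summaries, ANOVA
#' tables, signature graphs) are written as CSV/JSON/SVG under `out_dir`.
#'
#' @param input Either a directory containing recording CSV/JSON pairs or a
#'   named list of `pressure_recording`s.
#' @param out_dir Output directory, created if needed.
#' @param layout A `sensor_layout`, default the packaged one.
#' @param n_discard Outlier subjects to drop per task, default 4 (0 if the
#'   cohort is too small).
#' @param epsilon CGF guard in N, default 0.1.
#' @param threshold Signature edge threshold, default 0.05.
#' @param strategy,seed Passed to [optimize_warp()].
#' @return Invisibly, a list with `synced`, `retained`, `cgf`, `task_corr`,
#'   `region_corr`, `peaks`, `durations`, `anova_gf`, `signatures`.
#' @export
run_pipeline <- function(input, out_dir, layout = default_layout(),
                         n_discard = 4, epsilon = 0.1, threshold = 0.05,
                         strategy = "grid", seed = 42L) {
  recordings <- if (is.character(input)) {
    files <- sort(list.files(input, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) == 0) stop("no recordings found in ", input)
    recs <- lapply(files, read_recording, layout = layout)
    names(recs) <- vapply(recs, function(r)
      sprintf("%s_t%02d", r$subject_id, r$task_id), character(1))
    recs
  } else input
  if (length(recordings) == 0) stop("empty input")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  task_of <- vapply(recordings, `[[`, integer(1), "task_id")
  tasks <- sort(unique(task_of))
  subj_of <- vapply(recordings, `[[`, character(1), "subject_id")
  n_subjects <- length(unique(subj_of))
  if (n_discard >= n_subjects - 1) n_discard <- 0

  processed <- lapply(recordings, preprocess_recording, layout = layout)
  masked <- lapply(processed, attr, "recording")

  synced <- list()
  retained <- list()
  signatures <- list()
  mean_curves <- list()
  for (k in tasks) {
    fs_list <- processed[task_of == k]
    names(fs_list) <- subj_of[task_of == k]
    if (length(fs_list) < n_subjects)
      warning("task ", k, ": only ", length(fs_list), " of ", n_subjects,
              " subjects present")
    sy <- scale_to_reference(
      synchronize_task(fs_list, strategy = strategy, seed = seed))
    keep <- discard_outliers(sy$gf, n_discard)
    synced[[as.character(k)]] <- sy
    retained[[as.character(k)]] <- keep
    mc <- mean_task_curve(sy$gf[keep, , drop = FALSE])
    mean_curves[[as.character(k)]] <- mc
    sync_json <- list(task = k, reference = sy$reference,
                      retained = keep,
                      params = lapply(sy$params, unclass),
                      costs = as.list(sy$costs))
    jsonlite::write_json(sync_json,
                         file.path(out_dir, sprintf("sync_task%02d.json", k)),
                         auto_unbox = TRUE, digits = NA)
  }

  cgf <- cgf_matrix(synced, retained, epsilon = epsilon)
  for (k in tasks) {
    g <- build_signature(cgf$task_region_mean[as.character(k), ], layout,
                         threshold = threshold)
    signatures[[as.character(k)]] <- g
    render_signature(g, file.path(out_dir, sprintf("signature_task%02d.svg", k)))
  }

  tc <- if (length(tasks) >= 2) task_correlations(cgf) else NULL
  rc <- region_correlations(cgf)
  peaks <- peak_table(masked, layout, retained)
  durations <- task_duration_stats(
    vapply(recordings, function(r) max(r$timestamps_s), numeric(1)), task_of)

  # unscaled mean GF per subject x task for the ANOVA (no scaling factor)
  anova_gf <- NULL
  if (length(tasks) >= 2 && n_subjects >= 2) {
    gf_tab <- matrix(NA_real_, length(tasks), n_subjects,
                     dimnames = list(tasks, sort(unique(subj_of))))
    for (i in seq_along(processed)) {
      fs <- processed[[i]]
      g <- fs$gf_n
      win <- g > mean(g)
      gf_tab[as.character(fs$task_id), fs$subject_id] <-
        mean(g[if (any(win)) win else g > 0])
    }
    if (!any(is.na(gf_tab))) anova_gf <- two_way_anova(gf_tab)
  }

  mean_mat <- do.call(rbind, lapply(mean_curves, `[[`, "mean"))
  sd_mat <- do.call(rbind, lapply(mean_curves, `[[`, "sd"))
  utils::write.csv(data.frame(task = rep(tasks, each = 101),
                              tau = rep(normalized_grid(), length(tasks)),
                              mean = as.vector(t(mean_mat)),
                              sd = as.vector(t(sd_mat))),
                   file.path(out_dir, "mean_curves.csv"), row.names = FALSE)
  utils::write.csv(data.frame(task = tasks, cgf$task_region_mean),
                   file.path(out_dir, "cgf_matrix.csv"), row.names = FALSE)
  if (!is.null(tc))
    utils::write.csv(tc, file.path(out_dir, "task_corr.csv"),
                     row.names = FALSE)
  utils::write.csv(rc, file.path(out_dir, "region_corr.csv"),
                   row.names = FALSE)
  utils::write.csv(peaks, file.path(out_dir, "peak_table.csv"),
                   row.names = FALSE)
  utils::write.csv(durations, file.path(out_dir, "durations.csv"),
                   row.names = FALSE)
  if (!is.null(anova_gf))
    utils::write.csv(anova_gf, file.path(out_dir, "anova_gf.csv"),
                     row.names = FALSE)
  writeLines(c(
    sprintf("gripsig %s", as.character(utils::packageVersion("gripsig"))),
    sprintf("seed: %d; strategy: %s; n_discard: %d; epsilon: %g; threshold: %g",
            seed, strategy, n_discard, epsilon, threshold),
    sprintf("recordings: %d; tasks: %d; subjects: %d",
            length(recordings), length(tasks), n_subjects),
    sprintf("discarded sensels (per recording): %s",
            paste(vapply(processed, function(f)
              length(f$discarded_sensels), integer(1)), collapse = ","))),
    file.path(out_dir, "summary.log"))

  invisible(list(synced = synced, retained = retained, cgf = cgf,
                 task_corr = tc, region_corr = rc, peaks = peaks,
                 durations = durations, anova_gf = anova_gf,
                 signatures = signatures, mean_curves = mean_curves))
}
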