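# Post-synchronization statistics: amplitude scaling to the reference subject,
# outlier discard, mean task curves, contribution-to-grip-force (CGF) per
# region, correlation and peak-load summaries.

#' Scale each subject's forces to the reference subject's mean grip force
#'
#' Differences in sensor fit produce subject-specific amplitude offsets; each
#' subject's force channels are multiplied by
#' `meanGF(reference) / meanGF(subject)` so all subjects share the reference's
#' mean GF before averaging. CGF is a force ratio and is unaffected.
#'
#' @param sync A `sync_result` from [synchronize_task()].
#' @return The `sync_result` with `gf` and `region` scaled and a `factors`
#'   element added (reference factor is exactly 1). Subjects with zero mean GF
#'   are dropped with a warning.
#' @export
scale_to_reference <- function(sync) {
  stopifnot(inherits(sync, "sync_result"))
  mean_gf <- rowMeans(sync$gf)
  zero <- mean_gf == 0
  if (any(zero)) {
    warning("excluding subject(s) with zero mean GF: ",
            paste(sync$subjects[zero], collapse = ", "))
    sync$gf <- sync$gf[!zero, , drop = FALSE]
    sync$region <- sync$region[!zero, , , drop = FALSE]
    sync$subjects <- sync$subjects[!zero]
    mean_gf <- mean_gf[!zero]
  }
  factors <- mean_gf[sync$reference] / mean_gf
  sync$gf <- sync$gf * factors
  sync$region <- sweep(sync$region, 1, factors, `*`)
  sync$factors <- factors
  sync
}

#' Discard the subjects farthest from the mean curve
#'
#' The `n_discard` subjects whose (scaled, synchronized) GF curve has the
#' largest Euclidean distance to the pointwise mean over all subjects are
#' dropped; with the study's 22 subjects and the default of 4, 18 remain.
#' Ties break to keeping the lower subject id.
#'
#' @param gf Subjects x 101 matrix of GF curves (rownames = subject ids).
#' @param n_discard Number of subjects to drop, default 4.
#' @return Character vector of retained subject ids, in input order.
#' @export
discard_outliers <- function(gf, n_discard = 4) {
  ids <- rownames(gf)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(gf)))
  if (n_discard >= nrow(gf))
    stop("n_discard (", n_discard, ") must be smaller than the cohort (",
         nrow(gf), ")")
  if (n_discard == 0) return(ids)
  avg <- colMeans(gf)
  d <- sqrt(rowSums(sweep(gf, 2, avg)^2))
  drop_idx <- order(-d, ids)[seq_len(n_discard)]
  ids[-sort(drop_idx)]
}

#' Pointwise mean and SD curve over retained subjects
#'
#' @param gf Subjects x 101 matrix (already scaled and synchronized).
#' @return List with `mean` and `sd`, both length-101.
#' @export
mean_task_curve <- function(gf) {
  if (nrow(gf) < 2) stop("need at least 2 subjects for a mean curve")
  list(mean = colMeans(gf), sd = apply(gf, 2, stats::sd))
}

#' Mean contribution to grip force per region
#'
#' The instantaneous CGF of region r is `region_force(t, r) / GF(t)`. The mean
#' CGF averages it over the analysis window: the instants where GF exceeds its
#' mean over the task, i.e. the part of the task where force is significant.
#' If the window is empty (constant GF) it falls back to all instants with
#' GF > epsilon, flagged via attribute `fallback`.
#'
#' @param gf Length-T GF vector (N).
#' @param region T x 18 region force matrix (N).
#' @param epsilon Guard against 0/0, default 0.1 N: instants with
#'   GF <= epsilon never enter the window.
#' @return Length-18 vector of fractions summing to 1 (when the window is
#'   non-empty).
#' @export
mean_cgf <- function(gf, region, epsilon = 0.1) {
  if (inherits(gf, "force_series")) {
    region <- gf$region_force_n
    gf <- gf$gf_n
  }
  if (all(gf <= epsilon)) stop("grip force never exceeds ", epsilon, " N")
  win <- which(gf > mean(gf) & gf > epsilon)
  fallback <- FALSE
  if (length(win) == 0) {
    win <- which(gf > epsilon)
    fallback <- TRUE
  }
  cgf_t <- region[win, , drop = FALSE] / gf[win]
  out <- colMeans(cgf_t)
  attr(out, "fallback") <- fallback
  out
}

#' Subject x task x region CGF array for a study
#'
#' Runs [mean_cgf()] on each subject's synchronized (optionally scaled) curves
#' for each task and averages over the retained subjects.
#'
#' @param synced_tasks List of `sync_result`s (one per task, scaled).
#' @param retained Named list (by task) of retained subject ids.
#' @param epsilon Passed to [mean_cgf()].
#' @return A `cgf_matrix`: list with `mean_cgf` (subject x task x region
#'   array), `task_region_mean` (task x region matrix over retained subjects),
#'   `retained` (list).
#' @export
cgf_matrix <- function(synced_tasks, retained = NULL, epsilon = 0.1) {
  task_ids <- names(synced_tasks) %||% as.character(seq_along(synced_tasks))
  subjects <- sort(unique(unlist(lapply(synced_tasks, `[[`, "subjects"))))
  arr <- array(NA_real_, c(length(subjects), length(synced_tasks), 18),
               dimnames = list(subjects, task_ids, NULL))
  trm <- matrix(NA_real_, length(synced_tasks), 18,
                dimnames = list(task_ids, NULL))
  if (is.null(retained))
    retained <- lapply(synced_tasks, `[[`, "subjects")
  names(retained) <- task_ids
  for (k in seq_along(synced_tasks)) {
    sy <- synced_tasks[[k]]
    for (id in sy$subjects) {
      i <- match(id, sy$subjects)
      arr[id, k, ] <- mean_cgf(sy$gf[i, ], sy$region[i, , ],
                               epsilon = epsilon)
    }
    trm[k, ] <- colMeans(arr[retained[[k]], k, , drop = FALSE], na.rm = TRUE)
  }
  structure(list(mean_cgf = arr, task_region_mean = trm, retained = retained),
            class = "cgf_matrix")
}

#' Pearson correlation between tasks' region patterns
#'
#' Correlates each pair of tasks' subject-averaged 18-region CGF vectors.
#'
#' @param cgf A `cgf_matrix` (or a task x region matrix).
#' @return Symmetric task x task matrix with unit diagonal; zero-variance
#'   tasks give NA entries with a warning.
#' @export
task_correlations <- function(cgf) {
  m <- if (inherits(cgf, "cgf_matrix")) cgf$task_region_mean else cgf
  pearson_matrix(t(m))
}

#' Pearson correlation between regions across subject x task observations
#'
#' Each observation is one subject x task mean-CGF vector; regions that share
#' load positively co-vary, regions that split a fixed total are negatively
#' correlated.
#'
#' @param cgf A `cgf_matrix` (or an observations x region matrix).
#' @return Symmetric 18 x 18 matrix with unit diagonal.
#' @export
region_correlations <- function(cgf) {
  m <- if (inherits(cgf, "cgf_matrix")) {
    arr <- cgf$mean_cgf
    obs <- do.call(rbind, lapply(seq_len(dim(arr)[2]), function(k)
      arr[, k, , drop = TRUE]))
    obs[stats::complete.cases(obs), , drop = FALSE]
  } else cgf
  pearson_matrix(m)
}

pearson_matrix <- function(obs_by_var) {
  v <- apply(obs_by_var, 2, stats::var)
  if (any(v == 0, na.rm = TRUE))
    warning("zero-variance column(s): correlation undefined (NA) for ",
            paste(which(v == 0), collapse = ", "))
  suppressWarnings(r <- stats::cor(obs_by_var))
  diag(r) <- 1
  r
}

#' Peak force and pressure per sensing region
#'
#' For each region, subject and task the maximum over time of the region force
#' and of any single sensel's pressure in that region is taken; these are
#' averaged over the retained subjects per task, and the per-region maximum
#' over tasks is reported with its task.
#'
#' @param recordings Named list of preprocessed `pressure_recording`s (keys
#'   `"<subject>_t<task>"`), i.e. after median filtering and masking.
#' @param layout A `sensor_layout`.
#' @param retained Optional named list (by task id as character) of retained
#'   subject ids; default uses all subjects.
#' @return A data.frame with one row per region: `region`, `peak_force_n`,
#'   `peak_force_task`, `peak_pressure_kpa`, `peak_pressure_task`.
#' @export
peak_table <- function(recordings, layout, retained = NULL) {
  if (length(recordings) == 0) stop("no recordings supplied")
  info <- lapply(recordings, function(rec) {
    fs <- compute_forces(rec, layout)
    list(subject = rec$subject_id, task = rec$task_id,
         force = apply(fs$region_force_n, 2, max),
         pressure = vapply(layout$sensel_ids, function(ids)
           max(rec$pressures[, ids]), numeric(1)))
  })
  tasks <- sort(unique(vapply(info, `[[`, integer(1), "task")))
  per_task_force <- matrix(NA_real_, length(tasks), 18,
                           dimnames = list(tasks, NULL))
  per_task_press <- per_task_force
  for (ti in seq_along(tasks)) {
    sel <- Filter(function(x) x$task == tasks[ti], info)
    if (!is.null(retained)) {
      keep <- retained[[as.character(tasks[ti])]]
      if (!is.null(keep)) sel <- Filter(function(x) x$subject %in% keep, sel)
    }
    per_task_force[ti, ] <- colMeans(do.call(rbind, lapply(sel, `[[`, "force")))
    per_task_press[ti, ] <- colMeans(do.call(rbind, lapply(sel, `[[`,
                                                           "pressure")))
  }
  best_f <- apply(per_task_force, 2, which.max)
  best_p <- apply(per_task_press, 2, which.max)
  data.frame(
    region = 1:18,
    peak_force_n = per_task_force[cbind(best_f, 1:18)],
    peak_force_task = tasks[best_f],
    peak_pressure_kpa = per_task_press[cbind(best_p, 1:18)],
    peak_pressure_task = tasks[best_p])
}

#' Task duration summaries (boxplot statistics)
#'
#' Median, quartiles, whiskers and 1.5 x IQR outliers per task, matching the
#' usual boxplot convention.
#'
#' @param durations_s Numeric vector of execution times.
#' @param task_ids Parallel vector of task ids.
#' @return data.frame with one row per task: `task`, `n`, `lower_whisker`,
#'   `q1`, `median`, `q3`, `upper_whisker`, `n_outliers`.
#' @export
task_duration_stats <- function(durations_s, task_ids) {
  stopifnot(length(durations_s) == length(task_ids))
  tasks <- sort(unique(task_ids))
  rows <- lapply(tasks, function(k) {
    x <- durations_s[task_ids == k]
    bs <- grDevices::boxplot.stats(x)
    data.frame(task = k, n = length(x),
               lower_whisker = bs$stats[1], q1 = bs$stats[2],
               median = bs$stats[3], q3 = bs$stats[4],
               upper_whisker = bs$stats[5], n_outliers = length(bs$out))
  })
  do.call(rbind, rows)
}
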