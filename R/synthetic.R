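# Synthetic cohort generator. The generator states a world shaped like the
# study: 22 subjects x 21 activities of daily living, grip-force profiles that
# start and end at zero with peaks spanning roughly 5-100 N, per-task region
# contribution weights (the ground-truth CGF), subject-specific amplitude
# scaling and execution pace (a three-segment warp within the synchronization
# bounds), ~14 s mean task duration, sensor noise, single-frame spikes, and
# clipping at the 517 kPa full scale.

#' Task template: grip-force profile plus region contribution weights
#'
#' The GF profile is a sum of raised-cosine bumps in normalized time, zero at
#' both endpoints (the hand starts and ends free of contact). `region_weights`
#' is the ground-truth contribution of each of the 18 regions and must sum
#' to 1.
#'
#' @param centers,widths,heights_n Bump parameters: centers in (0,1), widths
#'   such that every bump support stays inside [0,1], heights in N.
#' @param region_weights Non-negative 18-vector summing to 1.
#' @param active_fraction Fraction of each region's sensels that carry load
#'   (the rest read zero), default 0.5.
#' @return A `task_template` with a vectorized `gf_profile(tau)` function.
#' @export
task_template <- function(centers, widths, heights_n, region_weights,
                          active_fraction = 0.5) {
  stopifnot(length(centers) == length(widths),
            length(centers) == length(heights_n))
  if (length(region_weights) != 18)
    stop("region_weights must have length 18")
  if (any(region_weights < 0))
    stop("region_weights must be non-negative")
  if (abs(sum(region_weights) - 1) > 1e-9)
    stop("region_weights must sum to 1, got ", sum(region_weights))
  if (any(centers - widths < 0) || any(centers + widths > 1))
    stop("bump supports must stay inside [0, 1]")
  profile <- function(tau) {
    out <- numeric(length(tau))
    for (k in seq_along(centers)) {
      inside <- abs(tau - centers[k]) < widths[k]
      out[inside] <- out[inside] + heights_n[k] * 0.5 *
        (1 + cos(pi * (tau[inside] - centers[k]) / widths[k]))
    }
    out
  }
  structure(list(gf_profile = profile, region_weights = region_weights,
                 active_fraction = active_fraction,
                 peak_n = max(profile(seq(0, 1, by = 1e-3)))),
            class = "task_template")
}

#' Per-subject execution effects
#'
#' @param amplitude_factor Positive multiplicative force scale (sensor fit
#'   differences between subjects).
#' @param warp A `warp_params`: the subject's pace deviation. The subject's
#'   curve is the template composed with this map, so synchronization should
#'   recover its effect.
#' @param duration_s Task execution time in seconds.
#' @param noise_sd_kpa Additive Gaussian sensor noise SD per sensel, kPa.
#' @param spike_rate Expected single-frame spikes per sensel-second.
#' @param saturate Clip pressures at 517 kPa and record clipping events.
#' @return A `subject_effects` object.
#' @export
subject_effects <- function(amplitude_factor = 1, warp = identity_warp(),
                            duration_s = 14, noise_sd_kpa = 0,
                            spike_rate = 0, saturate = TRUE) {
  if (amplitude_factor <= 0) stop("amplitude_factor must be positive")
  if (duration_s <= 0) stop("duration_s must be positive")
  if (noise_sd_kpa < 0) stop("noise_sd_kpa must be non-negative")
  stopifnot(inherits(warp, "warp_params"))
  structure(list(amplitude_factor = amplitude_factor, warp = warp,
                 duration_s = duration_s, noise_sd_kpa = noise_sd_kpa,
                 spike_rate = spike_rate, saturate = saturate),
            class = "subject_effects")
}

#' Generate one subject x task pressure recording
#'
#' The noiseless grip force is `amplitude_factor * gf_profile(phi(tau))` where
#' `phi` is the subject's warp evaluated in continuous normalized time before
#' 50 Hz sampling (so recovering the warp is a well-posed inverse problem).
#' Region force is `weight x GF`, split equally over the region's active
#' sensels; pressure is force / sensel area. Gaussian noise and isolated
#' single-frame spikes are then added and values clipped to [0, 517] kPa.
#'
#' @param template A `task_template`.
#' @param effects A `subject_effects`.
#' @param layout A `sensor_layout`.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param subject_id,task_id,sex Metadata carried into the recording.
#' @return A `pressure_recording` with attribute `ground_truth` (list with
#'   `warp`, `amplitude_factor`, `region_weights`, `active_sensels`,
#'   `n_clipped`).
#' @export
generate_subject_recording <- function(template, effects, layout, seed,
                                       subject_id = "s1", task_id = 1L,
                                       sex = NA) {
  stopifnot(inherits(template, "task_template"),
            inherits(effects, "subject_effects"),
            inherits(layout, "sensor_layout"))
  rng <- local_rng(seed)
  fs <- 50
  t_n <- max(3L, as.integer(round(effects$duration_s * fs)) + 1L)
  tau <- (seq_len(t_n) - 1) / (t_n - 1)
  w <- effects$warp
  gf <- effects$amplitude_factor *
    template$gf_profile(warp_map(w, tau))

  active <- lapply(layout$sensel_ids, function(ids) {
    k <- max(1L, ceiling(template$active_fraction * length(ids)))
    sort(rng$sample(ids, k))
  })
  n_per_kpa <- 1000 * layout$sensel_area_mm2 * 1e-6
  pressures <- matrix(0, t_n, layout$n_sensels)
  for (r in 1:18) {
    wgt <- template$region_weights[r]
    if (wgt == 0) next
    sensel_force <- wgt * gf / length(active[[r]])
    pressures[, active[[r]]] <- sensel_force / n_per_kpa
  }
  if (effects$noise_sd_kpa > 0)
    pressures <- pressures +
      matrix(rng$rnorm(length(pressures), sd = effects$noise_sd_kpa),
             nrow = t_n)
  if (effects$spike_rate > 0) {
    # interior frames only: a width-1 spike between two clean neighbors is
    # exactly removable by the width-3 median filter
    p_spike <- effects$spike_rate / fs
    n_cells <- (t_n - 2L) * layout$n_sensels
    n_spikes <- rng$rbinom(1, n_cells, p_spike)
    if (n_spikes > 0) {
      cell <- rng$sample(n_cells, n_spikes)
      row <- 2L + (cell - 1L) %% (t_n - 2L)
      col <- 1L + (cell - 1L) %/% (t_n - 2L)
      pressures[cbind(row, col)] <- pressures[cbind(row, col)] +
        rng$runif(n_spikes, 150, 480)
    }
  }
  pressures[pressures < 0] <- 0
  n_clipped <- 0L
  if (effects$saturate) {
    over <- pressures > layout$pressure_max_kpa
    n_clipped <- sum(over)
    pressures[over] <- layout$pressure_max_kpa
  }
  rec <- pressure_recording(pressures, subject_id = subject_id,
                            task_id = task_id, sample_rate_hz = fs, sex = sex)
  attr(rec, "ground_truth") <- list(
    warp = w, amplitude_factor = effects$amplitude_factor,
    region_weights = template$region_weights, active_sensels = active,
    duration_s = effects$duration_s, n_clipped = n_clipped)
  rec
}

# Seed-scoped RNG: draws come from a private stream so callers' RNG state is
# untouched and fixed seeds reproduce bit-for-bit.
local_rng <- function(seed) {
  env <- new.env()
  run <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    if (is.null(env$state)) set.seed(seed) else
      assign(".Random.seed", env$state, globalenv())
    out <- f(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    out
  }
  list(rnorm = run(stats::rnorm), runif = run(stats::runif),
       rbinom = run(stats::rbinom), sample = run(sample),
       rlnorm = run(stats::rlnorm))
}

#' Study-level synthetic configuration
#'
#' Defaults state the study's shape: 22 subjects x 21 tasks, ~14 s mean
#' execution (lognormal), lognormal amplitude spread, uniform in-bounds pace
#' warps, mild sensor noise and sparse single-frame spikes.
#'
#' @param n_subjects,n_tasks Cohort dimensions.
#' @param templates Optional list of `task_template`s (length `n_tasks`);
#'   defaults to [default_templates()].
#' @param amplitude_sdlog SD of log amplitude factor, default 0.2.
#' @param duration_mean_s Mean task duration, default 14.
#' @param duration_sdlog SD of log duration, default 0.25.
#' @param noise_sd_kpa Sensor noise SD in kPa: a scalar, a length-`n_tasks`
#'   vector, or the string `"2pct"` to use 2 percent of each task's peak
#'   active-sensel pressure. Default 0.5.
#' @param spike_rate Spikes per sensel-second, default 0.02.
#' @param saturate Clip at full scale, default TRUE.
#' @param seed Base RNG seed (all randomness derives from it).
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 22, n_tasks = 21, templates = NULL,
                             amplitude_sdlog = 0.2, duration_mean_s = 14,
                             duration_sdlog = 0.25, noise_sd_kpa = 0.5,
                             spike_rate = 0.02, saturate = TRUE, seed = 1L) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  if (n_tasks < 1) stop("need at least 1 task")
  if (is.null(templates)) templates <- default_templates(n_tasks, seed = seed)
  if (length(templates) != n_tasks)
    stop("templates must have length n_tasks")
  if (identical(noise_sd_kpa, "2pct"))
    noise_sd_kpa <- 0.02 * vapply(templates, peak_sensel_pressure,
                                  numeric(1))
  if (!length(noise_sd_kpa) %in% c(1L, n_tasks))
    stop("noise_sd_kpa must be scalar or one value per task")
  noise_sd_kpa <- rep_len(noise_sd_kpa, n_tasks)
  structure(list(n_subjects = n_subjects, n_tasks = n_tasks,
                 templates = templates, amplitude_sdlog = amplitude_sdlog,
                 duration_mean_s = duration_mean_s,
                 duration_sdlog = duration_sdlog,
                 noise_sd_kpa = noise_sd_kpa, spike_rate = spike_rate,
                 saturate = saturate, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Peak pressure (kPa) an active sensel sees under a template at unit
# amplitude, used to express noise relative to signal strength.
peak_sensel_pressure <- function(template, layout = default_layout()) {
  n_active <- vapply(layout$sensel_ids, function(ids)
    max(1, ceiling(template$active_fraction * length(ids))), numeric(1))
  n_per_kpa <- 1000 * layout$sensel_area_mm2 * 1e-6
  max(template$region_weights * template$peak_n / n_active / n_per_kpa)
}

#' Default task templates
#'
#' Builds `n_tasks` templates whose peak GF spans 5-100 N (the range observed
#' across activities of daily living, from key-pressing to door opening and
#' briefcase lifting) with one to three bumps and seeded Dirichlet-like region
#' weight patterns concentrated on a few opposing regions.
#'
#' @param n_tasks Number of templates.
#' @param seed Seed for the weight patterns.
#' @return List of `task_template`s.
#' @export
default_templates <- function(n_tasks, seed = 1L) {
  rng <- local_rng(seed * 1000L + 17L)
  peaks <- seq(5, 100, length.out = max(n_tasks, 2))[seq_len(n_tasks)]
  lapply(seq_len(n_tasks), function(k) {
    n_bumps <- 1 + (k %% 3)
    centers <- seq(0.3, 0.7, length.out = n_bumps)
    widths <- rep(0.25 / n_bumps + 0.05, n_bumps)
    heights <- peaks[k] * seq(1, 0.6, length.out = n_bumps)
    g <- rng$runif(18)^2
    # emphasize a few dominant regions, always some thumb/palm opposition
    dom <- rng$sample(1:18, 3)
    g[dom] <- g[dom] + 1.5
    g[rng$sample(c(1, 2, 15:18), 1)] <- max(g) + 0.5
    task_template(centers, widths, heights, g / sum(g))
  })
}

#' Generate a full synthetic study
#'
#' @param config A `synthetic_config`.
#' @return List with `recordings` (list of `pressure_recording`, one per
#'   subject x task, named `"<subject>_t<task>"`) and `ground_truth`
#'   (per-recording warp, amplitude, duration plus per-task region weights).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  rng <- local_rng(config$seed)
  n_s <- config$n_subjects
  n_t <- config$n_tasks
  subject_ids <- sprintf("sub%02d", seq_len(n_s))
  sexes <- rep(c("F", "M"), length.out = n_s)
  b <- warp_bounds()
  meanlog <- log(config$duration_mean_s) - config$duration_sdlog^2 / 2

  recordings <- list()
  gt <- list()
  for (s in seq_len(n_s)) {
    for (k in seq_len(n_t)) {
      w <- warp_params(
        t1 = rng$runif(1, b$early[1], b$early[2]),
        t2 = rng$runif(1, b$late[1], b$late[2]),
        t1ref = rng$runif(1, b$early[1], b$early[2]),
        t2ref = rng$runif(1, b$late[1], b$late[2]))
      eff <- subject_effects(
        amplitude_factor = rng$rlnorm(1, 0, config$amplitude_sdlog),
        warp = w,
        duration_s = rng$rlnorm(1, meanlog, config$duration_sdlog),
        noise_sd_kpa = config$noise_sd_kpa[k],
        spike_rate = config$spike_rate,
        saturate = config$saturate)
      rec_seed <- (config$seed * 7919L + s * 211L + k) %% 2147483647L
      rec <- generate_subject_recording(
        config$templates[[k]], eff, default_layout(), seed = rec_seed,
        subject_id = subject_ids[s], task_id = k, sex = sexes[s])
      key <- sprintf("%s_t%02d", subject_ids[s], k)
      if (!is.null(recordings[[key]])) stop("duplicate subject/task id: ", key)
      recordings[[key]] <- rec
      gt[[key]] <- attr(rec, "ground_truth")
    }
  }
  list(recordings = recordings, ground_truth = gt,
       subject_ids = subject_ids, task_ids = seq_len(n_t),
       templates = config$templates)
}
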