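# Shared fixtures, all built in code.

test_layout <- function() default_layout()

# recording with a given T x 361 pressure matrix (kPa)
toy_recording <- function(pressures, subject = "s1", task = 1L, sex = NA) {
  pressure_recording(pressures, subject_id = subject, task_id = task,
                     sex = sex)
}

# recording where selected sensels carry a common time profile
profile_recording <- function(profile_kpa, sensels, n_sensels = 361, ...) {
  m <- matrix(0, length(profile_kpa), n_sensels)
  m[, sensels] <- profile_kpa
  toy_recording(m, ...)
}

# single-bump template with given region weights
bump_template <- function(weights, peak_n = 40, center = 0.5, width = 0.3,
                          active_fraction = 0.5) {
  task_template(center, width, peak_n, weights,
                active_fraction = active_fraction)
}

uniform_weights <- function() rep(1 / 18, 18)

# pure-R warp + derivative-cost oracle, independent of the compiled path
r_sync_cost <- function(subject_vals, ref_vals, t1, t2, t1ref, t2ref) {
  grid <- seq(0, 1, by = 0.01)
  x <- stats::approx(c(0, t1ref, t2ref, 1), c(0, t1, t2, 1),
                     xout = grid, rule = 2)$y
  warped <- stats::approx(grid, subject_vals, xout = x, rule = 2)$y
  d <- function(v) {
    n <- length(v)
    c((v[2] - v[1]) * 100,
      (v[3:n] - v[1:(n - 2)]) * 50,
      (v[n] - v[n - 1]) * 100)
  }
  sqrt(sum((d(warped) - d(ref_vals))^2))
}
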