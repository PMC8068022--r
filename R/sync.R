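#' Bounded three-segment time-warp parameters
#'
#' Subjects execute a task at their own pace, so each subject's normalized GF
#' curve is aligned to a reference subject by a continuous piecewise-linear
#' map of normalized time with knots `t1 -> t1ref` and `t2 -> t2ref`, fixing 0
#' and 1. The early knots are bounded to [0.15, 0.35] and the late knots to
#' [0.65, 0.85], which keeps the map strictly increasing and limits the
#' deformation (unlike unconstrained dynamic time warping).
#'
#' @param t1,t2 Subject breakpoints in normalized time.
#' @param t1ref,t2ref Reference breakpoints.
#' @return A `warp_params` object.
#' @export
warp_params <- function(t1, t2, t1ref, t2ref) {
  b <- warp_bounds()
  eps <- 1e-9  # absorb accumulated floating error from lattice construction
  if (t1 < b$early[1] - eps || t1 > b$early[2] + eps ||
      t1ref < b$early[1] - eps || t1ref > b$early[2] + eps)
    stop("t1 and t1ref must lie in [", b$early[1], ", ", b$early[2], "]")
  if (t2 < b$late[1] - eps || t2 > b$late[2] + eps ||
      t2ref < b$late[1] - eps || t2ref > b$late[2] + eps)
    stop("t2 and t2ref must lie in [", b$late[1], ", ", b$late[2], "]")
  structure(list(t1 = t1, t2 = t2, t1ref = t1ref, t2ref = t2ref),
            class = "warp_params")
}

#' @rdname warp_params
#' @export
warp_bounds <- function() list(early = c(0.15, 0.35), late = c(0.65, 0.85))

#' @rdname warp_params
#' @export
identity_warp <- function() warp_params(0.25, 0.75, 0.25, 0.75)

#' Evaluate the warp map phi (subject time -> reference time)
#'
#' @param params A `warp_params`.
#' @param tau Normalized times in [0, 1].
#' @return phi(tau), piecewise linear through (0,0), (t1,t1ref), (t2,t2ref),
#'   (1,1).
#' @export
warp_map <- function(params, tau) {
  stats::approx(c(0, params$t1, params$t2, 1),
                c(0, params$t1ref, params$t2ref, 1),
                xout = tau, rule = 2)$y
}

#' Apply a three-segment warp to a normalized curve
#'
#' The warped curve is `subject(phi^-1(tau))` resampled on the 101-point grid:
#' a feature at subject time `t1` appears at reference time `t1ref`. Endpoints
#' are preserved and instantaneous values are never rescaled (time warping
#' must not change forces).
#'
#' @param curve A `normalized_curve` (or length-101 vector).
#' @param params A `warp_params`.
#' @return A `normalized_curve`.
#' @export
apply_warp <- function(curve, params) {
  v <- if (inherits(curve, "normalized_curve")) curve$values else curve
  stopifnot(inherits(params, "warp_params"))
  normalized_curve(cpp_apply_warp(v, params$t1, params$t2,
                                  params$t1ref, params$t2ref))
}

#' Synchronization cost of a candidate warp
#'
#' Euclidean distance between the first derivatives (central differences on
#' the 101-point grid) of the warped subject curve and the reference curve.
#' Derivatives rather than raw values are compared so that peak/valley timing
#' dominates the alignment and constant offsets are ignored.
#'
#' @param subject_curve,ref_curve `normalized_curve`s (or length-101 vectors).
#' @param params A `warp_params`.
#' @return Non-negative scalar cost.
#' @export
sync_cost <- function(subject_curve, ref_curve, params) {
  s <- if (inherits(subject_curve, "normalized_curve")) subject_curve$values
       else subject_curve
  r <- if (inherits(ref_curve, "normalized_curve")) ref_curve$values
       else ref_curve
  cpp_sync_cost(s, curve_derivative(r), params$t1, params$t2,
                params$t1ref, params$t2ref)
}

#' Select the reference subject for a task
#'
#' The reference is the subject whose filtered normalized GF curve has the
#' smallest Euclidean distance to the pointwise mean curve over all subjects;
#' ties break to the lowest subject id.
#'
#' @param curves Named list of `normalized_curve`s (names are subject ids).
#' @return The selected subject id (character).
#' @export
select_reference <- function(curves) {
  if (length(curves) == 0) stop("no curves supplied")
  m <- vapply(curves, function(c)
    if (inherits(c, "normalized_curve")) c$values else c, numeric(101))
  avg <- rowMeans(m)
  d <- sqrt(colSums((m - avg)^2))
  ids <- names(curves)
  if (is.null(ids)) ids <- as.character(seq_along(curves))
  ord <- order(d, ids)
  ids[ord[1]]
}

#' Find the optimal warp of a subject curve onto a reference
#'
#' The default strategy is an exhaustive lattice search over all
#' bound-respecting `(t1, t2, t1ref, t2ref)` tuples at the given resolution
#' (21^4 = 194,481 cost evaluations at 0.01), returning the deterministic
#' global lattice minimizer with ties broken to the lexicographically smallest
#' tuple. The `stochastic` strategy runs a seeded differential-evolution
#' search over the continuous box (the population-based global optimizer the
#' original analysis used); on fixtures it must match the grid optimum within
#' 1e-6.
#'
#' @inheritParams sync_cost
#' @param resolution Lattice step, default 0.01.
#' @param strategy `"grid"` (default) or `"stochastic"`.
#' @param seed RNG seed for the stochastic strategy.
#' @return A `warp_params` with attribute `cost` (and `n_eval` for grid).
#' @export
optimize_warp <- function(subject_curve, ref_curve, resolution = 0.01,
                          strategy = c("grid", "stochastic"), seed = 42L) {
  strategy <- match.arg(strategy)
  if (resolution <= 0) stop("resolution must be positive")
  s <- if (inherits(subject_curve, "normalized_curve")) subject_curve$values
       else subject_curve
  r <- if (inherits(ref_curve, "normalized_curve")) ref_curve$values
       else ref_curve
  dref <- curve_derivative(r)
  b <- warp_bounds()
  if (strategy == "grid") {
    res <- cpp_grid_search(s, dref, b$early[1], b$early[2],
                           b$late[1], b$late[2], resolution)
    out <- warp_params(res$t1, res$t2, res$t1ref, res$t2ref)
    attr(out, "cost") <- res$cost
    attr(out, "n_eval") <- res$n_eval
    return(out)
  }
  de_optimize_warp(s, dref, seed)
}

# Seeded differential evolution (rand/1/bin) over the bounded parameter box.
de_optimize_warp <- function(s, dref, seed, np = 40L, generations = 120L,
                             f = 0.7, cr = 0.9) {
  b <- warp_bounds()
  lo <- c(b$early[1], b$late[1], b$early[1], b$late[1])
  hi <- c(b$early[2], b$late[2], b$early[2], b$late[2])
  cost_of <- function(p) cpp_sync_cost(s, dref, p[1], p[2], p[3], p[4])
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  pop <- matrix(stats::runif(np * 4, lo, hi), nrow = 4)
  costs <- apply(pop, 2, cost_of)
  for (g in seq_len(generations)) {
    for (i in seq_len(np)) {
      idx <- sample(setdiff(seq_len(np), i), 3)
      trial <- pop[, idx[1]] + f * (pop[, idx[2]] - pop[, idx[3]])
      trial <- pmin(pmax(trial, lo), hi)
      keep <- stats::runif(4) >= cr
      keep[sample(4, 1)] <- FALSE
      trial[keep] <- pop[keep, i]
      tc <- cost_of(trial)
      if (tc <= costs[i]) {
        pop[, i] <- trial
        costs[i] <- tc
      }
    }
  }
  i <- which.min(costs)
  out <- warp_params(pop[1, i], pop[2, i], pop[3, i], pop[4, i])
  attr(out, "cost") <- costs[i]
  out
}

#' Synchronize all subjects' recordings of one task
#'
#' Runs the three-step procedure: (1) normalize each subject's GF to the
#' 101-point relative-time grid after zero-phase low-pass filtering at the
#' native rate; (2) average the filtered curves and pick the reference subject
#' (closest to the mean); (3) optimize each subject's warp against the
#' reference on the filtered curves. The optimal warp is then applied to the
#' unfiltered GF and to every region force series (filtering only stabilizes
#' the derivative cost; the data themselves are not smoothed).
#'
#' @param force_series_list Named list of `force_series`, one per subject, all
#'   for the same task.
#' @param strategy,resolution,seed Passed to [optimize_warp()].
#' @param lowpass If `FALSE`, skip the Butterworth step (for short test
#'   fixtures).
#' @return A `sync_result`: list with `reference`, `subjects`, `params` (list
#'   of `warp_params`), `costs`, `gf` (subjects x 101 matrix of warped
#'   unfiltered GF), `region` (subjects x 101 x 18 array), `excluded`
#'   (zero-GF subjects), and `diagnostics` (pre/post Euclidean distance to the
#'   reference curve).
#' @export
synchronize_task <- function(force_series_list, strategy = "grid",
                             resolution = 0.01, seed = 42L, lowpass = TRUE) {
  if (length(force_series_list) < 2)
    stop("synchronization needs at least 2 subjects")
  ids <- names(force_series_list)
  if (is.null(ids))
    ids <- vapply(force_series_list, `[[`, character(1), "subject_id")
  names(force_series_list) <- ids

  zero_gf <- vapply(force_series_list, function(fs) all(fs$gf_n == 0),
                    logical(1))
  if (any(zero_gf)) {
    warning("excluding subject(s) with zero grip force: ",
            paste(ids[zero_gf], collapse = ", "))
    force_series_list <- force_series_list[!zero_gf]
    ids <- ids[!zero_gf]
    if (length(force_series_list) < 2)
      stop("fewer than 2 subjects with nonzero grip force")
  }

  raw_curves <- lapply(force_series_list, function(fs)
    normalize_time(fs$gf_n, fs$timestamps_s))
  filt_curves <- lapply(force_series_list, function(fs) {
    g <- if (lowpass) lowpass_gf(fs$gf_n, fs = fs$sample_rate_hz %||% 50)
         else fs$gf_n
    normalize_time(g, fs$timestamps_s)
  })

  reference <- select_reference(filt_curves)
  ref_filt <- filt_curves[[reference]]

  params <- vector("list", length(ids))
  names(params) <- ids
  costs <- numeric(length(ids))
  names(costs) <- ids
  gf <- matrix(NA_real_, length(ids), 101, dimnames = list(ids, NULL))
  region <- array(NA_real_, c(length(ids), 101, 18),
                  dimnames = list(ids, NULL, NULL))
  pre_d <- post_d <- numeric(length(ids))
  names(pre_d) <- names(post_d) <- ids

  for (id in ids) {
    if (id == reference) {
      p <- identity_warp()
      p$t1 <- p$t1ref; p$t2 <- p$t2ref
      attr(p, "cost") <- sync_cost(filt_curves[[id]], ref_filt, p)
    } else {
      p <- optimize_warp(filt_curves[[id]], ref_filt, resolution = resolution,
                         strategy = strategy, seed = seed)
    }
    params[[id]] <- p
    costs[id] <- attr(p, "cost")
    gf[id, ] <- apply_warp(raw_curves[[id]], p)$values
    fs <- force_series_list[[id]]
    for (r in 1:18) {
      rc <- normalize_time(fs$region_force_n[, r], fs$timestamps_s)
      region[id, , r] <- apply_warp(rc, p)$values
    }
    pre_d[id] <- sqrt(sum((filt_curves[[id]]$values - ref_filt$values)^2))
    post_d[id] <- sqrt(sum((apply_warp(filt_curves[[id]], p)$values -
                              ref_filt$values)^2))
  }

  structure(list(
    reference = reference, subjects = ids, params = params, costs = costs,
    gf = gf, region = region, excluded = names(zero_gf)[zero_gf],
    diagnostics = data.frame(subject = ids, pre_distance = pre_d,
                             post_distance = post_d, row.names = NULL)
  ), class = "sync_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
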