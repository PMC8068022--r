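grid01 <- seq(0, 1, by = 0.01)

test_that("warp parameters are validated against the bounds", {
  expect_s3_class(warp_params(0.15, 0.65, 0.35, 0.85), "warp_params")
  expect_error(warp_params(0.10, 0.75, 0.25, 0.75), "t1 and t1ref")
  expect_error(warp_params(0.25, 0.90, 0.25, 0.75), "t2 and t2ref")
})

test_that("the warp map is strictly increasing and fixes the endpoints", {
  set.seed(5)
  for (i in 1:25) {
    p <- warp_params(stats::runif(1, 0.15, 0.35), stats::runif(1, 0.65, 0.85),
                     stats::runif(1, 0.15, 0.35), stats::runif(1, 0.65, 0.85))
    phi <- warp_map(p, grid01)
    expect_equal(phi[c(1, 101)], c(0, 1))
    expect_true(all(diff(phi) > 0))
  }
})

test_that("apply_warp moves features as specified", {
  # identity map leaves the curve unchanged
  curve <- normalized_curve(sin(grid01 * 6))
  idp <- identity_warp()
  expect_equal(apply_warp(curve, idp)$values, curve$values, tolerance = 1e-12)

  # bump at t1 = 0.35 relocates to t1ref = 0.16 (other knots near identity)
  bump <- normalized_curve(exp(-((grid01 - 0.35) / 0.03)^2))
  moved <- apply_warp(bump, warp_params(0.35, 0.75, 0.16, 0.75))
  expect_equal(grid01[which.max(moved$values)], 0.16)
  expect_equal(moved$values[c(1, 101)], bump$values[c(1, 101)])

  # forward then inverse warp is the identity (exact for linear curves)
  lin <- normalized_curve(2 + 3 * grid01)
  p <- warp_params(0.20, 0.80, 0.30, 0.70)
  pinv <- warp_params(0.30, 0.70, 0.20, 0.80)
  back <- apply_warp(apply_warp(lin, p), pinv)
  expect_equal(back$values, lin$values, tolerance = 1e-6)
  # and within interpolation tolerance for smooth curves
  smooth <- normalized_curve(sin(2 * pi * grid01))
  back2 <- apply_warp(apply_warp(smooth, p), pinv)
  expect_lt(max(abs(back2$values - smooth$values)), 5e-3)
})

test_that("warping preserves the value range", {
  set.seed(11)
  v <- cumsum(stats::rnorm(101))
  p <- warp_params(0.33, 0.67, 0.17, 0.83)
  w <- apply_warp(normalized_curve(v), p)$values
  expect_gte(min(w), min(v) - 1e-12)
  expect_lte(max(w), max(v) + 1e-12)
})

test_that("sync cost matches an independent R evaluation", {
  expect_equal(sync_cost(normalized_curve(sin(grid01 * 3)),
                         normalized_curve(sin(grid01 * 3)),
                         identity_warp()), 0)
  # derivatives kill constant offsets
  expect_equal(sync_cost(normalized_curve(rep(2, 101)),
                         normalized_curve(rep(7, 101)),
                         warp_params(0.2, 0.7, 0.3, 0.8)), 0)
  set.seed(19)
  for (i in 1:10) {
    s <- cumsum(stats::rnorm(101))
    r <- cumsum(stats::rnorm(101))
    p <- warp_params(stats::runif(1, 0.15, 0.35), stats::runif(1, 0.65, 0.85),
                     stats::runif(1, 0.15, 0.35), stats::runif(1, 0.65, 0.85))
    got <- sync_cost(normalized_curve(s), normalized_curve(r), p)
    expect_gte(got, 0)
    expect_equal(got, r_sync_cost(s, r, p$t1, p$t2, p$t1ref, p$t2ref),
                 tolerance = 1e-9)
  }
})

test_that("the reference subject minimizes distance to the mean curve", {
  a <- normalized_curve(sin(grid01 * 2))
  b <- normalized_curve(sin(grid01 * 2) + 1)
  mid <- normalized_curve(sin(grid01 * 2) + 0.5)  # the mean of a and b
  expect_identical(select_reference(list(s1 = a, s2 = b, s3 = mid)), "s3")

  # all identical: tie resolves to lowest id
  expect_identical(select_reference(list(s2 = a, s1 = a, s3 = a)), "s1")

  # two subjects: both equidistant from the midpoint -> tie rule again
  expect_identical(select_reference(list(z = a, y = b)), "y")
  expect_error(select_reference(list()), "no curves")
})

test_that("grid search recovers a constructed warp", {
  tpl <- bump_template(uniform_weights(), peak_n = 50, center = 0.45,
                       width = 0.25)
  ref <- normalized_curve(tpl$gf_profile(grid01))
  gen <- warp_params(0.16, 0.75, 0.30, 0.80)  # subject = ref warped
  sub <- apply_warp(ref, gen)
  opt <- optimize_warp(sub, ref)
  id_cost <- sync_cost(sub, ref, identity_warp())
  expect_lt(attr(opt, "cost"), id_cost)
  expect_gte(1 - attr(opt, "cost") / id_cost, 0.80)
  # the recovered map must act like the inverse of the generating map:
  # features generated at gen$t1ref must return to gen$t1
  phi <- warp_map(opt, c(gen$t1ref, gen$t2ref))
  expect_lt(abs(phi[1] - gen$t1), 0.02)
  expect_lt(abs(phi[2] - gen$t2), 0.02)
})

test_that("optimizing a curve against itself is identity-equivalent", {
  v <- normalized_curve(exp(-((grid01 - 0.5) / 0.15)^2))
  opt <- optimize_warp(v, v)
  expect_lt(attr(opt, "cost"), 1e-9)
  phi <- warp_map(opt, grid01)
  expect_lt(max(abs(phi - grid01)), 1e-9)
})

test_that("two shifted bumps are realigned with >= 80% cost reduction", {
  two_bumps <- function(c1, c2)
    exp(-((grid01 - c1) / 0.05)^2) + 0.7 * exp(-((grid01 - c2) / 0.05)^2)
  ref <- normalized_curve(two_bumps(0.25, 0.70))
  sub <- normalized_curve(two_bumps(0.30, 0.75))
  opt <- optimize_warp(sub, ref)
  id_cost <- sync_cost(sub, ref, identity_warp())
  expect_gte(1 - attr(opt, "cost") / id_cost, 0.80)
})

test_that("grid search equals an exhaustive pure-R search on a coarse lattice", {
  tpl <- bump_template(uniform_weights(), peak_n = 30, center = 0.5,
                       width = 0.3)
  ref <- tpl$gf_profile(grid01)
  sub <- apply_warp(normalized_curve(ref), warp_params(0.2, 0.7, 0.3, 0.8))$values

  early <- seq(0.15, 0.35, by = 0.05)
  late <- seq(0.65, 0.85, by = 0.05)
  best <- Inf
  best_p <- NULL
  for (t1 in early) for (t2 in late) for (t1r in early) for (t2r in late) {
    cost <- r_sync_cost(sub, ref, t1, t2, t1r, t2r)
    if (cost < best) {
      best <- cost
      best_p <- c(t1, t2, t1r, t2r)
    }
  }
  opt <- optimize_warp(normalized_curve(sub), normalized_curve(ref),
                       resolution = 0.05)
  expect_equal(attr(opt, "cost"), best, tolerance = 1e-9)
  expect_equal(c(opt$t1, opt$t2, opt$t1ref, opt$t2ref), best_p,
               tolerance = 1e-9)
})

test_that("the stochastic strategy matches the grid optimum", {
  tpl <- bump_template(uniform_weights(), peak_n = 50, center = 0.45,
                       width = 0.25)
  ref <- normalized_curve(tpl$gf_profile(grid01))
  sub <- apply_warp(ref, warp_params(0.16, 0.75, 0.30, 0.80))
  g <- optimize_warp(sub, ref, strategy = "grid")
  s <- optimize_warp(sub, ref, strategy = "stochastic", seed = 7L)
  expect_lte(attr(s, "cost"), attr(g, "cost") + 1e-6)
  # and it is reproducible for a fixed seed
  s2 <- optimize_warp(sub, ref, strategy = "stochastic", seed = 7L)
  expect_identical(unclass(s)[], unclass(s2)[])
})

test_that("synchronization is idempotent", {
  tpl <- bump_template(uniform_weights(), peak_n = 40, center = 0.5,
                       width = 0.25)
  ref <- normalized_curve(tpl$gf_profile(grid01))
  sub <- apply_warp(ref, warp_params(0.18, 0.72, 0.32, 0.78))
  opt <- optimize_warp(sub, ref)
  synced <- apply_warp(sub, opt)
  opt2 <- optimize_warp(synced, ref)
  id2 <- sync_cost(synced, ref, identity_warp())
  expect_lt(id2 - attr(opt2, "cost"), 1e-6 + 0.05 * id2)
})

test_that("synchronize_task aligns a cohort of known warps", {
  lay <- test_layout()
  tpl <- bump_template(uniform_weights(), peak_n = 40)
  warps <- list(warp_params(0.25, 0.75, 0.25, 0.75),
                warp_params(0.18, 0.70, 0.28, 0.78),
                warp_params(0.32, 0.80, 0.22, 0.70),
                warp_params(0.20, 0.82, 0.30, 0.72))
  fs_list <- lapply(seq_along(warps), function(i) {
    eff <- subject_effects(warp = warps[[i]], duration_s = 4,
                           noise_sd_kpa = 0, spike_rate = 0)
    rec <- generate_subject_recording(tpl, eff, lay, seed = 100 + i,
                                      subject_id = paste0("s", i))
    compute_forces(rec, lay)
  })
  names(fs_list) <- paste0("s", 1:4)
  sy <- synchronize_task(fs_list)
  nonref <- sy$diagnostics$subject != sy$reference
  ratio <- mean(sy$diagnostics$post_distance[nonref] /
                  sy$diagnostics$pre_distance[nonref])
  expect_lt(ratio, 0.20)
  # reference subject is untouched
  expect_equal(sy$params[[sy$reference]]$t1, sy$params[[sy$reference]]$t1ref)
  expect_equal(sy$params[[sy$reference]]$t2, sy$params[[sy$reference]]$t2ref)
})

test_that("identity cohorts need no alignment", {
  lay <- test_layout()
  tpl <- bump_template(uniform_weights(), peak_n = 20)
  fs_list <- lapply(1:3, function(i) {
    eff <- subject_effects(duration_s = 4, noise_sd_kpa = 0, spike_rate = 0)
    compute_forces(generate_subject_recording(tpl, eff, lay, seed = 50,
                                              subject_id = paste0("s", i)),
                   lay)
  })
  names(fs_list) <- paste0("s", 1:3)
  sy <- synchronize_task(fs_list)
  expect_true(all(sy$costs < 1e-6))
  for (p in sy$params) {
    phi <- warp_map(p, grid01)
    expect_lt(max(abs(phi - grid01)), 1e-9)
  }
})

test_that("degenerate cohorts are rejected or pruned", {
  lay <- test_layout()
  tpl <- bump_template(uniform_weights(), peak_n = 20)
  eff <- subject_effects(duration_s = 4, noise_sd_kpa = 0, spike_rate = 0)
  one <- compute_forces(generate_subject_recording(tpl, eff, lay, seed = 1,
                                                   subject_id = "s1"), lay)
  expect_error(synchronize_task(list(s1 = one)), "at least 2")

  zero <- compute_forces(toy_recording(matrix(0, 201, 361), subject = "s0"),
                         lay)
  two <- compute_forces(generate_subject_recording(tpl, eff, lay, seed = 2,
                                                   subject_id = "s2"), lay)
  expect_warning(
    sy <- synchronize_task(list(s1 = one, s2 = two, s0 = zero)),
    "zero grip force")
  expect_identical(sort(sy$subjects), c("s1", "s2"))
})
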