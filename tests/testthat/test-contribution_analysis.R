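# small synchronized cohort built directly from curves
fake_sync <- function(gf, region, reference = rownames(gf)[1]) {
  dimnames(region) <- list(rownames(gf), NULL, NULL)
  structure(list(reference = reference, subjects = rownames(gf),
                 params = NULL, costs = NULL, gf = gf, region = region,
                 excluded = character(0), diagnostics = NULL),
            class = "sync_result")
}

test_that("scaling equalizes mean GF and cancels out of CGF", {
  gf <- rbind(ref = rep(40, 101), low = rep(20, 101))
  region <- array(0, c(2, 101, 18))
  region[, , 1] <- 0.25 * gf
  region[, , 18] <- 0.75 * gf
  sy <- scale_to_reference(fake_sync(gf, region))
  expect_equal(unname(sy$factors), c(1, 2))
  expect_equal(unname(rowMeans(sy$gf)), c(40, 40))
  # reference untouched
  expect_equal(sy$gf["ref", ], rep(40, 101))
  # CGF invariant under scaling
  expect_equal(mean_cgf(sy$gf["low", ], sy$region["low", , ])[c(1, 18)],
               c(0.25, 0.75), ignore_attr = TRUE)
})

test_that("zero-GF subjects are dropped from scaling with a warning", {
  gf <- rbind(a = rep(10, 101), b = rep(0, 101))
  region <- array(0, c(2, 101, 18))
  region[, , 1] <- gf
  expect_warning(sy <- scale_to_reference(fake_sync(gf, region,
                                                    reference = "a")),
                 "zero mean GF")
  expect_identical(sy$subjects, "a")
})

test_that("outlier discard removes exactly the constructed outliers", {
  set.seed(3)
  base <- sin(seq(0, pi, length.out = 101)) * 30
  gf <- matrix(rep(base, each = 22), 22, 101)
  rownames(gf) <- sprintf("sub%02d", 1:22)
  bad <- c(3, 8, 15, 21)
  for (i in seq_along(bad))
    gf[bad[i], ] <- gf[bad[i], ] + (5 + i) * sin(seq(0, 2 * pi,
                                                     length.out = 101))
  kept <- discard_outliers(gf, 4)
  expect_length(kept, 18)
  expect_identical(setdiff(rownames(gf), kept), sprintf("sub%02d", bad))

  expect_identical(discard_outliers(gf, 0), rownames(gf))
  expect_error(discard_outliers(gf, 22), "smaller than the cohort")
})

test_that("mean task curve gives pointwise mean and SD", {
  gf <- rbind(a = rep(10, 101), b = rep(20, 101))
  mc <- mean_task_curve(gf)
  expect_equal(mc$mean, rep(15, 101))
  expect_equal(mc$sd, rep(stats::sd(c(10, 20)), 101))
  expect_equal(mc$sd[1], 7.0710678, tolerance = 1e-6)

  same <- rbind(a = 1:101, b = 1:101)
  expect_true(all(mean_task_curve(same)$sd == 0))
  expect_error(mean_task_curve(gf[1, , drop = FALSE]), "at least 2")
})

test_that("mean CGF averages region shares over the high-GF window", {
  # constant shares: result equals the weights exactly
  gf <- sin(seq(0, pi, length.out = 101)) * 10
  w <- c(0.2, 0.3, rep(0, 15), 0.5)
  region <- outer(gf, w)
  expect_equal(unname(mean_cgf(gf, region)), w, ignore_attr = TRUE)
  expect_equal(sum(mean_cgf(gf, region)), 1, tolerance = 1e-9)

  # all force in region 18
  r18 <- outer(gf, c(rep(0, 17), 1))
  expect_equal(unname(mean_cgf(gf, r18)), c(rep(0, 17), 1), ignore_attr = TRUE)

  # two-phase series: only the in-window share counts.
  # GF = 2 for 50 frames then 6 for 51 -> mean 4.02, window = the 6 N phase
  gf2 <- c(rep(2, 50), rep(6, 51))
  shares_lo <- c(0.5, 0.5, rep(0, 16))
  shares_hi <- c(0.1, 0.9, rep(0, 16))
  region2 <- rbind(outer(rep(2, 50), shares_lo), outer(rep(6, 51), shares_hi))
  expect_equal(unname(mean_cgf(gf2, region2)), shares_hi, ignore_attr = TRUE)

  # constant GF: empty window falls back to GF > 0, flagged
  gf3 <- rep(5, 101)
  got <- mean_cgf(gf3, outer(gf3, w))
  expect_true(attr(got, "fallback"))
  expect_equal(unname(got), w, ignore_attr = TRUE)

  expect_error(mean_cgf(rep(0, 101), matrix(0, 101, 18)), "never exceeds")
})

test_that("task correlations follow the Pearson formula", {
  m <- rbind(t1 = c(1:17, 20) / sum(c(1:17, 20)),
             t2 = c(1:17, 20) / sum(c(1:17, 20)),
             t3 = rev(1:18) / sum(1:18))
  r <- task_correlations(m)
  expect_equal(dim(r), c(3, 3))
  expect_equal(diag(r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(r, t(r))
  expect_equal(r["t1", "t2"], 1)
  # affine invariance with positive slope
  m2 <- rbind(a = m[1, ], b = 0.01 + 0.8 * m[1, ], c = m[3, ])
  expect_equal(task_correlations(m2)["a", "b"], 1)
  # brute-force check
  brute <- sum(scale(m[1, ]) * scale(m[3, ])) / 17
  expect_equal(r["t1", "t3"], brute, tolerance = 1e-12)
})

test_that("region correlations detect complementary shares", {
  set.seed(8)
  x <- stats::runif(40, 0.2, 0.6)
  obs <- cbind(x, 0.8 - x, matrix(stats::runif(40 * 16) * 0.0125, 40))
  r <- region_correlations(obs)
  expect_equal(r[1, 2], -1)
  dup <- cbind(x, x, obs[, -(1:2)])
  expect_equal(region_correlations(dup)[1, 2], 1)
  expect_true(all(abs(r) <= 1 + 1e-12))
  # zero variance flagged as NA, not silently 0
  obs0 <- obs
  obs0[, 3] <- 0.5
  expect_warning(r0 <- region_correlations(obs0), "zero-variance")
  expect_true(is.na(r0[1, 3]))
})

test_that("peak table reports per-region maxima and their tasks", {
  lay <- test_layout()
  mk <- function(scale, subject, task) {
    m <- matrix(0, 5, 361)
    m[, lay$sensel_ids[[1]][1]] <- scale * c(1, 3, 2, 1, 0)   # region 1
    m[, lay$sensel_ids[[16]][1:2]] <- scale * 2               # region 16
    toy_recording(m, subject = subject, task = task)
  }
  # single subject, single task: table equals that recording's maxima
  pt1 <- peak_table(list(a = mk(10, "s1", 1)), lay)
  expect_equal(pt1$peak_force_n[1], 30 * 0.016)       # 30 kPa * 16 mm^2
  expect_equal(pt1$peak_pressure_kpa[1], 30)
  expect_equal(pt1$peak_force_n[16], 2 * 20 * 0.016)  # two sensels at 20 kPa
  expect_equal(pt1$peak_pressure_kpa[16], 20)

  # task 2 doubles task 1 everywhere -> argmax task is 2 for every region
  recs <- list(a = mk(10, "s1", 1), b = mk(20, "s1", 2))
  pt2 <- peak_table(recs, lay)
  loaded <- c(1, 16)
  expect_true(all(pt2$peak_force_task[loaded] == 2))
  expect_true(all(pt2$peak_pressure_task[loaded] == 2))

  # 2 subjects x 2 tasks: averages over subjects, then max over tasks
  recs4 <- list(peak_table_a = mk(10, "s1", 1), b = mk(30, "s2", 1),
                c = mk(15, "s1", 2), d = mk(17, "s2", 2))
  pt4 <- peak_table(recs4, lay)
  # task 1 mean peak pressure region 1: (30+90)/2 = 60; task 2: (45+51)/2 = 48
  expect_equal(pt4$peak_pressure_kpa[1], 60)
  expect_equal(pt4$peak_force_task[1], 1)
  expect_error(peak_table(list(), lay), "no recordings")
})

test_that("duration summaries follow the 1.5 IQR boxplot rule", {
  d <- task_duration_stats(c(10, 12, 14), c(1, 1, 1))
  expect_equal(d$median, 12)
  expect_equal(d$n_outliers, 0)

  same <- task_duration_stats(rep(9, 6), rep(2, 6))
  expect_equal(same$q3 - same$q1, 0)
  expect_equal(same$n_outliers, 0)

  out <- task_duration_stats(c(10, 11, 12, 13, 40), rep(3, 5))
  expect_equal(out$n_outliers, 1)
  expect_lt(out$upper_whisker, 40)
})

test_that("cgf_matrix rows sum to 1 and recover generating weights", {
  set.seed(21)
  w1 <- c(0.3, rep(0.02, 16), 0.38)
  w2 <- c(rep(0.05, 10), rep(0.1, 5), rep(0, 3))
  gf <- matrix(rep(sin(seq(0, pi, length.out = 101)) * 25, each = 3), 3, 101)
  rownames(gf) <- paste0("s", 1:3)
  mkreg <- function(w) {
    a <- array(0, c(3, 101, 18))
    for (s in 1:3) a[s, , ] <- outer(gf[s, ], w)
    a
  }
  cg <- cgf_matrix(list(t1 = fake_sync(gf, mkreg(w1)),
                        t2 = fake_sync(gf, mkreg(w2))))
  sums <- apply(cg$mean_cgf, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_equal(unname(cg$task_region_mean["t1", ]), w1)
  expect_equal(unname(cg$task_region_mean["t2", ]), w2)
})
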