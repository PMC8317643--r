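clean_recording <- function(n_electrodes = 2, seed = 7, cohort = "SNLV") {
  spec <- cohort_spec(cohort, slope_sd_between = 0, slope_sd_within = 0,
                      intercept_sd = 0, ari_noise_sd = 0)
  tt <- synth_truth(spec, 1, n_electrodes, seed = seed)
  list(rec = synth_unieg(tt, noise = noise_none(), seed = seed + 1),
       truth = tt)
}

test_that("Wyatt extraction recovers every clean beat within one sample", {
  cr <- clean_recording()
  fs_err <- 1000 / cr$rec$fs  # one sample
  for (ch in 1:2) {
    m <- wyatt_ari(cr$rec, ch)
    tt <- cr$truth[cr$truth$electrode == ch, ]
    expect_equal(nrow(m), nrow(tt))
    expect_true(all(m$detected))
    i <- match(round(m$t_stim), round(tt$t_stim))
    expect_true(all(abs(m$ari - tt$ari[i]) <= fs_err + 1e-9))
  }
})

test_that("a constant offset leaves activation/repolarization times unchanged", {
  cr <- clean_recording(1)
  m1 <- wyatt_ari(cr$rec, 1)
  rec2 <- cr$rec
  rec2$channels[, 1] <- rec2$channels[, 1] + 3.7
  m2 <- wyatt_ari(rec2, 1)
  expect_identical(m1$at, m2$at)
  expect_identical(m1$rt, m2$rt)
})

test_that("beat exclusion arithmetic is exact for any burst length", {
  mk <- function(n) data.frame(
    burst = 1, cl = 500, beat = seq_len(n), t_stim = (seq_len(n) - 1) * 500,
    at = (seq_len(n) - 1) * 500 + 50, rt = (seq_len(n) - 1) * 500 + 300,
    ari = 250, di = c(NA, rep(250, n - 1)), detected = TRUE,
    exclusion = NA_character_)
  expect_equal(nrow(build_apdr(mk(20))), 16)
  expect_equal(nrow(build_apdr(mk(6))), 2)
  # 5-beat burst keeps one point, but its DI must exist; beat 4 has one
  m5 <- mk(5)
  expect_equal(nrow(build_apdr(m5)), 1)
  expect_error(build_apdr(mk(4)), "fewer than 5")
})

test_that("robust log fit: exact recovery, OLS limit, outlier resistance, R2 filter", {
  # noiseless points are recovered essentially to machine precision
  di <- seq(80, 340, by = 20)
  ari <- 100 + 50 * log(di)
  f <- fit_log_robust(di, ari)
  expect_equal(f$alpha, 100, tolerance = 1e-8)
  expect_equal(f$beta, 50, tolerance = 1e-9)
  expect_equal(f$r2, 100, tolerance = 1e-8)
  expect_true(f$accepted)

  # with well-behaved residuals the bisquare fit sits at the OLS solution
  t2 <- table2_reference()
  s <- t2[t2$cohort == "SNLV", ]
  fr <- fit_log_robust(s$di_mean, s$ari_mean)
  ols <- coef(lm(ari_mean ~ log(di_mean), data = s))
  expect_equal(fr$alpha, unname(ols[1]), tolerance = 0.05)
  expect_equal(fr$beta, unname(ols[2]), tolerance = 0.02)

  # 20% gross outliers: robust slope stays within 5%, OLS drifts further
  withr::with_seed(99, {
    di <- runif(50, 80, 340)
    ari <- 100 + 50 * log(di) + rnorm(50, 0, 1)
    out <- sample(50, 10)
    ari[out] <- ari[out] + sample(c(-100, 100), 10, replace = TRUE)
  })
  fr <- fit_log_robust(di, ari)
  fo <- coef(lm(ari ~ log(di)))
  expect_lt(abs(fr$beta - 50) / 50, 0.05)
  expect_gt(abs(unname(fo[2]) - 50), abs(fr$beta - 50))

  # noise-dominated points are rejected by the R2 > 50% rule
  withr::with_seed(100, {
    din <- runif(60, 80, 340)
    arin <- 240 + rnorm(60, 0, 40)
  })
  fn <- fit_log_robust(din, arin)
  expect_false(fn$accepted)

  expect_error(fit_log_robust(c(100, 100, 100), c(1, 2, 3)), "distinct")
  expect_error(fit_log_robust(c(-1, 10, 20), c(1, 2, 3)), "positive")
})

test_that("clean end-to-end recovery of per-electrode coefficients", {
  # synth -> wyatt -> exclusion -> robust fit; slope within 2% for >= 95%
  # of electrodes
  spec <- cohort_spec("SNLV", ari_noise_sd = 0)
  tt <- synth_truth(spec, 4, 3, seed = 55)
  n_ok <- 0; n <- 0
  for (pt in 1:4) {
    rec <- synth_unieg(tt[tt$patient == pt, ], noise = noise_none(),
                       seed = 60 + pt)
    for (ch in seq_len(ncol(rec$channels))) {
      m <- wyatt_ari(rec, ch)
      pts <- build_apdr(m)
      f <- fit_log_robust(pts$di, pts$ari)
      truth <- tt[tt$patient == pt & tt$electrode == ch, ]
      n <- n + 1
      if (abs(f$beta - truth$beta_pe[1]) / abs(truth$beta_pe[1]) < 0.02)
        n_ok <- n_ok + 1
    }
  }
  expect_gte(n_ok / n, 0.95)
})

test_that("cluster-bootstrap cohort contrast behaves correctly", {
  mk_curves <- function(beta0, n_pat, cohort, seed) {
    withr::with_seed(seed, do.call(rbind, lapply(seq_len(n_pat), function(p) {
      b <- beta0 + rnorm(1, 0, 5)
      data.frame(patient = paste0(cohort, p), cohort = cohort,
                 beta = b + rnorm(3, 0, 2))
    })))
  }
  # identical cohorts: difference near 0 and CI covers 0
  cv <- rbind(mk_curves(50, 8, "A", 1), mk_curves(50, 8, "B", 2))
  r <- compare_cohorts(cv, reps = 500, seed = 3)
  expect_lt(abs(r$estimate), 6)
  expect_true(r$ci[1] <= 0 && r$ci[2] >= 0)

  # known slope offset of 30 is recovered
  cv2 <- rbind(mk_curves(50, 10, "A", 4), mk_curves(80, 10, "B", 5))
  r2 <- compare_cohorts(cv2, reps = 500, seed = 6)
  expect_lt(abs(r2$estimate - 30), 8)
  expect_true(r2$ci[1] <= 30 && r2$ci[2] >= 30)

  # permuting electrode rows within patients leaves the estimate unchanged
  cv3 <- cv2[sample(nrow(cv2)), ]
  r3 <- compare_cohorts(cv3, reps = 10, seed = 7)
  expect_equal(r3$estimate, r2$estimate)

  # single-patient cohort is an error
  cv4 <- rbind(mk_curves(50, 1, "A", 8), mk_curves(50, 5, "B", 9))
  expect_error(compare_cohorts(cv4, reps = 10, seed = 1), ">= 2 patients")
})
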