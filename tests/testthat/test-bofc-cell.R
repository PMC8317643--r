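test_that("parameter container validates, orders and round-trips", {
  p <- base_params()
  expect_s3_class(p, "bofc_params")
  expect_length(p, 28)
  expect_identical(names(p), param_names())
  expect_true(all(p[grepl("^tau_", names(p))] > 0))

  # reordering on construction is lossless
  shuffled <- unclass(p)[sample(28)]
  expect_equal(as.numeric(bofc_params(shuffled)), as.numeric(p))

  # JSON and CSV round trips
  fj <- tempfile(fileext = ".json"); fc <- tempfile(fileext = ".csv")
  write_params(p, fj); write_params(p, fc)
  expect_equal(as.numeric(read_params(fj)), as.numeric(p), tolerance = 1e-12)
  expect_equal(as.numeric(read_params(fc)), as.numeric(p), tolerance = 1e-12)

  # missing key is named
  x <- jsonlite::fromJSON(fj); x$tau_si <- NULL
  jsonlite::write_json(x, fj, auto_unbox = TRUE)
  expect_error(read_params(fj), "tau_si")

  bad <- unclass(p); bad["tau_fi"] <- -1
  expect_error(bofc_params(bad), "tau_fi")
})

test_that("fold change is elementwise and excludes the pinned u_o", {
  p <- base_params()
  expect_equal(unname(param_fold_change(p)), rep(1, 27))
  p2 <- unclass(p) * 2
  p2["u_o"] <- 0
  expect_equal(unname(param_fold_change(bofc_params(p2))), rep(2, 27),
               tolerance = 1e-12)
})

test_that("voltage rescaling is affine, invertible and maps rest to -84 mV", {
  expect_equal(rescale_voltage(0), -84)
  u <- seq(-0.2, 1.6, by = 0.1)
  expect_equal(unscale_voltage(rescale_voltage(u)), u, tolerance = 1e-12)
  # affine: differences proportional
  d1 <- rescale_voltage(0.7) - rescale_voltage(0.2)
  d2 <- rescale_voltage(1.2) - rescale_voltage(0.7)
  expect_equal(d1, d2)
})

test_that("the resting state is an exact fixed point and currents vanish", {
  st <- rest_state()
  d <- bofc_derivatives(st, base_params(), i_stim = 0)
  expect_identical(unname(d$rates), c(0, 0, 0, 0))
  expect_identical(c(d$J_fi, d$J_so, d$J_si), c(0, 0, 0))

  # at rest with stimulus, du/dt equals the stimulus exactly
  d2 <- bofc_derivatives(st, base_params(), i_stim = 0.4)
  expect_identical(d2$rates[["u"]], 0.4)

  expect_error(bofc_derivatives(c(NA, 1, 1, 0)), "finite")
})

test_that("current decomposition holds at arbitrary states (R vs compiled)", {
  set.seed(31)
  p <- base_params()
  for (i in 1:25) {
    st <- c(runif(1, -0.1, 1.6), runif(3))
    istim <- runif(1, 0, 0.5)
    d <- bofc_derivatives(st, p, istim)
    expect_equal(d$rates[["u"]], -(d$J_fi + d$J_so + d$J_si) + istim,
                 tolerance = 1e-12)
    # compiled kernel agrees with the R reference implementation
    dc <- restforge:::cpp_bofc_rates(as.numeric(p), st, istim)
    expect_equal(unname(dc$rates), unname(d$rates), tolerance = 1e-12)
    expect_equal(c(dc$J_fi, dc$J_so, dc$J_si), c(d$J_fi, d$J_so, d$J_si),
                 tolerance = 1e-12)
  }
})

test_that("simulate_train produces flat trace without stimulus and converges in dt", {
  tr0 <- simulate_train(base_params(), 400, 2, stim = list(amp = 0, dur = 1))
  expect_lt(diff(range(tr0$v)), 1e-6)

  tr1 <- simulate_train(base_params(), 500, 5, dt = 0.02)
  tr2 <- simulate_train(base_params(), 500, 5, dt = 0.01)
  a1 <- extract_biomarkers(tr1)$APD90
  a2 <- extract_biomarkers(tr2)$APD90
  expect_lt(abs(a1 - a2), 0.5)
})

test_that("biomarker triangulation identities hold exactly", {
  bm <- extract_biomarkers(simulate_train(base_params(), 500, 3))
  expect_identical(bm$Tri_90_30, bm$APD90 - bm$APD30)
  expect_identical(bm$Tri_30_90, bm$APD30 / bm$APD90)
  expect_identical(bm$Tri_90_50, bm$APD90 - bm$APD50)
  expect_identical(bm$Tri_50_90, bm$APD50 / bm$APD90)
  expect_true(bm$APD30 < bm$APD50 && bm$APD50 < bm$APD90)
})

test_that("reference biomarker protocol reproduces the baseline biomarker table", {
  bm <- table_biomarkers()
  expect_equal(bm$RMP, -84.0, tolerance = 0.005)
  expect_equal(bm$APD90, 276.3, tolerance = 0.02)
  expect_equal(bm$APD50, 226.5, tolerance = 0.02)
  expect_equal(bm$APD30, 123.7, tolerance = 0.02)
  expect_equal(bm$Vmax, 53.8, tolerance = 0.02)
  expect_equal(round(bm$Tri_30_90, 2), 0.45)
  expect_equal(round(bm$Tri_50_90, 2), 0.82)
})

test_that("dynamic restitution satisfies the pacing identity and consistency", {
  res <- dynamic_restitution(base_params(), cls = seq(600, 350, -50),
                             beats_per_cl = 8, dt = 0.05)
  d <- res[res$included & res$beat >= 5, ]
  # every steady beat: APD90 + following DI = CL (within a step or two of
  # interpolation error)
  nxt <- match(paste(d$cl, d$beat + 1), paste(res$cl, res$beat))
  ok <- !is.na(nxt)
  expect_true(all(abs(d$apd90[ok] + res$di[nxt[ok]] - d$cl[ok]) < 0.2))

  # mean APD90 is non-increasing as CL decreases
  m <- tapply(d$apd90, d$cl, mean)
  expect_true(all(diff(m[order(as.numeric(names(m)))]) >= -0.5))

  # single-CL protocol equals simulate_train + biomarker extraction
  res1 <- dynamic_restitution(base_params(), cls = 500, beats_per_cl = 6,
                              dt = 0.02)
  tr <- simulate_train(base_params(), 500, 6, dt = 0.02)
  bm <- extract_biomarkers(tr)
  expect_equal(res1$apd90[6], bm$APD90, tolerance = 0.01)
})

test_that("alternans onset rule and the 1-D map oracle agree", {
  # onset = longest CL with >= 2 ms at two consecutive grid points
  cl <- seq(400, 300, -5)
  delta <- rep(0, length(cl))
  delta[cl <= 350] <- 3
  expect_equal(detect_alternans_onset(cl, delta), 350)
  delta2 <- rep(0, length(cl)); delta2[cl == 350] <- 3  # isolated hit
  expect_true(is.na(detect_alternans_onset(cl, delta2)))

  # memoryless log-curve map: alternans appears near CL* = alpha +
  # beta (1 + log(beta)) where the map slope crosses 1. Long blocks (15
  # beats) let transients settle so the rule detects true alternation;
  # with only 10 beats the rule fires a little above the bifurcation on
  # residual settling drift.
  for (co in list(c(alpha = -20, beta = 60), c(alpha = -150, beta = 90))) {
    sc <- map_alternans_scan(co[["alpha"]], co[["beta"]],
                             cl_hi = 500, cl_lo = 150, step = 5, beats = 15)
    pred <- co[["alpha"]] + co[["beta"]] * (1 + log(co[["beta"]]))
    expect_lt(abs(sc$onset_cl - pred), 20)
  }
})

test_that("a constant-APD artificial cell never satisfies the alternans rule", {
  sc <- map_alternans_scan(alpha = 200, beta = 0, cl_hi = 500, cl_lo = 260)
  expect_true(is.na(sc$onset_cl))
})
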