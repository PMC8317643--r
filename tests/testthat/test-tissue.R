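test_that("the no-flux Laplacian matches an R reference and sums to zero", {
  withr::with_seed(12, {
    u <- matrix(rnorm(30 * 25), 30, 25)
  })
  dx <- 0.025
  lap <- monodomain_laplacian(u, dx)
  # R reference with mirrored (copied) boundary neighbors
  ref <- matrix(0, 30, 25)
  for (i in 1:30) for (j in 1:25) {
    s <- 0
    if (i > 1) s <- s + u[i - 1, j] - u[i, j]
    if (i < 30) s <- s + u[i + 1, j] - u[i, j]
    if (j > 1) s <- s + u[i, j - 1] - u[i, j]
    if (j < 25) s <- s + u[i, j + 1] - u[i, j]
    ref[i, j] <- s / dx^2
  }
  expect_equal(lap, ref, tolerance = 1e-12)
  expect_lt(abs(sum(lap)) / (sum(abs(lap)) + 1), 1e-10)
})

test_that("zero diffusivity reproduces the single-cell trajectory exactly", {
  p <- base_params()
  st <- rest_state(p)
  stim <- default_stim()
  dt <- 0.05
  # 3 x 3 sheet, D = 0, one full-field stimulus train at CL 300
  stims <- matrix(c(0, stim$dur, stim$amp, 0, 2, 0, 2,
                    300, stim$dur, stim$amp, 0, 2, 0, 2), nrow = 2,
                  byrow = TRUE)
  out <- restforge:::cpp_tissue_run(as.numeric(p), 3L, 3L, 0.025, dt, 0,
                                    st, stims, 600, 4L, 0.513, 5, 0, 0.05,
                                    Inf, Inf)
  cell <- restforge:::cpp_simulate(as.numeric(p), st, 300, 2L, dt,
                                   stim$amp, stim$dur)
  expect_identical(out$traces[, 1], cell$u)
  # every node identical (uniform dynamics stay uniform)
  expect_equal(var(out$state$u), 0)
})

test_that("pre-paced state is converged, cached, and uniform under diffusion", {
  p <- base_params()
  s100 <- prepace_state(p, beats = 100)
  s150 <- prepace_state(p, beats = 150)
  expect_lt(max(abs(s100 - s150)), 1e-3)
  expect_identical(prepace_state(p, beats = 100), s100)  # memoised

  cache <- tempfile("ppc_")
  s1 <- prepace_state(p, beats = 20, cache_dir = cache)
  expect_true(length(list.files(cache)) == 1)
  # disk-cache hit returns the identical state
  expect_identical(prepace_state(p, beats = 20, cache_dir = cache), s1)

  # broadcasting the state and stepping without stimulus keeps spatial
  # variance at zero
  cfg <- tissue_config(kappa = 0.1)
  out <- restforge:::cpp_tissue_run(as.numeric(p), cfg$n, cfg$n, cfg$dx,
                                    cfg$dt, 0.1 * 0.009, s100,
                                    matrix(numeric(0), 0, 7), 5,
                                    integer(0), 0.513, 5, 0, 0.05, Inf, Inf)
  expect_equal(var(out$state$u), 0)
})

test_that("conduction velocity calibrates to the clinical range and scales with conductivity", {
  kap <- fixture_kappa()
  expect_lt(abs(attr(kap, "cv_achieved") - 74), 0.5)
  cfg <- tissue_config(kappa = as.numeric(kap))
  cv9 <- measure_cv(base_params(), 0.009, cfg)
  cv6 <- measure_cv(base_params(), 0.006, cfg)
  cv12 <- attr(kap, "cv_achieved")
  # CV at 0.009 S/m in the reported 62-64 cm/s window (+/- 3)
  expect_gt(cv9, 59); expect_lt(cv9, 67)
  # monotone in conductivity
  expect_true(cv6 < cv9 && cv9 < cv12)
  # square-root diffusivity scaling (doubling sigma) within 15%
  expect_lt(abs(cv12 / cv6 - sqrt(2)) / sqrt(2), 0.15)
})

test_that("halving dx changes the measured CV by less than 5%", {
  # measured on a narrow transverse strip (the wave is planar) in the
  # upstroke-resolving regime dx <= 0.0125 cm
  kap <- as.numeric(fixture_kappa())
  cfg1 <- tissue_config(dx = 0.0125, dt = 0.02, kappa = kap)
  cfg2 <- tissue_config(dx = 0.00625, dt = 0.01, kappa = kap)
  cv1 <- measure_cv(base_params(), 0.009, cfg1, t_end = 60, width_cm = 0.25)
  cv2 <- measure_cv(base_params(), 0.009, cfg2, t_end = 60, width_cm = 0.25)
  expect_lt(abs(cv2 - cv1) / cv1, 0.05)
})

test_that("tissue-level restitution matches cell-level within 5%", {
  kap <- as.numeric(fixture_kappa())
  cfg <- tissue_config(kappa = kap)
  cls <- c(600, 450, 350)
  tis <- tissue_restitution(base_params(), 0.009, cls, beats = 5, cfg)
  cel <- dynamic_restitution(base_params(), cls = cls, beats_per_cl = 5,
                             dt = cfg$dt, drop_first = 3, drop_last = 1)
  for (cl in cls) {
    a_t <- tis$apd90[tis$cl == cl][5]
    a_c <- cel$apd90[cel$cl == cl & cel$beat == 5]
    expect_lt(abs(a_t - a_c) / a_c, 0.05)
  }
})

test_that("a fully recovered sheet gives a planar S2 wave and no re-entry", {
  kap <- as.numeric(fixture_kappa())
  cfg <- tissue_config(kappa = kap)
  out <- s1s2_crossfield(base_params(), 0.009, 500, cfg)
  expect_false(out$induced)
  expect_false(out$sustained)
  expect_lt(out$duration_ms, 500)
})

test_that("stability bound and grid limits are enforced", {
  expect_error(tissue_config(dx = 0.05), "dx")
  cfg <- tissue_config(dt = 0.5, kappa = 0.1)
  expect_error(measure_cv(base_params(), 0.012, cfg), "stability")
})
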