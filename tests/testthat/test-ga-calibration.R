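# small fitness protocol shared by the cheap GA tests
tiny_cfg <- function(seed = 1, ...) {
  ga_config_desk(seed = seed, pop_size = 12, max_gen = 4,
                 beats_per_cl = 6, cls = c(500, 400), dt = 0.1, ...)
}

self_points_target <- function(params, cfg, lambda = 0.1, offset = 0) {
  res <- dynamic_restitution(params, cls = cfg$cls,
                             beats_per_cl = cfg$beats_per_cl, dt = cfg$dt,
                             stim = cfg$stim, drop_first = cfg$drop_first,
                             drop_last = cfg$drop_last)
  pts <- apdr_points(res)
  ga_target(points = data.frame(di = pts$di, ari = pts$apd90 + offset),
            lambda = lambda, label = "self")
}

test_that("fitness vanishes on a self-target and tracks uniform offsets", {
  cfg <- ga_config_desk(seed = 1)
  tg <- self_points_target(base_params(), cfg)
  expect_equal(apdr_fitness(base_params(), tg, cfg), 0, tolerance = 1e-10)

  # target shifted up by 10 ms: restitution term is exactly 10
  tg10 <- self_points_target(base_params(), cfg, lambda = 0, offset = 10)
  tg0 <- self_points_target(base_params(), cfg, lambda = 0)
  expect_equal(apdr_fitness(base_params(), tg10, cfg) -
                 apdr_fitness(base_params(), tg0, cfg), 10,
               tolerance = 1e-10)
})

test_that("non-capturing parameter sets receive the finite penalty, not an error", {
  cfg <- tiny_cfg()
  dead <- unclass(base_params())
  dead["theta_v"] <- 1.59  # excitation threshold above any reachable voltage
  f <- apdr_fitness(bofc_params(dead), cohort_target("SNLV"), cfg)
  expect_identical(f, cfg$penalty)
  expect_true(is.finite(f))
})

test_that("the GA is reproducible, elitist and bound-respecting", {
  tg <- cohort_target("SNLV")
  r1 <- run_ga(tiny_cfg(seed = 7), tg)
  r2 <- run_ga(tiny_cfg(seed = 7), tg)
  expect_identical(r1$population, r2$population)
  expect_identical(r1$fitness, r2$fitness)
  expect_identical(r1$history, r2$history)
  r3 <- run_ga(tiny_cfg(seed = 8), tg)
  expect_false(identical(r1$population, r3$population))

  # elitism: best fitness never increases
  expect_true(all(diff(r1$history) <= 1e-12))
  expect_equal(min(r1$fitness), r1$best_fitness)

  # every individual within bounds
  b <- tiny_cfg(seed = 7)$bounds
  for (j in seq_len(28)) {
    expect_true(all(r1$population[, j] >= b$lower[j] - 1e-9))
    expect_true(all(r1$population[, j] <= b$upper[j] + 1e-9))
  }
  # the pinned parameter never moves
  expect_true(all(r1$population[, "u_o"] == 0))
})

test_that("a scaled GA recovers a known model's restitution", {
  # target built from a perturbed model's own simulated APDR; the search
  # must travel from the base neighborhood to match it
  truth <- unclass(base_params())
  truth["tau_si"] <- truth["tau_si"] * 1.5
  truth["tau_w1_minus"] <- truth["tau_w1_minus"] * 3
  truth <- bofc_params(truth)
  cfg <- ga_config_desk(seed = 42, max_gen = 50, stall_gens = 50,
                        cls = c(600, 500, 400), beats_per_cl = 8)
  # lambda = 0: this experiment checks restitution recovery alone (the
  # morphology term would penalize the truth model itself, whose AP shape
  # differs from the base template)
  tg <- self_points_target(truth, cfg, lambda = 0)
  res <- run_ga(cfg, tg)
  expect_lt(res$best_fitness, 1)
  a_fit <- extract_biomarkers(simulate_train(res$best_params, 500, 20))$APD90
  a_tru <- extract_biomarkers(simulate_train(truth, 500, 20))$APD90
  expect_lt(abs(a_fit - a_tru), 3)
})

test_that("cohort targets encode the clinical slope contrast", {
  ts <- cohort_target("SNLV")
  ti <- cohort_target("ICMP")
  # ICMP steeper by the published 30.8 ms and lower intercept by ~182 ms
  expect_equal(ti$beta - ts$beta, 30.8, tolerance = 1e-9)
  expect_equal(ti$alpha - ts$alpha, -182.3, tolerance = 4)
  # anchor-fit variant is shallower for both cohorts
  expect_lt(cohort_target("SNLV", method = "anchors")$beta, ts$beta)
  expect_lt(cohort_target("ICMP", method = "anchors")$beta, ti$beta)
  # both reconstructions agree with the clinical steady point at 500 ms
  # (ARI 253.0 / 243.8 at the mean DI 245.2 / 255.3)
  expect_lt(abs(ts$alpha + ts$beta * log(245.2) - 253.0), 6)
  expect_lt(abs(ti$alpha + ti$beta * log(255.3) - 243.8), 6)
})

test_that("all-penalized initial populations abort with a diagnostic", {
  cfg <- tiny_cfg(seed = 3)
  # an impossible target range: no simulated DI can fall inside it
  tg <- ga_target(alpha = 0, beta = 10, di_range = c(0.1, 0.2), lambda = 0)
  expect_error(run_ga(cfg, tg), "penalized")
})
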