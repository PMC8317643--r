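# Session-scoped fixtures. The GA calibrations are the expensive shared
# inputs for the alternans, clustering and acceptance tests; they are
# computed once per test run, on first use, under fixed seeds.
fixture_env <- new.env(parent = emptyenv())

fixture_ga <- function(cohort) {
  key <- paste0("ga_", cohort)
  if (is.null(fixture_env[[key]])) {
    seed <- if (cohort == "SNLV") 101L else 202L
    cfg <- ga_config_desk(seed = seed)
    fixture_env[[key]] <- run_ga(cfg, cohort_target(cohort))
  }
  fixture_env[[key]]
}

fixture_scan <- function(cohort) {
  key <- paste0("scan_", cohort)
  if (is.null(fixture_env[[key]])) {
    res <- fixture_ga(cohort)
    fixture_env[[key]] <- alternans_scan(res$best_params, dt = 0.02)
  }
  fixture_env[[key]]
}

fixture_kappa <- function() {
  if (is.null(fixture_env$kappa)) {
    fixture_env$kappa <- calibrate_kappa(config = tissue_config())
  }
  fixture_env$kappa
}

# two well-separated Gaussian blobs in normalized (log2) parameter space,
# returned as a raw population matrix plus ground-truth labels
blob_population <- function(n_per = 30, sep = 6, sd = 0.1, seed = 5) {
  base <- base_params()
  nm <- setdiff(param_names(), "u_o")
  withr::with_seed(seed, {
    z1 <- matrix(rnorm(n_per * length(nm), 0, sd), n_per)
    z2 <- matrix(rnorm(n_per * length(nm), 0, sd), n_per)
    z2[, 1] <- z2[, 1] + sep
    z <- rbind(z1, z2)
    colnames(z) <- nm
    raw <- matrix(rep(as.numeric(base), each = nrow(z)), nrow = nrow(z),
                  dimnames = list(NULL, param_names()))
    raw[, nm] <- sweep(2^z, 2, as.numeric(base[nm]), `*`)
    list(raw = raw, labels = rep(1:2, each = n_per), centers_z = c(0, sep))
  })
}
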