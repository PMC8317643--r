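#' Deterministic per-stage seed
#'
#' Derives a stage seed from the global seed and the stage name, so that
#' changing one stage's stochastic behavior cannot perturb another's.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Pipeline configuration
#'
#' Presets: `"desk"` runs the full workflow at scaled-but-faithful sizes
#' (GA population 100, three-conductivity tissue sweep); `"test"` shrinks
#' every stage to smoke-test size for rapid end-to-end checks.
#'
#' @param preset `"desk"` or `"test"`.
#' @param seed Global seed; every stage derives its own via [stage_seed()].
#' @param out_dir Output directory.
#' @param run_tissue Include the tissue inducibility stage.
#' @return A `pipeline_config` list of per-stage blocks.
#' @export
pipeline_config <- function(preset = c("desk", "test"), seed = 1,
                            out_dir = tempfile("restforge_run_"),
                            run_tissue = preset == "desk") {
  preset <- match.arg(preset)
  force(run_tissue)
  if (preset == "desk") {
    list(preset = preset, seed = seed, out_dir = out_dir,
         synth = list(patients = 6, electrodes = 4, noise = noise_spec()),
         ga = list(pop_size = 100, max_gen = 60, beats_per_cl = 10),
         scan = list(cl_hi = 620, cl_lo = 260, step = 5, beats = 10),
         cluster = list(k = c(2, 4), percentiles = c(100, 99, 95)),
         tissue = if (run_tissue)
           list(sigmas = c(0.003, 0.006, 0.009),
                cis = seq(375, 180, by = -15)) else NULL)
  } else {
    list(preset = preset, seed = seed, out_dir = out_dir,
         synth = list(patients = 2, electrodes = 2, noise = noise_none()),
         ga = list(pop_size = 24, max_gen = 8, beats_per_cl = 6),
         scan = list(cl_hi = 500, cl_lo = 300, step = 20, beats = 6),
         cluster = list(k = c(2, 4), percentiles = c(100, 95)),
         tissue = if (run_tissue)
           list(sigmas = 0.006, cis = c(315, 300)) else NULL)
  }
}

.write_stage_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes synthesis -> ARI extraction -> APDR fitting -> GA calibration
#' (per cohort) -> clustering -> alternans scans (best fit + dominant
#' centroid) -> optional tissue inducibility sweep, writing CSV/JSON
#' artifacts and a manifest (inputs, stage seeds, checksums) to the output
#' directory. Fully deterministic under the configured seed.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  summarize <- list(preset = config$preset, seed = config$seed)

  # 1) synthetic cohorts + ARI extraction + per-electrode APDR fits
  curves <- list()
  for (cohort in c("SNLV", "ICMP")) {
    spec <- cohort_spec(cohort)
    sseed <- stage_seed(config$seed, paste0("synth_", cohort))
    truth <- synth_truth(spec, config$synth$patients,
                         config$synth$electrodes, seed = sseed)
    rows <- list()
    for (pt in unique(truth$patient)) {
      rec <- synth_unieg(truth[truth$patient == pt, ],
                         noise = config$synth$noise,
                         seed = stage_seed(sseed, paste0("egm", pt)))
      for (ch in seq_len(ncol(rec$channels))) {
        meas <- wyatt_ari(rec, ch)
        pts <- tryCatch(build_apdr(meas), error = function(e) NULL)
        if (is.null(pts) || length(unique(pts$di)) < 3) next
        fit <- fit_log_robust(pts$di, pts$ari)
        rows[[length(rows) + 1]] <- data.frame(
          cohort = cohort, patient = pt, electrode = ch,
          alpha = fit$alpha, beta = fit$beta, r2 = fit$r2,
          accepted = fit$accepted, n_points = fit$n_points)
      }
    }
    curves[[cohort]] <- do.call(rbind, rows)
  }
  curve_tab <- do.call(rbind, curves)
  artifacts <- c(artifacts,
                 .write_stage_csv(curve_tab, file.path(out, "apdr_curves.csv")))
  cmp <- compare_cohorts(curve_tab[curve_tab$accepted, ],
                         reps = if (config$preset == "desk") 2000 else 200,
                         seed = stage_seed(config$seed, "bootstrap"))
  summarize$slope_difference <- cmp$estimate
  summarize$slope_difference_ci <- cmp$ci

  # 2) GA calibration per cohort + clustering + alternans
  ga_out <- list()
  for (cohort in c("SNLV", "ICMP")) {
    target <- cohort_target(cohort)
    cfg <- ga_config_desk(seed = stage_seed(config$seed, paste0("ga_", cohort)),
                          pop_size = config$ga$pop_size,
                          max_gen = config$ga$max_gen,
                          beats_per_cl = config$ga$beats_per_cl)
    res <- run_ga(cfg, target)
    write_params(res$best_params,
                 file.path(out, sprintf("best_params_%s.json", cohort)))
    pop_df <- as.data.frame(cbind(res$population, fitness = res$fitness))
    artifacts <- c(artifacts, .write_stage_csv(
      pop_df, file.path(out, sprintf("population_%s.csv", cohort))),
      file.path(out, sprintf("best_params_%s.json", cohort)))

    nm <- normalize_population(res)
    tree <- ahc_linkage(nm)
    write_newick_tree(tree, file.path(out, sprintf("dendrogram_%s.nwk", cohort)))
    artifacts <- c(artifacts, file.path(out, sprintf("dendrogram_%s.nwk", cohort)))
    cuts <- lapply(config$cluster$k, function(k) cut_top(tree, nm, k))
    names(cuts) <- paste0("k", config$cluster$k)
    scan_best <- alternans_scan(res$best_params,
                                cl_hi = config$scan$cl_hi,
                                cl_lo = config$scan$cl_lo,
                                step = config$scan$step,
                                beats = config$scan$beats)
    dom_centroid <- bofc_params(cuts[[1]]$centroids[1, ])
    scan_dom <- alternans_scan(dom_centroid,
                               cl_hi = config$scan$cl_hi,
                               cl_lo = config$scan$cl_lo,
                               step = config$scan$step,
                               beats = config$scan$beats)
    ga_out[[cohort]] <- list(
      best_fitness = res$best_fitness, generations = res$generations,
      cophenetic = tree$cophenetic_cc,
      cluster_sizes = lapply(cuts, function(cu) cu$sizes),
      onset_best = scan_best$onset_cl, onset_centroid = scan_dom$onset_cl)
    artifacts <- c(artifacts, .write_stage_csv(
      scan_best$scan, file.path(out, sprintf("alternans_%s.csv", cohort))))
  }
  summarize$ga <- ga_out
  summarize$onset_ordering_icmp_gt_snlv <-
    isTRUE(ga_out$ICMP$onset_best > ga_out$SNLV$onset_best)

  # 3) tissue inducibility (optional)
  if (!is.null(config$tissue)) {
    cfg_t <- tissue_config()
    cfg_t$kappa <- as.numeric(calibrate_kappa(config = cfg_t))
    for (cohort in c("SNLV", "ICMP")) {
      best <- read_params(file.path(out, sprintf("best_params_%s.json", cohort)))
      map <- inducibility_sweep(best, config$tissue$sigmas,
                                config$tissue$cis, cfg_t)
      tab <- data.frame(
        sigma = rep(map$sigmas, times = length(map$cis)),
        ci = rep(map$cis, each = length(map$sigmas)),
        sustained = as.vector(map$sustained),
        duration_ms = as.vector(map$duration_ms))
      artifacts <- c(artifacts, .write_stage_csv(
        tab, file.path(out, sprintf("inducibility_%s.csv", cohort))))
      summarize[[paste0("reentry_windows_", cohort)]] <- map$windows
    }
  }

  manifest <- list(
    created = "run",  # no timestamps: manifests must be bit-reproducible
    preset = config$preset, seed = config$seed,
    stage_seeds = list(
      synth_SNLV = stage_seed(config$seed, "synth_SNLV"),
      synth_ICMP = stage_seed(config$seed, "synth_ICMP"),
      ga_SNLV = stage_seed(config$seed, "ga_SNLV"),
      ga_ICMP = stage_seed(config$seed, "ga_ICMP"),
      bootstrap = stage_seed(config$seed, "bootstrap")),
    summary = summarize,
    artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                       function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       pretty = TRUE)
  invisible(manifest)
}

#' Validate pipeline artifact files
#'
#' Checks every CSV (rectangular, non-empty, parseable), JSON (parseable;
#' parameter files must carry all 28 keys) and Newick file under a path,
#' with actionable per-file messages.
#'
#' @param path Directory (or single file).
#' @return Data frame report (`file`, `ok`, `message`); attribute `ok` is
#'   `TRUE` when every file passed.
#' @export
validate_files <- function(path) {
  stopifnot(file.exists(path))
  files <- if (dir.exists(path))
    list.files(path, recursive = TRUE, full.names = TRUE) else path
  rows <- lapply(files, function(f) {
    ext <- tolower(tools::file_ext(f))
    msg <- NA_character_; ok <- TRUE
    if (ext == "csv") {
      nf <- tryCatch(count.fields(f, sep = ",", quote = "\""),
                     error = function(e) conditionMessage(e))
      if (is.character(nf)) { ok <- FALSE; msg <- nf }
      else if (!length(nf)) { ok <- FALSE; msg <- "empty file" }
      else if (length(unique(nf)) != 1) {
        bad <- which(nf != nf[1])[1]
        ok <- FALSE
        msg <- sprintf("ragged CSV: line %d has %d fields, expected %d",
                       bad, nf[bad], nf[1])
      }
    } else if (ext == "json") {
      x <- tryCatch(jsonlite::fromJSON(f), error = function(e)
        structure(conditionMessage(e), class = "try-error"))
      if (inherits(x, "try-error")) { ok <- FALSE; msg <- unclass(x) }
      else if (grepl("params", basename(f))) {
        missing <- setdiff(param_names(), names(x))
        if (length(missing)) {
          ok <- FALSE
          msg <- paste("parameter JSON missing key(s):",
                       paste(missing, collapse = ", "))
        }
      }
    } else if (ext == "nwk") {
      x <- tryCatch(ape::read.tree(f), error = function(e) NULL)
      if (is.null(x)) { ok <- FALSE; msg <- "unparseable Newick tree" }
    }
    data.frame(file = f, ok = ok, message = msg)
  })
  rep <- do.call(rbind, rows)
  attr(rep, "ok") <- all(rep$ok)
  rep
}
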