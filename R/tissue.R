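#' Tissue simulation configuration
#'
#' A 2 cm x 2 cm isotropic sheet (the 0.25 mm physical thickness is
#' collapsed to a 2-D monolayer) discretized at `dx` with explicit time
#' stepping at `dt` and no-flux boundaries. Conductivity sigma (S/m) maps
#' to diffusivity via `D = kappa * sigma` (cm^2/ms); `kappa` is calibrated
#' once against the top of the clinically observed conduction-velocity
#' range (see [calibrate_kappa()]).
#'
#' @param L Side length (cm).
#' @param dx Node spacing (cm), at most 0.025.
#' @param dt Time step (ms).
#' @param kappa Conductivity-to-diffusivity constant (cm^2/ms per S/m).
#' @param stim Stimulus amplitude/duration (per-node, as in cell pacing).
#' @param act_thr_mv Activation-detection level (mV, upward crossing).
#' @param act_deadtime Per-node refractory deadtime for detection (ms).
#' @return A `tissue_config` list (includes derived grid size `n`).
#' @export
tissue_config <- function(L = 2, dx = 0.025, dt = 0.05, kappa = NULL,
                          stim = default_stim(), act_thr_mv = -40,
                          act_deadtime = 5) {
  if (dx > 0.025) stop("dx must be <= 0.025 cm")
  n <- round(L / dx)
  structure(list(L = L, dx = dx, dt = dt, n = n, kappa = kappa,
                 stim = stim, act_thr_mv = act_thr_mv,
                 act_deadtime = act_deadtime),
            class = "tissue_config")
}

.check_cfl <- function(config, D) {
  if (D > 0 && config$dt > config$dx^2 / (4 * D))
    stop(sprintf("stability bound violated: dt = %g > dx^2/(4D) = %g",
                 config$dt, config$dx^2 / (4 * D)))
}

#' No-flux five-point Laplacian
#'
#' Mirror boundaries: absent neighbors contribute nothing, so the operator
#' sums to zero over the sheet (discrete conservation).
#'
#' @param u Numeric matrix.
#' @param dx Node spacing (cm).
#' @return Matrix of the same shape (1/cm^2 units).
#' @export
monodomain_laplacian <- function(u, dx = 0.025) {
  cpp_laplacian(u, dx)
}

#' Steady pre-paced cell state
#'
#' Paces a single cell to its limit cycle (default 100 beats at 600 ms) and
#' returns the final state. Broadcasting this state uniformly over the
#' sheet is exactly equivalent to tissue-level pre-pacing, since diffusion
#' of a uniform state is zero, at a fraction of the cost. Results are
#' memoised (and optionally persisted) keyed by the parameter set and
#' protocol.
#'
#' @param params A `bofc_params`.
#' @param cl Pre-pacing cycle length (ms).
#' @param beats Number of pre-pacing beats.
#' @param dt Time step (ms).
#' @param stim Stimulus.
#' @param cache_dir Optional directory for a JSON state cache.
#' @return Named state vector `(u, v, w, s)`.
#' @export
prepace_state <- function(params, cl = 600, beats = 100, dt = 0.05,
                          stim = default_stim(), cache_dir = NULL) {
  p <- bofc_params(params)
  key <- paste(
    format(c(as.numeric(p), cl, beats, dt, stim$amp, stim$dur), digits = 17),
    collapse = "|")
  # cheap deterministic digest of the key for cache file names
  h <- sum(utf8ToInt(key) * (seq_len(nchar(key)) %% 97 + 1)) %% 1e9
  f <- if (!is.null(cache_dir))
    file.path(cache_dir, sprintf("prepace_%09.0f.json", h)) else NULL
  if (!is.null(.rf_cache[[key]])) return(.rf_cache[[key]])
  if (!is.null(f) && file.exists(f)) {
    st <- unlist(jsonlite::fromJSON(f))
    .rf_cache[[key]] <- st
    return(st)
  }
  df <- .run_protocol_df(p, cl, beats, dt, stim)
  if (attr(df, "blown")) stop("blow-up during pre-pacing")
  if (any(!df$captured)) stop("loss of capture during pre-pacing")
  st <- attr(df, "final_state")
  .rf_cache[[key]] <- st
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(as.list(st), f, auto_unbox = TRUE, digits = NA)
  }
  st
}

# Shared driver around the compiled monodomain kernel.
.tissue_run <- function(params, sigma, config, stims, t_end, state,
                        record_idx = integer(0), t_mark = 0,
                        quiet_after = Inf, sustain_t = Inf, ny = NULL) {
  p <- bofc_params(params)
  if (is.null(config$kappa)) stop("config$kappa is not set; calibrate first")
  if (is.null(ny)) ny <- config$n
  D <- config$kappa * sigma
  .check_cfl(config, D)
  act_u <- unscale_voltage(config$act_thr_mv)
  cpp_tissue_run(as.numeric(p), config$n, as.integer(ny), config$dx,
                 config$dt, D, state, stims, t_end, as.integer(record_idx),
                 act_u, config$act_deadtime, t_mark, 0.05, quiet_after,
                 sustain_t)
}

# Stimulus rows: t_on, dur, amp, x0, x1, y0, y1 (0-based inclusive).
.stim_row <- function(t_on, config, x0, x1, y0, y1, amp = NULL) {
  if (is.null(amp)) amp <- config$stim$amp
  c(t_on, config$stim$dur, amp, x0, x1, y0, y1)
}

#' Plane-wave conduction velocity
#'
#' Stimulates a two-node-wide strip on the left edge of a pre-paced sheet
#' and measures conduction velocity from the activation-time difference
#' between probes at 25% and 75% of the slab length on the propagation
#' axis.
#'
#' @param params A `bofc_params`.
#' @param sigma Conductivity (S/m).
#' @param config A [tissue_config()] with `kappa` set.
#' @param state Pre-paced cell state (computed if `NULL`).
#' @param t_end Simulation horizon (ms).
#' @param width_cm Optional transverse sheet width; the wave is planar, so
#'   a narrow strip gives the same velocity at a fraction of the cost
#'   (used by convergence checks at fine grids).
#' @return Conduction velocity (cm/s); `NA` with a warning if the far
#'   probe never activates (conduction block).
#' @export
measure_cv <- function(params, sigma, config, state = NULL, t_end = 250,
                       width_cm = NULL) {
  if (is.null(state)) state <- prepace_state(params, dt = config$dt,
                                             stim = config$stim)
  n <- config$n
  ny <- if (is.null(width_cm)) n else max(8, round(width_cm / config$dx))
  strip <- max(1, round(0.05 / config$dx)) - 1  # 0.5 mm physical width
  stims <- matrix(.stim_row(0, config, 0, strip, 0, ny - 1), nrow = 1)
  out <- .tissue_run(params, sigma, config, stims, t_end, state,
                     quiet_after = t_end + 1, ny = ny)
  fam <- out$first_activation_map
  x1 <- round(0.25 * n); x2 <- round(0.75 * n)
  ymid <- round(ny / 2)
  t1 <- fam[x1 + 1, ymid + 1]; t2 <- fam[x2 + 1, ymid + 1]
  if (!is.finite(t1) || !is.finite(t2)) {
    warning("conduction block: far probe never activated")
    return(NA_real_)
  }
  dist_cm <- (x2 - x1) * config$dx
  1000 * dist_cm / (t2 - t1)
}

#' One-time conductivity-to-diffusivity calibration
#'
#' Finds `kappa` such that the plane-wave conduction velocity at the
#' reference conductivity equals the top of the clinically observed range
#' (74 cm/s at 0.012 S/m by default), using the square-root CV-diffusivity
#' scaling of cable theory as the update rule.
#'
#' @param params A `bofc_params` (the baseline model by default).
#' @param config A [tissue_config()]; its `kappa` (if any) is ignored.
#' @param sigma_ref Reference conductivity (S/m).
#' @param cv_ref Target conduction velocity (cm/s).
#' @param kappa0 Starting guess (cm^2/ms per S/m).
#' @param tol Convergence tolerance on CV (cm/s).
#' @param max_iter Iteration cap.
#' @return Calibrated `kappa`, with attribute `cv_achieved`.
#' @export
calibrate_kappa <- function(params = base_params(), config = tissue_config(),
                            sigma_ref = 0.012, cv_ref = 74, kappa0 = 0.08,
                            tol = 0.5, max_iter = 6) {
  kappa <- kappa0
  cv <- NA_real_
  for (i in seq_len(max_iter)) {
    cfg <- config
    cfg$kappa <- kappa
    cv <- measure_cv(params, sigma_ref, cfg)
    if (!is.finite(cv)) stop("conduction block during kappa calibration")
    if (abs(cv - cv_ref) < tol) break
    kappa <- kappa * (cv_ref / cv)^2
  }
  structure(kappa, cv_achieved = cv)
}

#' S1S2 cross-field re-entry induction
#'
#' S1 (a planar stimulus on the bottom strip, 2 cm x 0.5 mm) at t = 0 on a
#' uniformly pre-paced sheet, S2 (the lower-left 1 cm x 1 cm square) at the
#' coupling interval `ci`; the simulation continues to `ci + 2500` ms.
#' Re-entry is "sustained" when activity persists beyond 2 s after S2
#' (last activation later than `ci + 2000` ms); "induced" means activity
#' outlasting a single planar response (> 500 ms after S2). The
#' first-activation map after S2 is recorded for isochrone plotting.
#'
#' @param params A `bofc_params`.
#' @param sigma Conductivity (S/m).
#' @param ci S1-S2 coupling interval (ms).
#' @param config A [tissue_config()] with `kappa` set.
#' @param state Pre-paced cell state (computed if `NULL`).
#' @return A `reentry_outcome`: list with `ci`, `induced`, `sustained`,
#'   `duration_ms`, `activation_map`, `stopped`.
#' @export
s1s2_crossfield <- function(params, sigma, ci, config, state = NULL) {
  if (is.null(state)) state <- prepace_state(params, dt = config$dt,
                                             stim = config$stim)
  n <- config$n
  s1_rows <- max(1, round(0.05 / config$dx)) - 1       # 0.5 mm strip
  s2_n <- max(1, round(1 / config$dx)) - 1             # 1 cm square
  stims <- rbind(.stim_row(0, config, 0, n - 1, 0, s1_rows),
                 .stim_row(ci, config, 0, s2_n, 0, s2_n))
  out <- .tissue_run(params, sigma, config, stims, ci + 2500, state,
                     t_mark = ci, quiet_after = ci + config$stim$dur + 1,
                     sustain_t = ci + 2000)
  last <- out$last_activation
  duration <- if (is.finite(last)) max(0, last - ci) else 0
  structure(list(ci = ci, sigma = sigma,
                 induced = out$n_activations_post > 1.3 * config$n^2,
                 sustained = is.finite(last) && last > ci + 2000,
                 duration_ms = duration,
                 n_activations_post = out$n_activations_post,
                 activation_map = out$first_activation_map,
                 stopped = out$stopped),
            class = "reentry_outcome")
}

#' @export
print.reentry_outcome <- function(x, ...) {
  cat(sprintf(
    "<reentry_outcome> sigma %g S/m, CI %g ms: %s (activity %0.0f ms after S2)\n",
    x$sigma, x$ci,
    if (x$sustained) "sustained re-entry"
    else if (x$induced) "non-sustained re-entry" else "no re-entry",
    x$duration_ms))
  invisible(x)
}

#' Conductivity x coupling-interval inducibility sweep
#'
#' Runs the S1S2 cross-field protocol over a conductivity grid and a
#' coupling-interval grid, recording sustained re-entry per cell and the
#' per-conductivity window (min, max CI) of sustained inducibility.
#' Individual simulation failures are recorded as `NA`, not fatal; a
#' partial map can be passed back in to resume.
#'
#' @param params A `bofc_params`.
#' @param sigmas Conductivity grid (S/m).
#' @param cis Coupling-interval grid (ms).
#' @param config A [tissue_config()] with `kappa` set.
#' @param resume Optional previous `inducibility_map` to fill in.
#' @param progress Print per-run progress.
#' @return An `inducibility_map`: list with `sigmas`, `cis`, `sustained`
#'   and `induced` (logical matrices sigma x ci), `duration_ms` (matrix),
#'   `windows` (data frame sigma, ci_min, ci_max, n_sustained).
#' @export
inducibility_sweep <- function(params, sigmas, cis, config, resume = NULL,
                               progress = FALSE) {
  sus <- matrix(NA, length(sigmas), length(cis),
                dimnames = list(sigmas, cis))
  dur <- sus
  ind <- sus
  if (!is.null(resume)) {
    sus[] <- resume$sustained
    dur[] <- resume$duration_ms
    ind[] <- resume$induced
  }
  state <- prepace_state(params, dt = config$dt, stim = config$stim)
  for (i in seq_along(sigmas)) {
    for (j in seq_along(cis)) {
      if (!is.na(sus[i, j])) next
      res <- tryCatch(
        s1s2_crossfield(params, sigmas[i], cis[j], config, state = state),
        error = function(e) NULL)
      if (!is.null(res)) {
        sus[i, j] <- res$sustained
        dur[i, j] <- res$duration_ms
        ind[i, j] <- res$induced
      }
      if (progress)
        message(sprintf("sigma %g, ci %g: %s", sigmas[i], cis[j],
                        if (is.na(sus[i, j])) "failed"
                        else if (sus[i, j]) "sustained" else "-"))
    }
  }
  windows <- do.call(rbind, lapply(seq_along(sigmas), function(i) {
    hit <- which(sus[i, ] %in% TRUE)
    data.frame(sigma = sigmas[i],
               ci_min = if (length(hit)) min(cis[hit]) else NA_real_,
               ci_max = if (length(hit)) max(cis[hit]) else NA_real_,
               n_sustained = length(hit))
  }))
  structure(list(sigmas = sigmas, cis = cis, sustained = sus,
                 induced = ind, duration_ms = dur, windows = windows),
            class = "inducibility_map")
}

#' @export
print.inducibility_map <- function(x, ...) {
  cat("<inducibility_map>\n")
  print(x$windows, row.names = FALSE)
  invisible(x)
}

#' Tissue-level restitution at a recording site
#'
#' Plane-wave pacing from the left edge through descending cycle-length
#' blocks; per-beat APD90 is measured on the mid-slab node's voltage trace
#' with the same activation/repolarization definitions as the cell-level
#' protocol, for direct comparison with [dynamic_restitution()].
#'
#' @param params A `bofc_params`.
#' @param sigma Conductivity (S/m).
#' @param cls Cycle lengths (ms), descending.
#' @param beats Beats per block.
#' @param config A [tissue_config()] with `kappa` set.
#' @param state Pre-paced cell state (computed if `NULL`).
#' @return Data frame with `cl`, `beat`, `apd90`.
#' @export
tissue_restitution <- function(params, sigma, cls, beats, config,
                               state = NULL) {
  if (is.null(state)) state <- prepace_state(params, dt = config$dt,
                                             stim = config$stim)
  n <- config$n
  onsets <- cumsum(c(0, rep(cls, each = beats)))
  onsets <- onsets[-length(onsets)]
  strip <- max(1, round(0.05 / config$dx)) - 1
  stims <- do.call(rbind, lapply(onsets, function(t0)
    .stim_row(t0, config, 0, strip, 0, n - 1)))
  t_end <- sum(cls * beats)
  mid <- (round(n / 2) - 1) + n * (round(n / 2) - 1)
  out <- .tissue_run(params, sigma, config, stims, t_end, state,
                     record_idx = mid, quiet_after = Inf)
  v <- rescale_voltage(out$traces[, 1])
  tgrid <- seq(0, by = config$dt, length.out = length(v))
  m <- .trace_beat_measures(tgrid, v, onsets, fractions = 0.9)
  cl_of <- rep(cls, each = beats)
  data.frame(cl = cl_of[m$beat], beat = m$beat, apd90 = m$apd90)
}
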