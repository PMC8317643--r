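# Smoothed derivative (mV/ms): Savitzky-Golay polynomial smoothing
# (cubic, 11-sample window) followed by a centred first difference.
.egm_derivative <- function(x, fs) {
  sm <- signal::sgolayfilt(x, p = 3, n = 11)
  d <- c(NA, (sm[-(1:2)] - sm[1:(length(sm) - 2)]) / 2, NA) * fs / 1000
  d
}

#' Wyatt-method activation-recovery intervals
#'
#' For every paced beat of one channel: activation time (AT) is the time of
#' the most negative smoothed derivative inside the activation window
#' `[stimulus + 2 ms, stimulus + 0.4 CL]`; repolarization time (RT) is the
#' time of the most positive derivative inside the repolarization window
#' `[AT + 0.25 CL, next stimulus - 5 ms]`; ARI = RT - AT. The preceding
#' diastolic interval is measured from the prior beat's RT to the current
#' AT. Beats whose windows contain no deflection above the channel noise
#' floor are marked `no-detection`.
#'
#' @param egm An `egm_recording`.
#' @param channel Channel index or name.
#' @param noise_mult No-detection criterion: the window's derivative
#'   extremum must exceed `noise_mult` times the channel-wide derivative MAD.
#' @return Data frame of beat measurements: `burst`, `cl`, `beat`,
#'   `t_stim`, `at`, `rt`, `ari`, `di`, `detected`, `exclusion`.
#' @export
wyatt_ari <- function(egm, channel = 1, noise_mult = 5) {
  stopifnot(inherits(egm, "egm_recording"))
  x <- egm$channels[, channel]
  fs <- egm$fs
  dt_ms <- 1000 / fs
  tgrid <- (seq_along(x) - 1) * dt_ms
  d <- .egm_derivative(x, fs)
  floor_d <- noise_mult * mad(d, na.rm = TRUE)

  stims <- sort(egm$stim_times)
  # group stimuli into bursts by inter-stimulus gaps (> 1.5x the longest CL)
  gaps <- diff(stims)
  burst_id <- cumsum(c(1, gaps > 1.5 * max(egm$bursts$cl)))
  rows <- vector("list", length(stims))
  rt_prev <- NA_real_
  for (k in seq_along(stims)) {
    ts <- stims[k]
    bid <- burst_id[k]
    cl <- egm$bursts$cl[min(bid, nrow(egm$bursts))]
    beat <- sum(burst_id[seq_len(k)] == bid)
    next_stim <- if (k < length(stims) && burst_id[k + 1] == bid)
      stims[k + 1] else ts + cl
    iw <- which(tgrid >= ts + 2 & tgrid <= ts + 0.4 * cl)
    at <- rt <- NA_real_
    detected <- FALSE
    if (length(iw)) {
      dmin <- d[iw]
      ia <- iw[which.min(dmin)]
      if (is.finite(d[ia]) && -d[ia] > floor_d) {
        at <- tgrid[ia]
        ir <- which(tgrid >= at + 0.25 * cl & tgrid <= next_stim - 5)
        if (length(ir)) {
          irt <- ir[which.max(d[ir])]
          if (is.finite(d[irt]) && d[irt] > 0.05 * floor_d) {
            rt <- tgrid[irt]
            detected <- TRUE
          }
        }
      }
    }
    rows[[k]] <- data.frame(
      burst = bid, cl = cl, beat = beat, t_stim = ts,
      at = at, rt = rt, ari = rt - at,
      di = if (detected && is.finite(rt_prev)) at - rt_prev else NA_real_,
      detected = detected,
      exclusion = if (detected) NA_character_ else "no-detection")
    if (detected) rt_prev <- rt else rt_prev <- NA_real_
  }
  do.call(rbind, rows)
}

#' Build an APDR point set with the clinical exclusion rule
#'
#' Removes the first `drop_first` and the last `drop_last` beats of each
#' pacing burst (non-steady-state waveforms) plus any undetected beats, and
#' pools the remaining (DI, ARI) points across bursts.
#'
#' @param meas Beat measurements from [wyatt_ari()].
#' @param drop_first,drop_last Exclusion counts per burst.
#' @return Data frame with `di`, `ari` (plus burst/beat bookkeeping);
#'   attribute `measurements` holds the annotated input. Errors if every
#'   beat is excluded.
#' @export
build_apdr <- function(meas, drop_first = 3, drop_last = 1) {
  stopifnot(is.data.frame(meas), nrow(meas) > 0)
  meas$n_in_burst <- ave(meas$beat, meas$burst, FUN = length)
  if (any(meas$n_in_burst < 5))
    stop("bursts with fewer than 5 beats cannot enter the APDR (rule ",
         "removes ", drop_first + drop_last, " beats per burst)")
  keep <- meas$beat > drop_first &
    meas$beat <= meas$n_in_burst - drop_last
  meas$exclusion[!keep & is.na(meas$exclusion)] <-
    ifelse(meas$beat[!keep & is.na(meas$exclusion)] <= drop_first,
           "first-three", "last")
  meas$included <- keep & meas$detected & is.finite(meas$di) &
    is.finite(meas$ari)
  pts <- meas[meas$included, c("burst", "cl", "beat", "di", "ari")]
  if (!nrow(pts)) stop("all beats excluded; no APDR points remain")
  attr(pts, "measurements") <- meas
  pts
}
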