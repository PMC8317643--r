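# Derivative-of-Gaussian wavelet: shape -(x/sigma) exp(-x^2 / (2 sigma^2)).
# Its time derivative has a single dominant extremum exactly at x = 0, which
# is what places the Wyatt fiducial points by construction.
.dog_wavelet <- function(t, center, sigma, amp) {
  x <- (t - center) / sigma
  -amp * x * exp(-x^2 / 2)
}

#' Render synthetic unipolar electrograms from a ground-truth table
#'
#' Each beat is the sum of a fast activation wavelet whose most negative
#' time-derivative falls at the true activation time and a slower
#' repolarization wave of opposite polarity whose most positive derivative
#' falls at the true repolarization time, sampled at 977 Hz, plus additive
#' noise. Ground truth is carried in the recording for validation.
#'
#' @param truth Ground-truth table from [synth_truth()] for one patient.
#' @param noise A [noise_spec()]; [noise_none()] gives a clean signal.
#' @param seed RNG seed.
#' @param fs Sampling frequency (Hz).
#' @param act_sigma,act_amp Activation wavelet scale (ms) and amplitude (mV).
#' @param rep_sigma,rep_amp Repolarization wavelet scale (ms), amplitude (mV).
#' @return An `egm_recording`: list with `fs`, `channels` (matrix, one
#'   column per electrode), `bursts`, `stim_times`, `truth`, `patient`.
#' @export
synth_unieg <- function(truth, noise = noise_spec(), seed, fs = 977,
                        act_sigma = 4, act_amp = 2,
                        rep_sigma = 20, rep_amp = 0.35) {
  if (!nrow(truth)) stop("truth table is empty")
  if (length(unique(truth$patient)) != 1)
    stop("synth_unieg renders one patient at a time")
  if (missing(seed)) stop("seed is required")
  bad <- by(truth, truth$electrode, function(d) {
    d <- d[order(d$at), ]
    any(d$rt[-nrow(d)] >= d$at[-1])
  })
  if (any(unlist(bad)))
    stop("overlapping beats: repolarization extends past the next activation")
  dt_ms <- 1000 / fs
  t_max <- max(truth$rt) + 500
  n <- ceiling(t_max / dt_ms) + 1
  tgrid <- (seq_len(n) - 1) * dt_ms
  electrodes <- sort(unique(truth$electrode))
  stim_times <- sort(unique(truth$t_stim))
  channels <- withr::with_seed(seed, {
    vapply(electrodes, function(el) {
      d <- truth[truth$electrode == el, ]
      sig <- numeric(n)
      for (i in seq_len(nrow(d))) {
        lo <- max(1, floor((d$at[i] - 6 * act_sigma) / dt_ms))
        hi <- min(n, ceiling((d$at[i] + 6 * act_sigma) / dt_ms))
        sig[lo:hi] <- sig[lo:hi] +
          .dog_wavelet(tgrid[lo:hi], d$at[i], act_sigma, act_amp)
        lo <- max(1, floor((d$rt[i] - 6 * rep_sigma) / dt_ms))
        hi <- min(n, ceiling((d$rt[i] + 6 * rep_sigma) / dt_ms))
        sig[lo:hi] <- sig[lo:hi] -
          .dog_wavelet(tgrid[lo:hi], d$rt[i], rep_sigma, rep_amp)
      }
      if (noise$artifact_amp > 0) {
        for (ts in stim_times) {
          i <- round(ts / dt_ms) + 1
          if (i >= 1 && i + 1 <= n)
            sig[i:(i + 1)] <- sig[i:(i + 1)] +
              noise$artifact_amp * c(1, -0.6)
        }
      }
      sig <- sig +
        noise$wander_amp * sin(2 * pi * noise$wander_freq * tgrid / 1000) +
        noise$line_amp * sin(2 * pi * 60 * tgrid / 1000)
      if (noise$white_sd > 0) sig <- sig + rnorm(n, 0, noise$white_sd)
      sig
    }, numeric(n))
  })
  colnames(channels) <- paste0("electrode_", electrodes)
  bursts <- unique(truth[, c("burst", "cl")])
  bursts <- bursts[order(bursts$burst), ]
  structure(list(fs = fs, channels = channels, bursts = bursts,
                 stim_times = stim_times, truth = truth,
                 patient = truth$patient[1]),
            class = "egm_recording")
}

#' @export
print.egm_recording <- function(x, ...) {
  cat(sprintf(
    "<egm_recording> patient %s: %d channel(s), %d samples at %g Hz, %d bursts\n",
    x$patient, ncol(x$channels), nrow(x$channels), x$fs, nrow(x$bursts)))
  invisible(x)
}

#' Write/read an electrogram recording (CSV channels + JSON sidecar)
#'
#' Layout: `dir/electrode_<k>.csv` (sample_index, mv), `dir/meta.json`
#' (fs, patient, bursts, stimulus times), `dir/truth.csv` when ground truth
#' is present.
#'
#' @param rec An `egm_recording`.
#' @param dir Directory (created if missing).
#' @return `read_egm()` returns an `egm_recording`; the writer returns
#'   `dir` invisibly.
#' @export
write_egm <- function(rec, dir) {
  stopifnot(inherits(rec, "egm_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in colnames(rec$channels)) {
    df <- data.frame(sample_index = seq_len(nrow(rec$channels)) - 1,
                     mv = rec$channels[, ch])
    write.csv(df, file.path(dir, paste0(ch, ".csv")), row.names = FALSE)
  }
  meta <- list(fs = rec$fs, patient = rec$patient,
               channels = colnames(rec$channels),
               bursts = rec$bursts, stim_times = rec$stim_times)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  if (!is.null(rec$truth))
    write.csv(rec$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_egm
#' @export
read_egm <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  channels <- vapply(meta$channels, function(ch)
    read.csv(file.path(dir, paste0(ch, ".csv")))$mv,
    numeric(length(read.csv(file.path(
      dir, paste0(meta$channels[1], ".csv")))$mv)))
  colnames(channels) <- meta$channels
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) read.csv(truth_path) else NULL
  structure(list(fs = meta$fs, channels = channels,
                 bursts = as.data.frame(meta$bursts),
                 stim_times = meta$stim_times, truth = truth,
                 patient = meta$patient),
            class = "egm_recording")
}
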