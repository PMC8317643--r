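# Run the compiled per-beat protocol and return an annotated data frame.
.run_protocol_df <- function(params, cls, beats_per_cl, dt, stim,
                             init_state = NULL, morph_cl = -1) {
  p <- bofc_params(params)
  if (is.null(init_state)) init_state <- rest_state(p)
  out <- cpp_protocol(as.numeric(p), init_state, cls, as.integer(beats_per_cl),
                      dt, stim$amp, stim$dur, morph_cl)
  df <- as.data.frame(out$beats)
  df$captured <- df$captured == 1
  attr(df, "morph") <- out$morph
  attr(df, "final_state") <- out$state
  attr(df, "blown") <- out$blown
  df
}

#' Dynamic restitution protocol
#'
#' Paces a single cell through a descending sequence of cycle-length blocks
#' with the state carried across blocks (no reset), recording per beat the
#' activation time, APD90 and the preceding diastolic interval (measured
#' from the previous beat's 90%-repolarization time to the current
#' activation). A beat-exclusion mask mirroring the clinical rule (drop the
#' first three and the last beat of each block) marks which beats enter the
#' restitution point set; blocks containing beats with no action potential
#' (loss of 1:1 capture) are flagged, not dropped.
#'
#' @param params A `bofc_params` object.
#' @param cls Descending cycle lengths (ms).
#' @param beats_per_cl Beats per block.
#' @param dt Time step (ms).
#' @param stim Stimulus (see [default_stim()]).
#' @param init_state Starting state; defaults to rest.
#' @param drop_first,drop_last Exclusion rule per block.
#' @return A `restitution_result`: data frame with columns `cl`, `beat`,
#'   `t_stim`, `t_act`, `apd90`, `di`, `captured`, `included`.
#' @export
dynamic_restitution <- function(params, cls = seq(600, 350, by = -50),
                                beats_per_cl = 20, dt = 0.02,
                                stim = default_stim(), init_state = NULL,
                                drop_first = 3, drop_last = 1) {
  if (!length(cls)) stop("cls must be non-empty")
  if (is.unsorted(rev(cls), strictly = FALSE) && length(cls) > 1)
    stop("cls must be in descending order")
  df <- .run_protocol_df(params, cls, beats_per_cl, dt, stim, init_state)
  if (attr(df, "blown"))
    stop("numerical blow-up during the restitution protocol")
  df$included <- df$beat > drop_first & df$beat <= beats_per_cl - drop_last &
    df$captured & is.finite(df$apd90) & is.finite(df$di)
  flagged <- unique(df$cl[!df$captured])
  structure(df, class = c("restitution_result", "data.frame"),
            protocol = list(cls = cls, beats_per_cl = beats_per_cl, dt = dt,
                            drop_first = drop_first, drop_last = drop_last),
            flagged_cls = flagged)
}

#' Restitution point set of a protocol run
#'
#' @param res A `restitution_result`.
#' @return Data frame with `di` and `apd90` for included beats.
#' @export
apdr_points <- function(res) {
  stopifnot(inherits(res, "restitution_result"))
  data.frame(di = res$di[res$included], apd90 = res$apd90[res$included])
}

#' Detect the alternans onset cycle length
#'
#' Applies the two-consecutive-cycle-length rule to a descending grid: the
#' onset is the longest cycle length at which the absolute difference of the
#' last two beats' APDs is at least `threshold` both at that cycle length
#' and at the next (shorter) one.
#'
#' @param cl Descending cycle-length grid (ms).
#' @param delta Per-grid-point `|APD_last - APD_prev|` (ms).
#' @param threshold Alternans magnitude criterion (ms), default 2.
#' @return Onset cycle length (ms) or `NA` if the rule is never satisfied.
#' @export
detect_alternans_onset <- function(cl, delta, threshold = 2) {
  stopifnot(length(cl) == length(delta))
  if (length(cl) < 2) return(NA_real_)
  hit <- is.finite(delta) & delta >= threshold
  both <- hit[-length(hit)] & hit[-1]
  if (!any(both)) return(NA_real_)
  cl[which(both)[1]]
}

#' Single-cell decremental alternans scan
#'
#' Paces the cell for `beats` beats at each cycle length from `cl_hi` down
#' to `cl_lo`, takes the APD90 of the last two beats of each block, and
#' reports the alternans onset by the two-consecutive-cycle-length >= 2 ms
#' rule. In `"burst"` mode (default) each cycle-length block starts from
#' the same pre-paced steady state (100 beats at 600 ms), so blocks are
#' independent and can be computed in parallel, as on a cluster; in
#' `"continuous"` mode the state is carried across blocks. The two modes
#' coincide for quickly-settling models and differ for models with long
#' pacing memory, whose post-step adaptation is part of what the last-two-
#' beat criterion measures. The grid is truncated at the first block that
#' loses 1:1 capture, since alternation cannot be assessed beyond that
#' point.
#'
#' @param params A `bofc_params` object.
#' @param cl_hi,cl_lo,step Scan grid (ms), descending.
#' @param beats Beats per cycle length.
#' @param dt Time step (ms).
#' @param stim Stimulus.
#' @param threshold Alternans criterion (ms).
#' @param mode Block chaining, see above.
#' @param prepace_cl,prepace_beats Pre-pacing protocol for `"burst"` mode.
#' @return A `bifurcation_scan`: list with `scan` (data frame `cl`,
#'   `apd_prev`, `apd_last`, `delta`), `onset_cl` (ms or `NA`), and
#'   `truncated_at` (first non-capturing cycle length, or `NA`).
#' @export
alternans_scan <- function(params, cl_hi = 620, cl_lo = 260, step = 5,
                           beats = 10, dt = 0.02, stim = default_stim(),
                           threshold = 2, mode = c("burst", "continuous"),
                           prepace_cl = 600, prepace_beats = 100) {
  mode <- match.arg(mode)
  if (cl_hi < cl_lo || step <= 0) stop("invalid scan grid")
  cls <- seq(cl_hi, cl_lo, by = -step)
  if (mode == "continuous") {
    df <- .run_protocol_df(params, cls, beats, dt, stim)
    if (attr(df, "blown"))
      stop("numerical blow-up during the alternans scan near CL ",
           min(df$cl), " ms")
  } else {
    st <- prepace_state(params, cl = prepace_cl, beats = prepace_beats,
                        dt = dt, stim = stim)
    df <- do.call(rbind, lapply(cls, function(cl) {
      b <- .run_protocol_df(params, cl, beats, dt, stim, init_state = st)
      if (attr(b, "blown"))
        stop("numerical blow-up during the alternans scan at CL ", cl, " ms")
      b
    }))
  }
  per_cl <- lapply(cls, function(cl) {
    b <- df[df$cl == cl, ]
    ok <- all(b$captured) && all(is.finite(b$apd90))
    lastb <- b[b$beat %in% c(beats - 1, beats), ]
    data.frame(cl = cl,
               apd_prev = lastb$apd90[1], apd_last = lastb$apd90[2],
               delta = abs(lastb$apd90[2] - lastb$apd90[1]),
               capture = ok)
  })
  scan <- do.call(rbind, per_cl)
  truncated_at <- NA_real_
  if (any(!scan$capture)) {
    truncated_at <- scan$cl[which(!scan$capture)[1]]
    scan <- scan[scan$cl > truncated_at, , drop = FALSE]
  }
  onset <- detect_alternans_onset(scan$cl, scan$delta, threshold)
  structure(list(scan = scan, onset_cl = onset, truncated_at = truncated_at,
                 grid = cls, threshold = threshold, mode = mode),
            class = "bifurcation_scan")
}

#' @export
print.bifurcation_scan <- function(x, ...) {
  cat(sprintf("<bifurcation_scan> %d cycle lengths (%g -> %g ms)\n",
              nrow(x$scan), max(x$scan$cl), min(x$scan$cl)))
  cat("alternans onset:",
      if (is.na(x$onset_cl)) "none" else paste(x$onset_cl, "ms"), "\n")
  if (!is.na(x$truncated_at))
    cat("1:1 capture lost at CL", x$truncated_at, "ms\n")
  invisible(x)
}

#' Alternans scan of the one-dimensional restitution map
#'
#' Iterates the memoryless restitution map `APD_{n+1} = alpha + beta *
#' log(CL - APD_n)` through the same decremental protocol as
#' [alternans_scan()] (beats per block, last-two-beat rule), providing an
#' analytically tractable reference: the map alternates where its slope
#' `beta / DI` exceeds 1, i.e. for DI below `beta`.
#'
#' @param alpha,beta Logarithmic restitution coefficients (ms).
#' @param cl_hi,cl_lo,step Scan grid (ms).
#' @param beats Beats per cycle length.
#' @param threshold Alternans criterion (ms).
#' @return A `bifurcation_scan` (no voltage; map iterates only).
#' @export
map_alternans_scan <- function(alpha, beta, cl_hi = 620, cl_lo = 260,
                               step = 5, beats = 10, threshold = 2) {
  cls <- seq(cl_hi, cl_lo, by = -step)
  apd <- alpha + beta * log(cls[1])  # long-CL quasi-steady start
  rows <- vector("list", length(cls))
  truncated_at <- NA_real_
  for (i in seq_along(cls)) {
    cl <- cls[i]
    apds <- numeric(beats)
    lost <- FALSE
    for (k in seq_len(beats)) {
      di <- cl - apd
      if (di <= 0) { lost <- TRUE; break }
      apd <- alpha + beta * log(di)
      apds[k] <- apd
    }
    if (lost) { truncated_at <- cl; break }
    rows[[i]] <- data.frame(cl = cl, apd_prev = apds[beats - 1],
                            apd_last = apds[beats],
                            delta = abs(apds[beats] - apds[beats - 1]),
                            capture = TRUE)
  }
  scan <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  onset <- detect_alternans_onset(scan$cl, scan$delta, threshold)
  structure(list(scan = scan, onset_cl = onset, truncated_at = truncated_at,
                 grid = cls, threshold = threshold),
            class = "bifurcation_scan")
}
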