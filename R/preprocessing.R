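# Signal conditioning and Q/R/S fiducial detection.
#
# The chain follows the classic QRS-energy recipe: zero-phase Butterworth
# bandpass (1-60 Hz), five-point derivative, squaring and sliding-window
# integration, then adaptive-threshold peak picking with a 200 ms refractory
# period. Q and S are the nearest local minima within 80 ms of each R peak;
# QRS onset/offset are delineated by walking outward from Q/S on the local
# slope energy until it returns to the noise floor.

#' Zero-phase 1--60 Hz Butterworth bandpass
#'
#' Fourth-order (per band edge) Butterworth bandpass applied
#' forward-backward, so the output is zero-phase and length-preserving. The
#' input is reflection-padded before filtering to suppress edge transients.
#'
#' @param samples Numeric amplitude series (mV).
#' @param fs Sampling rate in Hz; must exceed 120 Hz so the 60 Hz band edge
#'   is below Nyquist.
#' @param low,high Band edges in Hz.
#' @return Filtered series of identical length.
#' @export
bandpass_filter <- function(samples, fs, low = 1, high = 60) {
  if (length(samples) == 0) {
    stop_ecgmcda("ecgmcda_empty_input_error", "empty sample series")
  }
  if (!is.numeric(fs) || fs <= 2 * high) {
    stop_ecgmcda("ecgmcda_parameter_error",
                 "fs must exceed %g Hz for a %g Hz band edge (got %g)",
                 2 * high, high, fs)
  }
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  pad <- min(length(samples) - 1L, as.integer(fs))
  if (pad > 0) {
    head_ref <- 2 * samples[1] - samples[(pad + 1):2]
    tail_ref <- 2 * samples[length(samples)] -
      samples[(length(samples) - 1):(length(samples) - pad)]
    x <- c(head_ref, samples, tail_ref)
  } else {
    x <- samples
  }
  y <- signal::filtfilt(bf, x)
  y[(pad + 1):(pad + length(samples))]
}

#' Five-point derivative filter
#'
#' Classic five-point derivative kernel `(1, 2, 0, -2, -1) / 8` that sharpens
#' the QRS slopes. Output is in amplitude units per sample: a ramp of slope
#' `a` mV/sample maps to the constant `a`. Length is preserved by replicating
#' the edge samples before convolution.
#'
#' @param samples Numeric series of length at least 5.
#' @param fs Sampling rate in Hz (kept for interface symmetry; the kernel is
#'   defined per sample).
#' @return Slope series of identical length.
#' @export
derivative_filter <- function(samples, fs = NULL) {
  if (length(samples) < 5) {
    stop_ecgmcda("ecgmcda_parameter_error",
                 "need at least 5 samples for the derivative kernel (got %d)",
                 length(samples))
  }
  x <- c(rep(samples[1], 2), samples, rep(samples[length(samples)], 2))
  n <- length(samples)
  idx <- seq_len(n) + 2
  (x[idx + 2] + 2 * x[idx + 1] - 2 * x[idx - 1] - x[idx - 2]) / 8
}

#' Squaring and sliding-window integration
#'
#' Squares the input and averages it over a trailing window, yielding the
#' local QRS energy. Windows truncated by the start of the series average
#' over the samples available, so a constant input maps to a constant.
#'
#' @param samples Slope series (any sign; squaring removes it).
#' @param fs Sampling rate in Hz.
#' @param window Integration window in seconds; `window * fs` must be at
#'   least 1 sample. Default 0.150 s, a standard QRS-energy window.
#' @return Non-negative energy series of identical length.
#' @export
square_and_integrate <- function(samples, fs, window = 0.150) {
  if (!is.numeric(window) || window <= 0) {
    stop_ecgmcda("ecgmcda_parameter_error",
                 "integration window must be positive (got %s)", format(window))
  }
  n_win <- round(window * fs)
  if (n_win < 1) {
    stop_ecgmcda("ecgmcda_parameter_error",
                 "window of %g s spans less than one sample at %g Hz",
                 window, fs)
  }
  sq <- samples^2
  cs <- cumsum(sq)
  n <- length(sq)
  lag <- pmax(seq_len(n) - n_win, 0L)
  width <- pmin(seq_len(n), n_win)
  (cs - c(0, cs)[lag + 1L]) / width
}

# Centered moving average (used to stabilize the slope-energy envelope).
smooth_ma <- function(x, k) {
  if (k <= 1) return(x)
  stats::filter(c(rep(x[1], k), x, rep(x[length(x)], k)),
                rep(1 / k, k), sides = 2)[(k + 1):(k + length(x))]
}

#' Detect beats and their Q/R/S fiducials
#'
#' Runs the full conditioning chain and locates beats: candidate QRS regions
#' are energy peaks above an adaptive threshold (initialized at 0.3 times the
#' maximum energy of the first 2 s, updated as `0.125 * peak + 0.875 *
#' threshold`) separated by a 200 ms refractory period. Within each region, R
#' is the maximum of the bandpassed signal and Q and S the nearest minima
#' within 80 ms before/after R. QRS onset and offset are delineated on the
#' local slope energy (lightly smoothed squared derivative): starting from
#' the outer slope peak just beyond Q (resp. S), the walk moves outward, up
#' to 120 ms from R, until the energy excess over the local noise floor
#' stays below 1% of the beat's peak excess for 5 consecutive samples. Beats
#' whose search windows would leave the record are discarded.
#'
#' @param samples Raw amplitude series (mV), at least 2 s long.
#' @param fs Sampling rate in Hz.
#' @return A `data.frame` with one row per beat, sorted by `r_index`:
#'   `q_index`, `r_index`, `s_index` (1-based sample indices), `q_amp`,
#'   `r_amp`, `s_amp` (mV on the filtered signal), `qrs_onset_index`,
#'   `qrs_offset_index`. Zero rows when no beat is found.
#' @export
detect_beats <- function(samples, fs) {
  if (length(samples) < 2 * fs) {
    stop_ecgmcda("ecgmcda_parameter_error",
                 "need at least 2 s of signal (%d samples at %g Hz)",
                 ceiling(2 * fs), fs)
  }
  bp <- bandpass_filter(samples, fs)
  energy <- square_and_integrate(derivative_filter(bp, fs), fs, 0.150)

  refractory <- round(0.2 * fs)
  # `level` tracks the running QRS peak-energy estimate (exponential update
  # 0.125 * peak + 0.875 * level); beats must exceed 0.3 of it.
  level <- max(energy[seq_len(round(2 * fs))])
  n <- length(energy)
  # local maxima of the energy envelope
  is_peak <- c(FALSE, energy[2:(n - 1)] > energy[1:(n - 2)] &
                 energy[2:(n - 1)] >= energy[3:n], FALSE)
  peak_idx <- which(is_peak & energy > 0)
  accepted <- integer(0)
  last <- -Inf
  for (p in peak_idx) {
    if (energy[p] > 0.3 * level && (p - last) > refractory) {
      accepted <- c(accepted, p)
      last <- p
      level <- 0.125 * energy[p] + 0.875 * level
    }
  }
  if (length(accepted) == 0) return(empty_fiducials())

  # R peaks on the bandpassed signal; the trailing integration window delays
  # the energy peak, so search mostly backward.
  back <- round(0.15 * fs); fwd <- round(0.05 * fs)
  r_idx <- vapply(accepted, function(p) {
    lo <- max(1L, p - back); hi <- min(n, p + fwd)
    as.integer(lo + which.max(bp[lo:hi]) - 1L)
  }, integer(1))
  r_idx <- sort(unique(r_idx))
  # enforce refractory on the R times themselves (keep the larger peak)
  keep <- rep(TRUE, length(r_idx))
  for (i in seq_along(r_idx)[-1]) {
    prev <- max(which(keep[seq_len(i - 1)]))
    if (r_idx[i] - r_idx[prev] <= refractory) {
      if (bp[r_idx[i]] > bp[r_idx[prev]]) keep[prev] <- FALSE else keep[i] <- FALSE
    }
  }
  r_idx <- r_idx[keep]

  qs_win <- round(0.08 * fs)
  half_win <- round(0.12 * fs)  # local window for onset/offset delineation
  r_idx <- r_idx[r_idx - half_win >= 1 & r_idx + half_win <= n]
  if (length(r_idx) == 0) return(empty_fiducials())

  # Onset/offset are delineated on the local slope energy (squared
  # derivative, lightly smoothed): the QRS edges are the steepest parts of
  # the beat, while P/T waves and the residual baseline swing of the 1 Hz
  # highpass have much lower slopes and so cannot block the walk-out.
  d <- derivative_filter(bp, fs)
  e2 <- as.numeric(smooth_ma(d^2, max(3L, round(0.011 * fs))))
  beats <- lapply(r_idx, function(r) {
    q <- (r - qs_win) + which.min(bp[(r - qs_win):(r - 1L)]) - 1L
    s <- r + which.min(bp[(r + 1L):(r + qs_win)])
    pk <- max(e2[q:s])
    # The 10% quantile over the local window estimates the noise floor of
    # the slope energy (a median would be inflated by the QRS and T slopes
    # themselves); the walk stops at the first run of 5 samples whose excess
    # over the floor is below 1% of the peak excess, so isolated noise dips
    # cannot truncate it.
    noise_floor <- stats::quantile(e2[(r - half_win):(r + half_win)], 0.10,
                                   names = FALSE)
    thr <- noise_floor + 0.01 * (pk - noise_floor)
    # the slope is ~0 at the Q/S extrema themselves, so start each walk
    # from the outer slope peak just beyond the extremum
    w2 <- round(0.02 * fs)
    q0 <- (q - w2) + which.max(e2[(q - w2):q]) - 1L
    s0 <- s + which.max(e2[s:(s + w2)]) - 1L
    onset <- walk_below(e2, q0, -1L, r - half_win, thr, run_len = 5L)
    offset <- walk_below(e2, s0, +1L, r + half_win, thr, run_len = 5L)
    data.frame(q_index = q, r_index = r, s_index = s,
               q_amp = bp[q], r_amp = bp[r], s_amp = bp[s],
               qrs_onset_index = onset, qrs_offset_index = offset)
  })
  do.call(rbind, beats)
}

# Walk from `start` in direction `dir` (step of +/-1) until `x` stays below
# `thr` for `run_len` consecutive samples (returning the first of the run),
# stopping at `limit`.
walk_below <- function(x, start, dir, limit, thr, run_len = 1L) {
  i <- start
  run <- 0L
  first <- NA_integer_
  while (i != limit) {
    i <- i + dir
    if (x[i] < thr) {
      run <- run + 1L
      if (is.na(first)) first <- i
      if (run >= run_len) return(first)
    } else {
      run <- 0L
      first <- NA_integer_
    }
  }
  if (!is.na(first)) first else i
}

empty_fiducials <- function() {
  data.frame(q_index = integer(0), r_index = integer(0), s_index = integer(0),
             q_amp = numeric(0), r_amp = numeric(0), s_amp = numeric(0),
             qrs_onset_index = integer(0), qrs_offset_index = integer(0))
}

#' Match detected beats against ground-truth R times
#'
#' Greedy one-to-one matching of detected R times to truth times within a
#' tolerance, yielding detector recall and precision. Used to benchmark
#' [detect_beats()] against the synthetic generator's `truth`.
#'
#' @param detected_times,truth_times R-peak times in seconds.
#' @param tol Matching tolerance in seconds (default 0.05).
#' @return List with `recall`, `precision`, `n_matched`.
#' @export
match_beats <- function(detected_times, truth_times, tol = 0.05) {
  used <- rep(FALSE, length(detected_times))
  matched <- 0L
  for (t in truth_times) {
    d <- abs(detected_times - t)
    d[used] <- Inf
    if (length(d) && min(d) <= tol) {
      used[which.min(d)] <- TRUE
      matched <- matched + 1L
    }
  }
  list(recall = if (length(truth_times)) matched / length(truth_times) else NA_real_,
       precision = if (length(detected_times)) matched / length(detected_times) else NA_real_,
       n_matched = matched)
}
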