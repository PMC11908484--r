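#' Spike detection configuration
#'
#' @param band_low_hz,band_high_hz bandpass edges in Hz (defaults 300 and
#'   3000). Must satisfy `0 < band_low < band_high < sampling_rate / 2`.
#' @param threshold_multiplier detection threshold in multiples of the robust
#'   noise estimate sigma_m (default 5).
#' @param pre_samples,post_samples window layout: `pre_samples` points before
#'   the event plus `post_samples` points from the event onward (defaults 20
#'   and 44, i.e. 64-sample waveforms).
#' @param dead_time_samples minimum separation between detected events
#'   (default 32 samples = 1.6 ms at 20 kHz: below the 2 ms refractory
#'   period, above the waveform overlap scale).
#' @param align_on `"minimum"` (default) re-centers each window on the trough;
#'   `"threshold_crossing"` keeps the crossing sample at position
#'   `pre_samples`.
#' @param polarity `"negative"` (default) detects downward crossings of
#'   `-threshold_multiplier * sigma_m`; `"positive"` detects upward crossings
#'   of the positive threshold.
#' @return an object of class `detection_config`.
#' @export
detection_config <- function(band_low_hz = 300, band_high_hz = 3000,
                             threshold_multiplier = 5,
                             pre_samples = 20, post_samples = 44,
                             dead_time_samples = 32,
                             align_on = c("minimum", "threshold_crossing"),
                             polarity = c("negative", "positive")) {
  if (band_low_hz <= 0 || band_low_hz >= band_high_hz)
    stop_invalid("need 0 < band_low_hz < band_high_hz")
  if (pre_samples < 1 || post_samples < 1)
    stop_invalid("pre_samples and post_samples must be >= 1")
  structure(list(
    band_low_hz = band_low_hz, band_high_hz = band_high_hz,
    threshold_multiplier = threshold_multiplier,
    pre_samples = as.integer(pre_samples),
    post_samples = as.integer(post_samples),
    dead_time_samples = as.integer(dead_time_samples),
    align_on = match.arg(align_on), polarity = match.arg(polarity)
  ), class = "detection_config")
}

#' Aligned spike waveform container
#'
#' Holds n aligned spike waveforms (rows, microvolts), their occurrence times,
#' optional ground-truth labels, and (after [normalize_and_gradient()]) the
#' 63-column gradient feature matrix the encoder consumes.
#'
#' @param waveforms n x m numeric matrix (m = 64 by default layout).
#' @param times_ms per-spike occurrence times in ms.
#' @param labels optional integer labels (0-based); `NULL` when unknown.
#' @param dt_s sampling step in seconds (5e-5 at 20 kHz).
#' @param sigma_m robust noise estimate in microvolts (may be `NA` for
#'   datasets that bypass detection).
#' @return object of class `waveform_set` with fields `waveforms`, `times_ms`,
#'   `labels`, `features` (NULL until computed), `flat_rows`, `dt_s`,
#'   `sigma_m`, `n_dropped`.
#' @export
waveform_set <- function(waveforms, times_ms, labels = NULL,
                         dt_s = 5e-5, sigma_m = NA_real_) {
  waveforms <- as.matrix(waveforms)
  if (length(times_ms) != nrow(waveforms))
    stop_invalid("times_ms length must match waveform rows")
  if (!is.null(labels) && length(labels) != nrow(waveforms))
    stop_invalid("labels length must match waveform rows")
  structure(list(
    waveforms = waveforms, times_ms = as.numeric(times_ms),
    labels = if (is.null(labels)) NULL else as.integer(labels),
    features = NULL, flat_rows = integer(0),
    dt_s = dt_s, sigma_m = sigma_m, n_dropped = 0L
  ), class = "waveform_set")
}

#' @export
print.waveform_set <- function(x, ...) {
  cat(sprintf("<waveform_set> %d spikes x %d samples, dt = %g s\n",
              nrow(x$waveforms), ncol(x$waveforms), x$dt_s))
  if (!is.null(x$labels))
    cat("  labels:", length(unique(x$labels)), "classes\n")
  if (!is.null(x$features))
    cat("  features:", ncol(x$features), "gradient columns\n")
  invisible(x)
}

#' Zero-phase bandpass filter
#'
#' 4th-order Butterworth bandpass applied forward and backward
#' (zero phase), so spike times are not shifted by the filter.
#'
#' @param trace numeric voltage trace (microvolts).
#' @param sampling_rate_hz sampling rate in Hz.
#' @param cfg a [detection_config()] providing the band edges.
#' @param order filter order (default 4).
#' @return filtered trace, same length as the input.
#' @export
bandpass_filter <- function(trace, sampling_rate_hz, cfg = detection_config(),
                            order = 4) {
  nyq <- sampling_rate_hz / 2
  if (cfg$band_low_hz <= 0 || cfg$band_high_hz >= nyq)
    stop_invalid("band edges must lie strictly inside (0, Nyquist)")
  bf <- signal::butter(order, c(cfg$band_low_hz, cfg$band_high_hz) / nyq,
                       type = "pass")
  as.numeric(signal::filtfilt(bf, trace))
}

#' Robust background-noise estimate
#'
#' `sigma_m = median(|x|) / 0.6745`, the median-absolute-deviation estimate of
#' the standard deviation of Gaussian background noise; robust against the
#' spikes riding on it.
#'
#' @param x filtered voltage trace (non-empty).
#' @return sigma_m in the units of `x`.
#' @export
estimate_noise <- function(x) {
  if (length(x) == 0) stop_invalid("empty trace")
  median(abs(x)) / 0.6745
}

#' Threshold spike detection
#'
#' Marks crossings of `threshold_multiplier * sigma_m` (negative-going by
#' default: extracellular somatic spikes deflect downward). Events closer
#' than `dead_time_samples` to the previous accepted event are suppressed,
#' and events too close to the trace edges for a full extraction window are
#' dropped.
#'
#' @param x filtered trace.
#' @param cfg a [detection_config()].
#' @param sigma_m noise estimate; computed from `x` when `NULL`.
#' @return integer vector of event sample indices (1-based), possibly empty.
#' @export
detect_spikes <- function(x, cfg = detection_config(), sigma_m = NULL) {
  if (is.null(sigma_m)) sigma_m <- estimate_noise(x)
  thr <- cfg$threshold_multiplier * sigma_m
  n <- length(x)
  ev <- if (cfg$polarity == "negative")
    which(x[-1] <= -thr & x[-n] > -thr) + 1L
  else
    which(x[-1] >= thr & x[-n] < thr) + 1L
  # dead time: greedy left-to-right suppression
  if (length(ev) > 1 && cfg$dead_time_samples > 0) {
    keep <- ev[1]; last <- ev[1]
    for (e in ev[-1]) if (e - last >= cfg$dead_time_samples) {
      keep <- c(keep, e); last <- e
    }
    ev <- keep
  }
  # full-window feasibility
  ev[ev > cfg$pre_samples & ev + cfg$post_samples - 1L <= n]
}

#' Extract aligned spike waveforms
#'
#' Cuts a `pre_samples + post_samples` window around each event
#' (`pre_samples` points before the event plus `post_samples` points from the
#' event onward). With `align_on = "minimum"` each window is re-centered so
#' the trough sits at index `pre_samples` (0-based), matching the simulator's
#' template alignment. Events whose (re-centered) window would cross a trace
#' edge are silently dropped; the drop count is recorded in `n_dropped`.
#'
#' @param x filtered trace.
#' @param events event sample indices from [detect_spikes()].
#' @param sampling_rate_hz sampling rate in Hz.
#' @param cfg a [detection_config()].
#' @param sigma_m noise estimate stored with the result (computed from `x`
#'   when `NULL`).
#' @return a [waveform_set] (no features yet); `times_ms` is the time of the
#'   alignment sample.
#' @export
extract_waveforms <- function(x, events, sampling_rate_hz,
                              cfg = detection_config(), sigma_m = NULL) {
  if (is.null(sigma_m)) sigma_m <- estimate_noise(x)
  pre <- cfg$pre_samples; post <- cfg$post_samples
  len <- pre + post
  n <- length(x)
  centers <- integer(0); dropped <- 0L
  for (e in events) {
    if (e <= pre || e + post - 1L > n) { dropped <- dropped + 1L; next }
    c_i <- e
    if (cfg$align_on == "minimum") {
      w <- x[(e - pre):(e + post - 1L)]
      c_i <- e - pre - 1L +
        (if (cfg$polarity == "negative") which.min(w) else which.max(w))
      if (c_i <= pre || c_i + post - 1L > n) { dropped <- dropped + 1L; next }
    }
    centers <- c(centers, c_i)
  }
  W <- matrix(0, length(centers), len)
  for (i in seq_along(centers))
    W[i, ] <- x[(centers[i] - pre):(centers[i] + post - 1L)]
  ws <- waveform_set(W, times_ms = centers / sampling_rate_hz * 1000,
                     dt_s = 1 / sampling_rate_hz, sigma_m = sigma_m)
  ws$n_dropped <- dropped
  ws
}

#' Min-max normalization and gradient mapping
#'
#' Normalizes every waveform row to \[0, 1\] (min-max) and maps it to its
#' gradient, `g(t) = (x(t + 1) - x(t)) / dt`, the first difference divided by
#' the sampling step (50 microseconds at 20 kHz). The gradient of a 64-sample
#' waveform has exactly 63 entries -- the encoder's input width. Flat rows
#' (max equals min) get an all-zero feature row and are flagged in
#' `flat_rows` so dataset row indices stay stable.
#'
#' @param wset a [waveform_set].
#' @return the same `waveform_set` with `features` (n x 63, units 1/s) and
#'   `flat_rows` filled in.
#' @export
normalize_and_gradient <- function(wset) {
  stopifnot(inherits(wset, "waveform_set"))
  W <- wset$waveforms
  m <- ncol(W)
  lo <- apply(W, 1, min); hi <- apply(W, 1, max)
  rng <- hi - lo
  flat <- which(rng == 0)
  rng[rng == 0] <- 1
  N <- (W - lo) / rng
  G <- (N[, -1, drop = FALSE] - N[, -m, drop = FALSE]) / wset$dt_s
  if (length(flat)) G[flat, ] <- 0
  wset$features <- G
  wset$flat_rows <- flat
  wset
}

#' Normalize rows to \[0, 1\]
#'
#' Per-row min-max normalization; idempotent. Flat rows are returned as
#' zeros.
#'
#' @param W numeric matrix.
#' @return matrix of the same shape with rows in \[0, 1\].
#' @export
minmax_rows <- function(W) {
  lo <- apply(W, 1, min); hi <- apply(W, 1, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  (W - lo) / rng
}
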