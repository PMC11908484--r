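#' Simulation configuration
#'
#' Parameters of the synthetic single-electrode recording generator. The
#' defaults emulate the statistics of the single-channel benchmark datasets:
#' 5 source neurons placed at random normalized distances from the electrode,
#' per-neuron firing rates drawn uniformly from 15--35 Hz, additive white
#' Gaussian background noise, and per-spike signal-to-noise ratios spanning
#' roughly 4--12 (SNR = trough amplitude over noise standard deviation).
#'
#' The neuron-to-electrode distance is a normalized value in \[0, 1\] (0 =
#' closest, 1 = farthest single-unit distance). Spike amplitude follows
#' `amplitude(d) = snr_max * noise_sigma / (1 + alpha * d)` with `alpha`
#' chosen so distance 0 maps to `max(target_snr_range)` and distance 1 to
#' `min(target_snr_range)`; amplitude (hence SNR) is strictly decreasing in
#' distance.
#'
#' @param n_neurons number of source neurons (>= 0; 5--15 typical).
#' @param n_spikes total spike count for [generate_waveform_dataset()];
#'   ignored by [generate_recording()].
#' @param duration_s recording duration in seconds for [generate_recording()].
#' @param sampling_rate_hz sampling rate in Hz (default 20000).
#' @param firing_rate_range_hz interval from which per-neuron mean firing
#'   rates are drawn uniformly (default `c(15, 35)`).
#' @param distance_range normalized distance interval within \[0, 1\] from
#'   which per-neuron electrode distances are drawn (default `c(0, 1)`).
#' @param noise_sigma background noise standard deviation in microvolts.
#' @param target_snr_range SNR interval \[snr_min, snr_max\] mapped onto
#'   `distance_range` (default `c(4, 12)`).
#' @param refractory_ms absolute refractory period per neuron in ms
#'   (default 2): inter-spike intervals of one neuron never fall below it.
#' @param seed integer seed fixing all randomness end-to-end.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_neurons = 5, n_spikes = NULL, duration_s = 10,
                       sampling_rate_hz = 20000,
                       firing_rate_range_hz = c(15, 35),
                       distance_range = c(0, 1),
                       noise_sigma = 3,
                       target_snr_range = c(4, 12),
                       refractory_ms = 2,
                       seed = 1L) {
  if (n_neurons < 0) stop_invalid("n_neurons must be >= 0")
  if (any(firing_rate_range_hz <= 0)) stop_invalid("firing rates must be positive")
  if (noise_sigma < 0) stop_invalid("noise_sigma must be >= 0")
  if (distance_range[1] < 0 || distance_range[2] > 1 ||
      distance_range[1] > distance_range[2])
    stop_invalid("distance_range must be an interval within [0, 1]")
  if (target_snr_range[1] <= 0 || target_snr_range[1] > target_snr_range[2])
    stop_invalid("target_snr_range must be a positive increasing interval")
  # dead time must leave room for the requested rates
  max_rate <- max(firing_rate_range_hz)
  if (1 / max_rate <= refractory_ms / 1000)
    stop_invalid("firing rates incompatible with refractory dead time")
  structure(list(
    n_neurons = as.integer(n_neurons), n_spikes = n_spikes,
    duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
    firing_rate_range_hz = firing_rate_range_hz,
    distance_range = distance_range, noise_sigma = noise_sigma,
    target_snr_range = target_snr_range, refractory_ms = refractory_ms,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Random spike waveform templates
#'
#' Draws biphasic/triphasic negative-peak spike templates as sums of two or
#' three Gaussian lobes with randomized widths, latencies and amplitude
#' ratios. Each template is normalized so its trough (most negative value) is
#' exactly -1 and sits at sample index `pre_samples` (0-based 20, matching
#' the 20-before / 44-after extraction window), so simulated and detected
#' waveforms share the same alignment.
#'
#' @param n_neurons number of templates (>= 0).
#' @param n_samples samples per template (default 64; must be >= 8).
#' @param seed integer seed.
#' @param pre_samples 0-based trough index (default 20).
#' @return list of `n_neurons` numeric vectors of length `n_samples`.
#' @export
make_templates <- function(n_neurons, n_samples = 64, seed = 1L,
                           pre_samples = 20) {
  if (n_samples < 8) stop_invalid("n_samples must be >= 8")
  if (n_neurons == 0) return(list())
  with_seed(seed, {
    templates <- vector("list", n_neurons)
    t_idx <- seq_len(n_samples) - 1
    i <- 1L
    while (i <= n_neurons) {
      # main negative lobe: width spans spike FWHMs of ~0.1--0.5 ms at 20 kHz
      w1 <- runif(1, 1.2, 4.0)
      y <- -exp(-(t_idx - pre_samples)^2 / (2 * w1^2))
      # positive after-hyperpolarization rebound
      a2 <- runif(1, 0.2, 0.6); d2 <- runif(1, 5, 14); w2 <- runif(1, 3, 8)
      y <- y + a2 * exp(-(t_idx - pre_samples - d2)^2 / (2 * w2^2))
      # optional small positive pre-lobe (triphasic shape)
      if (runif(1) < 0.5) {
        a3 <- runif(1, 0.05, 0.25); d3 <- runif(1, 3, 6); w3 <- runif(1, 1.5, 3)
        y <- y + a3 * exp(-(t_idx - pre_samples + d3)^2 / (2 * w3^2))
      }
      # re-center so the global trough is exactly at pre_samples (edge-pad)
      shift <- (pre_samples + 1L) - which.min(y)
      if (shift != 0) {
        if (shift > 0) y <- c(rep(y[1], shift), y[seq_len(n_samples - shift)])
        else y <- c(y[(1 - shift):n_samples], rep(y[n_samples], -shift))
      }
      y <- y / abs(min(y))
      # reject near-duplicates of earlier templates (max normalized xcorr)
      dup <- FALSE
      if (i > 1L) for (j in seq_len(i - 1L)) {
        if (max_xcorr(y, templates[[j]]) > 0.995) { dup <- TRUE; break }
      }
      if (!dup) { templates[[i]] <- y; i <- i + 1L }
    }
    templates
  })
}

# maximum normalized cross-correlation over all lags; normalized by the full
# signal energies (Cauchy-Schwarz: equals 1 only for identical aligned shapes)
max_xcorr <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  n <- length(a)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  best <- -Inf
  for (lag in -(n - 1):(n - 1)) {
    ia <- max(1, 1 + lag):min(n, n + lag)
    best <- max(best, sum(a[ia] * b[ia - lag]) / den)
  }
  best
}

# per-neuron Poisson spike train with absolute refractory dead time.
# effective exponential rate solves  1/rate = dead + 1/lambda.
poisson_train <- function(rate_hz, duration_s, refractory_s, t_min = 0) {
  lambda <- 1 / (1 / rate_hz - refractory_s)
  times <- numeric(0)
  t <- t_min + rexp(1, rate_hz)          # first spike: plain exponential delay
  while (t < duration_s) {
    times <- c(times, t)
    t <- t + refractory_s + rexp(1, lambda)
  }
  times
}

# distance -> SNR law: snr(d) = snr_max / (1 + alpha d), snr(1) = snr_min
distance_to_snr <- function(distance, snr_range) {
  alpha <- snr_range[2] / snr_range[1] - 1
  snr_range[2] / (1 + alpha * distance)
}

# bandlimited background noise, sd scaled to sigma. Isolated spike waveforms
# come from bandpass-filtered recordings, so their noise is smooth (300-3000
# Hz at fs), not white; white noise would dominate the gradient features.
bandlimited_noise <- function(n, sigma, fs = 20000, low = 300, high = 3000) {
  if (sigma == 0 || n == 0) return(numeric(n))
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  pad <- 512L
  x <- as.numeric(signal::filtfilt(bf, rnorm(n + 2L * pad)))
  x <- x[(pad + 1L):(pad + n)]
  x * sigma / stats::sd(x)
}

#' Generate a synthetic extracellular recording
#'
#' Simulates a single-channel voltage trace: per-neuron homogeneous Poisson
#' spike trains with absolute refractory dead time, template insertion scaled
#' by a distance-dependent amplitude, and additive white Gaussian background
#' noise. Spikes of different neurons may overlap; within a neuron,
#' inter-spike intervals respect the refractory period.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `sim_recording` with elements
#'   \describe{
#'     \item{trace}{numeric vector, microvolts, length
#'       `duration_s * sampling_rate_hz`}
#'     \item{truth}{ground truth: `spike_times_ms` (trough times, sorted),
#'       `neuron_ids` (0-based), `snr` per spike, `templates`,
#'       `rates_hz`, `distances`}
#'     \item{sampling_rate_hz, noise_sigma}{copied from `cfg`}
#'   }
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    fs <- cfg$sampling_rate_hz
    n_samp <- round(cfg$duration_s * fs)
    trace <- rnorm(n_samp, 0, cfg$noise_sigma)
    templates <- if (cfg$n_neurons > 0)
      make_templates(cfg$n_neurons, seed = NULL) else list()
    rates <- runif(cfg$n_neurons, cfg$firing_rate_range_hz[1],
                   cfg$firing_rate_range_hz[2])
    distances <- runif(cfg$n_neurons, cfg$distance_range[1],
                       cfg$distance_range[2])
    snrs <- distance_to_snr(distances, cfg$target_snr_range)
    amps <- snrs * cfg$noise_sigma
    pre <- 20L; post <- 43L; len <- 64L
    all_t <- numeric(0); all_id <- integer(0)
    for (j in seq_len(cfg$n_neurons)) {
      st <- poisson_train(rates[j], cfg$duration_s, cfg$refractory_ms / 1000)
      trough_idx <- round(st * fs)
      ok <- trough_idx > pre & trough_idx + post <= n_samp
      trough_idx <- trough_idx[ok]
      for (ti in trough_idx) {
        w <- (ti - pre):(ti + post)
        trace[w] <- trace[w] + amps[j] * templates[[j]]
      }
      all_t <- c(all_t, trough_idx / fs * 1000)
      all_id <- c(all_id, rep(j - 1L, length(trough_idx)))
    }
    ord <- order(all_t)
    structure(list(
      trace = trace,
      truth = list(spike_times_ms = all_t[ord], neuron_ids = all_id[ord],
                   snr = snrs[all_id[ord] + 1L], templates = templates,
                   rates_hz = rates, distances = distances),
      sampling_rate_hz = fs, noise_sigma = cfg$noise_sigma
    ), class = "sim_recording")
  })
}

#' Generate a labeled spike-waveform dataset
#'
#' Produces a clean labeled waveform set in the same row layout as the
#' detection pipeline output (n x 64 matrix, trough aligned to index 20,
#' 0-based), bypassing threshold detection: each row is a noisy realization
#' of its neuron's template at the neuron's distance-determined amplitude.
#' Spike counts per neuron are proportional to the drawn firing rates, with
#' at least one spike per neuron; spike times come from refractory-respecting
#' Poisson trains.
#'
#' @param cfg a [sim_config()] with `n_spikes` set (`n_spikes >= n_neurons`).
#' @return a [waveform_set] with `labels` (0-based neuron ids), `times_ms`,
#'   per-spike `snr` attribute in `truth`, `sigma_m` set to the true noise
#'   sigma, and a `truth` element (templates, rates, distances, snr).
#' @export
generate_waveform_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$n_spikes)) stop_invalid("cfg$n_spikes must be set")
  if (cfg$n_neurons < 1) stop_invalid("need n_neurons >= 1 for a labeled dataset")
  if (cfg$n_spikes < cfg$n_neurons)
    stop_invalid("n_spikes must be >= n_neurons so every label occurs")
  with_seed(cfg$seed, {
    n <- as.integer(cfg$n_spikes)
    templates <- make_templates(cfg$n_neurons, seed = NULL)
    rates <- runif(cfg$n_neurons, cfg$firing_rate_range_hz[1],
                   cfg$firing_rate_range_hz[2])
    distances <- runif(cfg$n_neurons, cfg$distance_range[1],
                       cfg$distance_range[2])
    snrs <- distance_to_snr(distances, cfg$target_snr_range)
    # in the zero-noise limit SNR is undefined; keep unit amplitude scale
    amps <- snrs * (if (cfg$noise_sigma > 0) cfg$noise_sigma else 1)
    # counts proportional to rates, each neuron present at least once
    extra <- n - cfg$n_neurons
    counts <- rep(1L, cfg$n_neurons)
    if (extra > 0) {
      draw <- sample.int(cfg$n_neurons, extra, replace = TRUE, prob = rates)
      counts <- counts + tabulate(draw, nbins = cfg$n_neurons)
    }
    labels <- integer(0); times <- numeric(0)
    refr <- cfg$refractory_ms
    for (j in seq_len(cfg$n_neurons)) {
      isi <- refr + rexp(counts[j], 1 / (1000 / rates[j] - refr))
      times <- c(times, cumsum(isi))
      labels <- c(labels, rep(j - 1L, counts[j]))
    }
    ord <- order(times)
    labels <- labels[ord]; times <- times[ord]
    W <- matrix(bandlimited_noise(n * 64L, cfg$noise_sigma,
                                  cfg$sampling_rate_hz), n, 64L, byrow = TRUE)
    for (j in seq_len(cfg$n_neurons)) {
      rows <- which(labels == j - 1L)
      W[rows, ] <- W[rows, , drop = FALSE] +
        matrix(amps[j] * templates[[j]], length(rows), 64L, byrow = TRUE)
    }
    ws <- waveform_set(W, times_ms = times, labels = labels,
                       dt_s = 1 / cfg$sampling_rate_hz,
                       sigma_m = cfg$noise_sigma)
    ws$truth <- list(templates = templates, rates_hz = rates,
                     distances = distances, snr = snrs[labels + 1L])
    ws
  })
}
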