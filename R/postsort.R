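#' Full width at half maximum of a spike waveform
#'
#' Peak amplitude is the trough value measured against a 0 uV baseline
#' (bandpassed waveforms are zero-mean). The two points where the waveform
#' crosses half that amplitude on either side of the trough are located by
#' linear interpolation between samples; their time difference is the FWHM.
#' Scaling the waveform by any positive constant leaves it unchanged.
#'
#' @param waveform numeric vector (microvolts) with a negative trough.
#' @param dt_s sampling step in seconds (5e-5 at 20 kHz).
#' @return FWHM in milliseconds, or `NA` (with attribute
#'   `undefined = TRUE`) when no half-amplitude crossing exists on one side.
#' @export
fwhm <- function(waveform, dt_s = 5e-5) {
  n <- length(waveform)
  ti <- which.min(waveform)
  trough <- waveform[ti]
  if (trough >= 0) return(structure(NA_real_, undefined = TRUE))
  half <- trough / 2
  # left crossing: last sample at/above half before the trough
  left <- NA_real_
  if (ti > 1) for (i in (ti - 1):1) {
    if (waveform[i] >= half) {
      left <- i + (waveform[i] - half) / (waveform[i] - waveform[i + 1])
      break
    }
  }
  right <- NA_real_
  if (ti < n) for (i in (ti + 1):n) {
    if (waveform[i] >= half) {
      right <- i - (waveform[i] - half) / (waveform[i] - waveform[i - 1])
      break
    }
  }
  if (is.na(left) || is.na(right)) return(structure(NA_real_, undefined = TRUE))
  (right - left) * dt_s * 1000
}

#' Refractory-period violation rate
#'
#' Fraction of a unit's spikes whose preceding inter-spike interval is
#' shorter than the absolute refractory period: violations divided by the
#' total spike count. A well-isolated single unit cannot fire twice within
#' the refractory period, so a low RPV rate supports single-unit identity.
#' One violation is counted per short interval. Empty or singleton inputs
#' give 0.
#'
#' @param spike_times_ms spike times in ms, sorted ascending.
#' @param refractory_ms refractory period (default 2 ms).
#' @return violation rate in \[0, 1\].
#' @export
rpv_rate <- function(spike_times_ms, refractory_ms = 2) {
  if (length(spike_times_ms) < 2) return(0)
  if (is.unsorted(spike_times_ms)) stop_invalid("spike times must be sorted")
  sum(diff(spike_times_ms) < refractory_ms) / length(spike_times_ms)
}

#' Per-unit quality summaries
#'
#' Computes, for every predicted unit: spike count, mean waveform, signed
#' trough amplitude (negative microvolts), FWHM of the mean waveform, and
#' RPV rate.
#'
#' @param waveforms n x m waveform matrix (microvolts).
#' @param times_ms per-spike times in ms.
#' @param labels per-spike unit labels (0-based).
#' @param dt_s sampling step in seconds.
#' @param refractory_ms refractory period for the RPV rate (default 2).
#' @return data frame (one row per unit: `unit`, `n_spikes`, `amplitude_uv`,
#'   `fwhm_ms`, `rpv_rate`) with the unit mean waveforms attached as the
#'   `mean_waveforms` attribute (matrix, one row per unit).
#' @export
summarize_units <- function(waveforms, times_ms, labels, dt_s = 5e-5,
                            refractory_ms = 2) {
  waveforms <- as.matrix(waveforms)
  units <- sort(unique(labels))
  rows <- lapply(units, function(u) {
    sel <- labels == u
    mw <- colMeans(waveforms[sel, , drop = FALSE])
    data.frame(unit = u, n_spikes = sum(sel),
               amplitude_uv = min(mw),
               fwhm_ms = as.numeric(fwhm(mw, dt_s)),
               rpv_rate = rpv_rate(sort(times_ms[sel]), refractory_ms))
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_waveforms") <-
    do.call(rbind, lapply(units, function(u)
      colMeans(waveforms[labels == u, , drop = FALSE])))
  out
}

#' Filter units by refractory-period violations
#'
#' Retains only units whose RPV rate is strictly lower than the threshold
#' (default 0.1%), the criterion for accepting a cluster as a single unit.
#' Order is preserved; the number of dropped units is attached as the
#' `n_dropped` attribute. Idempotent.
#'
#' @param summaries data frame with an `rpv_rate` column (e.g. from
#'   [summarize_units()]).
#' @param rpv_threshold strict upper bound (default 0.001).
#' @return the retained rows.
#' @export
filter_units <- function(summaries, rpv_threshold = 0.001) {
  keep <- summaries$rpv_rate < rpv_threshold
  out <- summaries[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Relative firing-rate change between two recording phases
#'
#' `(rate_post - rate_pre) / rate_pre` with rates computed as spike count
#' over duration. Units silent before treatment (`rate_pre = 0`) have an
#' undefined relative change and return `NA` with attribute
#' `undefined = TRUE` (such units are excluded from aggregate plots).
#'
#' @param pre_times,post_times spike times (ms) in the two phases.
#' @param pre_duration_s,post_duration_s phase durations in seconds (> 0).
#' @return relative change (dimensionless), or flagged `NA`.
#' @export
rate_change <- function(pre_times, post_times, pre_duration_s, post_duration_s) {
  if (pre_duration_s <= 0 || post_duration_s <= 0)
    stop_invalid("durations must be > 0")
  rate_pre <- length(pre_times) / pre_duration_s
  rate_post <- length(post_times) / post_duration_s
  if (rate_pre == 0) return(structure(NA_real_, undefined = TRUE))
  (rate_post - rate_pre) / rate_pre
}
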