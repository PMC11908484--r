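#' Write a waveform set as CSV
#'
#' Uses the standard dataset layout: column 1 `label` (ground-truth class,
#' -1 when unknown), column 2 `time_ms`, columns 3..66 the 64 waveform
#' samples `s0..s63`.
#'
#' @param wset a [waveform_set].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_waveforms_csv <- function(wset, path) {
  stopifnot(inherits(wset, "waveform_set"))
  m <- ncol(wset$waveforms)
  df <- data.frame(
    label = if (is.null(wset$labels)) rep(-1L, nrow(wset$waveforms))
            else wset$labels,
    time_ms = wset$times_ms)
  W <- as.data.frame(wset$waveforms)
  names(W) <- paste0("s", seq_len(m) - 1L)
  write.csv(cbind(df, W), path, row.names = FALSE)
  invisible(path)
}

#' Read a waveform set from CSV
#'
#' Inverse of [write_waveforms_csv()]; `label = -1` is mapped back to "no
#' label" only if every label is -1.
#'
#' @param path CSV in the `label,time_ms,s0..s63` layout.
#' @param dt_s sampling step stored on the result (default 5e-5).
#' @param sigma_m noise estimate stored on the result (default `NA`).
#' @return a [waveform_set].
#' @export
read_waveforms_csv <- function(path, dt_s = 5e-5, sigma_m = NA_real_) {
  df <- read.csv(path)
  if (!all(c("label", "time_ms") %in% names(df)))
    stop_invalid("missing label/time_ms columns")
  W <- as.matrix(df[, grep("^s\\d+$", names(df)), drop = FALSE])
  labels <- if (all(df$label == -1L)) NULL else as.integer(df$label)
  waveform_set(W, times_ms = df$time_ms, labels = labels,
               dt_s = dt_s, sigma_m = sigma_m)
}

#' Write a raw trace as float32 binary with a JSON sidecar
#'
#' Little-endian float32 samples in `<path>`, metadata (sampling rate, units)
#' in `<path>.json`.
#'
#' @param trace numeric voltage trace (microvolts).
#' @param path output binary file.
#' @param sampling_rate_hz sampling rate recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trace_bin <- function(trace, path, sampling_rate_hz) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(trace), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(sampling_rate_hz = sampling_rate_hz, units = "uV",
         n_samples = length(trace)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a float32 binary trace and its JSON sidecar
#'
#' @param path binary file written by [write_trace_bin()].
#' @return list with `trace` (numeric) and `sampling_rate_hz`.
#' @export
read_trace_bin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  trace <- readBin(con, numeric(), n = meta$n_samples, size = 4L,
                   endian = "little")
  list(trace = trace, sampling_rate_hz = meta$sampling_rate_hz)
}

#' Write a pseudolabel set as CSV
#'
#' `index,label` rows (1-based indices, 0-based labels) preceded by comment
#' header lines recording fraction, k, method and seed.
#'
#' @param pls a `pseudo_label_set`.
#' @param path output file.
#' @param seed seed recorded in the header (optional).
#' @return `path`, invisibly.
#' @export
write_pseudolabels_csv <- function(pls, path, seed = NA) {
  stopifnot(inherits(pls, "pseudo_label_set"))
  hdr <- sprintf("# fraction=%s k=%d method=%s seed=%s",
                 format(pls$fraction), pls$k, pls$method, format(seed))
  writeLines(c(hdr, "index,label",
               paste(pls$indices, pls$labels, sep = ",")), path)
  invisible(path)
}
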