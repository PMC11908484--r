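# YAML-configured end-to-end pipeline: simulate -> detect -> sort -> evaluate
# -> unit summaries, with a run manifest for provenance. The CLI script in
# inst/cli/pseudosort wraps these functions.

# schema: required keys per block (validated before anything runs)
pipeline_required <- list(
  simulate = c("n_neurons", "duration_s", "sampling_rate_hz", "noise_sigma")
)

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, fills defaults for all optional keys and validates the
#' schema; a missing required key produces an error naming it.
#'
#' @param path YAML file. Recognized top-level blocks: `simulate`, `detect`,
#'   `sort` (with optional `pretrain`, `sampling`, `finetune` subkeys) and
#'   `seed`.
#' @return the resolved configuration (named list) with class
#'   `pipeline_config`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$simulate)) stop_invalid("config error: missing block 'simulate'")
  for (key in pipeline_required$simulate)
    if (is.null(cfg$simulate[[key]]))
      stop_invalid("config error: missing required key 'simulate.", key, "'")
  defaults <- list(seed = 1L,
                   detect = list(), sort = list(pretrain = list(),
                                                sampling = list(),
                                                finetune = list()))
  cfg <- utils::modifyList(defaults, cfg)
  structure(cfg, class = c("pipeline_config", "list"))
}

# atomically write a file: write to tempname in the same dir, then rename;
# writers may emit sidecar files ("<path>.json"), which are renamed along
atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writer(tmp)
  for (f in Sys.glob(paste0(tmp, "*")))
    file.rename(f, paste0(path, substring(f, nchar(tmp) + 1L)))
  invisible(path)
}

#' Run the configured end-to-end pipeline
#'
#' Chains simulation, spike detection, sorting, evaluation against the
#' simulated ground truth, and per-unit quality summaries; writes all
#' artifacts plus a run manifest (`manifest.json`: resolved config, stage
#' seeds, package version, stage timings, artifact list) to `out_dir`.
#' Artifacts are written atomically, so a failing stage leaves earlier
#' artifacts intact.
#'
#' @param config path to a YAML file or a `pipeline_config`.
#' @param out_dir output directory (created if needed).
#' @param seed overrides the config seed when not `NULL`.
#' @param dry_run print the resolved configuration and write nothing.
#' @return invisibly, a list with the sort result, evaluation report, unit
#'   summaries and the manifest.
#' @export
run_pipeline <- function(config, out_dir = ".", seed = NULL, dry_run = FALSE) {
  cfg <- if (is.character(config)) load_config(config) else config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (dry_run) {
    cat(yaml::as.yaml(unclass(cfg)))
    return(invisible(NULL))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  clock <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- expr
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  sc <- cfg$simulate
  sim_cfg <- sim_config(
    n_neurons = sc$n_neurons, duration_s = sc$duration_s,
    sampling_rate_hz = sc$sampling_rate_hz, noise_sigma = sc$noise_sigma,
    firing_rate_range_hz = sc$firing_rate_range_hz %||% c(15, 35),
    target_snr_range = sc$target_snr_range %||% c(4, 12),
    refractory_ms = sc$refractory_ms %||% 2, seed = cfg$seed)
  rec <- clock("simulate", generate_recording(sim_cfg))
  atomic_write(function(p) write_trace_bin(rec$trace, p, sc$sampling_rate_hz),
               file.path(out_dir, "trace.f32"))

  dc <- do.call(detection_config, cfg$detect)
  wset <- clock("detect", {
    filt <- bandpass_filter(rec$trace, sc$sampling_rate_hz, dc)
    sm <- estimate_noise(filt)
    ev <- detect_spikes(filt, dc, sm)
    normalize_and_gradient(
      extract_waveforms(filt, ev, sc$sampling_rate_hz, dc, sm))
  })
  atomic_write(function(p) write_waveforms_csv(wset, p),
               file.path(out_dir, "spikes.csv"))

  so <- cfg$sort
  pre_cfg <- do.call(contrastive_config,
                     utils::modifyList(list(seed = cfg$seed), so$pretrain))
  samp_cfg <- do.call(sampling_config,
                      utils::modifyList(list(seed = cfg$seed), so$sampling))
  ft_cfg <- do.call(finetune_config,
                    utils::modifyList(list(seed = cfg$seed), so$finetune))
  res <- clock("sort", run_pseudosorter(wset$features, encoder_spec(),
                                        pre_cfg, samp_cfg, ft_cfg,
                                        k = so$k))
  atomic_write(function(p)
    write.csv(data.frame(time_ms = wset$times_ms, label = res$labels),
              p, row.names = FALSE),
    file.path(out_dir, "labels.csv"))

  # evaluation against ground truth: match detected spikes to truth by time
  report <- clock("evaluate", {
    truth_lab <- match_truth_labels(wset$times_ms, rec$truth$spike_times_ms,
                                    rec$truth$neuron_ids,
                                    tol_ms = 2000 / sc$sampling_rate_hz)
    ok <- !is.na(truth_lab)
    if (sum(ok) > 0)
      list(accuracy = match_accuracy(res$labels[ok], truth_lab[ok]),
           k_true = sim_cfg$n_neurons, k_pred = res$k_estimate,
           k_error = predict_k_error(res$k_estimate, sim_cfg$n_neurons),
           n_matched = sum(ok), n_detected = length(truth_lab))
    else list(accuracy = NA, k_true = sim_cfg$n_neurons,
              k_pred = res$k_estimate, n_matched = 0L,
              n_detected = length(truth_lab))
  })
  atomic_write(function(p) jsonlite::write_json(report, p, auto_unbox = TRUE,
                                                digits = NA),
               file.path(out_dir, "report.json"))

  units <- clock("analyze", {
    filter_units(summarize_units(wset$waveforms, wset$times_ms, res$labels,
                                 dt_s = wset$dt_s))
  })
  atomic_write(function(p) write.csv(units, p, row.names = FALSE),
               file.path(out_dir, "units.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("pseudosort")),
    seed = cfg$seed, config = unclass(cfg), timings = timings,
    artifacts = c("trace.f32", "spikes.csv", "labels.csv", "report.json",
                  "units.csv"),
    model_fingerprint = res$fingerprint)
  atomic_write(function(p) jsonlite::write_json(manifest, p, auto_unbox = TRUE),
               file.path(out_dir, "manifest.json"))
  invisible(list(sort = res, report = report, units = units,
                 manifest = manifest))
}

#' Match detected spike times to ground-truth times
#'
#' Assigns each detected spike the neuron id of the nearest ground-truth
#' spike within a time tolerance, or `NA` when none is close enough.
#'
#' @param detected_ms detected spike times (ms).
#' @param truth_ms ground-truth spike times (ms).
#' @param truth_ids ground-truth neuron ids, parallel to `truth_ms`.
#' @param tol_ms matching tolerance in milliseconds.
#' @return integer vector of neuron ids (or `NA`) per detected spike.
#' @export
match_truth_labels <- function(detected_ms, truth_ms, truth_ids, tol_ms) {
  out <- rep(NA_integer_, length(detected_ms))
  if (length(truth_ms) == 0) return(out)
  for (i in seq_along(detected_ms)) {
    j <- which.min(abs(truth_ms - detected_ms[i]))
    if (abs(truth_ms[j] - detected_ms[i]) <= tol_ms) out[i] <- truth_ids[j]
  }
  out
}

#' Detection recall against ground truth
#'
#' Fraction of ground-truth spikes (optionally restricted to a minimum SNR)
#' recovered by detection within a sample tolerance.
#'
#' @param detected_ms detected spike times in ms.
#' @param truth_ms,truth_snr ground-truth times and per-spike SNRs.
#' @param sampling_rate_hz sampling rate.
#' @param min_snr only truth spikes at or above this SNR count (default 0).
#' @param tol_samples match tolerance in samples (default 2).
#' @return recall fraction in \[0, 1\].
#' @export
detection_recall <- function(detected_ms, truth_ms, truth_snr,
                             sampling_rate_hz, min_snr = 0, tol_samples = 2) {
  sel <- truth_snr >= min_snr
  truth <- truth_ms[sel]
  if (length(truth) == 0) return(NA_real_)
  tol <- tol_samples * 1000 / sampling_rate_hz
  hit <- vapply(truth, function(t) any(abs(detected_ms - t) <= tol), logical(1))
  mean(hit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
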