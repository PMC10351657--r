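#' Full pipeline configuration
#'
#' Bundles every stage's parameters. The defaults reproduce the reference
#' analysis settings: 3.3-z significance threshold, 5-Hz bins, z > 5
#' detection, 600-s (10-min) windows, 900-s (15-min) pre-ictal baseline,
#' 250 Hz sampling.
#'
#' @param wavelet a [wavelet_params()].
#' @param fingerprint a [fingerprint_params()].
#' @param detection a [detection_params()].
#' @param baseline_duration_s pre-ictal baseline length for spectrogram
#'   z-normalization, seconds (default 900).
#' @param window_s band-power window length, seconds (default 600).
#' @param detection_mode "fir" (zero-phase FIR band power) or "fft"
#'   (Percept-style periodogram power-in-band).
#' @param band optional [frequency_band()] overriding the fingerprint for
#'   the detect stage (e.g. a control band).
#' @param tolerance_windows diary-matching slack in windows (default 1).
#' @param synthetic optional [synthetic_config()] for the simulate stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(wavelet = wavelet_params(),
                            fingerprint = fingerprint_params(),
                            detection = detection_params(),
                            baseline_duration_s = 900,
                            window_s = 600,
                            detection_mode = c("fir", "fft"),
                            band = NULL,
                            tolerance_windows = 1,
                            synthetic = NULL) {
  detection_mode <- match.arg(detection_mode)
  stopifnot(inherits(wavelet, "wavelet_params"),
            inherits(fingerprint, "fingerprint_params"),
            inherits(detection, "detection_params"))
  if (!is.null(band)) stopifnot(inherits(band, "frequency_band"))
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  structure(
    list(wavelet = wavelet, fingerprint = fingerprint, detection = detection,
         baseline_duration_s = baseline_duration_s, window_s = window_s,
         detection_mode = detection_mode, band = band,
         tolerance_windows = as.integer(tolerance_windows),
         synthetic = synthetic),
    class = "pipeline_config")
}

strip_class <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_class)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Serialize a pipeline configuration to YAML
#'
#' @param config a [pipeline_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(strip_class(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' The inverse of [write_config()]: `read_config(write_config(cfg))`
#' reconstructs an equivalent, revalidated configuration.
#'
#' @param path YAML path.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  l <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(l$synthetic)) {
    s <- l$synthetic
    specs <- lapply(s$seizures, function(sp) do.call(seizure_spec, sp))
    syn <- synthetic_config(
      duration_s = s$duration_s, fs_hz = s$fs_hz,
      channel_labels = unlist(s$channel_labels), seizures = specs,
      background_exponent = s$background_exponent,
      background_rms = s$background_rms,
      background_flatten_hz = s$background_flatten_hz, seed = s$seed)
  }
  band <- if (!is.null(l$band)) frequency_band(l$band$low_hz, l$band$high_hz)
  wl <- l$wavelet
  pipeline_config(
    wavelet = wavelet_params(
      freqs_hz = if (!is.null(wl$freqs_hz)) unlist(wl$freqs_hz),
      fwhm_s = wl$fwhm_s, fwhm_ref_hz = wl$fwhm_ref_hz, scaling = wl$scaling,
      f_lo = wl$f_lo, f_hi = wl$f_hi, f_step = wl$f_step,
      time_decim = wl$time_decim),
    fingerprint = do.call(fingerprint_params, l$fingerprint),
    detection = detection_params(
      z_threshold = l$detection$z_threshold, baseline = l$detection$baseline,
      min_baseline_windows = l$detection$min_baseline_windows,
      merge_gap_windows = l$detection$merge_gap_windows,
      threshold_mode = l$detection$threshold_mode),
    baseline_duration_s = l$baseline_duration_s, window_s = l$window_s,
    detection_mode = l$detection_mode, band = band,
    tolerance_windows = l$tolerance_windows, synthetic = syn)
}

pipeline_paths <- function(out_dir) {
  list(edf = file.path(out_dir, "recording.edf"),
       annotations = file.path(out_dir, "annotations.csv"),
       fingerprint = file.path(out_dir, "fingerprint.json"),
       events = file.path(out_dir, "events.csv"),
       report = file.path(out_dir, "report.json"))
}

timeline_path <- function(out_dir, channel)
  file.path(out_dir, sprintf("timeline_%s.json", channel))

#' Run the seizure-fingerprinting pipeline
#'
#' Executes the requested stage(s), reading inputs from and writing
#' artifacts to `out_dir`:
#' \describe{
#'   \item{simulate}{synthetic EMU dataset -> `recording.edf`,
#'     `annotations.csv`}
#'   \item{fingerprint}{Morlet PSD of the recruited channel, 15-min-baseline
#'     z-normalization, significant bands, sliding 5-Hz bin scan ->
#'     `fingerprint.json`}
#'   \item{detect}{band-power timeline per channel on the selected (or
#'     overridden) band, z-threshold detection -> `timeline_<CH>.json`,
#'     `events.csv`}
#'   \item{evaluate}{events vs the annotation diary -> `report.json`}
#' }
#' All artifacts are deterministic given the config (and its seed): no
#' timestamps are embedded.
#'
#' @param config a [pipeline_config()].
#' @param stage one of "all", "simulate", "fingerprint", "detect",
#'   "evaluate".
#' @param out_dir artifact directory (created if missing).
#' @param verbose print progress and the thresholds applied (default TRUE).
#' @return (invisibly) a list of the stage results computed in this call.
#' @export
run_pipeline <- function(config, stage = c("all", "simulate", "fingerprint",
                                           "detect", "evaluate"),
                         out_dir, verbose = TRUE) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- pipeline_paths(out_dir)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  out <- list()

  if (stage %in% c("all", "simulate")) {
    if (is.null(config$synthetic))
      stopf("simulate stage requires a synthetic config")
    say("simulate: %g s, %d seizure(s), seed %d", config$synthetic$duration_s,
        length(config$synthetic$seizures), config$synthetic$seed)
    ds <- generate_emu_dataset(config$synthetic)
    write_edf(ds$recording, paths$edf)
    write_annotations(ds$annotations, paths$annotations)
    out$simulate <- ds
  }

  if (stage %in% c("all", "fingerprint")) {
    if (!file.exists(paths$edf) || !file.exists(paths$annotations))
      stopf("fingerprint stage needs recording.edf and annotations.csv in %s (run simulate first)",
            out_dir)
    rec <- read_edf(paths$edf)
    ann <- read_annotations(paths$annotations, channels = rec$channel_labels)
    if (nrow(ann) == 0) stopf("no annotated seizures to fingerprint")
    ch <- names(sort(table(ann$channel), decreasing = TRUE))[1]
    ann_ch <- ann[ann$channel == ch, , drop = FALSE]
    bl_end <- min(ann_ch$onset_s)
    bl_start <- bl_end - config$baseline_duration_s
    if (bl_start < 0)
      stopf("no room for a %g-s pre-ictal baseline before the first seizure",
            config$baseline_duration_s)
    say("fingerprint: channel %s, %d seizure(s), baseline [%g, %g] s, z > %g",
        ch, nrow(ann_ch), bl_start, bl_end, config$fingerprint$z_threshold)
    spec <- morlet_psd(rec, ch, config$wavelet)
    bl <- baseline_stats(spec, c(bl_start, bl_end), annotations = ann,
                         min_duration_s = config$baseline_duration_s)
    norm <- zscore_normalize(spec, bl)
    intervals <- mapply(function(a, b) c(a, b), ann_ch$onset_s,
                        ann_ch$offset_s, SIMPLIFY = FALSE)
    fp <- fingerprint_seizures(norm, intervals, config$fingerprint)
    say("fingerprint: selected %.2f-%.2f Hz (center %.2f Hz)",
        fp$selected$low_hz, fp$selected$high_hz, fp$selected$center_hz)
    jsonlite::write_json(
      list(selected = list(low_hz = fp$selected$low_hz,
                           high_hz = fp$selected$high_hz,
                           center_hz = fp$selected$center_hz),
           score = fp$score,
           channel = ch,
           significant_bands = lapply(fp$significant_bands, function(b)
             list(low_hz = b$low_hz, high_hz = b$high_hz)),
           bin_scores = list(center_hz = fp$bin_scores$center_hz,
                             score = fp$bin_scores$score),
           params = strip_class(config$fingerprint),
           package_version = as.character(utils::packageVersion("pulvfp"))),
      paths$fingerprint, auto_unbox = TRUE, digits = NA)
    out$fingerprint <- fp
  }

  if (stage %in% c("all", "detect")) {
    if (!file.exists(paths$edf))
      stopf("detect stage needs recording.edf in %s", out_dir)
    band <- config$band
    if (is.null(band)) {
      if (!file.exists(paths$fingerprint))
        stopf("detect stage needs a band: run fingerprint first or set config$band")
      fpj <- jsonlite::read_json(paths$fingerprint, simplifyVector = TRUE)
      band <- frequency_band(fpj$selected$low_hz, fpj$selected$high_hz)
    }
    rec <- read_edf(paths$edf)
    say("detect: band %.2f-%.2f Hz, %s mode, %g-s windows, z > %g",
        band$low_hz, band$high_hz, config$detection_mode, config$window_s,
        config$detection$z_threshold)
    events <- list(); timelines <- list()
    for (ch in rec$channel_labels) {
      tl <- if (config$detection_mode == "fir")
        fir_band_power(rec, ch, band, config$window_s)
      else percept_timeline(rec, ch, band, config$window_s,
                            device_fs_hz = rec$fs_hz)
      write_timeline_json(tl, timeline_path(out_dir, ch))
      ev <- detect_events(tl, config$detection)
      say("detect: channel %s -> %d event(s) over %d windows", ch, nrow(ev),
          length(tl$values))
      events[[ch]] <- ev
      timelines[[ch]] <- tl
    }
    all_ev <- do.call(rbind, lapply(events, as.data.frame))
    rownames(all_ev) <- NULL
    write_events(all_ev, paths$events)
    out$detect <- list(events = all_ev, timelines = timelines, band = band)
  }

  if (stage %in% c("all", "evaluate")) {
    if (!file.exists(paths$events) || !file.exists(paths$annotations))
      stopf("evaluate stage needs events.csv and annotations.csv in %s", out_dir)
    ann <- read_annotations(paths$annotations)
    ev <- utils::read.csv(paths$events, stringsAsFactors = FALSE)
    # any channel's timeline provides the window geometry (all share it)
    tl_files <- list.files(out_dir, pattern = "^timeline_.*\\.json$",
                           full.names = TRUE)
    if (length(tl_files) == 0) stopf("no timeline artifacts in %s", out_dir)
    tl <- read_timeline_json(sort(tl_files)[1])
    rep <- evaluate_against_diary(ev, ann, tl, config$tolerance_windows)
    say("evaluate: %d/%d detected, %d false positive(s)", rep$n_detected,
        rep$n_true, rep$n_false_positive)
    jsonlite::write_json(
      list(n_true = rep$n_true, n_detected = rep$n_detected,
           n_false_positive = rep$n_false_positive, n_missed = rep$n_missed,
           tolerance_windows = rep$tolerance_windows,
           band = list(low_hz = tl$band$low_hz, high_hz = tl$band$high_hz),
           window_s = tl$window_s, mode = tl$mode,
           z_threshold = config$detection$z_threshold,
           package_version = as.character(utils::packageVersion("pulvfp"))),
      paths$report, auto_unbox = TRUE, digits = NA)
    out$evaluate <- rep
  }
  invisible(out)
}
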