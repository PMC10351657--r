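#' Frequency band
#'
#' Half-open interval `[low, high)` in Hz.
#'
#' @param low_hz,high_hz band edges in Hz, `high_hz > low_hz > 0`.
#' @return object of class `frequency_band` with `low_hz`, `high_hz`,
#'   `center_hz`.
#' @export
frequency_band <- function(low_hz, high_hz) {
  if (!is_scalar_num(low_hz) || !is_scalar_num(high_hz) ||
      high_hz <= low_hz || low_hz <= 0)
    stopf("need 0 < low_hz < high_hz")
  structure(list(low_hz = low_hz, high_hz = high_hz,
                 center_hz = (low_hz + high_hz) / 2),
            class = "frequency_band")
}

#' @export
print.frequency_band <- function(x, ...) {
  cat(sprintf("<frequency_band> %.2f-%.2f Hz (center %.2f)\n",
              x$low_hz, x$high_hz, x$center_hz))
  invisible(x)
}

#' Fingerprint-scan parameters
#'
#' @param z_threshold per-frequency significance threshold on the summary
#'   ictal z (default 3.3, a >99th-percentile increase over baseline).
#' @param bin_width_hz width of the candidate power-in-band bins in Hz
#'   (default 5, the band width the Percept device can sense).
#' @param bin_step_hz step of the sliding bin in Hz (default 0.05).
#' @param min_band_width_hz significant bands narrower than this are
#'   discarded (default 1).
#' @param summary_stat how ictal time samples are collapsed per frequency
#'   before thresholding/scoring: "median" (default), "mean" or "max".
#' @return object of class `fingerprint_params`.
#' @export
fingerprint_params <- function(z_threshold = 3.3, bin_width_hz = 5,
                               bin_step_hz = 0.05, min_band_width_hz = 1,
                               summary_stat = c("median", "mean", "max")) {
  summary_stat <- match.arg(summary_stat)
  if (any(c(z_threshold, bin_width_hz, bin_step_hz, min_band_width_hz) <= 0))
    stopf("all fingerprint parameters must be positive")
  structure(
    list(z_threshold = z_threshold, bin_width_hz = bin_width_hz,
         bin_step_hz = bin_step_hz, min_band_width_hz = min_band_width_hz,
         summary_stat = summary_stat),
    class = "fingerprint_params")
}

#' Significant ictal frequency bands of one seizure
#'
#' Collapses the ictal interval to one summary z per frequency, then returns
#' the maximal contiguous frequency runs whose summary z exceeds
#' `z_threshold`, as grid-snapped half-open bands. Runs narrower than
#' `min_band_width_hz` are discarded.
#'
#' @param norm a `normalized_spectrogram`.
#' @param seizure_interval_s numeric length-2, (onset, offset) seconds.
#' @param params a [fingerprint_params()].
#' @return list of [frequency_band()] objects (possibly empty).
#' @export
significant_bands <- function(norm, seizure_interval_s,
                              params = fingerprint_params()) {
  stopifnot(inherits(params, "fingerprint_params"))
  zsum <- ictal_summary(norm, seizure_interval_s, params$summary_stat)
  freqs <- norm$freqs_hz
  step <- if (length(freqs) > 1) stats::median(diff(freqs)) else 1
  above <- !is.na(zsum) & zsum > params$z_threshold
  bands <- list()
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    lo <- freqs[starts[k]]
    hi <- freqs[ends[k]] + step            # half-open upper edge
    if (hi - lo >= params$min_band_width_hz - 1e-9)
      bands[[length(bands) + 1]] <- frequency_band(lo, hi)
  }
  bands
}

#' Merge overlapping or touching frequency bands
#'
#' @param bands list of [frequency_band()] objects.
#' @return list of disjoint bands sorted by lower edge.
#' @export
merge_bands <- function(bands) {
  if (length(bands) == 0) return(list())
  lo <- vapply(bands, `[[`, 0, "low_hz")
  hi <- vapply(bands, `[[`, 0, "high_hz")
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  out <- list(); cl <- lo[1]; ch <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= ch + 1e-9) ch <- max(ch, hi[i])
    else { out[[length(out) + 1]] <- frequency_band(cl, ch); cl <- lo[i]; ch <- hi[i] }
  }
  out[[length(out) + 1]] <- frequency_band(cl, ch)
  out
}

#' Score sliding power-in-band bins across seizures
#'
#' The second-level scan: a bin of width `bin_width_hz` slides in steps of
#' `bin_step_hz` over each significant band (only positions fully inside the
#' band are kept). Per bin and per seizure, the summary ictal z is averaged
#' over the grid frequencies inside the half-open bin; the bin score is the
#' unweighted mean across seizures.
#'
#' @param norms list of `normalized_spectrogram`, one per seizure (a single
#'   object is accepted).
#' @param intervals list of (onset, offset) second pairs, one per seizure.
#' @param bands list of [frequency_band()] to scan.
#' @param params a [fingerprint_params()].
#' @return data.frame of class `bin_scores`: `low_hz`, `high_hz`,
#'   `center_hz`, `score`, sorted by centre; per-seizure scores in the
#'   `per_seizure` attribute (bins x seizures matrix).
#' @export
scan_bins <- function(norms, intervals, bands, params = fingerprint_params()) {
  if (inherits(norms, "normalized_spectrogram")) norms <- list(norms)
  if (is.numeric(intervals) && length(intervals) == 2) intervals <- list(intervals)
  if (length(norms) == 0) stopf("need at least one seizure spectrogram")
  if (length(norms) == 1 && length(intervals) > 1)
    norms <- rep(norms, length(intervals))  # seizures from one continuous record
  if (length(norms) != length(intervals))
    stopf("need one ictal interval per spectrogram")
  if (length(bands) == 0) stopf("no significant bands to scan")
  freqs <- norms[[1]]$freqs_hz
  for (nm in norms[-1])
    if (length(nm$freqs_hz) != length(freqs) ||
        any(abs(nm$freqs_hz - freqs) > 1e-9))
      stopf("all spectrograms must share one frequency axis")
  zsums <- mapply(function(nm, iv) ictal_summary(nm, iv, params$summary_stat),
                  norms, intervals, SIMPLIFY = FALSE)
  w <- params$bin_width_hz; stp <- params$bin_step_hz
  rows <- list(); per <- list()
  for (b in bands) {
    span <- b$high_hz - w - b$low_hz
    if (span < -1e-9) {
      warning(sprintf("band %.2f-%.2f Hz narrower than bin width %g Hz; skipped",
                      b$low_hz, b$high_hz, w))
      next
    }
    lows <- b$low_hz + stp * (0:floor(span / stp + 1e-9))
    for (lo in lows) {
      sel <- freqs >= lo - 1e-9 & freqs < lo + w - 1e-9
      if (!any(sel)) next
      ps <- vapply(zsums, function(z) mean(z[sel], na.rm = TRUE), 0)
      rows[[length(rows) + 1]] <- c(lo, lo + w, lo + w / 2, mean(ps))
      per[[length(per) + 1]] <- ps
    }
  }
  if (length(rows) == 0) stopf("no valid bins inside the given bands")
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("low_hz", "high_hz", "center_hz", "score")
  pm <- do.call(rbind, per)
  o <- order(df$center_hz)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "per_seizure") <- pm[o, , drop = FALSE]
  class(df) <- c("bin_scores", class(df))
  df
}

#' Select the spectral fingerprint from scored bins
#'
#' Argmax over bin scores; exact ties are broken toward the lower centre
#' frequency. Records full provenance (all scores, bands, parameters).
#'
#' @param scores a `bin_scores` data.frame from [scan_bins()].
#' @param significant_bands optional list of the bands that were scanned.
#' @param params optional [fingerprint_params()] used.
#' @return object of class `fingerprint_result` with `selected`
#'   ([frequency_band()]), `score`, `bin_scores`, `significant_bands`,
#'   `params`.
#' @export
select_fingerprint <- function(scores, significant_bands = NULL, params = NULL) {
  if (is.null(scores) || nrow(scores) == 0) stopf("no bin scores to select from")
  best <- which(scores$score == max(scores$score))
  best <- best[which.min(scores$center_hz[best])]
  structure(
    list(selected = frequency_band(scores$low_hz[best], scores$high_hz[best]),
         score = scores$score[best], bin_scores = scores,
         significant_bands = significant_bands, params = params),
    class = "fingerprint_result")
}

#' @export
print.fingerprint_result <- function(x, ...) {
  cat(sprintf("<fingerprint_result> selected %.2f-%.2f Hz (center %.2f Hz), mean ictal z = %.2f\n",
              x$selected$low_hz, x$selected$high_hz, x$selected$center_hz,
              x$score))
  if (length(x$significant_bands))
    cat("  significant bands:",
        paste(vapply(x$significant_bands,
                     function(b) sprintf("%.2f-%.2f", b$low_hz, b$high_hz), ""),
              collapse = ", "), "Hz\n")
  invisible(x)
}

#' Two-level fingerprint identification across seizures
#'
#' Convenience wrapper running the full first- and second-level analysis:
#' per-seizure significant bands (z > threshold), merged across seizures,
#' then the sliding 5-Hz bin scan and selection.
#'
#' @inheritParams scan_bins
#' @return a `fingerprint_result`.
#' @export
fingerprint_seizures <- function(norms, intervals,
                                 params = fingerprint_params()) {
  if (inherits(norms, "normalized_spectrogram")) norms <- list(norms)
  if (is.numeric(intervals) && length(intervals) == 2) intervals <- list(intervals)
  if (length(norms) == 1 && length(intervals) > 1)
    norms <- rep(norms, length(intervals))
  per_sz <- mapply(function(nm, iv) significant_bands(nm, iv, params),
                   norms, intervals, SIMPLIFY = FALSE)
  bands <- merge_bands(do.call(c, per_sz))
  if (length(bands) == 0)
    stopf("no frequency exceeds z = %g in any seizure", params$z_threshold)
  scores <- scan_bins(norms, intervals, bands, params)
  select_fingerprint(scores, significant_bands = bands, params = params)
}
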