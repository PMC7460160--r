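#' Construct a heart-rate sample stream
#'
#' A stream of wearable heart-rate readings at a nominal 1 Hz sampling rate.
#' Each sample carries a timestamp in seconds since session start, a reading
#' in beats per minute and the identity of the device that produced it.
#' Readings with a missing bpm (empty record) are kept as `NA` so that
#' [clean_stream()] can drop and count them.
#'
#' @param t Numeric vector of timestamps, seconds since session start;
#'   must be non-negative and non-decreasing.
#' @param bpm Numeric vector of readings in beats per minute; `NA` marks an
#'   empty record.
#' @param device Character vector (recycled), one of `"band1"`, `"band2"`,
#'   `"simulated"`.
#' @return A `data.frame` of class `hr_stream` with columns `t`, `bpm`,
#'   `device`.
#' @examples
#' hr_stream(t = 0:2, bpm = c(82, NA, 85), device = "band2")
#' @export
hr_stream <- function(t, bpm, device = "band1") {
  stopifnot(length(t) == length(bpm))
  device <- rep_len(as.character(device), length(t))
  bad <- setdiff(unique(device), HR_DEVICES)
  if (length(bad) > 0L) {
    stop("unknown device(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("timestamps must be finite and non-negative")
  }
  if (is.unsorted(t)) {
    stop("timestamps must be non-decreasing within a stream")
  }
  out <- data.frame(t = as.numeric(t), bpm = as.numeric(bpm),
                    device = device, stringsAsFactors = FALSE)
  class(out) <- c("hr_stream", "data.frame")
  out
}

HR_DEVICES <- c("band1", "band2", "simulated")

#' Calibration settings for inter-device offset and outlier bounds
#'
#' The two wearable bands used for acquisition differ systematically: the
#' second band reads 9.13 bpm higher on average than the first, so that
#' offset is subtracted from every band-2 reading. Readings outside hard
#' physiological bounds are treated as sensor outliers and suppressed by
#' [clean_stream()].
#'
#' @param band2_offset_bpm Offset in bpm subtracted from band-2 readings
#'   (default 9.13).
#' @param outlier_floor_bpm,outlier_ceiling_bpm Physiological bounds in bpm
#'   outside which a reading is discarded (defaults 40 and 220).
#' @return A list of class `calibration_config`.
#' @export
calibration_config <- function(band2_offset_bpm = 9.13,
                               outlier_floor_bpm = 40,
                               outlier_ceiling_bpm = 220) {
  if (!is.finite(band2_offset_bpm)) stop("offset must be finite")
  if (outlier_floor_bpm >= outlier_ceiling_bpm) {
    stop("outlier floor must be below ceiling")
  }
  structure(list(band2_offset_bpm = band2_offset_bpm,
                 outlier_floor_bpm = outlier_floor_bpm,
                 outlier_ceiling_bpm = outlier_ceiling_bpm),
            class = "calibration_config")
}

#' Scaling settings for mapping bpm onto [0, 1]
#'
#' The controllers smooth the signal with the mean of the last 20 *scaled*
#' readings, where scaling is a linear min-max map onto \[0, 1\] clamped at
#' the ends. The default range 60-200 bpm spans a child's resting-to-maximal
#' band and guarantees the unit codomain.
#'
#' @param hr_lo,hr_hi Scaling anchors in bpm mapped to 0 and 1
#'   (defaults 60 and 200). `hr_lo` must be below `hr_hi`.
#' @return A list of class `scale_config`.
#' @export
scale_config <- function(hr_lo = 60, hr_hi = 200) {
  if (!is.finite(hr_lo) || !is.finite(hr_hi) || hr_lo >= hr_hi) {
    stop("degenerate scale config: hr_lo must be below hr_hi")
  }
  structure(list(hr_lo = hr_lo, hr_hi = hr_hi), class = "scale_config")
}

#' Apply inter-device calibration to a stream
#'
#' Subtracts the configured band-2 offset from every band-2 reading; band-1
#' and simulated readings pass through unchanged (the offset is defined
#' relative to band 1, and simulated streams are already on that scale).
#' Timestamps and device labels are preserved.
#'
#' @param stream An [hr_stream()].
#' @param cfg A [calibration_config()].
#' @return The calibrated `hr_stream`.
#' @examples
#' s <- hr_stream(5, 100, "band2")
#' apply_calibration(s, calibration_config())$bpm  # 90.87
#' @export
apply_calibration <- function(stream, cfg = calibration_config()) {
  stopifnot(inherits(stream, "hr_stream"), inherits(cfg, "calibration_config"))
  if (any(is.infinite(stream$bpm))) {
    stop("signal-quality error: non-finite bpm reading")
  }
  i <- stream$device == "band2" & !is.na(stream$bpm)
  stream$bpm[i] <- stream$bpm[i] - cfg$band2_offset_bpm
  stream
}

#' Drop empty records and suppress outliers
#'
#' Removes readings whose bpm is missing (`NA`/`NaN`, an empty record) and
#' readings outside the configured physiological bounds, preserving order.
#' The number of removals of each kind is attached as attribute `removed`,
#' a named integer vector with elements `empty` and `outlier`.
#'
#' @param stream An [hr_stream()], time-ordered.
#' @param cfg A [calibration_config()] supplying the outlier bounds.
#' @return The cleaned `hr_stream`, with attribute `removed`.
#' @examples
#' s <- hr_stream(0:2, c(80, NA, 85))
#' attr(clean_stream(s), "removed")
#' @export
clean_stream <- function(stream, cfg = calibration_config()) {
  stopifnot(inherits(stream, "hr_stream"), inherits(cfg, "calibration_config"))
  empty <- is.na(stream$bpm)
  outlier <- !empty & (stream$bpm < cfg$outlier_floor_bpm |
                         stream$bpm > cfg$outlier_ceiling_bpm)
  out <- stream[!(empty | outlier), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    stop("no usable signal: every record was empty or out of bounds")
  }
  attr(out, "removed") <- c(empty = sum(empty), outlier = sum(outlier))
  class(out) <- c("hr_stream", "data.frame")
  out
}

#' Scale a bpm reading onto [0, 1]
#'
#' Linear min-max map `(bpm - hr_lo) / (hr_hi - hr_lo)`, clamped to \[0, 1\].
#' Vectorised over `bpm`.
#'
#' @param bpm Numeric reading(s) in beats per minute, finite.
#' @param cfg A [scale_config()].
#' @return Numeric in \[0, 1\].
#' @examples
#' scale_hr(c(60, 130, 200))  # 0, 0.5, 1
#' @export
scale_hr <- function(bpm, cfg = scale_config()) {
  stopifnot(inherits(cfg, "scale_config"))
  if (any(!is.finite(bpm))) stop("bpm must be finite")
  pmin(1, pmax(0, (bpm - cfg$hr_lo) / (cfg$hr_hi - cfg$hr_lo)))
}

#' Rolling 20-sample window of scaled heart-rate readings
#'
#' The controllers' smoothing weight `w` is the mean of the last 20 scaled
#' readings; `avgHR` is the mean of the raw (calibrated) readings over the
#' same window. The window is a bounded FIFO: pushing at capacity evicts the
#' oldest entry.
#'
#' @param capacity Window length in samples (default 20).
#' @return A list of class `scaled_window` with fields `capacity`, `values`
#'   (scaled, in \[0, 1\]) and `raw_values` (bpm), both initially empty.
#' @export
scaled_window <- function(capacity = 20L) {
  stopifnot(capacity >= 1L)
  structure(list(capacity = as.integer(capacity),
                 values = numeric(0), raw_values = numeric(0)),
            class = "scaled_window")
}

#' Push one calibrated sample into the rolling window
#'
#' @param window A [scaled_window()].
#' @param bpm A single calibrated, cleaned reading in bpm.
#' @param cfg A [scale_config()] used to scale the reading.
#' @return The updated `scaled_window`.
#' @export
push_sample <- function(window, bpm, cfg = scale_config()) {
  stopifnot(inherits(window, "scaled_window"), length(bpm) == 1L)
  window$values <- c(window$values, scale_hr(bpm, cfg))
  window$raw_values <- c(window$raw_values, bpm)
  if (length(window$values) > window$capacity) {
    keep <- seq.int(length(window$values) - window$capacity + 1L,
                    length(window$values))
    window$values <- window$values[keep]
    window$raw_values <- window$raw_values[keep]
  }
  window
}

#' Smoothing weight w: mean of the scaled window
#'
#' With fewer samples than the capacity, the mean is taken over the samples
#' available.
#'
#' @param window A non-empty [scaled_window()].
#' @return The weight `w` in \[0, 1\].
#' @export
window_weight <- function(window) {
  stopifnot(inherits(window, "scaled_window"))
  if (length(window$values) == 0L) stop("insufficient signal: empty window")
  mean(window$values)
}

#' Average heart rate over the rolling window
#'
#' Arithmetic mean of the raw (calibrated) bpm readings over the same window
#' that yields the weight `w`.
#'
#' @param window A non-empty [scaled_window()].
#' @return Mean bpm.
#' @export
avg_hr <- function(window) {
  stopifnot(inherits(window, "scaled_window"))
  if (length(window$raw_values) == 0L) {
    stop("insufficient signal: empty window")
  }
  mean(window$raw_values)
}

#' Read a heart-rate stream from CSV or JSON-lines
#'
#' CSV requires a `t,bpm,device` header; JSON-lines requires one object per
#' line with the same keys. A missing bpm (empty field or `null`) is kept as
#' `NA` so cleaning can count it.
#'
#' @param path File path; format inferred from the extension (`.csv` vs
#'   `.jsonl`/`.json`) unless `format` is given.
#' @param format `"csv"`, `"jsonl"` or `NULL` to infer.
#' @return An [hr_stream()].
#' @export
read_hr_stream <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.jsonl?$", path)) "jsonl" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("t", "bpm", "device")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0L) {
      stop("malformed header: missing column(s) ", paste(miss, collapse = ", "))
    }
    hr_stream(df$t, as.numeric(df$bpm), df$device)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    recs <- lapply(lines, jsonlite::fromJSON)
    bpm <- vapply(recs, function(r) {
      if (is.null(r$bpm)) NA_real_ else as.numeric(r$bpm)
    }, numeric(1))
    hr_stream(vapply(recs, function(r) as.numeric(r$t), numeric(1)),
              bpm,
              vapply(recs, function(r) as.character(r$device), character(1)))
  }
}

#' @export
print.hr_stream <- function(x, ...) {
  cat(sprintf("<hr_stream> %d samples, %.0f-%.0f s, devices: %s\n",
              nrow(x),
              if (nrow(x)) min(x$t) else NA, if (nrow(x)) max(x$t) else NA,
              paste(unique(x$device), collapse = ", ")))
  NextMethod()
}
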