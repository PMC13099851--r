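#' Calibration constants for a head-mounted recording
#'
#' Bundles the linear pixel/degree conversion and the angular defaults used
#' throughout the package. The scene camera is treated with a small-angle
#' linear model: `px = deg * px_per_deg`. The default of 13 px/degree is a
#' typical value for wide-angle scene cameras on mobile eye trackers; it must
#' be replaced with the device-specific value for real data.
#'
#' @param px_per_deg Pixels per degree of visual angle (> 0).
#' @param patch_side_deg Side length, in degrees, of the square scene patch
#'   used by the patch-matching stage (default 15).
#' @param min_saccade_amplitude_deg Minimum amplitude, in degrees, for a
#'   candidate group to count as a gaze shift (default 1).
#' @return An object of class `calibration_constants`.
#' @export
calibration_constants <- function(px_per_deg = 13,
                                  patch_side_deg = 15,
                                  min_saccade_amplitude_deg = 1) {
  stopifnot(
    is.numeric(px_per_deg), length(px_per_deg) == 1L, px_per_deg > 0,
    is.numeric(patch_side_deg), patch_side_deg > 0,
    is.numeric(min_saccade_amplitude_deg), min_saccade_amplitude_deg > 0
  )
  structure(
    list(
      px_per_deg = px_per_deg,
      patch_side_deg = patch_side_deg,
      min_saccade_amplitude_deg = min_saccade_amplitude_deg
    ),
    class = "calibration_constants"
  )
}

#' Convert degrees of visual angle to scene-camera pixels
#'
#' @param value_deg Angle(s) in degrees.
#' @param cal A [calibration_constants()] object.
#' @return Value(s) in pixels.
#' @export
deg_to_px <- function(value_deg, cal) {
  stopifnot(inherits(cal, "calibration_constants"))
  value_deg * cal$px_per_deg
}

#' Convert scene-camera pixels to degrees of visual angle
#'
#' @inheritParams deg_to_px
#' @param value_px Value(s) in pixels.
#' @return Angle(s) in degrees.
#' @export
px_to_deg <- function(value_px, cal) {
  stopifnot(inherits(cal, "calibration_constants"))
  value_px / cal$px_per_deg
}

#' Construct a gaze recording
#'
#' The per-sample gaze signal every detector consumes: strictly increasing
#' timestamps in milliseconds, gaze position in scene-camera pixel
#' coordinates (origin top-left, x rightward, y downward), and a per-sample
#' blink flag. Non-finite positions are forced to blink.
#'
#' @param timestamps Numeric vector of sample times in ms, strictly increasing.
#' @param x,y Gaze position in pixels; may be `NA` at blink samples.
#' @param blink Logical vector; `TRUE` where the tracker reported a blink.
#' @param sampling_rate Nominal rate in Hz; inferred from the median timestamp
#'   spacing when `NULL`.
#' @param px_per_deg Pixels per degree used for angular thresholds.
#' @return An object of class `gaze_recording`: a list with fields
#'   `timestamps`, `x`, `y`, `blink`, `sampling_rate`, `px_per_deg`.
#' @export
gaze_recording <- function(timestamps, x, y, blink = NULL,
                           sampling_rate = NULL, px_per_deg = 13) {
  timestamps <- as.numeric(timestamps)
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(timestamps)
  if (length(x) != n || length(y) != n) {
    stop("timestamps, x and y must have equal length", call. = FALSE)
  }
  if (n >= 2L && any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (is.null(blink)) blink <- rep(FALSE, n)
  blink <- as.logical(blink)
  if (length(blink) != n) stop("blink must match the number of samples", call. = FALSE)
  blink[!is.finite(x) | !is.finite(y)] <- TRUE
  if (is.null(sampling_rate)) {
    sampling_rate <- if (n >= 2L) 1000 / median(diff(timestamps)) else NA_real_
  }
  stopifnot(px_per_deg > 0)
  structure(
    list(
      timestamps = timestamps, x = x, y = y, blink = blink,
      sampling_rate = sampling_rate, px_per_deg = px_per_deg
    ),
    class = "gaze_recording"
  )
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf(
    "<gaze_recording> %d samples, %.1f-%.1f ms, %.0f Hz nominal, %.1f%% blink\n",
    length(x$timestamps),
    min(x$timestamps), max(x$timestamps),
    x$sampling_rate, 100 * mean(x$blink)
  ))
  invisible(x)
}

#' Read a gaze recording from CSV
#'
#' Expects the header `timestamp_ms,x_px,y_px,blink` with blink coded 0/1.
#' Rows with non-finite positions are forced to blink.
#'
#' @param path Path to the CSV file.
#' @param px_per_deg Pixels per degree of visual angle.
#' @return A [gaze_recording()].
#' @export
read_gaze_csv <- function(path, px_per_deg = 13) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_ms", "x_px", "y_px", "blink")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("gaze CSV is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  gaze_recording(
    timestamps = df$timestamp_ms,
    x = df$x_px, y = df$y_px,
    blink = df$blink != 0,
    px_per_deg = px_per_deg
  )
}

#' Write a gaze recording to CSV
#'
#' Inverse of [read_gaze_csv()]; round-trips valid recordings exactly up to
#' numeric printing.
#'
#' @param rec A [gaze_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaze_csv <- function(rec, path) {
  stopifnot(inherits(rec, "gaze_recording"))
  df <- data.frame(
    timestamp_ms = rec$timestamps,
    x_px = rec$x, y_px = rec$y,
    blink = as.integer(rec$blink)
  )
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

EVENT_LABELS <- c("saccade", "non_saccade", "blink")

#' Construct a set of labeled event intervals
#'
#' Intervals are half-open `[start_ms, end_ms)` in milliseconds, sorted and
#' non-overlapping, with labels among `saccade`, `non_saccade`, `blink`.
#' A sample belongs to the interval containing its timestamp; timestamps in
#' gaps are implicitly `non_saccade` when the set is densified.
#'
#' @param start_ms,end_ms Numeric vectors of interval bounds (ms).
#' @param label Character vector of labels.
#' @return A tibble of class `event_intervals` with columns
#'   `start_ms`, `end_ms`, `label`.
#' @export
event_intervals <- function(start_ms = numeric(), end_ms = numeric(),
                            label = character()) {
  ev <- tibble(
    start_ms = as.numeric(start_ms),
    end_ms = as.numeric(end_ms),
    label = as.character(label)
  )
  validate_event_intervals(ev)
}

validate_event_intervals <- function(ev) {
  stopifnot(all(c("start_ms", "end_ms", "label") %in% names(ev)))
  if (nrow(ev) > 0L) {
    if (any(!ev$label %in% EVENT_LABELS)) {
      stop("labels must be one of: ", paste(EVENT_LABELS, collapse = ", "),
           call. = FALSE)
    }
    if (any(ev$start_ms >= ev$end_ms)) {
      stop("every interval must satisfy start_ms < end_ms", call. = FALSE)
    }
    o <- order(ev$start_ms)
    ev <- ev[o, , drop = FALSE]
    if (nrow(ev) > 1L && any(ev$start_ms[-1L] < ev$end_ms[-nrow(ev)])) {
      stop("intervals must not overlap", call. = FALSE)
    }
  }
  class(ev) <- unique(c("event_intervals", class(ev)))
  ev
}

#' Densify event intervals onto a sample grid
#'
#' Assigns exactly one label to every timestamp: the label of the interval
#' containing it, or `non_saccade` for timestamps in gaps or outside the span.
#'
#' @param ev An [event_intervals()] object.
#' @param timestamps Numeric vector of sample times (ms).
#' @return Character vector of labels, one per timestamp.
#' @export
densify_events <- function(ev, timestamps) {
  labels <- rep("non_saccade", length(timestamps))
  if (nrow(ev) == 0L) return(labels)
  # half-open [start, end): sample at exactly end_ms belongs to the next interval
  idx <- findInterval(timestamps, ev$start_ms)
  hit <- idx >= 1L & timestamps < ev$end_ms[pmax(idx, 1L)]
  labels[hit] <- ev$label[idx[hit]]
  labels
}

#' Convert per-sample labels back to event intervals
#'
#' Each maximal run of a constant label becomes one interval; the end of a
#' run is the timestamp of the following sample (half-open convention), and
#' the final run is closed one median sample period past the last timestamp.
#'
#' @param labels Character vector of per-sample labels.
#' @param timestamps Matching numeric vector of sample times (ms).
#' @return An [event_intervals()] object covering the full span.
#' @export
events_from_labels <- function(labels, timestamps) {
  n <- length(labels)
  stopifnot(length(timestamps) == n)
  if (n == 0L) return(event_intervals())
  dt <- if (n >= 2L) median(diff(timestamps)) else 1
  r <- rle(labels)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- c(1L, head(ends_idx, -1L) + 1L)
  start_ms <- timestamps[starts_idx]
  end_ms <- c(timestamps[starts_idx[-1L]], timestamps[n] + dt)
  event_intervals(start_ms, end_ms, r$values)
}

#' Blink intervals of a recording
#'
#' @param rec A [gaze_recording()].
#' @return An [event_intervals()] with one `blink` interval per maximal
#'   blink run (possibly empty).
#' @export
blink_intervals <- function(rec) {
  stopifnot(inherits(rec, "gaze_recording"))
  ev <- events_from_labels(ifelse(rec$blink, "blink", "non_saccade"),
                           rec$timestamps)
  ev[ev$label == "blink", , drop = FALSE]
}

#' Recode gaps between fixations as saccades or blinks
#'
#' For datasets labeled as fixations only, the gaps between consecutive
#' fixations are reinterpreted: a gap lasting at most `gap_threshold_ms`
#' becomes a saccade, a longer gap becomes a blink. The rationale is that
#' saccades in classical main-sequence data are shorter than 100 ms unless
#' exceptionally large, while blinks typically last at least 150 ms, so a
#' long gap cannot be a gaze shift.
#'
#' @param fixation_intervals An [event_intervals()] containing only
#'   `non_saccade` (fixation) intervals.
#' @param gap_threshold_ms Gap duration above which a gap is a blink
#'   (default 100; a gap of exactly 100 ms is a saccade).
#' @return An [event_intervals()] covering the span from the first fixation
#'   start to the last fixation end.
#' @export
recode_gaps_as_blinks <- function(fixation_intervals, gap_threshold_ms = 100) {
  ev <- validate_event_intervals(fixation_intervals)
  if (any(ev$label != "non_saccade")) {
    stop("input must contain only non_saccade (fixation) intervals", call. = FALSE)
  }
  n <- nrow(ev)
  if (n <= 1L) return(ev)
  gap_start <- ev$end_ms[-n]
  gap_end <- ev$start_ms[-1L]
  gap_dur <- gap_end - gap_start
  keep <- gap_dur > 0
  gap_label <- ifelse(gap_dur[keep] <= gap_threshold_ms, "saccade", "blink")
  event_intervals(
    start_ms = c(ev$start_ms, gap_start[keep]),
    end_ms = c(ev$end_ms, gap_end[keep]),
    label = c(ev$label, gap_label)
  )
}

#' Read event intervals from CSV
#'
#' Expects the header `start_ms,end_ms,label`.
#'
#' @param path Path to the CSV file.
#' @return An [event_intervals()] object.
#' @export
read_event_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_ms", "end_ms", "label")
  if (!all(need %in% names(df))) {
    stop("event CSV must have columns start_ms,end_ms,label", call. = FALSE)
  }
  event_intervals(df$start_ms, df$end_ms, df$label)
}

#' Write event intervals to CSV
#'
#' @param ev An [event_intervals()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_csv <- function(ev, path) {
  ev <- validate_event_intervals(ev)
  write.csv(as.data.frame(ev)[c("start_ms", "end_ms", "label")], path,
            row.names = FALSE)
  invisible(path)
}

#' Read event intervals from JSON
#'
#' JSON mirror of the event CSV: an array of objects with fields
#' `start_ms`, `end_ms`, `label`.
#'
#' @param path Path to the JSON file.
#' @return An [event_intervals()] object.
#' @export
read_event_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  if (length(df) == 0L) return(event_intervals())
  event_intervals(df$start_ms, df$end_ms, df$label)
}

#' Write event intervals to JSON
#'
#' @inheritParams write_event_csv
#' @return `path`, invisibly.
#' @export
write_event_json <- function(ev, path) {
  ev <- validate_event_intervals(ev)
  jsonlite::write_json(as.data.frame(ev)[c("start_ms", "end_ms", "label")],
                       path, digits = NA)
  invisible(path)
}
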