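#' Parameters for the dispersion-threshold detector (I-DT)
#'
#' @param dispersion_threshold_px Maximum dispersion of a fixation window,
#'   in pixels (default 22, about 1.7 degrees at 13 px/degree).
#' @param min_fixation_ms Minimum fixation duration in ms (default 0,
#'   i.e. no duration constraint).
#' @return An object of class `idt_params`.
#' @export
idt_params <- function(dispersion_threshold_px = 22, min_fixation_ms = 0) {
  stopifnot(dispersion_threshold_px >= 0, min_fixation_ms >= 0)
  structure(list(dispersion_threshold_px = dispersion_threshold_px,
                 min_fixation_ms = min_fixation_ms),
            class = "idt_params")
}

#' Parameters for the velocity-threshold detector (I-VT)
#'
#' @param velocity_threshold_px_ms Velocity threshold in px/ms (default 2,
#'   about 150 degrees/s at 13 px/degree).
#' @param min_fixation_ms Minimum fixation duration in ms (default 0).
#' @return An object of class `ivt_params`.
#' @export
ivt_params <- function(velocity_threshold_px_ms = 2, min_fixation_ms = 0) {
  stopifnot(velocity_threshold_px_ms >= 0, min_fixation_ms >= 0)
  structure(list(velocity_threshold_px_ms = velocity_threshold_px_ms,
                 min_fixation_ms = min_fixation_ms),
            class = "ivt_params")
}

#' Parameters for the adaptive moving-window detector
#'
#' @param lambda Multiplier on the velocity standard deviation (default 3.5).
#' @param window_samples Samples per window (default 6000, about half a
#'   minute at 200 Hz).
#' @param max_iterations Iteration cap for the adaptive threshold
#'   (default 50).
#' @param min_fixation_ms Fixations shorter than this are relabeled saccade
#'   (default 60).
#' @param min_saccade_deg Saccades smaller than this amplitude are removed
#'   and their flanking fixations merged (default 1).
#' @return An object of class `moving_window_params`.
#' @export
moving_window_params <- function(lambda = 3.5, window_samples = 6000,
                                 max_iterations = 50,
                                 min_fixation_ms = 60,
                                 min_saccade_deg = 1) {
  stopifnot(lambda > 0, window_samples >= 3, max_iterations >= 1,
            min_fixation_ms >= 0, min_saccade_deg >= 0)
  structure(list(lambda = lambda, window_samples = as.integer(window_samples),
                 max_iterations = as.integer(max_iterations),
                 min_fixation_ms = min_fixation_ms,
                 min_saccade_deg = min_saccade_deg),
            class = "moving_window_params")
}

#' Dispersion of a set of gaze points
#'
#' The sum of the x-range and the y-range:
#' `D = [max(x) - min(x)] + [max(y) - min(y)]`.
#'
#' @param points Two-column matrix (or data frame) of finite `(x, y)`
#'   positions in pixels, at least one row.
#' @return Non-negative scalar, in pixels.
#' @export
dispersion <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 1L || any(!is.finite(points))) {
    stop("points must be a non-empty matrix of finite coordinates",
         call. = FALSE)
  }
  (max(points[, 1L]) - min(points[, 1L])) +
    (max(points[, 2L]) - min(points[, 2L]))
}

#' Dispersion-threshold identification (I-DT)
#'
#' Grows a window from each starting sample while the dispersion of the
#' contained points stays within the threshold; a window that can no longer
#' grow becomes a fixation if it lasts at least `min_fixation_ms`, and the
#' scan restarts after it. Samples that cannot open a window (the window of
#' that sample and its successor already exceeds the threshold) are
#' saccades. Windows need at least two samples: dispersion of a single
#' point is zero by construction, so single-sample windows carry no
#' evidence. Blinks break windows and are labeled `blink`.
#'
#' @param rec A [gaze_recording()].
#' @param params An [idt_params()].
#' @return An [event_intervals()] covering the recording span.
#' @export
detect_idt <- function(rec, params = idt_params()) {
  stopifnot(inherits(rec, "gaze_recording"), inherits(params, "idt_params"))
  n <- length(rec$timestamps)
  labels <- ifelse(rec$blink, "blink", "saccade")
  ts <- rec$timestamps
  for (seg in contiguous_segments(!rec$blink)) {
    i <- seg[1L]; last <- seg[2L]
    while (i <= last) {
      # initial window: span min_fixation_ms, never fewer than 2 samples
      j <- i + 1L
      while (j <= last && ts[j] - ts[i] < params$min_fixation_ms) j <- j + 1L
      if (j > last) { # tail too short to open a window
        labels[i:last] <- "saccade"
        break
      }
      pts <- cbind(rec$x[i:j], rec$y[i:j])
      if (dispersion(pts) > params$dispersion_threshold_px) {
        labels[i] <- "saccade"
        i <- i + 1L
      } else {
        while (j < last &&
               dispersion(cbind(rec$x[i:(j + 1L)], rec$y[i:(j + 1L)])) <=
                 params$dispersion_threshold_px) {
          j <- j + 1L
        }
        labels[i:j] <- "non_saccade"
        i <- j + 1L
      }
    }
  }
  events_from_labels(labels, ts)
}

#' Velocity-threshold identification (I-VT)
#'
#' Classifies each sample by its raw sample-to-sample velocity (Euclidean
#' step over elapsed time, attributed to the later sample): strictly above
#' the threshold is a saccade. Fixation runs shorter than `min_fixation_ms`
#' are then relabeled saccade. The first sample of each non-blink segment
#' has no velocity and is treated as below threshold.
#'
#' @param rec A [gaze_recording()].
#' @param params An [ivt_params()].
#' @return An [event_intervals()] covering the recording span.
#' @export
detect_ivt <- function(rec, params = ivt_params()) {
  stopifnot(inherits(rec, "gaze_recording"), inherits(params, "ivt_params"))
  labels <- ifelse(rec$blink, "blink", "non_saccade")
  ts <- rec$timestamps
  for (seg in contiguous_segments(!rec$blink)) {
    i0 <- seg[1L]; i1 <- seg[2L]
    if (i1 - i0 < 1L) next
    i <- (i0 + 1L):i1
    v <- sqrt((rec$x[i] - rec$x[i - 1L])^2 + (rec$y[i] - rec$y[i - 1L])^2) /
      (ts[i] - ts[i - 1L])
    labels[i][v > params$velocity_threshold_px_ms] <- "saccade"
  }
  labels <- relabel_short_fixations(labels, ts, params$min_fixation_ms)
  events_from_labels(labels, ts)
}

# Fixation (non_saccade) runs shorter than min_ms, bounded by saccades on
# the side(s) within the same non-blink segment, become saccade.
relabel_short_fixations <- function(labels, ts, min_ms) {
  if (min_ms <= 0) return(labels)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  dt <- if (length(ts) >= 2L) median(diff(ts)) else 1
  for (k in seq_along(r$values)) {
    if (r$values[k] != "non_saccade") next
    run_end <- if (ends[k] < length(ts)) ts[ends[k] + 1L] else ts[ends[k]] + dt
    if (run_end - ts[starts[k]] < min_ms) {
      labels[starts[k]:ends[k]] <- "saccade"
    }
  }
  labels
}

#' Adaptive moving-window saccade detection
#'
#' Splits the recording into consecutive windows of `window_samples`
#' samples. Within each window, velocities come from the three-point
#' parabola estimator; the threshold `mean + lambda * SD` is computed over
#' the retained velocities, samples exceeding it are removed, and the
#' process repeats until the threshold stabilizes (relative change below
#' 1e-6) or `max_iterations` is reached. Samples above the final threshold
#' are saccades. Fixations shorter than `min_fixation_ms` are then excluded
#' (relabeled saccade), and saccades with endpoint-to-endpoint amplitude
#' below `min_saccade_deg` are removed, merging their flanking fixations.
#'
#' @param rec A [gaze_recording()].
#' @param params A [moving_window_params()].
#' @return An [event_intervals()] covering the recording span.
#' @export
detect_moving_window <- function(rec, params = moving_window_params()) {
  stopifnot(inherits(rec, "gaze_recording"),
            inherits(params, "moving_window_params"))
  kin <- parabola_velocity(rec)
  n <- length(rec$timestamps)
  labels <- ifelse(rec$blink, "blink", "non_saccade")
  windows <- split(seq_len(n), (seq_len(n) - 1L) %/% params$window_samples)
  for (w in windows) {
    vw <- kin$speed[w]
    usable <- which(kin$valid[w] & is.finite(vw))
    if (length(usable) < 3L) next
    v <- vw[usable]
    retained <- rep(TRUE, length(v))
    thr <- Inf
    for (it in seq_len(params$max_iterations)) {
      m <- mean(v[retained])
      s <- sd(v[retained])
      if (!is.finite(s)) break
      new_thr <- m + params$lambda * s
      drop <- retained & v > new_thr
      conv <- is.finite(thr) &&
        abs(new_thr - thr) <= 1e-6 * max(abs(thr), 1e-12)
      thr <- new_thr
      if (!any(drop) || conv) break
      retained[drop] <- FALSE
      if (sum(retained) < 2L) break
    }
    sacc <- usable[v > thr]
    labels[w[sacc]] <- "saccade"
  }
  labels <- relabel_short_fixations(labels, rec$timestamps,
                                    params$min_fixation_ms)
  labels <- remove_small_saccades(labels, rec, params$min_saccade_deg)
  events_from_labels(labels, rec$timestamps)
}

# Saccade runs whose endpoint-to-endpoint displacement is below min_deg
# become non_saccade, merging the flanking fixations.
remove_small_saccades <- function(labels, rec, min_deg) {
  if (min_deg <= 0) return(labels)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  for (k in seq_along(r$values)) {
    if (r$values[k] != "saccade") next
    i0 <- starts[k]; i1 <- ends[k]
    # displacement measured across the step into and out of the run where
    # neighbours exist, to capture the full jump
    a <- max(1L, i0 - 1L)
    b <- min(length(labels), i1 + 1L)
    if (rec$blink[a]) a <- i0
    if (rec$blink[b]) b <- i1
    amp <- sqrt((rec$x[b] - rec$x[a])^2 + (rec$y[b] - rec$y[a])^2) /
      rec$px_per_deg
    if (!is.finite(amp) || amp < min_deg) {
      labels[i0:i1] <- "non_saccade"
    }
  }
  labels
}
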