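#' Segmentation parameters
#'
#' The thresholding-and-grouping grammar that turns a per-sample probability
#' trace into discrete gaze-shift events. All boundary conventions are
#' strict: probability strictly above `prob_threshold`, amplitude strictly
#' above `min_amplitude_deg`, step deviation strictly above
#' `direction_outlier_deg` removed, gaps strictly below `merge_window_ms`
#' trigger merge-or-discard, direction differences strictly below
#' `merge_direction_deg` merge.
#'
#' @param prob_threshold Probability threshold (default 0.5).
#' @param min_amplitude_deg Minimum gaze-shift amplitude in degrees
#'   (default 1).
#' @param direction_outlier_deg Per-sample step direction deviation, in
#'   degrees, beyond which the sample is pruned (default 90).
#' @param merge_window_ms Minimum interval between shifts in ms (default 50).
#' @param merge_direction_deg Direction difference, in degrees, below which
#'   two close shifts merge rather than the smaller being discarded
#'   (default 45).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(prob_threshold = 0.5,
                                min_amplitude_deg = 1,
                                direction_outlier_deg = 90,
                                merge_window_ms = 50,
                                merge_direction_deg = 45) {
  stopifnot(
    prob_threshold > 0, prob_threshold < 1,
    min_amplitude_deg > 0, direction_outlier_deg > 0,
    merge_window_ms > 0, merge_direction_deg > 0
  )
  structure(
    list(prob_threshold = prob_threshold,
         min_amplitude_deg = min_amplitude_deg,
         direction_outlier_deg = direction_outlier_deg,
         merge_window_ms = merge_window_ms,
         merge_direction_deg = merge_direction_deg),
    class = "segmentation_params"
  )
}

# One candidate gaze shift: the sample indices of a supra-threshold run and
# its endpoint-to-endpoint geometry.
candidate_group <- function(indices, rec) {
  first <- indices[1L]
  last <- indices[length(indices)]
  dx <- rec$x[last] - rec$x[first]
  dy <- rec$y[last] - rec$y[first]
  n <- length(rec$timestamps)
  dt <- if (n >= 2L) median(diff(rec$timestamps)) else 1
  list(
    indices = indices,
    start_ms = rec$timestamps[first],
    end_ms = if (last < n) rec$timestamps[last + 1L] else rec$timestamps[last] + dt,
    displacement = c(dx, dy),
    amplitude_deg = sqrt(dx^2 + dy^2) / rec$px_per_deg,
    direction_deg = direction_deg(dx, dy)
  )
}

# Direction of a displacement vector in [0, 360); y grows downward in image
# coordinates but the convention only needs to be internally consistent.
direction_deg <- function(dx, dy) {
  (atan2(dy, dx) * 180 / pi) %% 360
}

# Shortest angular distance between two directions, in [0, 180].
angle_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Threshold a probability trace and group consecutive samples
#'
#' Marks every sample whose probability strictly exceeds the threshold as a
#' potential component of a gaze shift and groups maximal consecutive runs.
#' Runs never span blink samples.
#'
#' @param p Numeric vector of per-sample probabilities, aligned with `rec`.
#' @param rec The [gaze_recording()] the probabilities were computed from.
#' @param params A [segmentation_params()].
#' @return List of candidate groups (see Details of [detect_ranking()]).
#' @export
threshold_and_group <- function(p, rec, params = segmentation_params()) {
  stopifnot(length(p) == length(rec$timestamps))
  marked <- !is.na(p) & p > params$prob_threshold & !rec$blink
  segs <- contiguous_segments(marked)
  lapply(segs, function(s) candidate_group(s[1L]:s[2L], rec))
}

#' Prune direction-outlier samples from a candidate group
#'
#' Compares each within-group step (sample-to-sample displacement,
#' attributed to the arriving sample) with the group's overall displacement
#' direction and removes, in a single pass, samples whose step deviates by
#' strictly more than `direction_outlier_deg` (shortest angular distance).
#' Zero-length steps are never outliers. The group displacement is
#' recomputed afterwards; a group reduced below 2 samples is discarded.
#'
#' @param group A candidate group from [threshold_and_group()].
#' @param rec The source [gaze_recording()].
#' @param params A [segmentation_params()].
#' @return The pruned group, or `NULL` if discarded.
#' @export
prune_direction_outliers <- function(group, rec,
                                     params = segmentation_params()) {
  idx <- group$indices
  if (length(idx) < 2L) return(group)
  sdx <- rec$x[idx[-1L]] - rec$x[idx[-length(idx)]]
  sdy <- rec$y[idx[-1L]] - rec$y[idx[-length(idx)]]
  step_dir <- direction_deg(sdx, sdy)
  zero <- sdx == 0 & sdy == 0
  dev <- angle_diff(step_dir, group$direction_deg)
  drop_arrivals <- idx[-1L][!zero & dev > params$direction_outlier_deg]
  kept <- setdiff(idx, drop_arrivals)
  if (length(kept) < 2L) return(NULL)
  candidate_group(kept, rec)
}

#' Filter candidate groups by amplitude
#'
#' A group only counts as a true gaze shift if its total eye rotation
#' strictly exceeds `min_amplitude_deg`; a group at exactly the threshold is
#' removed.
#'
#' @param groups List of candidate groups.
#' @param params A [segmentation_params()].
#' @return The retained groups.
#' @export
filter_amplitude <- function(groups, params = segmentation_params()) {
  Filter(function(g) g$amplitude_deg > params$min_amplitude_deg, groups)
}

#' Merge or discard gaze shifts closer than the minimum interval
#'
#' Enforces a minimum interval between shifts: scanning left to right,
#' whenever the offset-to-onset gap between consecutive shifts is strictly
#' below `merge_window_ms`, the two are merged into a single shift if their
#' directions differ by strictly less than `merge_direction_deg` (shortest
#' angular distance, displacement recomputed endpoint to endpoint);
#' otherwise the shift with the smaller amplitude is discarded. The scan
#' re-examines after every change until no pair violates the rule. Gaps
#' containing blink samples are never merged or discarded across, so no
#' output saccade overlaps a blink.
#'
#' @param groups Time-sorted list of candidate groups.
#' @param rec The source [gaze_recording()].
#' @param params A [segmentation_params()].
#' @return An [event_intervals()] covering the recording span with labels
#'   `saccade`, `non_saccade` and `blink`.
#' @export
merge_or_discard <- function(groups, rec, params = segmentation_params()) {
  gs <- groups[order(vapply(groups, `[[`, numeric(1), "start_ms"))]
  blink_between <- function(a, b) {
    span <- rec$timestamps > a$end_ms - 1e-9 & rec$timestamps < b$start_ms
    any(rec$blink[span])
  }
  i <- 1L
  while (i < length(gs)) {
    a <- gs[[i]]; b <- gs[[i + 1L]]
    gap <- b$start_ms - a$end_ms
    if (gap < params$merge_window_ms && !blink_between(a, b)) {
      if (angle_diff(a$direction_deg, b$direction_deg) <
          params$merge_direction_deg) {
        gs[[i]] <- candidate_group(
          union(a$indices, b$indices), rec
        )
        gs[[i + 1L]] <- NULL
      } else if (a$amplitude_deg >= b$amplitude_deg) {
        gs[[i + 1L]] <- NULL
      } else {
        gs[[i]] <- NULL
      }
      i <- max(1L, i - 1L)
    } else {
      i <- i + 1L
    }
  }
  groups_to_events(gs, rec)
}

# Candidate groups -> dense event intervals over the recording span.
groups_to_events <- function(groups, rec) {
  labels <- ifelse(rec$blink, "blink", "non_saccade")
  for (g in groups) {
    run <- seq.int(g$indices[1L], g$indices[length(g$indices)])
    labels[run] <- ifelse(rec$blink[run], "blink", "saccade")
  }
  events_from_labels(labels, rec$timestamps)
}

#' Detect gaze shifts with the rank-based probabilistic method
#'
#' Full pipeline: Savitzky-Golay kinematics, rank-based eye probabilities,
#' optional scene patch-matching probabilities fused by geometric mean, then
#' thresholding, direction pruning, amplitude filtering, and
#' merge-or-discard segmentation.
#'
#' @param rec A [gaze_recording()].
#' @param scene Optional [scene_sequence()]; when `NULL` the eye-only
#'   variant is used.
#' @param cal A [calibration_constants()]; defaults to the recording's
#'   `px_per_deg`.
#' @param params A [segmentation_params()].
#' @param top_fraction Calibration of the rank power transform
#'   (default 0.10).
#' @param window_ms Savitzky-Golay window (default 40 ms).
#' @param search A [search_policy()] for patch matching.
#' @param hold Frame-pair-to-sample assignment, `"zoh"` or `"linear"`.
#' @param variant `"auto"` (use scene when given), `"eye"` (force eye-only),
#'   or `"gaze"` (require scene).
#' @return An [event_intervals()] with labels `saccade`, `non_saccade`,
#'   `blink`, plus attributes `p_trace` (the per-sample probability tibble)
#'   and `variant`.
#' @export
detect_ranking <- function(rec, scene = NULL,
                           cal = NULL,
                           params = segmentation_params(),
                           top_fraction = 0.10,
                           window_ms = 40,
                           search = search_policy(),
                           hold = c("zoh", "linear"),
                           variant = c("auto", "eye", "gaze")) {
  hold <- match.arg(hold)
  variant <- match.arg(variant)
  if (is.null(cal)) {
    cal <- calibration_constants(px_per_deg = rec$px_per_deg)
  }
  if (variant == "gaze" && is.null(scene)) {
    stop("variant 'gaze' requires a scene sequence", call. = FALSE)
  }
  if (variant == "eye") scene <- NULL
  kin <- savgol_kinematics(rec, window_ms = window_ms)
  if (!any(kin$valid)) { # e.g. one long blink: nothing to rank
    ev <- groups_to_events(list(), rec)
    attr(ev, "variant") <- if (is.null(scene)) "eye" else "gaze"
    return(ev)
  }
  eye <- eye_probability(kin, top_fraction = top_fraction)
  sp <- if (!is.null(scene)) scene_probability(scene, rec, cal, search) else NULL
  fused <- fuse_probabilities(eye, sp, hold = hold)
  params_cal <- params
  params_cal$min_amplitude_deg <- max(params$min_amplitude_deg,
                                      cal$min_saccade_amplitude_deg)
  groups <- threshold_and_group(fused$p_gaze, rec, params_cal)
  groups <- Filter(Negate(is.null),
                   lapply(groups, prune_direction_outliers,
                          rec = rec, params = params_cal))
  groups <- filter_amplitude(groups, params_cal)
  ev <- merge_or_discard(groups, rec, params_cal)
  attr(ev, "p_trace") <- fused
  attr(ev, "variant") <- if (is.null(scene)) "eye" else "gaze"
  ev
}
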