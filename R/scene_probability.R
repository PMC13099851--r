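#' Search policy for patch matching
#'
#' Controls how [find_best_match()] slides the previous-gaze patch across the
#' current frame. `"exhaustive"` evaluates every valid center (stride 1) at
#' full resolution -- the literal procedure, O(W x H x patch) per frame pair.
#' `"two-stage"` (default) first searches exhaustively on a block-averaged
#' downsampled frame, then refines at full resolution within
#' `refine_radius_px` of the coarse optimum; on textured natural images this
#' preserves the optimum at a fraction of the cost.
#'
#' @param type `"two-stage"` or `"exhaustive"`.
#' @param downsample Integer block size of the coarse stage (default 4).
#' @param refine_radius_px Full-resolution refinement radius in pixels
#'   (default 8).
#' @param stride Center stride of the exhaustive search (default 1).
#' @return An object of class `search_policy`.
#' @export
search_policy <- function(type = c("two-stage", "exhaustive"),
                          downsample = 4L, refine_radius_px = 8L,
                          stride = 1L) {
  type <- match.arg(type)
  stopifnot(downsample >= 1L, refine_radius_px >= 0L, stride >= 1L)
  structure(
    list(type = type, downsample = as.integer(downsample),
         refine_radius_px = as.integer(refine_radius_px),
         stride = as.integer(stride)),
    class = "search_policy"
  )
}

#' Extract a square patch around a point
#'
#' Returns the `side_px x side_px` patch centered at `center`; when the
#' centered patch would exceed the frame, the center is clamped so the patch
#' lies fully inside. `side_px` is forced to the nearest odd integer so the
#' center pixel is well defined.
#'
#' @param frame `H x W x 3` numeric array.
#' @param center Numeric `(x, y)` in pixel coordinates (x = column,
#'   y = row, 1-based).
#' @param side_px Patch side in pixels.
#' @return A `side x side x 3` numeric array.
#' @export
extract_patch <- function(frame, center, side_px) {
  d <- dim(frame)
  side <- odd_int(side_px)
  if (side > d[1] || side > d[2]) {
    stop("patch side exceeds a frame dimension", call. = FALSE)
  }
  h <- (side - 1L) %/% 2L
  cx <- clamp_int(round(center[1L]), h + 1L, d[2] - h)
  cy <- clamp_int(round(center[2L]), h + 1L, d[1] - h)
  frame[(cy - h):(cy + h), (cx - h):(cx + h), , drop = FALSE]
}

#' Mean squared RGB difference between two patches
#'
#' Intensities are on the 0-255 scale; the mean (rather than sum) over
#' pixels and channels keeps values comparable across patch sizes. The
#' probability ratios built from these differences are insensitive to this
#' constant factor.
#'
#' @param a,b Same-sized numeric arrays.
#' @return Non-negative scalar.
#' @export
patch_difference <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("patches must have identical dimensions", call. = FALSE)
  }
  mean((a - b)^2)
}

#' Locate the best-matching region for a patch in a frame
#'
#' Slides `prev_patch` across `current_frame` and returns the center of the
#' window minimizing the mean squared RGB difference. Ties break
#' deterministically to the smallest y, then smallest x.
#'
#' @param prev_patch Square `s x s x 3` patch (s odd).
#' @param current_frame `H x W x 3` numeric array.
#' @param search A [search_policy()].
#' @return List with `center` (numeric `(x, y)`) and `delta` (the minimal
#'   mean squared difference).
#' @export
find_best_match <- function(prev_patch, current_frame,
                            search = search_policy()) {
  stopifnot(inherits(search, "search_policy"))
  d <- dim(current_frame)
  p <- dim(prev_patch)
  if (p[1] > d[1] || p[2] > d[2]) {
    stop("patch does not fit in frame", call. = FALSE)
  }
  if (search$type == "exhaustive") {
    return(ssd_argmin(prev_patch, current_frame, stride = search$stride))
  }
  f <- search$downsample
  coarse_ok <- f > 1L &&
    floor(d[1] / f) >= ceiling(p[1] / f) + 1L &&
    floor(d[2] / f) >= ceiling(p[2] / f) + 1L
  if (!coarse_ok) {
    return(ssd_argmin(prev_patch, current_frame, stride = search$stride))
  }
  frame_ds <- downsample_frame(current_frame, f)
  patch_ds <- downsample_frame(prev_patch, f)
  coarse <- ssd_topk(patch_ds, frame_ds, k = 4L)
  h <- c((p[2] - 1L) %/% 2L, (p[1] - 1L) %/% 2L) # x, y half-sides
  r <- search$refine_radius_px + f
  best <- NULL
  for (i in seq_len(nrow(coarse))) {
    # map each coarse candidate back to full resolution (block center)
    cx <- (coarse[i, 1L] - 1L) * f + (f + 1) / 2
    cy <- (coarse[i, 2L] - 1L) * f + (f + 1) / 2
    xs <- clamp_int(round(cx - r), h[1L] + 1L, d[2] - h[1L]):
          clamp_int(round(cx + r), h[1L] + 1L, d[2] - h[1L])
    ys <- clamp_int(round(cy - r), h[2L] + 1L, d[1] - h[2L]):
          clamp_int(round(cy + r), h[2L] + 1L, d[1] - h[2L])
    cand <- ssd_argmin(prev_patch, current_frame,
                       xs = unique(xs), ys = unique(ys))
    if (is.null(best) || cand$delta < best$delta ||
        (cand$delta == best$delta &&
         (cand$center[2L] < best$center[2L] ||
          (cand$center[2L] == best$center[2L] &&
           cand$center[1L] < best$center[1L])))) {
      best <- cand
    }
  }
  best
}

# The k best-scoring coarse centers (well separated: greedy selection
# suppressing neighbours within 2 px of an already chosen center).
ssd_topk <- function(patch, frame, k) {
  d <- dim(frame)
  p <- dim(patch)
  hx <- (p[2] - 1L) %/% 2L
  hy <- (p[1] - 1L) %/% 2L
  xs <- seq.int(hx + 1L, d[2] - hx)
  ys <- seq.int(hy + 1L, d[1] - hy)
  grid <- expand.grid(x = xs, y = ys)
  vals <- ssd_search_cpp(frame, d[1], d[2], patch, p[1], p[2],
                         as.integer(grid$y - 1L - hy),
                         as.integer(grid$x - 1L - hx))
  ord <- order(vals)
  picked <- matrix(0L, 0L, 2L)
  for (i in ord) {
    cand <- c(grid$x[i], grid$y[i])
    if (nrow(picked) == 0L ||
        all(abs(picked[, 1L] - cand[1L]) > 2L |
            abs(picked[, 2L] - cand[2L]) > 2L)) {
      picked <- rbind(picked, cand)
    }
    if (nrow(picked) >= k) break
  }
  picked
}

# Exhaustive SSD argmin over a center grid; candidates enumerated y-major so
# the first minimum realises the (smallest y, smallest x) tie-break.
ssd_argmin <- function(patch, frame, stride = 1L, xs = NULL, ys = NULL) {
  d <- dim(frame)
  p <- dim(patch)
  hx <- (p[2] - 1L) %/% 2L
  hy <- (p[1] - 1L) %/% 2L
  if (is.null(xs)) xs <- seq.int(hx + 1L, d[2] - hx, by = stride)
  if (is.null(ys)) ys <- seq.int(hy + 1L, d[1] - hy, by = stride)
  grid <- expand.grid(x = xs, y = ys) # x varies fastest within each y
  vals <- ssd_search_cpp(frame, d[1], d[2], patch, p[1], p[2],
                         as.integer(grid$y - 1L - hy),
                         as.integer(grid$x - 1L - hx))
  k <- which.min(vals)
  list(center = c(grid$x[k], grid$y[k]), delta = vals[k])
}

# Block-mean downsampling by integer factor f (trailing partial blocks
# dropped), applied per channel.
downsample_frame <- function(frame, f) {
  d <- dim(frame)
  H2 <- d[1] %/% f
  W2 <- d[2] %/% f
  out <- array(0, c(H2, W2, 3L))
  for (ch in 1:3) {
    M <- frame[seq_len(H2 * f), seq_len(W2 * f), ch]
    dim(M) <- c(f, H2, W2 * f)
    B <- colMeans(M)              # H2 x (W2*f)
    dim(B) <- c(H2, f, W2)
    out[, , ch] <- colMeans(aperm(B, c(2L, 1L, 3L)))
  }
  out
}

odd_int <- function(x) {
  s <- max(1L, as.integer(round(x)))
  if (s %% 2L == 0L) s + 1L else s
}

clamp_int <- function(x, lo, hi) as.integer(pmin(pmax(x, lo), hi))

#' Scene-based saccade probabilities for one frame pair
#'
#' Compares the visual content around three places: the gaze position in the
#' current frame, the gaze position in the previous frame, and the location
#' in the current frame that best matches the previously fixated patch.
#' Two probabilities result: `p1` asks how much worse the patch at current
#' gaze matches the previously fixated patch than the best match does,
#' relative to the same excess at the previous gaze position; `p2` compares
#' the distance from current gaze to the best-match location
#' ("not tracking") against the distance from the previous gaze to it
#' ("image shift"). Degenerate 0/0 denominators give `p1 = 0.5` (no
#' evidence) and `p2 = 0` (gaze coincides with the tracked patch).
#'
#' @param prev_frame,cur_frame `H x W x 3` numeric arrays.
#' @param prev_gaze,cur_gaze Numeric `(x, y)` gaze positions in pixels;
#'   must be finite (non-blink).
#' @param cal A [calibration_constants()]; fixes the patch side in degrees.
#' @param search A [search_policy()].
#' @return List with `p1`, `p2`, and `match` (a list holding
#'   `best_match_center`, `delta_best`, `delta_current_gaze`,
#'   `delta_previous_gaze`, `dist_not_tracking`, `dist_image_shift`).
#' @export
scene_pair_probability <- function(prev_frame, cur_frame, prev_gaze, cur_gaze,
                                   cal = calibration_constants(),
                                   search = search_policy()) {
  if (any(!is.finite(c(prev_gaze, cur_gaze)))) {
    stop("gaze positions must be finite (non-blink) for both frames",
         call. = FALSE)
  }
  side <- odd_int(deg_to_px(cal$patch_side_deg, cal))
  ref <- extract_patch(prev_frame, prev_gaze, side)
  s_cur <- extract_patch(cur_frame, cur_gaze, side)
  s_prev <- extract_patch(cur_frame, prev_gaze, side)
  best <- find_best_match(ref, cur_frame, search)
  # restricted search grids can make delta_best exceed the gaze deltas;
  # clamp the excesses at zero (impossible under exhaustive search)
  d_current <- max(0, patch_difference(s_cur, ref) - best$delta)
  d_previous <- max(0, patch_difference(s_prev, ref) - best$delta)
  p1 <- if (d_current + d_previous == 0) 0.5 else d_current / (d_current + d_previous)
  d_nt <- sqrt(sum((cur_gaze - best$center)^2))
  d_is <- sqrt(sum((prev_gaze - best$center)^2))
  p2 <- if (d_nt + d_is == 0) 0 else d_nt / (d_nt + d_is)
  list(
    p1 = p1, p2 = p2,
    match = list(
      best_match_center = best$center,
      delta_best = best$delta,
      delta_current_gaze = patch_difference(s_cur, ref),
      delta_previous_gaze = patch_difference(s_prev, ref),
      dist_not_tracking = d_nt,
      dist_image_shift = d_is
    )
  )
}

#' Combine the two scene probabilities
#'
#' Geometric mean of the patch-similarity and gaze-versus-match-distance
#' probabilities.
#'
#' @param p1,p2 Probabilities in `[0, 1]`.
#' @return `sqrt(p1 * p2)`.
#' @export
combine_scene <- function(p1, p2) {
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  sqrt(p1 * p2)
}

#' Scene probability trace over a frame sequence
#'
#' Applies [scene_pair_probability()] to every consecutive frame pair,
#' reading the gaze position at each frame time from the nearest recording
#' sample. Pairs where either frame falls in a blink (or has no sample
#' within one frame interval) are marked unavailable.
#'
#' @param scene A [scene_sequence()].
#' @param rec A [gaze_recording()] spanning the frame schedule.
#' @param cal A [calibration_constants()].
#' @param search A [search_policy()].
#' @return A tibble of class `scene_prob_trace` with columns
#'   `frame_timestamp_ms` (the later frame of each pair), `p1`, `p2`,
#'   `p_scene`, `available`, `not_tracking_px`, `image_shift_px`.
#' @export
scene_probability <- function(scene, rec, cal = calibration_constants(),
                              search = search_policy()) {
  stopifnot(inherits(scene, "scene_sequence"), inherits(rec, "gaze_recording"))
  nf <- length(scene$frames)
  if (nf < 2L) {
    out <- tibble(frame_timestamp_ms = numeric(), p1 = numeric(),
                  p2 = numeric(), p_scene = numeric(), available = logical(),
                  not_tracking_px = numeric(), image_shift_px = numeric())
    class(out) <- c("scene_prob_trace", class(out))
    return(out)
  }
  ft <- scene$frame_timestamps
  tol <- median(diff(ft))
  gaze_at <- function(t) {
    i <- which.min(abs(rec$timestamps - t))
    if (abs(rec$timestamps[i] - t) > tol || rec$blink[i]) return(NULL)
    c(rec$x[i], rec$y[i])
  }
  n <- nf - 1L
  p1 <- rep(NA_real_, n); p2 <- rep(NA_real_, n)
  nt <- rep(NA_real_, n); is_ <- rep(NA_real_, n)
  avail <- rep(FALSE, n)
  for (j in seq_len(n)) {
    g_prev <- gaze_at(ft[j])
    g_cur <- gaze_at(ft[j + 1L])
    if (is.null(g_prev) || is.null(g_cur)) next
    r <- scene_pair_probability(scene$frames[[j]], scene$frames[[j + 1L]],
                                g_prev, g_cur, cal, search)
    p1[j] <- r$p1; p2[j] <- r$p2
    nt[j] <- r$match$dist_not_tracking
    is_[j] <- r$match$dist_image_shift
    avail[j] <- TRUE
  }
  out <- tibble(
    frame_timestamp_ms = ft[-1L],
    p1 = p1, p2 = p2,
    p_scene = ifelse(avail, combine_scene(ifelse(avail, p1, 0),
                                          ifelse(avail, p2, 0)), NA_real_),
    available = avail,
    not_tracking_px = nt, image_shift_px = is_
  )
  attr(out, "first_frame_ms") <- ft[1L]
  class(out) <- c("scene_prob_trace", class(out))
  out
}

#' Fuse eye- and scene-based probabilities
#'
#' Pairs every eye sample with the scene probability of the frame pair whose
#' interval `(t[f-1], t[f]]` contains it (zero-order hold, or linear
#' interpolation across pair midpoints with `hold = "linear"`), and takes
#' the geometric mean `p_gaze = sqrt(p_scene * p_eye)`. Samples with no
#' usable frame pair (blink frames, outside the frame span, or no scene at
#' all) fall back to the eye-only probability and are flagged.
#'
#' @param eye A `rank_prob_trace` from [eye_probability()].
#' @param scene_prob A `scene_prob_trace` from [scene_probability()], or
#'   `NULL` for the eye-only variant.
#' @param hold `"zoh"` (default) or `"linear"`.
#' @return A tibble with columns `timestamp_ms`, `p_eye`, `p_scene`,
#'   `p_gaze`, `mode` (`"fused"` or `"eye-only"`).
#' @export
fuse_probabilities <- function(eye, scene_prob = NULL,
                               hold = c("zoh", "linear")) {
  hold <- match.arg(hold)
  stopifnot(inherits(eye, "rank_prob_trace"))
  ts <- eye$timestamp_ms
  n <- length(ts)
  p_scene <- rep(NA_real_, n)
  if (!is.null(scene_prob) && nrow(scene_prob) > 0L) {
    av <- scene_prob$available
    ft_end <- scene_prob$frame_timestamp_ms
    first <- attr(scene_prob, "first_frame_ms")
    if (is.null(first)) {
      spacing <- if (length(ft_end) >= 2L) median(diff(ft_end)) else 1000 / 30
      first <- ft_end[1L] - spacing
    }
    ft_all <- c(first, ft_end)
    if (hold == "zoh") {
      # pair j covers (ft_all[j], ft_all[j+1]]
      i <- findInterval(ts, ft_all, left.open = TRUE)
      ok <- i >= 1L & i <= nrow(scene_prob)
      ok[ok] <- av[i[ok]]
      p_scene[ok] <- scene_prob$p_scene[i[ok]]
    } else {
      if (sum(av) >= 2L) {
        p_scene <- approx(ft_end[av], scene_prob$p_scene[av], xout = ts,
                          rule = 1)$y
      }
    }
  }
  fused <- !is.na(p_scene)
  tibble(
    timestamp_ms = ts,
    p_eye = eye$p_eye,
    p_scene = p_scene,
    p_gaze = ifelse(fused, sqrt(p_scene * eye$p_eye), eye$p_eye),
    mode = ifelse(fused, "fused", "eye-only")
  )
}

#' Write a scene-probability dump
#'
#' @param scene_prob A `scene_prob_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scene_probability_csv <- function(scene_prob, path) {
  write.csv(
    data.frame(
      frame_timestamp_ms = scene_prob$frame_timestamp_ms,
      p1 = scene_prob$p1, p2 = scene_prob$p2, p_scene = scene_prob$p_scene,
      not_tracking_px = scene_prob$not_tracking_px,
      image_shift_px = scene_prob$image_shift_px
    ),
    path, row.names = FALSE, na = ""
  )
  invisible(path)
}
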