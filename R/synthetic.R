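#' Scenario configuration for the synthetic recording generator
#'
#' Describes a simulated mobile eye-tracking session: a 200-Hz gaze trace of
#' alternating fixations and saccades (with optional blinks and VOR-like
#' tracking phases under head motion) paired with 30-Hz textured scene
#' frames. Saccade durations follow a main-sequence-like linear rule,
#' `duration_ms = 20 + 2 * amplitude_deg`, capped at 95 ms so every saccade
#' stays below the 100-ms bound of classical main-sequence data. Saccade
#' displacement follows a minimum-jerk profile, which places the velocity
#' peak mid-movement and the acceleration peaks at onset and offset.
#'
#' @param duration_s Recording length in seconds.
#' @param sampling_rate_hz Gaze sampling rate (default 200).
#' @param frame_rate_hz Scene frame rate (default 30).
#' @param n_saccades Number of saccades to schedule.
#' @param amplitude_range_deg Min/max saccade amplitude in degrees.
#' @param fixation_noise_sd_deg Gaussian jitter SD during all non-blink
#'   samples, degrees.
#' @param drift_velocity_deg_s Slow linear drift during fixations, deg/s
#'   (a random direction per fixation).
#' @param blink_rate_hz Expected blinks per second (default 0).
#' @param blink_duration_ms Blink duration (default 180, at least the
#'   ~150 ms physiological minimum).
#' @param blink_shift_deg Gaze displacement across each blink, degrees
#'   (default 0).
#' @param head_translation_px_per_frame Length-2 vector: image translation
#'   of the scene per frame caused by head motion. During fixations gaze
#'   rides a fixed scene location, so it translates along in image
#'   coordinates (a VOR/OKN-like slow phase).
#' @param n_objects Number of distinct high-contrast objects (at most; one
#'   per distinct fixation anchor).
#' @param object_size_px Object side length in pixels.
#' @param frame_size_px Square frame side in pixels.
#' @param patch_side_deg Side of the patch-matching window assumed when
#'   keeping gaze away from the frame border (default 15, matching the
#'   detector default).
#' @param px_per_deg Pixels per degree of the simulated scene camera.
#' @param background_texture_seed Seed of the background texture; derived
#'   from `rng_seed` when `NULL`.
#' @param rng_seed Integer seed; scenario plus seed fully determine every
#'   generated byte.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(duration_s = 10,
                            sampling_rate_hz = 200,
                            frame_rate_hz = 30,
                            n_saccades = 20,
                            amplitude_range_deg = c(5, 15),
                            fixation_noise_sd_deg = 0.05,
                            drift_velocity_deg_s = 0,
                            blink_rate_hz = 0,
                            blink_duration_ms = 180,
                            blink_shift_deg = 0,
                            head_translation_px_per_frame = c(0, 0),
                            n_objects = 6,
                            object_size_px = 24,
                            frame_size_px = 512,
                            patch_side_deg = 15,
                            px_per_deg = 13,
                            background_texture_seed = NULL,
                            rng_seed = 1) {
  stopifnot(
    duration_s > 0, sampling_rate_hz > 0, frame_rate_hz > 0,
    n_saccades >= 0, length(amplitude_range_deg) == 2L,
    amplitude_range_deg[1] > 0,
    amplitude_range_deg[2] >= amplitude_range_deg[1],
    fixation_noise_sd_deg >= 0, drift_velocity_deg_s >= 0,
    blink_rate_hz >= 0, blink_duration_ms > 0, blink_shift_deg >= 0,
    length(head_translation_px_per_frame) == 2L,
    n_objects >= 0, object_size_px > 0, frame_size_px > 16,
    patch_side_deg > 0, px_per_deg > 0
  )
  if (is.null(background_texture_seed)) {
    background_texture_seed <- (as.integer(rng_seed) %% 100000L) * 7919L + 101L
  }
  structure(
    list(duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
         frame_rate_hz = frame_rate_hz, n_saccades = n_saccades,
         amplitude_range_deg = amplitude_range_deg,
         fixation_noise_sd_deg = fixation_noise_sd_deg,
         drift_velocity_deg_s = drift_velocity_deg_s,
         blink_rate_hz = blink_rate_hz,
         blink_duration_ms = blink_duration_ms,
         blink_shift_deg = blink_shift_deg,
         head_translation_px_per_frame = head_translation_px_per_frame,
         n_objects = n_objects, object_size_px = object_size_px,
         frame_size_px = frame_size_px, patch_side_deg = patch_side_deg,
         px_per_deg = px_per_deg,
         background_texture_seed = background_texture_seed,
         rng_seed = as.integer(rng_seed)),
    class = "scenario_config"
  )
}

#' Saccade duration from amplitude
#'
#' Main-sequence-like linear stand-in: `20 + 2 * amplitude_deg` ms, capped
#' at 95 ms. A fixture rule, not a physiological claim; it is monotone and
#' keeps every simulated saccade under 100 ms.
#'
#' @param amplitude_deg Saccade amplitude(s) in degrees.
#' @return Duration(s) in ms.
#' @export
saccade_duration_ms <- function(amplitude_deg) {
  pmin(20 + 2 * amplitude_deg, 95)
}

# Minimum-jerk displacement profile on tau in [0, 1].
minimum_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# Image translation of the scene at time t (ms) under head motion.
head_offset <- function(cfg, t_ms) {
  f <- t_ms * cfg$frame_rate_hz / 1000
  cbind(cfg$head_translation_px_per_frame[1L] * f,
        cfg$head_translation_px_per_frame[2L] * f)
}

# Margin keeping gaze -- and the 15-degree patch around it, plus slack for
# per-frame head translation -- inside the frame.
frame_margin <- function(cfg) {
  patch_half <- ceiling(cfg$patch_side_deg * cfg$px_per_deg / 2)
  slack <- ceiling(max(abs(cfg$head_translation_px_per_frame))) + 8L
  max(cfg$object_size_px, patch_half + slack)
}

# Pick a direction for a displacement of length amp_px from img position
# `from`, such that the landing point and the point after the subsequent
# drift `drift_px` both stay inside [margin, size - margin]^2. Tries
# jittered candidate angles; falls back to the least-violating one.
choose_direction <- function(from, amp_px, drift_px, cfg) {
  m <- frame_margin(cfg)
  lo <- m; hi <- cfg$frame_size_px - m
  angles <- runif(24L, 0, 2 * pi)
  viol <- function(p) {
    sum(pmax(lo - p, 0) + pmax(p - hi, 0))
  }
  best <- NULL; best_v <- Inf
  for (th in angles) {
    u <- c(cos(th), sin(th))
    q0 <- from + amp_px * u
    q1 <- q0 + drift_px
    v <- viol(q0) + viol(q1)
    if (v == 0) return(th)
    if (v < best_v) { best_v <- v; best <- th }
  }
  best
}

#' Simulate a gaze recording with exact ground truth
#'
#' Generates alternating fixations and saccades on the sample grid.
#' Fixation anchors are fixed scene locations: under head motion the gaze
#' point rides its anchor, so it translates across the image like a VOR/OKN
#' slow phase. Saccades move between anchors along a minimum-jerk profile.
#' Blinks blank the gaze (`NA`, blink flag set) and may displace the anchor.
#' Ground-truth intervals are exact by construction and every output is
#' reproducible from `rng_seed`.
#'
#' @param cfg A [scenario_config()].
#' @return List with `gaze` (a [gaze_recording()]) and `truth`
#'   (an [event_intervals()] covering the full span).
#' @export
simulate_gaze <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  withr::with_seed(cfg$rng_seed, simulate_gaze_impl(cfg))
}

simulate_gaze_impl <- function(cfg) {
  dt <- 1000 / cfg$sampling_rate_hz
  n <- round(cfg$duration_s * 1000 / dt)
  ts <- (seq_len(n) - 1L) * dt
  size <- cfg$frame_size_px
  m <- frame_margin(cfg)
  ppd <- cfg$px_per_deg

  # --- schedule saccades in evenly spaced slots with jitter ---
  amps_deg <- runif(cfg$n_saccades, cfg$amplitude_range_deg[1L],
                    cfg$amplitude_range_deg[2L])
  dur_samp <- pmax(2L, round(saccade_duration_ms(amps_deg) / dt))
  onsets <- integer(0)
  if (cfg$n_saccades > 0L) {
    lo <- ceiling(0.05 * n); hi <- floor(0.95 * n)
    slot <- (hi - lo) / cfg$n_saccades
    gap <- ceiling(100 / dt) # >= 100 ms fixation before each saccade
    for (k in seq_len(cfg$n_saccades)) {
      s0 <- lo + round((k - 1) * slot)
      play <- max(0, floor(slot) - dur_samp[k] - gap)
      onsets[k] <- s0 + gap + sample.int(play + 1L, 1L) - 1L
    }
  }
  sacc_runs <- Map(function(o, d) c(o, min(o + d - 1L, n)), onsets, dur_samp)

  # --- schedule blinks inside fixations, never touching a saccade ---
  in_saccade <- rep(FALSE, n)
  for (r in sacc_runs) in_saccade[r[1L]:r[2L]] <- TRUE
  blink_samp <- max(2L, round(cfg$blink_duration_ms / dt))
  n_blinks <- round(cfg$blink_rate_hz * cfg$duration_s)
  pad <- ceiling(50 / dt)
  blink_runs <- list()
  occupied <- in_saccade
  for (b in seq_len(n_blinks)) {
    for (try in seq_len(200L)) {
      o <- sample.int(n - blink_samp - 2L * pad, 1L) + pad
      run <- (o - pad):(o + blink_samp - 1L + pad)
      if (!any(occupied[run])) {
        blink_runs[[length(blink_runs) + 1L]] <- c(o, o + blink_samp - 1L)
        occupied[run] <- TRUE
        break
      }
    }
  }

  # --- anchors: scene-fixed fixation targets between the saccades ---
  off <- head_offset(cfg, ts)
  drift_deg_ms <- cfg$drift_velocity_deg_s / 1000
  boundaries <- c(vapply(sacc_runs, `[`, numeric(1), 1L), n + 1L)
  anchor <- c(runif(1, m, size - m), runif(1, m, size - m))
  if (cfg$n_saccades > 0L) {
    # first anchor must allow the first (possibly large) saccade
    amp_px1 <- amps_deg[1L] * ppd
    for (try in seq_len(100L)) {
      cand <- c(runif(1, m, size - m), runif(1, m, size - m))
      from_img <- cand + off[min(boundaries[1L], n), ]
      if (any(from_img < m | from_img > size - m)) next
      th <- choose_direction(from_img, amp_px1, c(0, 0), cfg)
      q <- from_img + amp_px1 * c(cos(th), sin(th))
      if (all(q >= m & q <= size - m)) { anchor <- cand; break }
    }
  }
  anchors <- matrix(NA_real_, cfg$n_saccades + 1L, 2L)
  anchors[1L, ] <- anchor
  for (k in seq_len(cfg$n_saccades)) {
    r <- sacc_runs[[k]]
    t_off <- ts[min(r[2L] + 1L, n)]
    t_next_end <- ts[min(boundaries[k + 1L], n)]
    from_img <- anchors[k, ] + head_offset(cfg, t_off)[1L, ]
    drift_px <- head_offset(cfg, t_next_end)[1L, ] -
      head_offset(cfg, t_off)[1L, ]
    th <- choose_direction(from_img, amps_deg[k] * ppd, drift_px, cfg)
    anchors[k + 1L, ] <- anchors[k, ] +
      amps_deg[k] * ppd * c(cos(th), sin(th))
  }

  # --- assemble the per-sample anchor path ---
  path <- matrix(NA_real_, n, 2L)
  seg_anchor <- anchors[1L, ]
  k <- 1L
  i <- 1L
  sacc_start <- vapply(sacc_runs, `[`, numeric(1), 1L)
  labels <- rep("non_saccade", n)
  while (i <= n) {
    if (k <= cfg$n_saccades && i == sacc_start[k]) {
      r <- sacc_runs[[k]]
      idx <- r[1L]:r[2L]
      dur_ms <- (length(idx)) * dt
      tau <- (ts[idx] - ts[r[1L]]) / dur_ms
      s <- minimum_jerk(tau)
      path[idx, 1L] <- anchors[k, 1L] + (anchors[k + 1L, 1L] - anchors[k, 1L]) * s
      path[idx, 2L] <- anchors[k, 2L] + (anchors[k + 1L, 2L] - anchors[k, 2L]) * s
      labels[idx] <- "saccade"
      seg_anchor <- anchors[k + 1L, ]
      k <- k + 1L
      i <- r[2L] + 1L
    } else {
      nxt <- if (k <= cfg$n_saccades) sacc_start[k] else n + 1L
      idx <- i:(nxt - 1L)
      # per-fixation random drift direction (slow OKN-like component)
      if (drift_deg_ms > 0) {
        thd <- runif(1, 0, 2 * pi)
        d <- drift_deg_ms * ppd * (ts[idx] - ts[idx[1L]])
        path[idx, 1L] <- seg_anchor[1L] + d * cos(thd)
        path[idx, 2L] <- seg_anchor[2L] + d * sin(thd)
      } else {
        path[idx, 1L] <- seg_anchor[1L]
        path[idx, 2L] <- seg_anchor[2L]
      }
      i <- nxt
    }
  }

  # --- blinks: blank the gaze, optionally displace the anchor ---
  blink <- rep(FALSE, n)
  for (r in blink_runs) {
    idx <- r[1L]:r[2L]
    blink[idx] <- TRUE
    labels[idx] <- "blink"
    if (cfg$blink_shift_deg > 0 && r[2L] + 1L <= n) {
      after <- (r[2L] + 1L):n
      from_img <- path[r[2L] + 1L, ] + off[r[2L] + 1L, ]
      th <- choose_direction(from_img, cfg$blink_shift_deg * ppd, c(0, 0), cfg)
      shift <- cfg$blink_shift_deg * ppd * c(cos(th), sin(th))
      # shift persists only through the current fixation (next saccade
      # re-anchors explicitly), but cutting at the next saccade would
      # change its landing point; shift the remainder of this fixation only
      seg_end <- after[labels[after] != "non_saccade"][1L]
      seg_end <- if (is.na(seg_end)) n else seg_end - 1L
      if (r[2L] + 1L <= seg_end) {
        path[(r[2L] + 1L):seg_end, 1L] <- path[(r[2L] + 1L):seg_end, 1L] + shift[1L]
        path[(r[2L] + 1L):seg_end, 2L] <- path[(r[2L] + 1L):seg_end, 2L] + shift[2L]
      }
    }
  }

  sd_px <- cfg$fixation_noise_sd_deg * ppd
  x <- path[, 1L] + off[, 1L] + rnorm(n, 0, sd_px)
  y <- path[, 2L] + off[, 2L] + rnorm(n, 0, sd_px)
  x[blink] <- NA_real_
  y[blink] <- NA_real_

  gaze <- gaze_recording(ts, x, y, blink,
                         sampling_rate = cfg$sampling_rate_hz,
                         px_per_deg = ppd)
  truth <- events_from_labels(labels, ts)
  list(gaze = gaze, truth = truth)
}

# Circular (torus) box blur of a matrix, radius r, one pass per axis.
blur_circular <- function(M, r) {
  H <- nrow(M); W <- ncol(M)
  row_shift <- function(M, s) M[((seq_len(H) - 1L + s) %% H) + 1L, , drop = FALSE]
  col_shift <- function(M, s) M[, ((seq_len(W) - 1L + s) %% W) + 1L, drop = FALSE]
  A <- Reduce(`+`, lapply(-r:r, function(s) row_shift(M, s))) / (2 * r + 1)
  Reduce(`+`, lapply(-r:r, function(s) col_shift(A, s))) / (2 * r + 1)
}

#' Render scene frames consistent with a simulated gaze trace
#'
#' Produces frames of a procedurally textured background (seeded smoothed
#' noise with high local contrast) translated by
#' `head_translation_px_per_frame` each frame, with one distinct
#' high-contrast object at every fixation anchor the gaze trace visits.
#' Because the anchors are recovered from the gaze trace itself (median
#' gaze position minus the head offset within each fixation), the rendered
#' scene is exactly consistent with the trace: during fixations the gaze
#' rides a scene location, and saccades jump between objects.
#'
#' @param cfg The [scenario_config()] used to simulate the gaze.
#' @param gaze The simulated [gaze_recording()].
#' @param truth Its ground-truth [event_intervals()].
#' @return A [scene_sequence()].
#' @export
simulate_scene <- function(cfg, gaze, truth) {
  stopifnot(inherits(cfg, "scenario_config"),
            inherits(gaze, "gaze_recording"))
  if (cfg$object_size_px >= cfg$frame_size_px) {
    stop("objects do not fit in the frame", call. = FALSE)
  }
  size <- cfg$frame_size_px
  ft <- seq(0, max(gaze$timestamps), by = 1000 / cfg$frame_rate_hz)

  bg <- withr::with_seed(cfg$background_texture_seed, {
    a <- array(runif(size * size * 3), c(size, size, 3L))
    for (ch in 1:3) a[, , ch] <- blur_circular(a[, , ch], 3L)
    for (ch in 1:3) {
      v <- a[, , ch]
      a[, , ch] <- 30 + 195 * (v - min(v)) / (max(v) - min(v))
    }
    a
  })

  # fixation anchors in scene coordinates, recovered from the trace
  lab <- densify_events(truth, gaze$timestamps)
  off <- head_offset(cfg, gaze$timestamps)
  anchors <- list()
  fix <- truth[truth$label == "non_saccade", , drop = FALSE]
  for (k in seq_len(nrow(fix))) {
    idx <- which(gaze$timestamps >= fix$start_ms[k] &
                   gaze$timestamps < fix$end_ms[k] &
                   !gaze$blink & lab == "non_saccade")
    if (length(idx) == 0L) next
    a <- c(median(gaze$x[idx] - off[idx, 1L]),
           median(gaze$y[idx] - off[idx, 2L]))
    dup <- any(vapply(anchors, function(b) {
      sqrt(sum((a - b)^2)) < cfg$object_size_px / 2
    }, logical(1)))
    if (!dup) anchors[[length(anchors) + 1L]] <- a
  }
  if (length(anchors) > cfg$n_objects && cfg$n_objects > 0L) {
    anchors <- anchors[seq_len(cfg$n_objects)]
  }
  palette <- matrix(c(250, 40, 40, 40, 250, 40, 60, 60, 250,
                      250, 220, 30, 230, 40, 230, 30, 230, 230),
                    ncol = 3L, byrow = TRUE)

  half_obj <- cfg$object_size_px %/% 2L
  frames <- vector("list", length(ft))
  for (j in seq_along(ft)) {
    o <- round(head_offset(cfg, ft[j])[1L, ])
    rows <- ((seq_len(size) - 1L - o[2L]) %% size) + 1L
    cols <- ((seq_len(size) - 1L - o[1L]) %% size) + 1L
    fr <- bg[rows, cols, , drop = FALSE]
    for (i in seq_along(anchors)) {
      ctr <- round(anchors[[i]] + o)
      xs <- (ctr[1L] - half_obj):(ctr[1L] + half_obj)
      ys <- (ctr[2L] - half_obj):(ctr[2L] + half_obj)
      xs <- xs[xs >= 1L & xs <= size]
      ys <- ys[ys >= 1L & ys <= size]
      if (length(xs) == 0L || length(ys) == 0L) next
      col <- palette[((i - 1L) %% nrow(palette)) + 1L, ]
      for (ch in 1:3) fr[ys, xs, ch] <- col[ch]
      # darker core so the object interior is not uniform
      xi <- xs[xs >= ctr[1L] - half_obj %/% 2L & xs <= ctr[1L] + half_obj %/% 2L]
      yi <- ys[ys >= ctr[2L] - half_obj %/% 2L & ys <= ctr[2L] + half_obj %/% 2L]
      for (ch in 1:3) fr[yi, xi, ch] <- col[ch] * 0.35
    }
    frames[[j]] <- fr
  }
  scene_sequence(frames, ft)
}

#' Benchmark suite of named synthetic scenarios
#'
#' Fixed scenarios exercising each part of the pipeline:
#' \describe{
#'   \item{clean}{High signal-to-noise: 20 saccades of 5-15 degrees in 10 s,
#'     0.05-degree jitter, no blinks, no head motion, no scene.}
#'   \item{tracking}{Head translation of 6 px/frame with gaze riding the
#'     scene (VOR-like slow phases) and 12 resetting saccades of 12-16
#'     degrees in 3 s -- large enough that the fast phases can undo the
#'     accumulated slow-phase drift; scene frames rendered at 224 px,
#'     4 px/degree.}
#'   \item{jump}{Static background, one 50-degree (200-px) gaze jump
#'     between two distinct objects; scene rendered at 288 px, 4 px/degree.}
#'   \item{noisy}{As clean but with 0.5-degree jitter, comparable to the
#'     smallest saccades.}
#'   \item{blinky}{As clean with 0.4 blinks/s of 200 ms and a 3-degree gaze
#'     displacement across each blink.}
#'   \item{jitter_boundaries}{15 large saccades (12-20 degrees, at least 9
#'     samples each) plus a copy of the ground truth whose boundaries are
#'     jittered by up to 2 samples, for the evaluation-leniency check.}
#' }
#'
#' @param seed Integer master seed; each scenario derives its own sub-seed.
#' @return Named list; each element has fields `name`, `scenario`, `gaze`,
#'   `truth`, `scene` (`NULL` where not rendered) and, for
#'   `jitter_boundaries`, `truth_jittered`.
#' @export
make_benchmark_suite <- function(seed = 1L) {
  seed <- as.integer(seed)
  sub <- function(k) (seed %% 100000L) * 1009L + k
  build <- function(name, cfg, with_scene = FALSE) {
    sim <- simulate_gaze(cfg)
    scene <- if (with_scene) simulate_scene(cfg, sim$gaze, sim$truth) else NULL
    list(name = name, scenario = cfg, gaze = sim$gaze, truth = sim$truth,
         scene = scene)
  }
  suite <- list(
    clean = build("clean", scenario_config(
      duration_s = 10, n_saccades = 20, amplitude_range_deg = c(5, 15),
      fixation_noise_sd_deg = 0.05, frame_size_px = 512, px_per_deg = 13,
      rng_seed = sub(1L)
    )),
    tracking = build("tracking", scenario_config(
      duration_s = 3, n_saccades = 12, amplitude_range_deg = c(12, 16),
      fixation_noise_sd_deg = 0.05, frame_size_px = 224, px_per_deg = 4,
      head_translation_px_per_frame = c(6, 0), n_objects = 16,
      object_size_px = 16, rng_seed = sub(2L)
    ), with_scene = TRUE),
    jump = build("jump", scenario_config(
      duration_s = 2, n_saccades = 1, amplitude_range_deg = c(50, 50),
      fixation_noise_sd_deg = 0.05, frame_size_px = 288, px_per_deg = 4,
      n_objects = 2, object_size_px = 16, rng_seed = sub(3L)
    ), with_scene = TRUE),
    noisy = build("noisy", scenario_config(
      duration_s = 10, n_saccades = 20, amplitude_range_deg = c(5, 15),
      fixation_noise_sd_deg = 0.5, frame_size_px = 512, px_per_deg = 13,
      rng_seed = sub(4L)
    )),
    blinky = build("blinky", scenario_config(
      duration_s = 10, n_saccades = 20, amplitude_range_deg = c(5, 15),
      fixation_noise_sd_deg = 0.05, blink_rate_hz = 0.4,
      blink_duration_ms = 200, blink_shift_deg = 3,
      frame_size_px = 512, px_per_deg = 13, rng_seed = sub(5L)
    )),
    jitter_boundaries = build("jitter_boundaries", scenario_config(
      duration_s = 10, n_saccades = 15, amplitude_range_deg = c(12, 20),
      fixation_noise_sd_deg = 0.05, frame_size_px = 512, px_per_deg = 13,
      rng_seed = sub(6L)
    ))
  )
  suite$jitter_boundaries$truth_jittered <- jitter_boundaries(
    suite$jitter_boundaries$truth,
    dt_ms = 1000 / suite$jitter_boundaries$scenario$sampling_rate_hz,
    max_shift_samples = 2L, seed = sub(7L)
  )
  suite
}

#' Jitter the boundaries of saccade intervals
#'
#' Shifts every saccade onset and offset independently by 1 or 2 sample
#' periods in a random direction, then rebuilds a dense labeling. Emulates
#' inter-annotator boundary disagreement while preserving every event's
#' majority overlap (for events of at least 9 samples).
#'
#' @param truth An [event_intervals()].
#' @param dt_ms Sample period in ms.
#' @param max_shift_samples Maximum shift magnitude in samples (default 2).
#' @param seed Integer seed.
#' @return An [event_intervals()] with jittered saccade boundaries.
#' @export
jitter_boundaries <- function(truth, dt_ms, max_shift_samples = 2L, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    sacc <- which(truth$label == "saccade")
    start <- truth$start_ms
    end <- truth$end_ms
    shift <- function() sample(c(-max_shift_samples:-1L, 1L:max_shift_samples), 1L) * dt_ms
    for (k in sacc) {
      start[k] <- start[k] + shift()
      end[k] <- end[k] + shift()
    }
    span <- c(min(truth$start_ms), max(truth$end_ms))
    keep <- order(start[sacc])
    s <- start[sacc][keep]; e <- end[sacc][keep]
    # guard degeneracies (cannot occur with well-separated events)
    ok <- s < e
    s <- s[ok]; e <- e[ok]
    lab_s <- numeric(0); lab_e <- numeric(0); lab_l <- character(0)
    cursor <- span[1L]
    for (k in seq_along(s)) {
      if (s[k] > cursor) {
        lab_s <- c(lab_s, cursor); lab_e <- c(lab_e, s[k])
        lab_l <- c(lab_l, "non_saccade")
      }
      lab_s <- c(lab_s, s[k]); lab_e <- c(lab_e, e[k])
      lab_l <- c(lab_l, "saccade")
      cursor <- e[k]
    }
    if (cursor < span[2L]) {
      lab_s <- c(lab_s, cursor); lab_e <- c(lab_e, span[2L])
      lab_l <- c(lab_l, "non_saccade")
    }
    event_intervals(lab_s, lab_e, lab_l)
  })
}

#' Write a synthetic recording to disk
#'
#' Writes the gaze CSV, the ground-truth event CSV, the scenario YAML, and
#' (when present) the scene frames as a PNG directory with sidecar.
#'
#' @param simrec An element of [make_benchmark_suite()] or a list with the
#'   same fields.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_recording <- function(simrec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gaze_csv(simrec$gaze, file.path(dir, "gaze.csv"))
  write_event_csv(simrec$truth, file.path(dir, "truth.csv"))
  yaml::write_yaml(unclass(simrec$scenario), file.path(dir, "scenario.yaml"))
  if (!is.null(simrec$scene)) {
    write_scene(simrec$scene, file.path(dir, "frames"))
  }
  invisible(dir)
}
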