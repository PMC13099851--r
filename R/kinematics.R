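#' Velocity and acceleration from a local polynomial (Savitzky-Golay) fit
#'
#' Estimates eye-in-head velocity and acceleration at every sample by
#' least-squares fitting a polynomial of order `poly_order` to the gaze
#' positions inside a window of `window_ms` centered on the sample, fitting
#' against the actual timestamps (so dropped samples do not bias the
#' estimate). Fits are computed independently within each contiguous
#' non-blink segment; windows never cross blinks. A sample whose centered
#' window would cross a segment boundary gets a symmetrically truncated
#' window; if fewer than `poly_order + 1` samples remain it is marked
#' invalid. On noise-free polynomial trajectories of degree at most
#' `poly_order` the estimator is exact.
#'
#' @param rec A [gaze_recording()].
#' @param window_ms Window length in ms (default 40, i.e. 9 samples at
#'   200 Hz).
#' @param poly_order Polynomial order (default 2).
#' @return A tibble of class `kinematics_trace` with columns `timestamp_ms`,
#'   `vx`, `vy` (px/ms), `ax`, `ay` (px/ms^2), `speed`, `accel_mag`, `valid`.
#' @export
savgol_kinematics <- function(rec, window_ms = 40, poly_order = 2L) {
  stopifnot(inherits(rec, "gaze_recording"), window_ms > 0, poly_order >= 1L)
  n <- length(rec$timestamps)
  out <- tibble(
    timestamp_ms = rec$timestamps,
    vx = NA_real_, vy = NA_real_, ax = NA_real_, ay = NA_real_,
    speed = NA_real_, accel_mag = NA_real_,
    valid = FALSE
  )
  segs <- contiguous_segments(!rec$blink)
  dt <- if (n >= 2L) median(diff(rec$timestamps)) else 1
  half <- max(1L, floor(window_ms / (2 * dt)))
  min_pts <- poly_order + 1L
  if (sum(!rec$blink) < min_pts) {
    warning("fewer than poly_order + 1 non-blink samples; all invalid")
    class(out) <- c("kinematics_trace", class(out))
    return(out)
  }
  for (seg in segs) {
    i0 <- seg[1L]; i1 <- seg[2L]
    for (i in i0:i1) {
      h <- min(half, i - i0, i1 - i)
      if (2L * h + 1L < min_pts) next
      idx <- (i - h):(i + h)
      tau <- rec$timestamps[idx] - rec$timestamps[i]
      # columns: position, velocity, acceleration (via tau^2/2)
      A <- cbind(1, tau, tau^2 / 2)
      if (poly_order > 2L) {
        for (k in 3:poly_order) A <- cbind(A, tau^k / factorial(k))
      }
      coef <- tryCatch(
        qr.coef(qr(A), cbind(rec$x[idx], rec$y[idx])),
        error = function(e) NULL
      )
      if (is.null(coef) || anyNA(coef[2:3, ])) next
      out$vx[i] <- coef[2L, 1L]; out$vy[i] <- coef[2L, 2L]
      out$ax[i] <- coef[3L, 1L]; out$ay[i] <- coef[3L, 2L]
      out$valid[i] <- TRUE
    }
  }
  out$speed <- sqrt(out$vx^2 + out$vy^2)
  out$accel_mag <- sqrt(out$ax^2 + out$ay^2)
  class(out) <- c("kinematics_trace", class(out))
  out
}

#' Three-point parabola velocity
#'
#' Fits a parabola to every triple of consecutive gaze samples within each
#' non-blink segment and evaluates its derivative at the middle sample, per
#' axis. For uniform sampling this reduces to the central difference
#' `(x[i+1] - x[i-1]) / (t[i+1] - t[i-1])`. The first and last sample of
#' every segment are invalid; acceleration fields are left `NA`.
#'
#' @param rec A [gaze_recording()].
#' @return A tibble of class `kinematics_trace` (see [savgol_kinematics()]),
#'   with `ax`, `ay`, `accel_mag` all `NA`.
#' @export
parabola_velocity <- function(rec) {
  stopifnot(inherits(rec, "gaze_recording"))
  n <- length(rec$timestamps)
  vx <- rep(NA_real_, n); vy <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (seg in contiguous_segments(!rec$blink)) {
    i0 <- seg[1L]; i1 <- seg[2L]
    if (i1 - i0 < 2L) next
    i <- (i0 + 1L):(i1 - 1L)
    d1 <- rec$timestamps[i] - rec$timestamps[i - 1L]
    d2 <- rec$timestamps[i + 1L] - rec$timestamps[i]
    # derivative at the middle point of the interpolating parabola
    denom <- d1 * d2 * (d1 + d2)
    vx[i] <- (rec$x[i + 1L] * d1^2 - rec$x[i - 1L] * d2^2 +
                rec$x[i] * (d2^2 - d1^2)) / denom
    vy[i] <- (rec$y[i + 1L] * d1^2 - rec$y[i - 1L] * d2^2 +
                rec$y[i] * (d2^2 - d1^2)) / denom
    valid[i] <- TRUE
  }
  out <- tibble(
    timestamp_ms = rec$timestamps,
    vx = vx, vy = vy, ax = NA_real_, ay = NA_real_,
    speed = sqrt(vx^2 + vy^2), accel_mag = NA_real_,
    valid = valid
  )
  class(out) <- c("kinematics_trace", class(out))
  out
}

# Maximal runs of TRUE in `keep`, as a list of c(first, last) index pairs.
contiguous_segments <- function(keep) {
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  Map(function(s, e) c(s, e), starts[r$values], ends[r$values])
}

#' Write a kinematics debug dump
#'
#' @param kin A `kinematics_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kinematics_csv <- function(kin, path) {
  df <- data.frame(
    timestamp_ms = kin$timestamp_ms,
    speed_px_ms = kin$speed,
    accel_px_ms2 = kin$accel_mag,
    valid = as.integer(kin$valid)
  )
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
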