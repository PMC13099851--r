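#' Exponent of the rank power transform
#'
#' The rank-to-probability map is `p = (rank/N)^alpha` with `alpha` chosen so
#' that only the fraction `top_fraction` of highest ranks get a probability
#' above 0.5, i.e. `(1 - top_fraction)^alpha = 0.5`. For the default 10%
#' this gives `alpha = log(0.5)/log(0.9)`, approximately 6.58.
#'
#' @param top_fraction Fraction of highest ranks mapping above 0.5, in (0,1).
#' @return The exponent `alpha`.
#' @export
solve_exponent <- function(top_fraction = 0.10) {
  if (!is.numeric(top_fraction) || length(top_fraction) != 1L ||
      top_fraction <= 0 || top_fraction >= 1) {
    stop("top_fraction must be a single number in (0, 1)", call. = FALSE)
  }
  log(0.5) / log(1 - top_fraction)
}

#' Rank power transform
#'
#' Maps each value to `(rank/N)^alpha` where rank 1 is the smallest and N
#' the largest value; ties receive the mean of their tied ranks. Being
#' rank-based, the transform is invariant to any monotone rescaling of the
#' input.
#'
#' @param values Numeric vector, finite.
#' @param alpha Exponent, typically from [solve_exponent()].
#' @return Numeric vector of probabilities in `[0, 1]`, in input order.
#' @export
rank_to_prob <- function(values, alpha) {
  if (length(values) == 0L) return(numeric())
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  r <- rank(values, ties.method = "average")
  (r / length(values))^alpha
}

#' Per-sample fast-eye-movement probability
#'
#' Ranks the speed and acceleration magnitudes of a kinematics trace
#' separately over all valid samples, converts each rank to a probability
#' with the power transform, and takes the per-sample maximum: acceleration
#' is highest near the onset and offset of a gaze shift while velocity peaks
#' in the middle, so the max covers the whole shift. Invalid samples
#' (blinks, truncated windows) are excluded from the ranked population and
#' get probability 0.
#'
#' @param kin A `kinematics_trace` from [savgol_kinematics()].
#' @param top_fraction Calibration of the power transform (default 0.10).
#' @return A tibble of class `rank_prob_trace` with columns `timestamp_ms`,
#'   `p_v`, `p_a`, `p_eye`, `valid`, and attributes `N` and `alpha`.
#' @export
eye_probability <- function(kin, top_fraction = 0.10) {
  stopifnot(inherits(kin, "kinematics_trace"))
  alpha <- solve_exponent(top_fraction)
  valid <- kin$valid & is.finite(kin$speed)
  has_accel <- valid & is.finite(kin$accel_mag)
  if (!any(valid)) stop("no valid kinematic samples", call. = FALSE)
  p_v <- rep(0, nrow(kin))
  p_a <- rep(0, nrow(kin))
  p_v[valid] <- rank_to_prob(kin$speed[valid], alpha)
  if (any(has_accel)) {
    p_a[has_accel] <- rank_to_prob(kin$accel_mag[has_accel], alpha)
  }
  out <- tibble(
    timestamp_ms = kin$timestamp_ms,
    p_v = p_v, p_a = p_a,
    p_eye = pmax(p_a, p_v),
    valid = valid
  )
  attr(out, "N") <- sum(valid)
  attr(out, "alpha") <- alpha
  class(out) <- c("rank_prob_trace", class(out))
  out
}

#' Write a probability dump
#'
#' @param prob A `rank_prob_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_probability_csv <- function(prob, path) {
  write.csv(
    data.frame(timestamp_ms = prob$timestamp_ms,
               p_v = prob$p_v, p_a = prob$p_a, p_eye = prob$p_eye),
    path, row.names = FALSE
  )
  invisible(path)
}
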