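# Shared fixture builders. The benchmark suite is expensive enough to build
# once per test run; cache it lazily.

.fixture_cache <- new.env(parent = emptyenv())

get_suite <- function(seed = 1L) {
  key <- paste0("suite_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make_benchmark_suite(seed)
  }
  .fixture_cache[[key]]
}

# Uniformly sampled recording from explicit positions (dt in ms).
toy_recording <- function(x, y = rep(0, length(x)), dt = 5, blink = NULL,
                          px_per_deg = 13) {
  gaze_recording(seq_along(x) * dt - dt, x, y, blink = blink,
                 px_per_deg = px_per_deg)
}

# Smoothed-noise RGB frame, values on 0-255, deterministic given seed.
textured_frame <- function(h, w, seed = 1L) {
  withr::with_seed(seed, {
    a <- array(runif(h * w * 3), c(h, w, 3L))
    k <- matrix(1 / 9, 3L, 3L)
    sm <- function(M) {
      padded <- M[c(1L, seq_len(h), h), c(1L, seq_len(w), w)]
      out <- M
      for (i in seq_len(h)) for (j in seq_len(w)) {
        out[i, j] <- sum(padded[i:(i + 2L), j:(j + 2L)] * k)
      }
      out
    }
    for (ch in 1:3) a[, , ch] <- sm(sm(a[, , ch]))
    for (ch in 1:3) {
      v <- a[, , ch]
      a[, , ch] <- 255 * (v - min(v)) / (max(v) - min(v))
    }
    a
  })
}

# Shift frame content by (dx, dy) pixels with torus wrap.
shift_frame <- function(frame, dx, dy) {
  d <- dim(frame)
  rows <- ((seq_len(d[1]) - 1L - dy) %% d[1]) + 1L
  cols <- ((seq_len(d[2]) - 1L - dx) %% d[2]) + 1L
  frame[rows, cols, , drop = FALSE]
}
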