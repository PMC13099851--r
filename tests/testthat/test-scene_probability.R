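test_that("patch extraction clamps at the border and validates its size", {
  fr <- textured_frame(40, 40, seed = 2)
  p <- extract_patch(fr, c(20, 20), 11)
  expect_equal(dim(p), c(11L, 11L, 3L))
  expect_equal(p, fr[15:25, 15:25, , drop = FALSE])
  # corner request: center clamped so the patch stays inside
  pc <- extract_patch(fr, c(1, 1), 11)
  expect_equal(pc, fr[1:11, 1:11, , drop = FALSE])
  expect_error(extract_patch(fr, c(20, 20), 41), "exceeds")
})

test_that("patch difference is the mean squared intensity difference", {
  z <- array(0, c(2, 2, 3))
  w <- array(255, c(2, 2, 3))
  expect_equal(patch_difference(z, z), 0)
  expect_equal(patch_difference(z, w), 255^2)
  a <- array(0, c(2, 2, 3))
  b <- a
  b[1, 1, 1] <- 10 # single differing entry over 12
  expect_equal(patch_difference(a, b), 100 / 12)
  expect_error(patch_difference(z, array(0, c(3, 3, 3))), "dimensions")
})

test_that("best match recovers identity, translations and the tie-break", {
  fr <- textured_frame(48, 48, seed = 5)
  patch <- extract_patch(fr, c(24, 24), 13)
  hit <- find_best_match(patch, fr, search_policy("exhaustive"))
  expect_equal(hit$center, c(24, 24))
  expect_equal(hit$delta, 0)
  # pure translation: optimum moves with the content
  sh <- shift_frame(fr, 8, 0)
  hit <- find_best_match(patch, sh, search_policy("exhaustive"))
  expect_equal(hit$center, c(32, 24))
  expect_equal(hit$delta, 0)
  # constant frames tie everywhere: first center in (y, x) order wins
  flat <- array(100, c(30, 30, 3))
  hit <- find_best_match(extract_patch(flat, c(15, 15), 9), flat,
                         search_policy("exhaustive"))
  expect_equal(hit$center, c(5, 5))
})

test_that("two-stage search equals exhaustive search on textured frames", {
  withr::with_seed(31, {
    for (case in 1:50) {
      h <- sample(40:64, 1); w <- sample(40:64, 1)
      fr <- textured_frame(h, w, seed = 1000 + case)
      side <- sample(c(9, 13, 17), 1)
      cx <- sample(seq((side + 1) / 2, w - (side - 1) / 2), 1)
      cy <- sample(seq((side + 1) / 2, h - (side - 1) / 2), 1)
      patch <- extract_patch(fr, c(cx, cy), side)
      target <- shift_frame(fr, sample(-6:6, 1), sample(-6:6, 1))
      ex <- find_best_match(patch, target, search_policy("exhaustive"))
      ts <- find_best_match(patch, target, search_policy("two-stage"))
      expect_identical(ts$center, ex$center)
      expect_equal(ts$delta, ex$delta, tolerance = 1e-9)
    }
  })
})

test_that("scene pair probabilities implement the degenerate-case rules", {
  fr <- textured_frame(64, 64, seed = 7)
  cal <- calibration_constants(px_per_deg = 1, patch_side_deg = 15)
  # static scene, gaze unchanged: no patch evidence, gaze at the match
  r <- scene_pair_probability(fr, fr, c(32, 32), c(32, 32), cal,
                              search_policy("exhaustive"))
  expect_equal(r$p1, 0.5)
  expect_equal(r$p2, 0)
  expect_equal(r$match$best_match_center, c(32, 32))
  # gaze jumps across a static frame: match stays at old gaze, p2 ~ 1
  r <- scene_pair_probability(fr, fr, c(20, 20), c(45, 45), cal,
                              search_policy("exhaustive"))
  expect_equal(r$match$best_match_center, c(20, 20))
  expect_gt(r$p2, 0.95)
  expect_error(scene_pair_probability(fr, fr, c(NA, 2), c(3, 4), cal),
               "finite")
})

test_that("p2 is antisymmetric in the two gaze points for a fixed match", {
  withr::with_seed(40, {
    for (case in 1:20) {
      m <- runif(2, 0, 100)
      g1 <- runif(2, 0, 100)
      g2 <- runif(2, 0, 100)
      p2 <- function(a, b) {
        dn <- sqrt(sum((a - m)^2)); di <- sqrt(sum((b - m)^2))
        if (dn + di == 0) 0 else dn / (dn + di)
      }
      expect_equal(p2(g1, g2), 1 - p2(g2, g1), tolerance = 1e-12)
    }
  })
})

test_that("scene combination is a geometric mean with its edge cases", {
  expect_equal(combine_scene(1, 1), 1)
  expect_equal(combine_scene(0.8, 0), 0)
  expect_equal(combine_scene(0.5, 0.5), 0.5)
  expect_equal(combine_scene(0.9, 0.4), 0.6)
  expect_error(combine_scene(1.2, 0.5))
})

test_that("fusion holds frame-pair values and falls back to eye-only", {
  # hand-built eye trace at 200 Hz over 100 ms
  ts <- seq(0, 95, by = 5)
  eye <- tibble::tibble(timestamp_ms = ts, p_v = 0.6, p_a = 0.2,
                        p_eye = rep(0.81, 20), valid = TRUE)
  class(eye) <- c("rank_prob_trace", class(eye))
  sp <- tibble::tibble(
    frame_timestamp_ms = c(33, 66, 99),
    p1 = c(1, 0.25, 1), p2 = c(1, 0.25, 1),
    p_scene = c(1, 0.25, NA), available = c(TRUE, TRUE, FALSE),
    not_tracking_px = 0, image_shift_px = 0
  )
  attr(sp, "first_frame_ms") <- 0
  class(sp) <- c("scene_prob_trace", class(sp))
  fused <- fuse_probabilities(eye, sp)
  # pair 1 covers (0, 33]: samples 5..30; sample at 0 has no pair
  expect_equal(fused$mode[1], "eye-only")
  expect_equal(fused$p_gaze[1], 0.81)
  expect_equal(fused$p_gaze[fused$timestamp_ms == 30], sqrt(1 * 0.81))
  expect_equal(fused$p_gaze[fused$timestamp_ms == 50], sqrt(0.25 * 0.81))
  # unavailable third pair: eye-only fallback
  expect_equal(fused$mode[fused$timestamp_ms == 70], "eye-only")
  expect_equal(fused$p_gaze[fused$timestamp_ms == 70], 0.81)
  # no scene at all: the p_eye variant
  alone <- fuse_probabilities(eye, NULL)
  expect_true(all(alone$mode == "eye-only"))
  expect_equal(alone$p_gaze, eye$p_eye)
  # worked example of the geometric mean
  expect_equal(sqrt(0.4 * 0.9), 0.6)
})

test_that("fused probability lies between the eye and scene probabilities", {
  withr::with_seed(55, {
    pe <- runif(200); ps <- runif(200)
    pg <- sqrt(pe * ps)
    expect_true(all(pg <= pmax(pe, ps) + 1e-12))
    expect_true(all(pg >= pmin(pe, ps) - 1e-12))
  })
})
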