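# A recording whose samples step rightward 1 px per 5-ms sample, so group
# geometry is easy to reason about; px_per_deg = 1 makes px equal degrees.
stepper <- function(n, px_per_deg = 1) {
  toy_recording(seq_len(n), rep(0, n), px_per_deg = px_per_deg)
}

test_that("thresholding groups strict supra-threshold runs, breaking at blinks", {
  rec <- stepper(5)
  g <- threshold_and_group(c(0.1, 0.6, 0.7, 0.2, 0.8), rec)
  expect_length(g, 2L)
  expect_equal(g[[1]]$indices, 2:3)
  expect_equal(g[[2]]$indices, 5L)
  expect_length(threshold_and_group(rep(0.5, 5), rec), 0L) # strict >
  # one blink sample splits a run in two
  recb <- toy_recording(1:6, rep(0, 6), blink = c(F, F, F, T, F, F),
                        px_per_deg = 1)
  gb <- threshold_and_group(rep(0.9, 6), recb)
  expect_length(gb, 2L)
  expect_equal(gb[[1]]$indices, 1:3)
  expect_equal(gb[[2]]$indices, 5:6)
})

test_that("candidate geometry: displacement, amplitude, direction", {
  rec <- toy_recording(c(0, 3, 6), c(0, 4, 8), px_per_deg = 2)
  g <- threshold_and_group(c(0.9, 0.9, 0.9), rec)[[1]]
  expect_equal(g$displacement, c(6, 8))
  expect_equal(g$amplitude_deg, 5) # 10 px at 2 px/deg
  expect_equal(g$direction_deg, atan2(8, 6) * 180 / pi)
})

test_that("direction pruning removes only strictly deviating steps", {
  # monotone rightward shift is untouched
  rec <- stepper(6)
  g <- threshold_and_group(rep(0.9, 6), rec)[[1]]
  expect_equal(prune_direction_outliers(g, rec)$indices, g$indices)
  # one backward step (180 degrees) is pruned
  recb <- toy_recording(c(0, 2, 4, 3, 6, 8), rep(0, 6), px_per_deg = 1)
  gb <- threshold_and_group(rep(0.9, 6), recb)[[1]]
  pb <- prune_direction_outliers(gb, recb)
  expect_equal(pb$indices, c(1:3, 5:6))
  # a step at exactly 90 degrees is retained (strictly-more-than rule)
  recq <- toy_recording(c(0, 2, 2, 4), c(0, 0, 2, 2), px_per_deg = 1)
  gq <- threshold_and_group(rep(0.9, 4), recq)[[1]]
  # overall direction 45 deg; steps at 0, 90, 0 deviate by 45 at most
  expect_equal(prune_direction_outliers(gq, recq)$indices, gq$indices)
  recq2 <- toy_recording(c(0, 4, 4, 8), c(0, 0, -4, -4), px_per_deg = 1)
  # overall 8, -4 => -26.6 deg; down-step at -90 deviates 63.4, kept;
  # construct an exact 90-degree deviation instead:
  rec90 <- toy_recording(c(0, 10, 10), c(0, 0, -3), px_per_deg = 1)
  g90 <- threshold_and_group(rep(0.9, 3), rec90)[[1]]
  # overall direction atan2(-3,10); make the deviating step exactly 90 off
  # simpler canonical case: overall 0 deg, one step straight up (90 deg)
  rec90b <- toy_recording(c(0, 5, 5, 10), c(0, 0, 4, 0), px_per_deg = 1)
  g90b <- threshold_and_group(rep(0.9, 4), rec90b)[[1]]
  expect_equal(g90b$direction_deg, 0)
  pruned <- prune_direction_outliers(g90b, rec90b)
  # step 2->3 is exactly 90 deg (kept); step 3->4 is -38.66 (kept)
  expect_true(3L %in% pruned$indices)
})

test_that("amplitude filtering is strict at the 1-degree boundary", {
  rec <- toy_recording(c(0, 13), rep(0, 2)) # 13 px = 1.0 deg at default cal
  g <- threshold_and_group(c(0.9, 0.9), rec)
  expect_length(filter_amplitude(g), 0L) # exactly 1 degree is dropped
  rec2 <- toy_recording(c(0, 29.9), rep(0, 2)) # 2.3 deg
  g2 <- threshold_and_group(c(0.9, 0.9), rec2)
  expect_length(filter_amplitude(g2), 1L)
  rec3 <- toy_recording(c(0, 5.2), rep(0, 2)) # 0.4 deg
  expect_length(filter_amplitude(threshold_and_group(c(0.9, 0.9), rec3)), 0L)
})

test_that("close shifts merge when aligned and drop the smaller otherwise", {
  params <- segmentation_params()
  # two rightward shifts 20 ms apart, directions identical -> one event
  x <- c(0, 10, 20, 20, 20, 20, 30, 40)
  rec <- toy_recording(x, rep(0, 8), px_per_deg = 1)
  p <- c(0.9, 0.9, 0.9, 0, 0, 0, 0.9, 0.9)
  groups <- threshold_and_group(p, rec)
  ev <- merge_or_discard(groups, rec, params)
  expect_equal(sum(ev$label == "saccade"), 1L)
  sacc <- ev[ev$label == "saccade", ]
  expect_equal(sacc$start_ms, 0)
  expect_equal(sacc$end_ms, 40) # span includes the gap
  # opposite directions, 20-ms gap: smaller amplitude discarded
  x2 <- c(0, 10, 20, 20, 20, 20, 15, 10)
  rec2 <- toy_recording(x2, rep(0, 8), px_per_deg = 1)
  ev2 <- merge_or_discard(threshold_and_group(p, rec2), rec2, params)
  sacc2 <- ev2[ev2$label == "saccade", ]
  expect_equal(nrow(sacc2), 1L)
  expect_equal(sacc2$start_ms, 0) # the 20-px shift survives, 10-px dropped
  expect_equal(sacc2$end_ms, 15)
  # 80-ms gap: both kept
  x3 <- c(0, 10, 20, rep(20, 16), 30, 40)
  rec3 <- toy_recording(x3, rep(0, 21), px_per_deg = 1)
  p3 <- c(rep(0.9, 3), rep(0, 16), 0.9, 0.9)
  ev3 <- merge_or_discard(threshold_and_group(p3, rec3), rec3,
                          segmentation_params())
  expect_equal(sum(ev3$label == "saccade"), 2L)
  # a gap of exactly 50 ms keeps both (strictly-less-than rule)
  x4 <- c(0, 10, 20, rep(20, 10), 30, 40)
  rec4 <- toy_recording(x4, rep(0, 15), px_per_deg = 1)
  p4 <- c(rep(0.9, 3), rep(0, 10), 0.9, 0.9)
  ev4 <- merge_or_discard(threshold_and_group(p4, rec4), rec4,
                          segmentation_params())
  expect_equal(sum(ev4$label == "saccade"), 2L)
})

test_that("merging never crosses a blink and output respects the grammar", {
  # two aligned shifts 20 ms apart but separated by a blink: both kept
  x <- c(0, 10, 20, 20, 20, 20, 30, 40)
  blink <- c(F, F, F, F, T, F, F, F)
  rec <- toy_recording(x, rep(0, 8), blink = blink, px_per_deg = 1)
  p <- c(0.9, 0.9, 0.9, 0, 0, 0, 0.9, 0.9)
  ev <- merge_or_discard(threshold_and_group(p, rec), rec,
                         segmentation_params())
  expect_equal(sum(ev$label == "saccade"), 2L)
  expect_true(any(ev$label == "blink"))
})

test_that("the full ranking detector recovers clean events deterministically", {
  cl <- get_suite(1)$clean
  ev1 <- detect_ranking(cl$gaze, variant = "eye")
  ev2 <- detect_ranking(cl$gaze, variant = "eye")
  expect_identical(ev1$start_ms, ev2$start_ms)
  expect_identical(ev1$label, ev2$label)
  sacc <- ev1[ev1$label == "saccade", ]
  # grammar invariants on real output
  expect_true(all(sacc$end_ms > sacc$start_ms))
  expect_true(all(diff(ev1$start_ms) > 0))
  if (nrow(sacc) > 1L) {
    expect_true(all(sacc$start_ms[-1] - sacc$end_ms[-nrow(sacc)] >= 50))
  }
  amp <- vapply(seq_len(nrow(sacc)), function(k) {
    i <- which(cl$gaze$timestamps >= sacc$start_ms[k] &
                 cl$gaze$timestamps < sacc$end_ms[k])
    sqrt(diff(range(cl$gaze$x[i]))^2 + diff(range(cl$gaze$y[i]))^2) /
      cl$gaze$px_per_deg
  }, numeric(1))
  expect_true(all(amp > 1))
  # a recording that is one long blink yields no saccades
  nb <- 200
  recb <- gaze_recording(seq_len(nb) * 5 - 5, rep(NA_real_, nb),
                         rep(NA_real_, nb))
  evb <- suppressWarnings(detect_ranking(recb, variant = "eye"))
  expect_equal(sum(evb$label == "saccade"), 0L)
  expect_true(all(evb$label == "blink"))
})

test_that("raising the threshold never increases the marked sample count", {
  withr::with_seed(62, {
    p <- runif(300)
    rec <- toy_recording(cumsum(rnorm(300)), cumsum(rnorm(300)))
    n_marked <- function(thr) {
      sum(vapply(
        threshold_and_group(p, rec, segmentation_params(prob_threshold = thr)),
        function(g) length(g$indices), numeric(1)))
    }
    counts <- vapply(c(0.2, 0.4, 0.6, 0.8), n_marked, numeric(1))
    expect_true(all(diff(counts) <= 0))
  })
})
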