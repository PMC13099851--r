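test_that("gaze CSV round-trips and enforces its contract", {
  rec <- gaze_recording(c(0, 5, 10, 15), c(1.5, 2.25, NA, 4),
                        c(0, -1, 2, 3.5), blink = c(FALSE, FALSE, FALSE, TRUE))
  expect_true(rec$blink[3]) # non-finite position forces blink
  path <- withr::local_tempfile(fileext = ".csv")
  write_gaze_csv(rec, path)
  back <- read_gaze_csv(path)
  expect_identical(back$timestamps, rec$timestamps)
  expect_identical(back$x, rec$x)
  expect_identical(back$y, rec$y)
  expect_identical(back$blink, rec$blink)
  expect_equal(back$sampling_rate, 200)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp_ms,x_px", "0,1"), bad)
  expect_error(read_gaze_csv(bad), "missing column")
  expect_error(gaze_recording(c(0, 10, 5), 1:3, 1:3), "strictly increasing")
})

test_that("event intervals validate ordering, overlap and labels", {
  expect_error(event_intervals(0, 0, "saccade"), "start_ms < end_ms")
  expect_error(event_intervals(c(0, 50), c(100, 150),
                               c("saccade", "non_saccade")), "overlap")
  expect_error(event_intervals(0, 10, "pursuit"), "labels")
  ev <- event_intervals(c(100, 0), c(150, 100), c("saccade", "non_saccade"))
  expect_equal(ev$start_ms, c(0, 100)) # sorted on construction
})

test_that("event CSV and JSON round-trip", {
  ev <- event_intervals(c(0, 100, 180), c(100, 180, 400),
                        c("non_saccade", "saccade", "blink"))
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    if (fmt == "csv") write_event_csv(ev, path) else write_event_json(ev, path)
    back <- if (fmt == "csv") read_event_csv(path) else read_event_json(path)
    expect_equal(back$start_ms, ev$start_ms)
    expect_equal(back$end_ms, ev$end_ms)
    expect_equal(back$label, ev$label)
  }
})

test_that("densification assigns exactly one label per sample", {
  ev <- event_intervals(c(0, 20, 60), c(20, 40, 80),
                        c("non_saccade", "saccade", "blink"))
  ts <- seq(0, 95, by = 5)
  lab <- densify_events(ev, ts)
  expect_length(lab, length(ts))
  expect_equal(lab[ts == 20], "saccade") # half-open: boundary starts new event
  expect_equal(lab[ts == 40], "non_saccade") # gap
  expect_equal(lab[ts == 60], "blink")
  expect_equal(lab[ts == 80], "non_saccade") # past the last interval
  # events_from_labels inverts densify on full-cover labelings
  ev2 <- events_from_labels(lab, ts)
  expect_identical(densify_events(ev2, ts), lab)
})

test_that("gap recoding labels short gaps saccade and long gaps blink", {
  fx <- function(s, e) event_intervals(s, e, rep("non_saccade", length(s)))
  g80 <- recode_gaps_as_blinks(fx(c(0, 180), c(100, 300)))
  expect_equal(g80$label, c("non_saccade", "saccade", "non_saccade"))
  g150 <- recode_gaps_as_blinks(fx(c(0, 250), c(100, 400)))
  expect_equal(g150$label, c("non_saccade", "blink", "non_saccade"))
  # boundary: exactly 100 ms is still a saccade (only longer gaps are blinks)
  g100 <- recode_gaps_as_blinks(fx(c(0, 200), c(100, 300)))
  expect_equal(g100$label, c("non_saccade", "saccade", "non_saccade"))
  g0 <- recode_gaps_as_blinks(fx(c(0, 100), c(100, 200)))
  expect_equal(nrow(g0), 2L) # adjacent fixations: nothing inserted
  expect_error(recode_gaps_as_blinks(
    event_intervals(0, 100, "saccade")), "non_saccade")
})

test_that("gap recoding always produces a sorted non-overlapping cover", {
  withr::with_seed(11, {
    for (case in 1:25) {
      n <- sample(2:8, 1)
      starts <- cumsum(runif(n, 5, 300))
      ends <- starts + runif(n, 5, pmax(5, diff(c(starts, max(starts) + 300))) * 0.9)
      ends <- pmin(ends, c(starts[-1] - 1e-6, ends[n]))
      ok <- ends > starts
      fx <- event_intervals(starts[ok], ends[ok],
                            rep("non_saccade", sum(ok)))
      out <- recode_gaps_as_blinks(fx)
      expect_true(all(diff(out$start_ms) > 0))
      expect_true(all(out$start_ms[-1] >= out$end_ms[-nrow(out)] - 1e-9))
      # union covers the full span with no holes
      expect_equal(sum(out$end_ms - out$start_ms),
                   max(fx$end_ms) - min(fx$start_ms))
    }
  })
})

test_that("degree/pixel conversion matches the paired-unit calibration", {
  cal <- calibration_constants(px_per_deg = 12.94)
  expect_equal(deg_to_px(1.7, cal), 22, tolerance = 0.01)
  expect_equal(deg_to_px(0, cal), 0)
  cal13 <- calibration_constants(px_per_deg = 13)
  expect_equal(deg_to_px(15, cal13), 195)
  expect_equal(px_to_deg(deg_to_px(3.2, cal13), cal13), 3.2)
  expect_error(calibration_constants(px_per_deg = -1))
})

test_that("scene sequences read and write through PNG directories", {
  frames <- lapply(1:4, function(i) {
    array(round(seq(0, 255, length.out = 12 * 10 * 3))[
      (seq_len(12 * 10 * 3) + i) %% (12 * 10 * 3) + 1], c(12, 10, 3))
  })
  sc <- scene_sequence(frames, c(0, 33, 66, 99))
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  back <- read_scene(dir)
  expect_length(back$frames, 4L)
  expect_equal(back$frame_timestamps, sc$frame_timestamps)
  expect_equal(back$frames[[2]], sc$frames[[2]], tolerance = 0.51) # 8-bit
  # mismatched sidecar is a validation error
  write.csv(data.frame(frame_index = 1:3, timestamp_ms = c(0, 33, 66)),
            file.path(dir, "frames.csv"), row.names = FALSE)
  expect_error(read_scene(dir), "does not match")
  expect_error(scene_sequence(frames, c(0, 33, 66)), "differ")
})
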