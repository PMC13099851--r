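test_that("the F1 formula and its edge cases", {
  expect_equal(f1_score(confusion_counts(1, 0, 0)), 1)
  expect_equal(f1_score(confusion_counts(0, 3, 0)), 0)
  expect_equal(f1_score(confusion_counts(8, 2, 2)), 0.8)
  expect_equal(f1_score(8, fp = 2, fn = 2), 0.8)
  expect_error(f1_score(confusion_counts(0, 0, 0)), "undefined")
})

test_that("sample-level counts enumerate the grid correctly", {
  rec <- toy_recording(seq_len(10), rep(0, 10))
  mk <- function(idx) {
    lab <- rep("non_saccade", 10)
    lab[idx] <- "saccade"
    events_from_labels(lab, rec$timestamps)
  }
  pred <- mk(c(2, 3, 4)); truth <- mk(c(3, 4, 5))
  cc <- sample_level_eval(pred, truth, rec)
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(2L, 1L, 1L))
  # identical labelings agree perfectly
  cc2 <- sample_level_eval(truth, truth, rec)
  expect_equal(c(cc2$fp, cc2$fn), c(0L, 0L))
  # all-quiet prediction: every truth saccade sample is a miss
  cc3 <- sample_level_eval(mk(integer()), truth, rec)
  expect_equal(cc3$fn, 3L)
  # swapping prediction and truth swaps fp and fn, tp unchanged
  cc4 <- sample_level_eval(truth, pred, rec)
  expect_equal(cc4$tp, cc$tp)
  expect_equal(cc4$fp, cc$fn)
  expect_equal(cc4$fn, cc$fp)
})

test_that("blink samples are excluded from both evaluation levels", {
  rec <- toy_recording(seq_len(12), rep(0, 12),
                       blink = c(rep(FALSE, 10), TRUE, TRUE))
  lab <- rep("non_saccade", 12); lab[4:6] <- "saccade"
  truth <- events_from_labels(lab, rec$timestamps)
  # prediction marks the blink region saccade: those samples are excluded,
  # so no false positives arise from them
  labp <- rep("non_saccade", 12); labp[c(4:6, 11:12)] <- "saccade"
  pred <- events_from_labels(ifelse(rec$blink, "blink", labp),
                             rec$timestamps)
  cc <- sample_level_eval(pred, truth, rec)
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(3L, 0L, 0L))
})

test_that("event majorities follow the strict more-than-half rule", {
  rec <- toy_recording(seq_len(40), rep(0, 40))
  mk <- function(idx) {
    lab <- rep("non_saccade", 40); lab[idx] <- "saccade"
    events_from_labels(lab, rec$timestamps)
  }
  truth <- mk(11:19) # one 9-sample event
  # 5 of 9 predicted: majority -> tp
  cc <- event_level_eval(mk(11:15), truth, rec)
  expect_equal(c(cc$tp, cc$fn), c(1L, 0L))
  # 4 of 9: no majority -> fn
  cc <- event_level_eval(mk(11:14), truth, rec)
  expect_equal(c(cc$tp, cc$fn), c(0L, 1L))
  # exact ties fail the "most frequent class" test on both sides: the
  # truth event becomes an fn and the half-overlapping prediction an fp
  truth10 <- mk(11:20)
  cc <- event_level_eval(mk(16:25), truth10, rec)
  expect_equal(c(cc$tp, cc$fn, cc$fp), c(0L, 1L, 1L))
  # a predicted event fully inside a truth non-saccade region -> fp
  cc <- event_level_eval(mk(30:33), truth, rec)
  expect_equal(cc$fp, 1L)
  # boundary jitter by 2 samples on a 9-sample event: still tp both ways
  cc <- event_level_eval(mk(13:21), truth, rec)
  expect_equal(c(cc$tp, cc$fn, cc$fp), c(1L, 0L, 0L))
})

test_that("error rates normalize by the reference class sizes", {
  cc <- confusion_counts(7, 2, 3, level = "event")
  r <- rate_report(cc, n_saccade_units = 10, n_non_saccade_units = 20)
  expect_equal(r$fn_rate, 0.3)
  expect_equal(r$fp_rate, 0.1)
  r0 <- rate_report(confusion_counts(0, 0, 0), 0, 5)
  expect_true(is.na(r0$fn_rate))
})

test_that("self-agreement is perfect at both levels on any labeling", {
  suite <- get_suite(1)
  for (nm in c("clean", "blinky")) {
    rec <- suite[[nm]]$gaze
    truth <- suite[[nm]]$truth
    rep <- evaluate_events(truth, truth, rec)
    expect_equal(rep$sample_f1, 1)
    expect_equal(rep$event_f1, 1)
  }
})

test_that("event-level scoring is more lenient under boundary jitter", {
  jb <- get_suite(1)$jitter_boundaries
  rep <- evaluate_events(jb$truth_jittered, jb$truth, jb$gaze)
  expect_equal(rep$event_f1, 1)
  expect_lt(rep$sample_f1, 1)
  expect_gt(rep$event_f1, rep$sample_f1)
})

test_that("a 1x1 sweep equals direct evaluation and ties give equal rows", {
  cl <- get_suite(1)$clean
  res <- parameter_sweep("ivt", list(velocity_threshold_px_ms = 2),
                         cl$gaze, cl$truth)
  direct <- evaluate_events(detect_ivt(cl$gaze, ivt_params(2, 0)),
                            cl$truth, cl$gaze)
  expect_equal(nrow(res), 1L)
  expect_equal(res$sample_f1, direct$sample_f1)
  expect_equal(res$event_f1, direct$event_f1)
  # two settings that label identically produce identical rows
  res2 <- parameter_sweep("ivt",
                          list(velocity_threshold_px_ms = c(1e6, 1e7)),
                          cl$gaze, cl$truth)
  expect_equal(res2$sample_f1[1], res2$sample_f1[2])
  expect_equal(res2$event_f1[1], res2$event_f1[2])
})

test_that("a sweep spanning the generating regime peaks near it", {
  cl <- get_suite(1)$clean
  res <- parameter_sweep("ivt",
                         list(velocity_threshold_px_ms = c(0.2, 1, 2, 8, 20),
                              min_fixation_ms = 0),
                         cl$gaze, cl$truth)
  best <- attr(res, "best_event")
  # saccades of 5-15 degrees peak well above 2 px/ms; thresholds of 1-2
  # separate them from 0.2-px jitter, the extremes under- or over-segment
  expect_true(best$velocity_threshold_px_ms %in% c(1, 2))
})
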