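#' Confusion counts
#'
#' @param tp,fp,fn Non-negative integer counts.
#' @param level `"sample"` or `"event"`.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0L, fp = 0L, fn = 0L,
                             level = c("sample", "event")) {
  level <- match.arg(level)
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), level = level),
            class = "confusion_counts")
}

#' F1-score from confusion counts
#'
#' `F1 = TP / (TP + (FP + FN) / 2)`.
#'
#' @param c A [confusion_counts()] object, or a single tp count when `fp`
#'   and `fn` are given.
#' @param fp,fn Optional counts when `c` is given as a plain tp count.
#' @return F1 in `[0, 1]`; errors when all counts are zero.
#' @export
f1_score <- function(c, fp = NULL, fn = NULL) {
  if (inherits(c, "confusion_counts")) {
    tp <- c$tp; fp <- c$fp; fn <- c$fn
  } else {
    tp <- c
    stopifnot(!is.null(fp), !is.null(fn))
  }
  if (tp + fp + fn == 0) {
    stop("F1 undefined: tp, fp and fn are all zero", call. = FALSE)
  }
  tp / (tp + (fp + fn) / 2)
}

# Per-sample binary labels on the recording grid with the blink exclusion
# applied: union of recording, predicted and reference blink samples.
aligned_labels <- function(pred, truth, rec) {
  lp <- densify_events(pred, rec$timestamps)
  lt <- densify_events(truth, rec$timestamps)
  excluded <- rec$blink | lp == "blink" | lt == "blink"
  list(pred = lp, truth = lt, excluded = excluded)
}

#' Sample-level confusion counts
#'
#' Compares the two labelings sample by sample on the recording's grid as a
#' binary saccade / non-saccade decision. Samples that are blink in the
#' recording, the prediction, or the reference are excluded.
#'
#' @param pred,truth [event_intervals()] objects (prediction and reference).
#' @param rec The [gaze_recording()] providing the sample grid.
#' @return A [confusion_counts()] with `level = "sample"`.
#' @export
sample_level_eval <- function(pred, truth, rec) {
  al <- aligned_labels(pred, truth, rec)
  keep <- !al$excluded
  p <- al$pred[keep] == "saccade"
  t <- al$truth[keep] == "saccade"
  confusion_counts(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t),
                   level = "sample")
}

#' Event-level confusion counts by majority voting
#'
#' Each reference saccade event is assigned the most frequent predicted
#' class among its samples: a strict majority of saccade predictions makes
#' it a true positive, otherwise (including an exact tie) a false negative.
#' Symmetrically, each predicted saccade event whose samples fall by strict
#' majority in reference non-saccade regions is a false positive. Blink
#' samples are excluded from all majorities; events left without samples are
#' skipped. Slight boundary discrepancies therefore do not affect the
#' categorization.
#'
#' @inheritParams sample_level_eval
#' @return A [confusion_counts()] with `level = "event"`.
#' @export
event_level_eval <- function(pred, truth, rec) {
  al <- aligned_labels(pred, truth, rec)
  ts <- rec$timestamps
  majority_saccade <- function(ev_row, labels) {
    inside <- ts >= ev_row$start_ms & ts < ev_row$end_ms & !al$excluded
    n <- sum(inside)
    if (n == 0L) return(NA)
    sum(labels[inside] == "saccade") > n / 2
  }
  tp <- 0L; fn <- 0L; fp <- 0L
  truth_sacc <- truth[truth$label == "saccade", , drop = FALSE]
  for (k in seq_len(nrow(truth_sacc))) {
    m <- majority_saccade(truth_sacc[k, ], al$pred)
    if (is.na(m)) next
    if (m) tp <- tp + 1L else fn <- fn + 1L
  }
  pred_sacc <- pred[pred$label == "saccade", , drop = FALSE]
  for (k in seq_len(nrow(pred_sacc))) {
    m <- majority_saccade(pred_sacc[k, ], al$truth)
    if (is.na(m)) next
    if (!m) fp <- fp + 1L
  }
  confusion_counts(tp = tp, fp = fp, fn = fn, level = "event")
}

#' False-positive and false-negative rates
#'
#' `fn_rate` is the proportion of true saccade units (samples or events)
#' missed; `fp_rate` is the proportion of true non-saccade units falsely
#' called saccade.
#'
#' @param c A [confusion_counts()].
#' @param n_saccade_units Number of reference saccade units.
#' @param n_non_saccade_units Number of reference non-saccade units.
#' @return List with `fp_rate` and `fn_rate` (`NA` where the denominator is
#'   zero). At the event level an over-segmenting detector can produce more
#'   false-positive events than there are reference non-saccade intervals,
#'   so `fp_rate` may exceed 1.
#' @export
rate_report <- function(c, n_saccade_units, n_non_saccade_units) {
  stopifnot(inherits(c, "confusion_counts"),
            n_saccade_units >= 0, n_non_saccade_units >= 0)
  list(
    fp_rate = if (n_non_saccade_units > 0) c$fp / n_non_saccade_units else NA_real_,
    fn_rate = if (n_saccade_units > 0) c$fn / n_saccade_units else NA_real_
  )
}

#' Evaluate a prediction against a reference labeling
#'
#' Runs both evaluation levels and assembles F1-scores and error rates.
#'
#' @inheritParams sample_level_eval
#' @return An object of class `eval_report`: list with `sample_counts`,
#'   `event_counts`, `sample_f1`, `event_f1`, `sample_rates`, `event_rates`.
#' @export
evaluate_events <- function(pred, truth, rec) {
  sc <- sample_level_eval(pred, truth, rec)
  ec <- event_level_eval(pred, truth, rec)
  al <- aligned_labels(pred, truth, rec)
  keep <- !al$excluded
  n_sacc_samples <- sum(al$truth[keep] == "saccade")
  n_non_samples <- sum(al$truth[keep] != "saccade")
  truth_events <- truth[truth$label != "blink", , drop = FALSE]
  n_sacc_events <- sum(truth_events$label == "saccade")
  n_non_events <- sum(truth_events$label == "non_saccade")
  safe_f1 <- function(cc) {
    if (cc$tp + cc$fp + cc$fn == 0) NA_real_ else f1_score(cc)
  }
  structure(
    list(
      sample_counts = sc, event_counts = ec,
      sample_f1 = safe_f1(sc), event_f1 = safe_f1(ec),
      sample_rates = rate_report(sc, n_sacc_samples, n_non_samples),
      event_rates = rate_report(ec, n_sacc_events, n_non_events)
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    paste0("<eval_report>\n",
           "  sample level: F1 = %.3f (tp %d, fp %d, fn %d)\n",
           "  event level:  F1 = %.3f (tp %d, fp %d, fn %d)\n"),
    x$sample_f1, x$sample_counts$tp, x$sample_counts$fp, x$sample_counts$fn,
    x$event_f1, x$event_counts$tp, x$event_counts$fp, x$event_counts$fn
  ))
  invisible(x)
}

#' Sweep detector parameters against a reference labeling
#'
#' Evaluates a detector over the full Cartesian product of a parameter grid,
#' reporting sample- and event-level F1 for each setting -- the procedure
#' behind threshold-tuning heatmaps.
#'
#' @param detector One of `"idt"`, `"ivt"`, `"moving_window"`,
#'   `"ranking"`, `"ranking_eye"`.
#' @param grid Named list of parameter vectors; names must match the
#'   detector's parameter constructor arguments.
#' @param rec A [gaze_recording()].
#' @param truth Reference [event_intervals()].
#' @param scene Optional [scene_sequence()] (ranking only).
#' @return A tibble with one row per grid point: the parameter columns plus
#'   `sample_f1` and `event_f1`; the per-metric argmax rows are attached as
#'   attributes `best_sample` and `best_event`.
#' @export
parameter_sweep <- function(detector, grid, rec, truth, scene = NULL) {
  stopifnot(is.list(grid), length(grid) > 0L, !is.null(names(grid)))
  settings <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
  res <- vector("list", nrow(settings))
  for (i in seq_len(nrow(settings))) {
    args <- as.list(settings[i, , drop = FALSE])
    pred <- detect_events(rec, method = detector, scene = scene,
                          params = args)
    rep <- evaluate_events(pred, truth, rec)
    res[[i]] <- cbind(settings[i, , drop = FALSE],
                      sample_f1 = rep$sample_f1, event_f1 = rep$event_f1)
  }
  out <- as_tibble(do.call(rbind, res))
  attr(out, "best_sample") <- out[which.max(out$sample_f1), , drop = FALSE]
  attr(out, "best_event") <- out[which.max(out$event_f1), , drop = FALSE]
  out
}

#' Run a detector by name
#'
#' Dispatcher used by the sweep and the command-line interface.
#'
#' @param rec A [gaze_recording()].
#' @param method `"idt"`, `"ivt"`, `"moving_window"`, `"ranking"` (scene
#'   when available) or `"ranking_eye"` (eye-only).
#' @param scene Optional [scene_sequence()].
#' @param params Named list of parameters forwarded to the method's
#'   parameter constructor (threshold methods) or to [detect_ranking()].
#' @return An [event_intervals()].
#' @export
detect_events <- function(rec, method, scene = NULL, params = list()) {
  method <- match.arg(method,
                      c("idt", "ivt", "moving_window", "ranking",
                        "ranking_eye"))
  params <- params[!vapply(params, is.null, logical(1))]
  switch(
    method,
    idt = detect_idt(rec, do.call(idt_params, params)),
    ivt = detect_ivt(rec, do.call(ivt_params, params)),
    moving_window = detect_moving_window(rec, do.call(moving_window_params,
                                                      params)),
    ranking = do.call(detect_ranking,
                      c(list(rec = rec, scene = scene), params)),
    ranking_eye = do.call(detect_ranking,
                          c(list(rec = rec, scene = NULL, variant = "eye"),
                            params))
  )
}
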