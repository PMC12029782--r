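## Object-level evaluation: predictions are matched to ground-truth objects
## greedily by descending IoU (one-to-one); a matched pair at IoU >= the
## threshold is a true positive, an unmatched prediction a false positive,
## an unmatched truth a false negative. True negatives require an explicit
## caller-supplied count of negative evaluation units — object-free units —
## because a two-class segmentation task has no intrinsic "background
## object" count. All reported metrics are TRUNCATED (not rounded) to two
## decimals, and F1 is the harmonic mean of the truncated precision and
## recall; both conventions are needed to reproduce standard reported
## tables from raw counts (e.g. 9/17 = 0.529 reports as 0.52).

#' Per-class confusion counts
#'
#' @param class class label(s).
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return a tibble with one row per class.
#' @export
confusion_counts <- function(class, tp, fp, fn, tn) {
  out <- tibble(class = as.character(class), tp = as.integer(tp),
                fp = as.integer(fp), fn = as.integer(fn),
                tn = as.integer(tn))
  if (any(out$tp < 0 | out$fp < 0 | out$fn < 0 | out$tn < 0)) {
    abort("confusion counts must be non-negative.")
  }
  out
}

#' Match predicted to ground-truth masks and count the confusion cells
#'
#' @param pred_masks,truth_masks named lists (`BAC`, `AS`) of logical-mask
#'   lists sharing one image shape, as produced by [polygons_to_masks()].
#' @param iou_threshold match acceptance threshold in `(0, 1]`; default 0.5.
#' @param negative_units per-class count of evaluation units containing no
#'   object of that class; `tn = max(0, negative_units - fp)`. Either a
#'   single number or a named vector by class.
#' @return a [confusion_counts()] tibble with one row per class.
#' @export
match_and_count <- function(pred_masks, truth_masks, iou_threshold = 0.5,
                            negative_units = 0) {
  check_scalar_number(iou_threshold, "iou_threshold", min = 0, max = 1,
                      strict_min = TRUE)
  neg <- if (is.null(names(negative_units))) {
    setNames(rep_len(negative_units, length(.classes)), .classes)
  } else negative_units
  rows <- lapply(.classes, function(cl) {
    preds <- pred_masks[[cl]] %||% list()
    truths <- truth_masks[[cl]] %||% list()
    m <- greedy_match(preds, truths, iou_threshold)
    fp <- length(preds) - m
    confusion_counts(cl, tp = m, fp = fp, fn = length(truths) - m,
                     tn = max(0L, as.integer(neg[[cl]]) - fp))
  })
  dplyr::bind_rows(rows)
}

## greedy one-to-one matching by descending IoU; returns the TP count
greedy_match <- function(preds, truths, iou_threshold) {
  if (!length(preds) || !length(truths)) return(0L)
  iou <- matrix(0, length(preds), length(truths))
  for (i in seq_along(preds)) for (j in seq_along(truths)) {
    iou[i, j] <- suppressWarnings(mask_iou(preds[[i]], truths[[j]]))
  }
  tp <- 0L
  while (TRUE) {
    best <- which.max(iou)
    if (iou[best] < iou_threshold) break
    ij <- arrayInd(best, dim(iou))
    tp <- tp + 1L
    iou[ij[1], ] <- -1
    iou[, ij[2]] <- -1
    if (all(iou < 0)) break
  }
  tp
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Precision, truncated to two decimals
#'
#' `tp / (tp + fp)`; undefined (NA with a warning) when there are no
#' positive predictions.
#'
#' @param tp,fp,fn,tn confusion counts.
#' @return truncated metric value.
#' @export
precision_metric <- function(tp, fp) {
  if (tp + fp == 0) {
    warn("precision undefined: no positive predictions.")
    return(NA_real_)
  }
  truncate_decimals(tp / (tp + fp))
}

#' Recall, truncated to two decimals
#' @rdname precision_metric
#' @export
recall_metric <- function(tp, fn) {
  if (tp + fn == 0) {
    warn("recall undefined: no ground-truth positives.")
    return(NA_real_)
  }
  truncate_decimals(tp / (tp + fn))
}

#' F1 score from truncated precision and recall
#'
#' Harmonic mean `2PR / (P + R)` of the already-truncated precision and
#' recall, itself truncated to two decimals.
#'
#' @param precision,recall truncated metric values.
#' @return truncated F1.
#' @export
f1_metric <- function(precision, recall) {
  if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    warn("F1 undefined: precision + recall is zero or undefined.")
    return(NA_real_)
  }
  truncate_decimals(2 * precision * recall / (precision + recall))
}

#' Accuracy, truncated to two decimals
#' @rdname precision_metric
#' @export
accuracy_metric <- function(tp, fp, fn, tn) {
  total <- tp + fp + fn + tn
  if (total == 0) abort("accuracy undefined: total count is zero.")
  truncate_decimals((tp + tn) / total)
}

#' Metric table from confusion counts
#'
#' Computes truncated precision, recall, F1 (from truncated inputs) and
#' accuracy per row of a confusion-counts tibble. With a `run` column the
#' result pivots into a metric x class x run layout matching published
#' epoch-comparison tables.
#'
#' @param counts a [confusion_counts()] tibble, optionally with a `run`
#'   column identifying the training run / configuration.
#' @param wide pivot runs into columns (requires a `run` column).
#' @return a tibble of metrics.
#' @export
metrics_report <- function(counts, wide = FALSE) {
  if (!nrow(counts)) {
    return(tibble(class = character(), precision = numeric(),
                  recall = numeric(), f1 = numeric(), accuracy = numeric()))
  }
  out <- counts |>
    dplyr::rowwise() |>
    dplyr::mutate(precision = precision_metric(.data$tp, .data$fp),
                  recall = recall_metric(.data$tp, .data$fn),
                  f1 = f1_metric(.data$precision, .data$recall),
                  accuracy = accuracy_metric(.data$tp, .data$fp, .data$fn,
                                             .data$tn)) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::any_of(c("run", "class")), "precision", "recall",
                  "f1", "accuracy")
  if (wide) {
    if (!"run" %in% names(out)) abort("`wide = TRUE` needs a `run` column.")
    out <- out |>
      tidyr::pivot_longer(c("precision", "recall", "f1", "accuracy"),
                          names_to = "metric") |>
      tidyr::pivot_wider(names_from = "run", values_from = "value") |>
      dplyr::arrange(.data$metric, .data$class)
  }
  out
}
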