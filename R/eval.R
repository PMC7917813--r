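#' Confusion counts
#'
#' Counts true/false positives and negatives of a prediction vector
#' against ground truth for a designated positive class. In the
#' drowsiness pipeline the positive class is the closed-eye (drowsy)
#' state.
#'
#' @param pred,truth equal-length label vectors.
#' @param positive the label counted as positive.
#' @return A list of class `confusion_counts` with integer fields
#'   `tp`, `fp`, `tn`, `fn` summing to `length(truth)`.
#' @export
confusion_counts <- function(pred, truth, positive) {
  if (length(pred) != length(truth) || length(pred) < 1L) {
    stop("confusion_counts: pred and truth must have equal positive length",
         call. = FALSE)
  }
  p <- pred == positive
  t <- truth == positive
  structure(list(
    tp = sum(p & t), fp = sum(p & !t),
    tn = sum(!p & !t), fn = sum(!p & t)
  ), class = "confusion_counts")
}

#' Precision, recall, F1 and accuracy
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)`, `accuracy = (TP+TN)/n`. Zero-denominator cases
#' return 0 with a warning.
#'
#' @param counts a `confusion_counts` object.
#' @return Named numeric vector `precision`, `recall`, `f1`,
#'   `accuracy`, all in `[0, 1]`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$tp + counts$fp + counts$tn + counts$fn
  if (n < 1L) stop("classification_metrics: empty counts", call. = FALSE)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("classification_metrics: %s undefined (0/0), returning 0",
                      what), call. = FALSE)
      return(0)
    }
    num / den
  }
  precision <- safe_div(counts$tp, counts$tp + counts$fp, "precision")
  recall <- safe_div(counts$tp, counts$tp + counts$fn, "recall")
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  c(precision = precision, recall = recall, f1 = f1,
    accuracy = (counts$tp + counts$tn) / n)
}

#' Per-scenario evaluation report
#'
#' Builds the per-scenario report: for each of the five scenarios
#' (fixed row order, then an unweighted `average` row), the F1 score
#' with the drowsy (closed-eye) state as positive, the F1 score with
#' the non-drowsy state as positive, and the accuracy of each feature
#' path supplied in `predictions`.
#'
#' @param truth character vector of true labels (`"open"` /
#'   `"closed"`).
#' @param scenarios character vector of scenario tags (one of
#'   [scenario_names()]), same length.
#' @param predictions named list of prediction label vectors, one per
#'   feature path (e.g. `list(hog = ..., bosh = ...)`); F1 columns
#'   are computed from the last path in the list (the primary
#'   descriptor).
#' @param positive label treated as drowsy; default `"closed"`.
#' @return A data frame of class `eval_report` with columns
#'   `scenario`, `drowsy_f1`, `nondrowsy_f1`, and one
#'   `accuracy_<path>` column per feature path; metrics are
#'   proportions in `[0, 1]`. Scenarios with no samples are reported
#'   as `NA` and excluded from the average.
#' @export
scenario_report <- function(truth, scenarios, predictions,
                            positive = "closed") {
  if (!is.list(predictions) || is.null(names(predictions))) {
    stop("scenario_report: predictions must be a named list", call. = FALSE)
  }
  bad <- setdiff(unique(scenarios), scenario_names())
  if (length(bad) > 0) {
    stop(sprintf("scenario_report: unknown scenario tag(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (p in predictions) {
    if (length(p) != length(truth)) {
      stop("scenario_report: prediction length mismatch", call. = FALSE)
    }
  }
  negative_of <- function(pos, labels) setdiff(unique(labels), pos)[1]
  primary <- predictions[[length(predictions)]]
  rows <- lapply(scenario_names(), function(s) {
    in_s <- scenarios == s
    if (!any(in_s)) {
      acc <- stats::setNames(rep(NA_real_, length(predictions)),
                             paste0("accuracy_", names(predictions)))
      return(c(list(scenario = s, drowsy_f1 = NA_real_,
                    nondrowsy_f1 = NA_real_), as.list(acc)))
    }
    t_s <- truth[in_s]
    m_pos <- classification_metrics(
      confusion_counts(primary[in_s], t_s, positive))
    neg <- negative_of(positive, c(t_s, primary[in_s]))
    m_neg <- classification_metrics(
      confusion_counts(primary[in_s], t_s, neg))
    acc <- vapply(predictions, function(p) {
      classification_metrics(confusion_counts(p[in_s], t_s, positive))[["accuracy"]]
    }, numeric(1))
    names(acc) <- paste0("accuracy_", names(predictions))
    c(list(scenario = s, drowsy_f1 = m_pos[["f1"]],
           nondrowsy_f1 = m_neg[["f1"]]), as.list(acc))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  avg <- as.data.frame(c(list(scenario = "average"),
                         as.list(colMeans(df[, -1, drop = FALSE],
                                          na.rm = TRUE))))
  out <- rbind(df, avg)
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.eval_report <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf(paste0("%.", digits, "f"),
                                                 100 * v))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report
#'
#' Writes the report as CSV (metrics in percent) and as an aligned
#' plain-text table.
#'
#' @param report an `eval_report`.
#' @param csv_path,txt_path output paths (`NULL` to skip either).
#' @return The report, invisibly.
#' @export
write_report <- function(report, csv_path = NULL, txt_path = NULL) {
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round(100 * v, 2))
  if (!is.null(csv_path)) {
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(txt_path)) {
    widths <- pmax(nchar(names(df)),
                   vapply(df, function(c) max(nchar(format(c))), integer(1)))
    fmt_row <- function(vals) {
      paste(mapply(formatC, as.character(vals), width = widths),
            collapse = "  ")
    }
    lines <- c(fmt_row(names(df)),
               vapply(seq_len(nrow(df)), function(i) fmt_row(df[i, ]),
                      character(1)))
    writeLines(lines, txt_path)
  }
  invisible(report)
}
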