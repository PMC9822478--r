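# Evaluation quantities for conformal prediction sets: per-class validity and
# efficiency, the validity flag (observed error may exceed the significance
# level by at most 2.5 percentage points), and sensitivity / specificity /
# balanced accuracy over the single-label predictions.

check_sets <- function(sets, labels) {
  stopifnot(inherits(sets, "prediction_sets") || is.data.frame(sets))
  labels <- align_labels(labels, sets$id)
  labels
}

#' Per-class validity
#'
#' Among true-class-`class` compounds, the fraction whose prediction set
#' contains the true class. A both-label set is always correct; an empty set
#' is always an error.
#'
#' @param sets a [predict_set()] data.frame (single significance level).
#' @param labels true 0/1 labels, named by id or parallel to `sets`.
#' @param class 0 or 1.
#' @return fraction in \[0, 1\].
#' @export
cp_validity <- function(sets, labels, class) {
  labels <- check_sets(sets, labels)
  cls <- as.integer(class)
  idx <- labels == cls
  mean(grepl(as.character(cls), sets$set[idx], fixed = TRUE))
}

#' Per-class efficiency
#'
#' Among true-class-`class` compounds, the fraction receiving a single-label
#' prediction (either label, correct or not). Conditioning on the true class
#' matches the per-class validity reporting of Mondrian calibration.
#'
#' @inheritParams cp_validity
#' @return fraction in \[0, 1\].
#' @export
cp_efficiency <- function(sets, labels, class) {
  labels <- check_sets(sets, labels)
  idx <- labels == as.integer(class)
  mean(sets$outcome[idx] %in% c("single_0", "single_1"))
}

#' Validity flag
#'
#' A model is considered valid for a class when its observed error rate does
#' not exceed the significance level by more than `tolerance` (default 2.5
#' percentage points).
#'
#' @param validity observed per-class validity (fraction).
#' @param epsilon significance level.
#' @param tolerance allowed excess error, default 0.025.
#' @return logical.
#' @export
validity_flag <- function(validity, epsilon, tolerance = 0.025) {
  (1 - validity) <= epsilon + tolerance
}

#' Outcome-by-true-class contingency
#'
#' @inheritParams cp_validity
#' @return 2 x 4 integer table: rows = true class (0, 1), columns = outcome
#'   (`single_0`, `single_1`, `both`, `empty`).
#' @export
cp_contingency <- function(sets, labels) {
  labels <- check_sets(sets, labels)
  table(true_class = factor(labels, levels = c(0L, 1L)),
        outcome = factor(sets$outcome, levels = outcome_levels))
}

#' Sensitivity, specificity and balanced accuracy of single-label predictions
#'
#' Computed over single-label predictions only (both- and empty-set compounds
#' are excluded): `SE = TP/(TP+FN)`, `SP = TN/(TN+FP)`, `BA = (SE+SP)/2`, with
#' the positive class being class 1 (the minority/toxic class coding). A zero
#' denominator yields `NA`, never a silent 0/0.
#'
#' @inheritParams cp_validity
#' @param positive the positive class, default 1.
#' @return list with `SE`, `SP`, `BA`, and `counts` (TP, FN, TN, FP).
#' @export
confusion_metrics <- function(sets, labels, positive = 1L) {
  labels <- check_sets(sets, labels)
  positive <- as.integer(positive)
  negative <- 1L - positive
  single <- sets$outcome %in% c("single_0", "single_1")
  pred <- ifelse(sets$outcome == "single_1", 1L, 0L)[single]
  truth <- labels[single]
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred == negative)
  tn <- sum(truth == negative & pred == negative)
  fp <- sum(truth == negative & pred == positive)
  se <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  ba <- if (is.na(se) || is.na(sp)) NA_real_ else (se + sp) / 2
  list(SE = se, SP = sp, BA = ba, counts = c(TP = tp, FN = fn, TN = tn, FP = fp))
}

#' One evaluation-report row for a conformal run
#'
#' Bundles every reported quantity for one (dataset, method, significance)
#' combination: per-class validity and efficiency, the per-class validity
#' flags, SE/SP/BA, and the full outcome-by-true-class contingency.
#'
#' @inheritParams cp_validity
#' @param dataset,method tags identifying the run.
#' @param tolerance validity tolerance, see [validity_flag()].
#' @return one-row data.frame of class `cp_metrics_report` with the
#'   contingency table in the `"contingency"` attribute.
#' @export
cp_metrics <- function(sets, labels, dataset = "dataset", method = "method",
                       tolerance = 0.025) {
  labels <- check_sets(sets, labels)
  eps <- unique(sets$epsilon)
  if (length(eps) != 1L) stop("`sets` must be at a single significance level",
                              call. = FALSE)
  v1 <- cp_validity(sets, labels, 1L)
  v0 <- cp_validity(sets, labels, 0L)
  cm <- confusion_metrics(sets, labels)
  out <- data.frame(dataset = dataset, method = method, significance = eps,
                    validity_1 = v1, validity_0 = v0,
                    efficiency_1 = cp_efficiency(sets, labels, 1L),
                    efficiency_0 = cp_efficiency(sets, labels, 0L),
                    SE = cm$SE, SP = cm$SP, BA = cm$BA,
                    is_valid_1 = validity_flag(v1, eps, tolerance),
                    is_valid_0 = validity_flag(v0, eps, tolerance),
                    stringsAsFactors = FALSE)
  attr(out, "contingency") <- cp_contingency(sets, labels)
  class(out) <- c("cp_metrics_report", "data.frame")
  out
}

#' Render a results table from metric reports
#'
#' One row per (dataset, method); columns ordered validity before efficiency
#' before SE/SP/BA. For a row where either class fails the validity flag, the
#' efficiency and SE/SP/BA cells are blanked (`NA`, written as empty cells):
#' those quantities are not meaningful for an invalid model.
#'
#' @param reports list of [cp_metrics()] rows (or a single one).
#' @param file optional CSV path; `NA` cells are written blank.
#' @return data.frame with columns `dataset`, `method`, `significance`,
#'   `validity_1`, `validity_0`, `efficiency_1`, `efficiency_0`, `SE`, `SP`,
#'   `BA`.
#' @export
report_table <- function(reports, file = NULL) {
  if (inherits(reports, "cp_metrics_report")) reports <- list(reports)
  cols <- c("dataset", "method", "significance", "validity_1", "validity_0",
            "efficiency_1", "efficiency_0", "SE", "SP", "BA")
  if (length(reports) == 0L) {
    tab <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    tab <- do.call(rbind, lapply(reports, function(r) {
      stopifnot(inherits(r, "cp_metrics_report"))
      row <- as.data.frame(r)[, cols]
      if (!r$is_valid_1 || !r$is_valid_0) {
        row[, c("efficiency_1", "efficiency_0", "SE", "SP", "BA")] <- NA_real_
      }
      row
    }))
    rownames(tab) <- NULL
  }
  if (!is.null(file)) utils::write.csv(tab, file, row.names = FALSE, na = "")
  tab
}
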