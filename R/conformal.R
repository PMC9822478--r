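# Mondrian inductive conformal prediction primitives.
#
# Class-conditional (Mondrian) calibration: nonconformity scores of the
# calibration compounds are pooled per true class, and a test compound's
# p-value for candidate class c is its calibrated rank among the class-c
# scores. The Mondrian construction is what delivers per-class validity, and
# with it the graceful handling of class imbalance: each class is guaranteed
# its own error rate regardless of how rare it is.

#' Nonconformity from a class probability
#'
#' The inverse-probability nonconformity measure: `alpha = 1 - score`, where
#' `score` is the base learner's predicted probability for the candidate
#' class. Strictly decreasing in the score.
#'
#' @param class_score numeric vector of class probabilities in \[0, 1\].
#' @return numeric vector of nonconformity scores in \[0, 1\].
#' @export
nonconformity <- function(class_score) {
  if (!is.numeric(class_score) || any(!is.finite(class_score)) ||
      any(class_score < 0 | class_score > 1)) {
    stop("class scores must be finite and in [0, 1]", call. = FALSE)
  }
  1 - class_score
}

#' Build a Mondrian calibration table
#'
#' For each calibration compound, the nonconformity score is computed against
#' the probability of its own true class, and stored in that class's score
#' multiset.
#'
#' @param prob numeric matrix of calibration-set class probabilities, one row
#'   per compound, columns `"0"` and `"1"`.
#' @param labels 0/1 true labels of the calibration compounds; both classes
#'   must be present.
#' @return object of class `calib_table`: list with `scores` (list of numeric
#'   vectors, one per class) and `n` (named counts).
#' @export
build_calibration_table <- function(prob, labels) {
  prob <- as.matrix(prob)
  stopifnot(ncol(prob) == 2L)
  if (is.null(colnames(prob))) colnames(prob) <- c("0", "1")
  labels <- assert_binary_labels(labels)
  stopifnot(length(labels) == nrow(prob))
  if (length(unique(labels)) < 2L) {
    stop("calibration set must contain both classes", call. = FALSE)
  }
  scores <- lapply(c("0", "1"), function(cls) {
    idx <- labels == as.integer(cls)
    nonconformity(prob[idx, cls])
  })
  names(scores) <- c("0", "1")
  structure(list(scores = scores,
                 n = vapply(scores, length, integer(1))),
            class = "calib_table")
}

#' @export
print.calib_table <- function(x, ...) {
  cat(sprintf("Mondrian calibration table: n_0 = %d, n_1 = %d\n",
              x$n[["0"]], x$n[["1"]]))
  invisible(x)
}

#' Mondrian conformal p-value
#'
#' Without smoothing: `p = (#\{alpha_i >= alpha_test\} + 1) / (n_c + 1)` over
#' the class-`c` calibration scores — the conservative convention in which
#' ties count in the test compound's favour. With smoothing, ties (and the
#' test compound itself) contribute a uniform fraction drawn from `tie_seed`,
#' giving exact rather than conservative validity.
#'
#' @param alpha_test numeric vector of test nonconformity scores.
#' @param class `"0"` or `"1"` (or 0/1): which class's calibration scores to
#'   rank against.
#' @param table a [build_calibration_table()] result.
#' @param smoothing logical; default `FALSE`.
#' @param tie_seed integer seed for the smoothing draws (required when
#'   `smoothing = TRUE` for reproducibility).
#' @return numeric vector of p-values in (0, 1\].
#' @export
p_value <- function(alpha_test, class, table, smoothing = FALSE, tie_seed = NULL) {
  stopifnot(inherits(table, "calib_table"))
  class <- as.character(as.integer(as.character(class)))
  stopifnot(class %in% c("0", "1"))
  stopifnot(is.numeric(alpha_test), all(is.finite(alpha_test)))
  cal <- sort(table$scores[[class]])
  n_c <- length(cal)
  # counts via binary search on the sorted calibration scores
  n_le <- findInterval(alpha_test, cal)                       # #{alpha_i <= t}
  n_lt <- findInterval(alpha_test, cal, left.open = TRUE)     # #{alpha_i <  t}
  n_gt <- n_c - n_le
  n_eq <- n_le - n_lt
  if (smoothing) {
    if (!is.null(tie_seed)) set.seed(tie_seed)
    u <- stats::runif(length(alpha_test))
    p <- (n_gt + u * (n_eq + 1)) / (n_c + 1)
  } else {
    p <- (n_gt + n_eq + 1) / (n_c + 1)
  }
  pmin(pmax(p, .Machine$double.eps), 1)
}

#' Median-aggregate p-values across ensemble members
#'
#' Per compound and class, the sample median of the members' p-values; for an
#' even number of members, the mean of the two central order statistics.
#'
#' @param p_members list of K p-value matrices with identical rownames (ids)
#'   and colnames (`"p0"`, `"p1"`).
#' @return one aggregated p-value matrix.
#' @export
median_aggregate <- function(p_members) {
  stopifnot(is.list(p_members), length(p_members) >= 1L)
  ref <- p_members[[1L]]
  for (m in p_members[-1L]) {
    if (!identical(dimnames(m), dimnames(ref))) {
      stop("ensemble members disagree on compound ids or columns", call. = FALSE)
    }
  }
  arr <- array(unlist(p_members), dim = c(dim(ref), length(p_members)))
  out <- apply(arr, c(1L, 2L), stats::median)
  dimnames(out) <- dimnames(ref)
  out
}

outcome_levels <- c("single_0", "single_1", "both", "empty")

#' Prediction sets at a significance level
#'
#' Class `c` enters the set iff its p-value strictly exceeds `epsilon`. The
#' four possible outcomes of a binary conformal prediction: a single label
#' (`single_0`, `single_1`), both labels, or the empty set.
#'
#' @param p p-value matrix (columns `p0`, `p1`, rownames = ids).
#' @param epsilon significance level in (0, 1).
#' @return data.frame of class `prediction_sets` with columns `id`, `epsilon`,
#'   `set` (one of `"0"`, `"1"`, `"01"`, `""`), `outcome`.
#' @export
predict_set <- function(p, epsilon = 0.2) {
  p <- as.matrix(p)
  stopifnot(ncol(p) == 2L, epsilon > 0, epsilon < 1)
  in0 <- p[, 1L] > epsilon
  in1 <- p[, 2L] > epsilon
  set <- ifelse(in0 & in1, "01", ifelse(in0, "0", ifelse(in1, "1", "")))
  outcome <- ifelse(in0 & in1, "both",
                    ifelse(in0, "single_0", ifelse(in1, "single_1", "empty")))
  structure(data.frame(id = rownames(p) %||% as.character(seq_len(nrow(p))),
                       epsilon = epsilon, set = set,
                       outcome = factor(outcome, levels = outcome_levels),
                       stringsAsFactors = FALSE),
            class = c("prediction_sets", "data.frame"))
}

#' Calibrate external model scores into conformal p-values
#'
#' Converts per-compound class-1 scores (e.g. the output of an externally
#' trained classifier) into Mondrian conformal p-values, using a calibration
#' set scored by the same model. The binary score `s` maps to nonconformity
#' `alpha_1 = 1 - s` for class 1 and `alpha_0 = s` for class 0 — identical to
#' the internal inverse-probability path on the score matrix `(1 - s, s)`.
#'
#' @param calib_scores class-1 scores of the calibration compounds, in \[0, 1\].
#' @param calib_labels their 0/1 true labels (both classes required).
#' @param test_scores class-1 scores of the compounds to predict.
#' @param test_ids optional ids for the rows of the result; defaults to
#'   `names(test_scores)`.
#' @param smoothing,tie_seed as in [p_value()].
#' @return p-value matrix (columns `p0`, `p1`).
#' @export
calibrate_external_scores <- function(calib_scores, calib_labels, test_scores,
                                      test_ids = names(test_scores),
                                      smoothing = FALSE, tie_seed = NULL) {
  check_unit <- function(s, what, ids) {
    bad <- !is.finite(s) | s < 0 | s > 1
    if (any(bad)) {
      off <- if (is.null(ids)) which(bad) else ids[bad]
      stop(sprintf("%s scores outside [0, 1] for: %s", what,
                   paste(utils::head(off, 5L), collapse = ", ")), call. = FALSE)
    }
  }
  check_unit(calib_scores, "calibration", names(calib_scores))
  check_unit(test_scores, "test", test_ids)
  tab <- build_calibration_table(cbind("0" = 1 - calib_scores, "1" = calib_scores),
                                 calib_labels)
  p <- cbind(
    p0 = p_value(nonconformity(1 - test_scores), "0", tab, smoothing, tie_seed),
    p1 = p_value(nonconformity(test_scores), "1", tab, smoothing,
                 if (is.null(tie_seed)) NULL else tie_seed + 1L)
  )
  rownames(p) <- test_ids %||% as.character(seq_along(test_scores))
  p
}
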