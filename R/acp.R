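# The fitted-model surface: mondrian_acp() trains an ensemble of Mondrian
# inductive conformal predictors (one per split) and predict() emits
# median-aggregated p-values or prediction sets.

#' Random-forest base learner
#'
#' The default base-learner slot: a random forest with the toolkit's default
#' options, exposing class probabilities. Any list with the same `fit` /
#' `predict_prob` contract (class `cp_learner`) can stand in — e.g. a wrapper
#' around externally computed scores.
#'
#' @param ntree number of trees.
#' @param ... further arguments passed to [randomForest::randomForest()].
#' @return an object of class `cp_learner`.
#' @export
rf_learner <- function(ntree = 500, ...) {
  extra <- list(...)
  structure(list(
    name = "random forest",
    fit = function(x, y, seed) {
      set.seed(seed)
      do.call(randomForest::randomForest,
              c(list(x = x, y = factor(y, levels = c(0L, 1L)), ntree = ntree),
                extra))
    },
    predict_prob = function(model, x) {
      p <- stats::predict(model, x, type = "prob")
      p[, c("0", "1"), drop = FALSE]
    }
  ), class = "cp_learner")
}

#' Fit a Mondrian aggregated conformal predictor
#'
#' For each ensemble member: fit the base learner on the member's
#' proper-training part (the deep-learning-validation part, if any, is folded
#' in — it only exists for base learners that need early stopping), then build
#' the member's class-conditional calibration table from its calibration part.
#' Prediction median-aggregates the members' p-values.
#'
#' @param x numeric feature matrix with rownames = ids, covering the training
#'   pool (rows outside the splits are ignored).
#' @param y 0/1 labels, named by id or parallel to `rownames(x)`.
#' @param splits a [make_splits()] result; if `NULL`, splits are generated
#'   from `rownames(x)` with the given `fractions`, `K` and `seed`.
#' @param K,fractions passed to [make_splits()] when `splits` is `NULL`.
#' @param learner a `cp_learner`; default [rf_learner()].
#' @param smoothing default smoothing flag for [p_value()] at prediction time.
#' @param seed master seed; all member seeds derive from it.
#' @return an object of class `mondrian_acp`.
#' @seealso [predict.mondrian_acp()]
#' @export
mondrian_acp <- function(x, y, splits = NULL, K = 10L,
                         fractions = c(train = 0.72, dl_val = 0.08, calib = 0.20),
                         learner = rf_learner(), smoothing = FALSE, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop("`x` must have ids as rownames", call. = FALSE)
  stopifnot(inherits(learner, "cp_learner"))
  y <- align_labels(y, rownames(x), "y")
  if (is.null(splits)) {
    splits <- make_splits(rownames(x), y, fractions = fractions, K = K, seed = seed)
  }
  stopifnot(inherits(splits, "dataset_splits"))

  members <- lapply(splits, function(s) {
    train_ids <- c(s$proper_train_ids, s$dl_validation_ids)
    calib_ids <- s$calibration_ids
    missing <- setdiff(c(train_ids, calib_ids), rownames(x))
    if (length(missing) > 0L) {
      stop("split ids absent from feature matrix: ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    }
    learner_seed <- derive_seed(seed, s$member, stream = 2L)
    model <- tryCatch(
      learner$fit(x[train_ids, , drop = FALSE], y[train_ids], learner_seed),
      error = function(e) stop(sprintf("base learner failed on member %d: %s",
                                       s$member, conditionMessage(e)), call. = FALSE)
    )
    calib_prob <- learner$predict_prob(model, x[calib_ids, , drop = FALSE])
    list(model = model,
         table = build_calibration_table(calib_prob, y[calib_ids]),
         member = s$member,
         learner_seed = learner_seed)
  })

  structure(list(members = members, K = length(members), learner = learner,
                 smoothing = smoothing, seed = seed, splits = splits,
                 n_pool = length(unique(c(splits[[1L]]$proper_train_ids,
                                          splits[[1L]]$dl_validation_ids,
                                          splits[[1L]]$calibration_ids))),
                 call = match.call()),
            class = "mondrian_acp")
}

# p-value matrices for all members on a feature matrix
member_pvalues <- function(object, newx, smoothing) {
  lapply(object$members, function(m) {
    prob <- object$learner$predict_prob(m$model, newx)
    tie <- derive_seed(object$seed, m$member, stream = 3L)
    p <- cbind(p0 = p_value(nonconformity(prob[, "0"]), "0", m$table,
                            smoothing, tie),
               p1 = p_value(nonconformity(prob[, "1"]), "1", m$table,
                            smoothing, tie + 1L))
    rownames(p) <- rownames(newx)
    p
  })
}

#' Predict conformal p-values or prediction sets
#'
#' @param object a fitted [mondrian_acp()].
#' @param newdata feature matrix with ids as rownames.
#' @param type `"p.value"` for the p-value matrix, `"set"` for prediction
#'   sets at the given `epsilon` level(s).
#' @param epsilon significance level(s) used when `type = "set"`.
#' @param aggregate if `TRUE` (default) median-aggregate across members;
#'   if `FALSE` return the list of per-member p-value matrices.
#' @param smoothing override the fit-time smoothing flag.
#' @param ... unused.
#' @return a p-value matrix (columns `p0`, `p1`), a list of them
#'   (`aggregate = FALSE`), or a `prediction_sets` data.frame (`type = "set"`,
#'   rows stacked over `epsilon`).
#' @export
predict.mondrian_acp <- function(object, newdata, type = c("p.value", "set"),
                                 epsilon = 0.2, aggregate = TRUE,
                                 smoothing = object$smoothing, ...) {
  type <- match.arg(type)
  newx <- as.matrix(newdata)
  if (is.null(rownames(newx))) rownames(newx) <- as.character(seq_len(nrow(newx)))
  pm <- member_pvalues(object, newx, smoothing)
  if (!aggregate && type == "p.value") return(pm)
  p <- median_aggregate(pm)
  if (type == "p.value") return(p)
  do.call(rbind, lapply(epsilon, function(e) predict_set(p, e)))
}

#' @export
print.mondrian_acp <- function(x, ...) {
  cat("Mondrian aggregated conformal predictor\n")
  cat(sprintf("  members: %d (%s base learner), pool size %d\n",
              x$K, x$learner$name, x$n_pool))
  n <- sapply(x$members, function(m) m$table$n)
  cat(sprintf("  calibration per member: n_0 = %d, n_1 = %d\n",
              n["0", 1L], n["1", 1L]))
  cat(sprintf("  smoothing: %s, master seed: %d\n",
              if (x$smoothing) "on" else "off", x$seed))
  invisible(x)
}

#' @export
summary.mondrian_acp <- function(object, ...) {
  n <- sapply(object$members, function(m) m$table$n)
  structure(list(K = object$K, learner = object$learner$name,
                 n_pool = object$n_pool, seed = object$seed,
                 smoothing = object$smoothing,
                 calib_counts = t(n)), class = "summary.mondrian_acp")
}

#' @export
print.summary.mondrian_acp <- function(x, ...) {
  cat("Mondrian aggregated conformal predictor\n")
  cat(sprintf("  %d member(s), base learner: %s, pool size %d, seed %d\n",
              x$K, x$learner, x$n_pool, x$seed))
  cat("  calibration-set class counts per member:\n")
  print(x$calib_counts)
  invisible(x)
}

#' Empirical calibration of a conformal predictor
#'
#' Per-class error rate, validity and efficiency over a grid of significance
#' levels — the standard diagnostic for a conformal predictor: a valid model
#' keeps each class's error curve at or below the diagonal.
#'
#' @param p p-value matrix (columns `p0`, `p1`, rownames = ids).
#' @param labels true 0/1 labels, named by id or parallel to the rows.
#' @param epsilons grid of significance levels.
#' @return data.frame with columns `epsilon`, `class`, `error_rate`,
#'   `validity`, `efficiency`.
#' @export
cp_calibration <- function(p, labels, epsilons = seq(0.05, 0.5, by = 0.05)) {
  labels <- align_labels(labels, rownames(p))
  do.call(rbind, lapply(epsilons, function(e) {
    sets <- predict_set(p, e)
    do.call(rbind, lapply(c(0L, 1L), function(cls) {
      v <- cp_validity(sets, labels, cls)
      data.frame(epsilon = e, class = cls, error_rate = 1 - v, validity = v,
                 efficiency = cp_efficiency(sets, labels, cls))
    }))
  }))
}

#' Plot the calibration of a fitted conformal predictor
#'
#' Draws the per-class error rate against the significance level for held-out
#' data; the dashed diagonal is the validity bound that Mondrian calibration
#' guarantees (up to sampling noise) for each class separately.
#'
#' @param x a fitted `mondrian_acp`.
#' @param newdata evaluation feature matrix (ids as rownames).
#' @param labels true 0/1 labels for `newdata`.
#' @param epsilons significance grid.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the [cp_calibration()] table.
#' @method plot mondrian_acp
#' @export
plot.mondrian_acp <- function(x, newdata, labels,
                              epsilons = seq(0.05, 0.5, by = 0.05), ...) {
  p <- stats::predict(x, newdata)
  cal <- cp_calibration(p, labels, epsilons)
  graphics::plot(NA, xlim = range(epsilons), ylim = c(0, max(cal$error_rate, epsilons)),
                 xlab = "significance level", ylab = "observed error rate", ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  for (cls in c(0L, 1L)) {
    sub <- cal[cal$class == cls, ]
    graphics::lines(sub$epsilon, sub$error_rate, type = "b",
                    pch = c(1, 16)[cls + 1L], col = c("#1b6ca8", "#c0392b")[cls + 1L])
  }
  graphics::legend("topleft", legend = c("class 0", "class 1"), bty = "n",
                   pch = c(1, 16), col = c("#1b6ca8", "#c0392b"))
  invisible(cal)
}
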