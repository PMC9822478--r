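# Stratified partitioning of the training pool into proper-training /
# (optional) deep-learning-validation / conformal-calibration parts, one
# independent random partition per ensemble member. Default fractions
# (0.72 / 0.08 / 0.20) reflect the typical proportions of an acute-toxicity
# modelling campaign's training pool.

# largest-remainder apportionment: integer sizes summing exactly to n
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0L) {
    frac <- raw - sizes
    # ties broken by position, deterministically
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    sizes[add] <- sizes[add] + 1L
  }
  as.integer(sizes)
}

#' Generate ensemble splits of the training pool
#'
#' Produces `K` independent, label-stratified random partitions of the pool
#' into proper-training, deep-learning-validation and conformal-calibration
#' parts. Each ensemble member re-partitions the pool with its own seed,
#' derived deterministically from `seed` — the construction that makes median
#' aggregation of the members' p-values meaningful.
#'
#' Stratification is exact per class (largest-remainder apportionment within
#' each class), so each part's class ratio tracks the pool's.
#'
#' @param ids character vector of pool ids (unique).
#' @param labels 0/1 labels, named by id or parallel to `ids`.
#' @param fractions numeric length-3 vector `(train, dl_val, calib)` summing
#'   to 1. `dl_val` may be 0 (non-deep base learners fold it into training).
#' @param K number of ensemble members.
#' @param seed master seed; member seeds are derived via [derive_seed()].
#' @param evaluation_ids optional ids of the held-out evaluation set; must be
#'   disjoint from `ids`, and is carried on each split unchanged.
#' @return an object of class `dataset_splits`: a list of `K` `dataset_split`
#'   objects, each with `proper_train_ids`, `dl_validation_ids`,
#'   `calibration_ids`, `evaluation_ids`, `seed`, `member`.
#' @export
make_splits <- function(ids, labels,
                        fractions = c(train = 0.72, dl_val = 0.08, calib = 0.20),
                        K = 10L, seed = 1L, evaluation_ids = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("pool ids must be unique", call. = FALSE)
  stopifnot(length(fractions) == 3L, all(fractions >= 0), K >= 1L)
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1", call. = FALSE)
  labels <- align_labels(labels, ids)
  if (!is.null(evaluation_ids) && length(intersect(evaluation_ids, ids)) > 0L) {
    stop("evaluation ids must be disjoint from the training pool", call. = FALSE)
  }

  splits <- lapply(seq_len(K), function(k) {
    child <- derive_seed(seed, k, stream = 1L)
    set.seed(child)
    parts <- list(character(0), character(0), character(0))
    for (cls in c(0L, 1L)) {
      cls_ids <- ids[labels == cls]
      sizes <- largest_remainder(length(cls_ids), fractions)
      active <- fractions > 0
      if (any(sizes[active] < 2L)) {
        stop(sprintf("member %d: class %d would give a part fewer than 2 compounds",
                     k, cls), call. = FALSE)
      }
      perm <- sample(cls_ids)
      idx <- cumsum(sizes)
      parts[[1L]] <- c(parts[[1L]], perm[seq_len(sizes[1L])])
      if (sizes[2L] > 0L) parts[[2L]] <- c(parts[[2L]], perm[(idx[1L] + 1L):idx[2L]])
      if (sizes[3L] > 0L) parts[[3L]] <- c(parts[[3L]], perm[(idx[2L] + 1L):idx[3L]])
    }
    structure(list(proper_train_ids = parts[[1L]],
                   dl_validation_ids = parts[[2L]],
                   calibration_ids = parts[[3L]],
                   evaluation_ids = as.character(evaluation_ids %||% character(0)),
                   seed = child, member = k),
              class = "dataset_split")
  })
  structure(splits, class = "dataset_splits", master_seed = seed)
}

#' Flatten splits into a manifest table
#'
#' @param splits a `dataset_splits` object.
#' @return data.frame with columns `id`, `member_index`, `part`
#'   (train / dl_val / calib).
#' @export
split_manifest <- function(splits) {
  stopifnot(inherits(splits, "dataset_splits"))
  do.call(rbind, lapply(splits, function(s) {
    data.frame(
      id = c(s$proper_train_ids, s$dl_validation_ids, s$calibration_ids),
      member_index = s$member,
      part = rep(c("train", "dl_val", "calib"),
                 c(length(s$proper_train_ids), length(s$dl_validation_ids),
                   length(s$calibration_ids))),
      stringsAsFactors = FALSE
    )
  }))
}

#' @export
print.dataset_splits <- function(x, ...) {
  s <- x[[1L]]
  cat(sprintf("%d ensemble split(s) of a pool of %d ids (train %d / dl_val %d / calib %d)\n",
              length(x),
              length(s$proper_train_ids) + length(s$dl_validation_ids) +
                length(s$calibration_ids),
              length(s$proper_train_ids), length(s$dl_validation_ids),
              length(s$calibration_ids)))
  invisible(x)
}
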