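# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' One master seed drives every source of randomness in a run: per-member
#' split seeds, base-learner seeds and tie-break seeds are derived from it
#' with a fixed affine map, so a whole experiment is reproducible from a
#' single integer. Streams keep the different uses decorrelated: 1 = splits,
#' 2 = base learner, 3 = smoothing tie-breaks, 4 = data generation.
#'
#' @param master integer master seed.
#' @param index member index (1-based) or other counter.
#' @param stream integer stream id separating the uses of randomness.
#' @return an integer seed in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(master, index = 1L, stream = 1L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  # double arithmetic is exact here (values < 2^53)
  as.integer((abs(master) + 104729 * index + 7919 * stream) %% 2147483647)
}

assert_binary_labels <- function(labels, arg = "labels") {
  if (!all(labels %in% c(0L, 1L))) {
    stop(sprintf("`%s` must be coded 0/1", arg), call. = FALSE)
  }
  as.integer(labels)
}

# labels aligned to a character id vector; labels may be named or parallel
align_labels <- function(labels, ids, arg = "labels") {
  if (!is.null(names(labels))) {
    missing <- setdiff(ids, names(labels))
    if (length(missing) > 0L) {
      stop(sprintf("no label for id(s): %s", paste(utils::head(missing, 5L), collapse = ", ")),
           call. = FALSE)
    }
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop(sprintf("`%s` must be named by id or have one entry per row", arg), call. = FALSE)
  }
  stats::setNames(assert_binary_labels(labels, arg), ids)
}
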