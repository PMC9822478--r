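# Synthetic data with the statistical structure the conformal machinery
# assumes: exchangeable (i.i.d.) draws, binary labels at controllable
# imbalance, and Gaussian class-conditional features with controllable
# overlap. Two presets mirror the class structure of binary acute-toxicity
# benchmarks: "nt" (non-toxic endpoint, majority:minority ~ 1.6:1) and "vt"
# (very-toxic endpoint, ~ 11:1).

#' Configuration for the synthetic tabular generator
#'
#' @param regime `"nt"` (imbalance 1.6:1), `"vt"` (11:1) or `"custom"`.
#' @param n_total number of compounds. The default matches the scale of an
#'   acute-toxicity modelling campaign (~8,000 training + ~2,800 evaluation).
#' @param imbalance majority:minority ratio (used when `regime = "custom"`;
#'   the presets set 1.6 and 11).
#' @param dimension number of features.
#' @param delta class separation: distance between the two class mean vectors
#'   in units of the (identity) within-class standard deviation. 0 = classes
#'   indistinguishable.
#' @param label_noise probability, in \[0, 0.5), of independently flipping
#'   each label after the features are drawn.
#' @param seed integer seed.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(regime = c("custom", "nt", "vt"), n_total = 10800L,
                         imbalance = 11, dimension = 16L, delta = 1.5,
                         label_noise = 0, seed = 1L) {
  regime <- match.arg(regime)
  imbalance <- switch(regime, nt = 1.6, vt = 11, custom = imbalance)
  stopifnot(n_total >= 20L, imbalance >= 1, dimension >= 1L, delta >= 0,
            label_noise >= 0, label_noise < 0.5)
  structure(list(regime = regime, n_total = as.integer(n_total),
                 imbalance = imbalance, dimension = as.integer(dimension),
                 delta = delta, label_noise = label_noise,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate an exchangeable synthetic dataset
#'
#' Two multivariate-normal classes with identity within-class covariance and
#' mean vectors `delta` apart along a random unit direction; class counts
#' follow the configured imbalance ratio (minority = class 1); labels are then
#' flipped independently with probability `label_noise`; finally the rows are
#' shuffled. Rows are i.i.d. draws, hence exchangeable across any later
#' split — the precondition of the conformal coverage guarantee.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_data` with `x` (feature matrix, ids as
#'   rownames), `labels` (named 0/1 vector, 1 = minority) and `config`.
#' @export
generate_tabular <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n_min <- round(config$n_total / (config$imbalance + 1))
  n_maj <- config$n_total - n_min
  if (n_min < 10L) {
    stop("minority class would have fewer than 10 compounds; calibration would be meaningless",
         call. = FALSE)
  }
  set.seed(derive_seed(config$seed, 1L, stream = 4L))
  d <- config$dimension
  u <- stats::rnorm(d)
  u <- u / sqrt(sum(u^2))
  labels <- c(rep(0L, n_maj), rep(1L, n_min))
  x <- matrix(stats::rnorm(config$n_total * d), config$n_total, d)
  # class means at -delta/2 and +delta/2 along u
  x <- x + outer(ifelse(labels == 1L, config$delta / 2, -config$delta / 2), u)
  if (config$label_noise > 0) {
    flip <- stats::runif(config$n_total) < config$label_noise
    labels[flip] <- 1L - labels[flip]
  }
  ord <- sample.int(config$n_total)
  x <- x[ord, , drop = FALSE]
  labels <- labels[ord]
  ids <- sprintf("mol_%05d", seq_len(config$n_total))
  rownames(x) <- ids
  colnames(x) <- paste0("f", seq_len(d))
  structure(list(x = x, labels = stats::setNames(labels, ids), config = config),
            class = "synth_data")
}

#' @export
print.synth_data <- function(x, ...) {
  cat(sprintf("Synthetic dataset (%s regime): %d compounds, %d features, %d/%d class 0/1, delta = %g\n",
              x$config$regime, nrow(x$x), ncol(x$x),
              sum(x$labels == 0L), sum(x$labels == 1L), x$config$delta))
  invisible(x)
}

#' Generate a synthetic external-score fixture
#'
#' Emulates the per-compound class-1 score files produced by an externally
#' trained classifier. Scores are Beta draws whose class means separate with
#' `quality`: at `quality = 0` both classes share the uniform distribution;
#' at `quality = 1` the scores concentrate near the true label.
#'
#' @param labels 0/1 labels (named vector or plain).
#' @param quality real in \[0, 1\].
#' @param seed integer seed.
#' @return numeric vector of class-1 scores in \[0, 1\], named like `labels`.
#' @export
generate_score_fixture <- function(labels, quality, seed = 1L) {
  labels <- assert_binary_labels(labels)
  stopifnot(quality >= 0, quality <= 1)
  set.seed(derive_seed(seed, 1L, stream = 4L))
  k <- 30 * quality
  s <- numeric(length(labels))
  s[labels == 1L] <- stats::rbeta(sum(labels == 1L), 1 + k, 1)
  s[labels == 0L] <- stats::rbeta(sum(labels == 0L), 1, 1 + k)
  names(s) <- names(labels)
  s
}

#' Toy SMILES fixture
#'
#' A small hand-curated set of molecules exercising every standardization
#' branch — salts, charged species, stereocenters, a heteroatom tautomer pair,
#' an inorganic reject, an over-long SMILES and an unparsable string — shipped
#' with the expected standardized form (or exclusion reason) beside each
#' entry. Expected forms were verified once against an independent
#' cheminformatics toolkit and frozen.
#'
#' @return data.frame with columns `id`, `smiles`, `label`, `expect_reason`,
#'   `expect_std`.
#' @export
toy_smiles_fixture <- function() {
  utils::read.csv(system.file("extdata", "toy_smiles.csv", package = "macp"),
                  stringsAsFactors = FALSE)
}
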