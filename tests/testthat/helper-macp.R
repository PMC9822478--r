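# Shared test helpers.

# loop-based brute-force Mondrian p-value: the independent counting oracle
brute_pvalue <- function(alpha_test, cal_scores) {
  vapply(alpha_test, function(t) {
    (sum(cal_scores >= t) + 1) / (length(cal_scores) + 1)
  }, numeric(1))
}

# calibration table with prescribed per-class nonconformity scores; built
# directly so the tests control the exact score multisets
table_from_alphas <- function(alpha0, alpha1) {
  structure(list(scores = list("0" = alpha0, "1" = alpha1),
                 n = c("0" = length(alpha0), "1" = length(alpha1))),
            class = "calib_table")
}

# rank-based AUC of scores for binary labels
simple_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# small exchangeable gaussian problem with a fitted single-member predictor
fit_small_acp <- function(n = 800, delta = 1.5, imbalance = 2, K = 1L,
                          seed = 11L, n_eval = 300, ntree = 150) {
  syn <- generate_tabular(synth_config(n_total = n + n_eval, imbalance = imbalance,
                                       dimension = 6L, delta = delta, seed = seed))
  eval_ids <- tail(rownames(syn$x), n_eval)
  pool_ids <- setdiff(rownames(syn$x), eval_ids)
  fit <- mondrian_acp(syn$x[pool_ids, ], syn$labels[pool_ids], K = K,
                      fractions = c(train = 0.8, dl_val = 0, calib = 0.2),
                      learner = rf_learner(ntree = ntree), seed = seed)
  list(fit = fit, x_eval = syn$x[eval_ids, ], y_eval = syn$labels[eval_ids])
}
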