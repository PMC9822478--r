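# Mondrian conformal primitives: nonconformity, calibration tables, p-values,
# aggregation, prediction sets, and the external-score path.

test_that("nonconformity is one minus the class score and rejects bad input", {
  expect_equal(nonconformity(c(0.9, 0.5, 1.0)), c(0.1, 0.5, 0.0))
  expect_error(nonconformity(1.2), "\\[0, 1\\]")
  expect_error(nonconformity(-0.1), "\\[0, 1\\]")
})

test_that("calibration tables are built class-conditionally", {
  prob <- rbind(c(NA, 0.9), c(NA, 0.6), c(0.8, NA))
  prob[is.na(prob)] <- 0.5  # irrelevant cells
  colnames(prob) <- c("0", "1")
  tab <- build_calibration_table(prob, c(1L, 1L, 0L))
  expect_equal(sort(unname(tab$scores[["1"]])), c(0.1, 0.4))
  expect_equal(unname(tab$scores[["0"]]), 0.2)
  expect_equal(unname(tab$n), c(1L, 2L))

  expect_error(build_calibration_table(prob, c(1L, 1L, 1L)), "both classes")

  set.seed(1)
  prob100 <- matrix(runif(200), 100, 2, dimnames = list(NULL, c("0", "1")))
  lab100 <- rbinom(100, 1, 0.4)
  lab100[1:2] <- c(0L, 1L)
  tab100 <- build_calibration_table(prob100, lab100)
  expect_equal(sum(tab100$n), 100L)
})

test_that("p-values follow the counting formula with ties counted >=", {
  tab <- table_from_alphas(alpha0 = 0.5, alpha1 = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(p_value(0.5, "1", tab), 1 / 5)
  expect_equal(p_value(0.0, "1", tab), 1)
  expect_equal(p_value(0.25, "1", tab), 3 / 5)
  expect_equal(p_value(0.2, "1", tab), 4 / 5)  # tie counts toward the test point
})

test_that("p-values agree exactly with a brute-force counting oracle", {
  set.seed(77)
  for (i in 1:200) {
    n0 <- sample(3:40, 1); n1 <- sample(3:40, 1)
    a0 <- round(runif(n0), 2); a1 <- round(runif(n1), 2)  # rounded to force ties
    tab <- table_from_alphas(a0, a1)
    t_alpha <- round(runif(5), 2)
    expect_identical(p_value(t_alpha, "0", tab), brute_pvalue(t_alpha, a0))
    expect_identical(p_value(t_alpha, "1", tab), brute_pvalue(t_alpha, a1))
  }
})

test_that("p-values are non-increasing in the nonconformity score", {
  set.seed(8)
  tab <- table_from_alphas(runif(30), runif(25))
  a <- sort(runif(50))
  for (cls in c("0", "1")) {
    p <- p_value(a, cls, tab)
    expect_true(all(diff(p) <= 0))
    expect_true(all(p > 0 & p <= 1))
  }
})

test_that("smoothed p-values are reproducible, valid and tie-sensitive", {
  tab <- table_from_alphas(c(0.2, 0.2, 0.4), c(0.1, 0.3))
  p1 <- p_value(rep(0.2, 10), "0", tab, smoothing = TRUE, tie_seed = 5L)
  p2 <- p_value(rep(0.2, 10), "0", tab, smoothing = TRUE, tie_seed = 5L)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 <= 1))
  # smoothing never exceeds the conservative tie-inclusive p-value
  expect_true(all(p1 <= p_value(rep(0.2, 10), "0", tab)))
})

test_that("median aggregation uses the even-K central-mean convention", {
  m <- function(p1, p0 = rep(0.5, length(p1))) {
    cbind(p0 = p0, p1 = p1)
  }
  expect_equal(median_aggregate(list(m(0.1), m(0.9), m(0.2)))[, "p1"], c(p0 = 0.2),
               ignore_attr = TRUE)
  expect_equal(median_aggregate(list(m(0.1), m(0.3)))[, "p1"], 0.2,
               ignore_attr = TRUE)

  # sort-based oracle, K = 10
  set.seed(12)
  mats <- lapply(1:10, function(i) {
    x <- matrix(runif(12), 6, 2, dimnames = list(letters[1:6], c("p0", "p1")))
    x
  })
  agg <- median_aggregate(mats)
  for (r in 1:6) for (cc in 1:2) {
    v <- sort(vapply(mats, function(m) m[r, cc], numeric(1)))
    expect_equal(agg[r, cc], (v[5] + v[6]) / 2)
  }

  bad <- mats
  rownames(bad[[3]])[1] <- "zzz"
  expect_error(median_aggregate(bad), "disagree")
})

test_that("prediction sets implement the four outcomes with strict inclusion", {
  p <- rbind(a = c(0.5, 0.05), b = c(0.5, 0.5), c = c(0.1, 0.1), d = c(0.2, 0.9))
  colnames(p) <- c("p0", "p1")
  s <- predict_set(p, 0.2)
  expect_identical(s$set, c("0", "01", "", "1"))
  expect_identical(as.character(s$outcome),
                   c("single_0", "both", "empty", "single_1"))  # p = eps excluded
})

test_that("prediction sets are nested across significance levels", {
  set.seed(3)
  p <- matrix(runif(60), 30, 2, dimnames = list(sprintf("c%02d", 1:30),
                                                c("p0", "p1")))
  eps <- c(0.05, 0.1, 0.2, 0.3, 0.5)
  sets <- lapply(eps, function(e) predict_set(p, e))
  for (i in seq_along(eps)[-1]) {
    for (r in 1:30) {
      lo <- strsplit(sets[[i - 1]]$set[r], "")[[1]]
      hi <- strsplit(sets[[i]]$set[r], "")[[1]]
      expect_true(all(hi %in% lo))  # larger eps => subset
    }
  }
})

test_that("external score calibration equals the internal path bitwise", {
  set.seed(21)
  s_cal <- runif(80); lab_cal <- rbinom(80, 1, 0.4)
  lab_cal[1:2] <- c(0L, 1L)
  s_test <- runif(25)
  p_ext <- calibrate_external_scores(s_cal, lab_cal, s_test,
                                     test_ids = sprintf("t%02d", 1:25))
  prob_cal <- cbind("0" = 1 - s_cal, "1" = s_cal)
  tab <- build_calibration_table(prob_cal, lab_cal)
  p_int <- cbind(p0 = p_value(nonconformity(1 - s_test), "0", tab),
                 p1 = p_value(nonconformity(s_test), "1", tab))
  expect_identical(unname(p_ext), unname(p_int))
  expect_identical(rownames(p_ext), sprintf("t%02d", 1:25))

  expect_error(calibrate_external_scores(s_cal, rep(1L, 80), s_test), "both classes")
  expect_error(calibrate_external_scores(c(0.5, 1.7), c(0L, 1L), s_test,
                                         test_ids = NULL), "\\[0, 1\\]")
})

test_that("a K = 1 ensemble aggregates to the single member's p-values", {
  sm <- fit_small_acp(n = 400, n_eval = 100, K = 1L, ntree = 60)
  members <- predict(sm$fit, sm$x_eval, aggregate = FALSE)
  agg <- predict(sm$fit, sm$x_eval)
  expect_length(members, 1L)
  expect_identical(agg, members[[1]])
})

test_that("fitting and prediction are deterministic given the master seed", {
  a <- fit_small_acp(n = 400, n_eval = 80, K = 2L, seed = 31L, ntree = 60)
  b <- fit_small_acp(n = 400, n_eval = 80, K = 2L, seed = 31L, ntree = 60)
  expect_identical(predict(a$fit, a$x_eval), predict(b$fit, b$x_eval))
})

test_that("a strong scorer drives p-values to extremes", {
  # extreme separation: the wrong class is (essentially) never in the set
  sm <- fit_small_acp(n = 900, n_eval = 400, delta = 5, K = 1L, seed = 13L)
  sets <- predict(sm$fit, sm$x_eval, type = "set", epsilon = 0.2)
  wrong_in <- mapply(function(set, y) grepl(as.character(1L - y), set, fixed = TRUE),
                     sets$set, sm$y_eval)
  expect_lte(mean(wrong_in), 0.02)
  expect_equal(sum(sets$outcome == "both"), 0L, ignore_attr = TRUE)

  # moderate separation with tie-rich forest probabilities: conservative
  # p-values keep almost all predictions single-label at eps = 0.2
  sm2 <- fit_small_acp(n = 900, n_eval = 400, delta = 2, K = 1L, seed = 13L)
  sets2 <- predict(sm2$fit, sm2$x_eval, type = "set", epsilon = 0.2)
  for (cls in c(0L, 1L)) {
    expect_gte(cp_efficiency(sets2, sm2$y_eval, cls), 0.85)
  }
})
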