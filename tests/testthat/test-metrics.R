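# Validity, efficiency, validity flags, confusion metrics and report tables.

mk_sets <- function(outcomes, epsilon = 0.2) {
  set <- c(single_0 = "0", single_1 = "1", both = "01", empty = "")[outcomes]
  structure(data.frame(id = sprintf("c%03d", seq_along(outcomes)),
                       epsilon = epsilon, set = unname(set),
                       outcome = factor(outcomes,
                                        levels = c("single_0", "single_1",
                                                   "both", "empty")),
                       stringsAsFactors = FALSE),
            class = c("prediction_sets", "data.frame"))
}

test_that("validity counts both-sets as correct and empty-sets as errors", {
  sets <- mk_sets(c(rep("single_1", 7), "both", "empty", "single_0"))
  labels <- rep(1L, 10)
  expect_equal(cp_validity(sets, labels, 1L), 0.8)  # 7 singles + 1 both
  # degenerate: all both => both classes fully valid
  allboth <- mk_sets(rep("both", 6))
  mixed <- c(1L, 0L, 1L, 0L, 1L, 0L)
  expect_equal(cp_validity(allboth, mixed, 1L), 1.0)
  expect_equal(cp_validity(allboth, mixed, 0L), 1.0)
})

test_that("efficiency is the single-label fraction regardless of correctness", {
  sets <- mk_sets(c(rep("single_1", 4), rep("single_0", 3), rep("both", 2), "empty"))
  labels <- rep(1L, 10)
  expect_equal(cp_efficiency(sets, labels, 1L), 0.7)
  expect_equal(cp_efficiency(mk_sets(rep("both", 5)), rep(1L, 5), 1L), 0)
  expect_equal(cp_efficiency(mk_sets(rep("single_0", 5)), rep(1L, 5), 1L), 1)
})

test_that("the validity flag allows at most 2.5 points of excess error", {
  expect_true(validity_flag(0.78, 0.2))    # error 0.220
  expect_false(validity_flag(0.77, 0.2))   # error 0.230
  expect_true(validity_flag(0.775, 0.2))   # boundary, <=
})

test_that("confusion metrics are computed over single-label predictions only", {
  sets <- mk_sets(c(rep("single_1", 3), "single_0",           # true 1: TP3 FN1
                    rep("single_0", 4), "single_1",           # true 0: TN4 FP1
                    "both", "empty"))
  labels <- c(rep(1L, 4), rep(0L, 5), 1L, 0L)
  cm <- confusion_metrics(sets, labels)
  expect_equal(cm$SE, 0.75)
  expect_equal(cm$SP, 0.8)
  expect_equal(cm$BA, 0.775)
  expect_equal(unname(cm$counts), c(3L, 1L, 4L, 1L))

  none <- confusion_metrics(mk_sets(rep("both", 4)), c(1L, 0L, 1L, 0L))
  expect_true(is.na(none$SE) && is.na(none$SP) && is.na(none$BA))
})

test_that("balanced accuracy is the arithmetic mean of SE and SP", {
  # consistency of reported three-decimal metrics: SE .863, SP .878 -> BA .871
  expect_equal(round((0.863 + 0.878) / 2, 3), 0.871)
})

test_that("validity and efficiency identities hold against the contingency", {
  set.seed(60)
  outcomes <- sample(c("single_0", "single_1", "both", "empty"), 400,
                     replace = TRUE, prob = c(0.35, 0.35, 0.2, 0.1))
  labels <- rbinom(400, 1, 0.3)
  sets <- mk_sets(outcomes)
  ct <- cp_contingency(sets, labels)
  for (cls in c(0L, 1L)) {
    row <- ct[as.character(cls), ]
    n_c <- sum(row)
    expect_equal(n_c, sum(labels == cls))  # rows conserve class sizes
    single_correct <- row[[paste0("single_", cls)]]
    single_wrong <- row[[paste0("single_", 1L - cls)]]
    expect_equal(cp_validity(sets, labels, cls),
                 (single_correct + row[["both"]]) / n_c)
    expect_equal(cp_efficiency(sets, labels, cls),
                 (single_correct + single_wrong) / n_c)
  }
  cm <- confusion_metrics(sets, labels)
  expect_equal(cm$BA, (cm$SE + cm$SP) / 2)
})

test_that("report tables order columns and blank rows that fail validity", {
  sets <- mk_sets(c(rep("single_1", 40), rep("single_0", 40),
                    rep("both", 15), rep("empty", 5)))
  labels <- c(rep(1L, 48), rep(0L, 52))
  rep1 <- cp_metrics(sets, labels, dataset = "toy", method = "rf")
  tab <- report_table(rep1)
  expect_identical(names(tab),
                   c("dataset", "method", "significance", "validity_1",
                     "validity_0", "efficiency_1", "efficiency_0",
                     "SE", "SP", "BA"))
  expect_equal(nrow(tab), 1L)

  # invalid for class 1: mostly empty predictions for true-1 compounds
  bad <- mk_sets(c(rep("empty", 30), rep("single_0", 70)))
  bad_labels <- c(rep(1L, 30), rep(0L, 70))
  rep2 <- cp_metrics(bad, bad_labels, dataset = "toy", method = "rf")
  tab2 <- report_table(rep2)
  expect_false(rep2$is_valid_1)
  expect_true(all(is.na(tab2[, c("efficiency_1", "efficiency_0", "SE", "SP", "BA")])))
  expect_false(anyNA(tab2[, c("validity_1", "validity_0")]))

  empty_tab <- report_table(list())
  expect_equal(nrow(empty_tab), 0L)
  expect_equal(ncol(empty_tab), 10L)
})
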