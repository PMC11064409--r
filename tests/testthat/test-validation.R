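test_that("confusion metrics from counts, with unknown exclusion", {
  cm <- confusion_from_counts(tp = 85, fn = 9, fp = 3, tn = 91,
                              n_excluded_unknown = 12)
  expect_equal(cm$sensitivity_pct, 90)
  expect_equal(cm$specificity_pct, 97)
  expect_equal(cm$ppv_pct, 97)
  expect_equal(cm$npv_pct, 91)
  expect_equal(cm$accuracy_pct, 94)
  expect_equal(cm$n_evaluated, 188L)
  expect_equal(cm$n_excluded_unknown, 12L)

  perfect <- confusion_from_counts(10, 0, 0, 10)
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    expect_equal(perfect[[paste0(m, "_pct")]], 100)
  }

  degen <- confusion_from_counts(tp = 1, fn = 1, fp = 0, tn = 0)
  expect_equal(degen$sensitivity_pct, 50)
  expect_true(is.na(degen$specificity))
  expect_true("specificity" %in% degen$flags)
  expect_error(confusion_from_counts(0, 0, 0, 0), "no evaluable")
})

test_that("confusion percentages are scale-invariant in the counts", {
  a <- confusion_from_counts(17, 4, 6, 23)
  b <- confusion_from_counts(17 * 7, 4 * 7, 6 * 7, 23 * 7)
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    expect_equal(a[[m]], b[[m]])
  }
})

test_that("confusion pairs predictions with gold labels and excludes unknowns", {
  pred <- data.frame(child_id = sprintf("C%02d", 1:8),
                     classification = c("positive", "positive", "negative",
                                        "negative", "positive", "negative",
                                        "positive", "negative"))
  gold <- data.frame(child_id = sprintf("C%02d", 1:8),
                     status = c("has_disease", "no_disease", "has_disease",
                                "no_disease", "has_disease", "no_disease",
                                "unknown", "unknown"))
  cm <- confusion(pred, gold)
  expect_equal(cm$n_excluded_unknown, 2L)
  expect_equal(cm$tp, 2L)
  expect_equal(cm$fp, 1L)
  expect_equal(cm$fn, 1L)
  expect_equal(cm$tn, 2L)

  expect_error(confusion(pred[1:4, ], gold), "missing prediction")
  gold$status[1] <- "maybe"
  expect_error(confusion(pred, gold), "unknown gold status")
})

test_that("prevalence-adjusted PPV follows the Bayes formula and its limits", {
  expect_equal(round(100 * adjusted_ppv(0.90, 0.97, 0.03), 1), 48.1)
  expect_equal(adjusted_ppv(0.9, 0.97, 1), 1)
  expect_equal(adjusted_ppv(0.9, 1, 0.03), 1)
  expect_error(adjusted_ppv(0, 0.9, 0.03), "\\(0, 1\\]")
  expect_error(adjusted_ppv(0.9, 0.9, 1.2), "\\(0, 1\\]")

  # strictly increasing in prevalence and in specificity
  prev_grid <- seq(0.01, 0.5, by = 0.05)
  v <- adjusted_ppv(0.9, 0.97, prev_grid)
  expect_true(all(diff(v) > 0))
  spec_grid <- seq(0.5, 0.99, by = 0.05)
  v <- vapply(spec_grid, function(s) adjusted_ppv(0.9, s, 0.03), 0)
  expect_true(all(diff(v) > 0))
})

test_that("per-criterion accuracy counts agreements and averages them", {
  m <- matrix(FALSE, 200, 13, dimnames = list(NULL, criterion_ids()))
  ids <- sprintf("C%03d", 1:200)
  gold <- profiles_from_matrix(ids, rep("full_term", 200), m)
  pred_ident <- profiles_from_matrix(ids, rep("full_term", 200), m)
  acc <- per_criterion_accuracy(pred_ident, gold)
  expect_true(all(acc$table$accuracy_pct == 100))
  expect_equal(acc$mean_accuracy_pct, 100)

  m2 <- m
  m2[1:38, "nicu_stay"] <- TRUE  # 38 disagreements out of 200
  pred <- profiles_from_matrix(ids, rep("full_term", 200), m2)
  acc <- per_criterion_accuracy(pred, gold)
  expect_equal(acc$table$accuracy_pct[acc$table$criterion == "nicu_stay"], 81)

  # order-insensitive pairing; mismatched child sets are an error
  acc2 <- per_criterion_accuracy(pred, gold[sample.int(200), ])
  expect_equal(acc2$table, acc$table)
  expect_error(per_criterion_accuracy(pred, gold[1:100, ]), "same children")
})

test_that("chart-review sampling is seeded, stratified and validated", {
  set.seed(77)
  res <- data.frame(
    child_id = sprintf("C%04d", 1:3000),
    classification = rep(c("positive", "negative"), c(300, 2700)),
    score = c(sample(3:21, 300, TRUE), sample(0:6, 2700, TRUE)))
  s1 <- sample_chart_review(res, 100, 100, seed = 5)
  s2 <- sample_chart_review(res, 100, 100, seed = 5)
  s3 <- sample_chart_review(res, 100, 100, seed = 6)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_length(s1, 200L)
  expect_length(unique(s1), 200L)
  cls <- res$classification[match(s1, res$child_id)]
  expect_equal(sum(cls == "positive"), 100L)
  expect_equal(sum(cls == "negative"), 100L)
  # sampled scores span the class ranges
  sc_pos <- res$score[match(s1[cls == "positive"], res$child_id)]
  sc_neg <- res$score[match(s1[cls == "negative"], res$child_id)]
  expect_equal(range(sc_pos), range(res$score[res$classification == "positive"]))
  expect_equal(range(sc_neg), range(res$score[res$classification == "negative"]))

  expect_error(sample_chart_review(res, 400, 100, seed = 1),
               "positive stratum")
  degen <- res
  degen$score[degen$classification == "positive"] <- 5L
  expect_message(sample_chart_review(degen, 100, 100, seed = 1),
                 "single score")
})
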