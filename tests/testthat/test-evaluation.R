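test_that("multiclass metrics reproduce hand-computed confusion counts", {
  m <- multiclass_metrics(rep("a", 10), rep("a", 10))
  expect_equal(m$accuracy, 1)
  expect_equal(m$per_class$f1, 1)

  # one class with TP=8, FP=2, FN=1
  truth <- c(rep("a", 9), rep("b", 11))
  pred <- c(rep("a", 8), "b", rep("a", 2), rep("b", 9))
  m2 <- suppressMessages(multiclass_metrics(truth, pred))
  a <- m2$per_class[m2$per_class$label == "a", ]
  expect_equal(a$precision, 0.8)
  expect_equal(a$recall, 8 / 9)
  expect_equal(a$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))
  expect_equal(a$support, 9)

  # a class never predicted scores precision 0 by convention, with a note
  expect_message(m3 <- multiclass_metrics(c("a", "b"), c("a", "a")),
                 "never predicted")
  expect_equal(m3$per_class$precision[m3$per_class$label == "b"], 0)

  expect_error(multiclass_metrics(c("a", "b"), "a"),
               class = "tcm_contract_error")
})

test_that("undiagnosed (NA) predictions count as incorrect", {
  m <- suppressMessages(
    multiclass_metrics(c("a", "a", "b"), c("a", NA, "b")))
  expect_equal(m$accuracy, 2 / 3)
  expect_equal(m$per_class$recall[m$per_class$label == "a"], 0.5)
})

test_that("multiclass metrics agree with a brute-force oracle on random labels", {
  labs <- letters[1:10]
  withr::with_seed(123, {
    for (i in 1:50) {
      truth <- sample(labs, 200, replace = TRUE)
      pred <- sample(labs, 200, replace = TRUE)
      m <- suppressMessages(multiclass_metrics(truth, pred))
      o <- oracle_multiclass(truth, pred)
      expect_equal(m$accuracy, o$accuracy, tolerance = 1e-12)
      expect_equal(m$precision, o$precision, tolerance = 1e-12)
      expect_equal(m$recall, o$recall, tolerance = 1e-12)
      expect_equal(m$f1, o$f1, tolerance = 1e-12)
    }
  })
})

test_that("weighted averages satisfy the support-weighted identity", {
  withr::with_seed(7, {
    truth <- sample(letters[1:6], 500, replace = TRUE)
    pred <- sample(letters[1:6], 500, replace = TRUE)
  })
  m <- suppressMessages(multiclass_metrics(truth, pred))
  pc <- m$per_class
  expect_equal(m$f1, sum(pc$support * pc$f1) / sum(pc$support),
               tolerance = 1e-12)
  expect_equal(m$support, sum(pc$support))
})

test_that("multilabel metrics combine element scores with end-to-end accuracy", {
  els <- syndrome_elements()
  truth <- list(c("phlegm", "lung"), c("heat", "lung"), c("cold", "lung"))
  m <- multilabel_metrics(truth, truth, c(TRUE, TRUE, TRUE))
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1, 1)

  # perfect elements but ambiguous rules: accuracy drops, element F1 stays 1
  correct <- c(TRUE, TRUE, FALSE)
  m2 <- multilabel_metrics(truth, truth, correct)
  expect_equal(m2$accuracy, 2 / 3)
  expect_equal(m2$f1, 1)

  # one element always missed: its recall is 0 and the weighted recall drops
  # by its support share
  pred <- lapply(truth, setdiff, "lung")
  m3 <- multilabel_metrics(truth, pred, c(FALSE, FALSE, FALSE))
  lung_row <- m3$per_class[m3$per_class$label == "lung", ]
  expect_equal(lung_row$recall, 0)
  share <- lung_row$support / m3$support
  expect_equal(m3$recall, 1 - share)

  expect_error(multilabel_metrics(truth, list(c("bogus")), TRUE),
               class = "tcm_contract_error")
})

test_that("repeated CV yields ordered percentile intervals per metric", {
  rec <- fixture_records()[1:250, ]
  pl <- pipeline_spec("word2vec", "knn", dimension = 8, min_count = 2,
                      embed_epochs = 3, seed = 21)
  cv <- repeated_cv(rec, pl, folds = 3, repeats = 2, seed = 5)
  expect_equal(nrow(cv), 4)
  expect_true(all(cv$n_scores == 6))
  expect_true(all(cv$ci_low <= cv$mean & cv$mean <= cv$ci_high))
  scores <- attr(cv, "scores")
  expect_equal(nrow(scores), 6)
  # percentile CI brackets the raw scores
  acc <- cv[cv$metric == "accuracy", ]
  expect_gte(acc$ci_low, min(scores$accuracy))
  expect_lte(acc$ci_high, max(scores$accuracy))
})

test_that("repeated CV refuses classes smaller than the fold count", {
  rec <- fixture_records()[1:40, ]
  rare <- names(sort(table(rec$pattern)))[1]
  expect_error(repeated_cv(rec, pipeline_spec("word2vec", "knn"),
                           folds = 25, repeats = 1, seed = 1),
               class = "tcm_stratification_error")
})

test_that("degenerate CV score distributions give zero-width intervals", {
  scores <- tibble::tibble(repeat_id = 1, fold = 1:5, accuracy = 0.7,
                           precision = 0.7, recall = 0.7, f1 = 0.7)
  cv <- tcmreason:::summarise_cv(scores)
  expect_true(all(cv$ci_high - cv$ci_low == 0))
  expect_true(all(cv$mean == 0.7))
})

test_that("evaluate_diagnoses checks alignment and dispatches by path", {
  sp <- fixture_split()
  emb <- fixture_word_model()
  xtr <- embed_corpus(emb, build_corpus(sp$train))
  clf <- fit_classifier(classifier_spec("knn", "multiclass"), xtr,
                        sp$train$pattern)
  dg <- diagnose_mbr(clf, sp$test, emb)
  m <- suppressMessages(evaluate_diagnoses(sp$test, dg))
  expect_s3_class(m, "tcm_metrics")
  expect_identical(m$mode, "multiclass")
  expect_error(evaluate_diagnoses(sp$test[1:3, ], dg),
               class = "tcm_contract_error")
})
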