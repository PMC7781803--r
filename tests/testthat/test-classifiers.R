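# hand-made word model over a two-token vocabulary, via the text format
toy_embedding <- function() {
  path <- file.path(tempdir(), "toy_vec.txt")
  writeLines(c("2 4",
               "aa 1 0 0 0",
               "bb 0 1 0 0"), path)
  read_word_vectors(path)
}

toy_dense <- function(n = 20) {
  withr::with_seed(1, {
    x <- rbind(matrix(rnorm(2 * n, 0, 0.1), ncol = 2),
               matrix(rnorm(2 * n, 3, 0.1), ncol = 2))
    list(x = x, y = rep(c("alpha", "beta"), each = n))
  })
}

test_that("default specs carry the literature hyperparameters", {
  expect_equal(classifier_spec("rf", "multiclass")$hyperparameters$num_trees,
               1000L)
  expect_equal(classifier_spec("svm", "multiclass")$hyperparameters$kernel,
               "linear")
  mlp <- classifier_spec("mlp", "multiclass")$hyperparameters$hidden
  expect_length(mlp, 6)
  expect_true(all(mlp >= 64 & mlp <= 1024))
  knn <- classifier_spec("knn", "multiclass")$hyperparameters
  expect_equal(knn$k, 5L)
  xgb <- classifier_spec("xgboost", "multiclass")$hyperparameters
  expect_equal(xgb[c("nrounds", "max_depth", "eta")],
               list(nrounds = 100L, max_depth = 6L, eta = 0.3))
  cnn <- classifier_spec("cnn", "multiclass")$hyperparameters
  expect_equal(cnn$kernel_width, 3L)
  expect_error(classifier_spec("svm", "multilabel"),
               class = "tcm_unsupported_pair_error")
  expect_error(classifier_spec("rf", "multiclass", bogus = 1), "bogus")
})

test_that("every family separates a linearly separable toy problem", {
  toy <- toy_dense()
  for (alg in c("rf", "xgboost", "svm", "knn", "mlp")) {
    spec <- if (alg == "mlp") {
      classifier_spec(alg, "multiclass", seed = 3, epochs = 30L,
                      hidden = c(64L, 64L, 64L, 64L, 64L, 64L))
    } else {
      classifier_spec(alg, "multiclass", seed = 3)
    }
    clf <- fit_classifier(spec, toy$x, toy$y)
    pred <- predict(clf, toy$x)
    expect_equal(mean(pred$labels == toy$y), 1.0, info = alg)
    expect_equal(rowSums(pred$probabilities),
                 rep(1, nrow(toy$x)), tolerance = 1e-6, info = alg)
  }
  # CNN on token sequences: class decided by which token fills the document
  emb <- toy_embedding()
  n <- 30
  seqs <- rbind(matrix(1L, n, 5), matrix(2L, n, 5))
  y <- rep(c("alpha", "beta"), each = n)
  clf <- fit_classifier(classifier_spec("cnn", "multiclass", seed = 2,
                                        epochs = 30L, filters = 8L,
                                        dense = 8L),
                        seqs, y, embedding = emb)
  pred <- predict(clf, seqs)
  expect_equal(mean(pred$labels == y), 1.0)
})

test_that("multilabel training over rule-consistent data outputs 9 element scores", {
  sp <- fixture_split()
  emb <- fixture_word_model()
  xtr <- embed_corpus(emb, build_corpus(sp$train))
  clf <- fit_classifier(classifier_spec("knn", "multilabel", seed = 1),
                        xtr, sp$train$elements)
  pred <- predict(clf, xtr[1:20, ])
  expect_equal(ncol(pred$probabilities), 9)
  expect_setequal(colnames(pred$probabilities), syndrome_elements())
  expect_true(all(pred$probabilities >= 0 & pred$probabilities <= 1))
  # lung is in every record: constant-label guard must predict it always
  expect_true(all(vapply(pred$labels, function(s) "lung" %in% s,
                         logical(1))))
})

test_that("representation contracts are enforced", {
  toy <- toy_dense(5)
  expect_error(fit_classifier(classifier_spec("cnn", "multiclass"),
                              toy$x, toy$y, embedding = toy_embedding()),
               class = "tcm_contract_error")
  seqs <- matrix(1L, 4, 5)
  expect_error(fit_classifier(classifier_spec("rf", "multiclass"),
                              seqs, rep(c("a", "b"), 2)),
               class = "tcm_contract_error")
  expect_error(fit_classifier(classifier_spec("cnn", "multiclass"),
                              seqs, rep(c("a", "b"), 2)),
               class = "tcm_contract_error") # missing embedding
})

test_that("a class with zero training instances is rejected by name", {
  toy <- toy_dense(5)
  y <- factor(toy$y, levels = c("alpha", "beta", "gamma"))
  expect_error(fit_classifier(classifier_spec("rf", "multiclass"), toy$x, y),
               "gamma")
})

test_that("hard-label rules: argmax, threshold, and lexicographic ties", {
  # knn with two equidistant neighbours of different classes ties at 0.5
  xtr <- rbind(c(0, 1), c(0, -1))
  clf <- fit_classifier(classifier_spec("knn", "multiclass", k = 2L),
                        xtr, c("zeta", "alpha"))
  pred <- predict(clf, matrix(c(0, 0), 1))
  expect_equal(unname(pred$probabilities[1, ]), c(0.5, 0.5))
  expect_identical(pred$labels, "alpha")
  # multilabel: probabilities below threshold give the empty set
  clf2 <- fit_classifier(classifier_spec("knn", "multilabel", k = 2L),
                         xtr, list(c("cold"), c("heat")))
  pred2 <- predict(clf2, matrix(c(0, 0), 1), threshold = 0.6)
  expect_identical(pred2$labels[[1]], character(0))
  pred3 <- predict(clf2, matrix(c(0, 0), 1), threshold = 0.5)
  expect_setequal(pred3$labels[[1]], c("cold", "heat"))
})

test_that("fits are reproducible under a fixed seed", {
  sp <- fixture_split()
  emb <- fixture_word_model()
  x <- embed_corpus(emb, build_corpus(sp$train))[1:100, ]
  y <- sp$train$pattern[1:100]
  f1 <- fit_classifier(classifier_spec("mlp", "multiclass", seed = 7,
                                       hidden = c(64L, 64L), epochs = 5L),
                       x, y)
  f2 <- fit_classifier(classifier_spec("mlp", "multiclass", seed = 7,
                                       hidden = c(64L, 64L), epochs = 5L),
                       x, y)
  expect_identical(predict(f1, x)$labels, predict(f2, x)$labels)
  expect_identical(f1$fitted$W, f2$fitted$W)
})
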