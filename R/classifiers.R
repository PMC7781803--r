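#' Default classifier specification
#'
#' Builds the self-describing specification of one of the six classifier
#' families, in multiclass mode (predicting the syndrome pattern directly —
#' the MBR path) or multilabel mode (predicting the syndrome-element set —
#' the MBR+RBR path). Literature hyperparameters are filled in: random
#' forest with 1000 trees; linear-kernel SVM; MLP with 6 hidden layers whose
#' widths ramp within 64..1024; CNN with an embedding layer, one
#' convolutional layer, a global max-pooling layer and 2 fully connected
#' layers. Where the literature is silent (KNN's k, XGBoost's boosting
#' settings, CNN filter counts) the defaults are recorded explicitly in the
#' spec so every experiment is self-describing. The linear SVM is a
#' single-output classifier and is not offered in multilabel mode.
#'
#' @param algorithm One of `"rf"`, `"xgboost"`, `"svm"`, `"knn"`, `"mlp"`,
#'   `"cnn"`.
#' @param mode `"multiclass"` or `"multilabel"`.
#' @param seed Integer seed stored with the spec.
#' @param ... Hyperparameter overrides (must name existing defaults).
#' @return A `tcm_classifier_spec`.
#' @examples
#' classifier_spec("rf", "multiclass")$hyperparameters$num_trees
#' @export
classifier_spec <- function(algorithm = c("rf", "xgboost", "svm", "knn",
                                          "mlp", "cnn"),
                            mode = c("multiclass", "multilabel"),
                            seed = 1, ...) {
  algorithm <- match.arg(algorithm)
  mode <- match.arg(mode)
  if (algorithm == "svm" && mode == "multilabel") {
    abort("The linear SVM is not available in multilabel mode.",
          class = "tcm_unsupported_pair_error")
  }
  hp <- switch(algorithm,
    rf = list(num_trees = 1000L, mtry = NULL),
    xgboost = list(nrounds = 100L, max_depth = 6L, eta = 0.3),
    svm = list(kernel = "linear", cost = 1),
    knn = list(k = 5L),
    mlp = list(hidden = c(1024L, 512L, 256L, 128L, 64L, 64L), epochs = 60L,
               batch = 32L, lr = 1e-3, val_fraction = 0.1, patience = 5L),
    cnn = list(filters = 128L, kernel_width = 3L, dense = 128L,
               epochs = 40L, batch = 32L, lr = 1e-3, val_fraction = 0.1,
               patience = 5L, trainable_embedding = TRUE))
  dots <- list(...)
  bad <- setdiff(names(dots), names(hp))
  if (length(bad)) {
    abort(sprintf("Unknown hyperparameter(s) for %s: %s", algorithm,
                  paste(bad, collapse = ", ")))
  }
  hp[names(dots)] <- dots
  structure(list(algorithm = algorithm, mode = mode, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "tcm_classifier_spec")
}

#' @export
print.tcm_classifier_spec <- function(x, ...) {
  hp <- vapply(x$hyperparameters, function(v) paste(format(v), collapse = ","),
               character(1))
  cat(sprintf("<tcm_classifier_spec> %s (%s), seed %d\n  %s\n", x$algorithm,
              x$mode, x$seed, paste(names(hp), hp, sep = "=",
                                    collapse = "; ")))
  invisible(x)
}

label_matrix <- function(label_sets, inventory) {
  out <- matrix(0, nrow = length(label_sets), ncol = length(inventory),
                dimnames = list(NULL, inventory))
  for (i in seq_along(label_sets)) out[i, label_sets[[i]]] <- 1
  out
}

#' Fit a classifier on document representations
#'
#' Trains the algorithm named by the spec. All algorithms except the CNN
#' consume a numeric feature matrix (mean-pooled word vectors or document
#' vectors); the CNN consumes an integer index-sequence matrix plus the word
#' embedding model that initialises its embedding layer. Multiclass labels
#' are a character vector (or factor whose levels define the label
#' inventory); multilabel labels are a list of character sets over the
#' syndrome-element vocabulary. Training is reproducible under the spec
#' seed; model backends run single-threaded.
#'
#' @param spec A [classifier_spec()].
#' @param x Numeric matrix (all algorithms but `cnn`) or integer
#'   index-sequence matrix (`cnn` only).
#' @param labels Character vector / factor (multiclass) or list of character
#'   vectors (multilabel).
#' @param embedding For `cnn`: the word-level `tcm_embedding` whose vectors
#'   initialise the embedding layer.
#' @return A `tcm_classifier` carrying the spec, the fitted state and the
#'   ordered label inventory.
#' @export
fit_classifier <- function(spec, x, labels, embedding = NULL) {
  stopifnot(inherits(spec, "tcm_classifier_spec"))
  is_seq <- is.integer(x)
  if (spec$algorithm == "cnn" && !is_seq) {
    abort("The CNN consumes index-sequence representations, not dense vectors.",
          class = "tcm_contract_error")
  }
  if (spec$algorithm != "cnn" && is_seq) {
    abort(sprintf("Algorithm '%s' consumes dense numeric representations.",
                  spec$algorithm), class = "tcm_contract_error")
  }
  if (spec$mode == "multiclass") {
    f <- if (is.factor(labels)) labels else factor(labels)
    empty <- setdiff(levels(f), unique(as.character(f)))
    if (length(empty)) {
      abort(sprintf("Class(es) with zero training instances: %s",
                    paste(empty, collapse = "; ")))
    }
    inventory <- levels(f)
    y <- f
  } else {
    if (!is.list(labels)) abort("Multilabel labels must be a list of sets.")
    inventory <- sort(unique(unlist(labels)))
    if (length(inventory) == 0) abort("Multilabel labels are all empty.")
    y <- label_matrix(labels, inventory)
  }
  fitted <- switch(spec$algorithm,
    rf = fit_rf(spec, x, y, inventory),
    xgboost = fit_xgb(spec, x, y, inventory),
    svm = fit_svm(spec, x, y),
    knn = list(x = x, y = y),
    mlp = fit_mlp(spec, x, y, inventory),
    cnn = fit_cnn(spec, x, y, inventory, embedding))
  structure(list(spec = spec, fitted = fitted, inventory = inventory),
            class = "tcm_classifier")
}

#' @export
print.tcm_classifier <- function(x, ...) {
  cat(sprintf("<tcm_classifier> %s (%s), %d output label(s)\n",
              x$spec$algorithm, x$spec$mode, length(x$inventory)))
  invisible(x)
}

# -- per-algorithm fit helpers ------------------------------------------

# binary-relevance guard: a label observed at a single value (e.g. `lung`,
# present in every pattern) gets a constant-probability stub
fit_binary_relevance <- function(y, fit_one) {
  lapply(colnames(y), function(lab) {
    yy <- y[, lab]
    if (length(unique(yy)) == 1) {
      list(constant = yy[1])
    } else {
      fit_one(yy, lab)
    }
  })
}

fit_rf <- function(spec, x, y, inventory) {
  hp <- spec$hyperparameters
  df <- as.data.frame(x)
  args <- list(num.trees = hp$num_trees, probability = TRUE,
               num.threads = 1, seed = spec$seed)
  if (!is.null(hp$mtry)) args$mtry <- hp$mtry
  if (spec$mode == "multiclass") {
    do.call(ranger::ranger, c(list(x = df, y = y), args))
  } else {
    fit_binary_relevance(y, function(yy, lab) {
      do.call(ranger::ranger, c(list(x = df, y = factor(yy, levels = c(0, 1))),
                                args))
    })
  }
}

fit_xgb <- function(spec, x, y, inventory) {
  hp <- spec$hyperparameters
  if (spec$mode == "multiclass") {
    dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
    xgboost::xgb.train(
      params = list(objective = "multi:softprob",
                    num_class = length(inventory), max_depth = hp$max_depth,
                    eta = hp$eta, nthread = 1, seed = spec$seed),
      data = dtrain, nrounds = hp$nrounds, verbose = 0)
  } else {
    fit_binary_relevance(y, function(yy, lab) {
      dtrain <- xgboost::xgb.DMatrix(x, label = yy)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                      eta = hp$eta, nthread = 1, seed = spec$seed),
        data = dtrain, nrounds = hp$nrounds, verbose = 0)
    })
  }
}

fit_svm <- function(spec, x, y) {
  hp <- spec$hyperparameters
  with_rng_seed(spec$seed,
    e1071::svm(x, y, kernel = hp$kernel, cost = hp$cost, probability = TRUE))
}

fit_mlp <- function(spec, x, y, inventory) {
  hp <- spec$hyperparameters
  multilabel <- spec$mode == "multilabel"
  Y <- if (multilabel) y else label_matrix(as.list(as.character(y)), inventory)
  cpp_mlp_train(x, Y, as.integer(hp$hidden), multilabel,
                as.integer(hp$epochs), as.integer(hp$batch), hp$lr,
                hp$val_fraction, as.integer(hp$patience), spec$seed)
}

fit_cnn <- function(spec, x, y, inventory, embedding) {
  if (is.null(embedding) || !inherits(embedding, "tcm_embedding") ||
      embedding$level != "word") {
    abort("The CNN needs a word-level `embedding` to initialise its embedding layer.",
          class = "tcm_contract_error")
  }
  hp <- spec$hyperparameters
  multilabel <- spec$mode == "multilabel"
  Y <- if (multilabel) y else label_matrix(as.list(as.character(y)), inventory)
  emb_init <- rbind(numeric(embedding$dimension), embedding$vectors)
  storage.mode(x) <- "integer"
  fit <- cpp_cnn_train(x, emb_init, Y, multilabel,
                       as.integer(hp$kernel_width), as.integer(hp$dense),
                       isTRUE(hp$trainable_embedding), as.integer(hp$epochs),
                       as.integer(hp$batch), hp$lr, hp$val_fraction,
                       as.integer(hp$patience), spec$seed,
                       as.integer(hp$filters))
  fit$kernel_width <- as.integer(hp$kernel_width)
  fit
}

# -- prediction ----------------------------------------------------------

predict_binary_relevance <- function(models, predict_one, n) {
  probs <- vapply(models, function(m) {
    if (!is.null(m$constant)) rep(as.numeric(m$constant), n)
    else predict_one(m)
  }, numeric(n))
  if (n == 1) probs <- matrix(probs, nrow = 1)
  probs
}

#' Predict syndrome patterns or element sets
#'
#' Produces per-record probabilities and hard labels. In multiclass mode the
#' probability vector sums to 1 and the hard label is the highest-probability
#' class, ties broken by the lexicographically first label. In multilabel
#' mode each label carries an independent probability; the hard set keeps
#' labels with probability at or above `threshold` (an empty predicted set is
#' allowed and passed downstream).
#'
#' @param object A `tcm_classifier`.
#' @param x Representation matrix matching the training representation.
#' @param threshold Multilabel decision threshold (default 0.5).
#' @param ... Unused.
#' @return A `tcm_predictions` list: `mode`, `probabilities` (matrix with one
#'   column per label), and `labels` (character vector, or list of sets in
#'   multilabel mode).
#' @export
predict.tcm_classifier <- function(object, x, threshold = 0.5, ...) {
  spec <- object$spec
  inv <- object$inventory
  n <- nrow(x)
  probs <- switch(spec$algorithm,
    rf = {
      if (spec$mode == "multiclass") {
        p <- predict(object$fitted, data = as.data.frame(x),
                     num.threads = 1)$predictions
        p[, inv, drop = FALSE]
      } else {
        predict_binary_relevance(object$fitted, function(m) {
          predict(m, data = as.data.frame(x), num.threads = 1)$predictions[, "1"]
        }, n)
      }
    },
    xgboost = {
      if (spec$mode == "multiclass") {
        p <- predict(object$fitted, xgboost::xgb.DMatrix(x))
        if (!is.matrix(p)) p <- matrix(p, ncol = length(inv), byrow = TRUE)
        p
      } else {
        predict_binary_relevance(object$fitted, function(m) {
          predict(m, xgboost::xgb.DMatrix(x))
        }, n)
      }
    },
    svm = {
      p <- attr(predict(object$fitted, x, probability = TRUE),
                "probabilities")
      p[, inv, drop = FALSE]
    },
    knn = knn_probs(object, x),
    mlp = cpp_mlp_predict(x, object$fitted$W, object$fitted$b,
                          spec$mode == "multilabel"),
    cnn = {
      storage.mode(x) <- "integer"
      f <- object$fitted
      cpp_cnn_predict(x, f$emb, f$Wc, f$bc, f$W1, f$b1, f$W2, f$b2,
                      f$kernel_width, spec$mode == "multilabel")
    })
  dimnames(probs) <- list(rownames(x), inv)
  if (spec$mode == "multiclass") {
    probs <- probs / rowSums(probs)
    # argmax with deterministic lexicographic tie-break: inventory is sorted
    # by factor-level order, which is lexicographic for character labels
    hard <- inv[apply(probs, 1, which.max)]
  } else {
    hard <- apply(probs, 1, function(p) inv[p >= threshold],
                  simplify = FALSE)
  }
  structure(list(mode = spec$mode, probabilities = probs, labels = hard),
            class = "tcm_predictions")
}

knn_probs <- function(object, x) {
  k <- object$spec$hyperparameters$k
  xtr <- object$fitted$x
  ytr <- object$fitted$y
  inv <- object$inventory
  # squared Euclidean distances via the expansion trick
  d2 <- outer(rowSums(x^2), rowSums(xtr^2), "+") - 2 * tcrossprod(x, xtr)
  probs <- matrix(0, nrow(x), length(inv), dimnames = list(NULL, inv))
  for (i in seq_len(nrow(x))) {
    nn <- order(d2[i, ])[seq_len(min(k, ncol(d2)))] # distance ties: lower index
    if (object$spec$mode == "multiclass") {
      tab <- table(factor(ytr[nn], levels = inv))
      probs[i, ] <- as.numeric(tab) / length(nn)
    } else {
      probs[i, ] <- colMeans(ytr[nn, , drop = FALSE])
    }
  }
  probs
}

#' @export
print.tcm_predictions <- function(x, ...) {
  cat(sprintf("<tcm_predictions> %s over %d record(s), %d label(s)\n",
              x$mode, nrow(x$probabilities), ncol(x$probabilities)))
  invisible(x)
}

#' @export
as_tibble.tcm_predictions <- function(x, ...) {
  if (x$mode == "multiclass") {
    tibble(predicted = x$labels, as_tibble(as.data.frame(x$probabilities)))
  } else {
    tibble(predicted = x$labels, as_tibble(as.data.frame(x$probabilities)))
  }
}
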