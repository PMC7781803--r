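#' Multiclass evaluation metrics
#'
#' Computes the standard metric suite over predicted syndrome patterns:
#' overall accuracy (exact-match fraction; an `NA` prediction — an
#' undiagnosed record — is always incorrect) and per-class precision,
#' recall and F1 with support, averaged with support weights. Empty
#' denominators (a class never predicted, or never true) score 0 by
#' convention.
#'
#' @param truth Character vector of gold pattern labels.
#' @param predicted Character vector of predicted labels (`NA` allowed).
#' @return A `tcm_metrics` object: list with `accuracy`, `precision`,
#'   `recall`, `f1` (weighted averages), `per_class` tibble (`label`,
#'   `precision`, `recall`, `f1`, `support`), and `support` (total).
#' @examples
#' m <- multiclass_metrics(c("a", "a", "b"), c("a", "b", "b"))
#' glance(m)
#' @export
multiclass_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.",
          class = "tcm_contract_error")
  }
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  labels <- sort(unique(c(truth, predicted[!is.na(predicted)])))
  per_class <- purrr::map_dfr(labels, function(lab) {
    tp <- sum(truth == lab & !is.na(predicted) & predicted == lab)
    fp <- sum(truth != lab & !is.na(predicted) & predicted == lab)
    fn <- sum(truth == lab & (is.na(predicted) | predicted != lab))
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    tibble(label = lab, precision = prec, recall = rec, f1 = f1,
           support = tp + fn)
  })
  never_predicted <- per_class$label[per_class$support > 0 &
    !per_class$label %in% predicted]
  if (length(never_predicted)) {
    inform(sprintf("Class(es) never predicted (precision 0 by convention): %s",
                   paste(never_predicted, collapse = "; ")))
  }
  new_metrics(
    accuracy = mean(!is.na(predicted) & predicted == truth),
    per_class = per_class,
    mode = "multiclass")
}

#' Multilabel (hybrid-path) evaluation metrics
#'
#' The reporting convention of the hybrid MBR+RBR path: `accuracy` is the
#' end-to-end syndrome-pattern exact-match fraction, while precision, recall
#' and F1 are computed per syndrome element over the 9-element vocabulary
#' (support = count of true occurrences) and averaged with support weights.
#' Element-level metrics therefore routinely exceed the pattern accuracy:
#' a single missed element can break the pattern match while barely moving
#' the element scores.
#'
#' @param truth_sets List of gold element sets.
#' @param predicted_sets List of predicted element sets.
#' @param pattern_correct Logical vector: is the end-to-end pattern
#'   diagnosis exact for each record?
#' @return A `tcm_metrics` object (per-class rows are elements).
#' @export
multilabel_metrics <- function(truth_sets, predicted_sets, pattern_correct) {
  if (length(truth_sets) != length(predicted_sets) ||
      length(truth_sets) != length(pattern_correct)) {
    abort("Inputs must have equal length.", class = "tcm_contract_error")
  }
  check_labels(unlist(predicted_sets), syndrome_elements(),
               "syndrome element")
  check_labels(unlist(truth_sets), syndrome_elements(), "syndrome element")
  per_class <- purrr::map_dfr(syndrome_elements(), function(el) {
    y <- vapply(truth_sets, function(s) el %in% s, logical(1))
    p <- vapply(predicted_sets, function(s) el %in% s, logical(1))
    tp <- sum(y & p); fp <- sum(!y & p); fn <- sum(y & !p)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    tibble(label = el, precision = prec, recall = rec, f1 = f1,
           support = tp + fn)
  })
  new_metrics(accuracy = mean(pattern_correct), per_class = per_class,
              mode = "multilabel")
}

new_metrics <- function(accuracy, per_class, mode) {
  w <- per_class$support
  wavg <- function(v) if (sum(w) == 0) 0 else sum(v * w) / sum(w)
  structure(list(
    accuracy = accuracy,
    precision = wavg(per_class$precision),
    recall = wavg(per_class$recall),
    f1 = wavg(per_class$f1),
    per_class = per_class,
    support = sum(w),
    mode = mode
  ), class = "tcm_metrics")
}

#' @export
print.tcm_metrics <- function(x, digits = 4, ...) {
  cat(sprintf("<tcm_metrics> (%s) accuracy %.4f | weighted P %.4f R %.4f F1 %.4f | support %d\n",
              x$mode, x$accuracy, x$precision, x$recall, x$f1, x$support))
  df <- as.data.frame(x$per_class)
  df[2:4] <- lapply(df[2:4], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-class metric rows
#'
#' @param x A `tcm_metrics`.
#' @param ... Unused.
#' @return The per-class tibble (`label`, `precision`, `recall`, `f1`,
#'   `support`).
#' @export
tidy.tcm_metrics <- function(x, ...) x$per_class

#' One-row metric summary
#'
#' @param x A `tcm_metrics`.
#' @param ... Unused.
#' @return A one-row tibble with `accuracy`, weighted `precision`, `recall`,
#'   `f1`, and `support`.
#' @export
glance.tcm_metrics <- function(x, ...) {
  tibble(accuracy = x$accuracy, precision = x$precision, recall = x$recall,
         f1 = x$f1, support = x$support)
}

#' Evaluate diagnoses against gold labels
#'
#' Scores a diagnoses tibble against the records' gold annotations,
#' dispatching on the diagnosis path: MBR diagnoses get
#' [multiclass_metrics()] over patterns; MBR+RBR diagnoses get
#' [multilabel_metrics()] (element-level P/R/F1, end-to-end pattern
#' accuracy).
#'
#' @param records Records tibble with gold `pattern` (and `elements` for the
#'   hybrid path).
#' @param diagnoses Output of [diagnose()], [diagnose_mbr()] or
#'   [diagnose_mbr_rbr()] for the same records, in the same order.
#' @return A `tcm_metrics`.
#' @export
evaluate_diagnoses <- function(records, diagnoses) {
  if (nrow(records) != nrow(diagnoses) ||
      !identical(records$record_id, diagnoses$record_id)) {
    abort("`records` and `diagnoses` must align row by row.",
          class = "tcm_contract_error")
  }
  metrics_from_diagnoses(records, diagnoses)
}

metrics_from_diagnoses <- function(records, diagnoses) {
  if (all(diagnoses$path == "mbr")) {
    multiclass_metrics(records$pattern, diagnoses$predicted_pattern)
  } else {
    correct <- !is.na(diagnoses$predicted_pattern) &
      diagnoses$predicted_pattern == records$pattern
    multilabel_metrics(records$elements, diagnoses$predicted_elements,
                       correct)
  }
}

#' Repeated stratified cross-validation
#'
#' Runs k-fold cross-validation repeated several times (default 5 folds, 20
#' repeats, giving 100 scores per metric, the reference protocol) of a full
#' pipeline on the training records. Folds are stratified by syndrome
#' pattern and reshuffled every repeat from the seed stream; each fold fit
#' retrains the embedding and the classifier from scratch on the in-fold
#' data. The 95% confidence interval is the empirical 2.5/97.5 percentile of
#' the score distribution (`ci = "normal"` switches to the
#' mean ± 1.96·sd approximation).
#'
#' @param records Training records tibble.
#' @param pipeline A [pipeline_spec()].
#' @param rulebase Rule base for the hybrid path.
#' @param folds Number of folds (default 5).
#' @param repeats Number of repetitions (default 20).
#' @param seed Integer seed.
#' @param ci `"percentile"` (default) or `"normal"`.
#' @return A `tcm_cv` object: tibble of `metric`, `mean`, `ci_low`,
#'   `ci_high`, `n_scores`, with the raw per-fold scores in
#'   `attr(, "scores")`.
#' @export
repeated_cv <- function(records, pipeline, rulebase = default_rulebase(),
                        folds = 5, repeats = 20, seed = 1,
                        ci = c("percentile", "normal")) {
  ci <- match.arg(ci)
  counts <- table(records$pattern)
  small <- names(counts)[counts < folds]
  if (length(small)) {
    abort(sprintf("Class(es) with fewer records than folds (%d): %s", folds,
                  paste(small, collapse = "; ")),
          class = "tcm_stratification_error")
  }
  scores <- purrr::map_dfr(seq_len(repeats), function(r) {
    fold_id <- with_rng_seed(child_seed(seed, "folds", r), {
      id <- integer(nrow(records))
      for (cl in names(counts)) {
        idx <- which(records$pattern == cl)
        id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      id
    })
    purrr::map_dfr(seq_len(folds), function(k) {
      p <- pipeline
      p$seed <- child_seed(seed, "fit", r, k)
      fit <- fit_pipeline(records[fold_id != k, , drop = FALSE], p, rulebase)
      test <- records[fold_id == k, , drop = FALSE]
      m <- glance(metrics_from_diagnoses(test, diagnose(fit, test)))
      tibble(repeat_id = r, fold = k, accuracy = m$accuracy,
             precision = m$precision, recall = m$recall, f1 = m$f1)
    })
  })
  summarise_cv(scores, ci)
}

summarise_cv <- function(scores, ci = "percentile") {
  long <- tidyr::pivot_longer(scores, c("accuracy", "precision", "recall",
                                        "f1"),
                              names_to = "metric", values_to = "score")
  out <- long |>
    group_by(.data$metric) |>
    summarise(mean = mean(.data$score),
              ci_low = if (ci == "percentile") {
                quantile(.data$score, 0.025, names = FALSE)
              } else {
                mean(.data$score) - 1.96 * sd(.data$score)
              },
              ci_high = if (ci == "percentile") {
                quantile(.data$score, 0.975, names = FALSE)
              } else {
                mean(.data$score) + 1.96 * sd(.data$score)
              },
              n_scores = dplyr::n(), .groups = "drop") |>
    mutate(ci_low = pmin(.data$ci_low, .data$mean),
           ci_high = pmax(.data$ci_high, .data$mean)) |>
    arrange(match(.data$metric, c("accuracy", "precision", "recall", "f1")))
  structure(out, class = c("tcm_cv", class(out)), scores = scores)
}

#' @export
print.tcm_cv <- function(x, ...) {
  cat(sprintf("<tcm_cv> %d scores per metric (95%% CI)\n", x$n_scores[1]))
  NextMethod()
}

#' @rdname tidy.tcm_metrics
#' @export
tidy.tcm_cv <- function(x, ...) as_tibble(unclass(x)[1:5])

#' Paired corpus-1 vs corpus-2 comparison
#'
#' Measures the value of the modern-medicine diagnosis token: the same
#' records are split once (4:1, stratified), then the identical pipeline is
#' trained and evaluated twice — on corpus variant 1 (signs only) and on
#' corpus variant 2 (signs plus the diagnosis token) — with identical seeds,
#' so the two arms differ only in the corpus. Reports both metric sets, the
#' accuracy delta, and the per-pattern precision/recall/F1/support table in
#' the conventional two-arm layout.
#'
#' @param records Records tibble (disease labels required).
#' @param pipeline A [pipeline_spec()]; its `variant` field is overridden per
#'   arm.
#' @param rulebase Rule base for the hybrid path.
#' @param ratio Train:test ratio for the single split.
#' @param seed Integer seed shared by both arms.
#' @return A `tcm_corpus_comparison` list: `corpus1`, `corpus2`
#'   (`tcm_metrics`), `delta_accuracy`, and `per_class` (wide tibble).
#' @export
compare_corpora <- function(records, pipeline, rulebase = default_rulebase(),
                            ratio = c(4, 1), seed = 1) {
  if (is.null(records$disease) || anyNA(records$disease)) {
    abort("Records must carry disease labels for the corpus comparison.")
  }
  sp <- split_records(records, ratio = ratio, stratify_by = "pattern",
                      seed = child_seed(seed, "split"))
  arm <- function(variant) {
    p <- pipeline
    p$variant <- variant
    p$seed <- child_seed(seed, "arm") # same seed: paired arms
    fit <- fit_pipeline(sp$train, p, rulebase)
    metrics_from_diagnoses(sp$test, diagnose(fit, sp$test))
  }
  m1 <- arm(1L)
  m2 <- arm(2L)
  per_class <- dplyr::full_join(
    dplyr::rename_with(m1$per_class, ~ paste0(.x, "_corpus1"), -"label"),
    dplyr::rename_with(m2$per_class, ~ paste0(.x, "_corpus2"), -"label"),
    by = "label")
  structure(list(corpus1 = m1, corpus2 = m2,
                 delta_accuracy = m2$accuracy - m1$accuracy,
                 per_class = per_class,
                 n_train = nrow(sp$train), n_test = nrow(sp$test)),
            class = "tcm_corpus_comparison")
}

#' @export
print.tcm_corpus_comparison <- function(x, ...) {
  cat("<tcm_corpus_comparison>\n")
  cat(sprintf("  corpus 1 accuracy: %.4f\n", x$corpus1$accuracy))
  cat(sprintf("  corpus 2 accuracy: %.4f\n", x$corpus2$accuracy))
  cat(sprintf("  delta (corpus 2 - corpus 1): %+.4f  [test n = %d]\n",
              x$delta_accuracy, x$n_test))
  invisible(x)
}
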