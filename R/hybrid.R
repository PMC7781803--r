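#' End-to-end pipeline specification
#'
#' Describes one complete diagnosis pipeline: the embedding stage (word- or
#' document-level, with dimension/window/min-count/epochs), the classifier
#' family and mode, the document representation feeding it, the corpus
#' variant (1 = signs only, 2 = with the modern-medicine diagnosis token),
#' and the hybrid-path options (multilabel threshold, rule-match fallback).
#' The representation defaults to the natural pairing: index sequences for
#' the CNN, inferred document vectors for a document-level embedding, and
#' mean-pooled word vectors otherwise.
#'
#' @param embedding `"word2vec"` or `"doc2vec"`.
#' @param classifier Algorithm name (see [classifier_spec()]).
#' @param mode `"multiclass"` (MBR) or `"multilabel"` (MBR+RBR).
#' @param variant Corpus variant, 1 or 2.
#' @param dimension Embedding dimension; defaults to 256 (word) / 192
#'   (document).
#' @param window,min_count,embed_epochs,embed_alpha Embedding
#'   hyperparameters. The pipeline defaults (10 epochs at learning rate
#'   0.05) suit ward-scale corpora of a few thousand documents, which need
#'   more passes than the single-digit epochs conventional for web-scale
#'   text.
#' @param representation Override of the representation mode.
#' @param max_len Index-sequence length (default: model's 95th-percentile
#'   document length).
#' @param threshold Multilabel decision threshold.
#' @param fallback Rule-match fallback, `"best_overlap"` (default: partial
#'   and ambiguous matches resolve to the best-overlap rule) or `"none"`
#'   (only exact matches yield a pattern).
#' @param seed Integer seed driving every stochastic stage.
#' @param ... Hyperparameter overrides passed to [classifier_spec()].
#' @return A `tcm_pipeline` list.
#' @examples
#' pipeline_spec("word2vec", "cnn", dimension = 32)
#' @export
pipeline_spec <- function(embedding = c("word2vec", "doc2vec"),
                          classifier = "cnn",
                          mode = c("multiclass", "multilabel"),
                          variant = 1, dimension = NULL, window = 5,
                          min_count = 10, embed_epochs = NULL,
                          embed_alpha = 0.05,
                          representation = NULL, max_len = NULL,
                          threshold = 0.5,
                          fallback = c("best_overlap", "none"),
                          seed = 1, ...) {
  embedding <- match.arg(embedding)
  mode <- match.arg(mode)
  fallback <- match.arg(fallback)
  if (classifier == "cnn" && embedding == "doc2vec") {
    abort("The CNN pairs with word-level embeddings (index sequences).",
          class = "tcm_contract_error")
  }
  dimension <- dimension %||% if (embedding == "word2vec") 256L else 192L
  embed_epochs <- embed_epochs %||% if (embedding == "word2vec") 10L else 20L
  representation <- representation %||%
    if (classifier == "cnn") "index_sequence"
    else if (embedding == "doc2vec") "doc_vector" else "mean_vector"
  structure(list(
    embedding = embedding, classifier = classifier, mode = mode,
    variant = as.integer(variant), dimension = as.integer(dimension),
    window = as.integer(window), min_count = as.integer(min_count),
    embed_epochs = as.integer(embed_epochs), embed_alpha = embed_alpha,
    representation = representation, max_len = max_len,
    threshold = threshold, fallback = fallback, seed = as.integer(seed),
    classifier_args = list(...)
  ), class = "tcm_pipeline")
}

#' @export
print.tcm_pipeline <- function(x, ...) {
  cat(sprintf(
    "<tcm_pipeline> %s + %s (%s), corpus variant %d, dim %d, repr %s\n",
    x$embedding, x$classifier, x$mode, x$variant, x$dimension,
    x$representation))
  invisible(x)
}

#' Fit a diagnosis pipeline on training records
#'
#' Runs the full training path: builds the corpus at the pipeline's variant,
#' trains the embedding model, represents every training document, and fits
#' the classifier — on syndrome-pattern labels (multiclass/MBR) or on
#' syndrome-element sets (multilabel/MBR+RBR).
#'
#' @param records Training records tibble.
#' @param pipeline A [pipeline_spec()].
#' @param rulebase Rule base used by the hybrid path.
#' @return A `tcm_pipeline_fit` carrying the embedding model, the trained
#'   classifier, the pipeline and the rule base.
#' @export
fit_pipeline <- function(records, pipeline, rulebase = default_rulebase()) {
  stopifnot(inherits(pipeline, "tcm_pipeline"))
  corpus <- build_corpus(records, variant = pipeline$variant)
  emb_seed <- child_seed(pipeline$seed, "embedding")
  model <- if (pipeline$embedding == "word2vec") {
    train_word_model(corpus, dimension = pipeline$dimension,
                     window = pipeline$window,
                     min_count = pipeline$min_count,
                     epochs = pipeline$embed_epochs,
                     alpha = pipeline$embed_alpha, seed = emb_seed)
  } else {
    train_doc_model(corpus, dimension = pipeline$dimension,
                    window = pipeline$window,
                    min_count = pipeline$min_count,
                    epochs = pipeline$embed_epochs,
                    alpha = pipeline$embed_alpha, seed = emb_seed)
  }
  x <- embed_corpus(model, corpus, mode = pipeline$representation,
                    max_len = pipeline$max_len,
                    infer_seed = child_seed(pipeline$seed, "infer-train"))
  spec <- do.call(classifier_spec,
                  c(list(algorithm = pipeline$classifier,
                         mode = pipeline$mode,
                         seed = child_seed(pipeline$seed, "classifier")),
                    pipeline$classifier_args))
  labels <- if (pipeline$mode == "multiclass") {
    factor(records$pattern, levels = sort(syndrome_patterns()))
  } else {
    records$elements
  }
  if (pipeline$mode == "multiclass") {
    labels <- droplevels(labels)
  }
  clf <- fit_classifier(spec, x, labels, embedding = model)
  structure(list(embedding_model = model, classifier = clf,
                 pipeline = pipeline, rulebase = rulebase),
            class = "tcm_pipeline_fit")
}

#' @export
print.tcm_pipeline_fit <- function(x, ...) {
  cat("<tcm_pipeline_fit>\n")
  print(x$pipeline)
  print(x$classifier)
  invisible(x)
}

#' Diagnose records through the direct model-based path (MBR)
#'
#' Applies a trained multiclass classifier to records: each record's tokens
#' are embedded with the supplied model and the classifier predicts the
#' syndrome pattern directly. A corpus-variant mismatch between the records
#' and the embedding model degrades silently (missing tokens simply fall out
#' of vocabulary), so it raises a warning and proceeds. Records whose tokens
#' are entirely out of vocabulary still receive a (degenerate) prediction;
#' they are flagged with a message.
#'
#' @param model A multiclass `tcm_classifier`.
#' @param records Records tibble.
#' @param embedding The `tcm_embedding` used at training time.
#' @param representation Representation mode used at training time.
#' @param max_len Index-sequence length (CNN path).
#' @param infer_seed Seed for document-vector inference.
#' @return A diagnoses tibble: `record_id`, `path = "mbr"`,
#'   `predicted_pattern`, `predicted_elements` (empty sets), `match_status`
#'   (`NA`).
#' @export
diagnose_mbr <- function(model, records, embedding,
                         representation = c("mean_vector", "index_sequence",
                                            "doc_vector"),
                         max_len = NULL, infer_seed = 1) {
  stopifnot(inherits(model, "tcm_classifier"))
  if (model$spec$mode != "multiclass") {
    abort("`diagnose_mbr()` needs a multiclass (pattern) classifier.",
          class = "tcm_contract_error")
  }
  representation <- match.arg(representation)
  if (nrow(records) == 0) return(empty_diagnoses())
  corpus <- records_to_corpus(records, embedding)
  x <- embed_corpus(embedding, corpus, mode = representation,
                    max_len = max_len, infer_seed = infer_seed)
  if (representation == "mean_vector") {
    oov <- rowSums(abs(x)) == 0
    if (any(oov)) {
      inform(sprintf(
        "%d record(s) have no in-vocabulary token; their predictions are degenerate (zero-vector input).",
        sum(oov)))
    }
  }
  pred <- predict(model, x)
  tibble(record_id = records$record_id, path = "mbr",
         predicted_pattern = pred$labels,
         predicted_elements = replicate(nrow(records), character(),
                                        simplify = FALSE),
         match_status = NA_character_)
}

#' Diagnose records through the hybrid path (MBR+RBR)
#'
#' The two-stage hybrid path: a multilabel classifier predicts each record's
#' syndrome-element set (labels with probability at or above `threshold`),
#' and the rule knowledge base combines the predicted elements into a
#' syndrome pattern via [pattern_for_elements()]. With
#' `fallback = "best_overlap"` partial and ambiguous matches resolve to the
#' best-overlap (priority-tie-broken) rule; with `fallback = "none"` only
#' exact matches produce a pattern and everything else is left undiagnosed
#' (`NA`, scored as incorrect downstream — undiagnosed records are not
#' excluded from evaluation). An empty predicted element set always maps to
#' no pattern.
#'
#' @param model A multilabel `tcm_classifier` over syndrome elements.
#' @param rulebase A validated `tcm_rulebase`.
#' @inheritParams diagnose_mbr
#' @param threshold Multilabel decision threshold (default 0.5).
#' @param fallback `"best_overlap"` (default) or `"none"`.
#' @return A diagnoses tibble: `record_id`, `path = "mbr_rbr"`,
#'   `predicted_pattern` (`NA` when no rule applies), `predicted_elements`,
#'   `match_status`.
#' @export
diagnose_mbr_rbr <- function(model, rulebase, records, embedding,
                             representation = c("mean_vector",
                                                "index_sequence",
                                                "doc_vector"),
                             threshold = 0.5,
                             fallback = c("best_overlap", "none"),
                             max_len = NULL, infer_seed = 1) {
  stopifnot(inherits(model, "tcm_classifier"))
  if (model$spec$mode != "multilabel") {
    abort("`diagnose_mbr_rbr()` needs a multilabel (element) classifier.",
          class = "tcm_contract_error")
  }
  val <- validate_rulebase(rulebase)
  if (length(val$missing_patterns) == length(syndrome_patterns())) {
    abort("Rule base is empty; refusing to reason over it.")
  }
  representation <- match.arg(representation)
  fallback <- match.arg(fallback)
  if (nrow(records) == 0) return(empty_diagnoses())
  corpus <- records_to_corpus(records, embedding)
  x <- embed_corpus(embedding, corpus, mode = representation,
                    max_len = max_len, infer_seed = infer_seed)
  pred <- predict(model, x, threshold = threshold)
  combined <- combine_elements(rulebase, pred$labels, fallback)
  tibble(record_id = records$record_id, path = "mbr_rbr",
         predicted_pattern = combined$pattern,
         predicted_elements = pred$labels,
         match_status = combined$status)
}

# Rebuild the corpus at the embedding's training variant. The only genuine
# degradation is a variant-2 embedding applied to records without disease
# labels: the diagnosis token is then absent and its signal silently lost,
# so that case warns and proceeds at variant 1.
records_to_corpus <- function(records, embedding) {
  variant <- embedding$variant
  if (variant == 2 &&
      (is.null(records$disease) || anyNA(records$disease))) {
    warn(paste("Embedding was trained with the diagnosis token (corpus",
               "variant 2) but some records lack a disease label;",
               "proceeding without the token (its signal is lost)."))
    variant <- 1L
  }
  build_corpus(records, variant = variant)
}

combine_elements <- function(rulebase, element_sets, fallback) {
  res <- purrr::map_dfr(element_sets, function(els) {
    if (length(els) == 0) {
      return(tibble(pattern = NA_character_, status = "none"))
    }
    m <- pattern_for_elements(rulebase, els)
    keep <- if (fallback == "best_overlap") {
      m$status %in% c("exact", "partial", "ambiguous")
    } else {
      m$status == "exact"
    }
    tibble(pattern = if (keep) m$pattern else NA_character_,
           status = m$status)
  })
  res
}

empty_diagnoses <- function() {
  tibble(record_id = character(), path = character(),
         predicted_pattern = character(), predicted_elements = list(),
         match_status = character())
}

#' Diagnose records with a fitted pipeline
#'
#' Convenience wrapper dispatching to [diagnose_mbr()] or
#' [diagnose_mbr_rbr()] according to the fitted pipeline's mode.
#'
#' @param fit A `tcm_pipeline_fit`.
#' @param records Records tibble.
#' @return A diagnoses tibble.
#' @export
diagnose <- function(fit, records) {
  stopifnot(inherits(fit, "tcm_pipeline_fit"))
  p <- fit$pipeline
  seed <- child_seed(p$seed, "infer-test")
  if (p$mode == "multiclass") {
    diagnose_mbr(fit$classifier, records, fit$embedding_model,
                 representation = p$representation, max_len = p$max_len,
                 infer_seed = seed)
  } else {
    diagnose_mbr_rbr(fit$classifier, fit$rulebase, records,
                     fit$embedding_model,
                     representation = p$representation,
                     threshold = p$threshold, fallback = p$fallback,
                     max_len = p$max_len, infer_seed = seed)
  }
}
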