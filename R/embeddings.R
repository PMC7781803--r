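#' Train a word-level embedding model
#'
#' Learns skip-gram word vectors with negative sampling over the corpus. The
#' default hyperparameters follow the reference configuration for clinical
#' token streams: 256-dimensional vectors, a context window of 5, and a
#' minimum token count of 10 (rarer tokens are dropped from the vocabulary).
#' Training is single-threaded and seeded, so the same corpus and seed give
#' identical vectors. For desk-scale experiments the dimension can be reduced
#' (e.g. 32) without changing the pipeline's structure. Externally pretrained
#' vectors in the standard word-vector text format can be loaded with
#' [read_word_vectors()] instead.
#'
#' @param corpus A `tcm_corpus` (see [build_corpus()]).
#' @param dimension Embedding dimension (default 256).
#' @param window Context window size (default 5).
#' @param min_count Minimum corpus frequency for a token to enter the
#'   vocabulary (default 10).
#' @param epochs Training passes over the corpus.
#' @param negative Negative samples per positive pair.
#' @param alpha Initial learning rate.
#' @param seed Integer seed.
#' @return A `tcm_embedding` with `level = "word"`: vocabulary, a
#'   `vocab x dimension` vector matrix, and the training metadata.
#' @examples
#' rec <- generate_records(generator_config(n_records = 60, seed = 1))
#' emb <- train_word_model(build_corpus(rec), dimension = 16, min_count = 2,
#'                         epochs = 2, seed = 1)
#' dim(emb$vectors)
#' @export
train_word_model <- function(corpus, dimension = 256, window = 5,
                             min_count = 10, epochs = 5, negative = 5,
                             alpha = 0.025, seed = 1) {
  stopifnot(inherits(corpus, "tcm_corpus"))
  vocab <- embedding_vocab(corpus, min_count)
  sent <- docs_to_ids(corpus$documents$tokens, vocab$index)
  fit <- cpp_sgns_train(sent, length(vocab$tokens), as.integer(dimension),
                        as.integer(window), as.integer(negative),
                        as.integer(epochs), alpha, vocab$counts,
                        as.integer(seed))
  vectors <- t(fit$syn0) # trainer stores one column per token
  rownames(vectors) <- vocab$tokens
  new_embedding(level = "word", vectors = vectors, vocab = vocab,
                dimension = dimension, window = window,
                min_count = min_count, epochs = epochs, negative = negative,
                alpha = alpha, seed = seed, variant = corpus$variant,
                max_len_default = default_max_len(corpus))
}

#' Train a document-level embedding model
#'
#' Learns paragraph vectors with the distributed bag-of-words scheme: each
#' document owns a trainable vector optimised to predict its tokens under
#' negative sampling. Defaults follow the reference configuration
#' (192-dimensional vectors, window 5, minimum count 10 — the window is kept
#' for interface parity although the bag-of-words objective does not use
#' positional context). Vectors for unseen documents are inferred by
#' gradient steps against the frozen output layer, reproducibly under a
#' fixed inference seed.
#'
#' @inheritParams train_word_model
#' @param dimension Embedding dimension (default 192).
#' @param infer_epochs Gradient passes used when inferring a new document's
#'   vector.
#' @return A `tcm_embedding` with `level = "document"`.
#' @export
train_doc_model <- function(corpus, dimension = 192, window = 5,
                            min_count = 10, epochs = 20, negative = 5,
                            alpha = 0.05, infer_epochs = 50, seed = 1) {
  stopifnot(inherits(corpus, "tcm_corpus"))
  vocab <- embedding_vocab(corpus, min_count)
  sent <- docs_to_ids(corpus$documents$tokens, vocab$index)
  fit <- cpp_pvdbow_train(sent, length(vocab$tokens), as.integer(dimension),
                          as.integer(negative), as.integer(epochs), alpha,
                          vocab$counts, as.integer(seed))
  docvecs <- t(fit$docvecs) # trainer stores one column per document
  rownames(docvecs) <- corpus$documents$record_id
  m <- new_embedding(level = "document", vectors = docvecs, vocab = vocab,
                     dimension = dimension, window = window,
                     min_count = min_count, epochs = epochs,
                     negative = negative, alpha = alpha, seed = seed,
                     variant = corpus$variant,
                     max_len_default = default_max_len(corpus))
  m$syn1 <- fit$syn1
  m$infer_epochs <- infer_epochs
  m
}

embedding_vocab <- function(corpus, min_count) {
  counts <- corpus$vocabulary
  counts <- counts[counts >= min_count]
  if (length(counts) == 0) {
    abort(sprintf(
      "No token reaches min_count = %d; the embedding vocabulary is empty.",
      min_count), class = "tcm_empty_vocabulary_error")
  }
  # deterministic ordering: frequency-descending, then lexicographic
  ord <- order(-counts, names(counts), method = "radix")
  counts <- counts[ord]
  list(tokens = names(counts), counts = as.numeric(counts),
       index = setNames(seq_along(counts), names(counts)))
}

docs_to_ids <- function(token_lists, index) {
  lapply(token_lists, function(tok) {
    ids <- index[tok]
    as.integer(ids[!is.na(ids)] - 1L) # 0-based for the C++ trainers
  })
}

default_max_len <- function(corpus) {
  lens <- lengths(corpus$documents$tokens)
  max(3L, as.integer(ceiling(quantile(lens, 0.95, names = FALSE))))
}

new_embedding <- function(level, vectors, vocab, dimension, window, min_count,
                          epochs, negative, alpha, seed, variant,
                          max_len_default) {
  structure(list(
    level = level, vectors = vectors, vocabulary = vocab$tokens,
    vocab_index = vocab$index, vocab_counts = vocab$counts,
    dimension = as.integer(dimension), window = as.integer(window),
    min_count = as.integer(min_count), epochs = as.integer(epochs),
    negative = as.integer(negative), alpha = alpha, seed = as.integer(seed),
    variant = as.integer(variant), max_len_default = max_len_default
  ), class = "tcm_embedding")
}

#' @export
print.tcm_embedding <- function(x, ...) {
  cat(sprintf(
    "<tcm_embedding> level=%s dim=%d window=%d min_count=%d vocab=%d (corpus variant %d)\n",
    x$level, x$dimension, x$window, x$min_count, length(x$vocabulary),
    x$variant))
  invisible(x)
}

#' Represent a token sequence as a fixed-length numeric object
#'
#' Converts one document's tokens into classifier input. Mode `mean_vector`
#' averages the in-vocabulary token vectors (permutation-invariant; a zero
#' vector with a warning when no token is known) and is the representation
#' the classical classifiers consume. Mode `index_sequence` maps tokens to
#' 1-based vocabulary indices (0 = padding/unknown), right-pads with zeros
#' and truncates at `max_len` keeping the earliest tokens; it feeds the CNN's
#' embedding layer. Mode `doc_vector` requires a document-level model and
#' infers the paragraph vector.
#'
#' @param model A `tcm_embedding`.
#' @param tokens Character vector of tokens.
#' @param mode One of `"mean_vector"`, `"index_sequence"`, `"doc_vector"`.
#' @param max_len Sequence length for `index_sequence`; defaults to the 95th
#'   percentile of the model's training-document lengths.
#' @param infer_seed Seed for `doc_vector` inference.
#' @return A numeric vector (`mean_vector`, `doc_vector`) or an integer
#'   vector of length `max_len` (`index_sequence`).
#' @export
represent <- function(model, tokens,
                      mode = c("mean_vector", "index_sequence", "doc_vector"),
                      max_len = NULL, infer_seed = 1) {
  stopifnot(inherits(model, "tcm_embedding"))
  mode <- match.arg(mode)
  if (mode == "doc_vector" && model$level != "document") {
    abort("`doc_vector` representation requires a document-level model.",
          class = "tcm_contract_error")
  }
  if (mode != "doc_vector" && model$level == "document" &&
      mode == "index_sequence") {
    abort("`index_sequence` representation requires a word-level model.",
          class = "tcm_contract_error")
  }
  switch(mode,
    mean_vector = {
      ids <- model$vocab_index[tokens]
      ids <- ids[!is.na(ids)]
      if (length(ids) == 0) {
        warn("No token in vocabulary; returning the zero vector.")
        return(numeric(model$dimension))
      }
      colMeans(model$vectors[ids, , drop = FALSE])
    },
    index_sequence = {
      max_len <- max_len %||% model$max_len_default
      ids <- model$vocab_index[tokens]
      ids[is.na(ids)] <- 0L
      out <- integer(max_len)
      keep <- seq_len(min(length(ids), max_len))
      out[keep] <- as.integer(ids[keep])
      out
    },
    doc_vector = {
      ids <- model$vocab_index[tokens]
      ids <- as.integer(ids[!is.na(ids)] - 1L)
      as.numeric(cpp_pvdbow_infer(ids, model$syn1, model$dimension,
                                  model$negative, model$infer_epochs,
                                  model$alpha, model$vocab_counts,
                                  as.integer(infer_seed)))
    })
}

#' Represent every document of a corpus
#'
#' Vectorised companion of [represent()]: one row per document.
#'
#' @inheritParams represent
#' @param corpus A `tcm_corpus` (or a records tibble, converted with the
#'   model's corpus variant).
#' @return A numeric matrix (`mean_vector`/`doc_vector`) or integer matrix
#'   (`index_sequence`), rows named by record id.
#' @export
embed_corpus <- function(model, corpus,
                         mode = c("mean_vector", "index_sequence",
                                  "doc_vector"),
                         max_len = NULL, infer_seed = 1) {
  mode <- match.arg(mode)
  if (!inherits(corpus, "tcm_corpus")) {
    corpus <- build_corpus(corpus, variant = model$variant)
  }
  if (mode == "index_sequence") {
    max_len <- max_len %||% model$max_len_default
  }
  rows <- lapply(seq_len(nrow(corpus$documents)), function(i) {
    suppressWarnings(represent(model, corpus$documents$tokens[[i]], mode,
                               max_len = max_len,
                               infer_seed = child_seed(infer_seed, i)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- corpus$documents$record_id
  out
}

#' Read and write word vectors in the standard text format
#'
#' The plain-text interchange format of word-embedding tools: a header line
#' `vocab_size dimension`, then one `token v1 v2 ...` line per word. Allows
#' externally pretrained vectors to replace corpus-trained ones.
#'
#' @param model A word-level `tcm_embedding`.
#' @param path File path.
#' @return `write_word_vectors()` returns `path` invisibly;
#'   `read_word_vectors()` a word-level `tcm_embedding` (counts unknown, set
#'   to 1).
#' @export
write_word_vectors <- function(model, path) {
  stopifnot(inherits(model, "tcm_embedding"), model$level == "word")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(model$vectors), model$dimension), con,
             useBytes = TRUE)
  lines <- vapply(seq_len(nrow(model$vectors)), function(i) {
    paste(c(rownames(model$vectors)[i],
            sprintf("%.8g", model$vectors[i, ])),
          collapse = " ")
  }, character(1))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_word_vectors
#' @export
read_word_vectors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  if (length(hdr) != 2 || any(is.na(hdr))) {
    abort("Word-vector file must start with a 'vocab_size dimension' header.",
          class = "tcm_parse_error")
  }
  body <- strsplit(lines[-1], " ", fixed = TRUE)
  tokens <- vapply(body, `[[`, character(1), 1)
  vectors <- t(vapply(body, function(x) as.numeric(x[-1]),
                      numeric(hdr[2])))
  rownames(vectors) <- tokens
  vocab <- list(tokens = tokens, counts = rep(1, length(tokens)),
                index = setNames(seq_along(tokens), tokens))
  new_embedding(level = "word", vectors = vectors, vocab = vocab,
                dimension = hdr[2], window = NA_integer_,
                min_count = NA_integer_, epochs = NA_integer_,
                negative = NA_integer_, alpha = NA_real_, seed = NA_integer_,
                variant = 1L, max_len_default = 64L)
}
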