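#' Assemble a token corpus from clinical records
#'
#' Builds the corpus the embedding models train on. Variant 1 keeps each
#' record's section tokens (the combined "four diagnoses" context of chief
#' complaint, syndromes, and chest/tongue/pulse signs); variant 2 additionally
#' carries exactly one modern-medicine diagnosis token per record, appended at
#' the end of the document so the two corpora differ by a deterministic
#' one-token delta. Records already generated as variant 2 are converted
#' either way (the trailing diagnosis token is stripped for variant 1).
#'
#' @param records A records tibble (see [generate_records()]).
#' @param variant 1 or 2.
#' @return A `tcm_corpus`: list with `documents` (tibble of `record_id`,
#'   `tokens` list-column), `variant`, and `vocabulary` (named occurrence
#'   counts).
#' @examples
#' rec <- generate_records(generator_config(n_records = 4, seed = 1))
#' c2 <- build_corpus(rec, variant = 2)
#' tail(c2$documents$tokens[[1]], 3)
#' @export
build_corpus <- function(records, variant = 1) {
  if (!variant %in% c(1, 2)) abort("`variant` must be 1 or 2.")
  n <- nrow(records)
  rec_variant <- records$corpus_variant %||% rep(1L, n)
  docs <- vector("list", n)
  for (i in seq_len(n)) {
    tok <- records$tokens[[i]]
    has_dx <- rec_variant[i] == 2
    if (variant == 2) {
      if (is.na(records$disease[i]) || !nzchar(records$disease[i])) {
        abort(sprintf(
          "Record '%s' has no disease label; cannot build corpus variant 2.",
          records$record_id[i]))
      }
      if (!has_dx) tok <- c(tok, disease_token(records$disease[i]))
    } else if (has_dx) {
      tok <- tok[-length(tok)]
    }
    docs[[i]] <- tok
  }
  counts <- table(unlist(docs))
  structure(list(
    documents = tibble(record_id = records$record_id, tokens = docs),
    variant = as.integer(variant),
    vocabulary = setNames(as.integer(counts), names(counts))
  ), class = "tcm_corpus")
}

#' @export
print.tcm_corpus <- function(x, ...) {
  cat(sprintf("<tcm_corpus> variant %d: %d documents, %d distinct tokens\n",
              x$variant, nrow(x$documents), length(x$vocabulary)))
  invisible(x)
}

#' Segment raw text into tokens with a pluggable segmenter
#'
#' The package carries no built-in word segmentation (in particular none for
#' Chinese); raw-text input must supply a word-cutting function. The
#' segmenter's output is passed through unchanged apart from whitespace
#' trimming and removal of empty tokens.
#'
#' @param text A single character string.
#' @param segmenter A function `character(1) -> character()` returning the
#'   token sequence.
#' @return A character vector of tokens.
#' @examples
#' segment_text("cough  fever", function(x) strsplit(x, "\\s+")[[1]])
#' @export
segment_text <- function(text, segmenter = NULL) {
  if (is.null(segmenter) || !is.function(segmenter)) {
    abort("A segmenter function must be supplied for raw-text input.",
          class = "tcm_configuration_error")
  }
  tok <- as.character(segmenter(text))
  tok <- trimws(tok)
  tok[nzchar(tok)]
}

#' Read and write corpora in line-sentence format
#'
#' One document per line, tokens joined by single spaces — the standard
#' plain-text input format of word-embedding trainers.
#'
#' @param corpus A `tcm_corpus`.
#' @param path File path.
#' @param variant Variant tag to record on the corpus read back.
#' @return `write_corpus()` returns `path` invisibly; `read_corpus()` a
#'   `tcm_corpus` (record ids are regenerated as `doc_<n>`).
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "tcm_corpus"))
  lines <- vapply(corpus$documents$tokens, paste, character(1), collapse = " ")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path, variant = 1) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  docs <- lapply(lines, function(l) {
    tok <- strsplit(l, " ", fixed = TRUE)[[1]]
    tok[nzchar(tok)]
  })
  counts <- table(unlist(docs))
  structure(list(
    documents = tibble(record_id = sprintf("doc_%06d", seq_along(docs)),
                       tokens = docs),
    variant = as.integer(variant),
    vocabulary = setNames(as.integer(counts), names(counts))
  ), class = "tcm_corpus")
}
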