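#' Default marginal distribution of lung diseases
#'
#' Disease priors for the synthetic generator, calibrated to the published
#' proportions of the 8 common lung diseases in the reference development
#' corpus.
#'
#' @return A named probability vector over [lung_diseases()].
#' @export
default_disease_priors <- function() {
  reference_corpus_stats()$disease_proportions
}

#' Default syndrome-pattern marginal distribution
#'
#' Pattern priors calibrated to the per-pattern test-set supports of the
#' reference corpus.
#'
#' @return A named probability vector over [syndrome_patterns()].
#' @export
default_pattern_priors <- function() {
  s <- reference_corpus_stats()$pattern_support
  s / sum(s)
}

# Hand-specified clinical plausibility mask: which syndrome patterns occur
# under which modern-medicine diagnoses (2-4 patterns per disease). The
# reference study does not publish this table; the mask is invented structure
# whose only asserted property is that the diagnosis is informative about the
# pattern.
disease_pattern_mask <- function() {
  d <- lung_diseases()
  p <- syndrome_patterns()
  m <- matrix(0, nrow = length(d), ncol = length(p), dimnames = list(d, p))
  link <- list(
    "lung cancer" = c("qi-deficiency of lung and spleen",
                      "yin-deficiency of lung", "deficiency of qi and yin",
                      "phlegm obstruction in lung"),
    "pulmonary infection" = c("wind-heat attacking lung",
                              "phlegm-heat obstruction in lung",
                              "phlegm obstruction in lung"),
    "acute bronchitis" = c("wind-cold attacking lung",
                           "wind-heat attacking lung",
                           "phlegm-heat obstruction in lung"),
    "interstitial pneumonia" = c("yin-deficiency of lung",
                                 "deficiency of qi and yin"),
    "chronic bronchitis" = c("wind-cold attacking lung",
                             "phlegm-heat obstruction in lung",
                             "phlegm obstruction in lung"),
    "chronic obstructive pulmonary disease" =
      c("qi-deficiency of lung and spleen",
        "qi-deficiency of lung and kidney",
        "phlegm-heat obstruction in lung", "phlegm obstruction in lung"),
    "bronchiectasis" = c("yin-deficiency of lung",
                         "phlegm-heat obstruction in lung"),
    "asthma" = c("cold wheezing", "hot wheezing",
                 "qi-deficiency of lung and kidney")
  )
  for (dd in names(link)) m[dd, link[[dd]]] <- 1
  m
}

#' Default conditional distribution of syndrome pattern given disease
#'
#' An 8 x 10 row-stochastic table giving, for each lung disease, the
#' probability of each syndrome pattern. It is built by balancing a sparse
#' clinical-plausibility mask (each disease compatible with 2-4 patterns) to
#' the published disease and pattern marginals with iterative proportional
#' fitting, so that synthetic corpora reproduce both published margins while
#' the modern-medicine diagnosis stays informative about the pattern — the
#' premise behind appending the diagnosis token in corpus variant 2. The
#' table is deterministic and config-overridable; it is invented structure,
#' not an estimate from clinical data.
#'
#' @param max_iter,tol Iterative-proportional-fitting controls.
#' @return An 8 x 10 row-stochastic matrix (diseases x patterns).
#' @examples
#' round(default_pattern_given_disease(), 3)
#' @export
default_pattern_given_disease <- function(max_iter = 500, tol = 1e-10) {
  mask <- disease_pattern_mask()
  row_target <- default_disease_priors()
  col_target <- default_pattern_priors()
  joint <- mask / sum(mask)
  for (i in seq_len(max_iter)) {
    joint <- joint * (row_target / pmax(rowSums(joint), 1e-300))
    joint <- t(t(joint) * (col_target / pmax(colSums(joint), 1e-300)))
    if (max(abs(rowSums(joint) - row_target)) < tol) break
  }
  joint / rowSums(joint)
}

#' Configuration for the synthetic tokenized-EMR generator
#'
#' Bundles every knob of the record generator. Defaults emulate the reference
#' lung-ward corpus: published disease and pattern marginals, an informative
#' disease-to-pattern table, a mean of 3 tokens per syndrome element, and a
#' noise-token rate of 0.25 (one distractor per four content tokens —
#' free-text EMR narratives carry substantial non-diagnostic vocabulary).
#'
#' @param n_records Number of records to generate.
#' @param disease_priors Named probability vector over [lung_diseases()].
#' @param pattern_given_disease Row-stochastic diseases x patterns matrix.
#' @param tokens_per_element Mean token count drawn per syndrome element
#'   (Poisson with a floor of 1).
#' @param noise_token_rate Expected noise tokens per content token, in
#'   `[0, 1)`.
#' @param corpus_variant 1 (signs only) or 2 (disease-diagnosis token
#'   appended to each record).
#' @param seed Integer seed making generation reproducible.
#' @return A `tcm_generator_config` list.
#' @examples
#' cfg <- generator_config(n_records = 50, seed = 7)
#' @export
generator_config <- function(n_records = 1000,
                             disease_priors = default_disease_priors(),
                             pattern_given_disease = default_pattern_given_disease(),
                             tokens_per_element = 3,
                             noise_token_rate = 0.25,
                             corpus_variant = 1,
                             seed = 1) {
  assert_scalar_number(n_records, "n_records", lower = 1)
  assert_scalar_number(tokens_per_element, "tokens_per_element", lower = 1)
  assert_scalar_number(noise_token_rate, "noise_token_rate", lower = 0)
  if (noise_token_rate >= 1) abort("`noise_token_rate` must be < 1.")
  if (!corpus_variant %in% c(1, 2)) abort("`corpus_variant` must be 1 or 2.")
  d <- lung_diseases(); p <- syndrome_patterns()
  if (!setequal(names(disease_priors), d)) {
    abort("`disease_priors` must be named over lung_diseases().")
  }
  disease_priors <- disease_priors[d]
  if (abs(sum(disease_priors) - 1) > 1e-9) {
    abort("`disease_priors` must sum to 1 (tolerance 1e-9).")
  }
  if (!identical(dim(pattern_given_disease), c(length(d), length(p)))) {
    abort("`pattern_given_disease` must be an 8 x 10 matrix (diseases x patterns).")
  }
  pattern_given_disease <- pattern_given_disease[d, p]
  if (any(abs(rowSums(pattern_given_disease) - 1) > 1e-9)) {
    abort("Rows of `pattern_given_disease` must sum to 1 (tolerance 1e-9).")
  }
  structure(list(
    n_records = as.integer(n_records),
    disease_priors = disease_priors,
    pattern_given_disease = pattern_given_disease,
    tokens_per_element = tokens_per_element,
    noise_token_rate = noise_token_rate,
    section_order = c("chief_complaint", "syndromes", "chest_signs",
                      "tongue", "pulse"),
    corpus_variant = as.integer(corpus_variant),
    seed = as.integer(seed)
  ), class = "tcm_generator_config")
}

#' Read a generator configuration from YAML
#'
#' Scalar fields map directly onto [generator_config()] arguments;
#' `disease_priors` is a name-value mapping and `pattern_given_disease` a
#' nested mapping disease -> pattern -> probability (omitted fields keep
#' their defaults).
#'
#' @param path Path to a YAML file.
#' @return A `tcm_generator_config`.
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (f in c("n_records", "tokens_per_element", "noise_token_rate",
              "corpus_variant", "seed")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  if (!is.null(y$disease_priors)) {
    args$disease_priors <- unlist(y$disease_priors)
  }
  if (!is.null(y$pattern_given_disease)) {
    m <- matrix(0, length(lung_diseases()), length(syndrome_patterns()),
                dimnames = list(lung_diseases(), syndrome_patterns()))
    for (dd in names(y$pattern_given_disease)) {
      row <- unlist(y$pattern_given_disease[[dd]])
      m[dd, names(row)] <- row
    }
    args$pattern_given_disease <- m
  }
  do.call(generator_config, args)
}

disease_token <- function(disease) {
  paste0("dx_", gsub("[^a-z0-9]+", "_", tolower(disease)))
}

#' Synthetic lexicon for record generation
#'
#' Builds the token inventory the generator draws from: per-element symptom/
#' sign tokens (abstract ASCII identifiers such as `el_phlegm_07` — the
#' pipeline operates on token sequences, not on any particular language),
#' per-disease chief-complaint tokens drawn from a shared pool of
#' nonspecific complaints (so the free-text chief complaint carries only a
#' weak disease signal, unlike the unambiguous diagnosis token of corpus
#' variant 2), and noise tokens. Each element's tokens are assigned
#' round-robin to the four sign sections (syndromes, chest, tongue, pulse).
#'
#' @param tokens_per_element Lexicon size per syndrome element (>= 20).
#' @param element_overlap Fraction of each element's lexicon replaced by
#'   tokens from a pool shared across elements; 0 (default) keeps element
#'   lexicons disjoint, larger values create controlled label ambiguity for
#'   stress tests.
#' @param n_noise_tokens Size of the noise-token inventory.
#' @return A `tcm_lexicon` list with `element_tokens`, `element_sections`,
#'   `disease_tokens`, `noise_tokens`.
#' @export
default_lexicon <- function(tokens_per_element = 24, element_overlap = 0,
                            n_noise_tokens = 60) {
  assert_scalar_number(tokens_per_element, "tokens_per_element", lower = 20)
  assert_scalar_number(element_overlap, "element_overlap", 0, 1)
  els <- syndrome_elements()
  sections <- c("syndromes", "chest_signs", "tongue", "pulse")
  n_shared <- floor(element_overlap * tokens_per_element)
  shared <- sprintf("el_shared_%02d", seq_len(max(n_shared, 1)))
  element_tokens <- lapply(els, function(e) {
    slug <- gsub("[^a-z]+", "", e)
    own <- sprintf("el_%s_%02d", slug, seq_len(tokens_per_element - n_shared))
    c(own, if (n_shared > 0) shared[seq_len(n_shared)])
  })
  names(element_tokens) <- els
  element_sections <- lapply(element_tokens, function(tok) {
    setNames(sections[(seq_along(tok) - 1) %% length(sections) + 1], tok)
  })
  # overlapping windows over a common complaint pool: adjacent diseases share
  # most of their chief-complaint vocabulary
  pool <- sprintf("sx_common_%02d", 1:30)
  disease_tokens <- lapply(seq_along(lung_diseases()), function(i) {
    pool[((i - 1) * 3 + 0:7) %% length(pool) + 1]
  })
  names(disease_tokens) <- lung_diseases()
  structure(list(
    element_tokens = element_tokens,
    element_sections = element_sections,
    disease_tokens = disease_tokens,
    noise_tokens = sprintf("noise_%03d", seq_len(n_noise_tokens))
  ), class = "tcm_lexicon")
}

#' Generate synthetic tokenized clinical records
#'
#' Draws clinical-case records with the structure the diagnosis pipeline
#' assumes: a modern-medicine lung disease from the configured priors, a
#' syndrome pattern from the disease-conditional table, the pattern's
#' syndrome-element set from the rule base, and a token stream assembled from
#' five ordered sections — chief complaint (disease-lexicon tokens), then
#' syndromes / chest signs / tongue / pulse (per-element tokens routed to
#' their lexicon sections). Each element contributes a Poisson number of
#' tokens (mean `tokens_per_element`, at least 1); noise tokens are
#' interspersed at the configured rate; corpus variant 2 appends the disease
#' diagnosis token. Generation is reproducible under the config seed and
#' labels are rule-consistent by construction.
#'
#' @param config A [generator_config()].
#' @param rulebase A validated [tcm_rulebase][load_rulebase()].
#' @param lexicon A [default_lexicon()]-style lexicon.
#' @param patterns Optional character vector of length `n_records` forcing
#'   each record's syndrome pattern (used for balanced designs); diseases are
#'   then drawn from the conditional disease-given-pattern distribution.
#' @return A tibble with columns `record_id`, `disease`, `pattern`,
#'   `elements` (list-column), `tokens` (list-column), `corpus_variant`.
#' @examples
#' rec <- generate_records(generator_config(n_records = 5, seed = 42))
#' rec$tokens[[1]]
#' @export
generate_records <- function(config = generator_config(),
                             rulebase = default_rulebase(),
                             lexicon = default_lexicon(),
                             patterns = NULL) {
  stopifnot(inherits(config, "tcm_generator_config"),
            inherits(rulebase, "tcm_rulebase"),
            inherits(lexicon, "tcm_lexicon"))
  val <- validate_rulebase(rulebase)
  if (length(val$missing_patterns) > 0 && is.null(patterns)) {
    abort(sprintf("Rule base does not cover pattern(s): %s",
                  paste(val$missing_patterns, collapse = "; ")))
  }
  needed <- unique(unlist(rulebase$rules$elements))
  empty <- needed[!vapply(lexicon$element_tokens[needed], length,
                          1L) > 0]
  if (length(empty)) {
    abort(sprintf("Lexicon has no tokens for element(s): %s",
                  paste(empty, collapse = ", ")))
  }
  n <- config$n_records
  dvoc <- lung_diseases()
  with_rng_seed(config$seed, {
    if (is.null(patterns)) {
      disease <- sample(dvoc, n, replace = TRUE, prob = config$disease_priors)
      pattern <- vapply(disease, function(d) {
        sample(syndrome_patterns(), 1,
               prob = config$pattern_given_disease[d, ])
      }, character(1), USE.NAMES = FALSE)
    } else {
      if (length(patterns) != n) {
        abort("`patterns` must have length `n_records`.")
      }
      check_labels(patterns, syndrome_patterns(), "syndrome pattern")
      pattern <- patterns
      # Bayes inversion of the generator's joint for disease | pattern
      joint <- config$disease_priors * config$pattern_given_disease
      disease <- vapply(pattern, function(p) {
        w <- joint[, p]
        if (sum(w) <= 0) w <- config$disease_priors
        sample(dvoc, 1, prob = w)
      }, character(1), USE.NAMES = FALSE)
    }
    element_sets <- lapply(pattern, elements_for_pattern, rulebase = rulebase)
    sec_names <- config$section_order
    tokens <- vector("list", n)
    for (i in seq_len(n)) {
      secs <- setNames(vector("list", length(sec_names)), sec_names)
      n_dx <- poisson_min1(1, config$tokens_per_element)
      secs$chief_complaint <-
        sample(lexicon$disease_tokens[[disease[i]]], n_dx, replace = TRUE)
      for (el in element_sets[[i]]) {
        k <- poisson_min1(1, config$tokens_per_element)
        tok <- sample(lexicon$element_tokens[[el]], k, replace = TRUE)
        dest <- lexicon$element_sections[[el]][tok]
        for (s in unique(dest)) {
          secs[[s]] <- c(secs[[s]], tok[dest == s])
        }
      }
      stream <- unlist(secs, use.names = FALSE)
      if (config$noise_token_rate > 0) {
        n_noise <- rpois(1, config$noise_token_rate * length(stream))
        if (n_noise > 0) {
          noise <- sample(lexicon$noise_tokens, n_noise, replace = TRUE)
          pos <- sample(length(stream) + n_noise, n_noise)
          merged <- character(length(stream) + n_noise)
          merged[pos] <- noise
          merged[-pos] <- stream
          stream <- merged
        }
      }
      if (config$corpus_variant == 2) {
        stream <- c(stream, disease_token(disease[i]))
      }
      tokens[[i]] <- stream
    }
    tibble(
      record_id = sprintf("rec_%06d", seq_len(n)),
      disease = disease,
      pattern = pattern,
      elements = element_sets,
      tokens = tokens,
      corpus_variant = config$corpus_variant
    )
  })
}

#' Split records into train and test partitions
#'
#' Exact partition at the given ratio (default 4:1, the reference study's
#' development-set split); the remainder of a non-divisible split goes to the
#' train partition, so 14,075 records at 4:1 yield a test partition of 2,815.
#' Stratified splitting preserves per-pattern proportions within one record.
#'
#' @param records A records tibble (needs a `pattern` column when
#'   stratifying).
#' @param ratio Length-2 positive integer ratio `c(train, test)`.
#' @param stratify_by `"pattern"` (default) or `"none"`.
#' @param seed Integer seed for the randomised assignment.
#' @return A list with tibbles `train` and `test`.
#' @examples
#' rec <- generate_records(generator_config(n_records = 100, seed = 1))
#' sp <- split_records(rec, seed = 3)
#' nrow(sp$test)
#' @export
split_records <- function(records, ratio = c(4, 1),
                          stratify_by = c("pattern", "none"), seed = 1) {
  stratify_by <- match.arg(stratify_by)
  if (length(ratio) != 2 || any(ratio <= 0)) {
    abort("`ratio` must be two positive numbers (train:test).")
  }
  n <- nrow(records)
  test_frac <- ratio[2] / sum(ratio)
  n_test <- floor(n * test_frac)
  with_rng_seed(seed, {
    if (stratify_by == "none") {
      test_idx <- sample(n, n_test)
    } else {
      cls <- records$pattern
      counts <- table(cls)
      small <- names(counts)[counts * test_frac < 1]
      if (length(small) > 0) {
        abort(sprintf(
          "Cannot stratify: class(es) with too few records for a %s:%s split: %s",
          ratio[1], ratio[2], paste(small, collapse = "; ")),
          class = "tcm_stratification_error")
      }
      quota_raw <- as.numeric(counts) * test_frac
      quota <- floor(quota_raw)
      short <- n_test - sum(quota)
      if (short > 0) {
        # largest-remainder apportionment, ties broken by class order
        extra <- order(quota_raw - quota, decreasing = TRUE)[seq_len(short)]
        quota[extra] <- quota[extra] + 1
      }
      test_idx <- unlist(purrr::map2(names(counts), quota, function(cl, q) {
        idx <- which(cls == cl)
        if (q == 0) integer() else sample(idx, q)
      }))
    }
    list(train = records[-test_idx, , drop = FALSE],
         test = records[sort(test_idx), , drop = FALSE])
  })
}

#' Read and write records as JSON-lines
#'
#' One UTF-8 JSON object per line with fields `record_id`, `disease`,
#' `pattern`, `elements`, `tokens`, `corpus_variant`; the round trip is
#' lossless.
#'
#' @param records A records tibble.
#' @param path File path.
#' @return `write_records()` returns `path` invisibly; `read_records()`
#'   returns a records tibble.
#' @export
write_records <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    jsonlite::toJSON(list(
      record_id = records$record_id[i],
      disease = records$disease[i],
      pattern = records$pattern[i],
      elements = records$elements[[i]],
      tokens = records$tokens[[i]],
      corpus_variant = records$corpus_variant[i]
    ), auto_unbox = TRUE)
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  rows <- purrr::imap(lines, function(ln, i) {
    rec <- tryCatch(jsonlite::fromJSON(ln, simplifyVector = TRUE),
                    error = function(e) {
                      abort(sprintf("Malformed JSON at line %d of '%s': %s",
                                    i, path, conditionMessage(e)),
                            class = "tcm_parse_error")
                    })
    tibble(record_id = rec$record_id, disease = rec$disease,
           pattern = rec$pattern,
           elements = list(as.character(rec$elements)),
           tokens = list(as.character(rec$tokens)),
           corpus_variant = as.integer(rec$corpus_variant))
  })
  dplyr::bind_rows(rows)
}
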