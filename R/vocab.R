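#' Controlled vocabularies for the lung-disease syndrome corpus
#'
#' The package works over three closed label sets describing a lung-disease
#' ward in integrative medicine: 9 syndrome-element types (the atomic units of
#' TCM syndrome classification), 10 syndrome-pattern types (the diagnostic
#' targets, each a combination of elements), and 8 modern-medicine lung
#' diseases. Membership in these vocabularies is enforced wherever labels
#' enter the pipeline.
#'
#' @return A character vector of labels.
#' @examples
#' syndrome_elements()
#' syndrome_patterns()
#' lung_diseases()
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
syndrome_elements <- function() {
  c("phlegm", "wind", "cold", "heat", "qi-deficiency", "yin-deficiency",
    "lung", "spleen", "kidney")
}

#' @rdname vocabularies
#' @export
syndrome_patterns <- function() {
  c("qi-deficiency of lung and spleen",
    "qi-deficiency of lung and kidney",
    "yin-deficiency of lung",
    "wind-cold attacking lung",
    "wind-heat attacking lung",
    "cold wheezing",
    "deficiency of qi and yin",
    "hot wheezing",
    "phlegm-heat obstruction in lung",
    "phlegm obstruction in lung")
}

#' @rdname vocabularies
#' @export
lung_diseases <- function() {
  c("lung cancer", "pulmonary infection", "acute bronchitis",
    "interstitial pneumonia", "chronic bronchitis",
    "chronic obstructive pulmonary disease", "bronchiectasis", "asthma")
}

#' Published summary statistics of the reference lung-disease EMR corpus
#'
#' Headline counts of the real-world corpus that this package's synthetic
#' generator emulates: a development set of 14,075 clinical-case records
#' (split 4:1 into train and test), an external test set of 1,000 records,
#' 35,992 syndrome-element annotations over the development-set patterns, and
#' per-class test-set supports for the 10 patterns and 9 elements. These
#' numbers calibrate the generator's default class priors and provide the
#' arithmetic anchors (test-partition size, mean elements per pattern) that
#' the test-suite checks.
#'
#' @return A list with components `n_development`, `n_external`,
#'   `n_elements_development`, `n_elements_external`, `split_ratio`,
#'   `pattern_support` (named integer vector over [syndrome_patterns()]),
#'   `element_support` (named integer vector over [syndrome_elements()]), and
#'   `disease_proportions` (named numeric vector over [lung_diseases()]).
#' @examples
#' ref <- reference_corpus_stats()
#' ref$n_development / sum(ref$split_ratio) # records per split "part"
#' @export
reference_corpus_stats <- function() {
  pattern_support <- setNames(
    c(247L, 176L, 225L, 176L, 216L, 179L, 153L, 144L, 613L, 686L),
    syndrome_patterns())
  element_support <- setNames(
    c(1233L, 435L, 503L, 811L, 616L, 403L, 2815L, 258L, 171L),
    syndrome_elements())
  disease_pct <- setNames(
    c(18.42, 18.59, 8.39, 1.66, 9.78, 25.98, 4.31, 12.88),
    lung_diseases())
  list(
    n_development = 14075L,
    n_external = 1000L,
    n_elements_development = 35992L,
    n_elements_external = 2602L,
    split_ratio = c(train = 4L, test = 1L),
    pattern_support = pattern_support,
    element_support = element_support,
    disease_proportions = disease_pct / sum(disease_pct)
  )
}

#' Mean number of syndrome elements per syndrome pattern
#'
#' The element density of an annotated corpus: total element annotations
#' divided by the number of pattern-labelled records, rounded to two decimals
#' as conventionally reported.
#'
#' @param n_elements Total count of syndrome-element annotations.
#' @param n_patterns Number of records carrying a syndrome-pattern label.
#' @param digits Decimal places for rounding (default 2).
#' @return A single number.
#' @examples
#' ref <- reference_corpus_stats()
#' element_density(ref$n_elements_development, ref$n_development)
#' @export
element_density <- function(n_elements, n_patterns, digits = 2) {
  assert_scalar_number(n_elements, "n_elements", lower = 0)
  assert_scalar_number(n_patterns, "n_patterns", lower = 1)
  round(n_elements / n_patterns, digits)
}

check_labels <- function(labels, vocabulary, what) {
  bad <- setdiff(labels, vocabulary)
  if (length(bad) > 0) {
    abort(sprintf("Unknown %s label(s): %s", what,
                  paste(sprintf("'%s'", bad), collapse = ", ")),
          class = "tcm_vocabulary_error")
  }
  invisible(labels)
}
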