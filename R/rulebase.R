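#' The syndrome-element rule knowledge base
#'
#' The rule-based reasoning (RBR) half of the hybrid diagnosis pipeline is a
#' small forward-chaining knowledge base: each rule maps a set of syndrome
#' elements to the syndrome pattern their combination implies. A rule base is
#' a tibble of rules (`rule_id`, `pattern`, `elements` list-column,
#' `priority`) plus a free-text version tag. Lower `priority` values win ties
#' when two rules match equally well; priorities must be unique so ambiguity
#' resolution is reproducible under file re-serialisation.
#'
#' `load_rulebase()` reads a rule base from a JSON file of the form
#' `{"version": str, "rules": [{"pattern": str, "elements": [str...],
#' "priority": int}]}`; with `path = NULL` it loads the table shipped with the
#' package, in which each of the 10 syndrome patterns decomposes into its
#' constituent elements (every pattern includes the `lung` element; the two
#' wheezing patterns additionally carry the episodic `wind` trigger so that
#' all 10 element sets are distinct). The shipped file is a starting point:
#' edit or replace it to encode an authoritative clinical rule table.
#'
#' @param path Path to a rule-base JSON file, or `NULL` for the packaged
#'   default table.
#' @return A `tcm_rulebase` object.
#' @examples
#' rb <- load_rulebase()
#' rb
#' elements_for_pattern(rb, "yin-deficiency of lung")
#' @seealso [pattern_for_elements()], [validate_rulebase()]
#' @export
load_rulebase <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rulebase.json", package = "tcmreason",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) {
    abort(sprintf("Rule-base file not found: '%s'", path))
  }
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    error = function(e) abort(sprintf(
      "Malformed rule-base JSON in '%s': %s", path, conditionMessage(e)),
      class = "tcm_schema_error"))
  if (!is.list(raw) || is.null(raw$rules)) {
    abort("Rule-base JSON must contain a 'rules' array.",
          class = "tcm_schema_error")
  }
  rules <- purrr::imap(raw$rules, function(r, i) {
    if (is.null(r$pattern) || is.null(r$elements) || is.null(r$priority)) {
      abort(sprintf(
        "Rule %d is missing one of the required fields pattern/elements/priority.",
        i), class = "tcm_schema_error")
    }
    els <- unique(as.character(unlist(r$elements)))
    if (length(els) == 0) {
      abort(sprintf("Rule %d ('%s') has an empty element set.", i, r$pattern),
            class = "tcm_schema_error")
    }
    tibble(pattern = as.character(r$pattern),
           elements = list(els),
           priority = as.integer(r$priority))
  })
  rules <- dplyr::bind_rows(rules)
  rules$rule_id <- sprintf("R%02d", seq_len(nrow(rules)))
  new_rulebase(rules, version = raw$version %||% "unversioned")
}

#' @rdname load_rulebase
#' @export
default_rulebase <- function() load_rulebase(NULL)

new_rulebase <- function(rules, version) {
  check_labels(rules$pattern, syndrome_patterns(), "syndrome pattern")
  check_labels(unlist(rules$elements), syndrome_elements(), "syndrome element")
  if (anyDuplicated(rules$priority)) {
    abort("Rule priorities must be unique within a rule base.",
          class = "tcm_schema_error")
  }
  rules <- dplyr::arrange(rules, .data$priority)
  rules <- dplyr::select(rules, "rule_id", "pattern", "elements", "priority")
  structure(list(rules = as_tibble(rules), version = as.character(version)),
            class = "tcm_rulebase")
}

#' @export
print.tcm_rulebase <- function(x, ...) {
  cat(sprintf("<tcm_rulebase> version '%s', %d rules\n",
              x$version, nrow(x$rules)))
  df <- mutate(x$rules,
               elements = map_chr(.data$elements, paste, collapse = " + "))
  print(as.data.frame(df), right = FALSE, row.names = FALSE)
  invisible(x)
}

#' @export
format.tcm_rulebase <- function(x, ...) {
  sprintf("<tcm_rulebase: %d rules, version '%s'>", nrow(x$rules), x$version)
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Decompose a syndrome pattern into its syndrome elements
#'
#' Looks up the element set of the highest-priority rule concluding the given
#' pattern.
#'
#' @param rulebase A `tcm_rulebase`.
#' @param pattern A syndrome-pattern label present in the rule base.
#' @return A character vector of syndrome-element labels.
#' @examples
#' elements_for_pattern(default_rulebase(), "wind-cold attacking lung")
#' @export
elements_for_pattern <- function(rulebase, pattern) {
  stopifnot(inherits(rulebase, "tcm_rulebase"))
  check_labels(pattern, syndrome_patterns(), "syndrome pattern")
  hits <- rulebase$rules[rulebase$rules$pattern == pattern, ]
  if (nrow(hits) == 0) {
    abort(sprintf("Pattern '%s' has no rule in this rule base.", pattern),
          class = "tcm_lookup_error")
  }
  hits$elements[[which.min(hits$priority)]]
}

#' Infer a syndrome pattern from a set of syndrome elements
#'
#' The forward-reasoning step of MBR+RBR: a predicted element set is compared
#' against every rule's element set. Exact set equality with a single rule
#' yields an `exact` match; otherwise rules are ranked by Jaccard overlap
#' `|intersection| / |union|`. A unique maximiser at or above `partial_floor`
#' is a `partial` match; several tied maximisers give an `ambiguous` match
#' resolved in favour of the lowest priority rank (all tied rules are listed);
#' when no rule reaches the floor the status is `none` and no pattern is
#' returned.
#'
#' @inheritParams elements_for_pattern
#' @param elements Non-empty character vector of syndrome-element labels.
#' @param partial_floor Minimum Jaccard overlap for a non-exact match to count
#'   (default 0.5); below it single-element stubs are not force-assigned.
#' @return A one-row tibble with columns `pattern` (`NA` for status `none`),
#'   `status` (one of `exact`, `partial`, `ambiguous`, `none`),
#'   `matched_rule_ids` (list-column), and `overlap_score`.
#' @examples
#' rb <- default_rulebase()
#' pattern_for_elements(rb, c("yin-deficiency", "lung"))
#' pattern_for_elements(rb, c("yin-deficiency", "lung", "heat"))
#' @export
pattern_for_elements <- function(rulebase, elements, partial_floor = 0.5) {
  stopifnot(inherits(rulebase, "tcm_rulebase"))
  if (length(elements) == 0) {
    abort("`elements` must be a non-empty set of syndrome elements.",
          class = "tcm_precondition_error")
  }
  check_labels(elements, syndrome_elements(), "syndrome element")
  elements <- unique(elements)
  rules <- rulebase$rules
  scores <- map_dbl(rules$elements, jaccard, b = elements)
  best <- max(scores)
  winners <- which(scores == best)
  no_match <- function() tibble(pattern = NA_character_, status = "none",
                                matched_rule_ids = list(character()),
                                overlap_score = best)
  if (best < partial_floor && best < 1) return(no_match())
  # among tied maximisers the lowest priority rank wins deterministically
  pick <- winners[which.min(rules$priority[winners])]
  status <- if (length(winners) > 1) "ambiguous"
            else if (best == 1) "exact" else "partial"
  tibble(pattern = rules$pattern[pick], status = status,
         matched_rule_ids = list(rules$rule_id[winners]),
         overlap_score = best)
}

#' Validate a rule base
#'
#' Report-only diagnostics over a rule knowledge base: syndrome patterns with
#' no rule, rules sharing an identical element set (which make decomposition
#' non-injective and force ambiguity resolution by priority), elements never
#' used by any rule, and a round-trip check that decomposing every covered
#' pattern and recombining its elements recovers the same pattern with exact
#' status.
#'
#' @inheritParams elements_for_pattern
#' @return A `tcm_rulebase_validation` list with components
#'   `missing_patterns`, `duplicate_sets` (tibble of rule-id pairs),
#'   `unused_elements`, `roundtrip` (per-pattern tibble), and `ok`.
#' @examples
#' validate_rulebase(default_rulebase())
#' @export
validate_rulebase <- function(rulebase) {
  stopifnot(inherits(rulebase, "tcm_rulebase"))
  rules <- rulebase$rules
  missing_patterns <- setdiff(syndrome_patterns(), rules$pattern)
  unused_elements <- setdiff(syndrome_elements(), unlist(rules$elements))

  key <- map_chr(rules$elements, function(e) paste(sort(e), collapse = "|"))
  dup_pairs <- list()
  if (nrow(rules) > 1) {
    for (i in seq_len(nrow(rules) - 1)) {
      for (j in seq(i + 1, nrow(rules))) {
        if (key[i] == key[j]) {
          dup_pairs[[length(dup_pairs) + 1]] <-
            tibble(rule_id_a = rules$rule_id[i], rule_id_b = rules$rule_id[j],
                   elements = list(rules$elements[[i]]))
        }
      }
    }
  }
  duplicate_sets <- if (length(dup_pairs)) dplyr::bind_rows(dup_pairs) else
    tibble(rule_id_a = character(), rule_id_b = character(),
           elements = list())

  covered <- unique(rules$pattern)
  roundtrip <- purrr::map_dfr(covered, function(p) {
    els <- elements_for_pattern(rulebase, p)
    m <- pattern_for_elements(rulebase, els)
    tibble(pattern = p, recovered = m$pattern, status = m$status,
           pass = identical(m$pattern, p) && m$status == "exact")
  })

  structure(list(
    missing_patterns = missing_patterns,
    duplicate_sets = duplicate_sets,
    unused_elements = unused_elements,
    roundtrip = roundtrip,
    ok = length(missing_patterns) == 0 && nrow(duplicate_sets) == 0 &&
      all(roundtrip$pass)
  ), class = "tcm_rulebase_validation")
}

#' @export
print.tcm_rulebase_validation <- function(x, ...) {
  cat("<tcm_rulebase_validation>\n")
  cat(sprintf("  overall: %s\n", if (x$ok) "PASS" else "ISSUES FOUND"))
  if (length(x$missing_patterns))
    cat("  patterns without a rule:",
        paste(x$missing_patterns, collapse = "; "), "\n")
  if (nrow(x$duplicate_sets))
    cat(sprintf("  duplicate element sets: %d pair(s) (%s)\n",
                nrow(x$duplicate_sets),
                paste(paste(x$duplicate_sets$rule_id_a,
                            x$duplicate_sets$rule_id_b, sep = "~"),
                      collapse = ", ")))
  if (length(x$unused_elements))
    cat("  unused elements:", paste(x$unused_elements, collapse = ", "), "\n")
  cat(sprintf("  round-trip: %d/%d patterns exact\n",
              sum(x$roundtrip$pass), nrow(x$roundtrip)))
  invisible(x)
}

#' Write a rule base to JSON
#'
#' @inheritParams elements_for_pattern
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rulebase <- function(rulebase, path) {
  stopifnot(inherits(rulebase, "tcm_rulebase"))
  out <- list(version = rulebase$version,
              rules = purrr::pmap(rulebase$rules, function(rule_id, pattern,
                                                           elements, priority) {
                list(pattern = pattern, elements = as.list(elements),
                     priority = priority)
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
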