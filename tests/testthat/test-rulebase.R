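test_that("the shipped rule base covers all 10 patterns and matches the name-decomposition oracle", {
  rb <- default_rulebase()
  expect_s3_class(rb, "tcm_rulebase")
  expect_equal(nrow(rb$rules), 10)
  expect_setequal(rb$rules$pattern, syndrome_patterns())
  for (p in syndrome_patterns()) {
    expect_setequal(elements_for_pattern(rb, p), oracle_pattern_elements(p))
  }
})

test_that("rule-base loading rejects schema and vocabulary violations", {
  bad_empty <- file.path(tempdir(), "empty_els.json")
  jsonlite::write_json(list(version = "x", rules = list(
    list(pattern = "cold wheezing", elements = list(), priority = 1))),
    bad_empty, auto_unbox = TRUE)
  expect_error(load_rulebase(bad_empty), class = "tcm_schema_error")

  bad_vocab <- file.path(tempdir(), "bad_vocab.json")
  jsonlite::write_json(list(version = "x", rules = list(
    list(pattern = "cold wheezing", elements = list("dampness"),
         priority = 1))), bad_vocab, auto_unbox = TRUE)
  expect_error(load_rulebase(bad_vocab), class = "tcm_vocabulary_error")

  bad_prio <- file.path(tempdir(), "bad_prio.json")
  jsonlite::write_json(list(version = "x", rules = list(
    list(pattern = "cold wheezing", elements = list("cold"), priority = 1),
    list(pattern = "hot wheezing", elements = list("heat"), priority = 1))),
    bad_prio, auto_unbox = TRUE)
  expect_error(load_rulebase(bad_prio), class = "tcm_schema_error")

  expect_error(load_rulebase(file.path(tempdir(), "nope.json")), "not found")
})

test_that("duplicate element sets load but are reported by validation", {
  rb <- load_rulebase(toy_duplicate_rulebase_path())
  val <- validate_rulebase(rb)
  expect_equal(nrow(val$duplicate_sets), 1)
  expect_setequal(unlist(val$duplicate_sets[1, c("rule_id_a", "rule_id_b")]),
                  c("R01", "R02"))
  expect_false(val$ok)
  # elements never used anywhere in this 3-rule base
  expect_true("kidney" %in% val$unused_elements)
  # patterns absent from the base are reported
  expect_true("cold wheezing" %in% val$missing_patterns)
})

test_that("elements_for_pattern errors on a pattern missing from the base", {
  rb <- load_rulebase(toy_duplicate_rulebase_path())
  expect_error(elements_for_pattern(rb, "cold wheezing"),
               class = "tcm_lookup_error")
  expect_error(elements_for_pattern(rb, "not a pattern"),
               class = "tcm_vocabulary_error")
})

test_that("pattern_for_elements matches an exhaustive Jaccard comparison", {
  rb <- default_rulebase()
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  withr::with_seed(42, {
    for (i in 1:50) {
      els <- sample(syndrome_elements(), sample(1:5, 1))
      m <- pattern_for_elements(rb, els)
      scores <- vapply(rb$rules$elements, jac, numeric(1), a = els)
      best <- max(scores)
      expect_equal(m$overlap_score, best)
      if (best >= 0.5 || best == 1) {
        winners <- which(scores == best)
        pick <- winners[which.min(rb$rules$priority[winners])]
        expect_identical(m$pattern, rb$rules$pattern[pick])
        expect_identical(m$status,
                         if (length(winners) > 1) "ambiguous"
                         else if (best == 1) "exact" else "partial")
      } else {
        expect_identical(m$status, "none")
        expect_true(is.na(m$pattern))
      }
    }
  })
})

test_that("exact, partial, ambiguous and none statuses behave per contract", {
  rb <- default_rulebase()
  exact <- pattern_for_elements(rb, c("yin-deficiency", "lung"))
  expect_identical(exact$status, "exact")
  expect_identical(exact$pattern, "yin-deficiency of lung")
  expect_equal(exact$overlap_score, 1)

  part <- pattern_for_elements(rb, c("yin-deficiency", "lung", "kidney"))
  expect_identical(part$status, "partial")
  expect_identical(part$pattern, "yin-deficiency of lung")
  expect_equal(part$overlap_score, 2 / 3)

  dup <- load_rulebase(toy_duplicate_rulebase_path())
  amb <- pattern_for_elements(dup, c("heat", "phlegm", "lung"))
  expect_identical(amb$status, "ambiguous")
  expect_identical(amb$pattern, "hot wheezing") # priority 1 beats 2
  expect_setequal(amb$matched_rule_ids[[1]], c("R01", "R02"))

  none <- pattern_for_elements(rb, "kidney")
  expect_identical(none$status, "none")
  expect_true(is.na(none$pattern))

  expect_error(pattern_for_elements(rb, character()),
               class = "tcm_precondition_error")
})

test_that("overlap score is symmetric, bounded, and 1 only under set equality", {
  withr::with_seed(9, {
    for (i in 1:100) {
      a <- sample(syndrome_elements(), sample(1:6, 1))
      b <- sample(syndrome_elements(), sample(1:6, 1))
      j1 <- tcmreason:::jaccard(a, b)
      j2 <- tcmreason:::jaccard(b, a)
      expect_identical(j1, j2)
      expect_gte(j1, 0)
      expect_lte(j1, 1)
      expect_identical(j1 == 1, setequal(a, b))
    }
  })
})

test_that("match results are deterministic across repeated calls", {
  rb <- default_rulebase()
  els <- c("wind", "heat", "lung")
  expect_identical(pattern_for_elements(rb, els),
                   pattern_for_elements(rb, els))
})

test_that("rule-base JSON round trip preserves rules", {
  rb <- default_rulebase()
  path <- file.path(tempdir(), "rb_roundtrip.json")
  write_rulebase(rb, path)
  rb2 <- load_rulebase(path)
  expect_equal(rb$rules$pattern, rb2$rules$pattern)
  expect_equal(rb$rules$elements, rb2$rules$elements)
  expect_equal(rb$rules$priority, rb2$rules$priority)
})
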