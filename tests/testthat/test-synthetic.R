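test_that("generated records are rule-consistent and reproducible", {
  rb <- default_rulebase()
  cfg <- generator_config(n_records = 120, seed = 33)
  rec <- generate_records(cfg)
  expect_equal(nrow(rec), 120)
  # labels always decompose through the rule base with exact status
  for (i in seq_len(nrow(rec))) {
    m <- pattern_for_elements(rb, rec$elements[[i]])
    expect_identical(m$status, "exact")
    expect_identical(m$pattern, rec$pattern[i])
  }
  # same seed, byte-identical serialisation
  rec2 <- generate_records(cfg)
  f1 <- file.path(tempdir(), "a.jsonl")
  f2 <- file.path(tempdir(), "b.jsonl")
  write_records(rec, f1)
  write_records(rec2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("mean elements per record tracks the rule-table expectation", {
  rb <- default_rulebase()
  cfg <- generator_config(n_records = 1000, seed = 5)
  rec <- generate_records(cfg)
  # expectation = sum over patterns of |elements(p)| * Pr(p), with Pr the
  # generator's marginal pattern distribution
  marg <- default_disease_priors() %*% default_pattern_given_disease()
  sizes <- vapply(syndrome_patterns(),
                  function(p) length(elements_for_pattern(rb, p)), numeric(1))
  expected <- sum(sizes * marg[1, syndrome_patterns()])
  observed <- mean(lengths(rec$elements))
  expect_lt(abs(observed - expected), 0.15)
  # and the density sits in the published bracket around 2.56
  big <- generate_records(generator_config(n_records = 4000, seed = 6))
  dens <- mean(lengths(big$elements))
  expect_gte(dens, 2.3)
  expect_lte(dens, 2.8)
})

test_that("a keyword-count oracle recovers every noise-free element set", {
  lex <- default_lexicon()
  cfg <- generator_config(n_records = 150, noise_token_rate = 0,
                          tokens_per_element = 5, seed = 21)
  rec <- generate_records(cfg, lexicon = lex)
  token_to_element <- unlist(lapply(names(lex$element_tokens), function(e) {
    setNames(rep(e, length(lex$element_tokens[[e]])), lex$element_tokens[[e]])
  }))
  for (i in seq_len(nrow(rec))) {
    seen <- unique(token_to_element[rec$tokens[[i]]])
    expect_setequal(seen[!is.na(seen)], rec$elements[[i]])
  }
})

test_that("empirical disease and pattern frequencies match the priors", {
  rec <- generate_records(generator_config(n_records = 10000, seed = 14))
  p_dis <- default_disease_priors()
  gof_d <- chisq.test(table(factor(rec$disease, levels = names(p_dis))),
                      p = p_dis)
  expect_gt(gof_d$p.value, 0.01)
  marg <- (default_disease_priors() %*% default_pattern_given_disease())[1, ]
  gof_p <- chisq.test(table(factor(rec$pattern, levels = names(marg))),
                      p = marg)
  expect_gt(gof_p$p.value, 0.01)
})

test_that("corpus variant 2 carries the diagnosis token", {
  cfg <- generator_config(n_records = 30, corpus_variant = 2, seed = 8)
  rec <- generate_records(cfg)
  for (i in seq_len(nrow(rec))) {
    expect_identical(rec$tokens[[i]][length(rec$tokens[[i]])],
                     tcmreason:::disease_token(rec$disease[i]))
  }
})

test_that("splits are exact partitions with the remainder in train", {
  rec <- tibble::tibble(record_id = sprintf("r%05d", 1:14075),
                        pattern = sample(syndrome_patterns(), 14075,
                                         replace = TRUE))
  sp <- split_records(rec, ratio = c(4, 1), stratify_by = "none", seed = 1)
  expect_equal(nrow(sp$test), 2815)
  expect_equal(nrow(sp$train), 11260)
  expect_length(intersect(sp$train$record_id, sp$test$record_id), 0)
  expect_setequal(c(sp$train$record_id, sp$test$record_id), rec$record_id)

  small <- tibble::tibble(record_id = as.character(1:10),
                          pattern = rep("cold wheezing", 10))
  sp2 <- split_records(small, stratify_by = "none", seed = 2)
  expect_equal(nrow(sp2$train), 8)
  expect_equal(nrow(sp2$test), 2)
})

test_that("stratified splits preserve per-pattern proportions within one record", {
  rec <- generate_records(generator_config(n_records = 800, seed = 3))
  sp <- split_records(rec, stratify_by = "pattern", seed = 4)
  counts <- table(rec$pattern)
  test_counts <- table(factor(sp$test$pattern, levels = names(counts)))
  for (cl in names(counts)) {
    expect_lte(abs(test_counts[[cl]] - counts[[cl]] / 5), 1)
  }
  tiny <- tibble::tibble(record_id = as.character(1:6),
                         pattern = c(rep("cold wheezing", 4),
                                     rep("hot wheezing", 2)))
  expect_error(split_records(tiny, stratify_by = "pattern", seed = 1),
               class = "tcm_stratification_error")
})

test_that("JSON-lines round trip is lossless, including non-ASCII tokens", {
  rec <- generate_records(generator_config(n_records = 40, seed = 10))
  rec$tokens[[1]] <- c("咳嗽", "发热", rec$tokens[[1]])
  path <- file.path(tempdir(), "records.jsonl")
  write_records(rec, path)
  back <- read_records(path)
  expect_equal(back$record_id, rec$record_id)
  expect_equal(back$disease, rec$disease)
  expect_equal(back$pattern, rec$pattern)
  expect_equal(back$elements, rec$elements)
  expect_equal(back$tokens, rec$tokens)
  expect_equal(back$corpus_variant, rec$corpus_variant)

  lines <- readLines(path, warn = FALSE)
  lines[length(lines)] <- substr(lines[length(lines)], 1, 20)
  writeLines(lines, path)
  expect_error(read_records(path), class = "tcm_parse_error")
  expect_error(read_records(path), as.character(length(lines)))
})

test_that("generator configuration is validated and YAML-loadable", {
  expect_error(generator_config(noise_token_rate = 1), "< 1")
  bad <- default_pattern_given_disease()
  bad[1, 1] <- bad[1, 1] + 0.5
  expect_error(generator_config(pattern_given_disease = bad), "sum to 1")

  yml <- file.path(tempdir(), "cfg.yaml")
  writeLines(c("n_records: 25", "noise_token_rate: 0.1", "seed: 99",
               "corpus_variant: 2"), yml)
  cfg <- read_generator_config(yml)
  expect_equal(cfg$n_records, 25L)
  expect_equal(cfg$noise_token_rate, 0.1)
  expect_equal(cfg$corpus_variant, 2L)
  expect_equal(nrow(generate_records(cfg)), 25)
})

test_that("the disease-conditional table is row-stochastic and margin-calibrated", {
  pgd <- default_pattern_given_disease()
  expect_equal(rowSums(pgd), setNames(rep(1, 8), lung_diseases()),
               tolerance = 1e-9)
  marg <- (default_disease_priors() %*% pgd)[1, ]
  expect_equal(marg, default_pattern_priors(), tolerance = 1e-6)
  # each disease concentrates on 2-4 patterns
  expect_true(all(rowSums(pgd > 1e-9) >= 2 & rowSums(pgd > 1e-9) <= 4))
})
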