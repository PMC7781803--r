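test_that("first crossings find the smallest size reaching the threshold", {
  grid <- tibble::tibble(per_class_n = rep(c(160, 240, 320), 2),
                         n_classes = rep(2:3, each = 3),
                         accuracy = c(0.85, 0.91, 0.96, 0.80, 0.85, 0.89),
                         seed = 1L,
                         classes = replicate(6, character(),
                                             simplify = FALSE))
  class(grid) <- c("tcm_scaling_grid", class(grid))
  cr <- first_crossing(grid, 0.90)
  expect_equal(cr$per_class_n[cr$n_classes == 2], 240)
  expect_true(cr$censored[cr$n_classes == 3])
  # threshold 0 is crossed by the smallest size in the grid
  cr0 <- first_crossing(grid, 0)
  expect_true(all(cr0$per_class_n == 160))
})

test_that("crossing sizes are non-decreasing in the threshold", {
  grid <- reference_scaling_grid()
  for (n in c(2, 5, 9)) {
    sizes <- vapply(c(0.5, 0.7, 0.9, 0.95), function(th) {
      cr <- first_crossing(grid, th)
      s <- cr$per_class_n[cr$n_classes == n]
      if (is.na(s)) Inf else s
    }, numeric(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("the published grid yields the italicised crossings, censored at N=10 for 0.95", {
  grid <- reference_scaling_grid()
  cr90 <- first_crossing(grid, 0.90)
  expect_equal(cr90$per_class_n,
               c(160, 240, 240, 240, 320, 400, 400, 400, 480))
  expect_false(any(cr90$censored))
  cr95 <- first_crossing(grid, 0.95)
  expect_true(cr95$censored[cr95$n_classes == 10])
  expect_equal(cr95$per_class_n[cr95$n_classes == 2], 320)
})

test_that("an exact linear relationship is recovered exactly", {
  crossings <- tibble::tibble(n_classes = 2:10,
                              per_class_n = 30 * (2:10) + 100,
                              censored = FALSE, threshold = 0.9)
  # an exactly collinear input triggers R's perfect-fit note in summary.lm
  fit <- suppressWarnings(fit_size_vs_classes(crossings))
  expect_equal(fit$slope, 30, tolerance = 1e-10)
  expect_equal(fit$intercept, 100, tolerance = 1e-10)
  expect_lt(fit$p_value, 0.01)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "n_classes"], 30, tolerance = 1e-10)
})

test_that("censored points are excluded and tiny inputs rejected", {
  crossings <- tibble::tibble(n_classes = 2:5,
                              per_class_n = c(150, 200, NA, 250),
                              censored = c(FALSE, FALSE, TRUE, FALSE),
                              threshold = 0.9)
  fit <- fit_size_vs_classes(crossings)
  expect_equal(fit$n_censored, 1)
  expect_equal(sum(!fit$crossings$censored), 3)
  two <- crossings[1:2, ]
  expect_error(fit_size_vs_classes(two), class = "tcm_fit_error")
})

test_that("noisy crossings from a known line recover the slope", {
  truth_slope <- 35
  truth_intercept <- 110
  crossings <- withr::with_seed(2024, {
    tibble::tibble(n_classes = 2:10,
                   per_class_n = truth_slope * (2:10) + truth_intercept +
                     rnorm(9, 0, 20),
                   censored = FALSE, threshold = 0.9)
  })
  fit <- fit_size_vs_classes(crossings)
  expect_gte(fit$slope, 25)
  expect_lte(fit$slope, 45)
})

test_that("a small synthetic grid runs end to end with sane accuracies", {
  pl <- pipeline_spec("word2vec", "knn", dimension = 8, min_count = 2,
                      embed_epochs = 3, seed = 3)
  cfg <- generator_config(noise_token_rate = 0, seed = 1)
  grid <- run_scaling_grid(per_class_sizes = c(25, 250), class_counts = 2,
                           pipeline = pl, config = cfg, seed = 9,
                           class_subset_seed = 4)
  expect_equal(nrow(grid), 2)
  expect_true(all(grid$accuracy >= 0 & grid$accuracy <= 1))
  # the two cells of one column share the same class subset
  expect_identical(grid$classes[[1]], grid$classes[[2]])
  # learning-curve extremes: more data per class cannot hurt at this seed
  a_small <- grid$accuracy[grid$per_class_n == 25]
  a_large <- grid$accuracy[grid$per_class_n == 250]
  expect_gte(a_large, a_small)
  expect_gte(a_large, 0.9)
})

test_that("rule-identical class pairs collapse to the chance floor", {
  # two patterns forced onto the same element set are indistinguishable
  path <- file.path(tempdir(), "degenerate_rules.json")
  jsonlite::write_json(list(version = "degenerate", rules = list(
    list(pattern = "hot wheezing",
         elements = list("heat", "phlegm", "lung"), priority = 1),
    list(pattern = "phlegm-heat obstruction in lung",
         elements = list("heat", "phlegm", "lung"), priority = 2))),
    path, auto_unbox = TRUE)
  rb <- load_rulebase(path)
  # pattern made independent of disease, so no signal leaks through the
  # chief-complaint tokens either
  unif <- matrix(0.1, nrow = 8, ncol = 10,
                 dimnames = list(lung_diseases(), syndrome_patterns()))
  cfg <- generator_config(n_records = 300, noise_token_rate = 0,
                          pattern_given_disease = unif, seed = 2)
  rec <- generate_records(cfg, rb, default_lexicon(),
                          patterns = rep(c("hot wheezing",
                                           "phlegm-heat obstruction in lung"),
                                         150))
  sp <- split_records(rec, seed = 5)
  pl <- pipeline_spec("word2vec", "knn", dimension = 8, min_count = 2,
                      embed_epochs = 3, seed = 6)
  fit <- fit_pipeline(sp$train, pl, rb)
  m <- evaluate_diagnoses(sp$test, diagnose(fit, sp$test))
  expect_lt(m$accuracy, 0.7) # near the 0.5 chance floor, never high
  expect_gt(m$accuracy, 0.3)
})

test_that("grids export to CSV", {
  grid <- reference_scaling_grid()
  path <- file.path(tempdir(), "grid.csv")
  write_scaling_grid(grid, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(grid))
  expect_equal(back$accuracy, grid$accuracy)
})
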