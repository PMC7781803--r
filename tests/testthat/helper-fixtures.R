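# Shared fixtures, built once per test run and memoised; everything is
# generated in code under fixed seeds.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# noise-free medium corpus shared by embedding/classifier/hybrid tests
fixture_records <- function() {
  memo("records", generate_records(
    generator_config(n_records = 600, noise_token_rate = 0, seed = 101)))
}

fixture_split <- function() {
  memo("split", split_records(fixture_records(), seed = 7))
}

fixture_word_model <- function() {
  memo("word_model", {
    train_word_model(build_corpus(fixture_split()$train), dimension = 16,
                     min_count = 3, epochs = 20, alpha = 0.05, seed = 5)
  })
}

# a toy rule base with a deliberate duplicate element set, written to JSON
toy_duplicate_rulebase_path <- function() {
  path <- file.path(tempdir(), "dup_rulebase.json")
  jsonlite::write_json(list(
    version = "toy-dup",
    rules = list(
      list(pattern = "hot wheezing",
           elements = list("heat", "phlegm", "lung"), priority = 1),
      list(pattern = "phlegm-heat obstruction in lung",
           elements = list("phlegm", "heat", "lung"), priority = 2),
      list(pattern = "yin-deficiency of lung",
           elements = list("yin-deficiency", "lung"), priority = 3)
    )), path, auto_unbox = TRUE)
  path
}

# independent brute-force confusion-matrix oracle for multiclass metrics
oracle_multiclass <- function(truth, predicted) {
  labs <- sort(unique(c(truth, predicted)))
  cm <- table(factor(truth, levels = labs), factor(predicted, levels = labs))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) == 0, 0, tp / colSums(cm))
  rec <- ifelse(rowSums(cm) == 0, 0, tp / rowSums(cm))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  support <- rowSums(cm)
  w <- support / sum(support)
  list(accuracy = sum(tp) / sum(cm),
       precision = sum(w * prec), recall = sum(w * rec), f1 = sum(w * f1),
       per_class = data.frame(label = labs, precision = as.numeric(prec),
                              recall = as.numeric(rec), f1 = as.numeric(f1),
                              support = as.numeric(support)))
}

# string-decomposition oracle: elements whose name fragments occur in the
# pattern name (wheezing patterns additionally carry wind and phlegm; every
# pattern carries lung)
oracle_pattern_elements <- function(pattern) {
  frag <- c(phlegm = "phlegm", wind = "wind", cold = "cold", heat = "heat",
            `qi-deficiency` = "qi", `yin-deficiency` = "yin",
            lung = "lung", spleen = "spleen", kidney = "kidney")
  frag["heat"] <- "heat|hot"
  els <- names(frag)[vapply(frag, function(f) grepl(f, pattern),
                            logical(1))]
  if (grepl("wheezing", pattern)) els <- union(els, c("wind", "phlegm"))
  union(els, "lung")
}
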