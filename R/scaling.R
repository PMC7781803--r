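#' Accuracy-scaling grid over sample size and class count
#'
#' Reproduces the sample-size planning experiment: for each number of
#' syndrome-pattern types `n_classes` a random subset of patterns is fixed
#' (seeded per column), and for each per-class sample size a balanced
#' synthetic data set (`per_class_n` records per selected pattern) is
#' generated, split 4:1 (stratified), and the pipeline's test accuracy
#' recorded. One train/test split per cell, matching the convention of
#' reporting a single accuracy per cell.
#'
#' @param per_class_sizes Integer vector of per-class sample sizes.
#' @param class_counts Integer vector of pattern-type counts (2..10).
#' @param pipeline A [pipeline_spec()].
#' @param config Generator configuration (its `n_records` is overridden per
#'   cell).
#' @param rulebase,lexicon Generator inputs.
#' @param seed Seed stream for generation, splitting and fitting.
#' @param class_subset_seed Seed fixing each column's random class subset.
#' @return A `tcm_scaling_grid` tibble: `per_class_n`, `n_classes`,
#'   `accuracy`, `seed`, `classes` (list-column).
#' @export
run_scaling_grid <- function(per_class_sizes, class_counts, pipeline,
                             config = generator_config(),
                             rulebase = default_rulebase(),
                             lexicon = default_lexicon(),
                             seed = 1, class_subset_seed = 1) {
  if (any(class_counts < 2 | class_counts > length(syndrome_patterns()))) {
    abort("`class_counts` must lie in 2..10.")
  }
  cells <- tidyr::expand_grid(n_classes = sort(unique(class_counts)),
                              per_class_n = sort(unique(per_class_sizes)))
  rows <- purrr::pmap(cells, function(n_classes, per_class_n) {
    classes <- with_rng_seed(child_seed(class_subset_seed, n_classes),
                             sample(syndrome_patterns(), n_classes))
    cfg <- config
    cfg$n_records <- as.integer(per_class_n * n_classes)
    cfg$seed <- child_seed(seed, "gen", n_classes, per_class_n)
    rec <- generate_records(cfg, rulebase, lexicon,
                            patterns = rep(classes, each = per_class_n))
    sp <- split_records(rec, ratio = c(4, 1), stratify_by = "pattern",
                        seed = child_seed(seed, "split", n_classes,
                                          per_class_n))
    p <- pipeline
    p$seed <- child_seed(seed, "fit", n_classes, per_class_n)
    fit <- fit_pipeline(sp$train, p, rulebase)
    m <- metrics_from_diagnoses(sp$test, diagnose(fit, sp$test))
    tibble(per_class_n = per_class_n, n_classes = n_classes,
           accuracy = m$accuracy, seed = p$seed, classes = list(classes))
  })
  grid <- dplyr::bind_rows(rows)
  structure(grid, class = c("tcm_scaling_grid", class(grid)))
}

#' Published accuracy-scaling grid
#'
#' The reference study's accuracy table over per-class sample size (16..800)
#' and number of syndrome-pattern types (2..10), as printed. Useful for
#' demonstrating [first_crossing()] and [fit_size_vs_classes()] on the
#' published numbers without re-running the experiment.
#'
#' @return A `tcm_scaling_grid` tibble.
#' @examples
#' first_crossing(reference_scaling_grid(), 0.90)
#' @export
reference_scaling_grid <- function() {
  sizes <- c(16, 40, 64, 80, 160, 240, 320, 400, 480, 560, 640, 720, 800)
  acc <- rbind(
    c(0.5714, 0.4001, 0.3876, 0.3122, 0.2521, 0.3113, 0.3076, 0.2068, 0.1875),
    c(0.6575, 0.5001, 0.4375, 0.3511, 0.2916, 0.3751, 0.3751, 0.2916, 0.2251),
    c(0.7238, 0.6412, 0.5384, 0.5125, 0.4636, 0.4444, 0.4174, 0.4127, 0.3921),
    c(0.8751, 0.7291, 0.6406, 0.6311, 0.5521, 0.4732, 0.5468, 0.4513, 0.4001),
    c(0.9375, 0.8542, 0.8437, 0.8432, 0.8345, 0.7901, 0.7621, 0.7577, 0.7325),
    c(0.9375, 0.9097, 0.9014, 0.9011, 0.8993, 0.8482, 0.8515, 0.8487, 0.8083),
    c(0.9658, 0.9114, 0.9074, 0.9151, 0.9227, 0.8973, 0.8984, 0.8836, 0.8515),
    c(0.9688, 0.9433, 0.9384, 0.9281, 0.9301, 0.9266, 0.9023, 0.9025, 0.8929),
    c(0.9752, 0.9553, 0.9414, 0.9412, 0.9418, 0.9464, 0.9444, 0.9234, 0.9135),
    c(0.9762, 0.9583, 0.9534, 0.9521, 0.9532, 0.9482, 0.9487, 0.9394, 0.9304),
    c(0.9776, 0.9653, 0.9633, 0.9661, 0.9626, 0.9526, 0.9619, 0.9456, 0.9354),
    c(0.9786, 0.9708, 0.9688, 0.9712, 0.9709, 0.9672, 0.9678, 0.9591, 0.9356),
    c(0.9813, 0.9776, 0.9756, 0.9735, 0.9739, 0.9785, 0.9734, 0.9597, 0.9429))
  grid <- tidyr::expand_grid(per_class_n = sizes, n_classes = 2:10)
  grid$accuracy <- as.numeric(t(acc))
  # expand_grid nests n_classes inside per_class_n; acc rows are sizes
  grid$seed <- NA_integer_
  grid$classes <- replicate(nrow(grid), character(), simplify = FALSE)
  structure(grid, class = c("tcm_scaling_grid", class(grid)))
}

#' First threshold crossing per class count
#'
#' For each number of pattern types, the smallest per-class sample size at
#' which the grid accuracy first reaches `threshold`. Columns that never
#' reach it are reported as censored (`NA` size).
#'
#' @param grid A `tcm_scaling_grid`.
#' @param threshold Accuracy threshold (e.g. 0.90 or 0.95).
#' @return A tibble: `n_classes`, `per_class_n` (`NA` when censored),
#'   `censored`, `threshold`.
#' @export
first_crossing <- function(grid, threshold) {
  assert_scalar_number(threshold, "threshold", 0, 1)
  grid |>
    as_tibble() |>
    group_by(.data$n_classes) |>
    arrange(.data$per_class_n, .by_group = TRUE) |>
    summarise(per_class_n = {
      hit <- which(.data$accuracy >= threshold)
      if (length(hit)) .data$per_class_n[hit[1]] else NA_real_
    }, .groups = "drop") |>
    mutate(censored = is.na(.data$per_class_n), threshold = threshold)
}

#' Linear sample-size planning fit
#'
#' Ordinary least squares of the minimal per-class sample size needed to
#' reach the threshold (Y) on the number of syndrome-pattern types (X),
#' following the crossing-then-regression procedure. Censored crossings are
#' excluded (and reported); at least 3 non-censored points are required. The
#' slope's two-sided t-test p-value comes from the standard linear-model
#' summary.
#'
#' @param crossings Output of [first_crossing()].
#' @return A `tcm_scaling_fit`: list with `slope`, `intercept`, `p_value`,
#'   `threshold`, `model` (the underlying `lm`), `crossings`, and
#'   `n_censored`.
#' @examples
#' fit_size_vs_classes(first_crossing(reference_scaling_grid(), 0.90))
#' @export
fit_size_vs_classes <- function(crossings) {
  used <- dplyr::filter(crossings, !.data$censored)
  if (nrow(used) < 3) {
    abort("At least 3 non-censored crossing points are required for the fit.",
          class = "tcm_fit_error")
  }
  model <- lm(per_class_n ~ n_classes, data = used)
  coefs <- summary(model)$coefficients
  structure(list(
    slope = unname(coefs["n_classes", "Estimate"]),
    intercept = unname(coefs["(Intercept)", "Estimate"]),
    p_value = unname(coefs["n_classes", "Pr(>|t|)"]),
    threshold = crossings$threshold[1],
    model = model,
    crossings = crossings,
    n_censored = sum(crossings$censored)
  ), class = "tcm_scaling_fit")
}

#' @export
print.tcm_scaling_fit <- function(x, ...) {
  cat(sprintf(
    "<tcm_scaling_fit> threshold %.2f: Y = %.2f x X + %.2f (slope p = %.3g; %d point(s), %d censored)\n",
    x$threshold, x$slope, x$intercept, x$p_value,
    sum(!x$crossings$censored), x$n_censored))
  invisible(x)
}

#' @rdname tidy.tcm_metrics
#' @export
tidy.tcm_scaling_fit <- function(x, ...) {
  tibble(term = c("intercept", "n_classes"),
         estimate = c(x$intercept, x$slope),
         p_value = c(NA_real_, x$p_value))
}

#' @rdname glance.tcm_metrics
#' @export
glance.tcm_scaling_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, p_value = x$p_value,
         threshold = x$threshold, n_points = sum(!x$crossings$censored),
         n_censored = x$n_censored,
         r_squared = summary(x$model)$r.squared)
}

#' Export a scaling grid to CSV
#'
#' @param grid A `tcm_scaling_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scaling_grid <- function(grid, path) {
  utils::write.csv(
    dplyr::select(as_tibble(grid), "per_class_n", "n_classes", "accuracy",
                  "seed"),
    path, row.names = FALSE)
  invisible(path)
}
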