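#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n
#' @importFrom purrr map map_chr map_int map_dbl map2 pmap imap
#' @importFrom stats rpois runif setNames lm quantile sd predict
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never clobber the
# session RNG stream.
with_rng_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stream label; keeps independent
# randomisation streams (splitting, embedding, classifier init, ...) decoupled
# while remaining a deterministic function of the user-facing seed.
child_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  key <- paste(c(seed, ...), collapse = "/")
  # polynomial rolling hash folded into the positive 32-bit integer range
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483563
  as.integer(h + 1)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

poisson_min1 <- function(n, mean) {
  # Poisson token counts with a floor of one occurrence per drawn unit
  if (mean <= 1) return(rep(1L, n))
  rpois(n, lambda = mean - 1) + 1L
}
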