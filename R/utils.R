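#' @importFrom rlang abort warn %||% .data
#' @importFrom generics tidy glance
#' @importFrom dplyr mutate filter select group_by ungroup summarise arrange
#'   bind_rows bind_cols left_join anti_join n across all_of pull distinct
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_int map_chr map_lgl map2 imap pmap keep
#' @importFrom stats rnorm runif rbinom quantile median plogis qlogis var
#'   predict as.formula binomial coef vcov sigma setNames complete.cases
#' @importFrom utils head modifyList
NULL

# Deterministic sub-seed derivation: mixes a parent seed with one or more
# integer indices, staying below 2^31 so the result is a valid R seed.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (i in idx) {
    s <- (s * 48271 + as.double(i) * 16807 + 12345) %% 2147483647
  }
  as.integer(s)
}

# Evaluate an expression under a local RNG state so callers' streams are
# untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

assert_that <- function(ok, msg, class = "sdgaudit_validation_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x) && x >= 0
}

# Canonical missing-value sentinel used throughout matching and synthesis.
MISSING_TOKEN <- "__MISSING__"
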