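#' Describe one variable of a simulated reference population
#'
#' A variable is either categorical (levels `L1 ... L<cardinality>`, sampled
#' with the given weights or a truncated Zipf law for long-tailed codes) or
#' numeric (a mixture of normals, optionally rounded).
#'
#' @param name Variable name.
#' @param kind `"categorical"` or `"numeric"`.
#' @param cardinality Number of levels (categorical; >= 2) or a bin-resolution
#'   hint (numeric, unused during generation).
#' @param weights Optional category weights, summing to 1, length
#'   `cardinality`. Ignored for numeric variables.
#' @param tail_shape Optional Zipf exponent for long-tailed categorical codes;
#'   when given (and `weights` is `NULL`) level `i` gets weight proportional
#'   to `i^-tail_shape`. Default exponent used by the population suite is 1.2.
#' @param mixture For numeric variables, a list with `means`, `sds`, `weights`
#'   describing a normal mixture. Defaults to a standard normal.
#' @param round_digits Optional rounding applied to numeric draws.
#' @return A `var_spec` list.
#' @export
var_spec <- function(name, kind = c("categorical", "numeric"),
                     cardinality = 2, weights = NULL, tail_shape = NULL,
                     mixture = NULL, round_digits = NULL) {
  kind <- match.arg(kind)
  assert_that(is.character(name) && length(name) == 1 && nzchar(name),
              "var_spec: `name` must be a nonempty string")
  assert_that(is_count(cardinality) && cardinality >= 2,
              sprintf("var_spec: `cardinality` for '%s' must be an integer >= 2", name))
  if (kind == "categorical") {
    if (is.null(weights)) {
      weights <- if (is.null(tail_shape)) {
        rep(1 / cardinality, cardinality)
      } else {
        w <- (seq_len(cardinality))^(-tail_shape)
        w / sum(w)
      }
    }
    assert_that(length(weights) == cardinality,
                sprintf("var_spec: `weights` for '%s' must have length %d", name, cardinality))
    assert_that(abs(sum(weights) - 1) < 1e-8,
                sprintf("var_spec: `weights` for '%s' must sum to 1", name))
  } else {
    mixture <- mixture %||% list(means = 0, sds = 1, weights = 1)
    assert_that(abs(sum(mixture$weights) - 1) < 1e-8,
                sprintf("var_spec: mixture `weights` for '%s' must sum to 1", name))
  }
  structure(list(name = name, kind = kind,
                 cardinality = as.integer(cardinality),
                 weights = weights, tail_shape = tail_shape,
                 mixture = mixture, round_digits = round_digits),
            class = "var_spec")
}

#' Describe the binary outcome of a simulated population
#'
#' The outcome is drawn from a logistic model on a subset of core variables.
#' Categorical signal variables enter the linear predictor through their
#' 0-based level index (so a binary variable is coded 0/1 and its coefficient
#' is the usual log odds ratio); numeric variables enter as-is.
#'
#' @param outcome_name Name of the outcome column.
#' @param signal_vars Names of core variables carrying outcome signal.
#' @param coefficients Per-variable log-odds effects, same length/order as
#'   `signal_vars`.
#' @param intercept Log-odds intercept.
#' @param prevalence_target Optional target prevalence; when given, the
#'   intercept is shifted at generation time so the expected prevalence
#'   matches it.
#' @return An `outcome_spec` list.
#' @export
outcome_spec <- function(outcome_name, signal_vars = character(),
                         coefficients = numeric(), intercept = 0,
                         prevalence_target = NULL) {
  assert_that(length(signal_vars) == length(coefficients),
              "outcome_spec: `signal_vars` and `coefficients` lengths differ")
  structure(list(outcome_name = outcome_name, signal_vars = signal_vars,
                 coefficients = coefficients, intercept = intercept,
                 prevalence_target = prevalence_target),
            class = "outcome_spec")
}

#' Specify a simulated reference population
#'
#' A reference population stands in for a large individual-level health
#' dataset: a table of mostly categorical variables split into a *core* set
#' (used by the downstream prediction task) and an *adjunct* pool (varied to
#' modulate complexity), with a binary outcome and MCAR missingness.
#'
#' @param name Population label.
#' @param n_records Number of records (>= 1).
#' @param core_vars List of [var_spec()] for core variables.
#' @param adjunct_pool List of [var_spec()] for the adjunct pool (size m).
#' @param outcome An [outcome_spec()].
#' @param missing_rate MCAR missingness fraction per variable, in [0, 1).
#'   Never applied to the outcome.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A `population_spec` list.
#' @export
population_spec <- function(name, n_records, core_vars, adjunct_pool = list(),
                            outcome, missing_rate = 0, seed = 1L) {
  assert_that(is_count(n_records) && n_records >= 1,
              "population_spec: `n_records` must be >= 1")
  assert_that(is.numeric(missing_rate) && missing_rate >= 0 && missing_rate < 1,
              "population_spec: `missing_rate` must be in [0, 1)")
  core_names <- map_chr(core_vars, "name")
  adj_names <- map_chr(adjunct_pool, "name")
  all_names <- c(core_names, adj_names, outcome$outcome_name)
  dup <- all_names[duplicated(all_names)]
  assert_that(length(dup) == 0,
              sprintf("population_spec: duplicate variable names: %s",
                      paste(unique(dup), collapse = ", ")))
  bad <- setdiff(outcome$signal_vars, core_names)
  assert_that(length(bad) == 0,
              sprintf("population_spec: signal_vars not in core_vars: %s",
                      paste(bad, collapse = ", ")))
  structure(list(name = name, n_records = as.integer(n_records),
                 core_vars = core_vars, adjunct_pool = adjunct_pool,
                 outcome = outcome, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "population_spec")
}

draw_variable <- function(vs, n) {
  if (vs$kind == "categorical") {
    lev <- sprintf("L%d", seq_len(vs$cardinality))
    factor(sample(lev, n, replace = TRUE, prob = vs$weights), levels = lev)
  } else {
    comp <- sample(seq_along(vs$mixture$weights), n, replace = TRUE,
                   prob = vs$mixture$weights)
    x <- rnorm(n, mean = vs$mixture$means[comp], sd = vs$mixture$sds[comp])
    if (!is.null(vs$round_digits)) x <- round(x, vs$round_digits)
    x
  }
}

encode_signal <- function(x) {
  if (is.factor(x) || is.character(x)) as.numeric(factor(x)) - 1 else as.numeric(x)
}

#' Generate a reference population from its spec
#'
#' Draws every core and adjunct variable from its marginal law, the outcome
#' from the logistic model on the signal variables (before missingness, so
#' the outcome is never degenerate through missing predictors), then injects
#' MCAR missingness into predictors at `spec$missing_rate`.
#'
#' @param spec A [population_spec()].
#' @return An `sdg_population`: a list with `data` (tibble with `record_id`,
#'   all variables, and the outcome), `spec`, and `roles` (core/adjunct
#'   variable names).
#' @export
generate_population <- function(spec) {
  assert_that(inherits(spec, "population_spec"),
              "generate_population: `spec` must be a population_spec")
  with_seed(spec$seed, {
    n <- spec$n_records
    vars <- c(spec$core_vars, spec$adjunct_pool)
    cols <- map(vars, draw_variable, n = n)
    names(cols) <- map_chr(vars, "name")
    dat <- as_tibble(cols)

    oc <- spec$outcome
    eta <- rep(oc$intercept, n)
    for (i in seq_along(oc$signal_vars)) {
      eta <- eta + oc$coefficients[i] * encode_signal(dat[[oc$signal_vars[i]]])
    }
    if (!is.null(oc$prevalence_target)) {
      shift <- stats::uniroot(
        function(d) mean(plogis(eta + d)) - oc$prevalence_target,
        lower = -20, upper = 20)$root
      eta <- eta + shift
    }
    y <- rbinom(n, 1, plogis(eta))
    dat[[oc$outcome_name]] <- factor(ifelse(y == 1, "yes", "no"),
                                     levels = c("no", "yes"))

    if (spec$missing_rate > 0) {
      for (nm in names(cols)) {
        miss <- runif(n) < spec$missing_rate
        dat[[nm]][miss] <- NA
      }
    }
    dat <- bind_cols(tibble(record_id = seq_len(n)), dat)
    structure(list(data = dat, spec = spec,
                   roles = list(core = map_chr(spec$core_vars, "name"),
                                adjunct = map_chr(spec$adjunct_pool, "name"),
                                outcome = oc$outcome_name)),
              class = "sdg_population")
  })
}

#' @export
print.sdg_population <- function(x, ...) {
  cat(sprintf("<sdg_population '%s': %d records, %d core + %d adjunct variables, outcome '%s'>\n",
              x$spec$name, nrow(x$data), length(x$roles$core),
              length(x$roles$adjunct), x$roles$outcome))
  invisible(x)
}

#' Build a suite of population specs spanning small to large adjunct pools
#'
#' Returns `k` specs whose pool sizes are log-spaced from about 5 (emulating
#' small registries) to 120+ adjunct variables; large pools include
#' long-tailed high-cardinality coded variables (Zipf exponent 1.2). At least
#' 80% of variables are categorical.
#'
#' @param k Number of specs (>= 1).
#' @param seed Integer seed.
#' @param n_records Records per population.
#' @param missing_rate MCAR missingness per variable.
#' @return A list of [population_spec()] objects.
#' @export
default_population_suite <- function(k, seed = 1L, n_records = 30000,
                                     missing_rate = 0.02) {
  assert_that(is_count(k) && k >= 1, "default_population_suite: `k` must be >= 1")
  pool_sizes <- round(exp(seq(log(5), log(120), length.out = max(k, 2))))[seq_len(k)]
  map(seq_len(k), function(i) {
    s <- derive_seed(seed, i)
    m <- pool_sizes[i]
    core <- list(
      var_spec("age_band", "categorical", 5,
               weights = c(0.1, 0.25, 0.3, 0.25, 0.1)),
      var_spec("sex", "categorical", 2, weights = c(0.52, 0.48)),
      var_spec("comorbidity", "categorical", 4,
               weights = c(0.5, 0.25, 0.15, 0.1)),
      var_spec("severity_score", "numeric",
               mixture = list(means = c(0, 2), sds = c(1, 1),
                              weights = c(0.7, 0.3)),
               round_digits = 2)
    )
    adjunct <- with_seed(derive_seed(s, 7L), {
      map(seq_len(m), function(j) {
        if (m >= 20 && j <= ceiling(m / 10)) {
          # long-tailed high-cardinality codes (diagnoses, medications)
          var_spec(sprintf("code_%02d", j), "categorical",
                   cardinality = sample(50:200, 1), tail_shape = 1.2)
        } else if (j %% 6 == 0) {
          var_spec(sprintf("lab_%02d", j), "numeric", round_digits = 1)
        } else {
          card <- sample(2:12, 1)
          w <- runif(card); w <- w / sum(w)
          var_spec(sprintf("adj_%02d", j), "categorical",
                   cardinality = card, weights = w)
        }
      })
    })
    oc <- outcome_spec("outcome",
                       signal_vars = c("age_band", "comorbidity", "severity_score"),
                       coefficients = c(0.45, 0.6, 0.8),
                       intercept = -1.5, prevalence_target = 0.25)
    population_spec(sprintf("pop%02d", i), n_records, core, adjunct, oc,
                    missing_rate = missing_rate, seed = s)
  })
}

#' AUROC of the true generating risk (Bayes score)
#'
#' Simulates a large sample from the population spec (no missingness) and
#' computes the AUROC of the true linear predictor against the drawn outcome.
#' This is the ceiling any classifier can approach on data from this spec.
#'
#' @param spec A [population_spec()].
#' @param n Monte Carlo sample size.
#' @param seed Integer seed.
#' @return AUROC of the true risk score, a number in [0, 1].
#' @export
bayes_auroc <- function(spec, n = 200000, seed = 1L) {
  with_seed(seed, {
    vars <- spec$core_vars
    cols <- map(vars, draw_variable, n = n)
    names(cols) <- map_chr(vars, "name")
    oc <- spec$outcome
    eta <- rep(oc$intercept, n)
    for (i in seq_along(oc$signal_vars)) {
      eta <- eta + oc$coefficients[i] * encode_signal(cols[[oc$signal_vars[i]]])
    }
    if (!is.null(oc$prevalence_target)) {
      shift <- stats::uniroot(
        function(d) mean(plogis(eta + d)) - oc$prevalence_target,
        lower = -20, upper = 20)$root
      eta <- eta + shift
    }
    y <- rbinom(n, 1, plogis(eta))
    auroc(eta, y)
  })
}
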