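# Shared fixture builders: small populations and classification tables built
# in code at test time.

toy_population_spec <- function(name = "toy", n = 4000, seed = 42,
                                missing_rate = 0, m_small = 2,
                                with_highcard = TRUE, with_numeric = TRUE) {
  adjunct <- c(
    purrr::map(seq_len(m_small), function(j) {
      var_spec(paste0("z", j), "categorical", 3)
    }),
    if (with_highcard) list(var_spec("hc", "categorical", 80, tail_shape = 1.2)),
    if (with_numeric) list(var_spec("num1", "numeric"))
  )
  population_spec(
    name, n,
    core_vars = list(
      var_spec("a", "categorical", 2, weights = c(0.6, 0.4)),
      var_spec("b", "categorical", 3, weights = c(0.5, 0.3, 0.2)),
      var_spec("x", "numeric")
    ),
    adjunct_pool = adjunct,
    outcome = outcome_spec("outcome", signal_vars = c("a", "x"),
                           coefficients = c(1.5, 1.0), intercept = -0.5),
    missing_rate = missing_rate, seed = seed
  )
}

# binary-classification table with a known logistic law
toy_task_data <- function(n, beta = c(2, -1), seed = 1, null = FALSE) {
  withr::with_seed(seed, {
    x1 <- stats::rnorm(n)
    f <- sample(c("a", "b", "c"), n, TRUE)
    eta <- if (null) rep(0, n) else beta[1] * x1 + beta[2] * (f == "b")
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    tibble::tibble(x1 = x1, f = f,
                   outcome = factor(ifelse(y == 1, "yes", "no"),
                                    levels = c("no", "yes")))
  })
}

toy_task <- function() task_spec("outcome", c("x1", "f"))

fast_grid <- function() tibble::tibble(eta = 0.1, leaves = 15, nrounds = 50)

# random categorical/numeric fixture pair for antijoin vs oracle checks
random_match_fixture <- function(seed, n_s = 60, n_p = 200, overlap = TRUE) {
  withr::with_seed(seed, {
    n_col_cat <- sample(1:3, 1)
    n_col_num <- sample(0:2, 1)
    alphabet <- sample(2:6, 1)
    make_tab <- function(n, shift = 0) {
      cols <- c(
        purrr::map(seq_len(n_col_cat), function(j) {
          v <- sample(LETTERS[seq_len(alphabet) + shift], n, TRUE)
          v[stats::runif(n) < 0.1] <- NA
          v
        }),
        purrr::map(seq_len(n_col_num), function(j) {
          round(stats::rnorm(n), 1)
        })
      )
      names(cols) <- c(paste0("c", seq_len(n_col_cat)),
                       if (n_col_num) paste0("n", seq_len(n_col_num)))
      tibble::as_tibble(cols)
    }
    p <- make_tab(n_p)
    s <- if (overlap) {
      dplyr::bind_rows(p[sample(n_p, ceiling(n_s / 2), TRUE), ],
                       make_tab(floor(n_s / 2)))
    } else {
      make_tab(n_s, shift = alphabet) # disjoint categorical alphabet
    }
    list(s = s, p = p, policy = binning_policy(p, n_bins = 5))
  })
}
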