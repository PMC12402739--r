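sim_hr_table <- function(seed, or = 1.10, n_groups = 12, n_per_group = 100,
                         trials = 200, re_sd = 0.8) {
  withr::with_seed(seed, {
    tidyr::expand_grid(population = sprintf("p%02d", seq_len(n_groups)),
                       i = seq_len(n_per_group)) |>
      dplyr::mutate(
        complexity = stats::runif(dplyr::n(), 2, 8),
        b0 = stats::rnorm(n_groups, 0, re_sd)[as.integer(factor(population))],
        eta = -3 + log(or) * complexity + b0,
        trials = trials,
        hallucinated = stats::rbinom(dplyr::n(), trials, stats::plogis(eta)),
        mean_hr = hallucinated / trials,
        generator = "g")
  })
}

sim_tstr_table <- function(seed, slope = -0.0002, n_groups = 3,
                           n_per_group = 600, noise_sd = 0.005) {
  withr::with_seed(seed, {
    tidyr::expand_grid(population = sprintf("p%02d", seq_len(n_groups)),
                       i = seq_len(n_per_group)) |>
      dplyr::mutate(
        mean_hr = stats::runif(dplyr::n()),
        b0 = stats::rnorm(n_groups, 0.75, 0.05)[as.integer(factor(population))],
        tstr_gbm = b0 + slope * (100 * mean_hr) +
          stats::rnorm(dplyr::n(), 0, noise_sd),
        generator = "g")
  })
}

test_that("the spread filter keeps populations with P90-P10 >= 0.25", {
  flat <- tibble::tibble(generator = "g", population = "a",
                         mean_hr = rep(0.99, 20))
  wide <- tibble::tibble(generator = "g", population = "b",
                         mean_hr = withr::with_seed(1, runif(100, 0.3, 0.8)))
  both <- dplyr::bind_rows(flat, wide)
  out <- hr_spread_filter(both)
  expect_setequal(unique(out$table$population), "b")
  expect_equal(nrow(out$retained), 1)
  # uniform[0.3, 0.8] has P90-P10 close to 0.4
  expect_gt(out$retained$spread, 0.25)
  expect_warning(hr_spread_filter(flat), "no population meets")
})

test_that("filter retention arithmetic reproduces a known fraction", {
  expect_equal(round(100 * 8766 / 44478, 2), 19.71)
})

test_that("the GLMM recovers a generating odds ratio with its CI", {
  tab <- sim_hr_table(101)
  est <- suppressWarnings(fit_glmm_hr_on_complexity(tab))$g
  expect_equal(est$effect_scale, "odds-ratio")
  expect_true(est$ci_low <= 1.10 && 1.10 <= est$ci_high)
  expect_lt(est$p_value, 0.05)
  expect_lte(est$r2_marginal, est$r2_conditional)

  single <- dplyr::filter(tab, population == "p01")
  expect_error(fit_glmm_hr_on_complexity(single), "random effect unidentifiable")
  expect_error(fit_glmm_hr_on_complexity(tab[c(1:4, 101:105), ]),
               ">= 10 observations")
})

test_that("the LMM recovers a generating slope and falls back to OLS", {
  tab <- sim_tstr_table(102)
  est <- suppressWarnings(fit_lmm_tstr_on_hr(tab, "gbm"))$g
  expect_equal(est$effect_scale, "slope")
  expect_true(est$ci_low <= -0.0002 && -0.0002 <= est$ci_high)
  expect_equal(est$method, "lmm-reml-wald")

  one_pop <- dplyr::filter(tab, population == "p01")
  est1 <- fit_lmm_tstr_on_hr(one_pop, "gbm")$g
  expect_equal(est1$method, "ols-single-population")
  expect_equal(est1$r2_marginal, est1$r2_conditional)
  expect_error(fit_lmm_tstr_on_hr(tab[1:2, ], "gbm"), ">= 3 observations")

  # extreme-case arithmetic: a slope per percentage point over the full
  # 0-100 range implies an AUROC change of |slope| * 100
  expect_equal(abs(est$estimate) * 100, abs(est$estimate * 100))
  expect_equal(abs(-0.0002) * 100, 0.02)
})

test_that("Nakagawa R2 recovers a known variance decomposition", {
  # fixed 0.25, random 0.70, residual 0.05 of total variance
  # 200 groups so the random-intercept variance (the noisiest component,
  # chi-square with df ~ groups) is estimated tightly enough for a plug-in
  # comparison
  dat <- withr::with_seed(103, {
    g <- rep(sprintf("p%03d", 1:200), each = 50)
    x <- rnorm(10000, 0, 1)         # var(beta x) = 0.25 with beta = 0.5
    b0 <- rnorm(200, 0, sqrt(0.70))[as.integer(factor(g))]
    tibble::tibble(population = g, hr_pct = x,
                   .y = 0.5 * x + b0 + rnorm(10000, 0, sqrt(0.05)))
  })
  fit <- lme4::lmer(.y ~ hr_pct + (1 | population), data = dat, REML = TRUE)
  r2 <- nakagawa_r2(fit)
  expect_equal(unname(r2["r2_marginal"]), 0.25, tolerance = 0.1)
  expect_equal(unname(r2["r2_conditional"]), 0.95, tolerance = 0.02)

  # zero fixed effect
  dat0 <- dplyr::mutate(dat, .y = b0 + rnorm(10000, 0, sqrt(0.05)))
  fit0 <- lme4::lmer(.y ~ hr_pct + (1 | population), data = dat0, REML = TRUE)
  expect_lt(nakagawa_r2(fit0)["r2_marginal"], 0.01)

  # OLS fallback: marginal equals conditional
  lmfit <- lm(.y ~ hr_pct, data = dat)
  r2lm <- nakagawa_r2(lmfit)
  expect_equal(unname(r2lm["r2_marginal"]), unname(r2lm["r2_conditional"]))
})

test_that("tidy and glance expose estimates broom-style", {
  est <- suppressWarnings(fit_glmm_hr_on_complexity(sim_hr_table(104)))$g
  td <- generics::tidy(est)
  gl <- generics::glance(est)
  expect_named(td, c("generator", "term", "estimate", "conf.low",
                     "conf.high", "p.value"))
  expect_named(gl, c("r2.marginal", "r2.conditional", "nobs", "method"))
  expect_true(td$conf.low <= td$estimate && td$estimate <= td$conf.high)
})

test_that("subset sensitivity reproduces the full fit at fraction 1", {
  tab <- dplyr::mutate(sim_hr_table(105, n_per_group = 60),
                       tstr_gbm = 0.75 - 0.0002 * 100 * mean_hr +
                         stats::rnorm(dplyr::n(), 0, 0.005))
  sens <- suppressWarnings(subset_sensitivity(tab, fractions = 0.5,
                                              learner = "gbm", seed = 1,
                                              min_spread = 0.1))
  full_glmm <- suppressWarnings(fit_glmm_hr_on_complexity(tab))$g
  row_full <- dplyr::filter(sens, fraction == 1, model == "hr~complexity")
  expect_equal(row_full$estimate, full_glmm$estimate, tolerance = 1e-10)
  # the half-sample estimate falls inside the full fit's CI
  row_half <- dplyr::filter(sens, fraction == 0.5, model == "hr~complexity")
  expect_true(row_half$estimate >= full_glmm$ci_low - 0.02 &&
                row_half$estimate <= full_glmm$ci_high + 0.02)
})
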