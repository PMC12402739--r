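#' Keep populations with sufficient hallucination-rate spread
#'
#' Per generator family, retains the populations whose HR spread across
#' variants — the gap between the 90th and 10th percentiles (linear
#' interpolation) — is at least `min_spread`. Effect estimation of HR on
#' TSTR needs this spread: a population whose variants all hallucinate at
#' the same rate carries no information about the slope.
#'
#' @param table Observation table with one row per (population, plan,
#'   generator): columns `population`, `generator`, `mean_hr` (in [0, 1]).
#' @param low_pct,high_pct Percentiles defining the spread (default 10/90).
#' @param min_spread Minimum required spread on the HR scale (default 0.25).
#' @return A list with `table` (retained rows) and `retained` (tibble of
#'   generator/population kept, with their spreads). Empty retention returns
#'   an empty table with a warning.
#' @export
hr_spread_filter <- function(table, low_pct = 10, high_pct = 90,
                             min_spread = 0.25) {
  spreads <- table |>
    group_by(.data$generator, .data$population) |>
    summarise(spread = quantile(.data$mean_hr, high_pct / 100, type = 7) -
                quantile(.data$mean_hr, low_pct / 100, type = 7),
              .groups = "drop")
  retained <- filter(spreads, .data$spread >= min_spread)
  out <- dplyr::semi_join(table, retained, by = c("generator", "population"))
  if (nrow(out) == 0) {
    warn("hr_spread_filter: no population meets the spread requirement")
  }
  list(table = out, retained = retained)
}

wald_ci <- function(est, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(est - z * se, est + z * se)
}

effect_estimate <- function(scale, est, se, p, r2m, r2c, n_obs, method,
                            generator = NA_character_, transform = identity) {
  ci <- wald_ci(est, se)
  structure(list(effect_scale = scale,
                 estimate = transform(est), ci_low = transform(ci[1]),
                 ci_high = transform(ci[2]), p_value = p,
                 r2_marginal = r2m, r2_conditional = r2c,
                 n_obs = n_obs, method = method, generator = generator),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate [%s] %s = %.4g (95%% CI %.4g to %.4g), p = %.3g, R2m = %.3f, R2c = %.3f, n = %d>\n",
              x$generator, x$effect_scale, x$estimate, x$ci_low, x$ci_high,
              x$p_value, x$r2_marginal, x$r2_conditional, x$n_obs))
  invisible(x)
}

#' @export
generics::tidy

#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.effect_estimate <- function(x, ...) {
  tibble(generator = x$generator, term = x$effect_scale,
         estimate = x$estimate, conf.low = x$ci_low, conf.high = x$ci_high,
         p.value = x$p_value)
}

#' @exportS3Method generics::glance
glance.effect_estimate <- function(x, ...) {
  tibble(r2.marginal = x$r2_marginal, r2.conditional = x$r2_conditional,
         nobs = x$n_obs, method = x$method)
}

#' Nakagawa marginal and conditional R-squared of a random-intercept model
#'
#' Marginal R2 is the variance of the fixed-effect predictor over the total
#' (fixed + random-intercept + residual) variance; conditional R2 adds the
#' random-intercept variance to the numerator. For binomial-logit models the
#' residual variance on the latent scale is pi^2/3 (theoretical method).
#'
#' @param fit A fitted `lme4` model (`lmerMod` or binomial `glmerMod`), or an
#'   `lm` fallback (for which both values equal the ordinary R2).
#' @return Named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
nakagawa_r2 <- function(fit) {
  if (inherits(fit, "lm") && !inherits(fit, c("lmerMod", "glmerMod", "merMod"))) {
    r2 <- summary(fit)$r.squared
    return(c(r2_marginal = r2, r2_conditional = r2))
  }
  assert_that(inherits(fit, "merMod"), "nakagawa_r2: unsupported model type")
  var_fixed <- var(as.numeric(lme4::getME(fit, "X") %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)
  var_random <- sum(map_dbl(vc, function(m) m[1, 1]))
  var_resid <- if (inherits(fit, "glmerMod")) {
    fam <- stats::family(fit)
    assert_that(fam$family == "binomial" && fam$link == "logit",
                "nakagawa_r2: only binomial-logit GLMMs are supported")
    pi^2 / 3
  } else {
    sigma(fit)^2
  }
  tot <- var_fixed + var_random + var_resid
  c(r2_marginal = var_fixed / tot,
    r2_conditional = (var_fixed + var_random) / tot)
}

#' Effect of complexity on the hallucination rate (binomial GLMM)
#'
#' Fits, per generator family, a binomial-logit random-intercept model with
#' the population as the random effect and complexity as the fixed effect.
#' The response is the aggregated hallucinated count out of `k x |S|` trials
#' per trained generator, which handles HR = 1 observations without boundary
#' corrections. Reports the odds ratio per complexity unit with Wald 95% CI.
#'
#' @param table Observation table with columns `generator`, `population`,
#'   `complexity`, `hallucinated` (total hallucinated records), `trials`
#'   (k x synthetic size).
#' @return A named list of `effect_estimate`, one per generator family.
#' @export
fit_glmm_hr_on_complexity <- function(table) {
  split(table, table$generator) |>
    imap(function(df, gen) {
      assert_that(dplyr::n_distinct(df$population) >= 2,
                  sprintf("fit_glmm_hr_on_complexity [%s]: need >= 2 populations (random effect unidentifiable with 1)",
                          gen))
      assert_that(nrow(df) >= 10,
                  sprintf("fit_glmm_hr_on_complexity [%s]: need >= 10 observations", gen))
      fit <- lme4::glmer(
        cbind(hallucinated, trials - hallucinated) ~ complexity + (1 | population),
        data = df, family = binomial("logit"))
      conv <- fit@optinfo$conv$lme4
      if (!is.null(conv$messages)) {
        warn(sprintf("fit_glmm_hr_on_complexity [%s]: %s (max |gradient| %.3g); consider looser tolerance or fewer strata",
                     gen, paste(conv$messages, collapse = "; "),
                     max(abs(fit@optinfo$derivs$gradient))))
      }
      sm <- summary(fit)$coefficients
      r2 <- nakagawa_r2(fit)
      effect_estimate("odds-ratio", sm["complexity", "Estimate"],
                      sm["complexity", "Std. Error"],
                      sm["complexity", "Pr(>|z|)"],
                      r2[["r2_marginal"]], r2[["r2_conditional"]],
                      nrow(df), "glmm-binomial-logit-laplace-wald",
                      generator = gen, transform = exp)
    })
}

#' Effect of the hallucination rate on TSTR (linear mixed model)
#'
#' Fits, per generator family, a linear random-intercept model of TSTR AUROC
#' on the HR expressed in percentage points (0-100), with the population as
#' the random effect, by REML. The slope is the AUROC change per percentage
#' point of HR. When only one population remains after filtering, an
#' ordinary least-squares fit is used and the conditional R2 equals the
#' marginal R2.
#'
#' @param table Filtered observation table (see [hr_spread_filter()]) with
#'   columns `generator`, `population`, `mean_hr` (in [0, 1]) and a TSTR
#'   column per learner named `tstr_<learner>`.
#' @param learner Learner whose TSTR column to model (`"gbm"` or `"mlp"`).
#' @return A named list of `effect_estimate`, one per generator family.
#' @export
fit_lmm_tstr_on_hr <- function(table, learner = "gbm") {
  ycol <- paste0("tstr_", learner)
  assert_that(ycol %in% names(table),
              sprintf("fit_lmm_tstr_on_hr: no column '%s'", ycol))
  split(table, table$generator) |>
    imap(function(df, gen) {
      df <- filter(df, !is.na(.data[[ycol]]))
      assert_that(nrow(df) >= 3,
                  sprintf("fit_lmm_tstr_on_hr [%s]: need >= 3 observations", gen))
      df$hr_pct <- 100 * df$mean_hr
      df$.y <- df[[ycol]]
      if (dplyr::n_distinct(df$population) < 2) {
        fit <- stats::lm(.y ~ hr_pct, data = df)
        sm <- summary(fit)$coefficients
        r2 <- nakagawa_r2(fit)
        effect_estimate("slope", sm["hr_pct", "Estimate"],
                        sm["hr_pct", "Std. Error"],
                        sm["hr_pct", "Pr(>|t|)"],
                        r2[["r2_marginal"]], r2[["r2_conditional"]],
                        nrow(df), "ols-single-population",
                        generator = gen)
      } else {
        fit <- lme4::lmer(.y ~ hr_pct + (1 | population), data = df, REML = TRUE)
        sm <- summary(fit)$coefficients
        est <- sm["hr_pct", "Estimate"]
        se <- sm["hr_pct", "Std. Error"]
        p <- 2 * stats::pnorm(-abs(est / se))
        r2 <- nakagawa_r2(fit)
        effect_estimate("slope", est, se, p,
                        r2[["r2_marginal"]], r2[["r2_conditional"]],
                        nrow(df), "lmm-reml-wald", generator = gen)
      }
    })
}

#' Sensitivity of effect estimates to the number of population variants
#'
#' Refits the complexity-to-HR GLMM and the HR-to-TSTR LMM on random subsets
#' of the variants (per population), reporting the estimates side by side
#' with the full-data fit. A generator/fraction cell whose subset is too
#' small for the fit is marked missing.
#'
#' @param table Full observation table (see [fit_glmm_hr_on_complexity()]
#'   and [fit_lmm_tstr_on_hr()] for required columns).
#' @param fractions Subset fractions (default 0.5 and 0.25).
#' @param learner Learner for the TSTR model.
#' @param seed Integer seed for the subset draws.
#' @param min_spread Spread threshold passed to [hr_spread_filter()].
#' @return A tibble: one row per (fraction, generator, model) with estimate,
#'   CI, p, R2s, n_obs; fraction 1 is the full fit.
#' @export
subset_sensitivity <- function(table, fractions = c(0.5, 0.25), learner = "gbm",
                               seed = 1L, min_spread = 0.25) {
  fit_one <- function(fun, df, frac, label) {
    # per-generator so a sparse cell is marked missing, not fatal
    gens <- unique(df$generator)
    out <- map(setNames(gens, gens), function(g) {
      tryCatch(fun(filter(df, .data$generator == g))[[1]],
               error = function(e) {
                 warn(sprintf("subset_sensitivity (fraction %.2f, %s, %s): sparse coverage in the random effect (%s)",
                              frac, label, g, conditionMessage(e)))
                 NULL
               })
    })
    purrr::compact(out)
  }
  fit_both <- function(df, frac) {
    glmm <- fit_one(fit_glmm_hr_on_complexity, df, frac, "hr~complexity")
    filt <- suppressWarnings(hr_spread_filter(df, min_spread = min_spread))
    lmm <- fit_one(function(d) fit_lmm_tstr_on_hr(d, learner = learner),
                   filt$table, frac, "tstr~hr")
    bind_rows(c(
      unname(map(glmm, function(e) mutate(bind_cols(tidy(e), glance(e)),
                                          model = "hr~complexity"))),
      unname(map(lmm, function(e) mutate(bind_cols(tidy(e), glance(e)),
                                         model = "tstr~hr")))
    )) |> mutate(fraction = frac)
  }
  full <- fit_both(table, 1)
  subs <- map(fractions, function(fr) {
    sub <- with_seed(derive_seed(seed, round(fr * 100)), {
      table |>
        group_by(.data$population) |>
        dplyr::slice_sample(prop = fr) |>
        ungroup()
    })
    fit_both(sub, fr)
  })
  bind_rows(full, subs)
}
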