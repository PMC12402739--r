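#' Design-count arithmetic for a study layout
#'
#' Exact bookkeeping of the experiment size: with `n_variants_total`
#' population variants, `n_families` generator families and `k` synthetic
#' replicates per trained generator, the number of trained generators is
#' `variants x families`, and each learner is fitted once per synthetic
#' replicate (TSTR) plus once per variant (TRTR).
#'
#' @param n_variants_total Total population variants across populations.
#' @param n_families Number of generator families.
#' @param k Synthetic replicates per trained generator.
#' @param n_populations Number of reference populations (bookkeeping only).
#' @return A `design_counts` list: `n_populations`, `n_variants_total`,
#'   `n_trained_generators`, `n_replicates_total`,
#'   `n_classifier_fits_per_learner`.
#' @export
design_counts <- function(n_variants_total, n_families, k,
                          n_populations = NA_integer_) {
  assert_that(is_count(n_variants_total) && n_variants_total >= 1,
              "design_counts: `n_variants_total` must be a positive integer")
  assert_that(is_count(n_families) && n_families >= 1,
              "design_counts: `n_families` must be a positive integer")
  assert_that(is_count(k) && k >= 1, "design_counts: `k` must be a positive integer")
  gens <- n_variants_total * n_families
  structure(list(
    n_populations = n_populations,
    n_variants_total = n_variants_total,
    n_trained_generators = gens,
    n_replicates_total = gens * k,
    n_classifier_fits_per_learner = gens * k + n_variants_total
  ), class = "design_counts")
}

#' @export
print.design_counts <- function(x, ...) {
  cat(sprintf("<design_counts: %d variants x %d families -> %d trained generators, %d replicates, %d classifier fits per learner>\n",
              x$n_variants_total, x$n_trained_generators / x$n_variants_total,
              x$n_trained_generators, x$n_replicates_total,
              x$n_classifier_fits_per_learner))
  invisible(x)
}

#' Configure an end-to-end experiment
#'
#' @param population_specs List of [population_spec()] objects.
#' @param n_variants Variants sampled per population.
#' @param families Generator families (built-in or `plugin:<name>`).
#' @param n_train,n_holdout Fixed disjoint split sizes per population.
#' @param n_per_replicate Rows per synthetic replicate (default `n_train`).
#' @param k_replicates Synthetic replicates per trained generator.
#' @param learners Downstream learners to evaluate (`"gbm"`, `"mlp"`, or
#'   empty to skip the utility stage).
#' @param n_bins Bins per numeric variable for matching and synthesis.
#' @param min_spread HR-spread threshold for the effect-model filter.
#' @param gbm_grid Hyperparameter grid for the GBM (default
#'   [default_gbm_grid()]; pass a single row for speed in small runs).
#' @param cv_folds CV folds for GBM hyperparameter selection.
#' @param seed Master seed; every stage derives named sub-seeds from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(population_specs, n_variants = 20,
                              families = c("sequential_trees", "chow_liu_bn"),
                              n_train = 10000, n_holdout = 10000,
                              n_per_replicate = NULL, k_replicates = 10,
                              learners = c("gbm", "mlp"), n_bins = 10,
                              min_spread = 0.25, gbm_grid = NULL,
                              cv_folds = 5, seed = 1L) {
  assert_that(length(population_specs) >= 1 &&
                all(map_lgl(population_specs, inherits, "population_spec")),
              "experiment_config: `population_specs` must be population_spec objects")
  assert_that(all(c(n_variants, n_train, n_holdout, k_replicates, n_bins) > 0),
              "experiment_config: all counts must be positive")
  builtin <- c("sequential_trees", "st", "chow_liu_bn", "bn")
  unknown <- families[!(families %in% builtin | startsWith(families, "plugin:"))]
  assert_that(length(unknown) == 0,
              sprintf("experiment_config: unknown families: %s",
                      paste(unknown, collapse = ", ")))
  structure(list(population_specs = population_specs, n_variants = n_variants,
                 families = families, n_train = n_train, n_holdout = n_holdout,
                 n_per_replicate = n_per_replicate %||% n_train,
                 k_replicates = k_replicates, learners = learners,
                 n_bins = n_bins, min_spread = min_spread,
                 gbm_grid = gbm_grid, cv_folds = cv_folds,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the full hallucination-audit experiment
#'
#' Executes the workflow end to end: simulate populations, sample variant
#' plans and the fixed train/holdout split, build variants, fit and sample
#' each generator family, audit hallucination rates, measure TSTR/TRTR per
#' learner, and fit the two effect models. Every stage derives its seed from
#' the master seed and the (population, plan, family, replicate) indices, so
#' a re-run with the same config reproduces the bundle exactly and any stage
#' can be recomputed in isolation.
#'
#' @param config An [experiment_config()].
#' @param verbose Emit per-stage progress messages.
#' @return An `sdg_experiment`: list with `results` (tidy tibble, one row per
#'   population x plan x generator), `trtr` (one row per population x plan x
#'   learner), `effects` (GLMM and per-learner LMM estimates), `design`
#'   (design counts), `config`.
#' @export
run_experiment <- function(config, verbose = interactive()) {
  assert_that(inherits(config, "experiment_config"),
              "run_experiment: `config` must be an experiment_config")
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed

  rows <- list()
  trtr_rows <- list()
  for (pi in seq_along(config$population_specs)) {
    spec <- config$population_specs[[pi]]
    say("[%d/%d] simulating population '%s' (%d records)",
        pi, length(config$population_specs), spec$name, spec$n_records)
    pop <- generate_population(spec)
    plans <- sample_variant_plans(pop, config$n_variants,
                                  seed = derive_seed(seed, pi, 1L))
    split <- make_split(pop, config$n_train, config$n_holdout,
                        seed = derive_seed(seed, pi, 2L))
    task <- task_spec(pop$roles$outcome,
                      setdiff(pop$roles$core, pop$roles$outcome))

    for (li in seq_len(nrow(plans))) {
      plan <- plans[li, ]
      variant <- build_variant(pop, plan)
      vdata <- drop_record_id(variant$data)
      policy <- binning_policy(vdata, n_bins = config$n_bins)
      cx <- complexity(vdata, policy = policy)
      train <- filter(variant$data, .data$record_id %in% split$train_ids)
      holdout <- filter(variant$data, .data$record_id %in% split$holdout_ids)
      train_tbl <- drop_record_id(train)

      for (lrn in config$learners) {
        tr <- evaluate_trtr(train, holdout, task, learner = lrn,
                            seed = derive_seed(seed, pi, li, 900L),
                            gbm_grid = config$gbm_grid,
                            cv_folds = config$cv_folds)
        trtr_rows[[length(trtr_rows) + 1L]] <- tibble(
          population = spec$name, plan_id = plan$plan_id, learner = lrn,
          trtr = tr$trtr)
      }

      for (fi in seq_along(config$families)) {
        fam <- config$families[fi]
        gseed <- derive_seed(seed, pi, li, fi)
        gen <- fit_generator(train_tbl, fam, roles = variant$roles, seed = gseed)
        reps <- sample_replicates(gen, config$n_per_replicate,
                                  k = config$k_replicates, seed = gseed)
        hr <- hallucination_rate(reps, variant$data, policy)
        row <- tibble(
          population = spec$name, plan_id = plan$plan_id, v = plan$v,
          generator = gen$family, complexity = cx$complexity,
          mean_hr = hr$mean_rate,
          hallucinated = sum(hr$per_replicate_count),
          trials = as.double(hr$k) * hr$n_synthetic,
          per_replicate_hr = list(hr$per_replicate_rate),
          generator_seed = gseed)
        for (lrn in config$learners) {
          ut <- evaluate_tstr(reps, holdout, task, learner = lrn,
                              seed = derive_seed(gseed, 500L),
                              gbm_grid = config$gbm_grid,
                              cv_folds = config$cv_folds)
          row[[paste0("tstr_", lrn)]] <- ut$tstr_mean
          row[[paste0("tstr_", lrn, "_reps")]] <- list(ut$tstr_per_replicate)
        }
        rows[[length(rows) + 1L]] <- row
      }
      say("  variant %s (v=%d, complexity %.2f) done", plan$plan_id,
          plan$v, cx$complexity)
    }
  }
  results <- bind_rows(rows)
  trtr <- bind_rows(trtr_rows)
  if (nrow(trtr)) {
    wide <- tidyr::pivot_wider(trtr, names_from = "learner",
                               values_from = "trtr", names_prefix = "trtr_")
    results <- left_join(results, wide, by = c("population", "plan_id"))
  }

  say("fitting effect models")
  effects <- list(
    hr_on_complexity = tryCatch(fit_glmm_hr_on_complexity(results),
                                error = function(e) {
                                  warn(conditionMessage(e)); NULL
                                }))
  filt <- suppressWarnings(hr_spread_filter(results,
                                            min_spread = config$min_spread))
  effects$hr_filter <- filt$retained
  for (lrn in config$learners) {
    effects[[paste0("tstr_on_hr_", lrn)]] <-
      tryCatch(fit_lmm_tstr_on_hr(filt$table, learner = lrn),
               error = function(e) {
                 warn(conditionMessage(e)); NULL
               })
  }

  structure(list(
    results = results, trtr = trtr, effects = effects,
    design = design_counts(nrow(results) / length(config$families),
                           length(config$families), config$k_replicates,
                           n_populations = length(config$population_specs)),
    config = config
  ), class = "sdg_experiment")
}

#' @export
print.sdg_experiment <- function(x, ...) {
  cat(sprintf("<sdg_experiment: %d populations, %d variant x generator results, learners: %s>\n",
              x$design$n_populations, nrow(x$results),
              paste(x$config$learners, collapse = ", ")))
  invisible(x)
}
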