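test_that("rank-based AUROC matches an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(2, {
    for (i in 1:5) {
      y <- rbinom(200, 1, 0.4)
      s <- rnorm(200) + y
      s[sample(200, 20)] <- round(s[sample(200, 20)]) # force ties
      expect_equal(auroc(s, y),
                   as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
                   tolerance = 1e-12)
    }
  })
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(c(1, 2, 3, 4), c(1, 1, 0, 0)), 0)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("both learners separate separable data and stay at 1/2 on null data", {
  sep <- toy_task_data(2000, beta = c(8, 0), seed = 3)
  tr <- sep[1:1000, ]; ho <- sep[1001:2000, ]
  g <- train_gbm(tr, toy_task(), grid = fast_grid(), seed = 1)
  expect_gt(auroc(predict(g, ho), ho$outcome), 0.95)
  m <- train_mlp(tr, toy_task(), seed = 1)
  expect_gt(auroc(predict(m, ho), ho$outcome), 0.95)

  null <- toy_task_data(20000, seed = 4, null = TRUE)
  trn <- null[1:10000, ]; hon <- null[10001:20000, ]
  gn <- train_gbm(trn, toy_task(), grid = fast_grid(), seed = 1)
  expect_lt(abs(auroc(predict(gn, hon), hon$outcome) - 0.5), 0.02)
  mn <- train_mlp(trn, toy_task(), seed = 1)
  expect_lt(abs(auroc(predict(mn, hon), hon$outcome) - 0.5), 0.02)
})

test_that("GBM hyperparameter selection is CV-based and deterministic", {
  d <- toy_task_data(1200, seed = 5)
  grid <- tibble::tibble(eta = c(0.1, 0.1), leaves = c(15, 31),
                         nrounds = c(50, 50))
  g1 <- train_gbm(d, toy_task(), cv_folds = 3, grid = grid, seed = 9)
  g2 <- train_gbm(d, toy_task(), cv_folds = 3, grid = grid, seed = 9)
  expect_identical(g1$best_params, g2$best_params)
  expect_true(g1$best_params$leaves %in% grid$leaves)
})

test_that("single-class training outcomes are refused with the level named", {
  d <- toy_task_data(100, seed = 6)
  d$outcome <- factor("yes", levels = c("no", "yes"))
  expect_error(train_gbm(d, toy_task(), grid = fast_grid()), "only level 'yes'")
  expect_error(train_mlp(d, toy_task()), "only level 'yes'")
})

test_that("the MLP approaches the Bayes AUROC on a logistic ground truth", {
  spec <- population_spec(
    "bayes", 20000,
    core_vars = list(var_spec("a", "categorical", 2, weights = c(0.5, 0.5)),
                     var_spec("x", "numeric")),
    outcome = outcome_spec("outcome", c("a", "x"), c(1.0, 1.2),
                           intercept = -0.5),
    seed = 23)
  pop <- generate_population(spec)
  bayes <- bayes_auroc(spec, n = 200000, seed = 1)
  sp <- make_split(pop, 10000, 10000, seed = 2)
  tr <- dplyr::filter(pop$data, record_id %in% sp$train_ids)
  ho <- dplyr::filter(pop$data, record_id %in% sp$holdout_ids)
  task <- task_spec("outcome", c("a", "x"))
  m <- train_mlp(dplyr::select(tr, -record_id), task, seed = 3)
  expect_lt(abs(auroc(predict(m, ho), ho$outcome) - bayes), 0.03)
})

test_that("TSTR degenerates to TRTR when replicates equal the real data", {
  d <- toy_task_data(8000, seed = 7)
  tr <- d[1:4000, ]; ho <- d[4001:8000, ]
  trtr <- evaluate_trtr(tr, ho, toy_task(), learner = "gbm", seed = 1,
                        gbm_grid = fast_grid())
  ut <- evaluate_tstr(list(tr, tr), ho, toy_task(), learner = "gbm", seed = 1,
                      gbm_grid = fast_grid())
  expect_lt(abs(ut$tstr_mean - trtr$trtr), 0.01)

  # permuted outcome destroys the signal
  perm <- tr
  perm$outcome <- withr::with_seed(8, sample(perm$outcome))
  utp <- evaluate_tstr(list(perm), ho, toy_task(), learner = "gbm", seed = 1,
                       gbm_grid = fast_grid())
  expect_lt(abs(utp$tstr_mean - 0.5), 0.05)
})

test_that("degenerate replicates are excluded from the TSTR mean with a warning", {
  d <- toy_task_data(1000, seed = 9)
  tr <- d[1:500, ]; ho <- d[501:1000, ]
  bad <- tr
  bad$outcome <- factor("no", levels = c("no", "yes"))
  expect_warning(
    ut <- evaluate_tstr(list(tr, bad), ho, toy_task(), learner = "gbm",
                        seed = 1, gbm_grid = fast_grid()),
    "recorded as missing")
  expect_true(is.na(ut$tstr_per_replicate[2]))
  expect_false(is.na(ut$tstr_mean))
})

test_that("holdout leakage into TRTR training is caught", {
  pop <- generate_population(toy_population_spec(n = 1000, seed = 24))
  sp <- make_split(pop, 400, 400, seed = 1)
  tr <- dplyr::filter(pop$data, record_id %in% sp$train_ids)
  ho <- dplyr::filter(pop$data, record_id %in% sp$holdout_ids)
  leaky <- dplyr::bind_rows(tr, ho[1:5, ])
  task <- task_spec("outcome", c("a", "b", "x"))
  expect_error(evaluate_trtr(leaky, ho, task, gbm_grid = fast_grid()),
               "leak")
})

test_that("TRTR varies little across re-splits of a stable population", {
  spec <- toy_population_spec(n = 24000, seed = 25, with_highcard = FALSE,
                              with_numeric = FALSE, m_small = 1)
  pop <- generate_population(spec)
  sp <- make_split(pop, 10000, 10000, seed = 1)
  variant <- build_variant(pop, character(0))
  tr <- dplyr::filter(variant$data, record_id %in% sp$train_ids)
  ho <- dplyr::filter(variant$data, record_id %in% sp$holdout_ids)
  task <- task_spec("outcome", c("a", "b", "x"))
  res <- evaluate_trtr(tr, ho, task, learner = "gbm", seed = 2,
                       extra_splits = 10, population = pop,
                       variant_columns = variant$columns,
                       gbm_grid = fast_grid())
  spread <- max(res$split_aurocs) - min(res$split_aurocs)
  expect_lte(spread, 0.02)
  expect_lt(abs(res$trtr - median(res$split_aurocs)), 0.02)
})
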