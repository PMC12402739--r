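#' Define the downstream binary prediction task
#'
#' @param outcome_name Outcome column name.
#' @param feature_names Predictor columns (core variables minus the outcome).
#' @param positive_level Outcome level treated as the positive class.
#' @return A `task_spec` list.
#' @export
task_spec <- function(outcome_name, feature_names, positive_level = "yes") {
  assert_that(!outcome_name %in% feature_names,
              "task_spec: outcome cannot be a feature")
  structure(list(outcome_name = outcome_name, feature_names = feature_names,
                 positive_level = positive_level),
            class = "task_spec")
}

#' Rank-based AUROC (Mann-Whitney statistic)
#'
#' AUROC computed from average ranks, so ties contribute 1/2; identical to
#' the probability that a random positive scores above a random negative.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels 0/1 vector, logical, or factor/character compared against
#'   `positive_level`.
#' @param positive_level Positive label for factor/character input.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels, positive_level = "yes") {
  y <- if (is.numeric(labels) || is.logical(labels)) {
    as.integer(labels)
  } else {
    as.integer(as.character(labels) == positive_level)
  }
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  n1 <- as.double(sum(y == 1)); n0 <- as.double(sum(y == 0))
  assert_that(n1 > 0 && n0 > 0, "auroc: both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ---- feature encoding ------------------------------------------------------

# One-hot encodes categoricals (with an explicit missing category), median-
# imputes numerics with a missingness indicator. Level sets and imputation
# constants are frozen from the training table so the same encoder maps the
# holdout; unseen holdout levels encode as all-zero dummies.
fit_encoder <- function(train, task) {
  feats <- task$feature_names
  enc <- map(setNames(feats, feats), function(nm) {
    x <- train[[nm]]
    if (is.numeric(x)) {
      list(kind = "numeric",
           median = median(x, na.rm = TRUE) %||% 0,
           mean = mean(x, na.rm = TRUE),
           sd = max(stats::sd(x, na.rm = TRUE), 1e-8))
    } else {
      list(kind = "categorical",
           levels = sort(unique(as.character(x[!is.na(x)]))))
    }
  })
  structure(list(features = feats, encoders = enc), class = "sdg_encoder")
}

encode_features <- function(data, encoder, standardize = FALSE) {
  blocks <- map(encoder$features, function(nm) {
    e <- encoder$encoders[[nm]]
    x <- data[[nm]]
    if (e$kind == "numeric") {
      v <- as.numeric(x)
      miss <- as.numeric(is.na(v))
      med <- if (is.na(e$median)) 0 else e$median
      v[is.na(v)] <- med
      if (standardize) v <- (v - e$mean) / e$sd
      m <- cbind(v, miss)
      colnames(m) <- paste0(nm, c("", "_missing"))
      m
    } else {
      s <- as.character(x)
      s[is.na(s)] <- MISSING_TOKEN
      levs <- c(e$levels, MISSING_TOKEN)
      m <- matrix(0, nrow = length(s), ncol = length(levs),
                  dimnames = list(NULL, paste0(nm, "=", levs)))
      hit <- match(s, levs)
      ok <- !is.na(hit)
      m[cbind(which(ok), hit[ok])] <- 1
      m
    }
  })
  do.call(cbind, blocks)
}

outcome01 <- function(y, task) {
  yc <- as.character(y)
  as.integer(yc == task$positive_level)
}

check_two_classes <- function(y01, task) {
  if (length(unique(y01)) < 2) {
    lev <- if (all(y01 == 1)) task$positive_level else
      paste0("non-", task$positive_level)
    abort(sprintf("degenerate training outcome: only level '%s' present", lev),
          class = "sdgaudit_degenerate_outcome")
  }
}

# ---- gradient-boosted trees ------------------------------------------------

#' Default hyperparameter grid for the gradient-boosted learner
#'
#' Learning rate x leaf count x boosting rounds; selection is by mean AUROC
#' in k-fold cross-validation.
#' @return A tibble with columns `eta`, `leaves`, `nrounds`.
#' @export
default_gbm_grid <- function() {
  tidyr::expand_grid(eta = c(0.05, 0.1), leaves = c(15, 31, 63),
                     nrounds = c(100, 300))
}

xgb_fit <- function(X, y01, eta, leaves, nrounds, seed) {
  with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = eta,
                  max_leaves = leaves, grow_policy = "lossguide",
                  max_depth = 0, tree_method = "hist",
                  eval_metric = "auc", nthread = 1),
    data = xgboost::xgb.DMatrix(X, label = y01),
    nrounds = nrounds, verbose = 0))
}

#' Train the gradient-boosted classifier with CV-selected hyperparameters
#'
#' Hyperparameters (learning rate, leaf count, boosting rounds) are chosen by
#' mean AUROC over `cv_folds`-fold cross-validation on the training table;
#' the winning configuration is refit on all training rows. Trees are grown
#' leaf-wise (lossguide) with the leaf count as the capacity control.
#'
#' @param train_table Training data containing the task's features + outcome.
#' @param task A [task_spec()].
#' @param cv_folds Cross-validation folds (default 5).
#' @param grid Hyperparameter grid, see [default_gbm_grid()]. A single-row
#'   grid skips cross-validation.
#' @param seed Integer seed.
#' @return An `sdg_gbm` classifier with `$booster`, `$encoder`, `$task`,
#'   `$best_params`.
#' @export
train_gbm <- function(train_table, task, cv_folds = 5,
                      grid = default_gbm_grid(), seed = 1L) {
  y01 <- outcome01(train_table[[task$outcome_name]], task)
  check_two_classes(y01, task)
  encoder <- fit_encoder(train_table, task)
  X <- encode_features(train_table, encoder)

  best <- grid[1, ]
  if (nrow(grid) > 1) {
    folds <- with_seed(derive_seed(seed, 11L),
                       sample(rep_len(seq_len(cv_folds), nrow(X))))
    cv_auc <- map_dbl(seq_len(nrow(grid)), function(g) {
      mean(map_dbl(seq_len(cv_folds), function(f) {
        tr <- folds != f
        fit <- xgb_fit(X[tr, , drop = FALSE], y01[tr],
                       grid$eta[g], grid$leaves[g], grid$nrounds[g],
                       derive_seed(seed, g, f))
        p <- predict(fit, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE]))
        if (length(unique(y01[!tr])) < 2) NA_real_ else auroc(p, y01[!tr])
      }), na.rm = TRUE)
    })
    best <- grid[which.max(cv_auc), ]
  }
  booster <- xgb_fit(X, y01, best$eta, best$leaves, best$nrounds,
                     derive_seed(seed, 99L))
  structure(list(booster = booster, encoder = encoder, task = task,
                 best_params = as.list(best)),
            class = "sdg_gbm")
}

#' @export
predict.sdg_gbm <- function(object, newdata, ...) {
  X <- encode_features(newdata, object$encoder)
  predict(object$booster, xgboost::xgb.DMatrix(X))
}

# ---- multilayer perceptron -------------------------------------------------

mlp_forward <- function(params, X, drop_mask = NULL) {
  A1 <- pmax(X %*% params$W1 + rep(params$b1, each = nrow(X)), 0)
  if (!is.null(drop_mask)) A1 <- A1 * drop_mask
  A2 <- pmax(A1 %*% params$W2 + rep(params$b2, each = nrow(A1)), 0)
  z <- drop(A2 %*% params$W3) + params$b3
  list(A1 = A1, A2 = A2, p = plogis(z))
}

#' Train the multilayer-perceptron classifier
#'
#' A compact feed-forward network: dense layer of 16 ReLU units, dropout,
#' a second dense layer of 16 ReLU units, and a single sigmoid output.
#' Trained with Adam on binary cross-entropy in mini-batches, with a
#' validation split and early stopping to avoid overfitting. Categorical
#' features are one-hot encoded, numeric features standardized.
#'
#' @inheritParams train_gbm
#' @param hidden Units per hidden layer (default 16).
#' @param dropout Dropout rate after the first hidden layer (default 0.2).
#' @param batch_size Mini-batch size (default 256).
#' @param max_epochs Training epoch cap (default 100).
#' @param val_frac Validation fraction for early stopping (default 0.1).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param lr Adam learning rate.
#' @return An `sdg_mlp` classifier.
#' @export
train_mlp <- function(train_table, task, seed = 1L, hidden = 16, dropout = 0.2,
                      batch_size = 256, max_epochs = 100, val_frac = 0.1,
                      patience = 10, lr = 1e-3) {
  y01 <- outcome01(train_table[[task$outcome_name]], task)
  check_two_classes(y01, task)
  encoder <- fit_encoder(train_table, task)
  X <- encode_features(train_table, encoder, standardize = TRUE)
  n <- nrow(X); d <- ncol(X)

  with_seed(derive_seed(seed, 21L), {
    val_n <- max(1L, floor(val_frac * n))
    idx <- sample(n)
    val <- idx[seq_len(val_n)]
    trn <- idx[-seq_len(val_n)]
    Xv <- X[val, , drop = FALSE]; yv <- y01[val]
    Xt <- X[trn, , drop = FALSE]; yt <- y01[trn]

    init <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
    params <- list(W1 = init(d, hidden), b1 = rep(0, hidden),
                   W2 = init(hidden, hidden), b2 = rep(0, hidden),
                   W3 = init(hidden, 1), b3 = 0)
    mom <- map(params, function(p) p * 0)
    vel <- map(params, function(p) p * 0)
    b1p <- 1; b2p <- 1
    best_loss <- Inf; best_params <- params; wait <- 0L; step <- 0L

    bce <- function(p, y) {
      p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
      -mean(y * log(p) + (1 - y) * log(1 - p))
    }

    for (epoch in seq_len(max_epochs)) {
      ord <- sample(length(yt))
      starts <- seq(1, length(yt), by = batch_size)
      for (s in starts) {
        b <- ord[s:min(s + batch_size - 1, length(yt))]
        Xb <- Xt[b, , drop = FALSE]; yb <- yt[b]
        mask <- (matrix(runif(length(b) * hidden), length(b), hidden) >=
                   dropout) / (1 - dropout)
        fw <- mlp_forward(params, Xb, mask)
        nb <- length(b)
        dz3 <- matrix((fw$p - yb) / nb, ncol = 1)
        gW3 <- t(fw$A2) %*% dz3
        gb3 <- sum(dz3)
        dA2 <- dz3 %*% t(params$W3)
        dz2 <- dA2 * (fw$A2 > 0)
        gW2 <- t(fw$A1) %*% dz2
        gb2 <- colSums(dz2)
        dA1 <- (dz2 %*% t(params$W2)) * mask
        dz1 <- dA1 * (fw$A1 > 0)
        gW1 <- t(Xb) %*% dz1
        gb1 <- colSums(dz1)
        grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                      W3 = gW3, b3 = gb3)
        step <- step + 1L
        b1p <- b1p * 0.9; b2p <- b2p * 0.999
        for (nm in names(params)) {
          mom[[nm]] <- 0.9 * mom[[nm]] + 0.1 * grads[[nm]]
          vel[[nm]] <- 0.999 * vel[[nm]] + 0.001 * grads[[nm]]^2
          mhat <- mom[[nm]] / (1 - b1p)
          vhat <- vel[[nm]] / (1 - b2p)
          params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
        }
      }
      vloss <- bce(mlp_forward(params, Xv)$p, yv)
      if (vloss < best_loss - 1e-6) {
        best_loss <- vloss; best_params <- params; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    structure(list(params = best_params, encoder = encoder, task = task,
                   val_loss = best_loss, epochs = epoch),
              class = "sdg_mlp")
  })
}

#' @export
predict.sdg_mlp <- function(object, newdata, ...) {
  X <- encode_features(newdata, object$encoder, standardize = TRUE)
  mlp_forward(object$params, X)$p
}

# ---- TSTR / TRTR -----------------------------------------------------------

train_learner <- function(train_table, task, learner, seed, gbm_grid = NULL,
                          cv_folds = 5) {
  switch(learner,
         gbm = train_gbm(train_table, task, cv_folds = cv_folds,
                         grid = gbm_grid %||% default_gbm_grid(), seed = seed),
         mlp = train_mlp(train_table, task, seed = seed),
         abort(sprintf("unknown learner '%s'", learner)))
}

#' Train-synthetic-test-real utility of a replicate set
#'
#' Trains one classifier per synthetic replicate and scores it on the fixed
#' real holdout; the generator's TSTR is the mean holdout AUROC over
#' replicates. A replicate whose outcome collapses to a single class is
#' recorded as `NA`, excluded from the mean, and flagged with a warning.
#'
#' @param replicates An `sdg_replicates` or list of synthetic tables.
#' @param holdout Real holdout table (never used in generator training).
#' @param task A [task_spec()].
#' @param learner `"gbm"` or `"mlp"`.
#' @param seed Integer seed; replicate `r` trains with sub-seed `(seed, r)`.
#' @param gbm_grid Optional hyperparameter grid override for the GBM.
#' @param cv_folds CV folds for GBM selection.
#' @return A `utility_report`: list with `learner`, `tstr_per_replicate`,
#'   `tstr_mean`.
#' @export
evaluate_tstr <- function(replicates, holdout, task, learner = "gbm",
                          seed = 1L, gbm_grid = NULL, cv_folds = 5) {
  reps <- if (inherits(replicates, "sdg_replicates")) {
    replicates$replicates
  } else replicates
  y_hold <- outcome01(holdout[[task$outcome_name]], task)
  per_rep <- map_dbl(seq_along(reps), function(r) {
    fit <- tryCatch(
      train_learner(reps[[r]], task, learner, derive_seed(seed, r),
                    gbm_grid = gbm_grid, cv_folds = cv_folds),
      sdgaudit_degenerate_outcome = function(e) {
        warn(sprintf("replicate %d: %s; AUROC recorded as missing", r,
                     conditionMessage(e)))
        NULL
      })
    if (is.null(fit)) return(NA_real_)
    auroc(predict(fit, holdout), y_hold)
  })
  structure(list(learner = learner, tstr_per_replicate = per_rep,
                 tstr_mean = mean(per_rep, na.rm = TRUE)),
            class = "utility_report")
}

#' Train-real-test-real reference performance
#'
#' AUROC of a classifier trained on the real training split and evaluated on
#' the fixed holdout. With `extra_splits > 0` (and the parent population
#' supplied), the population is re-split that many times and the AUROC
#' distribution across splits is reported, quantifying sensitivity to the
#' single fixed split.
#'
#' @inheritParams evaluate_tstr
#' @param train Real training table.
#' @param extra_splits Number of additional random re-splits (default 0).
#' @param population Parent `sdg_population`, required when
#'   `extra_splits > 0`.
#' @param variant_columns Columns defining the variant, used for re-splits.
#' @return A list with `trtr` (AUROC on the fixed split) and, when
#'   requested, `split_aurocs` over the extra splits.
#' @export
evaluate_trtr <- function(train, holdout, task, learner = "gbm", seed = 1L,
                          extra_splits = 0, population = NULL,
                          variant_columns = NULL, gbm_grid = NULL,
                          cv_folds = 5) {
  if ("record_id" %in% names(train) && "record_id" %in% names(holdout)) {
    overlap <- intersect(train$record_id, holdout$record_id)
    assert_that(length(overlap) == 0,
                sprintf("evaluate_trtr: %d holdout records leak into training",
                        length(overlap)))
  }
  fit <- train_learner(drop_record_id(train), task, learner,
                       derive_seed(seed, 0L), gbm_grid = gbm_grid,
                       cv_folds = cv_folds)
  trtr <- auroc(predict(fit, holdout), outcome01(holdout[[task$outcome_name]], task))
  out <- list(trtr = trtr)
  if (extra_splits > 0) {
    assert_that(!is.null(population),
                "evaluate_trtr: `population` is required for extra splits")
    n_train <- nrow(train); n_hold <- nrow(holdout)
    cols <- variant_columns %||% setdiff(names(train), "record_id")
    dat <- select(population$data, all_of(c("record_id", cols)))
    out$split_aurocs <- map_dbl(seq_len(extra_splits), function(s) {
      sp <- make_split(population, n_train, n_hold, seed = derive_seed(seed, 100L, s))
      tr <- filter(dat, .data$record_id %in% sp$train_ids)
      ho <- filter(dat, .data$record_id %in% sp$holdout_ids)
      f <- train_learner(drop_record_id(tr), task, learner,
                         derive_seed(seed, 200L, s), gbm_grid = gbm_grid,
                         cv_folds = cv_folds)
      auroc(predict(f, ho), outcome01(ho[[task$outcome_name]], task))
    })
  }
  out
}
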