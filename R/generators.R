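# Both built-in synthesizers operate on a canonical categorical scale: every
# column is mapped to string tokens (numeric values to fixed-width bins,
# missing values to the sentinel token), models are fitted and sampled on
# tokens, and sampled tokens are mapped back (numerics by drawing uniformly
# within the bin). This aligns generation with the exact-match convention
# used for hallucination detection.

canon_schema <- function(train, n_bins = 10) {
  train <- drop_record_id(as_tibble(train))
  policy <- binning_policy(train, n_bins = n_bins)
  tokens <- canonicalize(train, policy)
  levels <- map(tokens, function(x) sort(unique(x)))
  list(policy = policy, tokens = tokens, levels = levels,
       kinds = map_chr(train, function(x) if (is.numeric(x)) "numeric" else "categorical"),
       columns = names(train))
}

decanonicalize <- function(tokens, schema) {
  out <- map(setNames(schema$columns, schema$columns), function(nm) {
    x <- tokens[[nm]]
    x[x == schema$policy$missing_token] <- NA
    if (schema$kinds[[nm]] == "numeric") {
      edges <- schema$policy$bin_edges[[nm]]
      idx <- suppressWarnings(as.integer(sub("^bin_", "", x)))
      lo <- edges[idx]
      hi <- edges[idx + 1L]
      v <- rep(NA_real_, length(x))
      ok <- !is.na(idx)
      v[ok] <- runif(sum(ok), lo[ok], hi[ok])
      v
    } else {
      x
    }
  })
  as_tibble(out)
}

# Frequency-rank integer code for a token column: predictors enter the CART
# fits as ordinal codes (most frequent level = 1). Keeps split search
# tractable at high cardinality; targets stay multiclass factors.
freq_rank_map <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  setNames(seq_along(tab), names(tab))
}

default_visit_order <- function(columns, roles = NULL) {
  if (is.null(roles)) return(columns)
  core <- intersect(roles$core, columns)
  adj <- setdiff(columns, c(core, roles$outcome))
  c(core, intersect(roles$outcome, columns), adj)
}

#' Fit a sequential decision-tree synthesizer
#'
#' The first variable in the visit order is modeled by its empirical
#' marginal; each subsequent variable by a CART on all previously visited
#' variables (minimum leaf size 20, no complexity pruning). Sampling walks
#' the same order, drawing each value from the empirical distribution of the
#' reached leaf's training records.
#'
#' @param train Training table (a `record_id` column is ignored).
#' @param roles Optional roles list (`core`, `adjunct`, `outcome`) used for
#'   the default visit order: core variables first with the outcome last
#'   among them, then adjuncts in schema order.
#' @param visit_order Optional explicit column visit order.
#' @param tree_params CART controls: `minbucket`, `cp`, `maxdepth`.
#' @param n_bins Bins used to discretize numeric variables for synthesis.
#' @param seed Integer seed stored with the generator.
#' @return An `sdg_generator` with `family = "sequential_trees"`.
#' @export
fit_sequential_trees <- function(train, roles = NULL, visit_order = NULL,
                                 tree_params = list(minbucket = 20, cp = 0,
                                                    maxdepth = 30),
                                 n_bins = 10, seed = 1L) {
  schema <- canon_schema(train, n_bins = n_bins)
  assert_that(nrow(schema$tokens) >= 1, "fit_sequential_trees: empty training data")
  order <- visit_order %||% default_visit_order(schema$columns, roles)
  assert_that(setequal(order, schema$columns),
              "fit_sequential_trees: visit order must cover exactly the training columns")

  ctrl <- rpart::rpart.control(
    minbucket = tree_params$minbucket %||% 20,
    cp = tree_params$cp %||% 0,
    maxdepth = tree_params$maxdepth %||% 30,
    xval = 0, maxcompete = 0, maxsurrogate = 0)

  models <- vector("list", length(order))
  names(models) <- order
  rank_maps <- list()
  for (j in seq_along(order)) {
    nm <- order[j]
    y <- schema$tokens[[nm]]
    if (j == 1 || length(unique(y)) == 1) {
      tab <- table(y)
      models[[nm]] <- list(type = "marginal",
                           levels = names(tab),
                           probs = as.numeric(tab) / sum(tab))
    } else {
      preds <- order[seq_len(j - 1)]
      df <- as_tibble(map(setNames(preds, preds), function(p) {
        unname(rank_maps[[p]][schema$tokens[[p]]])
      }))
      df$.y <- factor(y)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class", control = ctrl)
      models[[nm]] <- list(type = "tree", fit = fit, predictors = preds,
                           levels = levels(df$.y))
    }
    rank_maps[[nm]] <- freq_rank_map(y)
  }
  structure(list(family = "sequential_trees",
                 state = list(order = order, models = models,
                              rank_maps = rank_maps),
                 training_schema = schema, seed = as.integer(seed)),
            class = "sdg_generator")
}

sample_categorical_rows <- function(prob_matrix, levels) {
  if (ncol(prob_matrix) == 1) return(rep(levels[1], nrow(prob_matrix)))
  cs <- t(apply(prob_matrix, 1, cumsum))
  u <- runif(nrow(prob_matrix)) * cs[, ncol(cs)]
  idx <- rowSums(cs < u) + 1L
  levels[pmin(idx, length(levels))]
}

sample_st_tokens <- function(generator, n) {
  st <- generator$state
  out <- vector("list", length(st$order))
  names(out) <- st$order
  for (nm in st$order) {
    m <- st$models[[nm]]
    if (m$type == "marginal") {
      out[[nm]] <- sample(m$levels, n, replace = TRUE, prob = m$probs)
    } else {
      nd <- as_tibble(map(setNames(m$predictors, m$predictors), function(p) {
        unname(st$rank_maps[[p]][out[[p]]])
      }))
      pm <- predict(m$fit, newdata = nd, type = "prob")
      if (is.null(dim(pm))) {
        pm <- matrix(pm, nrow = 1, dimnames = list(NULL, names(pm)))
      }
      out[[nm]] <- sample_categorical_rows(pm, colnames(pm))
    }
  }
  as_tibble(out)[generator$training_schema$columns]
}

# Plug-in mutual information between two token vectors (natural log).
mutual_information <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  nz <- pxy > 0
  sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
}

#' Fit a Chow-Liu Bayesian-network synthesizer
#'
#' Learns the spanning tree that maximizes total pairwise mutual information
#' over the discretized variables, roots it at the first variable of the
#' visit order, estimates conditional probability tables with additive
#' (Laplace) smoothing, and samples ancestrally from the root. A single
#' variable falls back to its smoothed marginal.
#'
#' @inheritParams fit_sequential_trees
#' @param smoothing_alpha Additive smoothing strength (default 1). Pseudo-
#'   counts are spread over a child's levels in proportion to its marginal
#'   (total pseudo-mass `alpha * n_levels` per parent level, as in uniform
#'   Laplace smoothing, but shaped by the marginal so long-tailed variables
#'   are not flattened); every observed level keeps nonzero probability
#'   under every parent level, so unseen combinations remain reachable.
#' @return An `sdg_generator` with `family = "chow_liu_bn"`.
#' @export
fit_chow_liu_bn <- function(train, roles = NULL, visit_order = NULL,
                            smoothing_alpha = 1, n_bins = 10, seed = 1L) {
  schema <- canon_schema(train, n_bins = n_bins)
  order <- visit_order %||% default_visit_order(schema$columns, roles)
  cols <- schema$columns
  p <- length(cols)
  tok <- schema$tokens
  lev <- schema$levels

  if (p == 1) {
    tab <- table(factor(tok[[1]], levels = lev[[1]])) + smoothing_alpha
    nodes <- list(list(name = cols[1], parent = NA_character_,
                       levels = lev[[1]], probs = as.numeric(tab) / sum(tab)))
    names(nodes) <- cols[1]
  } else {
    pairs <- utils::combn(cols, 2, simplify = FALSE)
    mi <- map_dbl(pairs, function(pr) mutual_information(tok[[pr[1]]], tok[[pr[2]]]))
    g <- igraph::graph_from_data_frame(
      tibble(from = map_chr(pairs, 1), to = map_chr(pairs, 2),
             weight = -mi),
      directed = FALSE, vertices = cols)
    tree <- igraph::mst(g)
    root <- order[1]
    bfs <- igraph::bfs(tree, root = root, father = TRUE)
    visit <- names(bfs$order)
    fathers <- igraph::V(tree)$name[as.integer(bfs$father)]
    names(fathers) <- names(bfs$father)

    nodes <- map(setNames(visit, visit), function(nm) {
      par <- if (nm == root) NA_character_ else fathers[[nm]]
      if (is.na(par)) {
        tab <- table(factor(tok[[nm]], levels = lev[[nm]])) + smoothing_alpha
        list(name = nm, parent = NA_character_, levels = lev[[nm]],
             probs = as.numeric(tab) / sum(tab))
      } else {
        marg <- table(factor(tok[[nm]], levels = lev[[nm]]))
        marg <- as.numeric(marg) / sum(marg)
        pseudo <- smoothing_alpha * length(lev[[nm]]) *
          pmax(marg, 1e-8 / length(lev[[nm]]))
        ct <- table(factor(tok[[par]], levels = lev[[par]]),
                    factor(tok[[nm]], levels = lev[[nm]]))
        ct <- sweep(unclass(ct), 2, pseudo, "+")
        cpt <- ct / rowSums(ct)
        list(name = nm, parent = par, levels = lev[[nm]],
             parent_levels = lev[[par]], cpt = cpt)
      }
    })
  }
  structure(list(family = "chow_liu_bn",
                 state = list(nodes = nodes, order = names(nodes),
                              smoothing_alpha = smoothing_alpha),
                 training_schema = schema, seed = as.integer(seed)),
            class = "sdg_generator")
}

sample_bn_tokens <- function(generator, n) {
  st <- generator$state
  out <- list()
  for (nm in st$order) {
    node <- st$nodes[[nm]]
    if (is.na(node$parent)) {
      out[[nm]] <- sample(node$levels, n, replace = TRUE, prob = node$probs)
    } else {
      par_idx <- match(out[[node$parent]], node$parent_levels)
      pm <- node$cpt[par_idx, , drop = FALSE]
      out[[nm]] <- sample_categorical_rows(pm, node$levels)
    }
  }
  as_tibble(out)[generator$training_schema$columns]
}

#' @export
print.sdg_generator <- function(x, ...) {
  cat(sprintf("<sdg_generator family='%s', %d variables>\n",
              x$family, length(x$training_schema$columns)))
  invisible(x)
}

# ---- plugin registry -------------------------------------------------------

plugin_registry <- new.env(parent = emptyenv())

#' Register an external generator family
#'
#' Adapter for generator families not built in (e.g. GAN-, VAE- or
#' flow-based synthesizers): `fit_fn(train, seed)` must return an object
#' usable by `sample_fn(state, n, seed)`, which must return a table with
#' exactly the training columns and `n` rows; the pipeline then treats the
#' plugin identically to the built-ins. Contract violations are rejected at
#' sampling time with a diagnostic.
#'
#' @param name Plugin family name (used as `plugin:<name>`).
#' @param fit_fn Function `(train, seed)` returning arbitrary fitted state.
#' @param sample_fn Function `(state, n, seed)` returning a data frame.
#' @return The registered family label, invisibly.
#' @export
register_plugin <- function(name, fit_fn, sample_fn) {
  assert_that(is.function(fit_fn) && is.function(sample_fn),
              "register_plugin: fit_fn and sample_fn must be functions")
  assign(name, list(fit = fit_fn, sample = sample_fn), envir = plugin_registry)
  invisible(paste0("plugin:", name))
}

#' Fit any registered generator family
#'
#' Dispatches to [fit_sequential_trees()] (`"sequential_trees"` or `"st"`),
#' [fit_chow_liu_bn()] (`"chow_liu_bn"` or `"bn"`), or a registered plugin
#' (`"plugin:<name>"`).
#'
#' @param train Training table.
#' @param family Family label.
#' @param roles Optional roles list passed to built-ins.
#' @param seed Integer seed.
#' @param ... Further arguments for the family's fit function.
#' @return An `sdg_generator`.
#' @export
fit_generator <- function(train, family, roles = NULL, seed = 1L, ...) {
  if (family %in% c("sequential_trees", "st")) {
    fit_sequential_trees(train, roles = roles, seed = seed, ...)
  } else if (family %in% c("chow_liu_bn", "bn")) {
    fit_chow_liu_bn(train, roles = roles, seed = seed, ...)
  } else if (startsWith(family, "plugin:")) {
    nm <- sub("^plugin:", "", family)
    assert_that(exists(nm, envir = plugin_registry),
                sprintf("fit_generator: no plugin registered as '%s'", nm))
    pl <- get(nm, envir = plugin_registry)
    schema <- canon_schema(train)
    structure(list(family = family,
                   state = pl$fit(drop_record_id(as_tibble(train)), seed),
                   training_schema = schema, seed = as.integer(seed),
                   plugin = pl),
              class = "sdg_generator")
  } else {
    abort(sprintf("fit_generator: unknown family '%s'", family))
  }
}

#' Sample replicate synthetic datasets from a fitted generator
#'
#' Draws `k` synthetic tables of `n_per_replicate` rows each. Replicate `r`
#' uses a deterministic sub-seed derived from `(seed, r)`, so replicates are
#' independent but the whole set is reproducible.
#'
#' @param generator An `sdg_generator`.
#' @param n_per_replicate Rows per synthetic table (>= 1).
#' @param k Number of replicates (>= 1; the study convention is 10).
#' @param seed Integer seed.
#' @return An `sdg_replicates`: list with `replicates` (list of tibbles),
#'   `n_per_replicate`, `k`, `family`, `seed`.
#' @export
sample_replicates <- function(generator, n_per_replicate, k = 10, seed = 1L) {
  assert_that(inherits(generator, "sdg_generator"),
              "sample_replicates: `generator` must be an sdg_generator")
  assert_that(is_count(n_per_replicate) && n_per_replicate >= 1,
              "sample_replicates: `n_per_replicate` must be >= 1")
  assert_that(is_count(k) && k >= 1, "sample_replicates: `k` must be >= 1")
  schema <- generator$training_schema
  reps <- map(seq_len(k), function(r) {
    with_seed(derive_seed(seed, r), {
      if (generator$family == "sequential_trees") {
        decanonicalize(sample_st_tokens(generator, n_per_replicate), schema)
      } else if (generator$family == "chow_liu_bn") {
        decanonicalize(sample_bn_tokens(generator, n_per_replicate), schema)
      } else {
        out <- as_tibble(generator$plugin$sample(generator$state,
                                                 n_per_replicate,
                                                 derive_seed(seed, r)))
        assert_that(setequal(names(out), schema$columns),
                    sprintf("plugin '%s' returned wrong column set (got: %s)",
                            generator$family, paste(names(out), collapse = ", ")))
        assert_that(nrow(out) == n_per_replicate,
                    sprintf("plugin '%s' returned %d rows, expected %d",
                            generator$family, nrow(out), n_per_replicate))
        out[schema$columns]
      }
    })
  })
  structure(list(replicates = reps, n_per_replicate = as.integer(n_per_replicate),
                 k = as.integer(k), family = generator$family,
                 seed = as.integer(seed)),
            class = "sdg_replicates")
}

#' @export
print.sdg_replicates <- function(x, ...) {
  cat(sprintf("<sdg_replicates: %d replicates x %d rows from '%s'>\n",
              x$k, x$n_per_replicate, x$family))
  invisible(x)
}
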