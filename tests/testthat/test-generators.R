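test_that("a single-column sequential-tree generator reproduces the marginal", {
  train <- tibble::tibble(a = rep(c("x", "y"), c(600, 400)))
  gen <- fit_sequential_trees(train, seed = 1)
  reps <- sample_replicates(gen, 10000, k = 1, seed = 2)
  p_hat <- mean(reps$replicates[[1]]$a == "x")
  expect_lt(abs(p_hat - 0.6), 4 * sqrt(0.6 * 0.4 / 10000))
})

test_that("perfectly correlated columns synthesize only observed combinations", {
  # the tree on the second column reduces to a deterministic mapping, so
  # leaf-donor sampling can only emit the two observed combinations
  # (enumeration over the sampled table verifies this)
  train <- tibble::tibble(a = rep(c("0", "1"), c(300, 300)))
  train$b <- train$a
  gen <- fit_generator(train, "st", seed = 3)
  reps <- sample_replicates(gen, 2000, k = 1, seed = 4)
  combos <- unique(paste(reps$replicates[[1]]$a, reps$replicates[[1]]$b))
  expect_setequal(combos, c("0 0", "1 1"))
})

test_that("fitting and sampling are deterministic given seeds", {
  pop <- generate_population(toy_population_spec(n = 800, seed = 15))
  train <- dplyr::select(pop$data, -record_id)[1:400, ]
  for (fam in c("st", "bn")) {
    g1 <- fit_generator(train, fam, roles = pop$roles, seed = 7)
    g2 <- fit_generator(train, fam, roles = pop$roles, seed = 7)
    r1 <- sample_replicates(g1, 200, k = 3, seed = 9)
    r2 <- sample_replicates(g2, 200, k = 3, seed = 9)
    expect_identical(r1$replicates, r2$replicates)
    r3 <- sample_replicates(g1, 200, k = 3, seed = 10)
    expect_false(identical(r1$replicates, r3$replicates))
  }
})

test_that("independent variables stay independent through the Chow-Liu model", {
  train <- withr::with_seed(11, tibble::tibble(
    a = sample(c("x", "y"), 5000, TRUE),
    b = sample(c("p", "q"), 5000, TRUE)))
  gen <- fit_chow_liu_bn(train, seed = 1)
  reps <- sample_replicates(gen, 5000, k = 1, seed = 2)
  s <- reps$replicates[[1]]
  joint <- mean(s$a == "x" & s$b == "p")
  expect_lt(abs(joint - mean(s$a == "x") * mean(s$b == "p")), 0.02)
  expect_lt(sdgaudit:::mutual_information(s$a, s$b), 0.005)
})

test_that("Chow-Liu recovers a dependence chain", {
  train <- withr::with_seed(12, {
    x <- sample(c("0", "1"), 20000, TRUE)
    flip <- function(v) ifelse(stats::runif(length(v)) < 0.9, v,
                               ifelse(v == "0", "1", "0"))
    y <- flip(x)
    z <- flip(y)
    tibble::tibble(x = x, y = y, z = z)
  })
  # oracle: under the generating law MI(x,y) = MI(y,z) > MI(x,z), so the
  # maximum-MI spanning tree is the chain x - y - z in either orientation
  gen <- fit_chow_liu_bn(train, seed = 1)
  edges <- purrr::imap(gen$state$nodes, function(nd, nm) {
    if (is.na(nd$parent)) NULL else sort(c(nm, nd$parent))
  })
  edges <- purrr::compact(edges)
  expect_setequal(purrr::map_chr(edges, paste, collapse = "-"),
                  c("x-y", "y-z"))
})

test_that("Laplace smoothing keeps unseen combinations reachable", {
  train <- tibble::tibble(a = rep(c("0", "1"), c(50, 50)))
  train$b <- train$a
  gen <- fit_chow_liu_bn(train, smoothing_alpha = 1, seed = 1)
  child <- purrr::detect(gen$state$nodes, function(nd) !is.na(nd$parent))
  expect_true(all(child$cpt > 0)) # unseen (a, b) combos keep mass
})

test_that("replicate sets have the configured shape and schema", {
  pop <- generate_population(toy_population_spec(n = 600, seed = 16,
                                                 missing_rate = 0.05))
  train <- dplyr::select(pop$data, -record_id)[1:300, ]
  gen <- fit_sequential_trees(train, roles = pop$roles, seed = 2)
  reps <- sample_replicates(gen, 150, k = 4, seed = 3)
  expect_length(reps$replicates, 4)
  expect_true(all(purrr::map_int(reps$replicates, nrow) == 150))
  expect_true(all(purrr::map_lgl(reps$replicates, function(r) {
    setequal(names(r), names(train))
  })))

  one <- sample_replicates(gen, 1, k = 1, seed = 5)
  expect_equal(nrow(one$replicates[[1]]), 1)
  # schema closure: categorical draws are training-observed levels
  for (nm in names(train)) {
    if (!is.numeric(train[[nm]])) {
      lv <- unique(as.character(train[[nm]]))
      got <- as.character(one$replicates[[1]][[nm]])
      expect_true(is.na(got) || got %in% lv)
    }
  }
})

test_that("built-in generators keep marginal fidelity at scale", {
  pop <- generate_population(toy_population_spec(n = 20000, seed = 17,
                                                 missing_rate = 0.03))
  sp <- make_split(pop, 10000, 10000, seed = 1)
  train <- dplyr::select(
    dplyr::filter(pop$data, record_id %in% sp$train_ids), -record_id)
  pol <- binning_policy(train)
  train_tok <- canonicalize(train, pol)
  for (fam in c("st", "bn")) {
    gen <- fit_generator(train, fam, roles = pop$roles, seed = 8)
    s <- sample_replicates(gen, 10000, k = 1, seed = 9)$replicates[[1]]
    s_tok <- canonicalize(s, pol)
    tvd <- purrr::map_dbl(names(train_tok), function(nm) {
      lv <- union(train_tok[[nm]], s_tok[[nm]])
      pt <- table(factor(train_tok[[nm]], lv)) / nrow(train_tok)
      ps <- table(factor(s_tok[[nm]], lv)) / nrow(s_tok)
      sum(abs(pt - ps)) / 2
    })
    expect_true(all(tvd <= 0.05),
                label = sprintf("%s TVD max %.3f", fam, max(tvd)))
  }
})

test_that("plugins join the pipeline and contract violations are rejected", {
  pop <- generate_population(toy_population_spec(n = 500, seed = 18))
  variant <- build_variant(pop, pop$roles$adjunct)
  train <- dplyr::select(variant$data, -record_id)[1:250, ]

  register_plugin("verbatim",
                  fit_fn = function(train, seed) list(data = train),
                  sample_fn = function(state, n, seed) {
                    state$data[rep_len(seq_len(nrow(state$data)), n), ]
                  })
  gen <- fit_generator(train, "plugin:verbatim", seed = 1)
  reps <- sample_replicates(gen, 100, k = 2, seed = 2)
  pol <- binning_policy(dplyr::select(variant$data, -record_id))
  hr <- hallucination_rate(reps, variant$data, pol)
  expect_equal(hr$mean_rate, 0) # S is a resample of T subset of P

  register_plugin("broken",
                  fit_fn = function(train, seed) list(cols = names(train)),
                  sample_fn = function(state, n, seed) {
                    tibble::tibble(wrong = rep(1, n))
                  })
  genb <- fit_generator(train, "plugin:broken", seed = 1)
  expect_error(sample_replicates(genb, 10, k = 1, seed = 1),
               "wrong column set")
  expect_error(fit_generator(train, "plugin:unregistered"), "no plugin")
  expect_error(fit_generator(train, "nonsense"), "unknown family")
})
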