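#' Count the population variants attainable from an adjunct pool
#'
#' Exact integer (double-precision for display) count of adjunct subsets:
#' `choose(m, v)` for a fixed subset size, or `2^m` over all sizes.
#'
#' @param m Adjunct pool size.
#' @param v Subset size, or `"all"` for the whole combinatorial space.
#' @return The count as a double (exact up to 2^53; beyond that the usual
#'   floating representation, e.g. `2^100 = 1.267651e30`).
#' @export
count_subsets <- function(m, v = "all") {
  assert_that(is_count(m), "count_subsets: `m` must be a nonnegative integer")
  if (identical(v, "all")) return(2^m)
  assert_that(is_count(v), "count_subsets: `v` must be a nonnegative integer or 'all'")
  assert_that(v <= m, sprintf("count_subsets: v = %d exceeds pool size m = %d", v, m))
  choose(m, v)
}

#' Sample distinct variant plans over the adjunct pool
#'
#' Draws `n_variants` distinct adjunct subsets from a population's pool. The
#' core-only plan (no adjuncts) is always included. For pools with `m <= 5`
#' the full space of `2^m` subsets is enumerated; otherwise target subset
#' sizes are stratified over a log-spaced grid from 0 to `m` and a uniform
#' random subset of each target size is drawn, rejecting duplicates, so the
#' plans cover the whole complexity range without combinatorial blow-up.
#'
#' @param population An `sdg_population`.
#' @param n_variants Number of plans (>= 1, <= `2^m`).
#' @param seed Integer seed.
#' @return A tibble of plans: `plan_id`, `population_name`, `v` (subset
#'   size), `adjunct_subset` (list-column of sorted adjunct names), `seed`.
#' @export
sample_variant_plans <- function(population, n_variants, seed = 1L) {
  assert_that(inherits(population, "sdg_population"),
              "sample_variant_plans: `population` must be an sdg_population")
  assert_that(is_count(n_variants) && n_variants >= 1,
              "sample_variant_plans: `n_variants` must be >= 1")
  pool <- population$roles$adjunct
  m <- length(pool)
  maxn <- 2^m
  assert_that(n_variants <= maxn,
              sprintf("sample_variant_plans: requested %d variants but only %.0f distinct subsets exist for m = %d",
                      n_variants, maxn, m))

  subsets <- if (m <= 5) {
    all_subsets <- map(seq_len(maxn) - 1L, function(b) {
      sort(pool[bitwAnd(b, bitwShiftL(1L, seq_len(m) - 1L)) != 0L])
    })
    sizes <- lengths(all_subsets)
    ord <- order(sizes, map_chr(all_subsets, paste, collapse = "|"))
    head(all_subsets[ord], n_variants)
  } else {
    with_seed(derive_seed(seed, 2L), {
      out <- list(character(0)) # core-only plan always present
      seen <- ""
      grid <- unique(round(exp(seq(log(1), log(m), length.out = 12))))
      i <- 0L
      while (length(out) < n_variants) {
        i <- i + 1L
        v <- grid[((i - 1L) %% length(grid)) + 1L]
        cand <- sort(sample(pool, v))
        key <- paste(cand, collapse = "|")
        if (!key %in% seen) {
          out[[length(out) + 1L]] <- cand
          seen <- c(seen, key)
        }
        if (i > 200L * n_variants) {
          abort("sample_variant_plans: could not find enough distinct subsets")
        }
      }
      out
    })
  }
  tibble(
    plan_id = sprintf("%s_v%04d", population$spec$name, seq_along(subsets)),
    population_name = population$spec$name,
    v = lengths(subsets),
    adjunct_subset = subsets,
    seed = as.integer(seed)
  )
}

#' Restrict a population to a variant's column set
#'
#' A variant keeps every record of the parent population but only the core
#' variables, the plan's adjunct subset, and the outcome. Record ids and
#' order are preserved.
#'
#' @param population An `sdg_population`.
#' @param plan One row of [sample_variant_plans()] output (a data frame with
#'   one row), or a character vector of adjunct names.
#' @return An `sdg_variant`: list with `data` (tibble), `plan_id`,
#'   `population_name`, `columns`, `roles`.
#' @export
build_variant <- function(population, plan) {
  adjuncts <- if (is.character(plan)) {
    plan
  } else {
    assert_that(is.data.frame(plan) && nrow(plan) == 1,
                "build_variant: `plan` must be a single plan row or character vector")
    plan$adjunct_subset[[1]]
  }
  unknown <- setdiff(adjuncts, population$roles$adjunct)
  assert_that(length(unknown) == 0,
              sprintf("build_variant: unknown adjunct variables: %s",
                      paste(unknown, collapse = ", ")))
  cols <- c(population$roles$core, sort(adjuncts), population$roles$outcome)
  structure(list(
    data = select(population$data, all_of(c("record_id", cols))),
    plan_id = if (is.character(plan)) NA_character_ else plan$plan_id,
    population_name = population$spec$name,
    columns = cols,
    roles = list(core = population$roles$core, adjunct = sort(adjuncts),
                 outcome = population$roles$outcome)
  ), class = "sdg_variant")
}

#' Draw the fixed, disjoint train/holdout record split for a population
#'
#' One split is made per population and reused by every variant of it, so
#' TSTR/TRTR results are comparable across variants and the holdout never
#' leaks into generator training.
#'
#' @param population An `sdg_population`.
#' @param n_train,n_holdout Exact split sizes; their sum must not exceed the
#'   population size.
#' @param seed Integer seed.
#' @return A list with integer id vectors `train_ids` and `holdout_ids`.
#' @export
make_split <- function(population, n_train, n_holdout, seed = 1L) {
  n <- nrow(population$data)
  assert_that(n_train + n_holdout <= n,
              sprintf("make_split: requested %d + %d records but population has only %d",
                      n_train, n_holdout, n))
  with_seed(derive_seed(seed, 3L), {
    ids <- sample(population$data$record_id, n_train + n_holdout)
    list(train_ids = sort(ids[seq_len(n_train)]),
         holdout_ids = sort(ids[n_train + seq_len(n_holdout)]))
  })
}
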