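# Row keys for exact matching: canonical tokens joined with an unprintable
# separator, so two rows match iff all columns (missing included) agree.
row_keys <- function(canon) {
  do.call(paste, c(as.list(canon), sep = "\x1f"))
}

#' Identify hallucinated synthetic records by antijoin
#'
#' A synthetic record is hallucinated when it does not exist in the
#' population variant: the hallucinated set is the set difference S \ P,
#' computed as a row-wise antijoin on canonicalized tables over every column
#' of the variant (outcome included). Duplicated synthetic rows are counted
#' individually.
#'
#' @param synthetic Synthetic table.
#' @param population_variant The variant's records (an `sdg_variant` or a
#'   data frame; a `record_id` column is ignored).
#' @param policy A [binning_policy()] built from the population variant and
#'   shared by both tables.
#' @return Integer vector of hallucinated synthetic row indices.
#' @export
hallucinated_records <- function(synthetic, population_variant, policy) {
  pop <- if (inherits(population_variant, "sdg_variant")) {
    population_variant$data
  } else population_variant
  s_keys <- row_keys(canonicalize(synthetic, policy))
  p_keys <- row_keys(canonicalize(pop, policy))
  which(!(s_keys %in% p_keys))
}

#' Hamming-distance oracle for hallucination detection
#'
#' Returns the synthetic rows whose minimum record-level Hamming distance to
#' any population row exceeds 0 — by definition exactly the antijoin result.
#' Kept as an independent check: it computes pairwise distances directly and
#' refuses instances beyond 10^4 x 10^4 comparisons.
#'
#' @inheritParams hallucinated_records
#' @return Integer vector of synthetic row indices with min Hamming > 0.
#' @export
hamming_oracle <- function(synthetic, population_variant, policy) {
  pop <- if (inherits(population_variant, "sdg_variant")) {
    population_variant$data
  } else population_variant
  s <- canonicalize(synthetic, policy)
  p <- canonicalize(pop, policy)
  assert_that(as.double(nrow(s)) * nrow(p) <= 1e8,
              "hamming_oracle: instance too large; use hallucinated_records (antijoin)")
  # distance accumulated column-wise over the synthetic x population grid
  dist <- matrix(0L, nrow(s), nrow(p))
  for (nm in policy$columns) {
    dist <- dist + outer(s[[nm]], p[[nm]], "!=")
  }
  which(apply(dist, 1, min) > 0)
}

#' Hallucination rate of a replicate set against its population variant
#'
#' Per replicate, the rate is |HA| / |S| — hallucinated records over
#' synthetic dataset size; the trained generator's HR is the arithmetic mean
#' over replicates.
#'
#' @param replicates An `sdg_replicates` or a list of synthetic tables.
#' @param population_variant The variant's records.
#' @param policy A [binning_policy()] from the variant; when `NULL` it is
#'   built from the variant with defaults.
#' @return An `hr_report`: tibble-backed list with `per_replicate_count`,
#'   `per_replicate_rate`, `mean_rate`, `n_synthetic`, `k`.
#' @export
hallucination_rate <- function(replicates, population_variant, policy = NULL) {
  reps <- if (inherits(replicates, "sdg_replicates")) {
    replicates$replicates
  } else replicates
  assert_that(length(reps) >= 1, "hallucination_rate: no replicates")
  pop <- if (inherits(population_variant, "sdg_variant")) {
    population_variant$data
  } else population_variant
  policy <- policy %||% binning_policy(drop_record_id(pop))
  counts <- map_int(reps, function(s) {
    assert_that(nrow(s) >= 1, "hallucination_rate: empty replicate")
    length(hallucinated_records(s, pop, policy))
  })
  sizes <- map_int(reps, nrow)
  rates <- counts / sizes
  structure(list(per_replicate_count = counts,
                 per_replicate_rate = rates,
                 mean_rate = mean(rates),
                 n_synthetic = sizes[1],
                 k = length(reps)),
            class = "hr_report")
}

#' @export
print.hr_report <- function(x, ...) {
  cat(sprintf("<hr_report: mean HR %.4f over %d replicates of %d records>\n",
              x$mean_rate, x$k, x$n_synthetic))
  invisible(x)
}
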