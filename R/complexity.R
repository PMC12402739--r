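#' Observed cardinality of one variable
#'
#' Categorical: number of distinct observed non-missing levels, plus one when
#' any value is missing (missing counts as its own level, matching the
#' exact-match convention). Numeric: number of occupied discretization bins
#' under the shared binning policy, plus one for missingness. An all-missing
#' column has cardinality 1 (the missing level).
#'
#' @param column A vector.
#' @param policy Optional [binning_policy()]; required to discretize numeric
#'   columns consistently with hallucination matching. When `NULL`, numeric
#'   columns get equal-width edges computed from the column itself with
#'   `n_bins` bins.
#' @param name Column name used to look up edges in the policy.
#' @param n_bins Fallback bin count when no policy is supplied.
#' @return Integer cardinality (>= 1).
#' @export
variable_cardinality <- function(column, policy = NULL, name = NULL, n_bins = 10) {
  assert_that(length(column) >= 1, "variable_cardinality: empty column")
  if (is.numeric(column)) {
    edges <- if (!is.null(policy) && !is.null(name) &&
                 name %in% names(policy$bin_edges)) {
      policy$bin_edges[[name]]
    } else {
      x <- column[!is.na(column)]
      if (length(x) == 0 || min(x) == max(x)) c(0, 1) else
        seq(min(x), max(x), length.out = n_bins + 1)
    }
    lab <- bin_assign(as.numeric(column), edges)
    n_levels <- length(unique(lab[!is.na(lab)]))
  } else {
    n_levels <- length(unique(as.character(column[!is.na(column)])))
  }
  as.integer(n_levels + any(is.na(column)))
}

#' Structural complexity of a dataset
#'
#' Complexity is the log of the sum of the variables' cardinalities — a
#' structural proxy combining dimensionality (more variables add terms) and
#' cardinality (high-cardinality codes add large terms). Natural log by
#' default; the base only rescales, leaving all monotone relationships
#' unchanged.
#'
#' @param data A data frame (a `record_id` column is ignored).
#' @param policy Optional [binning_policy()] shared with hallucination
#'   matching, used to discretize numeric variables.
#' @param base Log base (default `exp(1)`).
#' @return A `complexity_result`: list with `complexity`,
#'   `per_variable_cardinality` (named integer vector), and `log_base`.
#' @export
complexity <- function(data, policy = NULL, base = exp(1)) {
  data <- drop_record_id(as_tibble(data))
  assert_that(ncol(data) >= 1, "complexity: dataset has no variables")
  cards <- map_int(setNames(names(data), names(data)), function(nm) {
    variable_cardinality(data[[nm]], policy = policy, name = nm)
  })
  structure(list(complexity = log(sum(cards), base = base),
                 per_variable_cardinality = cards,
                 log_base = if (isTRUE(all.equal(base, exp(1)))) "natural" else
                   as.character(base)),
            class = "complexity_result")
}

#' @export
print.complexity_result <- function(x, ...) {
  cat(sprintf("<complexity %.4f (%s log, sum of %d cardinalities = %d)>\n",
              x$complexity, x$log_base, length(x$per_variable_cardinality),
              sum(x$per_variable_cardinality)))
  invisible(x)
}
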