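#' Fix the discretization and missing-value convention for record matching
#'
#' Builds the shared canonicalization policy from a population variant:
#' per-numeric-variable bin edges (computed on the variant's full record set
#' and then applied unchanged to synthetic tables), the missing-value
#' sentinel, and the column order. Bins are left-closed/right-open with the
#' final bin closed; values outside the variant's observed range fall into
#' out-of-range bins.
#'
#' @param data A data frame (typically a variant's records, without
#'   `record_id`).
#' @param n_bins Bins per numeric variable (default 10). More bins make
#'   hallucination detection more sensitive; fewer are more tolerant.
#' @param strategy `"equal-width"` or `"quantile"` bin edges.
#' @param missing_token Sentinel string for missing values.
#' @return A `binning_policy` list with `columns`, `n_bins`, `strategy`,
#'   `missing_token`, and per-variable `bin_edges`.
#' @export
binning_policy <- function(data, n_bins = 10, strategy = c("equal-width", "quantile"),
                           missing_token = MISSING_TOKEN) {
  strategy <- match.arg(strategy)
  assert_that(is.data.frame(data) && ncol(data) >= 1,
              "binning_policy: `data` must be a data frame with >= 1 column")
  data <- drop_record_id(data)
  num_cols <- names(data)[map_lgl(data, is.numeric)]
  edges <- map(setNames(num_cols, num_cols), function(nm) {
    x <- data[[nm]][!is.na(data[[nm]])]
    if (length(x) == 0 || min(x) == max(x)) {
      e <- c(0, 1) + if (length(x)) min(x) - 0.5 else 0
    } else if (strategy == "equal-width") {
      e <- seq(min(x), max(x), length.out = n_bins + 1)
    } else {
      e <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                           type = 7, names = FALSE))
      if (length(e) < 2) e <- c(e, e + 1)
    }
    e
  })
  structure(list(columns = names(data), n_bins = as.integer(n_bins),
                 strategy = strategy, missing_token = missing_token,
                 bin_edges = edges),
            class = "binning_policy")
}

drop_record_id <- function(data) {
  if ("record_id" %in% names(data)) data$record_id <- NULL
  data
}

bin_assign <- function(x, edges) {
  k <- length(edges) - 1L
  lab <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  i <- findInterval(x[ok], edges, rightmost.closed = TRUE)
  lab[ok] <- dplyr::case_when(
    i < 1L ~ "bin_below",
    i > k ~ "bin_above",
    TRUE ~ sprintf("bin_%02d", i)
  )
  lab
}

#' Canonicalize a table for exact-match comparison
#'
#' Replaces numerics by bin labels under the policy's fixed edges, missing
#' values by the sentinel token, normalizes categorical levels to strings,
#' and fixes column order to the policy's. Two canonicalized rows match iff
#' they agree on every column, missing included.
#'
#' @param data A data frame with (at least) the policy's columns.
#' @param policy A [binning_policy()].
#' @return A tibble of character columns in the policy's column order.
#' @export
canonicalize <- function(data, policy) {
  assert_that(inherits(policy, "binning_policy"),
              "canonicalize: `policy` must be a binning_policy")
  data <- drop_record_id(as_tibble(data))
  missing_cols <- setdiff(policy$columns, names(data))
  assert_that(length(missing_cols) == 0,
              sprintf("canonicalize: data lacks policy columns: %s",
                      paste(missing_cols, collapse = ", ")))
  extra <- setdiff(names(data), policy$columns)
  assert_that(length(extra) == 0,
              sprintf("canonicalize: data has columns outside the policy: %s",
                      paste(extra, collapse = ", ")))
  out <- map(setNames(policy$columns, policy$columns), function(nm) {
    x <- data[[nm]]
    s <- if (nm %in% names(policy$bin_edges)) {
      bin_assign(as.numeric(x), policy$bin_edges[[nm]])
    } else {
      as.character(x)
    }
    s[is.na(s)] <- policy$missing_token
    s
  })
  as_tibble(out)
}
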