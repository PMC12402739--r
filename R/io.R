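#' Write a population to disk with a sidecar schema
#'
#' The records go to CSV (or Parquet when the `arrow` package is available)
#' and the variable roles, kinds, and seed to a JSON sidecar next to it, so
#' a population round-trips with its metadata.
#'
#' @param population An `sdg_population`.
#' @param path Output file path (`.csv` or `.parquet`).
#' @return `path`, invisibly.
#' @export
write_population <- function(population, path) {
  fmt <- tolower(tools::file_ext(path))
  if (fmt == "parquet") {
    assert_that(requireNamespace("arrow", quietly = TRUE),
                "write_population: the 'arrow' package is needed for Parquet")
    arrow::write_parquet(population$data, path)
  } else {
    utils::write.csv(population$data, path, row.names = FALSE)
  }
  kinds <- map_chr(population$data, function(x) {
    if (is.numeric(x)) "numeric" else "categorical"
  })
  sidecar <- list(
    name = population$spec$name,
    n_records = nrow(population$data),
    seed = population$spec$seed,
    roles = population$roles,
    kinds = as.list(kinds[setdiff(names(kinds), "record_id")])
  )
  jsonlite::write_json(sidecar, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a population written by [write_population()]
#'
#' @param path Path previously given to [write_population()].
#' @return An `sdg_population` (with a reconstructed minimal spec).
#' @export
read_population <- function(path) {
  fmt <- tolower(tools::file_ext(path))
  dat <- if (fmt == "parquet") {
    assert_that(requireNamespace("arrow", quietly = TRUE),
                "read_population: the 'arrow' package is needed for Parquet")
    as_tibble(arrow::read_parquet(path))
  } else {
    as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  }
  meta <- jsonlite::read_json(paste0(path, ".schema.json"), simplifyVector = TRUE)
  roles <- list(core = as.character(meta$roles$core),
                adjunct = as.character(meta$roles$adjunct),
                outcome = as.character(meta$roles$outcome))
  for (nm in names(meta$kinds)) {
    if (meta$kinds[[nm]] == "numeric") dat[[nm]] <- as.numeric(dat[[nm]])
  }
  structure(list(data = dat,
                 spec = structure(list(name = meta$name,
                                       n_records = meta$n_records,
                                       seed = meta$seed),
                                  class = "population_spec_stub"),
                 roles = roles),
            class = "sdg_population")
}
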