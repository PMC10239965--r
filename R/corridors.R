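#' Pool rib records into population corridors
#'
#' Pools per-subject rib records by sex, rib number and station and reports,
#' for each of the six cross-sectional properties, the across-subject mean,
#' sample standard deviation (n - 1 denominator) and contributing subject
#' count at every station. Missing stations simply do not contribute to `n`.
#'
#' @param records a tidy record table with columns `subject_id`, `sex`,
#'   `rib`, `station_pct` and the property columns `tt_ar`, `ct_ar`,
#'   `es_ar`, `i_max`, `i_min`, `i_rat` (as produced by
#'   [assemble_rib_record()] or [simulate_population()]).
#' @param grid stations to keep (default [station_grid()]); records at other
#'   stations are dropped.
#' @return A `rib_corridors` tibble with columns `sex`, `rib`, `property`,
#'   `station_pct`, `mean`, `sd`, `n`. `sd` is `NA` where only one subject
#'   contributes.
#' @export
build_corridors <- function(records, grid = station_grid()) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("empty record pool", call. = FALSE)
  }
  keep <- c("subject_id", "sex", "rib", "station_pct", names(property_columns))
  long <- records_long(records[, keep])
  long <- dplyr::filter(long, .data$station_pct %in% grid)
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$sex, .data$rib, .data$property, .data$station_pct),
    mean = mean(.data$value),
    sd = stats::sd(.data$value),
    n = dplyr::n(),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$sex, .data$rib, .data$property, .data$station_pct)
  new_rib_corridors(out)
}

new_rib_corridors <- function(x) {
  class(x) <- c("rib_corridors", class(x))
  x
}

#' Corridor band (mean +/- k SD)
#'
#' @param corridors a [build_corridors()] table.
#' @param k band half-width in standard deviations (k = 1 gives the
#'   corridors used for model audits).
#' @return The corridor tibble with `lower` and `upper` columns added;
#'   stations with undefined SD (single subject) are omitted.
#' @export
corridor_band <- function(corridors, k = 1) {
  out <- dplyr::filter(tibble::as_tibble(corridors), !is.na(.data$sd))
  dplyr::mutate(out,
    lower = .data$mean - k * .data$sd,
    upper = .data$mean + k * .data$sd
  )
}

#' Corridor CSV serialisation
#'
#' Writes/reads the corridor table in its portable CSV schema: columns
#' `sex`, `rib`, `station_pct` (one decimal), `property`, `mean`, `sd`, `n`,
#' UTF-8 with a header row. The round trip is lossless (means and SDs are
#' written at full double precision).
#'
#' @param corridors a [build_corridors()] table.
#' @param path file path.
#' @return `write_corridor_csv()` returns `path` invisibly;
#'   `read_corridor_csv()` returns a `rib_corridors` tibble.
#' @export
write_corridor_csv <- function(corridors, path) {
  out <- tibble::as_tibble(corridors)[, c("sex", "rib", "station_pct", "property",
                                          "mean", "sd", "n")]
  out$station_pct <- sprintf("%.1f", out$station_pct)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_corridor_csv
#' @export
read_corridor_csv <- function(path) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      sex = readr::col_character(),
      rib = readr::col_integer(),
      station_pct = readr::col_double(),
      property = readr::col_character(),
      mean = readr::col_double(),
      sd = readr::col_double(),
      n = readr::col_integer()
    )
  )
  pb <- readr::problems(x)
  if (nrow(pb)) {
    stop(sprintf("malformed corridor CSV: first problem at line %d (%s)",
                 pb$row[1L] + 1L, pb$expected[1L]), call. = FALSE)
  }
  required <- c("sex", "rib", "station_pct", "property", "mean", "sd", "n")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop(sprintf("corridor CSV missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  check_sex(x$sex)
  if (!all(x$property %in% property_levels)) {
    stop("corridor CSV has unknown property labels", call. = FALSE)
  }
  x$property <- factor(x$property, levels = property_levels)
  new_rib_corridors(x[, c("sex", "rib", "property", "station_pct", "mean", "sd", "n")])
}
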