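#' Per-station z-scores of a model trace against a corridor
#'
#' Standardises a model's property trace against a population corridor:
#' `z(s) = (model(s) - mean(s)) / sd(s)` on the stations shared by the trace
#' and the corridor. Stations with zero or undefined corridor SD are excluded
#' with a warning.
#'
#' @param trace a tibble with columns `station_pct` and `value` (the model's
#'   property values along the rib).
#' @param corridor corridor rows for one (sex, rib, property): columns
#'   `station_pct`, `mean`, `sd`.
#' @return A tibble with `station_pct` and `z`.
#' @export
zscore_series <- function(trace, corridor) {
  joined <- dplyr::inner_join(
    trace[, c("station_pct", "value")],
    tibble::as_tibble(corridor)[, c("station_pct", "mean", "sd")],
    by = "station_pct"
  )
  if (nrow(joined) == 0L) stop("no overlapping stations with the corridor", call. = FALSE)
  bad <- is.na(joined$sd) | joined$sd == 0
  if (any(bad)) {
    warning(sprintf("%d station(s) excluded: corridor SD undefined or zero", sum(bad)),
            call. = FALSE)
    joined <- joined[!bad, , drop = FALSE]
  }
  if (nrow(joined) == 0L) stop("no stations with defined corridor SD", call. = FALSE)
  tibble::tibble(
    station_pct = joined$station_pct,
    z = (joined$value - joined$mean) / joined$sd
  )
}

#' Summarise a z-score series into a discrepancy row
#'
#' Collapses per-station z-scores into the rib-level audit statistics: the
#' signed mean z over stations (`avg_sds`) and the percentage of rib length
#' above (`z > 1`), within (`|z| <= 1`) or below (`z < -1`) the 1 SD
#' corridor. The boundary `|z| = 1` counts as "in" (tested with a 1e-9
#' absolute tolerance so that traces constructed exactly at mean + 1 SD land
#' on the boundary, not outside it).
#'
#' @param z a [zscore_series()] tibble (or any tibble with a `z` column).
#' @param model,rib,property row metadata.
#' @return A one-row tibble with `model`, `rib`, `property`, `avg_sds`,
#'   `pct_high`, `pct_in`, `pct_low`, `n_stations`. Percentages are exact
#'   multiples of `100 / n_stations` (rounding happens only in the formatted
#'   report).
#' @export
summarize_comparison <- function(z, model = "model", rib = NA_integer_,
                                 property = NA_character_) {
  zv <- z$z
  stopifnot(length(zv) >= 1L)
  tol <- 1e-9
  high <- zv > 1 + tol
  low <- zv < -1 - tol
  tibble::tibble(
    model = model, rib = as.integer(rib), property = property,
    avg_sds = mean(zv),
    pct_high = 100 * sum(high) / length(zv),
    pct_in = 100 * sum(!high & !low) / length(zv),
    pct_low = 100 * sum(low) / length(zv),
    n_stations = length(zv)
  )
}

#' Model-versus-population comparison table
#'
#' Builds the full audit table: one row per (model, rib, property) giving the
#' average signed SD offset and the percentage of rib length above / within /
#' below the 1 SD corridor of the sex-matched population. Model ribs with no
#' matching corridor are skipped with a warning.
#'
#' @param models a tidy model record table: columns `model`, `sex`, `rib`,
#'   `station_pct` and the property columns `tt_ar` ... `i_rat` (as produced
#'   by [hbm_rib_to_record()]).
#' @param corridors a [build_corridors()] table (or [read_corridor_csv()]).
#' @return A `rib_comparison` tibble with columns `model`, `sex`, `rib`,
#'   `property`, `avg_sds`, `pct_high`, `pct_in`, `pct_low`, `n_stations`.
#' @export
comparison_table <- function(models, corridors) {
  corridors <- tibble::as_tibble(corridors)
  keep <- c("model", "sex", "rib", "station_pct", names(property_columns))
  long <- records_long(models[, keep])
  groups <- dplyr::group_split(
    dplyr::group_by(long, .data$model, .data$sex, .data$rib, .data$property)
  )
  skipped <- character(0)
  rows <- purrr::map(groups, function(g) {
    corr <- dplyr::filter(corridors,
      .data$sex == g$sex[1L], .data$rib == g$rib[1L],
      .data$property == as.character(g$property[1L])
    )
    if (nrow(corr) == 0L) {
      skipped <<- c(skipped, sprintf("%s rib %d %s", g$sex[1L], g$rib[1L], g$property[1L]))
      return(NULL)
    }
    z <- zscore_series(g, corr)
    row <- summarize_comparison(z, model = g$model[1L], rib = g$rib[1L],
                                property = as.character(g$property[1L]))
    dplyr::mutate(row, sex = g$sex[1L], .after = "model")
  })
  if (length(skipped)) {
    warning(sprintf("no corridor for %d group(s), rows skipped (first: %s)",
                    length(skipped), skipped[1L]), call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      model = character(), sex = character(), rib = integer(),
      property = character(), avg_sds = double(), pct_high = double(),
      pct_in = double(), pct_low = double(), n_stations = integer()
    )
  }
  out$property <- factor(out$property, levels = property_levels)
  out <- dplyr::arrange(out, .data$model, .data$rib, .data$property)
  class(out) <- c("rib_comparison", class(out))
  out
}

#' Format a comparison table as a fixed-width audit report
#'
#' Renders the comparison table in the conventional audit layout: models as
#' column groups, ribs as row blocks and the six properties as rows, each
#' cell giving the signed average SD offset (one decimal, explicit sign) and
#' the integer percentages of rib length high / in / low relative to the
#' 1 SD corridor. Rounded percentages may sum to 99-101.
#'
#' @param comparison a [comparison_table()] result.
#' @return A character vector of report lines (invisibly printed with
#'   `cat(..., sep = "\n")`).
#' @export
format_comparison_report <- function(comparison) {
  comp <- tibble::as_tibble(comparison)
  models <- unique(comp$model)
  header1 <- paste0(sprintf("%-8s%-7s", "", ""),
                    paste(sprintf("%-24s", models), collapse = ""))
  header2 <- paste0(sprintf("%-8s%-7s", "", ""),
                    paste(rep(sprintf("%6s%6s%6s%6s", "Avg", "high", "in", "low"),
                              length(models)), collapse = ""))
  header3 <- paste0(sprintf("%-8s%-7s", "", ""),
                    paste(rep(sprintf("%6s%6s%6s%6s", "SDs", "%", "%", "%"),
                              length(models)), collapse = ""))
  lines <- c(header1, header2, header3)
  for (rb in sort(unique(comp$rib))) {
    first <- TRUE
    for (prop in property_levels) {
      cells <- character(0)
      any_cell <- FALSE
      for (m in models) {
        row <- comp[comp$model == m & comp$rib == rb & comp$property == prop, ]
        if (nrow(row) == 0L) {
          cells <- c(cells, sprintf("%6s%6s%6s%6s", "-", "-", "-", "-"))
        } else {
          any_cell <- TRUE
          avg <- round(row$avg_sds, 1) + 0 # `+ 0` turns -0.0 into +0.0
          cells <- c(cells, sprintf("%+6.1f%6.0f%6.0f%6.0f",
                                    avg, row$pct_high, row$pct_in, row$pct_low))
        }
      }
      if (!any_cell) next
      lab <- if (first) sprintf("Rib %-4d", rb) else sprintf("%-8s", "")
      lines <- c(lines, paste0(lab, sprintf("%-7s", prop), paste(cells, collapse = "")))
      first <- FALSE
    }
  }
  lines
}

#' Comparison CSV serialisation
#'
#' Full-precision machine-readable companion to the formatted report.
#'
#' @param comparison a [comparison_table()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comparison, path) {
  out <- tibble::as_tibble(comparison)[, c("model", "sex", "rib", "property", "avg_sds",
                                           "pct_high", "pct_in", "pct_low", "n_stations")]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
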