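#' Tidy and glance methods
#'
#' broom-style accessors for the pipeline's result objects. `tidy()` returns
#' the underlying tibble (one row per corridor station or comparison row);
#' `glance()` returns a one-row-per-group summary: per (sex, rib) coverage
#' for corridors, per model overall discrepancy for comparisons.
#'
#' @param x a `rib_corridors` or `rib_comparison` object.
#' @param ... unused.
#' @name ribmorph-tidiers
NULL

#' @rdname ribmorph-tidiers
#' @method tidy rib_corridors
#' @export
tidy.rib_corridors <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname ribmorph-tidiers
#' @method glance rib_corridors
#' @export
glance.rib_corridors <- function(x, ...) {
  tbl <- tibble::as_tibble(x)
  dplyr::summarise(
    dplyr::group_by(tbl, .data$sex, .data$rib),
    n_stations = dplyr::n_distinct(.data$station_pct),
    n_properties = dplyr::n_distinct(.data$property),
    n_subjects_max = max(.data$n),
    n_subjects_min = min(.data$n),
    .groups = "drop"
  )
}

#' @rdname ribmorph-tidiers
#' @method tidy rib_comparison
#' @export
tidy.rib_comparison <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname ribmorph-tidiers
#' @method glance rib_comparison
#' @export
glance.rib_comparison <- function(x, ...) {
  tbl <- tibble::as_tibble(x)
  dplyr::summarise(
    dplyr::group_by(tbl, .data$model, .data$sex),
    n_rows = dplyr::n(),
    mean_abs_avg_sds = mean(abs(.data$avg_sds)),
    pct_in_overall = sum(.data$pct_in * .data$n_stations) / sum(.data$n_stations),
    .groups = "drop"
  )
}
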