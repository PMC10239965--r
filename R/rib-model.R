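#' Station grid along a rib
#'
#' Positions along a rib are expressed as percent of total arc length
#' ("stations"), with 0% at the vertebral (costovertebral) end and 100% at
#' the sternal end. The default grid samples every 2.5% of rib length with
#' the endpoints excluded: 2.5, 5, ..., 97.5 (39 stations).
#'
#' @param step station spacing in percent of rib length.
#' @param from,to first and last station in percent (defaults exclude the
#'   rib ends).
#' @return Numeric vector of stations, strictly increasing, all in (0, 100).
#' @export
station_grid <- function(step = 2.5, from = step, to = 100 - step) {
  s <- seq(from, to, by = step)
  if (any(s <= 0) || any(s >= 100) || any(diff(s) <= 0)) {
    stop("stations must be strictly increasing and inside (0, 100)", call. = FALSE)
  }
  s
}

#' Sample a rib midline curve at arc-length stations
#'
#' Given an ordered 3D polyline along the rib midline (vertebral end first),
#' returns the 3D point at each station's fraction of total arc length
#' (linear interpolation along the polyline) together with the local unit
#' tangent of the containing segment.
#'
#' @param curve an `n x 3` numeric matrix (or data frame) of midline points
#'   in mm, ordered vertebral to sternal.
#' @param grid stations in percent of arc length (default [station_grid()]).
#' @return A tibble with `station_pct`, point columns `x`, `y`, `z` and unit
#'   tangent columns `tx`, `ty`, `tz`.
#' @export
arc_length_stations <- function(curve, grid = station_grid()) {
  p <- as.matrix(curve)
  storage.mode(p) <- "double"
  if (ncol(p) != 3L || nrow(p) < 2L) {
    stop("degenerate curve: need an n x 3 polyline with n >= 2", call. = FALSE)
  }
  seg <- diff(p)
  len <- sqrt(rowSums(seg^2))
  if (any(len == 0)) {
    p <- p[c(TRUE, len > 0), , drop = FALSE]
    if (nrow(p) < 2L) stop("degenerate curve: zero length", call. = FALSE)
    seg <- diff(p)
    len <- sqrt(rowSums(seg^2))
  }
  if (sum(len) == 0) stop("degenerate curve: zero length", call. = FALSE)
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  target <- grid / 100 * total
  i <- findInterval(target, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(seg))
  frac <- (target - cum[i]) / len[i]
  pts <- p[i, , drop = FALSE] + seg[i, , drop = FALSE] * frac
  tan <- seg[i, , drop = FALSE] / len[i]
  tibble::tibble(
    station_pct = grid,
    x = pts[, 1L], y = pts[, 2L], z = pts[, 3L],
    tx = tan[, 1L], ty = tan[, 2L], tz = tan[, 3L]
  )
}

#' Section-plane basis at a rib station
#'
#' Builds the in-plane orthonormal basis used to express cross-section
#' contours: `e_north` points to the rib's superior aspect (the supplied up
#' hint projected off the tangent) and `e_east` to the cutaneous aspect,
#' with `(e_east, e_north, tangent)` right-handed. Left and right ribs are
#' mirrored explicitly by the caller through the choice of hint.
#'
#' @param tangent nonzero 3D tangent vector of the rib midline.
#' @param up_hint 3D vector indicating the superior direction; must not be
#'   parallel to `tangent`.
#' @return A list with unit vectors `e_north` and `e_east` (length-3).
#' @examples
#' section_frame(c(1, 0, 0), c(0, 0, 1)) # e_north (0,0,1), e_east (0,1,0)
#' @export
section_frame <- function(tangent, up_hint) {
  t_ <- tangent / sqrt(sum(tangent^2))
  h <- up_hint - sum(up_hint * t_) * t_
  hn <- sqrt(sum(h^2))
  if (hn < 1e-8 * sqrt(sum(up_hint^2))) {
    stop("up hint parallel to tangent", call. = FALSE)
  }
  e_north <- h / hn
  e_east <- c(
    e_north[2L] * t_[3L] - e_north[3L] * t_[2L],
    e_north[3L] * t_[1L] - e_north[1L] * t_[3L],
    e_north[1L] * t_[2L] - e_north[2L] * t_[1L]
  )
  list(e_north = e_north, e_east = e_east)
}

#' Assemble per-station section properties into a rib record
#'
#' Measures every provided periosteal/endosteal contour pair and returns one
#' tidy row per station. Stations whose contours fail validation are recorded
#' as missing (dropped from the record, kept in the `missing` attribute with
#' the error message) rather than aborting the rib.
#'
#' @param sections a list of `list(periosteal =, endosteal =)` contour pairs,
#'   in station order.
#' @param stations station percentages, one per section.
#' @param subject_id,sex,age,rib record metadata; `sex` must be `"M"` or
#'   `"F"`, `rib` an integer in 2..11.
#' @return A tibble with columns `subject_id`, `sex`, `age`, `rib`,
#'   `station_pct` and the six section properties plus `theta_max`,
#'   `centroid_x`, `centroid_y`; attribute `missing` is a tibble of skipped
#'   stations.
#' @export
assemble_rib_record <- function(sections, stations, subject_id, sex, age, rib) {
  stopifnot(length(sections) == length(stations))
  check_sex(sex)
  check_rib(rib)
  rows <- vector("list", length(sections))
  miss <- list()
  for (i in seq_along(sections)) {
    props <- tryCatch(
      composite_section_properties(sections[[i]]$periosteal, sections[[i]]$endosteal),
      error = function(e) conditionMessage(e)
    )
    if (is.character(props)) {
      miss[[length(miss) + 1L]] <- tibble::tibble(station_pct = stations[i], error = props)
    } else {
      rows[[i]] <- dplyr::mutate(props, station_pct = stations[i], .before = 1L)
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out,
    subject_id = subject_id, sex = sex, age = age, rib = as.integer(rib),
    .before = 1L
  )
  missing <- dplyr::bind_rows(miss)
  if (nrow(missing)) {
    warning(sprintf("rib %d: %d station(s) skipped (invalid contours)", rib, nrow(missing)),
            call. = FALSE)
  }
  attr(out, "missing") <- missing
  out
}

check_sex <- function(sex) {
  if (!all(sex %in% c("M", "F"))) stop('sex must be "M" or "F"', call. = FALSE)
  invisible(sex)
}

check_rib <- function(rib) {
  if (any(rib != as.integer(rib)) || any(rib < 2L) || any(rib > 11L)) {
    stop("rib number must be an integer in 2..11", call. = FALSE)
  }
  invisible(rib)
}

# canonical property labels used in corridors, comparisons and CSV schemas
property_levels <- c("Tt.Ar", "Ct.Ar", "Es.Ar", "Imax", "Imin", "Irat")
property_columns <- c(
  tt_ar = "Tt.Ar", ct_ar = "Ct.Ar", es_ar = "Es.Ar",
  i_max = "Imax", i_min = "Imin", i_rat = "Irat"
)

# wide per-station record -> long (property, value) with canonical labels
records_long <- function(records) {
  long <- tidyr::pivot_longer(
    records,
    cols = dplyr::all_of(names(property_columns)),
    names_to = "property", values_to = "value"
  )
  long$property <- factor(unname(property_columns[long$property]),
                          levels = property_levels)
  long
}
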