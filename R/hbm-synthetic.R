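#' Synthesise an HBM-style ring mesh that traces a population corridor
#'
#' Builds a shell-element-style rib mesh (ordered circumferential node rings
#' with thickness) whose extracted cross-sectional properties follow a
#' population corridor at a chosen signed SD offset, to exercise the mesh
#' extraction and comparison stages end to end. Rings are elliptical n-gons
#' (12 THUMS-style or 16 VIVA+/GHBMC-style nodes) placed along a straight
#' midline at the grid stations plus the two rib ends (end targets clamped
#' to the nearest station so the arc-length re-measurement reproduces the
#' targets at every grid station).
#'
#' Per ring, the node ellipse and thickness are solved by fixed-point
#' iteration through the actual extraction arithmetic (midsurface +/- t/2
#' node-normal offsets, polygon area/moment formulas) so that the extracted
#' `Tt.Ar`, `Es.Ar` and `Irat` equal `corridor mean + offset * SD` to
#' relative 1e-12. With a fixed uniform `thickness` (e.g. the 0.7 mm
#' THUMS/VIVA+ convention) only `Tt.Ar` and `Irat` are matched and the
#' cortical area follows from the thickness. `Ct.Ar`, `Imax` and `Imin` are
#' determined by the elliptical-ring family; when all offsets are zero they
#' track the corridor means closely (the family bias is second order in the
#' population noise).
#'
#' @param corridors a [build_corridors()] table containing the target sex
#'   and rib.
#' @param sex,rib which corridor to trace.
#' @param size_offset_sds named numeric of signed SD offsets for any of
#'   `Tt.Ar`, `Es.Ar`, `Irat` (missing entries default to 0).
#' @param nodes_per_ring 12 or 16 (other values >= 8 accepted).
#' @param thickness `NULL` (default) to solve per-ring thickness so `Es.Ar`
#'   hits its target, or a positive scalar for uniform shell thickness.
#' @param model_name model label carried into comparisons.
#' @param rib_length rib midline length in mm (cosmetic; stations are
#'   fractions of it).
#' @return A `ring_mesh`.
#' @export
simulate_hbm_mesh <- function(corridors, sex, rib,
                              size_offset_sds = c(Tt.Ar = 0, Es.Ar = 0, Irat = 0),
                              nodes_per_ring = 16L, thickness = NULL,
                              model_name = "synthetic", rib_length = 250) {
  check_sex(sex)
  check_rib(rib)
  stopifnot(nodes_per_ring >= 8L, is.null(thickness) || thickness > 0)
  offs <- c(Tt.Ar = 0, Es.Ar = 0, Irat = 0)
  extra <- setdiff(names(size_offset_sds), names(offs))
  if (length(extra)) {
    stop(sprintf("offsets are applied to Tt.Ar, Es.Ar and Irat only (got: %s)",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  offs[names(size_offset_sds)] <- size_offset_sds
  corr <- tibble::as_tibble(corridors)
  corr <- corr[corr$sex == sex & corr$rib == rib, ]
  if (nrow(corr) == 0L) stop(sprintf("no %s corridor for rib %d", sex, rib), call. = FALSE)
  target_for <- function(prop) {
    rows <- corr[corr$property == prop, ]
    rows <- rows[order(rows$station_pct), ]
    if (any(is.na(rows$sd))) stop("corridor SD undefined: cannot place SD offsets", call. = FALSE)
    list(station = rows$station_pct, value = rows$mean + offs[[prop]] * rows$sd)
  }
  tt <- target_for("Tt.Ar")
  es <- target_for("Es.Ar")
  ir <- target_for("Irat")
  stations <- tt$station
  # rings at the grid stations plus clamped ends
  ring_station <- c(0, stations, 100)
  clamp <- function(v) c(v[1L], v, v[length(v)])
  tt_t <- clamp(tt$value); es_t <- clamp(es$value); ir_t <- clamp(ir$value)
  phi <- 2 * pi * (seq_len(nodes_per_ring) - 1L) / nodes_per_ring
  rings <- purrr::map(seq_along(ring_station), function(i) {
    sol <- solve_ring(tt_t[i], es_t[i], ir_t[i], phi, thickness)
    nodes <- cbind(
      ring_station[i] / 100 * rib_length,
      sol$a * cos(phi),
      sol$b * sin(phi)
    )
    list(nodes = nodes, thickness = rep(sol$t, length(phi)))
  })
  new_ring_mesh(model_name, sex, as.integer(rib), rings)
}

# measure an elliptical n-gon ring with uniform thickness through the same
# arithmetic as ring_to_borders (+/- t/2 unit-bisector node offsets)
ring_measure <- function(a, b, t, phi) {
  p <- cbind(a * cos(phi), b * sin(phi))
  po <- offset_vertices(p, t / 2)
  pe <- offset_vertices(p, -t / 2)
  props <- section_props_batch(
    rbind(po[, 1L]), rbind(po[, 2L]),
    rbind(pe[, 1L]), rbind(pe[, 2L])
  )
  list(tt = props$tt_ar, es = props$es_ar, irat = props$i_rat,
       perim = sum(sqrt(rowSums((p - p[c(2:nrow(p), 1L), ])^2))))
}

solve_ring <- function(tt_t, es_t, ir_t, phi, thickness) {
  if (es_t <= 0 || es_t >= tt_t) stop("endosteal collapse: infeasible area targets", call. = FALSE)
  q <- exp(ir_t / 2)
  a_unit <- unit_polygon_area(length(phi))
  ab <- (tt_t + es_t) / 2 / a_unit
  a <- sqrt(ab * q); b <- sqrt(ab / q)
  perim0 <- sum(sqrt(rowSums((cbind(a * cos(phi), b * sin(phi)) -
                                cbind(a * cos(phi), b * sin(phi))[c(2:length(phi), 1L), ])^2)))
  t <- if (is.null(thickness)) (tt_t - es_t) / perim0 else thickness
  for (iter in seq_len(300L)) {
    if (b <= t / 2 * 1.01) stop("endosteal collapse: thickness too large for ring", call. = FALSE)
    m <- ring_measure(a, b, t, phi)
    err_tt <- tt_t / m$tt - 1
    err_ir <- ir_t - m$irat
    err_es <- if (is.null(thickness)) es_t / m$es - 1 else 0
    if (abs(err_tt) < 1e-13 && abs(err_es) < 1e-13 && abs(err_ir) < 1e-12) break
    f <- sqrt(1 + err_tt)
    g <- exp(err_ir / 4)
    a <- a * f * g
    b <- b * f / g
    if (is.null(thickness)) t <- t - (es_t - m$es) / m$perim
  }
  list(a = a, b = b, t = t)
}
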