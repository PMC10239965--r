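#' Area and centroid of a polygonal lamina
#'
#' Green's-theorem (shoelace) evaluation of the area enclosed by a contour and
#' the centroid of the enclosed solid lamina.
#'
#' @param contour a [validate_contour()] contour, or raw points accepted by it.
#' @return A list with `area` (mm^2, positive) and `centroid` (length-2, mm).
#' @examples
#' sq <- validate_contour(rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)))
#' polygon_area_centroid(sq) # area 4, centroid (0, 0)
#' @export
polygon_area_centroid <- function(contour) {
  p <- validate_contour(contour)
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  list(
    area = a,
    centroid = c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
  )
}

#' Second moments of area of a polygonal lamina
#'
#' Second moments of the enclosed solid lamina about axes through `origin`,
#' by the closed-form vertex summation for polygons. `ixx` is the moment about
#' the x-axis (integral of y^2 dA), `iyy` about the y-axis (integral of x^2
#' dA), and `ixy` the product moment.
#'
#' @inheritParams polygon_area_centroid
#' @param origin length-2 numeric, the axis origin in mm (default `c(0, 0)`).
#' @return Named numeric vector `c(ixx, iyy, ixy)` in mm^4.
#' @examples
#' sq <- validate_contour(rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)))
#' polygon_second_moments(sq) # ixx = iyy = 2 * 2^3 / 12, ixy = 0
#' @export
polygon_second_moments <- function(contour, origin = c(0, 0)) {
  p <- validate_contour(contour)
  x <- p[, 1L] - origin[1L]; y <- p[, 2L] - origin[2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  c(
    ixx = sum((y * y + y * yn + yn * yn) * cr) / 12,
    iyy = sum((x * x + x * xn + xn * xn) * cr) / 12,
    ixy = sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  )
}

#' Cross-sectional properties of a hollow (cortical ring) section
#'
#' Computes the standard cortical bone cross-section measures from a
#' periosteal (outer) and endosteal (inner) border pair: total sub-periosteal
#' area `tt_ar`, endosteal area `es_ar`, cortical area `ct_ar = tt_ar -
#' es_ar`, the ring's principal (`i_max`) and secondary (`i_min`) second
#' moments of area about axes through the ring's own composite centroid,
#' `i_rat = ln(i_max / i_min)`, and the principal-axis angle `theta_max`
#' (radians in (-pi/2, pi/2]; the axis about which the moment is maximal).
#'
#' Ring moments are outer-polygon minus inner-polygon moments evaluated about
#' the composite centroid (equivalent to the parallel-axis transfer of each
#' lamina). When the two principal moments coincide to relative 1e-12 the
#' orientation is undefined; `theta_max` is reported as 0 and `i_rat` as
#' exactly 0.
#'
#' @param periosteal,endosteal outer and inner contours ([validate_contour()]
#'   inputs); the endosteal contour must lie strictly inside the periosteal.
#' @return A one-row [tibble::tibble()] with columns `tt_ar`, `ct_ar`,
#'   `es_ar` (mm^2), `i_max`, `i_min` (mm^4), `i_rat`, `theta_max`,
#'   `centroid_x`, `centroid_y` (mm).
#' @examples
#' outer <- regular_polygon_contour(64, 10)
#' inner <- regular_polygon_contour(64, 8)
#' composite_section_properties(outer, inner) # near-annulus: i_rat ~ 0
#' @export
composite_section_properties <- function(periosteal, endosteal) {
  po <- validate_contour(periosteal)
  pi_ <- validate_contour(endosteal)
  if (!all(points_in_polygon(pi_[, 1L], pi_[, 2L], po))) {
    stop("endosteal outside periosteal", call. = FALSE)
  }
  if (contours_cross(po, pi_)) stop("contours intersect", call. = FALSE)
  props <- section_props_batch(
    rbind(po[, 1L]), rbind(po[, 2L]),
    rbind(pi_[, 1L]), rbind(pi_[, 2L])
  )
  props
}

contours_cross <- function(a, b) {
  # called after the vertex-containment check: a convex polygon whose
  # vertices all lie inside a convex outer cannot cross it
  if (is_convex_polygon(a) && is_convex_polygon(b)) return(FALSE)
  x1 <- a[, 1L]; y1 <- a[, 2L]
  x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
  u1 <- b[, 1L]; v1 <- b[, 2L]
  u2 <- c(u1[-1L], u1[1L]); v2 <- c(v1[-1L], v1[1L])
  for (i in seq_along(x1)) {
    if (any(segments_intersect(x1[i], y1[i], x2[i], y2[i], u1, v1, u2, v2))) {
      return(TRUE)
    }
  }
  FALSE
}

# Vectorised hollow-section properties for N sections sharing vertex counts:
# xo, yo are N x m matrices of outer vertices (CCW), xi, yi N x k inner.
# This is the same Green's-theorem arithmetic as the scalar path, evaluated
# row-wise; composite_section_properties() is its one-row case.
section_props_batch <- function(xo, yo, xi, yi) {
  tibble::as_tibble(section_props_core(xo, yo, xi, yi))
}

# same computation returning a plain list of columns (hot path: no tibble
# construction per call)
section_props_core <- function(xo, yo, xi, yi) {
  shoe <- function(x, y) {
    m <- ncol(x)
    idx <- c(seq_len(m)[-1L], 1L)
    xn <- x[, idx, drop = FALSE]; yn <- y[, idx, drop = FALSE]
    cr <- x * yn - xn * y
    a <- rowSums(cr) / 2
    list(
      a = a,
      cx = rowSums((x + xn) * cr) / (6 * a),
      cy = rowSums((y + yn) * cr) / (6 * a)
    )
  }
  mom <- function(x, y, cx, cy) {
    m <- ncol(x)
    idx <- c(seq_len(m)[-1L], 1L)
    x <- x - cx; y <- y - cy
    xn <- x[, idx, drop = FALSE]; yn <- y[, idx, drop = FALSE]
    cr <- x * yn - xn * y
    list(
      ixx = rowSums((y * y + y * yn + yn * yn) * cr) / 12,
      iyy = rowSums((x * x + x * xn + xn * xn) * cr) / 12,
      ixy = rowSums((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
    )
  }
  so <- shoe(xo, yo); si <- shoe(xi, yi)
  ct <- so$a - si$a
  cx <- (so$a * so$cx - si$a * si$cx) / ct
  cy <- (so$a * so$cy - si$a * si$cy) / ct
  mo <- mom(xo, yo, cx, cy); mi <- mom(xi, yi, cx, cy)
  ixx <- mo$ixx - mi$ixx
  iyy <- mo$iyy - mi$iyy
  ixy <- mo$ixy - mi$ixy
  avg <- (ixx + iyy) / 2
  dif <- (ixx - iyy) / 2
  rad <- sqrt(dif * dif + ixy * ixy)
  i_max <- avg + rad
  i_min <- avg - rad
  tie <- rad <= 1e-12 * avg
  theta <- ifelse(tie, 0, atan2(-ixy, dif) / 2)
  i_rat <- ifelse(tie, 0, log(i_max / i_min))
  list(
    tt_ar = so$a, ct_ar = ct, es_ar = si$a,
    i_max = i_max, i_min = i_min, i_rat = i_rat,
    theta_max = theta, centroid_x = cx, centroid_y = cy
  )
}

#' Offset a contour along its outward vertex normals
#'
#' Moves every vertex outward along the angle bisector of its two adjacent
#' edge normals. Positive `delta` dilates the contour, negative `delta`
#' erodes it. Two corner conventions are provided:
#'
#' * `corner = "miter"` (default): the mitered offset, displacement
#'   `delta / cos(theta/2)` where `theta` is the corner turn angle, so every
#'   edge line moves outward by exactly `delta`. This is the polygon analogue
#'   of boundary (Minkowski) dilation and is used for the segmentation-bias
#'   demonstration; for convex polygons the area increase is
#'   `delta * P + delta^2 * sum(tan(theta/2))`, slightly above the rounded
#'   Minkowski value `delta * P + pi * delta^2`.
#' * `corner = "vertex"`: the node-displacement convention, each vertex moved
#'   by exactly `delta` along the unit bisector. This is how shell-element
#'   node rings are offset by their half-thickness (the node carries the
#'   thickness, not the edge): a regular-polygon ring with vertex radius `r`
#'   maps to vertex radius `r + delta` exactly.
#'
#' The two coincide as the vertex density grows (turn angles go to zero).
#'
#' @inheritParams polygon_area_centroid
#' @param delta offset in mm (scalar, or one value per vertex).
#' @param corner `"miter"` or `"vertex"` (see above).
#' @return The offset contour (validated, CCW). Erosions that invert or
#'   self-intersect the polygon raise "offset collapses contour".
#' @examples
#' circ <- regular_polygon_contour(256, 5)
#' attr(offset_contour(circ, 0.42), "area") / attr(circ, "area") # ~ (5.42/5)^2
#' @export
offset_contour <- function(contour, delta, corner = c("miter", "vertex")) {
  corner <- match.arg(corner)
  p <- validate_contour(contour)
  n <- nrow(p)
  if (!length(delta) %in% c(1L, n)) {
    stop("delta must be a scalar or one value per vertex", call. = FALSE)
  }
  if (all(delta == 0)) return(p)
  q <- offset_vertices(unclass(p), delta, corner = corner)
  # a collapsed erosion can invert the polygon while staying "simple":
  # require every edge to keep its direction
  e_old <- rbind(p[-1L, ], p[1L, ]) - p
  e_new <- rbind(q[-1L, ], q[1L, ]) - q
  if (any(rowSums(e_old * e_new) <= 0)) stop("offset collapses contour", call. = FALSE)
  out <- tryCatch(validate_contour(q), error = function(e) NULL)
  if (is.null(out) || signed_area(q) <= 0) {
    stop("offset collapses contour", call. = FALSE)
  }
  out
}

offset_vertices <- function(p, delta, corner = "vertex") {
  x <- p[, 1L]; y <- p[, 2L]
  n <- length(x)
  ex <- c(x[-1L], x[1L]) - x
  ey <- c(y[-1L], y[1L]) - y
  len <- sqrt(ex * ex + ey * ey)
  # outward edge normals for CCW polygons
  nx <- ey / len
  ny <- -ex / len
  # vertex i joins edge i-1 and edge i
  pxn <- c(nx[n], nx[-n]); pyn <- c(ny[n], ny[-n])
  bx <- nx + pxn; by <- ny + pyn
  if (corner == "miter") {
    # |n1 + n2|^2 = 2 (1 + n1.n2); displacement delta / cos(theta/2)
    denom <- 1 + nx * pxn + ny * pyn
    if (any(denom < 1e-9)) stop("offset collapses contour", call. = FALSE)
    cbind(x + delta * bx / denom, y + delta * by / denom)
  } else {
    bl <- sqrt(bx * bx + by * by)
    if (any(bl < 1e-9)) stop("offset collapses contour", call. = FALSE)
    cbind(x + delta * bx / bl, y + delta * by / bl)
  }
}

#' Brute-force rasterisation oracle for hollow-section properties
#'
#' Samples a regular pixel grid over the periosteal bounding box and
#' classifies pixel centres by point-in-polygon tests, then accumulates pixel
#' sums for areas, the cortical-ring centroid, and second moments (each pixel
#' contributes its own `pixel^4 / 12` self-moment). Deliberately independent
#' of the closed-form polygon formulas; intended as a test oracle, not for
#' production use.
#'
#' @inheritParams composite_section_properties
#' @param pixel pixel edge length in mm (> 0).
#' @return A list with `tt_ar`, `ct_ar`, `es_ar`, `i_max`, `i_min`, `i_rat`,
#'   `centroid_x`, `centroid_y`.
#' @export
rasterize_section <- function(periosteal, endosteal, pixel) {
  stopifnot(pixel > 0)
  po <- validate_contour(periosteal)
  pi_ <- validate_contour(endosteal)
  xr <- range(po[, 1L]); yr <- range(po[, 2L])
  gx <- seq(xr[1L] - pixel / 2, xr[2L] + pixel / 2, by = pixel)
  gy <- seq(yr[1L] - pixel / 2, yr[2L] + pixel / 2, by = pixel)
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  in_o <- points_in_polygon(px, py, po)
  px <- px[in_o]; py <- py[in_o]
  in_i <- points_in_polygon(px, py, pi_)
  a_pix <- pixel * pixel
  tt <- sum(in_o) * a_pix # count of retained outer pixels
  es <- sum(in_i) * a_pix
  rx <- px[!in_i]; ry <- py[!in_i]
  ct <- length(rx) * a_pix
  cx <- mean(rx); cy <- mean(ry)
  self <- a_pix * a_pix / 12
  ixx <- sum((ry - cy)^2) * a_pix + length(rx) * self
  iyy <- sum((rx - cx)^2) * a_pix + length(rx) * self
  ixy <- sum((rx - cx) * (ry - cy)) * a_pix
  avg <- (ixx + iyy) / 2
  rad <- sqrt(((ixx - iyy) / 2)^2 + ixy^2)
  list(
    tt_ar = tt, ct_ar = ct, es_ar = es,
    i_max = avg + rad, i_min = avg - rad,
    i_rat = log((avg + rad) / (avg - rad)),
    centroid_x = cx, centroid_y = cy
  )
}

#' Regular and elliptical polygon contours
#'
#' Convenience constructors for discretised circles and ellipses used
#' throughout the synthetic generator, the mesh builder and the tests.
#' `ellipse_contour(a, b, ...)` is the affine image of a regular `n`-gon, so
#' its polygon area is `a * b * n * sin(2 * pi / n) / 2`.
#'
#' @param n number of vertices.
#' @param r vertex radius in mm.
#' @param a,b semi-axes in mm along x and y before rotation.
#' @param rot rotation angle in radians.
#' @param center length-2 centre in mm.
#' @return A validated contour.
#' @export
regular_polygon_contour <- function(n, r, center = c(0, 0)) {
  ellipse_contour(n, r, r, center = center)
}

#' @rdname regular_polygon_contour
#' @export
ellipse_contour <- function(n, a, b, rot = 0, center = c(0, 0)) {
  phi <- 2 * pi * (seq_len(n) - 1L) / n
  x0 <- a * cos(phi); y0 <- b * sin(phi)
  validate_contour(cbind(
    center[1L] + x0 * cos(rot) - y0 * sin(rot),
    center[2L] + x0 * sin(rot) + y0 * cos(rot)
  ))
}
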