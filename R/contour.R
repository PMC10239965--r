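#' Planar contours
#'
#' A contour is a closed, simple (non-self-intersecting) polygon in the
#' cross-section plane, stored as an `n x 2` numeric matrix of vertex
#' coordinates in millimetres, closed by convention (the last vertex connects
#' back to the first; the first vertex is not repeated). On validation the
#' orientation is normalised to counter-clockwise (positive signed area), so
#' downstream signed-area formulas never depend on input winding.
#'
#' @param points a two-column numeric matrix or data frame of `(x, y)`
#'   vertex coordinates in mm, in order around the border.
#' @return An object of class `rib_contour`: the CCW-normalised vertex matrix.
#' @details Validation removes an exactly repeated closing vertex and exact
#'   consecutive duplicates, then requires at least 3 distinct vertices,
#'   strictly positive enclosed area, and simplicity. A convex polygon is
#'   accepted by an O(n) turning test; non-convex polygons fall back to a
#'   pairwise segment-intersection test.
#' @examples
#' sq <- validate_contour(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0))) # CW input
#' attr(sq, "area") # +1, orientation normalised
#' @export
validate_contour <- function(points) {
  if (inherits(points, "rib_contour")) return(points)
  p <- as_xy_matrix(points)
  if (nrow(p) < 3L) stop("degenerate contour: fewer than 3 points", call. = FALSE)
  # drop exact closing repeat and exact consecutive duplicates
  if (all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  nxt <- rbind(p[-1L, , drop = FALSE], p[1L, , drop = FALSE])
  dup <- (p[, 1L] == nxt[, 1L]) & (p[, 2L] == nxt[, 2L])
  if (any(dup)) p <- p[!dup, , drop = FALSE]
  if (nrow(p) < 3L) stop("degenerate contour: fewer than 3 distinct points", call. = FALSE)
  if (!is_simple_polygon(p)) stop("invalid contour: self-intersecting", call. = FALSE)
  a <- signed_area(p)
  scale2 <- max(diff(range(p[, 1L])), diff(range(p[, 2L])))^2
  if (abs(a) <= 1e-12 * max(scale2, .Machine$double.xmin)) {
    stop("degenerate contour: zero area", call. = FALSE)
  }
  if (a < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  structure(p, class = "rib_contour", area = abs(a))
}

as_xy_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, 1:2])
  if (!is.matrix(points) || ncol(points) < 2L) {
    stop("contour points must be an n x 2 matrix or data frame", call. = FALSE)
  }
  p <- unname(points[, 1:2, drop = FALSE])
  storage.mode(p) <- "double"
  if (anyNA(p) || any(!is.finite(p))) stop("contour points must be finite", call. = FALSE)
  p
}

signed_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# convex polygons (either winding, allowing collinear runs) are simple; O(n)
is_convex_polygon <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  n <- length(x)
  xp <- c(x[n], x[-n]); yp <- c(y[n], y[-n])
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- (x - xp) * (yn - y) - (y - yp) * (xn - x)
  tol <- 1e-12 * max(abs(cr))
  if (any(cr < -tol) && any(cr > tol)) return(FALSE)
  # total turning must be one full revolution (rules out multiply-wound polygons)
  ang <- sum(atan2(cr, (x - xp) * (xn - x) + (y - yp) * (yn - y)))
  abs(abs(ang) - 2 * pi) < 1e-6
}

is_simple_polygon <- function(p) {
  n <- nrow(p)
  if (n == 3L) return(TRUE)
  if (is_convex_polygon(p)) return(TRUE)
  x1 <- p[, 1L]; y1 <- p[, 2L]
  x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
  for (i in seq_len(n - 2L)) {
    # candidate edges j > i, non-adjacent (skip j = i + 1; skip j = n when i = 1)
    j <- seq.int(i + 2L, n)
    if (i == 1L) j <- j[j != n]
    if (!length(j)) next
    if (any(segments_intersect(
      x1[i], y1[i], x2[i], y2[i],
      x1[j], y1[j], x2[j], y2[j]
    ))) {
      return(FALSE)
    }
  }
  TRUE
}

# vectorised proper-or-touching intersection of segment (ax,ay)-(bx,by)
# against segments (cx,cy)-(dx,dy)
segments_intersect <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  d1 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d2 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
  d3 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
  d4 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
  proper <- (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
               ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
  onseg <- function(px, py, qx, qy, rx, ry) {
    # r collinear with p-q; is r within the box?
    rx >= pmin(px, qx) & rx <= pmax(px, qx) & ry >= pmin(py, qy) & ry <= pmax(py, qy)
  }
  touching <- (d1 == 0 & onseg(ax, ay, bx, by, cx, cy)) |
    (d2 == 0 & onseg(ax, ay, bx, by, dx, dy)) |
    (d3 == 0 & onseg(cx, cy, dx, dy, ax, ay)) |
    (d4 == 0 & onseg(cx, cy, dx, dy, bx, by))
  proper | touching
}

# even-odd point-in-polygon, vectorised over points
points_in_polygon <- function(px, py, p) {
  x <- p[, 1L]; y <- p[, 2L]
  n <- length(x)
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  inside <- logical(length(px))
  for (i in seq_len(n)) {
    crosses <- (y[i] > py) != (yn[i] > py)
    if (any(crosses)) {
      xint <- x[i] + (py - y[i]) * (xn[i] - x[i]) / (yn[i] - y[i])
      inside <- xor(inside, crosses & (px < xint))
    }
  }
  inside
}

#' @export
print.rib_contour <- function(x, ...) {
  cat(sprintf("<rib_contour: %d vertices, area %.4f mm^2 (CCW)>\n",
              nrow(x), attr(x, "area")))
  invisible(x)
}
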