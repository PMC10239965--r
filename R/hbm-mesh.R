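#' Read and write shell-element rib ring meshes (neutral JSON)
#'
#' Human-body-model rib cortical shells are exchanged in a neutral JSON
#' format: `{"model": str, "sex": "M"|"F", "rib": int, "rings": [{"nodes":
#' [[x, y, z], ...], "thickness": scalar-or-list}, ...]}`. Rings are ordered
#' along the rib (vertebral end first) and each ring's nodes are ordered
#' around the circumference. A scalar thickness is broadcast to all nodes of
#' the ring (the THUMS/VIVA+ uniform-thickness convention, e.g. 0.7 mm);
#' per-node lists carry GHBMC-style spatially varying thickness (per-element
#' values averaged onto nodes upstream). Parsing native FE keyword decks is
#' out of scope.
#'
#' @param path JSON file path.
#' @return A `ring_mesh` object: list with `model`, `sex`, `rib` and
#'   `rings`, each ring a list with `nodes` (k x 3 matrix, mm) and
#'   `thickness` (length-k vector, mm).
#' @export
read_ring_mesh <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("model", "sex", "rib", "rings")) {
    if (is.null(raw[[field]])) {
      stop(sprintf("ring mesh JSON missing field '%s'", field), call. = FALSE)
    }
  }
  check_sex(raw$sex)
  rings <- purrr::map(raw$rings, function(r) {
    nodes <- do.call(rbind, purrr::map(r$nodes, function(pt) {
      if (length(pt) != 3L) stop("ring mesh nodes must be [x, y, z] triples", call. = FALSE)
      as.numeric(pt)
    }))
    list(nodes = nodes, thickness = as.numeric(unlist(r$thickness)))
  })
  new_ring_mesh(raw$model, raw$sex, raw$rib, rings)
}

new_ring_mesh <- function(model, sex, rib, rings) {
  if (length(rings) < 2L) stop("ring mesh needs at least 2 rings", call. = FALSE)
  counts <- purrr::map_int(rings, ~ nrow(.x$nodes))
  if (length(unique(counts)) != 1L) {
    stop("inconsistent ring sizes: all rings must have the same node count", call. = FALSE)
  }
  if (counts[1L] < 3L) stop("rings need at least 3 nodes", call. = FALSE)
  rings <- purrr::map(rings, function(r) {
    if (length(r$thickness) == 1L) r$thickness <- rep(r$thickness, nrow(r$nodes))
    r
  })
  for (r in rings) {
    if (length(r$thickness) != nrow(r$nodes)) {
      stop("thickness must be scalar or one value per node", call. = FALSE)
    }
    if (any(!is.finite(r$thickness)) || any(r$thickness <= 0)) {
      stop("nonpositive thickness", call. = FALSE)
    }
    if (any(!is.finite(r$nodes))) stop("non-finite node coordinates", call. = FALSE)
  }
  structure(
    list(model = model, sex = sex, rib = as.integer(rib), rings = rings,
         nodes_per_ring = counts[1L]),
    class = "ring_mesh"
  )
}

#' @rdname read_ring_mesh
#' @param mesh a `ring_mesh` object.
#' @export
write_ring_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "ring_mesh"))
  obj <- list(
    model = mesh$model, sex = mesh$sex, rib = mesh$rib,
    rings = purrr::map(mesh$rings, function(r) {
      th <- if (length(unique(r$thickness)) == 1L) r$thickness[1L] else r$thickness
      list(nodes = purrr::map(seq_len(nrow(r$nodes)), ~ r$nodes[.x, ]),
           thickness = th)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.ring_mesh <- function(x, ...) {
  cat(sprintf("<ring_mesh '%s': sex %s, rib %d, %d rings x %d nodes>\n",
              x$model, x$sex, x$rib, length(x$rings), x$nodes_per_ring))
  invisible(x)
}

#' Periosteal/endosteal borders from one node ring
#'
#' Projects a circumferential ring of shell nodes into its section plane and
#' offsets the projected polygon node-wise by the shell thickness to obtain
#' the cortical bone borders. Under the default midsurface convention the
#' nodes sit on the shell midsurface and the periosteal/endosteal borders
#' are the +/- thickness/2 offsets; `node_surface = "outer"` treats nodes as
#' the periosteal surface (endosteal = inward offset by the full thickness),
#' `"inner"` the reverse.
#'
#' @param nodes k x 3 matrix of ring node coordinates (mm), ordered around
#'   the circumference.
#' @param thickness shell thickness in mm: scalar or one value per node.
#' @param frame optional [section_frame()] basis (`list(e_north, e_east)`).
#'   When `NULL`, the least-squares plane of the nodes (principal plane of
#'   the centred coordinates) is used, since FE rings need not be planar.
#' @param node_surface `"mid"` (default), `"outer"` or `"inner"`.
#' @return A list with `periosteal` and `endosteal` contours (2D, in the
#'   section plane) and `center` (the 3D ring centroid).
#' @export
ring_to_borders <- function(nodes, thickness, frame = NULL,
                            node_surface = c("mid", "outer", "inner")) {
  node_surface <- match.arg(node_surface)
  nodes <- as.matrix(nodes)
  k <- nrow(nodes)
  if (length(thickness) == 1L) thickness <- rep(thickness, k)
  stopifnot(length(thickness) == k, all(thickness > 0))
  center <- colMeans(nodes)
  centered <- sweep(nodes, 2L, center)
  if (is.null(frame)) {
    sv <- svd(centered, nu = 0L, nv = 3L)
    e1 <- sv$v[, 1L]; e2 <- sv$v[, 2L]
  } else {
    e1 <- frame$e_east; e2 <- frame$e_north
  }
  u <- centered %*% e1
  v <- centered %*% e2
  poly <- cbind(as.numeric(u), as.numeric(v))
  # normalise winding so outward offsets dilate; keep thickness aligned
  if (signed_area(poly) < 0) {
    poly <- poly[rev(seq_len(k)), , drop = FALSE]
    thickness <- rev(thickness)
  }
  mid <- validate_contour(poly)
  if (nrow(mid) != k) stop("ring projects to a degenerate polygon", call. = FALSE)
  deltas <- switch(node_surface,
    mid = c(0.5, -0.5),
    outer = c(0, -1),
    inner = c(1, 0)
  )
  off <- function(d) {
    if (d == 0) return(mid)
    out <- tryCatch(offset_contour(mid, d * thickness, corner = "vertex"),
                    error = function(e) NULL)
    if (is.null(out)) stop("endosteal collapse: thickness too large for ring", call. = FALSE)
    out
  }
  list(
    periosteal = off(deltas[1L]),
    endosteal = off(deltas[2L]),
    center = center
  )
}

#' Measure an HBM rib mesh into a station-indexed record
#'
#' Treats the ring centroids as the rib midline, assigns each ring an
#' arc-length station (0% at the first ring, 100% at the last), measures the
#' cross-sectional properties of each ring's offset borders, and linearly
#' interpolates every property trace onto the requested station grid
#' (clamped at the terminal rings; no extrapolation). Each property is
#' interpolated independently, so interpolated `i_rat` is the interpolant of
#' the per-ring log-ratios.
#'
#' @param mesh a [read_ring_mesh()] mesh.
#' @param grid target stations (default [station_grid()]).
#' @param node_surface passed to [ring_to_borders()].
#' @param up_hint superior-direction hint for the per-ring section frames;
#'   set `NULL` (default) to use each ring's least-squares plane.
#' @return A tibble with `model`, `sex`, `rib`, `station_pct` and the
#'   property columns, one row per grid station.
#' @export
hbm_rib_to_record <- function(mesh, grid = station_grid(),
                              node_surface = c("mid", "outer", "inner"),
                              up_hint = NULL) {
  stopifnot(inherits(mesh, "ring_mesh"))
  node_surface <- match.arg(node_surface)
  n_rings <- length(mesh$rings)
  centers <- matrix(unlist(purrr::map(mesh$rings, ~ colMeans(.x$nodes))),
                    ncol = 3L, byrow = TRUE)
  seg <- diff(centers)
  len <- sqrt(rowSums(seg^2))
  if (any(len == 0)) stop("coincident ring centroids", call. = FALSE)
  cum <- c(0, cumsum(len))
  ring_station <- cum / cum[n_rings] * 100
  props <- purrr::map_dfr(seq_len(n_rings), function(i) {
    ring <- mesh$rings[[i]]
    frame <- NULL
    if (!is.null(up_hint)) {
      tangent <- if (i == 1L) seg[1L, ] else if (i == n_rings) seg[n_rings - 1L, ] else
        seg[i - 1L, ] + seg[i, ]
      frame <- section_frame(tangent, up_hint)
    }
    borders <- tryCatch(
      ring_to_borders(ring$nodes, ring$thickness, frame = frame,
                      node_surface = node_surface),
      error = function(e) stop(sprintf("ring %d: %s", i, conditionMessage(e)), call. = FALSE)
    )
    composite_section_properties(borders$periosteal, borders$endosteal)
  })
  out <- purrr::map_dfc(names(property_columns), function(col) {
    tibble::as_tibble_col(
      stats::approx(ring_station, props[[col]], xout = grid, rule = 2)$y,
      column_name = col
    )
  })
  dplyr::mutate(out,
    model = mesh$model, sex = mesh$sex, rib = mesh$rib, station_pct = grid,
    .before = 1L
  )
}
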