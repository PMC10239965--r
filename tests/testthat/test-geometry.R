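test_that("polygon area and centroid match closed forms", {
  sq <- validate_contour(rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)))
  ac <- polygon_area_centroid(sq)
  expect_equal(ac$area, 4)
  expect_equal(ac$centroid, c(0, 0))

  # regular 16-gon, vertex radius R: area = (1/2) n R^2 sin(2 pi / n)
  R <- 3.7
  g16 <- regular_polygon_contour(16, R)
  expect_equal(polygon_area_centroid(g16)$area, 0.5 * 16 * R^2 * sin(2 * pi / 16),
               tolerance = 1e-12)
})

test_that("random simple polygon area agrees with the pixel-count oracle", {
  set.seed(7)
  phi <- sort(runif(12, 0, 2 * pi))
  r <- runif(12, 2, 4)
  poly <- validate_contour(cbind(r * cos(phi), r * sin(phi)))
  tiny <- regular_polygon_contour(8, 0.05) # negligible inner hole for the ring oracle
  oracle <- rasterize_section(poly, tiny, pixel = 0.05)
  expect_equal(polygon_area_centroid(poly)$area, oracle$tt_ar, tolerance = 5e-3)
})

test_that("second moments match closed forms and the parallel-axis law", {
  sq <- validate_contour(rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)))
  m <- polygon_second_moments(sq)
  expect_equal(unname(m), c(2 * 2^3 / 12, 2 * 2^3 / 12, 0))

  # solid ellipse a=3, b=1 at 4096 vertices: ixx ~ pi a b^3 / 4, iyy ~ pi a^3 b / 4
  ell <- ellipse_contour(4096, 3, 1)
  m <- polygon_second_moments(ell)
  expect_equal(m[["ixx"]], pi * 3 * 1^3 / 4, tolerance = 1e-5)
  expect_equal(m[["iyy"]], pi * 3^3 * 1 / 4, tolerance = 1e-5)
  expect_equal(m[["ixy"]], 0, tolerance = 1e-12)

  # origin shift: iyy picks up A d^2
  m2 <- polygon_second_moments(sq, origin = c(1, 0))
  expect_equal(m2[["iyy"]], 2 * 2^3 / 12 + 4 * 1^2)
  expect_equal(m2[["ixx"]], 2 * 2^3 / 12)
})

test_that("hollow-section properties match annulus and elliptical closed forms", {
  ann <- annulus_section(10, 8, n = 4096)
  p <- composite_section_properties(ann$periosteal, ann$endosteal)
  expect_equal(p$tt_ar, pi * 100, tolerance = 1e-5)
  expect_equal(p$es_ar, pi * 64, tolerance = 1e-5)
  expect_equal(p$ct_ar, pi * 36, tolerance = 1e-5)
  expect_equal(p$i_max, pi * (10^4 - 8^4) / 4, tolerance = 1e-5)
  expect_equal(p$i_min, pi * (10^4 - 8^4) / 4, tolerance = 1e-5)
  expect_lt(abs(p$i_rat), 1e-9)
  expect_equal(p$tt_ar, p$ct_ar + p$es_ar, tolerance = 1e-12)

  # concentric elliptical annulus outer (3,2), inner (2,1)
  o <- ellipse_contour(4096, 3, 2)
  i <- ellipse_contour(4096, 2, 1)
  p <- composite_section_properties(o, i)
  expect_equal(p$ct_ar, 4 * pi, tolerance = 1e-5)
  expect_equal(p$i_min, pi * (3 * 2^3 - 2 * 1^3) / 4, tolerance = 1e-5)
  expect_equal(p$i_max, pi * (3^3 * 2 - 2^3 * 1) / 4, tolerance = 1e-5)
  expect_equal(p$i_rat, log(46 / 22), tolerance = 1e-5)
  # elongated along x: max-moment axis is y (sign of the +/- pi/2 boundary
  # is fp-indeterminate for symmetric sections; compare the axis)
  expect_equal(abs(p$theta_max), pi / 2, tolerance = 1e-6)
})

test_that("off-centre hollow sections use the composite centroid", {
  o <- regular_polygon_contour(2048, 5)
  i <- regular_polygon_contour(2048, 2, center = c(1, 0))
  p <- composite_section_properties(o, i)
  expect_equal(p$centroid_x, -4 / 21, tolerance = 1e-6)
  expect_equal(p$centroid_y, 0, tolerance = 1e-9)
  oracle <- rasterize_section(o, i, pixel = 0.02)
  expect_equal(p$i_max, oracle$i_max, tolerance = 5e-3)
  expect_equal(p$i_min, oracle$i_min, tolerance = 5e-3)
})

test_that("containment violations are rejected", {
  o <- regular_polygon_contour(64, 5)
  expect_error(
    composite_section_properties(o, regular_polygon_contour(64, 2, center = c(4.5, 0))),
    "endosteal outside periosteal"
  )
  expect_error(
    composite_section_properties(o, regular_polygon_contour(3, 4.999, center = c(2.5, 0))),
    "endosteal outside periosteal|contours intersect"
  )
})

test_that("contour offsetting dilates and erodes as expected", {
  c5 <- regular_polygon_contour(4096, 5)
  dil <- offset_contour(c5, 0.42)
  expect_equal(attr(dil, "area") / attr(c5, "area"), (5.42 / 5)^2, tolerance = 1e-6)

  # node-displacement convention: vertex radius grows by exactly delta
  g16 <- regular_polygon_contour(16, 5)
  v16 <- offset_contour(g16, 0.35, corner = "vertex")
  expect_equal(attr(v16, "area"), 8 * sin(2 * pi / 16) * 5.35^2, tolerance = 1e-12)

  expect_identical(offset_contour(c5, 0), c5)

  ero <- offset_contour(c5, -1)
  expect_equal(attr(ero, "area") / attr(c5, "area"), (4 / 5)^2, tolerance = 1e-6)

  # erosion beyond the inradius collapses
  expect_error(offset_contour(regular_polygon_contour(32, 1), -1.5),
               "offset collapses contour")
})

test_that("convex polygon dilation follows the Minkowski area formula", {
  set.seed(11)
  for (rep in 1:5) {
    phi <- sort(2 * pi * (0:5) / 6 + runif(6, -0.25, 0.25))
    hexa <- validate_contour(cbind(5 * cos(phi), 5 * sin(phi)))
    delta <- 0.3
    grown <- offset_contour(hexa, delta)
    P <- shoelace_perimeter(hexa)
    predicted <- delta * P + pi * delta^2
    actual <- attr(grown, "area") - attr(hexa, "area")
    expect_equal(actual, predicted, tolerance = 1e-2)
  }
})

test_that("properties are invariant to rigid transforms and scale correctly", {
  set.seed(23)
  for (rep in 1:8) {
    sec <- random_star_section(n = 64)
    p0 <- composite_section_properties(sec$periosteal, sec$endosteal)
    ang <- runif(1, 0, 2 * pi)
    shift <- runif(2, -30, 30)
    p1 <- composite_section_properties(
      rigid_transform(sec$periosteal, ang, shift),
      rigid_transform(sec$endosteal, ang, shift)
    )
    for (col in c("tt_ar", "ct_ar", "es_ar", "i_max", "i_min")) {
      expect_equal(p1[[col]], p0[[col]], tolerance = 1e-9)
    }
    expect_equal(p1$i_rat, p0$i_rat, tolerance = 1e-8)

    s <- runif(1, 0.3, 3)
    p2 <- composite_section_properties(unclass(sec$periosteal) * s,
                                       unclass(sec$endosteal) * s)
    expect_equal(p2$tt_ar, p0$tt_ar * s^2, tolerance = 1e-9)
    expect_equal(p2$i_max, p0$i_max * s^4, tolerance = 1e-9)
    expect_equal(p2$i_min, p0$i_min * s^4, tolerance = 1e-9)
    expect_equal(p2$i_rat, p0$i_rat, tolerance = 1e-9)
    expect_equal(p2$tt_ar, p2$ct_ar + p2$es_ar, tolerance = 1e-12)
  }
})

test_that("rectangle sections obey i_rat = 2 ln(w/h)", {
  rect <- function(w, h) validate_contour(rbind(
    c(-w / 2, -h / 2), c(w / 2, -h / 2), c(w / 2, h / 2), c(-w / 2, h / 2)
  ))
  # thin similar-rectangle ring: ratio law holds exactly for similar shapes
  p <- composite_section_properties(rect(6, 2), rect(6 * 0.8, 2 * 0.8))
  expect_equal(p$i_rat, 2 * log(6 / 2), tolerance = 1e-12)
})

test_that("batch and scalar section-property paths agree bit-for-bit", {
  set.seed(99)
  n <- 40
  phi <- 2 * pi * (seq_len(n) - 1L) / n
  a <- runif(5, 3, 6); b <- runif(5, 1.5, 3); k <- runif(5, 0.5, 0.8)
  xo <- a %o% cos(phi); yo <- b %o% sin(phi)
  batch <- ribmorph:::section_props_batch(xo, yo, xo * k, yo * k)
  for (r in 1:5) {
    single <- composite_section_properties(cbind(xo[r, ], yo[r, ]),
                                           cbind(xo[r, ] * k[r], yo[r, ] * k[r]))
    expect_identical(as.data.frame(single), as.data.frame(batch[r, ]))
  }
})

test_that("rasterisation oracle recovers annulus properties and limits", {
  ann <- annulus_section(10, 8, n = 1024)
  o <- rasterize_section(ann$periosteal, ann$endosteal, pixel = 0.05)
  expect_equal(o$ct_ar, pi * 36, tolerance = 5e-3)
  expect_equal(o$tt_ar, pi * 100, tolerance = 5e-3)

  thin <- annulus_section(5, 4.999, n = 256)
  othin <- rasterize_section(thin$periosteal, thin$endosteal, pixel = 0.02)
  expect_lt(othin$ct_ar, 0.2) # ring area vanishes as r -> R
})
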