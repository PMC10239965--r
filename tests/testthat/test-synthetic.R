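test_that("the default spec encodes the study conditions", {
  spec <- default_population_spec()
  expect_equal(spec$n_male + spec$n_female, 240L)
  expect_equal(c(spec$n_male, spec$n_female), c(118L, 122L))
  expect_equal(spec$ribs, 2:11)
  expect_length(spec$grid, 39L)

  # aspect-ratio profile peaks at station 90% at ratio 18 (F) / 15 (M), ribs 2-5
  s <- spec$grid
  rho_f <- ribmorph:::profile_rho(spec, "F", 3, s)
  expect_equal(s[which.max(rho_f)], 90)
  expect_equal(max(rho_f), 18, tolerance = 1e-9)
  expect_equal(log(max(rho_f)), 2.890, tolerance = 1e-3)
  expect_equal(max(ribmorph:::profile_rho(spec, "M", 3, s)), 15, tolerance = 1e-9)
  # lower ribs peak lower
  expect_lt(max(ribmorph:::profile_rho(spec, "F", 10, s)), 6)

  # Tt.Ar declines monotonically vertebral -> sternal
  expect_true(all(diff(ribmorph:::profile_ttar(spec, "F", 6, s)) < 0))

  # sex differences off: identical profiles
  off <- default_population_spec(sex_differences = FALSE)
  expect_equal(ribmorph:::profile_ttar(off, "M", 4, s),
               ribmorph:::profile_ttar(off, "F", 4, s))
  expect_equal(ribmorph:::profile_rho(off, "M", 4, s),
               ribmorph:::profile_rho(off, "F", 4, s))

  # spec round-trips through JSON
  f <- withr::local_tempfile(fileext = ".json")
  write_population_spec(spec, f)
  back <- read_population_spec(f)
  expect_equal(back$grid, spec$grid)
  expect_equal(back$male_area_mult, spec$male_area_mult)
})

test_that("simulation is reproducible and zero-noise recovers the profiles exactly", {
  spec <- small_spec(3, 3)
  p1 <- simulate_population(spec, seed = 7)
  p2 <- simulate_population(spec, seed = 7)
  expect_identical(p1$records, p2$records)
  expect_identical(p1$demographics, p2$demographics)
  p3 <- simulate_population(spec, seed = 8)
  expect_false(identical(p1$records, p3$records))

  z <- zero_noise_spec()
  pop <- simulate_population(z, seed = 1)
  corr <- build_corridors(pop$records)
  expect_true(all(corr$sd == 0))
  expected <- population_expected_means(z)
  joined <- dplyr::inner_join(tibble::as_tibble(corr), expected,
                              by = c("sex", "rib", "station_pct", "property"))
  expect_equal(nrow(joined), 4680L)
  expect_equal(joined$mean.x, joined$mean.y, tolerance = 1e-9)

  # demographics are internally consistent
  d <- pop$demographics
  expect_true(all(d$age >= 18 & d$age <= 90))
  expect_equal(d$bmi, d$weight / (d$height / 100)^2, tolerance = 1e-9)
})

test_that("generated sections satisfy the geometry invariants", {
  pop <- simulate_population(small_spec(2, 2), seed = 3, keep_contours = TRUE)
  set.seed(4)
  take <- sample(nrow(pop$contours), 40)
  for (i in take) {
    p <- composite_section_properties(pop$contours$periosteal[[i]],
                                      pop$contours$endosteal[[i]])
    expect_gt(p$ct_ar, 0)
    expect_gt(p$i_min, 0)
    expect_equal(p$tt_ar, p$ct_ar + p$es_ar, tolerance = 1e-12)
  }
  # measured properties in the records match the full validation path
  row <- pop$contours[117, ]
  props <- composite_section_properties(row$periosteal[[1]], row$endosteal[[1]])
  rec <- dplyr::filter(pop$records, .data$subject_id == row$subject_id,
                       .data$rib == row$rib, .data$station_pct == row$station_pct)
  expect_equal(rec$tt_ar, props$tt_ar, tolerance = 1e-12)
  expect_equal(rec$i_max, props$i_max, tolerance = 1e-12)
})

test_that("male sections exceed female by about the configured SD offset", {
  spec <- default_population_spec()
  pop <- simulate_population(spec, seed = 11)
  corr <- tibble::as_tibble(build_corridors(pop$records))
  tt <- corr[corr$property == "Tt.Ar", ]
  wide <- tidyr::pivot_wider(tt[, c("sex", "rib", "station_pct", "mean", "sd")],
                             names_from = "sex", values_from = c("mean", "sd"))
  gap_sd <- (wide$mean_M - wide$mean_F) / wide$sd_F
  expect_gte(mean(abs(gap_sd - spec$sex_offset_sd) <= 0.5), 0.9)
})

test_that("contour archives round-trip and measure back to the same records", {
  spec <- small_spec(2, 2, ribs = 2:3)
  pop <- simulate_population(spec, seed = 5, keep_contours = TRUE)
  f <- withr::local_tempfile(fileext = ".csv")
  write_contour_archive(pop, f)
  arch <- read_contour_archive(f)
  measured <- measure_contour_archive(arch)
  joined <- dplyr::inner_join(
    pop$records, measured,
    by = c("subject_id", "sex", "rib", "station_pct")
  )
  expect_equal(nrow(joined), nrow(pop$records))
  expect_equal(joined$tt_ar.y, joined$tt_ar.x, tolerance = 1e-12)
  expect_equal(joined$i_rat.y, joined$i_rat.x, tolerance = 1e-10)
})

test_that("segmentation bias dilates periosteal borders as predicted", {
  # circle R = 5: 0.42 mm border overestimate inflates Tt.Ar by 17.5%
  circ <- tibble::tibble(
    subject_id = "S1", sex = "M", age = 40, rib = 4, station_pct = 50,
    periosteal = list(unclass(regular_polygon_contour(512, 5))),
    endosteal = list(unclass(regular_polygon_contour(512, 4)))
  )
  out <- apply_segmentation_bias(circ, delta = 0.42)
  expect_equal(out$dilation_pct, 100 * (5.42^2 - 25) / 25, tolerance = 1e-4)

  out0 <- apply_segmentation_bias(circ, delta = 0)
  expect_equal(out0$dilation_pct, 0)

  # synthetic population sections follow the Minkowski dilation formula
  pop <- simulate_population(small_spec(2, 2, ribs = c(3L, 8L)), seed = 9,
                             keep_contours = TRUE)
  biased <- apply_segmentation_bias(pop$contours, delta = 0.42)
  pred <- purrr::map_dbl(pop$contours$periosteal, function(p) {
    per <- shoelace_perimeter(validate_contour(p))
    area <- polygon_area_centroid(p)$area
    100 * (0.42 * per + pi * 0.42^2) / area
  })
  expect_equal(biased$dilation_pct, pred, tolerance = 1e-2)
  expect_equal(attr(biased, "mean_dilation_pct"), mean(biased$dilation_pct))
})

test_that("synthetic HBM meshes trace corridors at the requested offsets", {
  pop <- simulate_population(small_spec(25, 25), seed = 13)
  corr <- build_corridors(pop$records)

  mesh <- simulate_hbm_mesh(corr, "F", 4, nodes_per_ring = 16)
  comp <- comparison_table(hbm_rib_to_record(mesh), corr)
  expect_true(all(comp$pct_in == 100))
  targeted <- comp$property %in% c("Tt.Ar", "Es.Ar", "Irat")
  expect_equal(comp$avg_sds[targeted], rep(0, 3), tolerance = 1e-9)

  mesh25 <- simulate_hbm_mesh(corr, "F", 4, size_offset_sds = c(Tt.Ar = 2.5))
  comp25 <- comparison_table(hbm_rib_to_record(mesh25), corr)
  tt <- comp25[comp25$property == "Tt.Ar", ]
  expect_equal(tt$avg_sds, 2.5, tolerance = 1e-9)
  expect_equal(tt$pct_high, 100)

  # THUMS-style 12-node uniform-thickness mesh: thin-shell cortical area
  m12 <- simulate_hbm_mesh(corr, "M", 5, nodes_per_ring = 12, thickness = 0.7)
  expect_equal(m12$nodes_per_ring, 12L)
  rec <- hbm_rib_to_record(m12)
  perims <- purrr::map_dbl(m12$rings, function(r) {
    p <- r$nodes[, 2:3]
    sum(sqrt(rowSums((p - p[c(2:nrow(p), 1L), ])^2)))
  })
  ring_ct <- purrr::map_dbl(m12$rings, function(r) {
    b <- ring_to_borders(r$nodes, r$thickness)
    polygon_area_centroid(b$periosteal)$area - polygon_area_centroid(b$endosteal)$area
  })
  # thin shell: Ct.Ar ~ perimeter x thickness to first order (the
  # node-displacement offsets contribute a corner deficit of order
  # 1 - cos(pi/n), ~3.4% for 12-node rings)
  expect_equal(ring_ct, perims * 0.7, tolerance = 4e-2)
  expect_true(all(ring_ct < perims * 0.7))
})
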