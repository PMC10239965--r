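# Shape generators shared across tests. All randomness uses the calling
# test's RNG state; tests set their own seeds.

# star-convex hollow section: smooth radial wobble on outer and inner borders
random_star_section <- function(n = 72, r0 = 4, wobble = 0.12) {
  phi <- 2 * pi * (seq_len(n) - 1L) / n
  harm <- function(amp) {
    amp * (runif(1, -1, 1) * cos(phi + runif(1, 0, 2 * pi)) +
             0.6 * runif(1, -1, 1) * cos(2 * phi + runif(1, 0, 2 * pi)) +
             0.3 * runif(1, -1, 1) * cos(3 * phi + runif(1, 0, 2 * pi)))
  }
  ro <- r0 * (1 + harm(wobble))
  ri <- ro * (runif(1, 0.45, 0.65) + harm(0.06))
  list(
    periosteal = validate_contour(cbind(ro * cos(phi), ro * sin(phi))),
    endosteal = validate_contour(cbind(ri * cos(phi), ri * sin(phi)))
  )
}

# concentric circular annulus pair (polygonised)
annulus_section <- function(R, r, n = 256) {
  list(
    periosteal = regular_polygon_contour(n, R),
    endosteal = regular_polygon_contour(n, r)
  )
}

# similar elliptical annulus: inner = outer scaled by k (exact ratio q^2 law)
elliptical_annulus <- function(a, b, k, n = 256, rot = 0) {
  list(
    periosteal = ellipse_contour(n, a, b, rot = rot),
    endosteal = ellipse_contour(n, a * k, b * k, rot = rot)
  )
}

# rigid transform of a contour (rotation + translation)
rigid_transform <- function(contour, angle, shift) {
  p <- unclass(contour)
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  validate_contour(sweep(p %*% t(R), 2L, -shift))
}

shoelace_perimeter <- function(contour) {
  p <- unclass(contour)
  sum(sqrt(rowSums((p - p[c(2:nrow(p), 1L), ])^2)))
}

# small population spec for fast pipeline tests
small_spec <- function(n_male = 4L, n_female = 4L, ...) {
  spec <- default_population_spec(n_male = n_male, n_female = n_female)
  extra <- list(...)
  spec[names(extra)] <- extra
  spec
}

zero_noise_spec <- function(n_male = 3L, n_female = 3L) {
  small_spec(n_male, n_female,
             subject_sdlog = 0, station_noise_sd = 0,
             log_aspect_noise_sd = 0, tilt_sd = 0)
}
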