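# Beam tests run the reference geometry at 1 MHz where physics allows: the
# coarser wavelength keeps the element count (pitch <= lambda/2 on the cap
# surface) small enough for the exact direct summation.

lossless_water <- function() {
  w <- reference_media()$water
  w$alpha0 <- 1e-300
  layered_medium(list(w))
}

test_that("aperture discretization recovers the cap area and honours the hole", {
  spec <- transducer_spec(hole_width = 0, hole_height = 0)
  el <- discretize_aperture(spec)
  expect_equal(sum(el$area), cap_area(0.038, 0.028), tolerance = 5e-3)

  spec_h <- transducer_spec()  # default 20 x 8 mm hole
  el_h <- discretize_aperture(spec_h)
  # deficit equals the hole area integrated with the surface Jacobian
  u <- seq(-10e-3 + 1e-5, 10e-3, by = 2e-5)
  v <- seq(-4e-3 + 1e-5, 4e-3, by = 2e-5)
  rho2 <- outer(u^2, v^2, "+")
  hole_area <- sum(0.038 / sqrt(0.038^2 - rho2)) * (2e-5)^2
  expect_equal(sum(el$area) - sum(el_h$area), hole_area, tolerance = 1e-2)

  big_hole <- transducer_spec(hole_width = 0.056, hole_height = 0.056)
  expect_error(discretize_aperture(big_hole), "empty")
  expect_error(discretize_aperture(spec, n_elements = 50), "pitch")
})

test_that("on-axis field matches the closed-form focused-cap solution", {
  spec <- transducer_spec(hole_width = 0, hole_height = 0, frequency = 1e6,
                          acoustic_power = 10)
  g <- build_grid(3, 3, 61, 0.5e-3, origin = c(-0.5e-3, -0.5e-3, 23e-3),
                  focus = c(0, 0, 38e-3))
  f <- rayleigh_field(spec, g, lossless_water(), method = "direct")
  el <- discretize_aperture(spec, c_ref = 1447)
  u0 <- sqrt(2 * 10 / (1000 * 1447 * sum(el$area)))
  k <- 2 * pi * 1e6 / 1447
  p_ref <- oneil_on_axis(g$z, 0.038, 0.028, k, 1000 * 1447 * u0)
  expect_lt(max(abs(Mod(f$p[2, 2, ]) - p_ref)) / max(p_ref), 0.02)
})

test_that("hole-free field is mirror symmetric; the cutout breaks it", {
  spec <- transducer_spec(hole_width = 0, hole_height = 0, frequency = 1e6,
                          acoustic_power = 10)
  g <- small_focus_grid(11, 11, 9, dx = 1e-3)
  f <- rayleigh_field(spec, g, lossless_water(), method = "direct")
  a <- Mod(f$p)
  expect_lt(max(abs(a - a[11:1, , ])) / max(a), 1e-9)
  expect_lt(max(abs(a - a[, 11:1, ])) / max(a), 1e-9)

  spec_h <- transducer_spec(frequency = 1e6, acoustic_power = 10)
  fh <- rayleigh_field(spec_h, g, lossless_water(), method = "direct")
  ah <- Mod(fh$p)
  # focal-plane lateral second moments along x and y differ
  kf <- which.min(abs(g$z - 0.038))
  pl <- ah[, , kf]^2
  mx <- sum(pl * g$x^2) / sum(pl)
  my <- sum(pl * rep(g$y, each = 11)^2) / sum(pl)
  expect_gt(abs(mx - my) / (mx + my), 1e-3)
})

test_that("discretization is converged and the field is linear in amplitude", {
  med <- lossless_water()
  spec <- transducer_spec(hole_width = 0, hole_height = 0, frequency = 1e6,
                          acoustic_power = 10)
  g <- build_grid(3, 3, 3, 2e-4, origin = c(-2e-4, -2e-4, 37.8e-3),
                  focus = c(0, 0, 38e-3))
  lam <- 1447 / 1e6
  f1 <- rayleigh_field(spec, g, med, method = "direct", pitch = lam / 3)
  f2 <- rayleigh_field(spec, g, med, method = "direct", pitch = lam / 3 / sqrt(2))
  expect_lt(abs(max(Mod(f1$p)) - max(Mod(f2$p))) / max(Mod(f2$p)), 5e-3)

  spec4 <- spec; spec4$acoustic_power <- 40
  f4 <- rayleigh_field(spec4, g, med, method = "direct", pitch = lam / 3)
  expect_equal(f4$p, 2 * f1$p, tolerance = 1e-12)
})

test_that("fast evaluation path agrees with the direct summation at 3 MHz", {
  cfg <- default_config()
  res <- resolve_config(cfg)
  g <- build_grid(11, 11, 11, 2e-4, origin = c(-1e-3, -1e-3, 37e-3),
                  focus = c(0, 0, 38e-3))
  fd <- rayleigh_field(res$spec, g, res$media, method = "direct")
  ff <- rayleigh_field(res$spec, g, res$media, method = "fast")
  pk <- max(Mod(fd$p))
  expect_lt(max(Mod(ff$p - fd$p)) / pk, 0.01)
  # analytic intensity agrees too
  expect_lt(max(abs(ff$I$z - fd$I$z)) / max(abs(fd$I$z)), 0.03)
})

test_that("centered-difference intensity matches plane-wave relations", {
  med <- reference_media()$liver
  lm <- layered_medium(list(med))
  f <- 1e6
  lam <- med$c_s / f
  g <- build_grid(5, 5, 81, lam / 20, origin = c(-lam / 10, -lam / 10, 20e-3),
                  focus = c(0, 0, 20e-3 + 40 * lam / 20))
  k <- 2 * pi * f / med$c_s
  p <- array(rep(1e6 * exp(1i * k * (g$z - g$z[1])), each = 25), dim = dim(g))
  fld <- hifusim:::.acoustic_field(p, g, f)
  fld <- intensity_from_pressure(fld, lm)
  I_ref <- 1e12 / (2 * med$rho0 * med$c_s)  # 3.110e5 W/m^2 for 1 MPa in liver
  expect_equal(I_ref, 3.110e5, tolerance = 1e-3)
  mid <- fld$I$z[3, 3, 20:60]
  expect_equal(mean(mid) / I_ref, 1, tolerance = 0.02)
  expect_lt(max(abs(fld$I$x)), 1e-9 * I_ref)

  # standing wave: real pressure, quadrature velocity, zero mean intensity
  ps <- array(rep(1e6 * cos(k * (g$z - g$z[1])), each = 25), dim = dim(g))
  fs <- hifusim:::.acoustic_field(ps + 0i, g, f)
  fs <- intensity_from_pressure(fs, lm)
  expect_lt(max(abs(fs$I$z)), 1e-9 * I_ref)
})

test_that("normalize_to_power rescales the focal-plane power", {
  g <- small_focus_grid(21, 21, 21, dx = 5e-4)
  lm <- layered_medium(list(reference_media()$liver))
  f <- synthetic_focal_beam(g, lm, peak = 1e6, sigma_lat = 1e-3,
                            sigma_ax = 2e-3)
  f10 <- normalize_to_power(f, 10)
  kf <- nearest_voxel(g, g$focus)[3] + 1
  expect_equal(sum(f10$I$z[, , kf]) * g$dx^2, 10, tolerance = 1e-12)
  # scaling to the current power is the identity
  pw <- sum(f$I$z[, , kf]) * g$dx^2
  fid <- normalize_to_power(f, pw)
  expect_equal(fid$p, f$p, tolerance = 1e-12)
  fz <- f; fz$I <- lapply(f$I, function(a) a * 0)
  expect_error(normalize_to_power(fz, 10), "not positive")
})

test_that("field export/import round-trips and validates the grid", {
  g <- small_focus_grid(9, 9, 9, dx = 1e-3)
  lm <- layered_medium(list(reference_media()$liver))
  f <- synthetic_focal_beam(g, lm, peak = 2e6, sigma_lat = 2e-3, sigma_ax = 3e-3)
  path <- file.path(tempdir(), "fieldtest")
  export_field(f, path)
  f2 <- import_field(path, g)
  expect_identical(f2$p, f$p)
  # stored intensity is reused, not recomputed
  expect_identical(f2$I$z, f$I$z)
  g_bad <- small_focus_grid(9, 9, 9, dx = 2e-3)
  expect_error(import_field(path, g_bad), "spacing|shape")
})
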