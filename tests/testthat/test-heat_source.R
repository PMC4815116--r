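test_that("plane-wave heat source reproduces the hand-computed values", {
  med <- reference_media()
  g <- small_focus_grid(5, 5, 11, dx = 1e-3)
  pw <- plane_wave_field(g, med$liver, p0 = 1e6)
  q <- plane_wave_heat_source(pw$field, pw$media)
  # 1 MPa in liver at 3 MHz: Q = 2 * 17.19 * 3.110e5 = 1.070e7 W/m^3
  expect_equal(q$Q[3, 3, 1], 1.0697e7, tolerance = 1e-3)
  # water voxel at the same pressure: smaller by the alpha/(rho c) ratio
  pww <- plane_wave_field(g, med$water, p0 = 1e6)
  qw <- plane_wave_heat_source(pww$field, pww$media)
  ratio <- (attenuation_at_frequency(med$water, 3) / (1000 * 1447)) /
    (attenuation_at_frequency(med$liver, 3) / (996 * 1614))
  expect_equal(qw$Q[3, 3, 1] / q$Q[3, 3, 1], ratio, tolerance = 1e-9)
  # zero pressure, zero source
  z <- pw$field; z$p <- z$p * 0
  expect_true(all(plane_wave_heat_source(z, pw$media)$Q == 0))
})

test_that("divergence form is the signed analytic loss for simple fields", {
  med <- reference_media()$liver
  g <- small_focus_grid(5, 5, 41, dx = 2.5e-4)
  pw <- plane_wave_field(g, med, p0 = 1e6)
  f <- pw$field
  # uniform intensity: zero divergence in the interior
  fu <- f
  fu$I <- list(x = array(0, dim(g)), y = array(0, dim(g)),
               z = array(1e5, dim(g)))
  du <- divergence_heat_source(fu)
  expect_equal(max(abs(du[, , 2:40])), 0)
  # attenuated plane wave: -dI/dz = 2 alpha I
  d <- divergence_heat_source(f)
  mid <- 5:37
  expect_equal(d[3, 3, mid] / (2 * pw$alpha * f$I$z[3, 3, mid]),
               rep(1, length(mid)), tolerance = 1e-3)
})

test_that("axial power profile conserves, decays and absorbs side flux", {
  med <- reference_media()$liver
  g <- small_focus_grid(5, 5, 41, dx = 2.5e-4)
  # lossless plane wave fully inside the domain: P constant
  pl <- plane_wave_field(g, med, p0 = 1e6, lossless = TRUE)
  P <- axial_power_profile(pl$field)$P
  expect_lt(diff(range(P)) / mean(P), 1e-12)
  # attenuated plane wave: P proportional to exp(-2 alpha z)
  pa <- plane_wave_field(g, med, p0 = 1e6)
  Pa <- axial_power_profile(pa$field)$P
  expect_equal(Pa / Pa[1], exp(-2 * pa$alpha * (g$z - g$z[1])),
               tolerance = 1e-9)
  # pure outward side flux: correction terms grow linearly with z
  fs <- pl$field
  c0 <- 1e4
  Ix <- array(rep(sign(g$x), times = 5 * 41) * c0, dim = dim(g))
  fs$I <- list(x = Ix, y = array(0, dim(g)), z = array(0, dim(g)))
  prof <- axial_power_profile(fs)
  expect_equal(diff(prof$P), rep(2 * c0 * 5 * g$dx^2, 40), tolerance = 1e-9)
})

test_that("conservative source matches the plane-wave form and telescopes", {
  med <- reference_media()$liver
  g <- small_focus_grid(5, 5, 41, dx = 2.5e-4)
  pw <- plane_wave_field(g, med, p0 = 1e6)
  prof <- axial_power_profile(pw$field)
  qc <- conservative_heat_source(prof, pw$field)
  qp <- plane_wave_heat_source(pw$field, pw$media)
  mid <- 3:39
  expect_equal(qc$Q[3, 3, mid] / qp$Q[3, 3, mid], rep(1, length(mid)),
               tolerance = 0.02)
  # exact telescoping of the deposited power (no clipped layers here)
  expect_equal(qc$clipped, 0)
  expect_equal(sum(qc$Q) * g$dx^3, prof$P[1] - prof$P[41], tolerance = 1e-12)
  # lossless wave: no layer loses power, so no heat anywhere
  pl <- plane_wave_field(g, med, p0 = 1e6, lossless = TRUE)
  ql <- conservative_heat_source(axial_power_profile(pl$field), pl$field)
  expect_lt(max(ql$Q) * g$dx^3, 1e-12 * prof$P[1])
  # a plane with zero pressure but nonzero loss is an error
  bad <- pw$field
  bad$p[, , 20] <- 0
  expect_error(conservative_heat_source(prof, bad), "zero pressure")
})

test_that("absorption ratio and defocus blur preserve per-plane power", {
  g <- small_focus_grid(31, 31, 11, dx = 4e-4)
  lm <- layered_medium(list(reference_media()$liver))
  f <- synthetic_focal_beam(g, lm, peak = 5e6, sigma_lat = 8e-4, sigma_ax = 3e-3)
  q <- conservative_heat_source(axial_power_profile(f), f)
  # identity when sigma = 0, A = 1
  q_id <- apply_absorption_and_defocus(q, 1, 0)
  expect_equal(q_id$Q, q$Q, tolerance = 1e-14)
  # calibrated values: peak drops, plane totals keep A * total
  q0 <- apply_absorption_and_defocus(q, 0.37, 290e-6)
  expect_lt(max(q0$Q), 0.37 * max(q$Q))
  tot <- apply(q$Q, 3, sum)
  tot0 <- apply(q0$Q, 3, sum)
  nz <- tot > 1e-6 * max(tot)
  expect_equal(tot0[nz] / (0.37 * tot[nz]), rep(1, sum(nz)), tolerance = 5e-3)
  expect_error(apply_absorption_and_defocus(q, 1.5, 0))
})

test_that("source translation is exact for integer shifts, conservative otherwise", {
  g <- small_focus_grid(31, 31, 11, dx = 4e-4)
  lm <- layered_medium(list(reference_media()$liver))
  f <- synthetic_focal_beam(g, lm, peak = 5e6, sigma_lat = 8e-4, sigma_ax = 3e-3)
  q <- conservative_heat_source(axial_power_profile(f), f)
  expect_equal(translate_source(q, c(0, 0))$Q, q$Q)
  q_sh <- translate_source(q, c(3 * g$dx, -2 * g$dx))
  expect_equal(q_sh$Q[10 + 3, 10 - 2, 5], q$Q[10, 10, 5])
  # sub-voxel: total power preserved within 0.5% (beam far from edges)
  q_sub <- translate_source(q, c(0.65e-3, 0.3e-3))
  expect_equal(sum(q_sub$Q) / sum(q$Q), 1, tolerance = 5e-3)
  expect_error(translate_source(q, c(1, 0)), "extent")
})
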