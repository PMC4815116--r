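test_that("Deming regression matches independent minimizers", {
  set.seed(1)
  x <- seq(1, 6, length.out = 10)
  # perfect line: slope recovered exactly for any variance ratio
  y0 <- -0.27 * x + 5
  for (sy in c(0.05, 0.1, 0.5)) {
    f <- deming_regression(x, y0, sx = 0.1, sy = sy, nboot = 50, seed = 1)
    expect_equal(f$slope, -0.27, tolerance = 1e-9)
    expect_equal(f$intercept, 5, tolerance = 1e-9)
  }
  # noisy sets: closed form equals the brute-force grid search
  for (i in 1:3) {
    y <- -0.5 * x + 4 + stats::rnorm(10, 0, 0.3)
    f <- deming_regression(x, y, sx = 0.1, sy = 0.1, nboot = 50, seed = 1)
    b_grid <- deming_grid_search(x, y, 0.1, 0.1)
    expect_equal(f$slope, b_grid, tolerance = 1e-3)
    expect_true(f$ci[1] <= f$slope && f$slope <= f$ci[2])
  }
  # large variance ratio tends to ordinary least squares of y on x
  y <- -0.5 * x + 4 + stats::rnorm(10, 0, 0.3)
  f_inf <- deming_regression(x, y, sx = 1e-3, sy = 1, nboot = 50, seed = 1)
  expect_equal(f_inf$slope, unname(stats::coef(stats::lm(y ~ x))[2]),
               tolerance = 1e-4)
  # reproducible bootstrap under a fixed seed
  f1 <- deming_regression(x, y, nboot = 200, seed = 42)
  f2 <- deming_regression(x, y, nboot = 200, seed = 42)
  expect_identical(f1$ci, f2$ci)
  expect_error(deming_regression(rep(1, 5), 1:5), "degenerate")
  expect_error(deming_regression(1:2, 1:2), "3 points")
})

test_that("a zero-power pulse leaves the tissue untouched", {
  cfg <- fast_config(peak = 0)
  r <- run_pulse(cfg)
  expect_true(is.na(r$onset))
  expect_equal(r$metrics$volume_mm3, 0)
  expect_true(all(r$state$T == 37))
})

test_that("a single-pulse treatment reduces to run_pulse", {
  cfg <- fast_config()
  r1 <- run_pulse(cfg)
  cfg$treatment <- list(offsets = matrix(0, 1, 2), cooling = 5)
  r2 <- run_treatment(cfg, beam = r1$beam)
  expect_equal(r2$state$T, r1$state$T, tolerance = 1e-12)
  expect_equal(r2$state$D, r1$state$D, tolerance = 1e-12)
  expect_equal(r2$onset, r1$onset)
})

test_that("far-apart pulses produce additive composite lesions", {
  cfg <- fast_config(peak = 5e6, cooldown = 10)
  r1 <- run_pulse(cfg)
  v1 <- r1$metrics$volume_mm3
  expect_gt(v1, 0)
  cfg$treatment <- list(offsets = rbind(c(-4e-3, -4e-3), c(4e-3, 4e-3)),
                        cooling = 10)
  r2 <- run_treatment(cfg, beam = r1$beam)
  expect_equal(sum(lesion_mask(r2$state$D)) * (r1$beam$res$grid$dx * 1e3)^3,
               2 * v1, tolerance = 0.05)
})

test_that("treatment pattern is a compact center-out spiral", {
  p <- treatment_pattern(19, 1.8e-3, 1.6e-3)
  expect_equal(dim(p), c(19, 2))
  expect_equal(p[1, ], c(x = 0, y = 0))
  r <- sqrt(p[, 1]^2 + p[, 2]^2)
  expect_true(all(diff(r) >= -1e-12))
  expect_lt(max(abs(p)), 5e-3)
})

test_that("boiling onset is monotone in the absorption ratio", {
  cfg <- fast_config(peak = 6.5e6, duration = 8)
  beam_field <- build_beam(cfg)$field
  onsets <- vapply(c(0.25, 0.37, 0.55), function(A) {
    ci <- cfg
    ci$source$A <- A
    r <- run_pulse(ci, field = beam_field, stop_at_onset = TRUE)
    if (is.na(r$onset)) Inf else r$onset
  }, numeric(1))
  expect_true(all(diff(onsets) < 0))
})

test_that("two-stage calibration hits both onset targets on a coarse model", {
  cfg_s <- fast_config(peak = 6.5e6, duration = 8)
  cfg_m <- fast_config(peak = 6.5e6, duration = 8,
                       trajectory = list(diameter = 2e-3, period = 2))
  beams <- list(stationary = build_beam(cfg_s)$field,
                moving = build_beam(cfg_m)$field)
  # targets taken from direct runs at a known (A, sigma) pair, so a
  # consistent solution exists inside the search bounds
  truth <- c(A = 0.45, sigma = 5e-4)
  t_s <- hifusim:::.onset_for(cfg_s, truth[["A"]], truth[["sigma"]],
                              beams$stationary)
  t_m <- hifusim:::.onset_for(cfg_m, truth[["A"]], truth[["sigma"]],
                              beams$moving)
  expect_false(anyNA(c(t_s, t_m)))
  cal <- calibrate_A_sigma(cfg_s, cfg_m,
                           targets = c(stationary = t_s, moving = t_m),
                           tol = 0.3, A_bounds = c(0.2, 0.8),
                           sigma_bounds = c(0, 1.2e-3), beams = beams)
  expect_true(abs(cal$onsets[["stationary"]] - t_s) <= 0.3)
  expect_true(abs(cal$onsets[["moving"]] - t_m) <= 0.3)
  expect_true(cal$A >= 0.2 && cal$A <= 0.8)
  # unreachable targets report a bracketing failure
  expect_error(
    calibrate_A_sigma(cfg_s, cfg_m, targets = c(stationary = 50, moving = 60),
                      tol = 0.1, beams = beams),
    "not bracketed")
})

test_that("defocus sweep yields negative size-versus-onset slopes", {
  cfg <- fast_config(peak = 5.6e6, duration = 6, cooldown = 12)
  cfg$source$sigma_defoc <- 4e-4
  beam <- build_beam(cfg)
  sw <- slope_experiment(cfg, factors = c(0.5, 0.8, 1.1, 1.4, 1.7),
                         beam = beam, seed = 1)
  expect_true(all(sw$slopes < 0))
  ok <- !is.na(sw$sweep$onset)
  # the headline mechanism: earlier boiling, larger lesion
  vol <- sw$sweep$x[ok] * sw$sweep$y[ok] * sw$sweep$z[ok]
  expect_lt(stats::cor(sw$sweep$onset[ok], vol), 0)
  expect_error(slope_experiment(cfg, factors = c(1, 1, 1), beam = beam),
               "identical")
})
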