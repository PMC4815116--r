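test_that("bubble-cloud mask uses a strict threshold", {
  T <- array(37, c(4, 4, 4))
  expect_false(any(boiling_region(T)))
  T[2, 2, 2] <- 85
  expect_false(any(boiling_region(T)))  # boundary excluded
  T[3, 3, 3] <- 90
  expect_equal(which(boiling_region(T)), which(T == 90))
})

test_that("shielding coefficient picks the worst plane", {
  Q <- array(0, c(4, 4, 3))
  Q[, , 1] <- 1
  Q[, , 2] <- 1
  B <- array(FALSE, c(4, 4, 3))
  expect_equal(shielding_coefficient(Q, B)$r_shield, 0)
  # plane 1: 6/16 of the power in B, plane 2: 10/16
  B[cbind(c(1, 2, 3, 4, 1, 2), c(1, 1, 1, 1, 2, 2), 1)] <- TRUE
  B[cbind(c(1, 2, 3, 4, 1, 2, 3, 4, 1, 2), rep(c(1, 2, 3), c(4, 4, 2)), 2)] <- TRUE # 10/16
  sh <- shielding_coefficient(Q, B)
  expect_equal(sh$r_shield, 10 / 16)
  expect_equal(sh$z_shield, 2)
  # full plane with power: complete shielding
  B2 <- array(FALSE, c(4, 4, 3)); B2[, , 2] <- TRUE
  expect_equal(shielding_coefficient(Q, B2)$r_shield, 1)
})

test_that("enhanced zone equals brute-force lattice-ball dilation", {
  g <- small_focus_grid(15, 15, 15, dx = 2e-4)
  B <- array(FALSE, dim(g)); B[8, 8, 8] <- TRUE
  H <- enhanced_zone(B, 2 * g$dx, g)
  expect_equal(sum(H), 33)  # lattice ball of radius 2
  expect_equal(nrow(lattice_ball(2)), 33)
  set.seed(11)
  for (i in 1:3) {
    B <- array(stats::runif(prod(dim(g))) < 0.01, dim(g))
    H <- enhanced_zone(B, 2.3 * g$dx, g)
    expect_identical(H, brute_dilate(B, 2.3))
  }
  expect_identical(enhanced_zone(array(FALSE, dim(g)), 1e-3, g),
                   array(FALSE, dim(g)))
  expect_error(enhanced_zone(B, 1e-4, g), "voxel")
})

test_that("intercepted power follows eta * r_shield * P(z_shield)", {
  prof <- structure(list(P = c(45, 40, 35), z = 1:3),
                    class = "axial_power_profile")
  expect_equal(intercepted_power(0.5, 2, prof, 0.31), 6.2)
  expect_equal(intercepted_power(0, NA, prof, 0.31), 0)
  expect_equal(intercepted_power(0.5, 2, prof, 0), 0)
})

test_that("local convexity of the cloud top follows the focal column", {
  g <- small_focus_grid(11, 11, 11, dx = 1e-3)
  col <- nearest_voxel(g, g$focus)[1:2] + 1
  # solid ball centered on the column: convex
  B <- array(FALSE, dim(g))
  for (dz in -2:2) for (dxy in which(abs(-5:5) <= 2))
    B[col[1] + (-5:5)[dxy], col[2], 6 + dz] <- TRUE
  expect_true(cloud_convexity(B, g))
  # single voxel on the column
  B1 <- array(FALSE, dim(g)); B1[col[1], col[2], 4] <- TRUE
  expect_true(cloud_convexity(B1, g))
  # ring with a hole at the column, plus a deeper on-column voxel
  B2 <- array(FALSE, dim(g))
  B2[cbind(col[1] + c(-1, 1, 0, 0), col[2] + c(0, 0, -1, 1), 3)] <- TRUE
  B2[col[1], col[2], 6] <- TRUE
  expect_false(cloud_convexity(B2, g))
  expect_error(cloud_convexity(array(FALSE, dim(g)), g), "empty")
})

test_that("redistribution weights implement W1, W2, W3", {
  g <- small_focus_grid(15, 15, 15, dx = 5e-4)
  col <- nearest_voxel(g, g$focus) + 1
  B <- array(FALSE, dim(g)); B[col[1], col[2], col[3]] <- TRUE
  H <- enhanced_zone(B, 3 * g$dx, g)
  Q0 <- array(stats::runif(prod(dim(g)), 1, 2), dim(g))
  sh <- list(r_shield = 0.4, z_shield = col[3])
  w <- boiling_weights(B, H, Q0, sh$r_shield, sh$z_shield, g,
                       params = boiling_params(R_SE = 3 * g$dx))
  expect_true(w$convex)
  ar <- arrayInd(w$idx, dim(g))
  d <- sqrt((ar[, 1] - col[1])^2 + (ar[, 2] - col[2])^2 + (ar[, 3] - col[3])^2)
  # W1 is the inverse voxel distance: ratio 2 between d = 1 and d = 2
  expect_equal(w$W1, 1 / d)
  expect_equal(w$W1[d == 1][1] / w$W1[d == 2][1], 2)
  # W2: unity up to the shielding plane, r_shield beyond
  expect_true(all(w$W2[ar[, 3] <= col[3]] == 1))
  expect_true(all(w$W2[ar[, 3] > col[3]] == 0.4))
  # convex: W3 proportional to the undisturbed source on H \ B
  expect_equal(w$W3, Q0[w$idx])

  # concave cloud: W3 is W_plus inside the prefocal cone, 1 outside
  B2 <- array(FALSE, dim(g))
  B2[col[1] + c(-2, 2), col[2], col[3]] <- TRUE
  B2[col[1], col[2], col[3] + 2] <- TRUE
  H2 <- enhanced_zone(B2, 4 * g$dx, g)
  w2 <- boiling_weights(B2, H2, Q0, 0.4, col[3], g,
                        params = boiling_params(R_SE = 4 * g$dx,
                                                theta_cone = pi / 10))
  expect_false(w2$convex)
  ar2 <- arrayInd(w2$idx, dim(g))
  xyz <- voxel_center(g, ar2 - 1)
  dxy <- sqrt((xyz[, 1] - g$focus[1])^2 + (xyz[, 2] - g$focus[2])^2)
  dz <- g$focus[3] - xyz[, 3]
  incone <- dz > 0 & atan2(dxy, dz) <= pi / 10
  expect_true(all(w2$W3[incone] == 10))
  expect_true(all(w2$W3[!incone] == 1))
})

test_that("boiling source integrates exactly to the intercepted power", {
  g <- small_focus_grid(15, 15, 15, dx = 5e-4)
  col <- nearest_voxel(g, g$focus) + 1
  B <- array(FALSE, dim(g)); B[col[1], col[2], col[3]] <- TRUE
  H <- enhanced_zone(B, 3 * g$dx, g)
  Q0 <- array(1, dim(g))
  w <- boiling_weights(B, H, Q0, 0.5, col[3], g,
                       params = boiling_params(R_SE = 3 * g$dx))
  Qb <- boiling_heat_source(4.7, w, g)
  expect_equal(sum(Qb) * g$dx^3, 4.7, tolerance = 1e-12)
  expect_true(all(Qb[B] == 0))
  # single-voxel support receives everything
  w1 <- w; w1$idx <- w$idx[1]; w1$W1 <- 1; w1$W2 <- 1; w1$W3 <- 1
  Qb1 <- boiling_heat_source(2, w1, g)
  expect_equal(Qb1[w$idx[1]], 2 / g$dx^3)
  expect_true(all(boiling_heat_source(0, w, g) == 0))
  w0 <- w; w0$W1 <- w$W1 * 0
  expect_error(boiling_heat_source(1, w0, g), "zero")
})

test_that("total source zeroes the cloud and honours the shielding flag", {
  g <- small_focus_grid(9, 9, 9, dx = 1e-3)
  Q0 <- array(stats::runif(prod(dim(g))), dim(g))
  B <- array(FALSE, dim(g))
  Qb <- array(0, dim(g))
  expect_equal(compose_total_source(Q0, B, Qb, 0, NA), Q0)
  B[5, 5, 5] <- TRUE
  qt <- compose_total_source(Q0, B, Qb, 0.5, 5L)
  expect_equal(qt[5, 5, 5], 0)
  qt2 <- compose_total_source(Q0, B, Qb, 1, 5L,
                              params = boiling_params(postfocal_base_attenuation = TRUE))
  expect_true(all(qt2[, , 6:9] == 0))
})

test_that("r_shield never decreases as the cloud grows", {
  set.seed(23)
  g <- small_focus_grid(9, 9, 9, dx = 1e-3)
  Q <- array(stats::runif(prod(dim(g))), dim(g))
  B <- array(stats::runif(prod(dim(g))) < 0.05, dim(g))
  r_prev <- shielding_coefficient(Q, B)$r_shield
  for (i in 1:5) {
    grow <- which(!B)[sample(sum(!B), 20)]
    B[grow] <- TRUE
    r_now <- shielding_coefficient(Q, B)$r_shield
    expect_gte(r_now, r_prev - 1e-12)
    r_prev <- r_now
  }
})
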