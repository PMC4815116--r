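# Independent oracles and small fixtures shared across the suite.

# On-axis pressure of a focused spherical cap in a lossless medium
# (closed form): |p| = 2 rho c u0 R / |z - R| * |sin(k (r_edge - z) / 2)|,
# with the apex at z = 0 and the focus at z = R; at the focus the limit is
# rho c u0 k h.
oneil_on_axis <- function(z, R, a, k, rho_c_u0) {
  h <- R - sqrt(R^2 - a^2)
  r_edge <- sqrt((z - h)^2 + a^2)
  ifelse(abs(z - R) < 1e-9,
         rho_c_u0 * k * h,
         2 * rho_c_u0 * R / abs(z - R) * abs(sin(k * (r_edge - z) / 2)))
}

# all integer offsets within a Euclidean ball of given radius (voxels)
lattice_ball <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(i = -r:r, j = -r:r, k = -r:r)
  g[sqrt(g$i^2 + g$j^2 + g$k^2) <= radius, ]
}

# brute-force binary dilation of a small 3D mask with a lattice ball
brute_dilate <- function(mask, radius) {
  d <- dim(mask)
  out <- array(FALSE, d)
  offs <- lattice_ball(radius)
  idx <- which(mask, arr.ind = TRUE)
  for (s in seq_len(nrow(idx))) {
    ii <- idx[s, 1] + offs$i
    jj <- idx[s, 2] + offs$j
    kk <- idx[s, 3] + offs$k
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
    out[cbind(ii[ok], jj[ok], kk[ok])] <- TRUE
  }
  out
}

# brute-force Deming slope: scan the weighted orthogonal loss over a slope
# grid (intercept optimal in closed form for fixed slope)
deming_grid_search <- function(x, y, sx, sy, b_range = c(-20, 20), n = 400001) {
  bs <- seq(b_range[1], b_range[2], length.out = n)
  loss <- vapply(bs, function(b) {
    a <- mean(y - b * x)
    sum((y - a - b * x)^2 / (sy^2 + b^2 * sx^2))
  }, numeric(1))
  bs[which.min(loss)]
}

# analytic traveling plane wave along z in a single-medium stack, with the
# intensity filled in analytically (plane-wave relation)
plane_wave_field <- function(grid, med, p0 = 1e6, f = 3e6, lossless = FALSE) {
  m <- med
  if (lossless) m$alpha0 <- 1e-300
  lm <- layered_medium(list(m))
  alpha <- attenuation_at_frequency(m, f / 1e6)
  k <- 2 * pi * f / m$c_s
  zrel <- grid$z - grid$z[1]
  pz <- p0 * exp((1i * k - alpha) * zrel)
  p <- array(rep(pz, each = grid$nx * grid$ny), dim = dim(grid))
  fld <- hifusim:::.acoustic_field(p, grid, f)
  Iz <- Mod(p)^2 / (2 * m$rho0 * m$c_s)
  zero <- array(0, dim(grid))
  fld$I <- list(x = zero, y = zero, z = Iz)
  list(field = fld, media = lm, alpha = alpha, k = k)
}

# a small grid centered on a 38-mm focus, matching the reference geometry
small_focus_grid <- function(nx = 21, ny = 21, nz = 21, dx = 5e-4) {
  iz <- round(0.6 * (nz - 1))
  build_grid(nx, ny, nz, dx,
             origin = c(-(nx - 1) / 2 * dx, -(ny - 1) / 2 * dx, 0.038 - iz * dx),
             focus = c(0, 0, 0.038))
}

# Coarse, fast configuration driven by the synthetic focal beam: used by the
# pulse-level behaviour and monotonicity tests. Boiling onset falls around
# 1-2 s for the default peak pressure.
fast_config <- function(peak = 5.5e6, duration = 4, cooldown = 15,
                        trajectory = NULL) {
  cfg <- default_config()
  cfg$grid <- list(nx = 31L, ny = 31L, nz = 41L, dx = 5e-4, focus_frac_z = 0.6)
  cfg$beam <- list(type = "synthetic", peak = peak, sigma_lat = 1e-3,
                   sigma_ax = 3e-3)
  cfg$source$formulation <- "plane_wave"
  cfg$thermal$dt <- 0.25
  cfg$thermal$cooldown <- cooldown
  cfg$pulse$duration <- duration
  cfg$pulse$trajectory <- trajectory
  cfg
}
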