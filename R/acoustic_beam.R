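#' Focused spherical-cap transducer
#'
#' Geometry and drive of a single-element spherical-cap transducer with an
#' optional rectangular central cutout for a confocal imaging probe (the
#' cutout is what breaks the axial symmetry of the beam). The default
#' geometry is a 38-mm curvature radius, 56-mm aperture cap driven at 3 MHz
#' (f-number 0.68).
#'
#' @param curvature_radius Radius of curvature (m); the geometric focus sits
#'   on the axis at this distance from the cap apex.
#' @param aperture_diameter Aperture diameter (m), must be < 2 * curvature
#'   radius.
#' @param hole_width,hole_height Rectangular cutout extents (m) along x and y
#'   (0 for none). The imaging-probe long side is parallel to x.
#' @param frequency Drive frequency (Hz).
#' @param acoustic_power Total radiated acoustic power (W).
#' @return An object of class `transducer_spec`.
#' @export
transducer_spec <- function(curvature_radius = 0.038,
                            aperture_diameter = 0.056,
                            hole_width = 0.020, hole_height = 0.008,
                            frequency = 3e6, acoustic_power = 43.3) {
  stopifnot(curvature_radius > 0, aperture_diameter > 0,
            aperture_diameter < 2 * curvature_radius,
            hole_width >= 0, hole_height >= 0,
            frequency > 0, acoustic_power > 0)
  a <- aperture_diameter / 2
  if (hole_width / 2 > a || hole_height / 2 > a)
    stop("hole does not fit inside the aperture")
  s <- list(curvature_radius = curvature_radius,
            aperture_diameter = aperture_diameter,
            hole_width = hole_width, hole_height = hole_height,
            frequency = frequency, acoustic_power = acoustic_power)
  class(s) <- "transducer_spec"
  s
}

#' Area of a spherical cap
#' @param R Curvature radius (m).
#' @param a Aperture (rim) radius (m).
#' @return Cap surface area 2*pi*R*h with h = R - sqrt(R^2 - a^2).
#' @export
cap_area <- function(R, a) 2 * pi * R * (R - sqrt(R^2 - a^2))

#' Discretize the transducer surface into point elements
#'
#' Samples the spherical cap on a square lattice in the aperture plane and
#' lifts the points onto the cap, excluding the rectangular cutout. Element
#' areas carry the surface Jacobian `R / sqrt(R^2 - rho^2)` so that they sum
#' to the true cap area (minus the cutout) to well under 1 percent.
#'
#' The element pitch on the surface (largest at the rim) must not exceed half
#' a wavelength in water; the default projected pitch of one third of a
#' wavelength satisfies this for the reference geometry.
#'
#' @param spec A `transducer_spec`.
#' @param pitch Projected lattice pitch (m); default one third of the
#'   wavelength in water.
#' @param n_elements Alternative to `pitch`: approximate number of elements.
#' @param c_ref Sound speed (m/s) used for the wavelength check.
#' @return A data.frame with columns `x`, `y`, `z`, `area` (the cap apex is
#'   at z = 0, the focus at z = curvature_radius), with attributes `pitch`
#'   (projected) and `surface_pitch` (worst case, at the rim).
#' @export
discretize_aperture <- function(spec, pitch = NULL, n_elements = NULL,
                                c_ref = 1447) {
  R <- spec$curvature_radius
  a <- spec$aperture_diameter / 2
  lambda <- c_ref / spec$frequency
  if (is.null(pitch)) {
    pitch <- if (is.null(n_elements)) lambda / 3 else sqrt(pi * a^2 / n_elements)
  }
  surface_pitch <- pitch * R / sqrt(R^2 - a^2)
  if (surface_pitch > lambda / 2 + 1e-12)
    stop(sprintf(paste0("element pitch on the surface (%.3g m) exceeds half a ",
                        "wavelength (%.3g m); increase n_elements or reduce pitch"),
                 surface_pitch, lambda / 2))
  u <- pitch * seq(-floor(a / pitch), floor(a / pitch))  # symmetric lattice
  gx <- rep(u, times = length(u))
  gy <- rep(u, each = length(u))
  rho2 <- gx^2 + gy^2
  keep <- rho2 <= a^2
  if (spec$hole_width > 0 && spec$hole_height > 0)
    keep <- keep & !(abs(gx) < spec$hole_width / 2 &
                     abs(gy) < spec$hole_height / 2)
  if (!any(keep)) stop("aperture discretization is empty (hole covers the cap)")
  gx <- gx[keep]; gy <- gy[keep]; rho2 <- rho2[keep]
  el <- data.frame(x = gx, y = gy,
                   z = R - sqrt(R^2 - rho2),
                   area = pitch^2 * R / sqrt(R^2 - rho2))
  attr(el, "pitch") <- pitch
  attr(el, "surface_pitch") <- surface_pitch
  el
}

.empty_intensity <- function(dims) {
  list(x = NULL, y = NULL, z = NULL)
}

.acoustic_field <- function(p, grid, frequency, I = NULL) {
  f <- list(p = p, I = I, frequency = frequency, grid = grid)
  class(f) <- "acoustic_field"
  f
}

#' @export
print.acoustic_field <- function(x, ...) {
  cat(sprintf("<acoustic_field> %s voxels at %.3g MHz, |p| max = %.3g MPa%s\n",
              paste(dim(x$p), collapse = " x "), x$frequency / 1e6,
              max(Mod(x$p)) / 1e6,
              if (is.null(x$I)) " (no intensity yet)" else ""))
  invisible(x)
}

# Source-surface normal velocity amplitude that radiates `power` watts,
# using the plane-wave impedance relation P = rho*c*u0^2/2 * area.
.u0_for_power <- function(power, rho_c, area) sqrt(2 * power / (rho_c * area))

#' Steady-state pressure field of the focused transducer
#'
#' Sums the monochromatic point-source kernel `exp(ikr)/r` over the
#' discretized cap, with straight-ray per-layer amplitude attenuation and
#' phase speed (refraction at the layer interfaces is neglected). The source
#' amplitude is set so that the radiated acoustic power equals
#' `spec$acoustic_power` through the plane-wave impedance relation at the
#' source surface. Nonlinear propagation is not modelled; the
#' absorption-to-attenuation ratio applied downstream is understood to fold
#' in the nonlinear enhancement of absorption near the focus.
#'
#' Two evaluation paths produce the same sum: `"direct"` evaluates the kernel
#' at every voxel (exact, slow) while `"fast"` decomposes the aperture into a
#' hole-free cap, whose field is axisymmetric and is evaluated on a radial
#' table then spline-interpolated, minus the cutout patch, evaluated directly
#' (on a quarter of the grid when the grid is laterally symmetric about the
#' axis). `"auto"` picks `"fast"` above 100k voxel-element pairs per point.
#'
#' @param spec A `transducer_spec`.
#' @param grid A `cartesian_grid` whose z axis is the transducer axis
#'   (x = y = 0), with the cap apex at z = 0.
#' @param media A `layered_medium`.
#' @param method One of `"auto"`, `"direct"`, `"fast"`.
#' @param pitch Element pitch forwarded to [discretize_aperture()].
#' @return An `acoustic_field` with the complex pressure amplitude `p` (Pa);
#'   intensity is not yet filled (see [intensity_from_pressure()]).
#' @export
rayleigh_field <- function(spec, grid, media, method = c("auto", "direct", "fast"),
                           pitch = NULL) {
  method <- match.arg(method)
  el <- discretize_aperture(spec, pitch = pitch,
                            c_ref = media$media[[1]]$c_s)
  f <- spec$frequency
  omega <- 2 * pi * f
  ks <- vapply(media$media, function(m) omega / m$c_s, numeric(1))
  alphas <- vapply(media$media, attenuation_at_frequency, numeric(1),
                   f_MHz = f / 1e6)
  src <- media$media[[1]]
  u0 <- .u0_for_power(spec$acoustic_power, src$rho0 * src$c_s, sum(el$area))
  pref <- -1i * omega * src$rho0 * u0 / (2 * pi)

  if (method == "auto")
    method <- if (prod(dim(grid)) * nrow(el) > 5e8) "fast" else "direct"

  if (method == "direct") {
    pts <- as.matrix(expand.grid(x = grid$x, y = grid$y, z = grid$z))
    raw <- rayleigh_sum_cpp(el$x, el$y, el$z, el$area,
                            pts[, 1], pts[, 2], pts[, 3],
                            ks, alphas, media$boundaries)
    p <- array(pref * raw[, 1], dim = dim(grid))
    grads <- lapply(2:4, function(c) array(pref * raw[, c], dim = dim(grid)))
  } else {
    pg <- .rayleigh_fast(spec, grid, media, el, ks, alphas, pref)
    p <- pg$p
    grads <- pg$grads
  }
  field <- .acoustic_field(p, grid, f)
  field$I <- .intensity_analytic(p, grads, grid, media, omega)
  field
}

# I = Re(p conj(v))/2 with v = grad(p)/(i omega rho), rho from the point's
# layer; used by the Rayleigh stage whose kernel gradients are exact.
.intensity_analytic <- function(p, grads, grid, media, omega) {
  prof <- vapply(media$media, function(m) m$rho0, numeric(1))
  rho <- rep(prof[layer_index(media, grid$z)], each = grid$nx * grid$ny)
  res <- lapply(grads, function(gcomp) {
    I <- 0.5 * Re(p * Conj(gcomp / (1i * omega * rho)))
    dim(I) <- dim(p)
    I
  })
  names(res) <- c("x", "y", "z")
  res
}

# Fast path: axisymmetric hole-free cap evaluated by ring quadrature on an
# (r, z) table + spline interpolation in r, minus the directly-evaluated
# cutout patch.
.rayleigh_fast <- function(spec, grid, media, el, ks, alphas, pref) {
  R <- spec$curvature_radius
  a <- spec$aperture_diameter / 2
  pitch <- attr(el, "pitch")
  psi_max <- asin(a / R)
  n_rings <- ceiling(R * psi_max / pitch)

  lat_x <- rep(grid$x, times = grid$ny)
  lat_y <- rep(grid$y, each = grid$nx)
  rho_vox <- sqrt(lat_x^2 + lat_y^2)
  rmax <- max(rho_vox)
  r_tab <- seq(0, rmax + 25e-6, by = 25e-6)
  nt <- length(r_tab); nz <- grid$nz
  pts_r <- rep(r_tab, times = nz)
  pts_z <- rep(grid$z, each = nt)
  tab <- rayleigh_ring_cpp(R, psi_max, n_rings, pts_r, pts_z,
                           ks, alphas, media$boundaries)
  # interpolate the (r, z) tables of the kernel and its (radial, axial)
  # gradient onto the voxel lattice; the radial component is projected on
  # x and y with the direction cosines
  dims <- dim(grid)
  raw_p <- array(0i, dim = dims)
  raw_g <- list(array(0i, dims), array(0i, dims), array(0i, dims))
  cosx <- ifelse(rho_vox > 0, lat_x / rho_vox, 0)
  cosy <- ifelse(rho_vox > 0, lat_y / rho_vox, 0)
  interp <- function(col, k)
    complex(real = stats::spline(r_tab, Re(col[, k]), xout = rho_vox)$y,
            imaginary = stats::spline(r_tab, Im(col[, k]), xout = rho_vox)$y)
  tp <- matrix(tab[, 1], nt, nz)
  tr <- matrix(tab[, 2], nt, nz)
  tz <- matrix(tab[, 3], nt, nz)
  for (k in seq_len(nz)) {
    raw_p[, , k] <- interp(tp, k)
    gr <- interp(tr, k)
    raw_g[[1]][, , k] <- gr * cosx
    raw_g[[2]][, , k] <- gr * cosy
    raw_g[[3]][, , k] <- interp(tz, k)
  }

  if (spec$hole_width > 0 && spec$hole_height > 0) {
    u <- pitch * seq(-floor(a / pitch), floor(a / pitch))
    gx <- rep(u, times = length(u)); gy <- rep(u, each = length(u))
    rho2 <- gx^2 + gy^2
    hk <- rho2 <= a^2 & (abs(gx) < spec$hole_width / 2) &
      (abs(gy) < spec$hole_height / 2)
    hx <- gx[hk]; hy <- gy[hk]; hrho2 <- rho2[hk]
    hz <- R - sqrt(R^2 - hrho2)
    ha <- pitch^2 * R / sqrt(R^2 - hrho2)
    tol <- grid$dx * 1e-6
    sym_x <- grid$nx %% 2L == 1L && all(abs(grid$x + rev(grid$x)) < tol)
    sym_y <- grid$ny %% 2L == 1L && all(abs(grid$y + rev(grid$y)) < tol)
    if (sym_x && sym_y) {
      # centered hole: evaluate one lateral quadrant, mirror the rest
      # (pressure and the z gradient are even under x or y reflection, the
      # x and y gradients odd under their own reflection)
      ix <- which(grid$x <= tol); iy <- which(grid$y <= tol)
      qx <- rep(grid$x[ix], times = length(iy))
      qy <- rep(grid$y[iy], each = length(ix))
      qpts_x <- rep(qx, times = nz)
      qpts_y <- rep(qy, times = nz)
      qpts_z <- rep(grid$z, each = length(qx))
      raw <- rayleigh_sum_cpp(hx, hy, hz, ha, qpts_x, qpts_y, qpts_z,
                              ks, alphas, media$boundaries, fast_trig = TRUE)
      mi <- c(seq_along(ix), rev(seq_len(length(ix) - 1)))
      mj <- c(seq_along(iy), rev(seq_len(length(iy) - 1)))
      sx <- c(rep(1, length(ix)), rep(-1, grid$nx - length(ix)))
      sy <- c(rep(1, length(iy)), rep(-1, grid$ny - length(iy)))
      expand <- function(col, sgn_x = NULL, sgn_y = NULL) {
        q <- array(col, dim = c(length(ix), length(iy), nz))
        full <- array(0i, dim = dims)
        full[] <- q[mi, mj, , drop = FALSE]
        if (!is.null(sgn_x)) full <- full * sx
        if (!is.null(sgn_y)) full <- sweep(full, 2, sy, "*")
        full
      }
      raw_p <- raw_p - expand(raw[, 1])
      raw_g[[1]] <- raw_g[[1]] - expand(raw[, 2], sgn_x = TRUE)
      raw_g[[2]] <- raw_g[[2]] - expand(raw[, 3], sgn_y = TRUE)
      raw_g[[3]] <- raw_g[[3]] - expand(raw[, 4])
    } else {
      pts <- as.matrix(expand.grid(x = grid$x, y = grid$y, z = grid$z))
      raw <- rayleigh_sum_cpp(hx, hy, hz, ha, pts[, 1], pts[, 2], pts[, 3],
                              ks, alphas, media$boundaries, fast_trig = TRUE)
      raw_p <- raw_p - array(raw[, 1], dims)
      for (c in 1:3)
        raw_g[[c]] <- raw_g[[c]] - array(raw[, c + 1], dims)
    }
  }
  list(p = raw_p * pref, grads = lapply(raw_g, function(a) a * pref))
}

#' Time-averaged intensity from the complex pressure
#'
#' Fills the intensity vector `I = 0.5 * Re(p * conj(v))` using the
#' time-harmonic momentum relation `v = grad(p) / (i * omega * rho)`; the
#' pressure gradient is taken by centered differences (one-sided at the grid
#' faces). For a plane wave this reduces to `I_z = |p|^2 / (2 rho c)`.
#'
#' @param field An `acoustic_field`.
#' @param media A `layered_medium` (density per z plane).
#' @return The field with `I$x`, `I$y`, `I$z` filled (W/m^2).
#' @export
intensity_from_pressure <- function(field, media) {
  g <- field$grid
  prof <- media_profiles(media, g, field$frequency / 1e6)
  omega <- 2 * pi * field$frequency
  p <- field$p
  gx <- .gradient3(p, g$dx, 1)
  gy <- .gradient3(p, g$dx, 2)
  gz <- .gradient3(p, g$dx, 3)
  rho <- rep(prof$rho0, each = g$nx * g$ny)
  iwr <- 1i * omega * rho
  Ix <- 0.5 * Re(p * Conj(gx / iwr))
  Iy <- 0.5 * Re(p * Conj(gy / iwr))
  Iz <- 0.5 * Re(p * Conj(gz / iwr))
  dim(Ix) <- dim(Iy) <- dim(Iz) <- dim(p)
  field$I <- list(x = Ix, y = Iy, z = Iz)
  field
}

# centered-difference gradient along axis `ax`, one-sided at the two faces
.gradient3 <- function(arr, dx, ax) {
  d <- dim(arr)
  n <- d[ax]
  idx_p <- c(2:n, n)
  idx_m <- c(1, 1:(n - 1))
  denom <- rep(2 * dx, n)
  denom[c(1, n)] <- dx
  sel <- function(i) switch(ax, arr[i, , , drop = FALSE],
                            arr[, i, , drop = FALSE],
                            arr[, , i, drop = FALSE])
  out <- (sel(idx_p) - sel(idx_m))
  scale <- switch(ax,
                  array(rep(denom, times = d[2] * d[3]), dim = d),
                  aperm(array(rep(denom, times = d[1] * d[3]), dim = d[c(2, 1, 3)]),
                        c(2, 1, 3)),
                  array(rep(denom, each = d[1] * d[2]), dim = d))
  out / scale
}

#' Scale a field to a target plane-integrated power
#'
#' Scales the pressure (by the square root) and intensity so that the
#' integral of the axial intensity over the reference xy plane equals
#' `P_target`. Meant for imported or synthetic fields whose beam is fully
#' contained laterally at the reference plane; the built-in Rayleigh stage
#' sets its power at the source instead.
#'
#' @param field An `acoustic_field` with intensity filled.
#' @param P_target Target power (W).
#' @param z_index 1-based index of the reference plane (default: the focal
#'   plane).
#' @return The scaled field.
#' @export
normalize_to_power <- function(field, P_target, z_index = NULL) {
  g <- field$grid
  if (is.null(field$I)) stop("fill intensity first (intensity_from_pressure)")
  if (is.null(z_index)) z_index <- nearest_voxel(g, g$focus)[3] + 1L
  pw <- sum(field$I$z[, , z_index]) * g$dx^2
  if (pw <= 0) stop("plane-integrated power at the reference plane is not positive")
  s <- P_target / pw
  field$p <- field$p * sqrt(s)
  field$I <- lapply(field$I, function(a) a * s)
  field
}

#' Export / import a field volume
#'
#' The container is a pair of NIfTI volumes (real and imaginary pressure,
#' plus optional intensity components) with a JSON sidecar recording the
#' grid spacing, origin, focus and frequency.
#'
#' @param field An `acoustic_field`.
#' @param path Path prefix (files `<path>_preal.nii.gz`, `<path>_pimag.nii.gz`,
#'   optionally `<path>_i{x,y,z}.nii.gz`, and `<path>.json` are written).
#' @return `export_field`: `path`, invisibly. `import_field`: an
#'   `acoustic_field` on `grid`.
#' @export
export_field <- function(field, path) {
  g <- field$grid
  write_volume(Re(field$p), paste0(path, "_preal.nii.gz"), g$dx)
  write_volume(Im(field$p), paste0(path, "_pimag.nii.gz"), g$dx)
  has_I <- !is.null(field$I)
  if (has_I)
    for (cc in c("x", "y", "z"))
      write_volume(field$I[[cc]], paste0(path, "_i", cc, ".nii.gz"), g$dx)
  meta <- list(dx = g$dx, origin = g$origin, focus = g$focus,
               shape = dim(g), frequency = field$frequency,
               has_intensity = has_I)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @param path Path prefix used at export time.
#' @param grid The `cartesian_grid` the field is expected to live on.
#' @param media Optional `layered_medium`; if given and the container has no
#'   intensity, [intensity_from_pressure()] is applied.
#' @rdname export_field
#' @export
import_field <- function(path, grid, media = NULL) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!isTRUE(all(meta$shape == dim(grid))))
    stop("stored field shape does not match the grid")
  if (abs(meta$dx - grid$dx) > 1e-9 * grid$dx)
    stop("stored voxel spacing does not match the grid")
  re <- read_volume(paste0(path, "_preal.nii.gz"))$data
  im <- read_volume(paste0(path, "_pimag.nii.gz"))$data
  p <- array(complex(real = re, imaginary = im), dim = dim(grid))
  field <- .acoustic_field(p, grid, meta$frequency)
  if (isTRUE(meta$has_intensity)) {
    field$I <- list(x = read_volume(paste0(path, "_ix.nii.gz"))$data,
                    y = read_volume(paste0(path, "_iy.nii.gz"))$data,
                    z = read_volume(paste0(path, "_iz.nii.gz"))$data)
  } else if (!is.null(media)) {
    field <- intensity_from_pressure(field, media)
  }
  field
}
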