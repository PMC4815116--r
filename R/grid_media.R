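#' Cartesian voxel grid
#'
#' Builds the isotropic voxel lattice on which acoustic, heat-source and
#' thermal fields live. Voxel indices are 0-based; the voxel `(i, j, k)` has
#' its center at `origin + c(i, j, k) * dx`. The z axis points from the
#' transducer toward the focus.
#'
#' @param nx,ny,nz Voxel counts along x, y, z (each >= 3).
#' @param dx Isotropic voxel spacing in meters.
#' @param origin Physical coordinate (m) of the center of voxel (0, 0, 0),
#'   numeric length 3.
#' @param focus Physical coordinate (m) of the geometric focus; must lie
#'   strictly inside the grid extents.
#' @return An object of class `cartesian_grid` with fields `nx`, `ny`, `nz`,
#'   `dx`, `origin`, `focus`, and cached axis coordinate vectors `x`, `y`, `z`.
#' @examples
#' g <- build_grid(71, 71, 111, 200e-6,
#'                 origin = c(-7e-3, -7e-3, 24.8e-3),
#'                 focus  = c(0, 0, 38e-3))
#' prod(dim(g))  # 559191 voxels
#' @export
build_grid <- function(nx, ny, nz, dx, origin, focus) {
  stopifnot(length(origin) == 3, length(focus) == 3)
  if (any(c(nx, ny, nz) < 3)) stop("grid needs at least 3 voxels per axis")
  if (dx <= 0) stop("dx must be positive")
  n <- c(nx, ny, nz)
  lo <- origin
  hi <- origin + (n - 1) * dx
  if (any(focus <= lo) || any(focus >= hi))
    stop("focus must lie strictly inside the grid extents")
  g <- list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
            dx = dx, origin = origin, focus = focus,
            x = origin[1] + (seq_len(nx) - 1) * dx,
            y = origin[2] + (seq_len(ny) - 1) * dx,
            z = origin[3] + (seq_len(nz) - 1) * dx)
  class(g) <- "cartesian_grid"
  g
}

#' @export
dim.cartesian_grid <- function(x) c(x$nx, x$ny, x$nz)

#' @export
print.cartesian_grid <- function(x, ...) {
  cat(sprintf("<cartesian_grid> %d x %d x %d voxels, dx = %g um\n",
              x$nx, x$ny, x$nz, x$dx * 1e6))
  cat(sprintf("  z extent: [%.2f, %.2f] mm, focus at (%.2f, %.2f, %.2f) mm\n",
              x$z[1] * 1e3, x$z[x$nz] * 1e3,
              x$focus[1] * 1e3, x$focus[2] * 1e3, x$focus[3] * 1e3))
  invisible(x)
}

#' Physical coordinates of a voxel index triple
#'
#' @param grid A `cartesian_grid`.
#' @param ijk Integer 0-based voxel indices, length 3 or an n-by-3 matrix.
#' @return Physical coordinates in meters (same shape as `ijk`).
#' @export
voxel_center <- function(grid, ijk) {
  if (is.matrix(ijk)) {
    sweep(ijk * grid$dx, 2, grid$origin, "+")
  } else {
    grid$origin + ijk * grid$dx
  }
}

#' Voxel index nearest to a physical coordinate
#'
#' @param grid A `cartesian_grid`.
#' @param xyz Physical coordinate (m), length 3.
#' @return Integer 0-based voxel indices, length 3.
#' @export
nearest_voxel <- function(grid, xyz) {
  as.integer(round((xyz - grid$origin) / grid$dx))
}

#' Acoustic and thermal properties of a medium
#'
#' The attenuation entry follows the usual power law
#' \eqn{\alpha(f) = \alpha_0 f^y} with `alpha0` in dB cm^-1 MHz^-y.
#' `A` is the absorption-to-attenuation ratio: only the fraction `A` of the
#' power lost by the wave is converted into heat, the rest being scattered.
#'
#' @param name Medium label.
#' @param c_s Sound speed (m/s).
#' @param rho0 Density (kg/m^3).
#' @param alpha0 Attenuation at 1 MHz (dB cm^-1 MHz^-y).
#' @param y Attenuation frequency-power-law exponent.
#' @param C0 Baseline specific heat (J kg^-1 K^-1).
#' @param k_t Thermal conductivity (W m^-1 K^-1).
#' @param w_b0 Perfusion rate at zero thermal dose (s^-1).
#' @param A Absorption-to-attenuation ratio in (0, 1].
#' @param tissue Logical; `TRUE` for soft tissue (denaturation/boiling
#'   excess specific heat applies), `FALSE` for coupling water.
#' @return An object of class `medium_properties`.
#' @export
medium <- function(name, c_s, rho0, alpha0, y, C0, k_t, w_b0 = 0,
                   A = 1, tissue = TRUE) {
  stopifnot(c_s > 0, rho0 > 0, alpha0 > 0, y > 0, C0 > 0, k_t > 0,
            w_b0 >= 0, A > 0, A <= 1)
  m <- list(name = name, c_s = c_s, rho0 = rho0, alpha0 = alpha0, y = y,
            C0 = C0, k_t = k_t, w_b0 = w_b0, A = A, tissue = isTRUE(tissue))
  class(m) <- "medium_properties"
  m
}

#' Reference media
#'
#' Acoustic and thermal properties of the coupling water, superficial tissue
#' (skin, subcutaneous fat, muscle lumped into one homogeneous layer) and
#' liver used throughout the package. Thermal properties of water are the
#' textbook values at body temperature; the superficial-tissue layer reuses
#' the liver thermal properties (only its acoustic properties differ).
#'
#' @return A named list of `medium_properties`: `water`, `superficial`,
#'   `liver`.
#' @export
reference_media <- function() {
  list(
    water = medium("water", c_s = 1447, rho0 = 1000, alpha0 = 2.2e-3, y = 2,
                   C0 = 4180, k_t = 0.60, w_b0 = 0, A = 1, tissue = FALSE),
    superficial = medium("superficial tissue", c_s = 1547, rho0 = 1214,
                         alpha0 = 0.62, y = 1.27,
                         C0 = 3700, k_t = 0.55, w_b0 = 0.018, A = 1),
    liver = medium("liver", c_s = 1614, rho0 = 996, alpha0 = 0.37, y = 1.27,
                   C0 = 3700, k_t = 0.55, w_b0 = 0.018, A = 1)
  )
}

#' Power-law attenuation at a given frequency
#'
#' Converts the dB cm^-1 MHz^-y entry to Np/m at frequency `f_MHz`:
#' \eqn{\alpha = \alpha_0 f^y \cdot \ln(10)/20 \cdot 100}. The result is an
#' amplitude attenuation (pressure decays as \eqn{e^{-\alpha z}}, intensity
#' as \eqn{e^{-2\alpha z}}).
#'
#' @param medium A `medium_properties`.
#' @param f_MHz Frequency in MHz (> 0).
#' @return Attenuation in Np/m.
#' @examples
#' attenuation_at_frequency(reference_media()$liver, 3)  # ~17.19 Np/m
#' @export
attenuation_at_frequency <- function(medium, f_MHz) {
  stopifnot(f_MHz > 0)
  db_per_cm <- medium$alpha0 * f_MHz^medium$y
  db_per_cm * log(10) / 20 * 100
}

#' Layered medium stack
#'
#' A piecewise-constant assignment of media to z intervals. Intervals are
#' contiguous and half-open `[z_i, z_{i+1})`; the first boundary is -Inf and
#' the last +Inf so that any grid is covered. Medium is independent of x, y.
#'
#' @param media List of `medium_properties`, proximal to distal.
#' @param boundaries Increasing z coordinates (m) of the internal interfaces;
#'   length must be `length(media) - 1`.
#' @return An object of class `layered_medium`.
#' @examples
#' med <- reference_media()
#' lm <- layered_medium(list(med$water, med$liver), boundaries = 22e-3)
#' @export
layered_medium <- function(media, boundaries = numeric(0)) {
  stopifnot(length(boundaries) == length(media) - 1)
  if (length(boundaries) > 1 && any(diff(boundaries) <= 0))
    stop("layer boundaries must be strictly increasing")
  lm <- list(media = media, boundaries = as.numeric(boundaries))
  class(lm) <- "layered_medium"
  lm
}

#' Layer index for z coordinates
#'
#' @param lm A `layered_medium`.
#' @param z Numeric vector of z coordinates (m).
#' @return Integer layer indices (1-based into `lm$media`).
#' @export
layer_index <- function(lm, z) {
  findInterval(z, lm$boundaries) + 1L
}

#' Per-z-plane medium property vectors for a grid
#'
#' Samples the layered medium at the grid's z planes and returns one value
#' per plane for each property the solvers need.
#'
#' @param lm A `layered_medium`.
#' @param grid A `cartesian_grid`.
#' @param f_MHz Frequency (MHz) at which attenuation is evaluated.
#' @return A list of numeric vectors of length `nz`: `c_s`, `rho0`, `alpha`
#'   (Np/m at `f_MHz`), `C0`, `k_t`, `w_b0`, `A`, and logical `tissue`.
#' @export
media_profiles <- function(lm, grid, f_MHz) {
  idx <- layer_index(lm, grid$z)
  pull <- function(field) vapply(lm$media, function(m) m[[field]], numeric(1))[idx]
  list(c_s = pull("c_s"), rho0 = pull("rho0"),
       alpha = vapply(lm$media, attenuation_at_frequency,
                      numeric(1), f_MHz = f_MHz)[idx],
       C0 = pull("C0"), k_t = pull("k_t"), w_b0 = pull("w_b0"),
       A = pull("A"),
       tissue = vapply(lm$media, function(m) m$tissue, logical(1))[idx])
}
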