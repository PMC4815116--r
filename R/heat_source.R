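.heat_source_field <- function(Q, grid, provenance, A = NA_real_,
                               sigma_defoc = NA_real_, clipped = 0) {
  h <- list(Q = Q, grid = grid, provenance = provenance, A = A,
            sigma_defoc = sigma_defoc, clipped = clipped)
  class(h) <- "heat_source_field"
  h
}

#' @export
print.heat_source_field <- function(x, ...) {
  cat(sprintf("<heat_source_field> %s, max Q = %.3g W/m^3 (%s%s)\n",
              paste(dim(x$Q), collapse = " x "), max(x$Q), x$provenance,
              if (!is.na(x$A)) sprintf(", A = %.3g, sigma = %.3g um",
                                       x$A, x$sigma_defoc * 1e6) else ""))
  invisible(x)
}

#' Plane-wave linear heat source
#'
#' Under the plane-wave approximation the power lost by the wave per unit
#' volume is `Q = 2 * alpha_att * I` with `I = |p|^2 / (2 rho c)`, i.e.
#' `Q = alpha_att * |p|^2 / (rho c)` with per-voxel medium properties.
#' The absorption ratio is not applied here (see
#' [apply_absorption_and_defocus()]).
#'
#' @param field An `acoustic_field`.
#' @param media A `layered_medium`.
#' @return A `heat_source_field` (W/m^3).
#' @export
plane_wave_heat_source <- function(field, media) {
  g <- field$grid
  prof <- media_profiles(media, g, field$frequency / 1e6)
  per_plane <- prof$alpha / (prof$rho0 * prof$c_s)
  Q <- Mod(field$p)^2 * rep(per_plane, each = g$nx * g$ny)
  dim(Q) <- dim(g)
  .heat_source_field(Q, g, "plane_wave")
}

#' Divergence-form heat source (diagnostic)
#'
#' The exact local power loss is `-div(I)`. On finite-difference grids this
#' produces locally negative values in focused beams and is exposed as a
#' signed diagnostic only; it is never fed to the thermal solver.
#'
#' @param field An `acoustic_field` with intensity filled.
#' @return A signed numeric array (W/m^3).
#' @export
divergence_heat_source <- function(field) {
  if (is.null(field$I)) stop("fill intensity first (intensity_from_pressure)")
  dx <- field$grid$dx
  -(.gradient3(field$I$x, dx, 1) +
    .gradient3(field$I$y, dx, 2) +
    .gradient3(field$I$z, dx, 3))
}

#' Axial power profile with side-flux compensation
#'
#' The acoustic power crossing each xy plane: the plane integral of `I_z`
#' plus the cumulative integrals of the lateral intensity over the four side
#' faces of the domain from `z_min` up to the plane. The side terms
#' compensate for power entering or leaving through the sides, so that in a
#' lossless medium the profile is constant and its z derivative measures
#' exactly the power absorbed per layer. Midpoint quadrature with cell
#' area dx^2.
#'
#' @param field An `acoustic_field` with intensity filled.
#' @return An object of class `axial_power_profile` with fields `P` (W,
#'   length nz), `P_plane` (the uncorrected plane integrals), `side_cum`,
#'   and `z` (m).
#' @export
axial_power_profile <- function(field) {
  if (is.null(field$I)) stop("fill intensity first (intensity_from_pressure)")
  g <- field$grid
  dA <- g$dx^2
  P_plane <- apply(field$I$z, 3, sum) * dA
  nx <- g$nx; ny <- g$ny
  side <- (colSums(-field$I$x[1, , , drop = TRUE]) +
           colSums(field$I$x[nx, , , drop = TRUE]) +
           colSums(-field$I$y[, 1, , drop = TRUE]) +
           colSums(field$I$y[, ny, , drop = TRUE])) * dA
  side_cum <- cumsum(side)
  # Anchor at the focal plane: there the beam is laterally contained, so the
  # plane integral alone is the power crossing. The side terms then carry
  # the correct derivative (in-box absorption per layer) to every other
  # plane. For a beam fully contained at all z the anchor is a no-op.
  kf <- nearest_voxel(g, g$focus)[3] + 1L
  P <- P_plane + side_cum - side_cum[kf]
  out <- list(P = P, P_plane = P_plane, side_cum = side_cum, z = g$z)
  class(out) <- "axial_power_profile"
  out
}

#' Energy-conserving heat source
#'
#' Distributes the power lost within each voxel layer, `-dP/dz * dz` from the
#' axial power profile, across the layer's xy plane proportionally to
#' `|p|^2`. Layer losses are taken as differences of the profile interpolated
#' at half-planes (centered differences in the interior, one-sided halves at
#' the two ends), so that the total deposited power telescopes exactly to
#' `P(z_min) - P(z_max)`. Layers with a negative loss (artefactual gain) are
#' clipped to zero and the clipped magnitude is recorded in the `clipped`
#' field.
#'
#' @param profile An `axial_power_profile`.
#' @param field The `acoustic_field` on the same grid.
#' @return A `heat_source_field` (W/m^3), provenance `"conservative"`.
#' @export
conservative_heat_source <- function(profile, field) {
  g <- field$grid
  P <- profile$P
  nz <- g$nz
  Phalf <- c(P[1], (P[-nz] + P[-1]) / 2, P[nz])  # length nz + 1
  loss <- Phalf[-(nz + 1)] - Phalf[-1]           # per-layer lost power (W)
  clipped <- -sum(loss[loss < 0])
  loss[loss < 0] <- 0
  w <- Mod(field$p)^2
  plane_norm <- apply(w, 3, sum)
  bad <- plane_norm <= 0 & loss > 0
  if (any(bad))
    stop("layer with zero pressure norm but nonzero power loss")
  scale <- ifelse(plane_norm > 0, loss / plane_norm, 0) / g$dx^3
  Q <- w * rep(scale, each = g$nx * g$ny)
  dim(Q) <- dim(g)
  .heat_source_field(Q, g, "conservative", clipped = clipped)
}

# truncated (4 sigma) renormalized 1D Gaussian kernel in voxel units
.gauss_kernel <- function(sigma_vox) {
  h <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-h):h)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# zero-padded separable 2D convolution of every xy plane of a 3D array
.convolve_planes <- function(arr, kernel) {
  d <- dim(arr)
  h <- (length(kernel) - 1L) / 2L
  band <- function(n) {
    K <- matrix(0, n, n)
    for (o in -h:h) {
      idx <- seq_len(n - abs(o))
      if (o >= 0) K[cbind(idx + o, idx)] <- kernel[h + 1 + o]
      else K[cbind(idx, idx - o)] <- kernel[h + 1 - o]
    }
    K
  }
  Kx <- band(d[1]); Ky <- band(d[2])
  out <- arr
  for (k in seq_len(d[3]))
    out[, , k] <- Kx %*% arr[, , k] %*% t(Ky)
  out
}

#' Absorption ratio and defocusing blur
#'
#' Produces the working heat source `Q0 = A * (Q_cons convolved with a 2D
#' Gaussian of standard deviation sigma_defoc in each xy plane)`. The
#' convolution models the defocusing induced by tissue heterogeneity and
#' interface irregularities; it is two-dimensional (per plane) so the axial
#' deposition profile is untouched, and the kernel is truncated at 4 sigma
#' and renormalized so per-plane power is preserved for beams away from the
#' lateral boundaries.
#'
#' @param Q A `heat_source_field` (typically from
#'   [conservative_heat_source()]).
#' @param A Absorption-to-attenuation ratio in (0, 1].
#' @param sigma_defoc Defocusing standard deviation (m), >= 0.
#' @return A `heat_source_field` with `A` applied and `sigma_defoc` recorded.
#' @export
apply_absorption_and_defocus <- function(Q, A, sigma_defoc) {
  stopifnot(A > 0, A <= 1, sigma_defoc >= 0)
  g <- Q$grid
  out <- Q$Q
  if (sigma_defoc > 0)
    out <- .convolve_planes(out, .gauss_kernel(sigma_defoc / g$dx))
  .heat_source_field(out * A, g, Q$provenance, A = A,
                     sigma_defoc = sigma_defoc, clipped = Q$clipped)
}

# integer-shift a 3D array laterally with zero fill
.shift_xy <- function(arr, ix, iy) {
  d <- dim(arr)
  out <- array(0, dim = d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2])
  dst_x <- sx + ix; dst_y <- sy + iy
  okx <- dst_x >= 1 & dst_x <= d[1]
  oky <- dst_y >= 1 & dst_y <= d[2]
  out[dst_x[okx], dst_y[oky], ] <- arr[sx[okx], sy[oky], ]
  out
}

#' Translate the heat source laterally
#'
#' Models the movement of the focus (robotic trajectories) as a simple
#' translation of the heat source in the xy plane. Sub-voxel offsets use
#' bilinear interpolation; integer-voxel offsets are exact array shifts.
#' Power shifted out of the grid is lost (and the fraction retained can be
#' checked by summing before and after).
#'
#' @param Q0 A `heat_source_field`.
#' @param offset Numeric length 2, lateral offset (m) along x and y.
#' @return The translated `heat_source_field`.
#' @export
translate_source <- function(Q0, offset) {
  stopifnot(length(offset) == 2)
  g <- Q0$grid
  o <- offset / g$dx
  if (max(abs(o)) >= max(dim(g)[1:2]))
    stop("offset larger than the grid extent")
  i0 <- floor(o)
  fr <- o - i0
  arr <- Q0$Q
  out <- (1 - fr[1]) * (1 - fr[2]) * .shift_xy(arr, i0[1], i0[2])
  if (fr[1] > 0) out <- out + fr[1] * (1 - fr[2]) * .shift_xy(arr, i0[1] + 1, i0[2])
  if (fr[2] > 0) out <- out + (1 - fr[1]) * fr[2] * .shift_xy(arr, i0[1], i0[2] + 1)
  if (fr[1] > 0 && fr[2] > 0)
    out <- out + fr[1] * fr[2] * .shift_xy(arr, i0[1] + 1, i0[2] + 1)
  res <- Q0
  res$Q <- out
  res
}
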