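#' Boiling equivalent-model parameters
#'
#' Bubble clouds reflect most of the incident beam, so once tissue boils the
#' heat deposition pattern changes qualitatively. No tractable acoustic
#' solver captures the scattering, so a phenomenological equivalent model
#' redistributes the power intercepted by the cloud into an enhanced-heating
#' zone around it. Four knobs govern it: the radius of the enhanced zone,
#' the fraction of intercepted power converted to heat, the boost factor of
#' the prefocal refocusing cone, and the cone half-aperture. Defaults are
#' the calibrated values for the reference transducer.
#'
#' @param T_boil Boiling temperature threshold (deg C).
#' @param R_SE Radius (m) of the spherical structuring element dilating the
#'   cloud into the enhanced zone.
#' @param eta_intercept Fraction of the intercepted acoustic power deposited
#'   as heat in the enhanced zone (the rest is treated as scattered away).
#' @param W_plus Heating boost inside the refocusing cone when the cloud top
#'   is locally concave.
#' @param theta_cone Cone half-aperture (rad), apex at the instantaneous
#'   focus, axis toward the transducer.
#' @param postfocal_base_attenuation If TRUE, additionally multiply the base
#'   source beyond the shielding plane by (1 - r_shield). Off by default:
#'   the equivalent model only zeroes the source inside the cloud and adds
#'   the redistributed term.
#' @param enabled Master switch for the boiling model.
#' @return An object of class `boiling_params`.
#' @export
boiling_params <- function(T_boil = 85, R_SE = 2.5e-3, eta_intercept = 0.31,
                           W_plus = 10, theta_cone = pi / 18,
                           postfocal_base_attenuation = FALSE,
                           enabled = TRUE) {
  stopifnot(R_SE > 0, eta_intercept >= 0, eta_intercept <= 1, W_plus >= 1,
            theta_cone > 0, theta_cone < pi / 2)
  p <- list(T_boil = T_boil, R_SE = R_SE, eta_intercept = eta_intercept,
            W_plus = W_plus, theta_cone = theta_cone,
            postfocal_base_attenuation = isTRUE(postfocal_base_attenuation),
            enabled = isTRUE(enabled))
  class(p) <- "boiling_params"
  p
}

#' Bubble-cloud mask
#'
#' Grid points strictly above the boiling temperature at the current time.
#'
#' @param T Temperature array (deg C).
#' @param T_boil Boiling threshold (deg C).
#' @return Logical array.
#' @export
boiling_region <- function(T, T_boil = 85) {
  T > T_boil
}

#' Shielding coefficient of the bubble cloud
#'
#' Per xy plane, the fraction of the deposited power intercepted by the
#' cloud; the shielding coefficient is the maximum over planes and
#' `z_shield` the plane where it is reached (smallest z on ties; planes with
#' no deposited power contribute zero).
#'
#' @param Q A `heat_source_field` (or numeric array), the unmodified source.
#' @param B Logical array, the bubble-cloud mask.
#' @return List with `r_shield` in `[0, 1]` and `z_shield` (1-based plane
#'   index, `NA` if the cloud is empty).
#' @export
shielding_coefficient <- function(Q, B) {
  Qarr <- if (inherits(Q, "heat_source_field")) Q$Q else Q
  stopifnot(identical(dim(Qarr), dim(B)))
  tot <- apply(Qarr, 3, sum)
  inB <- apply(Qarr * B, 3, sum)
  ratio <- ifelse(tot > 0, inB / tot, 0)
  if (!any(B)) return(list(r_shield = 0, z_shield = NA_integer_))
  list(r_shield = max(ratio), z_shield = which.max(ratio))
}

#' Enhanced-heating zone
#'
#' Morphological dilation of the bubble cloud with a voxelized ball of
#' radius `R_SE`: the set of offsets whose Euclidean length times dx does
#' not exceed `R_SE`.
#'
#' @param B Logical array (bubble cloud).
#' @param R_SE Structuring-element radius (m).
#' @param grid The `cartesian_grid`.
#' @return Logical array containing `B`.
#' @export
enhanced_zone <- function(B, R_SE, grid) {
  if (R_SE < grid$dx) stop("R_SE must be at least one voxel")
  idx <- which(B)
  H <- array(FALSE, dim(B))
  if (length(idx) == 0) return(H)
  d <- dilate_distance_cpp(as.integer(idx - 1L), grid$nx, grid$ny, grid$nz,
                           R_SE / grid$dx)
  H[is.finite(d)] <- TRUE
  H
}

#' Power intercepted by the bubble cloud
#'
#' The total power redistributed into the enhanced zone: a fraction
#' `eta_intercept` of the shielded share of the acoustic power reaching the
#' shielding plane.
#'
#' @param r_shield,z_shield Output of [shielding_coefficient()].
#' @param profile An `axial_power_profile`.
#' @param eta_intercept Interception efficiency in `[0, 1]`.
#' @return Power (W).
#' @export
intercepted_power <- function(r_shield, z_shield, profile, eta_intercept) {
  if (r_shield == 0 || is.na(z_shield)) return(0)
  eta_intercept * r_shield * profile$P[z_shield]
}

#' Local convexity of the bubble-cloud top
#'
#' The cloud top (most proximal extent, smallest z) is locally convex when
#' the global minimum z over the cloud is attained on the focal column, the
#' (x, y) voxel column nearest the instantaneous focus. A concave top means
#' the cloud has grown a rim that reaches closer to the transducer off-axis,
#' which redirects the refocused energy.
#'
#' @param B Logical array, nonempty.
#' @param grid The `cartesian_grid`.
#' @param focus Instantaneous focus coordinates (m), length 3 (z unused).
#' @return TRUE if locally convex.
#' @export
cloud_convexity <- function(B, grid, focus = grid$focus) {
  idx <- which(B)
  if (length(idx) == 0) stop("bubble cloud is empty")
  ar <- arrayInd(idx, dim(grid))
  zmin_global <- min(ar[, 3])
  col <- nearest_voxel(grid, focus)[1:2] + 1L
  oncol <- ar[, 1] == col[1] & ar[, 2] == col[2]
  if (!any(oncol)) return(FALSE)
  min(ar[oncol, 3]) == zmin_global
}

#' Redistribution weights on the enhanced zone
#'
#' The intercepted power is spread over the enhanced zone minus the cloud
#' (heating is null inside the cloud itself) proportionally to the product
#' of three factors: `W1`, the inverse distance to the cloud (voxel-center
#' distances in voxel units); `W2`, equal to 1 up to the shielding plane and
#' `r_shield` beyond it (the cloud shadows the distal side); and `W3`, which
#' follows the undisturbed source term when the cloud top is locally convex,
#' and otherwise is uniform except for a boost `W_plus` inside the
#' refocusing cone (apex at the instantaneous focus, axis toward the
#' transducer, half-aperture `theta_cone`).
#'
#' @param B,H Logical arrays, `H` containing `B`.
#' @param Q0 A `heat_source_field` (or array): the source in the absence of
#'   boiling, already translated to the instantaneous focus.
#' @param r_shield,z_shield Output of [shielding_coefficient()].
#' @param grid The `cartesian_grid`.
#' @param focus Instantaneous focus (m).
#' @param params A `boiling_params`.
#' @param dist Optional precomputed distance array (voxel units) from
#'   [dilate_distance_cpp()]; recomputed if missing.
#' @return A list with integer vector `idx` (1-based indices of `H \ B`) and
#'   numeric vectors `W1`, `W2`, `W3` on those voxels, plus `convex`.
#' @export
boiling_weights <- function(B, H, Q0, r_shield, z_shield, grid,
                            focus = grid$focus, params = boiling_params(),
                            dist = NULL) {
  Qarr <- if (inherits(Q0, "heat_source_field")) Q0$Q else Q0
  if (is.null(dist)) {
    idxB <- which(B)
    dist <- dilate_distance_cpp(as.integer(idxB - 1L),
                                grid$nx, grid$ny, grid$nz,
                                params$R_SE / grid$dx)
  }
  idx <- which(H & !B)
  if (length(idx) == 0)
    return(list(idx = integer(0), W1 = numeric(0), W2 = numeric(0),
                W3 = numeric(0), convex = NA))
  ar <- arrayInd(idx, dim(grid))
  W1 <- 1 / dist[idx]
  W2 <- ifelse(!is.na(z_shield) & ar[, 3] > z_shield, r_shield, 1)
  convex <- cloud_convexity(B, grid, focus)
  if (convex) {
    W3 <- Qarr[idx]
  } else {
    W3 <- rep(1, length(idx))
    xyz <- voxel_center(grid, ar - 1L)
    dxy <- sqrt((xyz[, 1] - focus[1])^2 + (xyz[, 2] - focus[2])^2)
    dz <- focus[3] - xyz[, 3]   # positive toward the transducer
    incone <- dz > 0 & atan2(dxy, dz) <= params$theta_cone
    W3[incone] <- params$W_plus
  }
  list(idx = idx, W1 = W1, W2 = W2, W3 = W3, convex = convex)
}

#' Redistributed boiling heat source
#'
#' Normalizes the weight product so the redistributed power integrates
#' exactly to `P_H`.
#'
#' @param P_H Intercepted power (W).
#' @param weights Output of [boiling_weights()].
#' @param grid The `cartesian_grid`.
#' @return A numeric array (W/m^3), nonzero only on `H \ B`.
#' @export
boiling_heat_source <- function(P_H, weights, grid) {
  Qb <- array(0, dim(grid))
  if (P_H <= 0) return(Qb)
  w <- weights$W1 * weights$W2 * weights$W3
  s <- sum(w)
  if (s <= 0) stop("all boiling weights are zero but P_H > 0")
  Qb[weights$idx] <- P_H * w / (s * grid$dx^3)
  Qb
}

#' Total heat source in the presence of boiling
#'
#' The base source is zeroed inside the bubble cloud (the energy there is
#' spent on mechanical and thermal damage, not temperature rise) and the
#' redistributed term is added on the enhanced zone. Optionally the base
#' source beyond the shielding plane is attenuated by (1 - r_shield).
#'
#' @param Q0 A `heat_source_field` (or array), translated to the current
#'   focus.
#' @param B Logical array (bubble cloud).
#' @param Q_boil Numeric array from [boiling_heat_source()].
#' @param r_shield,z_shield Output of [shielding_coefficient()].
#' @param params A `boiling_params`.
#' @return A numeric array (W/m^3).
#' @export
compose_total_source <- function(Q0, B, Q_boil, r_shield, z_shield,
                                 params = boiling_params()) {
  Qarr <- if (inherits(Q0, "heat_source_field")) Q0$Q else Q0
  out <- Qarr
  if (params$postfocal_base_attenuation && !is.na(z_shield) &&
      z_shield < dim(out)[3]) {
    post <- seq(z_shield + 1L, dim(out)[3])
    out[, , post] <- out[, , post] * (1 - r_shield)
  }
  out[B] <- 0
  out + Q_boil
}

# One full boiling-model update: from the current temperature field and
# translated base source to the composed total source. Returns the total
# source plus the per-step diagnostics.
.boiling_update <- function(T, Q0, profile, grid, focus, params) {
  B <- boiling_region(T, params$T_boil)
  idxB <- which(B)
  if (length(idxB) == 0)
    return(list(Q_total = if (inherits(Q0, "heat_source_field")) Q0$Q else Q0,
                n_cloud = 0L, r_shield = 0, z_shield = NA_integer_,
                P_H = 0, convex = NA))
  dist <- dilate_distance_cpp(as.integer(idxB - 1L),
                              grid$nx, grid$ny, grid$nz,
                              params$R_SE / grid$dx)
  H <- array(is.finite(dist), dim(grid))
  sh <- shielding_coefficient(Q0, B)
  P_H <- intercepted_power(sh$r_shield, sh$z_shield, profile,
                           params$eta_intercept)
  w <- boiling_weights(B, H, Q0, sh$r_shield, sh$z_shield, grid, focus,
                       params, dist = dist)
  Qb <- boiling_heat_source(P_H, w, grid)
  Qt <- compose_total_source(Q0, B, Qb, sh$r_shield, sh$z_shield, params)
  list(Q_total = Qt, n_cloud = length(idxB), r_shield = sh$r_shield,
       z_shield = sh$z_shield, P_H = P_H, convex = w$convex)
}
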