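#' Accumulate CEM43 thermal dose
#'
#' Adds `dt * 0.5^(43 - T)` to the dose field using the current (post-step)
#' temperature, updates the cumulative boiling mask (`T > T_boil` at any
#' time), stashes the current maximum temperature in `state$last_max_T`, and
#' advances the clock. The single-exponent base-0.5 form is applied at all
#' temperatures, during heating and cooling alike.
#'
#' @param state A `thermal_state`.
#' @param dt Time step (s), > 0.
#' @param T_boil Boiling threshold (deg C) for the cumulative mask.
#' @return The updated `thermal_state`.
#' @export
accumulate_dose <- function(state, dt, T_boil = 85) {
  stopifnot(dt > 0)
  D <- state$D + 0           # force copies: the kernel updates in place
  boiled <- state$boiled | FALSE
  state$last_max_T <- dose_update_cpp(D, state$T, dt, T_boil, boiled)
  state$D <- D
  state$boiled <- boiled
  state$t <- state$t + dt
  state
}

#' Lesion mask from the thermal-dose field
#'
#' Voxels whose accumulated dose reaches the destruction threshold
#' (inclusive).
#'
#' @param D Thermal dose array (s).
#' @param threshold Destruction threshold (s), default 14.4e3.
#' @return A logical array.
#' @export
lesion_mask <- function(D, threshold = 14.4e3) {
  D >= threshold
}

#' Bounding-box extents of the largest lesion component
#'
#' Measures the lesion the way calipers would on the largest 6-connected
#' component: per axis, `(max index - min index + 1) * dx`. An empty mask
#' yields zeros.
#'
#' @param mask Logical array.
#' @param grid The `cartesian_grid` the mask lives on.
#' @return Named numeric: `x`, `y`, `z` extents in mm, with attribute
#'   `volume_mm3` (voxel count of the component times dx^3) and `component`
#'   (1-based linear indices).
#' @export
lesion_extents <- function(mask, grid) {
  idx <- which(mask)
  if (length(idx) == 0) {
    out <- c(x = 0, y = 0, z = 0)
    attr(out, "volume_mm3") <- 0
    return(out)
  }
  comp <- largest_component_cpp(as.integer(idx - 1L),
                                grid$nx, grid$ny, grid$nz) + 1L
  ar <- arrayInd(comp, dim(grid))
  spans <- apply(ar, 2, function(v) diff(range(v)) + 1L)
  out <- c(x = spans[1], y = spans[2], z = spans[3]) * grid$dx * 1e3
  names(out) <- c("x", "y", "z")
  attr(out, "volume_mm3") <- length(comp) * (grid$dx * 1e3)^3
  attr(out, "component") <- comp
  out
}

#' Boiling onset time from a maximum-temperature history
#'
#' The simulated analogue of the appearance of the hyperechoic mark on
#' B-mode imaging: the first time any voxel exceeds the boiling temperature,
#' linearly interpolated between the bracketing samples.
#'
#' @param times Sample times (s), increasing.
#' @param max_T Field maximum temperature at each sample (deg C).
#' @param T_boil Boiling threshold (deg C).
#' @return Onset time (s), or `NA_real_` if boiling never occurs. If the
#'   first sample already exceeds the threshold, 0.
#' @export
boiling_onset_time <- function(times, max_T, T_boil = 85) {
  stopifnot(length(times) == length(max_T))
  hit <- which(max_T > T_boil)
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1]
  if (i == 1) return(0)
  t0 <- times[i - 1]; t1 <- times[i]
  m0 <- max_T[i - 1]; m1 <- max_T[i]
  t0 + (T_boil - m0) / (m1 - m0) * (t1 - t0)
}

#' Bubble-cloud area in the central xz plane
#'
#' Area of the cumulative boiling mask in the single-voxel-thick y plane
#' through the focus: the simulated counterpart of the hyperechoic mark area
#' manually segmented in the (x, z) imaging plane.
#'
#' @param boiled Logical array (cumulative boiling mask).
#' @param grid The `cartesian_grid`.
#' @param projected If TRUE, use the projection of the mask along y instead
#'   of the central plane.
#' @return Area in mm^2.
#' @export
hem_area_xz <- function(boiled, grid, projected = FALSE) {
  if (projected) {
    sl <- apply(boiled, c(1, 3), any)
  } else {
    j <- nearest_voxel(grid, grid$focus)[2] + 1L
    sl <- boiled[, j, ]
  }
  sum(sl) * (grid$dx * 1e3)^2
}

#' Lesion metrics from a finished simulation
#'
#' @param state A `thermal_state` at the end of a run.
#' @param times,max_T Maximum-temperature history of the run.
#' @param T_boil Boiling threshold (deg C).
#' @param dose_threshold Lesion dose threshold (s).
#' @return A list of class `lesion_metrics`: `extents` (mm), `volume_mm3`,
#'   `onset` (s or NA), `hem_area_xz_mm2`, `mask`.
#' @export
lesion_metrics <- function(state, times, max_T, T_boil = 85,
                           dose_threshold = 14.4e3) {
  mask <- lesion_mask(state$D, dose_threshold)
  ext <- lesion_extents(mask, state$grid)
  out <- list(extents = ext[c("x", "y", "z")],
              volume_mm3 = attr(ext, "volume_mm3"),
              onset = boiling_onset_time(times, max_T, T_boil),
              hem_area_xz_mm2 = hem_area_xz(state$boiled, state$grid),
              mask = mask)
  class(out) <- "lesion_metrics"
  out
}

#' @export
print.lesion_metrics <- function(x, ...) {
  cat(sprintf("<lesion_metrics> %.1f x %.1f x %.1f mm (%.1f mm^3), onset %s s, HEM %.2f mm^2\n",
              x$extents["x"], x$extents["y"], x$extents["z"], x$volume_mm3,
              if (is.na(x$onset)) "-" else sprintf("%.2f", x$onset),
              x$hem_area_xz_mm2))
  invisible(x)
}
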