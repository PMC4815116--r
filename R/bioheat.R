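#' Temperature-dependent specific-heat model
#'
#' The tissue specific heat is `C_t(T) = C0 + C_denat(T) + C_boil(T)`. The
#' two excess profiles account for the energy consumed by protein
#' denaturation and by the progressive vaporization of tissue water, so the
#' solver does not overestimate temperature at high power. They are modelled
#' as Gaussian bumps truncated to the working range and rescaled so that
#' their integrals match the calorimetric constraints: the denaturation
#' profile integrates to `denat_enthalpy` (22 kJ/kg for liver homogenate)
#' and the boiling profile over `boil_range` integrates to
#' `water_fraction * H_vap` (tissue taken as 75 percent water, vaporization
#' enthalpy 2260 kJ/kg). The integral constraints, not the bump shapes, are
#' the contract.
#'
#' @param C0 Baseline specific heat (J kg^-1 K^-1).
#' @param denat_enthalpy Denaturation enthalpy (J/kg).
#' @param denat_center,denat_width Center and standard deviation (deg C) of
#'   the denaturation bump.
#' @param water_fraction Tissue water mass fraction.
#' @param H_vap Vaporization enthalpy of water (J/kg).
#' @param boil_center,boil_width Center and standard deviation (deg C) of the
#'   vaporization bump.
#' @param boil_range Temperature interval (deg C) over which the vaporization
#'   integral constraint is imposed; both bumps are truncated to it.
#' @param T_boil Temperature (deg C) above which the boiling equivalent model
#'   engages; 85 deg C, consistent with the onset of the vaporization bump.
#' @return An object of class `specific_heat_model`.
#' @export
specific_heat_model <- function(C0 = 3700,
                                denat_enthalpy = 22e3,
                                denat_center = 60, denat_width = 6,
                                water_fraction = 0.75, H_vap = 2260e3,
                                boil_center = 100, boil_width = 12,
                                boil_range = c(37, 140),
                                T_boil = 85) {
  stopifnot(C0 > 0, denat_enthalpy >= 0, denat_width > 0, boil_width > 0,
            water_fraction > 0, water_fraction <= 1, H_vap > 0,
            length(boil_range) == 2, boil_range[1] < boil_range[2])
  trunc_mass <- function(center, width)
    width * sqrt(2 * pi) *
      (stats::pnorm((boil_range[2] - center) / width) -
       stats::pnorm((boil_range[1] - center) / width))
  m <- list(C0 = C0,
            denat_enthalpy = denat_enthalpy,
            denat_center = denat_center, denat_width = denat_width,
            denat_amp = denat_enthalpy / trunc_mass(denat_center, denat_width),
            water_fraction = water_fraction, H_vap = H_vap,
            boil_center = boil_center, boil_width = boil_width,
            boil_amp = water_fraction * H_vap / trunc_mass(boil_center, boil_width),
            boil_range = boil_range, T_boil = T_boil)
  class(m) <- "specific_heat_model"
  m
}

.bump <- function(T, center, width, amp, range) {
  ifelse(T >= range[1] & T <= range[2],
         amp * exp(-(T - center)^2 / (2 * width^2)), 0)
}

#' Effective specific heat at a temperature
#'
#' @param model A `specific_heat_model`.
#' @param T Temperature(s), deg C.
#' @param component `"total"` (default), `"denat"` or `"boil"`.
#' @return Specific heat (J kg^-1 K^-1), vectorized over `T`.
#' @examples
#' m <- specific_heat_model()
#' effective_specific_heat(m, 37)   # ~ C0
#' @export
effective_specific_heat <- function(model, T, component = c("total", "denat", "boil")) {
  component <- match.arg(component)
  d <- .bump(T, model$denat_center, model$denat_width, model$denat_amp,
             model$boil_range)
  b <- .bump(T, model$boil_center, model$boil_width, model$boil_amp,
             model$boil_range)
  switch(component, total = model$C0 + d + b, denat = d, boil = b)
}

# lookup table of the excess specific heat (denat + boil) for the C++ stepper
.ct_bump_table <- function(model, t0 = 30, t1 = 170, dt = 0.05) {
  tt <- seq(t0, t1, by = dt)
  list(values = effective_specific_heat(model, tt) - model$C0,
       t0 = t0, dt = dt)
}

#' Dose-dependent perfusion rate
#'
#' Perfusion shuts down linearly with accumulated thermal dose, vanishing at
#' the tissue-destruction threshold (14.4e3 s): once the microvasculature is
#' coagulated there is no blood cooling left.
#'
#' @param w_b0 Perfusion rate at zero dose (s^-1).
#' @param D Thermal dose (s), vectorized.
#' @param D_destroy Destruction threshold (s).
#' @return Perfusion rate(s), s^-1.
#' @export
perfusion_rate <- function(w_b0, D, D_destroy = 14.4e3) {
  pmax(1 - D / D_destroy, 0) * w_b0
}

#' Blood compartment parameters
#'
#' @param rho_b Blood density (kg/m^3).
#' @param C_b Blood specific heat (J kg^-1 K^-1).
#' @param T_b Arterial blood (and boundary/initial) temperature, deg C.
#' @return A named list.
#' @export
blood_params <- function(rho_b = 1050, C_b = 3800, T_b = 37) {
  list(rho_b = rho_b, C_b = C_b, T_b = T_b)
}

#' Explicit-scheme stability limit
#'
#' Maximum stable time step of the 3D explicit Euler / 7-point Laplacian
#' scheme, `dx^2 * rho * C0 / (6 * k_t)`, minimized over the media present
#' on the grid. The baseline `C0` is used (the temperature-dependent excess
#' only raises the effective heat capacity, which relaxes the limit).
#'
#' @param grid A `cartesian_grid`.
#' @param media A `layered_medium`.
#' @param model A `specific_heat_model` (unused beyond its baseline; kept for
#'   signature stability).
#' @return Maximum stable dt (s).
#' @export
stability_limit <- function(grid, media, model = specific_heat_model()) {
  prof <- media_profiles(media, grid, 1)
  min(grid$dx^2 * prof$rho0 * prof$C0 / (6 * prof$k_t))
}

#' Thermal simulation state
#'
#' Holds the temperature field (deg C), the accumulated CEM43 thermal dose
#' (equivalent seconds at 43 deg C), the cumulative boiling mask (voxels that
#' ever exceeded the boiling temperature, the simulated analogue of the
#' hyperechoic mark), and the simulation clock.
#'
#' @param grid A `cartesian_grid`.
#' @param T0 Initial (and boundary) temperature, deg C.
#' @return An object of class `thermal_state`.
#' @export
thermal_state <- function(grid, T0 = 37) {
  d <- dim(grid)
  s <- list(T = array(T0, d), D = array(0, d),
            boiled = array(FALSE, d), t = 0, grid = grid)
  class(s) <- "thermal_state"
  s
}

#' @export
print.thermal_state <- function(x, ...) {
  cat(sprintf("<thermal_state> t = %.2f s, max T = %.2f C, max D = %.3g s, |boiled| = %d\n",
              x$t, max(x$T), max(x$D), sum(x$boiled)))
  invisible(x)
}

#' One explicit time step of the generalized Pennes equation
#'
#' Advances the temperature by one explicit Euler step of
#' `rho_t C_t(T) dT/dt = k_t lap(T) + w_b(D) rho_b C_b (T_b - T) + Q`
#' with a 7-point centered Laplacian and Dirichlet `T = T_b` on all faces,
#' then accumulates thermal dose with the post-step temperature, updates the
#' cumulative boiling mask and advances the clock. The specific heat is
#' evaluated at the pre-step temperature (explicit scheme). A warning is
#' emitted if `dt` exceeds the nominal stability limit.
#'
#' @param state A `thermal_state`.
#' @param Q A `heat_source_field` (or numeric array, W/m^3), or NULL for
#'   cooling.
#' @param dt Time step (s).
#' @param media A `layered_medium`.
#' @param model A `specific_heat_model`.
#' @param blood Output of [blood_params()].
#' @param warn_stability Check dt against [stability_limit()] (default TRUE).
#' @return The advanced `thermal_state`.
#' @export
step_temperature <- function(state, Q, dt, media, model = specific_heat_model(),
                             blood = blood_params(), warn_stability = TRUE) {
  g <- state$grid
  if (warn_stability) {
    lim <- stability_limit(g, media, model)
    if (dt > lim)
      warning(sprintf("dt = %g s exceeds the nominal stability limit %.4g s",
                      dt, lim))
  }
  Qarr <- if (is.null(Q)) array(0, dim(g)) else if (inherits(Q, "heat_source_field")) Q$Q else Q
  if (!identical(dim(Qarr), dim(state$T)))
    stop("heat source and state grids do not match")
  prof <- media_profiles(media, g, 1)
  tab <- .ct_bump_table(model)
  Tnew <- state$T + 0  # force a copy; the kernel writes into it
  bioheat_step_cpp(state$T, Tnew, Qarr, state$D,
                   g$nx, g$ny, g$nz, g$dx, dt,
                   prof$k_t, prof$rho0, prof$w_b0, prof$C0, prof$tissue,
                   tab$values, tab$t0, tab$dt,
                   blood$rho_b, blood$C_b, blood$T_b, 14.4e3)
  if (anyNA(Tnew) || any(!is.finite(Tnew)))
    stop(sprintf("temperature became non-finite at t = %.3f s (unstable dt?)",
                 state$t + dt))
  state$T <- Tnew
  state <- accumulate_dose(state, dt, T_boil = model$T_boil)
  state
}
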