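#' Linear cooling protocol
#'
#' @param B Cooling rate (K/min, equal in magnitude to degC/min), strictly
#'   positive.
#' @param T_start Starting temperature (K); default 272.65 K (-0.5 degC),
#'   the isotonic equilibrium freezing point at which the cell starts at its
#'   isotonic volume.
#' @param T_end Terminal temperature (K), below `T_start`.
#'
#' @return An object of class `cooling_protocol`.
#' @export
cooling_protocol <- function(B, T_start = 272.65, T_end = 223.15) {
  stopifnot(B > 0)
  if (T_end >= T_start) stop("T_end must lie below T_start")
  structure(list(B = B, T_start = T_start, T_end = T_end),
            class = "cooling_protocol")
}

#' Rate of osmotic volume change with temperature
#'
#' Mazur-type transmembrane water-transport law with temperature as the
#' independent variable along a linear ramp at rate `B`:
#' \deqn{\frac{dV}{dT} = \frac{L_p A R T}{B\, v_w}\left[\ln x_w -
#'   \frac{\Delta H_f}{R}\left(\frac{1}{T_R} - \frac{1}{T}\right)\right].}
#' The bracket vanishes exactly at the equilibrium volume at `T` and is
#' positive when `V` exceeds it, so volume falls as temperature falls.
#'
#' @param T Temperature (K).
#' @param V Cell volume (um^3), above `cell$Vb`.
#' @param cell A [cell_params()] object.
#' @param B Cooling rate (K/min).
#' @param constants An [iif_constants()] object.
#' @param area_mode `"sphere_dynamic"` recomputes the surface area from the
#'   instantaneous volume; `"constant"` freezes it at the isotonic area.
#'
#' @return dV/dT in um^3/K.
#' @export
dV_dT <- function(T, V, cell, B, constants = iif_constants(),
                  area_mode = c("sphere_dynamic", "constant")) {
  area_mode <- match.arg(area_mode)
  if (any(V <= cell$Vb)) {
    stop("V must exceed the osmotically inactive volume Vb")
  }
  A <- switch(area_mode,
              sphere_dynamic = sphere_geometry(V)$area,
              constant = sphere_geometry(cell$V0)$area)
  Lp <- water_permeability(T, cell, constants)
  xw <- water_mole_fraction(V, cell, constants)
  driving <- log(xw) - (constants$dHf / constants$R_kcal) *
    (1 / constants$T_R - 1 / T)
  (Lp * A * constants$R_um3atm * T) / (B * constants$vw) * driving
}

#' Equilibrium cell volume at a temperature
#'
#' The volume at which the cytoplasm freezing point equals `T` (the
#' infinitely-slow-cooling reference curve). Obtained by closed-form
#' inversion of the ideal-solution relations: the equilibrium water mole
#' fraction is `exp[(dHf/R)(1/T_R - 1/T)]` and the volume follows from the
#' salt content.
#'
#' @param T Temperature (K), at or below the isotonic freezing point
#'   `cell$T0`; scalar or vector.
#' @inheritParams dV_dT
#'
#' @return Equilibrium volume (um^3) in `(Vb, V0]`.
#' @export
equilibrium_volume <- function(T, cell, constants = iif_constants()) {
  if (any(T > cell$T0 + 1e-9)) {
    stop("T must not exceed the isotonic freezing point T0")
  }
  xw <- exp((constants$dHf / constants$R_kcal) * (1 / constants$T_R - 1 / T))
  cell$Vb + constants$vw * cell$phi_diss * cell$ns * xw / (1 - xw)
}

#' Simulate cell dehydration along a linear cooling ramp
#'
#' Integrates [dV_dT()] from the isotonic volume at `T_start` down to
#' `T_end` with a stiff-capable adaptive solver and fills in surface area,
#' cytoplasm freezing temperature, viscosity and membrane permeability along
#' the ramp.
#'
#' @param protocol A [cooling_protocol()] object.
#' @param cell A [cell_params()] object.
#' @param constants An [iif_constants()] object.
#' @param fv A [free_volume_params()] object.
#' @param dT Output grid spacing (K); default 0.05 K.
#' @param rtol,atol Solver tolerances (relative; absolute in um^3).
#' @param area_mode See [dV_dT()].
#' @param method deSolve integration method; default `"lsoda"`.
#'
#' @return An object of class `iif_trajectory`: a data frame with columns
#'   `temperature_K`, `volume_um3`, `norm_volume`, `area_um2`, `Tf_K`,
#'   `viscosity_mPas`, `Lp_um_min_atm`, with the protocol and cell attached
#'   as attributes.
#' @export
integrate_water_transport <- function(protocol, cell,
                                      constants = iif_constants(),
                                      fv = free_volume_params(),
                                      dT = 0.05,
                                      rtol = 1e-8, atol = 1e-10,
                                      area_mode = "sphere_dynamic",
                                      method = "lsoda") {
  stopifnot(inherits(protocol, "cooling_protocol"),
            inherits(cell, "cell_params"), dT > 0)
  times <- seq(protocol$T_start, protocol$T_end, by = -dT)
  if (times[length(times)] > protocol$T_end) {
    times <- c(times, protocol$T_end)
  }
  trajectory_at(times, protocol, cell, constants, fv,
                rtol = rtol, atol = atol, area_mode = area_mode,
                method = method)
}

# Integrate on an arbitrary (strictly decreasing) output grid starting at
# T_start. Shared by integrate_water_transport and the fitting code, which
# requests output only at observation temperatures.
trajectory_at <- function(times, protocol, cell,
                          constants = iif_constants(),
                          fv = free_volume_params(),
                          rtol = 1e-8, atol = 1e-10,
                          area_mode = "sphere_dynamic",
                          method = "lsoda") {
  Vb <- cell$Vb
  rhs <- function(t, y, parms) {
    # guard: the solver may probe marginally below Vb during a trial step
    V <- max(y[1], Vb * (1 + 1e-12))
    list(dV_dT(t, V, cell, protocol$B, constants, area_mode = area_mode))
  }
  sol <- try(deSolve::ode(y = c(V = cell$V0), times = times, func = rhs,
                          parms = NULL, method = method,
                          rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(times) ||
      anyNA(sol[, "V"])) {
    ngood <- if (inherits(sol, "try-error")) 0 else sum(!is.na(sol[, "V"]))
    stop(sprintf(
      "water-transport integration failed after %d of %d grid points (B = %g)",
      ngood, length(times), protocol$B))
  }
  V <- pmin(pmax(as.numeric(sol[, "V"]), Vb * (1 + 1e-12)), cell$V0)
  Tg <- as.numeric(sol[, "time"])
  geom <- sphere_geometry(V)
  xw <- water_mole_fraction(V, cell, constants)
  out <- data.frame(
    temperature_K = Tg,
    volume_um3 = V,
    norm_volume = V / cell$V0,
    area_um2 = geom$area,
    Tf_K = equilibrium_freezing_temperature(xw, constants),
    viscosity_mPas = cytoplasm_viscosity(Tg, salt_volume_fraction(V, cell),
                                         fv),
    Lp_um_min_atm = water_permeability(Tg, cell, constants)
  )
  structure(out,
            class = c("iif_trajectory", "data.frame"),
            protocol = protocol, cell = cell,
            constants = constants, free_volume = fv)
}

#' @export
print.iif_trajectory <- function(x, ...) {
  p <- attr(x, "protocol")
  cat(sprintf(
    "Dehydration trajectory: B = %g K/min, %.2f -> %.2f degC, %d points\n",
    p$B, p$T_start - 273.15, p$T_end - 273.15, nrow(x)))
  cat(sprintf("  terminal normalized volume %.4f\n",
              x$norm_volume[nrow(x)]))
  invisible(x)
}
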