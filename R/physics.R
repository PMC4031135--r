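# Internal unit system: um, um^3, minutes, atm, K, kcal/mol.
# The gas constant is kept in two views: a pressure view (um^3.atm/mol/K) for
# the osmotic driving term and an energy view (kcal/mol/K) for Arrhenius and
# freezing-point-depression terms.

#' Physical constants
#'
#' Bundle of the physical constants used throughout the water-transport and
#' nucleation models.
#'
#' @param dHf Molar heat of fusion of water (kcal/mol). Assumed independent of
#'   temperature.
#' @param T_R Reference temperature (K); fixed at 273.15 K.
#' @param R_um3atm Universal gas constant in the pressure view
#'   (um^3 atm mol^-1 K^-1; 0.0820574 L atm mol^-1 K^-1 = 8.20574e13 in um^3).
#' @param R_kcal Universal gas constant in the energy view (kcal mol^-1 K^-1).
#' @param vw Partial molar volume of water (um^3/mol; 18.02 cm^3/mol).
#'
#' @return An object of class `iif_constants`.
#' @export
iif_constants <- function(dHf = 1.436,
                          T_R = 273.15,
                          R_um3atm = 8.20574e13,
                          R_kcal = 1.9872042e-3,
                          vw = 1.802e13) {
  stopifnot(dHf > 0, R_um3atm > 0, R_kcal > 0, vw > 0)
  if (T_R != 273.15) {
    stop("T_R is the 273.15 K reference temperature and cannot be changed")
  }
  structure(list(dHf = dHf, T_R = T_R, R_um3atm = R_um3atm,
                 R_kcal = R_kcal, vw = vw),
            class = "iif_constants")
}

#' Free-volume viscosity parameters for water
#'
#' Parameters of the Vrentas-Duda free-volume expression for the viscosity of
#' (supercooled) water,
#' \deqn{\eta_w(T) = \eta_{w,0} \exp\left[\frac{\hat V_w}
#'   {(K_{11}/\lambda)(K_{21} + T - T_{gw})}\right].}
#' The default set uses the standard water free-volume parameters
#' (specific hole free volume 0.91 cm^3/g, K11/lambda = 1.945e-3 cm^3/(g K),
#' K21 = -19.73 K) with the glass-transition temperature of water at 136 K;
#' the pre-exponential constant is calibrated so that the model reproduces
#' the tabulated viscosity of water at 20 degC (1.002 mPa s).
#'
#' @param eta_w0 Pre-exponential constant (mPa s).
#' @param Vhat_w Specific volume of water required for a diffusive jump
#'   (cm^3/g).
#' @param K11_over_lambda First free-volume parameter (cm^3 g^-1 K^-1).
#' @param K21 Second free-volume parameter (K).
#' @param T_gw Glass-transition temperature of water (K).
#'
#' @return An object of class `free_volume_params`.
#' @export
free_volume_params <- function(eta_w0 = 0.0333,
                               Vhat_w = 0.91,
                               K11_over_lambda = 1.945e-3,
                               K21 = -19.73,
                               T_gw = 136) {
  stopifnot(eta_w0 > 0, Vhat_w > 0, K11_over_lambda > 0, T_gw > 0)
  structure(list(eta_w0 = eta_w0, Vhat_w = Vhat_w,
                 K11_over_lambda = K11_over_lambda, K21 = K21, T_gw = T_gw),
            class = "free_volume_params")
}

#' Membrane and osmotic parameters of one cell type
#'
#' @param V0 Isotonic cell volume (um^3).
#' @param Vb Osmotically inactive volume (um^3); solids and bound water that
#'   take no part in osmotic exchange. Must satisfy 0 < Vb < V0.
#' @param Lpg Membrane hydraulic permeability at the reference temperature
#'   273.15 K (um min^-1 atm^-1).
#' @param ELp Activation energy for transmembrane water transport (kcal/mol).
#' @param phi_diss Dissociation constant of the intracellular salt
#'   (dimensionless; 2 for a fully dissociated 1:1 salt).
#' @param ns Molar amount of intracellular salt (mol). If `NULL` (the
#'   default) it is derived from the isotonic condition that the cytoplasm
#'   freezing point at `V0` equals `T0` (see [isotonic_salt_content()]).
#' @param vs Partial molar volume of the salt (um^3/mol; default NaCl,
#'   16.6 cm^3/mol), used only for the salt volume fraction entering the
#'   cytoplasm viscosity.
#' @param T0 Isotonic equilibrium freezing temperature (K); default
#'   272.65 K (-0.5 degC).
#' @param constants An [iif_constants()] object.
#'
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(V0, Vb, Lpg, ELp,
                        phi_diss = 2,
                        ns = NULL,
                        vs = 1.66e13,
                        T0 = 272.65,
                        constants = iif_constants()) {
  stopifnot(V0 > 0, Lpg > 0, ELp > 0, phi_diss > 0, vs > 0)
  if (!(Vb > 0 && Vb < V0)) stop("Vb must satisfy 0 < Vb < V0")
  if (is.null(ns)) {
    ns <- isotonic_salt_content(V0, Vb, phi_diss, T0, constants)
  }
  if (ns <= 0) stop("ns must be strictly positive")
  structure(list(V0 = V0, Vb = Vb, Lpg = Lpg, ELp = ELp,
                 phi_diss = phi_diss, ns = ns, vs = vs, T0 = T0),
            class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat("Cell parameters\n")
  cat(sprintf("  V0  = %.1f um^3   Vb = %.1f um^3 (%.3f V0)\n",
              x$V0, x$Vb, x$Vb / x$V0))
  cat(sprintf("  Lpg = %.4f um/min/atm   ELp = %.4f kcal/mol\n",
              x$Lpg, x$ELp))
  cat(sprintf("  ns  = %.4g mol (phi = %g)   T0 = %.2f K\n",
              x$ns, x$phi_diss, x$T0))
  invisible(x)
}

#' Water mole fraction of the cytosol
#'
#' The cytosol is treated as an ideal binary solution of osmotically active
#' water, `(V - Vb)/vw` moles, and dissociated salt, `phi_diss * ns` osmoles.
#'
#' @param V Cell volume (um^3); scalar or vector, each element must exceed
#'   `cell$Vb`.
#' @param cell A [cell_params()] object.
#' @param constants An [iif_constants()] object.
#'
#' @return Water mole fraction in (0, 1).
#' @export
water_mole_fraction <- function(V, cell, constants = iif_constants()) {
  if (any(V <= cell$Vb)) {
    stop("V must exceed the osmotically inactive volume Vb")
  }
  mw <- (V - cell$Vb) / constants$vw
  mw / (mw + cell$phi_diss * cell$ns)
}

#' Equilibrium freezing temperature of an ideal solution
#'
#' Solves the ideal freezing-point-depression relation
#' \deqn{\ln x_w = \frac{\Delta H_f}{R}\left(\frac{1}{T_R} -
#'   \frac{1}{T_f}\right)}
#' for the equilibrium freezing temperature.
#'
#' @param x_w Water mole fraction, in (0, 1]; scalar or vector.
#' @inheritParams water_mole_fraction
#'
#' @return Freezing temperature (K), `<= 273.15`, strictly increasing in
#'   `x_w`.
#' @export
equilibrium_freezing_temperature <- function(x_w,
                                             constants = iif_constants()) {
  if (any(x_w <= 0)) stop("x_w must be strictly positive")
  if (any(x_w > 1)) stop("x_w cannot exceed 1")
  1 / (1 / constants$T_R - (constants$R_kcal / constants$dHf) * log(x_w))
}

#' Intracellular salt content from the isotonic freezing point
#'
#' Closes the osmotic system: the amount of intracellular salt is chosen so
#' that the cytoplasm at the isotonic volume `V0` freezes at `T0`
#' (-0.5 degC by default). Closed-form inversion of
#' [equilibrium_freezing_temperature()] and [water_mole_fraction()].
#'
#' @param V0,Vb Isotonic and osmotically inactive volumes (um^3).
#' @param phi_diss Salt dissociation constant.
#' @param T0 Isotonic freezing temperature (K), strictly below 273.15.
#' @inheritParams water_mole_fraction
#'
#' @return Molar salt content (mol), strictly positive.
#' @export
isotonic_salt_content <- function(V0, Vb, phi_diss = 2, T0 = 272.65,
                                  constants = iif_constants()) {
  if (T0 >= constants$T_R) {
    stop("T0 must lie strictly below the reference temperature 273.15 K")
  }
  x_w0 <- exp((constants$dHf / constants$R_kcal) *
                (1 / constants$T_R - 1 / T0))
  mw0 <- (V0 - Vb) / constants$vw
  mw0 * (1 - x_w0) / (x_w0 * phi_diss)
}

#' Viscosity of water from the free-volume model
#'
#' @param T Temperature (K); scalar or vector. Must exceed
#'   `T_gw - K21`, below which the free volume vanishes and the viscosity
#'   diverges.
#' @param fv A [free_volume_params()] object.
#'
#' @return Viscosity (mPa s), strictly decreasing in `T`.
#' @export
water_viscosity <- function(T, fv = free_volume_params()) {
  denom <- fv$K21 + T - fv$T_gw
  if (any(denom <= 0)) {
    stop("free volume non-positive: T must exceed T_gw - K21 (",
         format(fv$T_gw - fv$K21), " K)")
  }
  fv$eta_w0 * exp(fv$Vhat_w / (fv$K11_over_lambda * denom))
}

#' Krieger-Dougherty crowding correction
#'
#' Default composition dependence of the cytoplasm viscosity:
#' `g(phi) = (1 - phi/phi_max)^(-intrinsic * phi_max)` with `g(0) = 1`,
#' strictly increasing, diverging at the packing limit.
#'
#' @param phi Solute volume fraction, `0 <= phi < phi_max`.
#' @param phi_max Random close-packing limit (default 0.64).
#' @param intrinsic Intrinsic viscosity (default 2.5, rigid spheres).
#'
#' @return Dimensionless multiplier `>= 1`.
#' @export
krieger_dougherty <- function(phi, phi_max = 0.64, intrinsic = 2.5) {
  if (any(phi < 0)) stop("phi must be non-negative")
  if (any(phi >= phi_max)) stop("phi must stay below the packing limit")
  (1 - phi / phi_max)^(-intrinsic * phi_max)
}

#' Cytoplasm viscosity
#'
#' Viscosity of the cytoplasm as the free-volume water viscosity times a
#' crowding correction in the salt volume fraction. The crowding form is a
#' pluggable strategy; the default is [krieger_dougherty()].
#'
#' @inheritParams water_viscosity
#' @param phi_salt_vol Salt volume fraction `ns*vs/V` (dimensionless).
#' @param crowding Function `g(phi)` with `g(0) = 1`, strictly increasing.
#'
#' @return Viscosity (mPa s).
#' @export
cytoplasm_viscosity <- function(T, phi_salt_vol,
                                fv = free_volume_params(),
                                crowding = krieger_dougherty) {
  water_viscosity(T, fv) * crowding(phi_salt_vol)
}

#' Membrane hydraulic permeability (Arrhenius law)
#'
#' \deqn{L_p(T) = L_{pg} \exp\left[-\frac{E_{Lp}}{R}\left(\frac{1}{T} -
#'   \frac{1}{T_R}\right)\right]}
#' so that `L_p(273.15 K) = Lpg` exactly.
#'
#' @param T Temperature (K); scalar or vector, strictly positive.
#' @inheritParams water_mole_fraction
#'
#' @return Permeability (um min^-1 atm^-1).
#' @export
water_permeability <- function(T, cell, constants = iif_constants()) {
  stopifnot(all(T > 0))
  cell$Lpg * exp(-(cell$ELp / constants$R_kcal) *
                   (1 / T - 1 / constants$T_R))
}

#' Surface area and radius of a spherical cell
#'
#' @param V Cell volume (um^3), strictly positive; scalar or vector.
#'
#' @return A list with components `radius` (um) and `area` (um^2).
#' @export
sphere_geometry <- function(V) {
  if (any(V <= 0)) stop("V must be strictly positive")
  r <- (3 * V / (4 * pi))^(1 / 3)
  list(radius = r, area = 4 * pi * r^2)
}

#' Salt volume fraction of the cytoplasm
#'
#' @inheritParams water_mole_fraction
#' @return `ns * vs / V`, dimensionless.
#' @export
salt_volume_fraction <- function(V, cell) {
  cell$ns * cell$vs / V
}
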