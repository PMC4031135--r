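#' Nucleation parameters for one catalytic mechanism
#'
#' Kinetic and thermodynamic parameters of heterogeneous intracellular ice
#' nucleation for the surface-catalyzed (SCN) or volume-catalyzed (VCN)
#' mechanism, optionally carrying the critical volume `Vf` below which the
#' mechanism is switched off (the modified model). Without `Vf` the original
#' Toner-type rate applies.
#'
#' @param mechanism `"SCN"` or `"VCN"`.
#' @param Omega0 Kinetic prefactor: nucleation events per m^2 membrane per
#'   second (SCN) or per m^3 cell volume per second (VCN) at isotonic
#'   composition.
#' @param kappa0 Thermodynamic barrier parameter (K^5).
#' @param Vf Critical cell volume (um^3), or `NULL` for the original model.
#'   When present it must lie in `(Vb, V0]` of the cell it is used with;
#'   that is checked at evaluation time.
#'
#' @return An object of class `nucleation_params`.
#' @export
nucleation_params <- function(mechanism = c("SCN", "VCN"),
                              Omega0, kappa0, Vf = NULL) {
  mechanism <- match.arg(mechanism)
  stopifnot(Omega0 >= 0, kappa0 > 0)
  if (!is.null(Vf)) stopifnot(Vf > 0)
  structure(list(mechanism = mechanism, Omega0 = Omega0,
                 kappa0 = kappa0, Vf = Vf),
            class = "nucleation_params")
}

# Isotonic reference state: the freezing temperature Tf0 and cytoplasm
# viscosity eta_ref at isotonic composition. Omega0 is the rate scale at this
# state; the temperature dependence of the kinetics enters through
# eta_ref/eta(T).
isotonic_reference <- function(cell, constants = iif_constants(),
                               fv = free_volume_params()) {
  xw0 <- water_mole_fraction(cell$V0, cell, constants)
  Tf0 <- equilibrium_freezing_temperature(xw0, constants)
  list(Tf0 = Tf0,
       eta_ref = cytoplasm_viscosity(Tf0, salt_volume_fraction(cell$V0, cell),
                                     fv))
}

#' Heterogeneous ice nucleation rate (Toner-type)
#'
#' \deqn{I(T) = \Omega_0\,\frac{\eta_0}{\eta(T)}\,
#'   \exp\left[-\frac{\kappa_0\,(T_f/T_{f,0})^4}{(T_f-T)^2\,T^3}\right]}
#' for `T < Tf`, and 0 for `T >= Tf` (no supercooling, infinite barrier).
#' `kappa0` carries units of K^5 so the exponent is dimensionless.
#'
#' @param T Temperature (K); scalar or vector.
#' @param Tf Cytoplasm equilibrium freezing temperature (K) at the cell's
#'   instantaneous composition; recycled against `T`.
#' @param eta Cytoplasm viscosity (mPa s) at `T`.
#' @param np A [nucleation_params()] object.
#' @param eta_ref Isotonic cytoplasm viscosity (mPa s) at `Tf0`.
#' @param Tf0 Isotonic freezing temperature (K).
#'
#' @return Nucleation rate, per m^2 s (SCN) or per m^3 s (VCN); non-negative
#'   and finite.
#' @export
nucleation_rate <- function(T, Tf, eta, np, eta_ref, Tf0) {
  stopifnot(all(T > 0), all(eta > 0))
  dT <- Tf - T
  rate <- numeric(length(T))
  sup <- dT > 0
  if (any(sup)) {
    Tfs <- rep_len(Tf, length(T))[sup]
    expo <- -np$kappa0 * (Tfs / Tf0)^4 / (dT[sup]^2 * T[sup]^3)
    rate[sup] <- np$Omega0 * (eta_ref / rep_len(eta, length(T))[sup]) *
      exp(expo)
  }
  rate
}

#' Critical-volume-gated nucleation rate
#'
#' The modified rate: equal to [nucleation_rate()] while the cell volume is
#' at or above the critical volume `np$Vf`, and exactly zero below it (the
#' gate boundary `V == Vf` is inclusive). With `Vf = NULL` the original rate
#' is returned unchanged.
#'
#' @inheritParams nucleation_rate
#' @param V Cell volume (um^3) at each `T`.
#'
#' @return Gated nucleation rate; same units as [nucleation_rate()].
#' @export
modified_nucleation_rate <- function(T, V, Tf, eta, np, eta_ref, Tf0) {
  rate <- nucleation_rate(T, Tf, eta, np, eta_ref, Tf0)
  if (!is.null(np$Vf)) {
    rate[rep_len(V, length(rate)) < np$Vf] <- 0
  }
  rate
}

# Per-K hazard of one mechanism along a trajectory: 60 * I(T) * S(T) / B,
# with S the membrane area in m^2 (SCN) or cell volume in m^3 (VCN).
# Unit conversions um^2 -> m^2, um^3 -> m^3 and min -> s live only here.
mechanism_hazard <- function(traj, np, prefactor_mode = "none",
                             volume_basis = "total") {
  cell <- attr(traj, "cell")
  constants <- attr(traj, "constants")
  fv <- attr(traj, "free_volume")
  if (!is.null(np$Vf) && !(np$Vf > cell$Vb && np$Vf <= cell$V0)) {
    stop("Vf must lie in (Vb, V0]")
  }
  ref <- isotonic_reference(cell, constants, fv)
  I <- modified_nucleation_rate(traj$temperature_K, traj$volume_um3,
                                traj$Tf_K, traj$viscosity_mPas,
                                np, ref$eta_ref, ref$Tf0)
  S <- if (np$mechanism == "SCN") {
    traj$area_um2 * 1e-12
  } else if (volume_basis == "total") {
    traj$volume_um3 * 1e-18
  } else {
    (traj$volume_um3 - cell$Vb) * 1e-18
  }
  if (prefactor_mode == "dehydration") {
    I <- I * if (np$mechanism == "SCN") {
      traj$area_um2 / sphere_geometry(cell$V0)$area
    } else {
      (traj$volume_um3 - cell$Vb) / (cell$V0 - cell$Vb)
    }
  }
  B <- attr(traj, "protocol")$B
  60 * I * S / B
}

# Cumulative trapezoidal integral of a per-K hazard along the (decreasing)
# trajectory temperature grid.
cumulative_hazard <- function(temperature_K, hazard_per_K) {
  as.numeric(pracma::cumtrapz(-temperature_K, hazard_per_K))
}

#' Probability of ice formation for one mechanism
#'
#' Survival-model composition of the nucleation hazard along a dehydration
#' trajectory:
#' \deqn{PIF(T) = 1 - \exp\left[-\frac{1}{B}\int_T^{T_{start}}
#'   I(T')\,S(T')\,dT'\right]}
#' with `S` the membrane area (SCN) or the cell volume (VCN). The integral
#' is evaluated by cumulative trapezoidal quadrature on the trajectory grid.
#'
#' @param traj An [integrate_water_transport()] trajectory.
#' @param np A [nucleation_params()] object.
#' @param prefactor_mode `"none"` (default) or `"dehydration"`, which
#'   multiplies the rate by the fraction of catalytic sites remaining
#'   (`A/A0` for SCN, `(V-Vb)/(V0-Vb)` for VCN).
#' @param volume_basis `"total"` (default) uses the whole cell volume as the
#'   VCN catalytic measure; `"water"` uses `V - Vb`.
#'
#' @return Numeric vector of PIF values on `traj$temperature_K`, in `[0, 1]`,
#'   zero at the start and non-decreasing along cooling. The per-K hazard is
#'   attached as attribute `"hazard_per_K"`.
#' @export
pif_mechanism <- function(traj, np, prefactor_mode = "none",
                          volume_basis = "total") {
  h <- mechanism_hazard(traj, np, prefactor_mode, volume_basis)
  H <- cumulative_hazard(traj$temperature_K, h)
  # The volume is monotone non-increasing along cooling, so the critical
  # volume is crossed at most once. Resolve the crossing inside its grid
  # interval instead of at the nearest node: the cumulative hazard is
  # truncated at the interpolated gate temperature, which makes PIF vary
  # continuously with Vf (needed both for quadrature accuracy and for
  # gradient-based fitting of the critical volume).
  if (!is.null(np$Vf)) {
    V <- traj$volume_um3
    j <- which(V < np$Vf)[1]
    if (!is.na(j)) {
      if (j == 1L) {
        H[] <- 0
      } else {
        Tg <- traj$temperature_K
        # ungated hazard at the crossing (h is already 0 at and past j)
        np_open <- np
        np_open$Vf <- NULL
        h_open <- mechanism_hazard(
          traj, np_open, prefactor_mode, volume_basis)
        frac <- (V[j - 1L] - np$Vf) / (V[j - 1L] - V[j])
        T_gate <- Tg[j - 1L] + frac * (Tg[j] - Tg[j - 1L])
        h_gate <- h_open[j - 1L] + frac * (h_open[j] - h_open[j - 1L])
        H_gate <- H[j - 1L] +
          0.5 * (h_open[j - 1L] + h_gate) * (Tg[j - 1L] - T_gate)
        H <- pmin(cumulative_hazard(Tg, h_open), H_gate)
      }
    }
  }
  structure(1 - exp(-H), hazard_per_K = h)
}

#' Combine SCN and VCN ice-formation probabilities
#'
#' Independent-competition composition: a cell escapes IIF only if it escapes
#' both mechanisms, so
#' `pif_total = 1 - (1 - pif_scn) (1 - pif_vcn)`.
#'
#' @param pif_scn,pif_vcn Probabilities in `[0, 1]` on a common grid.
#'
#' @return Combined PIF, in `[0, 1]`; commutative in its arguments.
#' @export
pif_total <- function(pif_scn, pif_vcn) {
  if (length(pif_scn) != length(pif_vcn)) {
    stop("pif_scn and pif_vcn must share one grid")
  }
  if (any(pif_scn < 0 | pif_scn > 1 | pif_vcn < 0 | pif_vcn > 1)) {
    stop("PIF inputs must lie in [0, 1]")
  }
  pif_scn + (1 - pif_scn) * pif_vcn
}

#' PIF curve along a freezing trajectory
#'
#' Evaluates the per-mechanism and combined probability of intracellular ice
#' formation along a dehydration trajectory.
#'
#' @inheritParams pif_mechanism
#' @param scn,vcn [nucleation_params()] objects for the two mechanisms.
#'
#' @return An object of class `pif_curve`: a data frame with columns
#'   `temperature_K`, `pif_scn`, `pif_vcn`, `pif_total`, with the trajectory
#'   attached as attribute `"trajectory"`.
#' @export
pif_curve <- function(traj, scn, vcn, prefactor_mode = "none",
                      volume_basis = "total") {
  stopifnot(scn$mechanism == "SCN", vcn$mechanism == "VCN")
  ps <- pif_mechanism(traj, scn, prefactor_mode, volume_basis)
  pv <- pif_mechanism(traj, vcn, prefactor_mode, volume_basis)
  structure(data.frame(temperature_K = traj$temperature_K,
                       pif_scn = as.numeric(ps),
                       pif_vcn = as.numeric(pv),
                       pif_total = pif_total(as.numeric(ps),
                                             as.numeric(pv))),
            class = c("pif_curve", "data.frame"),
            trajectory = traj)
}

#' @export
print.pif_curve <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf(
    "PIF curve: %d points, %.2f -> %.2f degC; terminal PIF %.4f (SCN %.4f, VCN %.4f)\n",
    n, x$temperature_K[1] - 273.15, x$temperature_K[n] - 273.15,
    x$pif_total[n], x$pif_scn[n], x$pif_vcn[n]))
  invisible(x)
}
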