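#' Full-loop two-stage parameter recovery from synthetic data
#'
#' Exercises the complete analysis pipeline on data generated from known
#' ground truth: (1) generate multi-rate normalized-volume tables and fit
#' the membrane parameters by pooled least squares; (2) using trajectories
#' predicted from the stage-1 estimates, simulate per-cell IIF events at the
#' IIF cooling rates, tally empirical PIF, and fit the nucleation parameters
#' (one shared set across rates, matching the shared generating set).
#'
#' @param gt A [ground_truth()] object.
#' @param n_starts_volume,n_starts_pif Multistart counts for the two stages.
#' @param seed Optimizer seed (the data seed lives in `gt$seed`).
#' @param model PIF model variant to fit (default `"modified"`).
#' @param pif_grid_dK Temperature grid spacing (K) at which empirical PIF is
#'   tallied before fitting.
#'
#' @return A list of class `recovery_result` with elements `truth` (the
#'   generating parameter values), `water_fit`, `pif_fit`, `errors`
#'   (relative errors for `Lpg`, `ELp`; absolute errors in fractions of `V0`
#'   for the critical volumes), plus the intermediate `volume_obs`,
#'   `pif_obs` and `trajectories`.
#' @export
recover_parameters <- function(gt, n_starts_volume = 4, n_starts_pif = 40,
                               seed = 1, model = "modified",
                               pif_grid_dK = 2) {
  stopifnot(inherits(gt, "ground_truth"))
  vol_obs <- generate_volume_observations(gt)
  water_fit <- pooled_fit_water_transport(vol_obs, gt$cell,
                                          n_starts = n_starts_volume,
                                          seed = seed)
  # stage 2 uses trajectories predicted from the stage-1 estimates
  fitted_cell <- cell_params(V0 = gt$cell$V0,
                             Vb = water_fit$parameters$Vb,
                             Lpg = water_fit$parameters$Lpg,
                             ELp = water_fit$parameters$ELp,
                             phi_diss = gt$cell$phi_diss, vs = gt$cell$vs,
                             T0 = gt$cell$T0)
  trajs <- lapply(gt$iif_rates, function(B) {
    integrate_water_transport(
      cooling_protocol(B, gt$cell$T0, gt$T_end_iif), fitted_cell)
  })
  names(trajs) <- as.character(gt$iif_rates)

  grid <- seq(gt$cell$T0 - pif_grid_dK, gt$T_end_iif, by = -pif_grid_dK)
  events <- do.call(rbind, lapply(gt$iif_rates, function(B) {
    simulate_iif_events(gt, B)
  }))
  pif_obs <- empirical_pif(events, grid)
  pif_obs$pif <- pif_obs$pif_both
  pif_fit <- fit_pif_pooled(pif_obs, trajs, model = model,
                            n_starts = n_starts_pif, seed = seed)

  truth <- list(Lpg = gt$cell$Lpg, ELp = gt$cell$ELp, Vb = gt$cell$Vb,
                vf_frac_scn = if (!is.null(gt$scn$Vf)) gt$scn$Vf / gt$cell$V0,
                vf_frac_vcn = if (!is.null(gt$vcn$Vf)) gt$vcn$Vf / gt$cell$V0)
  errors <- list(
    lpg_rel = abs(water_fit$parameters$Lpg - truth$Lpg) / truth$Lpg,
    elp_rel = abs(water_fit$parameters$ELp - truth$ELp) / truth$ELp)
  if (model == "modified" && !is.null(truth$vf_frac_scn)) {
    errors$vf_scn_frac <- abs(pif_fit$parameters$vf_frac_scn -
                                truth$vf_frac_scn)
    errors$vf_vcn_frac <- abs(pif_fit$parameters$vf_frac_vcn -
                                truth$vf_frac_vcn)
  }
  structure(list(truth = truth, water_fit = water_fit, pif_fit = pif_fit,
                 errors = errors, volume_obs = vol_obs, pif_obs = pif_obs,
                 trajectories = trajs, events = events),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat("Two-stage parameter recovery\n")
  cat(sprintf("  Lpg: true %.4f, fitted %.4f (rel err %.2f%%)\n",
              x$truth$Lpg, x$water_fit$parameters$Lpg,
              100 * x$errors$lpg_rel))
  cat(sprintf("  ELp: true %.4f, fitted %.4f (rel err %.2f%%)\n",
              x$truth$ELp, x$water_fit$parameters$ELp,
              100 * x$errors$elp_rel))
  if (!is.null(x$errors$vf_scn_frac)) {
    cat(sprintf("  Vf_SCN/V0: true %.3f, fitted %.3f (abs err %.3f)\n",
                x$truth$vf_frac_scn, x$pif_fit$parameters$vf_frac_scn,
                x$errors$vf_scn_frac))
    cat(sprintf("  Vf_VCN/V0: true %.3f, fitted %.3f (abs err %.3f)\n",
                x$truth$vf_frac_vcn, x$pif_fit$parameters$vf_frac_vcn,
                x$errors$vf_vcn_frac))
  }
  invisible(x)
}
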