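# Two-stage pooled estimation:
#   stage 1 - membrane parameters (Lpg, ELp, Vb) against normalized-volume
#             observations pooled over all cooling rates;
#   stage 2 - nucleation parameters against PIF observations, with the
#             stage-1 dehydration trajectories held fixed.

#' Coefficient of determination
#'
#' `1 - sum((o - p)^2) / sum((o - mean(o))^2)`.
#'
#' @param observed,predicted Numeric vectors of equal length `>= 2`.
#' @return R-squared (`<= 1`; negative when the fit is worse than the mean).
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    stop("observed and predicted must have equal length >= 2")
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("observed values have zero variance")
  1 - sum((observed - predicted)^2) / sst
}

# run `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# seeded multistart design: the caller-supplied centre start plus a
# Latin-hypercube candidate pool scaled into [lower, upper]. The pool is
# screened on the raw objective and only the best `n_starts` points are
# handed to the local optimizer (best-of-k polishing).
multistart_design <- function(centre, lower, upper, n_starts, seed,
                              pool_factor = 10) {
  k <- length(lower)
  centre <- pmin(pmax(centre, lower), upper)
  if (n_starts <= 1) return(matrix(centre, nrow = 1))
  n_pool <- max(n_starts - 1, pool_factor * (n_starts - 1))
  lh <- with_seed(seed, lhs::randomLHS(n_pool, k))
  rbind(centre,
        sweep(sweep(lh, 2, upper - lower, "*"), 2, lower, "+"))
}

screen_starts <- function(residual_fn, candidates, n_starts) {
  if (nrow(candidates) <= n_starts) return(candidates)
  sse <- vapply(seq_len(nrow(candidates)), function(i) {
    r <- try(residual_fn(candidates[i, ]), silent = TRUE)
    if (inherits(r, "try-error")) Inf else sum(r^2)
  }, numeric(1))
  candidates[order(sse)[seq_len(n_starts)], , drop = FALSE]
}

# bounded least squares from multiple starts; returns the best fit plus the
# per-start trace. residual_fn(p) -> numeric vector (large finite values on
# model failure).
multistart_nls <- function(residual_fn, starts, lower, upper,
                           control = minpack.lm::nls.lm.control(maxiter = 200)) {
  best <- NULL
  trace <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(par = starts[i, ], lower = lower,
                                  upper = upper, fn = residual_fn,
                                  control = control), silent = TRUE)
    if (inherits(fit, "try-error")) {
      trace[[i]] <- data.frame(start = i, sse = NA_real_, converged = FALSE)
      next
    }
    sse <- sum(fit$fvec^2)
    conv <- fit$info %in% 1:4
    trace[[i]] <- data.frame(start = i, sse = sse, converged = conv)
    if (is.null(best) || sse < best$sse) {
      best <- list(par = fit$par, sse = sse, converged = conv,
                   message = fit$message, fvec = fit$fvec)
    }
  }
  if (is.null(best)) stop("all optimizer starts failed")
  best$trace <- do.call(rbind, trace)
  best
}

fit_result <- function(parameters, r_squared, sse, residuals, converged,
                       message, n_starts, seed, trace, warnings = character()) {
  structure(list(parameters = parameters, r_squared = r_squared, sse = sse,
                 residuals = residuals, converged = converged,
                 message = message, n_starts = n_starts, seed = seed,
                 trace = trace, warnings = warnings),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit result (", if (x$converged) "converged" else "NOT converged",
      ")\n", sep = "")
  for (nm in names(x$parameters)) {
    cat(sprintf("  %-12s %.6g\n", nm, x$parameters[[nm]]))
  }
  cat(sprintf("  R^2 = %.6f   SSE = %.6g   (%d starts, seed %d)\n",
              x$r_squared, x$sse, x$n_starts, x$seed))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}

#' Pooled fit of the water-transport model to multi-rate volume data
#'
#' Estimates one shared `(Lpg, ELp, Vb)` triple by bounded nonlinear least
#' squares against normalized-volume observations from two or more cooling
#' rates simultaneously (pooled fitting: a single sum of squares over all
#' `(rate, temperature)` records). `Lpg` and `ELp` are searched in log10
#' space, `Vb` as a fraction of `V0`; the salt content is re-derived from the
#' isotonic condition for every candidate `Vb`.
#'
#' @param obs A [volume_observations()] table (or data frame with columns
#'   `cooling_rate`, `temperature_K`, `norm_volume_mean`, `norm_volume_sem`,
#'   `n_cells`) covering at least two cooling rates and two temperatures.
#' @param cell_template A [cell_params()] object supplying `V0`, `phi_diss`,
#'   `vs` and `T0` (its `Lpg`, `ELp`, `Vb` seed the optimizer centre).
#' @param constants,fv Physics parameter objects.
#' @param lower,upper Bounds on `(log10 Lpg, log10 ELp, Vb/V0)`.
#' @param n_starts Number of multistart points (seeded Latin hypercube).
#' @param seed Integer seed making the multistart design reproducible.
#' @param weighting `"none"` (default) or `"sem"` (residuals scaled by
#'   1/SEM).
#' @param rtol ODE relative tolerance during fitting.
#'
#' @return A `fit_result` with `parameters` `Lpg`, `ELp`, `Vb`, `vb_frac`;
#'   `r_squared` is computed unweighted over the pooled records.
#' @export
pooled_fit_water_transport <- function(obs, cell_template,
                                       constants = iif_constants(),
                                       fv = free_volume_params(),
                                       lower = c(-3, 0.3, 0.05),
                                       upper = c(1, 2, 0.8),
                                       n_starts = 5, seed = 1,
                                       weighting = c("none", "sem"),
                                       rtol = 1e-6) {
  weighting <- match.arg(weighting)
  obs <- as.data.frame(obs)
  rates <- sort(unique(obs$cooling_rate))
  if (length(rates) < 2) stop("pooled fitting needs at least 2 cooling rates")
  if (length(unique(obs$temperature_K)) < 2) {
    stop("degenerate data: a single observation temperature")
  }
  T0 <- cell_template$T0
  if (any(obs$temperature_K >= T0)) {
    stop("observation temperatures must lie below the isotonic freezing point")
  }
  by_rate <- lapply(rates, function(b) {
    o <- obs[obs$cooling_rate == b, ]
    o[order(-o$temperature_K), ]
  })
  w <- if (weighting == "sem") {
    lapply(by_rate, function(o) 1 / pmax(o$norm_volume_sem, 1e-6))
  } else {
    lapply(by_rate, function(o) rep(1, nrow(o)))
  }
  V0 <- cell_template$V0

  model_norm_volume <- function(p, i) {
    cell <- cell_params(V0 = V0, Vb = p[3] * V0, Lpg = 10^p[1],
                        ELp = 10^p[2], phi_diss = cell_template$phi_diss,
                        vs = cell_template$vs, T0 = T0,
                        constants = constants)
    times <- c(T0, by_rate[[i]]$temperature_K)
    tr <- trajectory_at(times, cooling_protocol(rates[i], T0,
                                                min(times)),
                        cell, constants, fv, rtol = rtol, atol = 1e-8)
    tr$norm_volume[match(by_rate[[i]]$temperature_K, tr$temperature_K)]
  }
  residual_fn <- function(p) {
    res <- lapply(seq_along(rates), function(i) {
      m <- try(model_norm_volume(p, i), silent = TRUE)
      if (inherits(m, "try-error") || anyNA(m)) {
        return(rep(1e3, nrow(by_rate[[i]])))
      }
      (m - by_rate[[i]]$norm_volume_mean) * w[[i]]
    })
    unlist(res)
  }

  centre <- c(log10(cell_template$Lpg), log10(cell_template$ELp),
              cell_template$Vb / V0)
  starts <- multistart_design(centre, lower, upper, n_starts, seed,
                              pool_factor = 4)
  starts <- screen_starts(residual_fn, starts, n_starts)
  best <- multistart_nls(residual_fn, starts, lower, upper)

  p <- best$par
  pred <- unlist(lapply(seq_along(rates), function(i) model_norm_volume(p, i)))
  obs_all <- unlist(lapply(by_rate, function(o) o$norm_volume_mean))
  warn <- character()
  if (any(abs(p - lower) < 1e-8) || any(abs(p - upper) < 1e-8)) {
    warn <- c(warn, "parameter pinned at a bound")
  }
  fit_result(parameters = list(Lpg = 10^p[1], ELp = 10^p[2],
                               Vb = p[3] * V0, vb_frac = p[3]),
             r_squared = r_squared(obs_all, pred),
             sse = best$sse, residuals = obs_all - pred,
             converged = best$converged, message = best$message,
             n_starts = n_starts, seed = seed, trace = best$trace,
             warnings = warn)
}

# Variance-stabilizing weights for cumulative-PIF residuals: the reciprocal
# binomial standard error sqrt(p(1-p)/n) with an Agresti-style continuity
# correction so the weight stays finite at p = 0 or 1.
binomial_pif_weights <- function(pif, n_cells) {
  p <- (pif * n_cells + 0.5) / (n_cells + 1)
  1 / sqrt(p * (1 - p) / n_cells)
}

resolve_pif_weights <- function(obs_by_rate, weighting) {
  has_n <- all(vapply(obs_by_rate, function(o) "n_cells" %in% names(o),
                      logical(1)))
  if (weighting == "auto") {
    weighting <- if (has_n) "binomial" else "none"
  }
  if (weighting == "binomial" && !has_n) {
    stop("binomial weighting needs an n_cells column")
  }
  lapply(obs_by_rate, function(o) {
    if (weighting == "binomial") binomial_pif_weights(o$pif, o$n_cells)
    else rep(1, nrow(o))
  })
}

# shared engine for single-rate and pooled PIF fitting.
# obs_by_rate: list of data.frames (temperature_K, pif), aligned with trajs.
#
# In the modified model the two critical volumes are constrained to the
# ordering Vf_SCN >= Vf_VCN seen in every fitted parameter set and implied
# by the sequential surface-then-volume nucleation interpretation; without
# it the two mechanisms are nearly exchangeable when only the combined PIF
# is observed. Internally p[6] is the position of Vf_VCN between its lower
# bound and Vf_SCN.
fit_pif_engine <- function(obs_by_rate, trajs, model, lower, upper,
                           n_starts, seed, prefactor_mode, volume_basis,
                           weighting = "auto") {
  cell <- attr(trajs[[1]], "cell")
  V0 <- cell$V0
  modified <- model == "modified"
  wts <- resolve_pif_weights(obs_by_rate, weighting)
  f_lo <- if (modified) lower[5] else NA_real_
  vf_fracs <- function(p) {
    c(scn = p[5], vcn = f_lo + p[6] * (p[5] - f_lo))
  }

  predict_pif <- function(p, i) {
    f <- if (modified) vf_fracs(p)
    scn <- nucleation_params("SCN", 10^p[1], 10^p[2],
                             Vf = if (modified) f[["scn"]] * V0)
    vcn <- nucleation_params("VCN", 10^p[3], 10^p[4],
                             Vf = if (modified) f[["vcn"]] * V0)
    pc <- pif_curve(trajs[[i]], scn, vcn, prefactor_mode, volume_basis)
    stats::approx(pc$temperature_K, pc$pif_total,
                  xout = obs_by_rate[[i]]$temperature_K, rule = 2)$y
  }
  residual_fn <- function(p) {
    unlist(lapply(seq_along(trajs), function(i) {
      m <- try(predict_pif(p, i), silent = TRUE)
      if (inherits(m, "try-error") || anyNA(m)) {
        return(rep(1e3, nrow(obs_by_rate[[i]])))
      }
      (m - obs_by_rate[[i]]$pif) * wts[[i]]
    }))
  }

  centre <- (lower + upper) / 2
  starts <- multistart_design(centre, lower, upper, n_starts, seed,
                              pool_factor = 25)
  starts <- screen_starts(residual_fn, starts, n_starts)
  best <- multistart_nls(residual_fn, starts, lower, upper)

  p <- best$par
  pred <- unlist(lapply(seq_along(trajs), function(i) predict_pif(p, i)))
  obs_all <- unlist(lapply(obs_by_rate, function(o) o$pif))
  warn <- character()
  if (modified) {
    f <- vf_fracs(p)
    if (abs(p[5] - lower[5]) < 1e-6 || abs(p[5] - upper[5]) < 1e-6 ||
        abs(f[["vcn"]] - f_lo) < 1e-6) {
      warn <- c(warn, "critical-volume estimate pinned at a bound")
    }
  }
  # ill-conditioning probe: Table-style VCN prefactors span many decades;
  # flag a near-flat objective under a 10x Omega_VCN perturbation
  p10 <- p
  p10[3] <- min(p[3] + 1, upper[3])
  if (abs(sum(residual_fn(p10)^2) - best$sse) < 1e-3) {
    warn <- c(warn, "objective nearly flat under 10x Omega_VCN perturbation")
  }

  pars <- list(Omega0_scn = 10^p[1], kappa0_scn = 10^p[2],
               Omega0_vcn = 10^p[3], kappa0_vcn = 10^p[4])
  if (modified) {
    pars$vf_frac_scn <- f[["scn"]]
    pars$vf_frac_vcn <- f[["vcn"]]
    pars$Vf_scn <- f[["scn"]] * V0
    pars$Vf_vcn <- f[["vcn"]] * V0
  }
  fit_result(parameters = pars,
             r_squared = r_squared(obs_all, pred),
             sse = best$sse, residuals = obs_all - pred,
             converged = best$converged, message = best$message,
             n_starts = n_starts, seed = seed, trace = best$trace,
             warnings = warn)
}

pif_fit_bounds <- function(model, vb_frac) {
  lower <- c(5, 8, 5, 8)
  upper <- c(30, 13, 30, 13)
  if (model == "modified") {
    # p5 = vf_frac_scn; p6 in [0, 1] places vf_frac_vcn between its lower
    # bound and vf_frac_scn (ordering constraint Vf_SCN >= Vf_VCN)
    lower <- c(lower, vb_frac + 0.02, 0)
    upper <- c(upper, 1, 1)
  }
  list(lower = lower, upper = upper)
}

#' Fit nucleation parameters to PIF observations at one cooling rate
#'
#' Stage 2 of the two-stage procedure: the dehydration trajectory computed
#' from the stage-1 membrane parameters is held fixed and the SCN/VCN
#' nucleation parameters are estimated against observed cumulative PIF by
#' bounded least squares. The kinetic (`Omega0`) and thermodynamic
#' (`kappa0`) parameters are searched in log10 space because their fitted
#' magnitudes span many decades; critical volumes are searched as fractions
#' of `V0`. The original model has 4 free parameters, the modified model 6.
#'
#' @param obs Data frame with columns `temperature_K` and `pif` (cumulative
#'   PIF, darkening and twitching combined) at a single cooling rate.
#' @param traj The [integrate_water_transport()] trajectory at that rate.
#' @param model `"modified"` (with critical volumes) or `"original"`.
#' @param lower,upper Bounds on `(log10 Omega_SCN, log10 kappa_SCN,
#'   log10 Omega_VCN, log10 kappa_VCN[, vf_frac_SCN, vf_frac_VCN])`; defaults
#'   are log10 Omega in `[5, 30]`, log10 kappa in `[8, 13]`, `vf_frac` in
#'   `(Vb/V0, 1]`.
#' @param n_starts Multistart count (default 20, seeded Latin hypercube).
#' @param seed Integer seed.
#' @param prefactor_mode,volume_basis Passed to [pif_curve()].
#' @param weighting `"auto"` (default) applies reciprocal binomial-standard-
#'   error weights when the observations carry an `n_cells` column and is
#'   unweighted otherwise; `"binomial"` and `"none"` force either choice.
#'   The reported `r_squared` and `residuals` are always unweighted.
#'
#' @return A `fit_result`; its `warnings` flag bound-pinned critical volumes
#'   and a near-degenerate `Omega_VCN` direction.
#' @export
fit_pif <- function(obs, traj, model = c("modified", "original"),
                    lower = NULL, upper = NULL,
                    n_starts = 20, seed = 1,
                    prefactor_mode = "none", volume_basis = "total",
                    weighting = c("auto", "binomial", "none")) {
  weighting <- match.arg(weighting)
  model <- match.arg(model)
  obs <- as.data.frame(obs)
  stopifnot(all(c("temperature_K", "pif") %in% names(obs)))
  if (any(obs$pif < 0 | obs$pif > 1)) stop("pif values must lie in [0, 1]")
  cell <- attr(traj, "cell")
  b <- pif_fit_bounds(model, cell$Vb / cell$V0)
  if (is.null(lower)) lower <- b$lower
  if (is.null(upper)) upper <- b$upper
  fit_pif_engine(list(obs), list(traj), model, lower, upper,
                 n_starts, seed, prefactor_mode, volume_basis, weighting)
}

#' Fit one shared nucleation parameter set across several cooling rates
#'
#' Global variant of [fit_pif()]: a single `(Omega0, kappa0[, Vf])` pair per
#' mechanism is fitted to PIF observations pooled over all supplied cooling
#' rates, each with its own fixed trajectory.
#'
#' @param obs Data frame with columns `cooling_rate`, `temperature_K`,
#'   `pif`.
#' @param trajs Named list of trajectories, names matching the cooling rates
#'   in `obs`.
#' @inheritParams fit_pif
#' @return A `fit_result`.
#' @export
fit_pif_pooled <- function(obs, trajs, model = c("modified", "original"),
                           lower = NULL, upper = NULL,
                           n_starts = 20, seed = 1,
                           prefactor_mode = "none", volume_basis = "total",
                           weighting = c("auto", "binomial", "none")) {
  model <- match.arg(model)
  weighting <- match.arg(weighting)
  obs <- as.data.frame(obs)
  rates <- sort(unique(obs$cooling_rate))
  if (!all(as.character(rates) %in% names(trajs))) {
    stop("trajs must carry one trajectory per cooling rate, named by rate")
  }
  obs_by_rate <- lapply(rates, function(b) obs[obs$cooling_rate == b, ])
  trajs <- trajs[as.character(rates)]
  cell <- attr(trajs[[1]], "cell")
  b <- pif_fit_bounds(model, cell$Vb / cell$V0)
  if (is.null(lower)) lower <- b$lower
  if (is.null(upper)) upper <- b$upper
  fit_pif_engine(obs_by_rate, trajs, model, lower, upper,
                 n_starts, seed, prefactor_mode, volume_basis, weighting)
}
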