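# Synthetic observation tables with known ground truth, emulating the two
# raw-data products of a cryomicroscopy freezing study: per-temperature mean
# normalized cell volumes at several cooling rates, and per-cell IIF event
# records from which empirical PIF curves are tallied.

#' Ground truth for synthetic data generation
#'
#' Defines the generating model and study design for the synthetic tables.
#' The defaults emulate the study conditions of a HeLa-cell cryomicroscopy
#' experiment: volumes measured at 5, 10, 15, 30 and 60 K/min from -0.5 to
#' -45 degC with about 30 cells per rate, and IIF events at 45, 60, 75 and
#' 100 K/min from -0.5 to -50 degC with 200 cells per rate.
#'
#' @param cell A [cell_params()] object (default: spherical cell of radius
#'   7.51 um, `Vb = 0.25 V0`, `Lpg = 0.1166` um/min/atm,
#'   `ELp = 11.9236` kcal/mol).
#' @param scn,vcn [nucleation_params()] for the two mechanisms. The default
#'   set is calibrated so the model reproduces the qualitative PIF
#'   observables of such experiments: total PIF plateaus between roughly 0.3
#'   and 0.75, increasing with cooling rate; surface-catalyzed events
#'   dominate between about -10 and -35 degC; volume-catalyzed events appear
#'   at deeper supercooling and faster rates; critical volumes lie in the
#'   0.30-0.55 `V0` range with `Vf_SCN > Vf_VCN`.
#' @param volume_rates,iif_rates Cooling rates (K/min) for the two table
#'   types.
#' @param sigma Multiplicative Gaussian noise s.d. on per-cell normalized
#'   volumes (default 0.02).
#' @param cells_volume,cells_iif Cells per rate in each table type.
#' @param T_end_volume,T_end_iif Terminal temperatures (K).
#' @param grid_dK Sampling interval of the volume table (K; default 2).
#' @param seed Mandatory integer seed; all randomness flows from it through
#'   named substreams.
#' @param label_map Mapping from mechanism to the morphological event label
#'   carried in the event table. The default ties SCN to "darkening" and VCN
#'   to "twitching" as a generator convenience, not a mechanistic claim.
#'
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(cell = NULL, scn = NULL, vcn = NULL,
                         volume_rates = c(5, 10, 15, 30, 60),
                         iif_rates = c(45, 60, 75, 100),
                         sigma = 0.02,
                         cells_volume = 30, cells_iif = 200,
                         T_end_volume = 228.15, T_end_iif = 223.15,
                         grid_dK = 2, seed,
                         label_map = c(SCN = "darkening",
                                       VCN = "twitching")) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(sigma >= 0, cells_volume >= 1, cells_iif >= 1, grid_dK > 0)
  if (is.null(cell)) {
    V0 <- 4 / 3 * pi * 7.51^3
    cell <- cell_params(V0 = V0, Vb = 0.25 * V0, Lpg = 0.1166,
                        ELp = 11.9236)
  }
  if (is.null(scn)) {
    scn <- nucleation_params("SCN", Omega0 = 5e8, kappa0 = 4.3e9,
                             Vf = 0.45 * cell$V0)
  }
  if (is.null(vcn)) {
    vcn <- nucleation_params("VCN", Omega0 = 5e15, kappa0 = 5e10,
                             Vf = 0.36 * cell$V0)
  }
  stopifnot(scn$mechanism == "SCN", vcn$mechanism == "VCN",
            all(c("SCN", "VCN") %in% names(label_map)))
  structure(list(cell = cell, scn = scn, vcn = vcn,
                 volume_rates = volume_rates, iif_rates = iif_rates,
                 sigma = sigma, cells_volume = cells_volume,
                 cells_iif = cells_iif, T_end_volume = T_end_volume,
                 T_end_iif = T_end_iif, grid_dK = grid_dK,
                 seed = as.integer(seed), label_map = label_map),
            class = "ground_truth")
}

# named substreams off the master seed; offsets keep the derived seeds
# distinct per task and per cooling rate while staying well below 2^31
substream_seed <- function(gt, stream, rate = 0) {
  offsets <- c(volume_noise = 101L, event_draw = 211L, attribution = 307L)
  if (!stream %in% names(offsets)) stop("unknown substream: ", stream)
  (gt$seed %% 1000003L) * 1009L + offsets[[stream]] * 97L +
    as.integer(round(rate * 10))
}

#' Volume observation table
#'
#' Validating constructor for normalized-volume observation records.
#'
#' @param df Data frame with columns `cooling_rate` (K/min),
#'   `temperature_K`, `norm_volume_mean`, `norm_volume_sem`, `n_cells`.
#' @return The validated data frame with class `volume_observations`.
#' @export
volume_observations <- function(df) {
  need <- c("cooling_rate", "temperature_K", "norm_volume_mean",
            "norm_volume_sem", "n_cells")
  if (!all(need %in% names(df))) {
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (any(df$norm_volume_mean <= 0 | df$norm_volume_mean > 1.2)) {
    stop("normalized volumes must lie in (0, 1.2]")
  }
  if (any(df$n_cells < 1)) stop("n_cells must be >= 1")
  if (anyDuplicated(df[c("cooling_rate", "temperature_K")])) {
    stop("duplicate (cooling_rate, temperature) records")
  }
  structure(as.data.frame(df)[need],
            class = c("volume_observations", "data.frame"))
}

#' Generate a synthetic normalized-volume observation table
#'
#' For each cooling rate the true dehydration trajectory is integrated,
#' sampled on a regular temperature grid, and per-cell multiplicative
#' Gaussian noise is applied; per-temperature mean, SEM and cell count are
#' reported. Bit-reproducible given the ground-truth seed.
#'
#' @param gt A [ground_truth()] object.
#' @return A [volume_observations()] table.
#' @export
generate_volume_observations <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  T0 <- gt$cell$T0
  temps <- seq(T0 - gt$grid_dK, gt$T_end_volume, by = -gt$grid_dK)
  rows <- lapply(gt$volume_rates, function(B) {
    tr <- trajectory_at(c(T0, temps), cooling_protocol(B, T0, min(temps)),
                        gt$cell)
    nv <- tr$norm_volume[match(temps, tr$temperature_K)]
    noise <- with_seed(substream_seed(gt, "volume_noise", B), {
      matrix(stats::rnorm(gt$cells_volume * length(temps), mean = 1,
                          sd = gt$sigma),
             nrow = gt$cells_volume)
    })
    samples <- sweep(noise, 2, nv, "*")
    data.frame(cooling_rate = B,
               temperature_K = temps,
               norm_volume_mean = colMeans(samples),
               norm_volume_sem = apply(samples, 2, stats::sd) /
                 sqrt(gt$cells_volume),
               n_cells = gt$cells_volume)
  })
  volume_observations(do.call(rbind, rows))
}

#' IIF event table
#'
#' Validating constructor for per-cell IIF event records. Censored cells
#' (no event by `T_end`) carry `event_temperature_K = NA`, no mechanism,
#' and `event_type = "none"`.
#'
#' @param df Data frame with columns `cooling_rate`, `cell_id`,
#'   `event_temperature_K`, `mechanism`, `event_type`.
#' @return The validated data frame with class `iif_event_table`.
#' @export
iif_event_table <- function(df) {
  need <- c("cooling_rate", "cell_id", "event_temperature_K", "mechanism",
            "event_type")
  if (!all(need %in% names(df))) {
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (!all(df$event_type %in% c("darkening", "twitching", "none"))) {
    stop("event_type must be darkening, twitching or none")
  }
  cens <- df$event_type == "none"
  if (any(!is.na(df$mechanism[cens]))) {
    stop("censored cells must not carry a mechanism")
  }
  if (any(is.na(df$event_temperature_K[!cens]))) {
    stop("events must carry an event temperature")
  }
  structure(as.data.frame(df)[need],
            class = c("iif_event_table", "data.frame"))
}

#' Simulate per-cell IIF events at one cooling rate
#'
#' Views the PIF model as a survival model: the per-kelvin hazard along the
#' true trajectory is `h(T) = 60 [I_SCN(T) A(T) + I_VCN(T) V(T)] / B`; each
#' cell's first-event temperature is drawn by inverse-CDF sampling on the
#' cumulative hazard (censored at `T_end` if the total hazard is never
#' reached). The mechanism at an event is attributed by a Bernoulli draw
#' with probability `h_SCN / (h_SCN + h_VCN)` at the event temperature
#' (exact for competing risks with independent hazards), and the
#' morphological label follows `gt$label_map`.
#'
#' @param gt A [ground_truth()] object.
#' @param B Cooling rate (K/min), one of `gt$iif_rates` (not enforced).
#' @param dT Trajectory grid spacing (K).
#' @return An [iif_event_table()].
#' @export
simulate_iif_events <- function(gt, B, dT = 0.05) {
  stopifnot(inherits(gt, "ground_truth"))
  traj <- integrate_water_transport(
    cooling_protocol(B, gt$cell$T0, gt$T_end_iif), gt$cell, dT = dT)
  h_s <- mechanism_hazard(traj, gt$scn)
  h_v <- mechanism_hazard(traj, gt$vcn)
  Tg <- traj$temperature_K
  H <- cumulative_hazard(Tg, h_s + h_v)
  n <- gt$cells_iif
  e <- with_seed(substream_seed(gt, "event_draw", B), stats::rexp(n))
  # inverse-CDF: H is non-decreasing along the grid; linear interpolation
  # H -> T between the bracketing grid points (ties broken at first hit)
  ev_T <- rep(NA_real_, n)
  Hmax <- H[length(H)]
  hit <- e <= Hmax
  for (i in which(hit)) {
    j <- which(H >= e[i])[1]
    if (j == 1L || H[j] == H[j - 1L]) {
      ev_T[i] <- Tg[j]
    } else {
      frac <- (e[i] - H[j - 1L]) / (H[j] - H[j - 1L])
      ev_T[i] <- Tg[j - 1L] + frac * (Tg[j] - Tg[j - 1L])
    }
  }
  share <- function(Te) {
    hs <- stats::approx(Tg, h_s, xout = Te, rule = 2)$y
    hv <- stats::approx(Tg, h_v, xout = Te, rule = 2)$y
    ifelse(hs + hv > 0, hs / (hs + hv), 0.5)
  }
  mech <- rep(NA_character_, n)
  if (any(hit)) {
    p_scn <- share(ev_T[hit])
    u <- with_seed(substream_seed(gt, "attribution", B),
                   stats::runif(sum(hit)))
    mech[hit] <- ifelse(u < p_scn, "SCN", "VCN")
  }
  label <- ifelse(is.na(mech), "none", unname(gt$label_map[mech]))
  iif_event_table(data.frame(
    cooling_rate = B,
    cell_id = seq_len(n),
    event_temperature_K = ev_T,
    mechanism = mech,
    event_type = label))
}

#' Aggregated PIF observations
#'
#' Validating constructor for cumulative-PIF observation records.
#'
#' @param df Data frame with columns `cooling_rate`, `temperature_K`,
#'   `pif_darkening`, `pif_twitching`, `pif_both`, `n_cells`.
#' @return The validated data frame with class `iif_observations`.
#' @export
iif_observations <- function(df) {
  need <- c("cooling_rate", "temperature_K", "pif_darkening",
            "pif_twitching", "pif_both", "n_cells")
  if (!all(need %in% names(df))) {
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  pcols <- c("pif_darkening", "pif_twitching", "pif_both")
  if (any(unlist(df[pcols]) < 0 | unlist(df[pcols]) > 1)) {
    stop("PIF values must lie in [0, 1]")
  }
  for (b in unique(df$cooling_rate)) {
    o <- df[df$cooling_rate == b, ]
    o <- o[order(-o$temperature_K), ]
    if (is.unsorted(o$pif_both)) {
      stop("cumulative PIF must be non-decreasing along cooling (rate ",
           b, ")")
    }
  }
  structure(as.data.frame(df)[need],
            class = c("iif_observations", "data.frame"))
}

#' Empirical PIF from an event table
#'
#' Cumulative fraction of cells whose IIF event occurred at or above each
#' grid temperature, per cooling rate and per morphological label.
#'
#' @param events An [iif_event_table()].
#' @param grid Temperature grid (K), strictly decreasing.
#' @return An [iif_observations()] table.
#' @export
empirical_pif <- function(events, grid) {
  events <- as.data.frame(events)
  if (nrow(events) == 0) stop("empty event table")
  rows <- lapply(sort(unique(events$cooling_rate)), function(b) {
    ev <- events[events$cooling_rate == b, ]
    n <- nrow(ev)
    by_T <- function(keep) {
      vapply(grid, function(Tq) {
        sum(keep & !is.na(ev$event_temperature_K) &
              ev$event_temperature_K >= Tq) / n
      }, numeric(1))
    }
    data.frame(cooling_rate = b,
               temperature_K = grid,
               pif_darkening = by_T(ev$event_type == "darkening"),
               pif_twitching = by_T(ev$event_type == "twitching"),
               pif_both = by_T(ev$event_type != "none"),
               n_cells = n)
  })
  iif_observations(do.call(rbind, rows))
}
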