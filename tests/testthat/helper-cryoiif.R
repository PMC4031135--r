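# Shared fixtures: one cell type and a few cached trajectories so the
# slower ODE integrations run once per test session.

hela_cell <- function() {
  V0 <- 4 / 3 * pi * 7.51^3
  cell_params(V0 = V0, Vb = 0.25 * V0, Lpg = 0.1166, ELp = 11.9236)
}

.traj_cache <- new.env(parent = emptyenv())

cached_trajectory <- function(B, T_end = 223.15, dT = 0.05,
                              cell = hela_cell()) {
  key <- paste(B, T_end, dT, signif(cell$Vb, 8), sep = "_")
  if (is.null(.traj_cache[[key]])) {
    .traj_cache[[key]] <- integrate_water_transport(
      cooling_protocol(B, T_end = T_end), cell, dT = dT)
  }
  .traj_cache[[key]]
}

default_scn <- function(cell = hela_cell(), gated = TRUE) {
  nucleation_params("SCN", Omega0 = 5e8, kappa0 = 4.3e9,
                    Vf = if (gated) 0.45 * cell$V0)
}

default_vcn <- function(cell = hela_cell(), gated = TRUE) {
  nucleation_params("VCN", Omega0 = 5e15, kappa0 = 5e10,
                    Vf = if (gated) 0.36 * cell$V0)
}
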