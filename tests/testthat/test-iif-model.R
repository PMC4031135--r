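ref_state <- function(cell = hela_cell()) {
  xw0 <- water_mole_fraction(cell$V0, cell)
  Tf0 <- equilibrium_freezing_temperature(xw0)
  list(Tf0 = Tf0,
       eta_ref = cytoplasm_viscosity(Tf0, salt_volume_fraction(cell$V0,
                                                               cell)))
}

test_that("nucleation rate vanishes without supercooling and under an
           infinite barrier", {
  np <- nucleation_params("SCN", 1e8, 5e9)
  r <- ref_state()
  expect_identical(nucleation_rate(272.65, 272.65, 2, np, r$eta_ref,
                                   r$Tf0), 0)
  expect_identical(nucleation_rate(273, 272.65, 2, np, r$eta_ref, r$Tf0), 0)
  big <- nucleation_params("SCN", 1e8, 1e30)
  expect_identical(nucleation_rate(262, 272.65, 2, big, r$eta_ref, r$Tf0),
                   0)
  expect_gt(nucleation_rate(262, 272.65, 2, np, r$eta_ref, r$Tf0), 0)
})

test_that("viscosity divergence makes the rate non-monotone in supercooling", {
  np <- nucleation_params("VCN", 1e15, 5e10)
  r <- ref_state()
  fv <- free_volume_params()
  Tf <- 272.65
  T <- seq(Tf - 1, fv$T_gw - fv$K21 + 2, by = -0.5)
  eta <- water_viscosity(T, fv)
  rate <- nucleation_rate(T, Tf, eta, np, r$eta_ref, r$Tf0)
  k <- which.max(rate)
  expect_gt(k, 1)
  expect_lt(k, length(rate))
})

test_that("the critical-volume gate is inclusive and only removes hazard", {
  np <- nucleation_params("SCN", 1e8, 5e9, Vf = 1000)
  r <- ref_state()
  open <- nucleation_rate(260, 272, 3, np, r$eta_ref, r$Tf0)
  expect_identical(
    modified_nucleation_rate(260, 1000, 272, 3, np, r$eta_ref, r$Tf0),
    open)
  expect_identical(
    modified_nucleation_rate(260, 999.9, 272, 3, np, r$eta_ref, r$Tf0), 0)
  # a gate below Vb can never close along an admissible trajectory
  tr <- cached_trajectory(60)
  cell <- hela_cell()
  np_low <- nucleation_params("SCN", 1e8, 5e9, Vf = 0.5 * cell$Vb)
  np_open <- nucleation_params("SCN", 1e8, 5e9)
  expect_identical(
    modified_nucleation_rate(tr$temperature_K, tr$volume_um3, tr$Tf_K,
                             tr$viscosity_mPas, np_low, r$eta_ref, r$Tf0),
    nucleation_rate(tr$temperature_K, tr$Tf_K, tr$viscosity_mPas,
                    np_open, r$eta_ref, r$Tf0))
})

test_that("PIF curves are proper cumulative probabilities", {
  tr <- cached_trajectory(60)
  pc <- pif_curve(tr, default_scn(), default_vcn())
  for (col in c("pif_scn", "pif_vcn", "pif_total")) {
    expect_true(all(pc[[col]] >= 0 & pc[[col]] <= 1))
    expect_true(all(diff(pc[[col]]) >= -1e-12))
    expect_equal(pc[[col]][1], 0)
  }
  expect_true(all(pc$pif_total >= pmax(pc$pif_scn, pc$pif_vcn) - 1e-12))
  none <- nucleation_params("SCN", 0, 1e9)
  expect_true(all(pif_mechanism(tr, none) == 0))
})

test_that("PIF quadrature agrees with a dense Riemann-sum oracle", {
  tr <- cached_trajectory(60)
  np <- default_scn(gated = FALSE)
  pif <- as.numeric(pif_mechanism(tr, np))
  h <- attr(pif_mechanism(tr, np), "hazard_per_K")
  # oracle: midpoint Riemann sum on 1e4 sub-intervals of the linearly
  # interpolated hazard
  Tg <- tr$temperature_K
  fine <- seq(Tg[1], Tg[length(Tg)], length.out = 1e4 + 1)
  mid <- (fine[-1] + fine[-length(fine)]) / 2
  hm <- approx(Tg, h, xout = mid)$y
  Hf <- cumsum(hm * abs(diff(fine)))
  pif_oracle <- approx(fine[-1], 1 - exp(-Hf), xout = Tg, rule = 2)$y
  pif_oracle[1] <- 0
  expect_lt(max(abs(pif - pif_oracle)), 1e-4)
})

test_that("gating the rate produces a plateau and never raises PIF", {
  tr <- cached_trajectory(60)
  cell <- hela_cell()
  gated <- pif_mechanism(tr, default_scn())
  open <- pif_mechanism(tr, default_scn(gated = FALSE))
  expect_true(all(gated <= open + 1e-12))
  j <- which(tr$volume_um3 < 0.45 * cell$V0)[1]
  expect_false(is.na(j))
  tail_vals <- as.numeric(gated)[j:nrow(tr)]
  expect_lt(max(tail_vals) - min(tail_vals), 1e-12)
  expect_lt(max(tail_vals), 1)
})

test_that("the SCN gate closes before the VCN gate when Vf_SCN > Vf_VCN", {
  tr <- cached_trajectory(60)
  hs <- attr(pif_mechanism(tr, default_scn()), "hazard_per_K")
  hv <- attr(pif_mechanism(tr, default_vcn()), "hazard_per_K")
  shutoff <- function(h) {
    active <- which(h > 0)
    tr$temperature_K[active[length(active)]]
  }
  expect_gt(shutoff(hs), shutoff(hv))
})

test_that("PIF is invariant to grid refinement", {
  tr1 <- cached_trajectory(60, dT = 0.05)
  tr2 <- cached_trajectory(60, dT = 0.025)
  p1 <- pif_curve(tr1, default_scn(), default_vcn())
  p2 <- pif_curve(tr2, default_scn(), default_vcn())
  fine <- approx(p2$temperature_K, p2$pif_total,
                 xout = p1$temperature_K)$y
  d <- abs(fine - p1$pif_total)
  expect_lt(max(d / pmax(p1$pif_total, 1e-3)), 1e-3)
})

test_that("total PIF composes the two mechanisms as independent risks", {
  expect_identical(pif_total(0, 0), 0)
  expect_equal(pif_total(0.3, 0.5), 0.65)
  expect_identical(pif_total(1, 0.7), 1)
  expect_equal(pif_total(0.2, 0.6), pif_total(0.6, 0.2))
  expect_error(pif_total(1.2, 0.5), "\\[0, 1\\]")
  expect_error(pif_total(c(0.1, 0.2), 0.5), "grid")
})
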