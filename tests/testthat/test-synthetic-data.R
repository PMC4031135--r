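test_that("a noiseless generator reproduces the model curve exactly", {
  gt <- ground_truth(seed = 5, sigma = 0, cells_volume = 3,
                     volume_rates = c(10, 60))
  obs <- generate_volume_observations(gt)
  for (b in c(10, 60)) {
    o <- obs[obs$cooling_rate == b, ]
    trb <- integrate_water_transport(
      cooling_protocol(b, T_end = min(o$temperature_K)), gt$cell, dT = 0.05)
    model <- approx(trb$temperature_K, trb$norm_volume,
                    xout = o$temperature_K)$y
    expect_equal(o$norm_volume_mean, model, tolerance = 1e-6)
    expect_true(all(o$norm_volume_sem == 0))
  }
})

test_that("generation is bit-reproducible from the seed", {
  gt <- ground_truth(seed = 99, volume_rates = c(10, 30), cells_volume = 8,
                     cells_iif = 25)
  expect_identical(generate_volume_observations(gt),
                   generate_volume_observations(gt))
  expect_identical(simulate_iif_events(gt, 60, dT = 0.2),
                   simulate_iif_events(gt, 60, dT = 0.2))
  gt2 <- ground_truth(seed = 100, volume_rates = c(10, 30),
                      cells_volume = 8, cells_iif = 25)
  expect_false(identical(generate_volume_observations(gt),
                         generate_volume_observations(gt2)))
})

test_that("the SEM of the volume table scales as 1/sqrt(n)", {
  sems <- vapply(c(10, 40, 160), function(n) {
    gt <- ground_truth(seed = 31, volume_rates = 30, cells_volume = n,
                       sigma = 0.02)
    mean(generate_volume_observations(gt)$norm_volume_sem)
  }, numeric(1))
  expect_equal(sems[1] / sems[2], 2, tolerance = 0.25)
  expect_equal(sems[2] / sems[3], 2, tolerance = 0.25)
})

test_that("event simulation respects the gates and the no-nucleation limit", {
  cell <- hela_cell()
  off <- ground_truth(seed = 3, cells_iif = 50,
                      scn = nucleation_params("SCN", 0, 1e9,
                                              Vf = 0.45 * cell$V0),
                      vcn = nucleation_params("VCN", 0, 1e10,
                                              Vf = 0.36 * cell$V0))
  ev <- simulate_iif_events(off, 60, dT = 0.2)
  expect_true(all(ev$event_type == "none"))
  expect_true(all(is.na(ev$event_temperature_K)))

  gt <- ground_truth(seed = 3, cells_iif = 400)
  ev <- simulate_iif_events(gt, 60)
  tr <- cached_trajectory(60)
  # no events once both gates have closed (VCN closes last, at 0.36 V0)
  T_gate <- tr$temperature_K[which(tr$volume_um3 < 0.36 * cell$V0)[1]]
  hit <- !is.na(ev$event_temperature_K)
  expect_gt(sum(hit), 0)
  expect_true(all(ev$event_temperature_K[hit] >= T_gate - 0.05))
  expect_true(all(is.na(ev$mechanism[ev$event_type == "none"])))
  expect_true(all(ev$event_type[hit] %in% c("darkening", "twitching")))
})

test_that("empirical PIF matches a hand count on a toy table", {
  ev <- iif_event_table(data.frame(
    cooling_rate = 60,
    cell_id = 1:5,
    event_temperature_K = c(263.15, 258.15, 258.15, NA, 243.15),
    mechanism = c("SCN", "SCN", "VCN", NA, "VCN"),
    event_type = c("darkening", "darkening", "twitching", "none",
                   "twitching")))
  grid <- c(268.15, 260.15, 253.15, 240.15)
  pif <- empirical_pif(ev, grid)
  expect_equal(pif$pif_both, c(0, 0.2, 0.6, 0.8))
  expect_equal(pif$pif_darkening, c(0, 0.2, 0.4, 0.4))
  expect_equal(pif$pif_twitching, c(0, 0, 0.2, 0.4))
  expect_equal(pif$n_cells, rep(5, 4))
  expect_error(empirical_pif(ev[0, ], grid), "empty")
})

test_that("empirical PIF handles the all-event and no-event extremes", {
  ev_all <- iif_event_table(data.frame(
    cooling_rate = 10, cell_id = 1:4,
    event_temperature_K = rep(271.65, 4),
    mechanism = rep("SCN", 4), event_type = rep("darkening", 4)))
  pif <- empirical_pif(ev_all, c(272.15, 271.15))
  expect_equal(pif$pif_both, c(0, 1))
  ev_none <- iif_event_table(data.frame(
    cooling_rate = 10, cell_id = 1:4,
    event_temperature_K = rep(NA_real_, 4),
    mechanism = rep(NA_character_, 4), event_type = rep("none", 4)))
  expect_true(all(empirical_pif(ev_none, c(272, 260))$pif_both == 0))
})

test_that("empirical PIF converges to the analytic curve as cells grow", {
  tr <- cached_trajectory(60)
  analytic <- pif_curve(tr, default_scn(), default_vcn())
  grid <- seq(270.65, 223.15, by = -1)
  target <- approx(analytic$temperature_K, analytic$pif_total,
                   xout = grid)$y
  err <- vapply(c(100, 1600), function(n) {
    gt <- ground_truth(seed = 77, cells_iif = n)
    pif <- empirical_pif(simulate_iif_events(gt, 60), grid)
    max(abs(pif$pif_both - target))
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})
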