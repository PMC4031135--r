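test_that("water mole fraction has the right limits and domain", {
  cell <- hela_cell()
  expect_lt(abs(water_mole_fraction(1e12, cell) - 1), 1e-6)
  expect_lt(water_mole_fraction(cell$Vb * (1 + 1e-9), cell), 1e-4)
  expect_error(water_mole_fraction(cell$Vb, cell), "inactive volume")
  expect_error(water_mole_fraction(0.5 * cell$Vb, cell), "inactive volume")
})

test_that("isotonic construction freezes at -0.5 degC and inverts cleanly", {
  cell <- hela_cell()
  Tf0 <- equilibrium_freezing_temperature(
    water_mole_fraction(cell$V0, cell))
  expect_equal(Tf0, 272.65, tolerance = 1e-10)

  # closed form agrees with a brute-force root solve of the same condition
  co <- iif_constants()
  oracle <- uniroot(function(ns) {
    mw <- (cell$V0 - cell$Vb) / co$vw
    xw <- mw / (mw + 2 * ns)
    equilibrium_freezing_temperature(xw, co) - 272.65
  }, c(1e-16, 1e-10), tol = 1e-22)$root
  expect_equal(cell$ns, oracle, tolerance = 1e-6)

  # ns is proportional to the active water volume at fixed T0
  ns_half <- isotonic_salt_content(cell$Vb + (cell$V0 - cell$Vb) / 2,
                                   cell$Vb)
  expect_equal(ns_half, cell$ns / 2, tolerance = 1e-12)

  expect_error(isotonic_salt_content(cell$V0, cell$Vb, T0 = 273.15),
               "strictly below")
  expect_error(cell_params(V0 = cell$V0, Vb = cell$Vb, Lpg = 0.1,
                           ELp = 10, T0 = 273.15))
})

test_that("freezing temperature is the ideal-solution law", {
  expect_equal(equilibrium_freezing_temperature(1), 273.15)
  expect_error(equilibrium_freezing_temperature(0), "positive")
  expect_error(equilibrium_freezing_temperature(-0.1), "positive")
  xw <- seq(0.2, 1, length.out = 100)
  Tf <- equilibrium_freezing_temperature(xw)
  expect_true(all(diff(Tf) > 0))
  expect_true(all(Tf <= 273.15))
})

test_that("free-volume water viscosity is calibrated and diverges at Tg", {
  expect_lt(abs(water_viscosity(293.15) - 1.0), 0.25)
  eta <- water_viscosity(c(263, 273, 293))
  expect_true(all(diff(eta) < 0))
  fv <- free_volume_params()
  expect_error(water_viscosity(fv$T_gw - fv$K21, fv), "free volume")
  expect_gt(water_viscosity(fv$T_gw - fv$K21 + 0.5, fv), 1e6)
})

test_that("cytoplasm viscosity factorizes as water times crowding", {
  fv <- free_volume_params()
  expect_identical(cytoplasm_viscosity(260, 0, fv), water_viscosity(260, fv))
  phi <- seq(0, 0.5, by = 0.05)
  expect_true(all(diff(krieger_dougherty(phi)) > 0))
  expect_equal(cytoplasm_viscosity(250, 0.3, fv),
               water_viscosity(250, fv) * krieger_dougherty(0.3))
  expect_error(krieger_dougherty(0.64), "packing")
})

test_that("membrane permeability follows the Arrhenius law", {
  cell <- hela_cell()
  expect_identical(water_permeability(273.15, cell), cell$Lpg)
  # a forty-fold collapse between -0.5 and -40 degC
  ratio <- water_permeability(233.15, cell) /
    water_permeability(272.65, cell)
  expect_equal(ratio, 0.024, tolerance = 0.05)
  # composition law to machine precision
  l <- function(T) water_permeability(T, cell)
  expect_equal(l(260) / l(250) * l(250) / l(240), l(260) / l(240),
               tolerance = 1e-14)
  Ts <- seq(272, 230, by = -2)
  expect_true(all(diff(water_permeability(Ts, cell)) < 0))
})

test_that("sphere geometry matches closed forms", {
  g <- sphere_geometry(4 * pi / 3)
  expect_equal(g$radius, 1)
  expect_equal(g$area, 4 * pi)
  g2 <- sphere_geometry(4 / 3 * pi * 7.51^3)
  expect_equal(g2$radius, 7.51)
  expect_equal(g2$area, 4 * pi * 7.51^2)
  V <- exp(runif(50, log(1), log(1e5)))
  A <- sphere_geometry(V)$area
  expect_equal(A^3, 36 * pi * V^2, tolerance = 1e-12)
  expect_error(sphere_geometry(0), "positive")
})

test_that("freezing point and equilibrium volume round-trip along a ramp", {
  cell <- hela_cell()
  Ts <- seq(272.65, 233.15, length.out = 80)
  Veq <- equilibrium_volume(Ts, cell)
  Tf <- equilibrium_freezing_temperature(water_mole_fraction(Veq, cell))
  expect_lt(max(abs(Tf - Ts)), 1e-8)
})

test_that("physics outputs are finite and positive on their domains", {
  cell <- hela_cell()
  set.seed(11)
  V <- runif(200, cell$Vb * 1.001, cell$V0)
  T <- runif(200, 180, 273)
  expect_true(all(is.finite(water_mole_fraction(V, cell))))
  expect_true(all(water_mole_fraction(V, cell) > 0))
  expect_true(all(is.finite(water_viscosity(T))))
  expect_true(all(water_viscosity(T) > 0))
  expect_true(all(is.finite(water_permeability(T, cell))))
  expect_true(all(water_permeability(T, cell) > 0))
  expect_true(all(is.finite(sphere_geometry(V)$area)))
})
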