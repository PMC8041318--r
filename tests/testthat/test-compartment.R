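test_that("charge-state arithmetic matches the printed parent ions", {
  M <- neutral_mass_from_mz(478.5515, 3)
  expect_equal(M, 3 * (478.5515 - 1.00728))
  expect_equal(round(M, 2), 1432.63)
  # bi-charged ion back-predicted from the tri-charged one
  expect_equal(round(predict_mz(neutral_mass_from_mz(478.5, 3), 2), 1),
               717.2)
})

test_that("neutral_mass_from_mz and predict_mz are exact inverses", {
  set.seed(2)
  for (r in 1:50) {
    M <- runif(1, 300, 5000); z <- sample(1:6, 1)
    expect_equal(neutral_mass_from_mz(predict_mz(M, z), z), M,
                 tolerance = 1e-12)
  }
  expect_equal(neutral_mass_from_mz(1000 + 1.00728, 1), 1000)
  expect_error(neutral_mass_from_mz(500, 0), "positive integer")
  expect_error(predict_mz(-5, 2), "positive")
})

test_that("conjugate identity enforces charge-state consistency", {
  ci <- conjugate_identity(charge_states = data.frame(z = 3, mz = 478.5515))
  expect_equal(ci$neutral_mass, 1432.63266, tolerance = 1e-6)
  expect_error(
    conjugate_identity(1432.63,
                       charge_states = data.frame(z = 2, mz = 800)),
    "implies M")
})

test_that("compartment volumes follow the geometry", {
  g <- compartment_geometry(2e6)
  expect_equal(compartment_volume(g, "cytosolic"), 2.4e-6)
  expect_equal(compartment_volume(g, "vesicles"), 1.0e-7)
  expect_equal(compartment_volume(g, "extracellular"), 3e-3)
  g2 <- compartment_geometry(2e6, cytosol_fraction = 0.3,
                             vesicle_fraction = 0.3)
  expect_equal(compartment_volume(g2, "cytosolic"),
               compartment_volume(g2, "vesicles"))
  expect_error(compartment_volume(g, "nucleus"))
  expect_error(compartment_geometry(2e6, cytosol_fraction = 0.7,
                                    vesicle_fraction = 0.4),
               "less than 1")
})

test_that("fraction concentration is linear in mass, inverse in volume", {
  g <- compartment_geometry(2e6)
  vves <- compartment_volume(g, "vesicles")
  c1 <- fraction_concentration(34.4, 1432.63, vves)
  expect_equal(round(c1, 0), 240)   # from the m/z-derived molar mass
  expect_equal(fraction_concentration(0, 1432.63, vves), 0)
  set.seed(3)
  for (r in 1:20) {
    m <- runif(1, 1, 100); M <- runif(1, 500, 2000); v <- runif(1, 1e-8, 1e-3)
    expect_equal(fraction_concentration(2 * m, M, v),
                 2 * fraction_concentration(m, M, v))
    expect_equal(fraction_concentration(m, M, 2 * v),
                 fraction_concentration(m, M, v) / 2)
  }
  expect_error(fraction_concentration(1, 1432, 0), "positive")
})

test_that("vesicle/cytosol ratio is mass- and cell-count-independent", {
  g <- compartment_geometry(2e6)
  expect_equal(round(vesicle_cytosol_ratio(34.4, 60.2, g), 1), 13.7)
  expect_equal(round(vesicle_cytosol_ratio(18.6, 31.6, g), 1), 14.1)
  g_other <- compartment_geometry(7e6)   # n_cells cancels
  expect_equal(vesicle_cytosol_ratio(34.4, 60.2, g_other),
               vesicle_cytosol_ratio(34.4, 60.2, g))
  g_eq <- compartment_geometry(1e6, cytosol_fraction = 0.2,
                               vesicle_fraction = 0.2)
  expect_equal(vesicle_cytosol_ratio(5, 5, g_eq), 1)
  expect_error(vesicle_cytosol_ratio(5, 0, g), "undefined")
})

test_that("fluorometric back-calculation reproduces the signal workflow", {
  g <- compartment_geometry(6e6)
  res <- fluorometric_concentration(c(834, 1120), c(747, 994),
                                    calibration_factor = 0.598, geom = g)
  expect_equal(res$difference_kcounts, c(87, 126))
  # study-consistent calibration factor: 87 kcounts correspond to
  # 20.2 muM over the pooled 7.2 uL cytosol
  cal <- 87 / (20.2 * 7.2e-6 * 1e6)
  res2 <- fluorometric_concentration(834, 747, cal, g)
  expect_equal(res2$concentration_uM, 20.2, tolerance = 1e-10)
  expect_equal(fluorometric_concentration(500, 500, 1, g)$concentration_uM,
               0)
  expect_warning(fluorometric_concentration(400, 500, 1, g), "clamped")
  expect_error(fluorometric_concentration(834, 747, geom = g),
               "calibration_factor")
})

test_that("single-cell concentration follows the dilution formula", {
  # 1.2 pmol in the diluted sample (2.4e-3 muM x 500 uL) over 1e6 cells
  # of 1.2 pL cytosol each -> 1 muM
  expect_equal(single_cell_concentration(2.4e-3, 500e-6, 1e6, 1.2e-12), 1)
  expect_equal(single_cell_concentration(2.4e-3, 500e-6, 2e6, 1.2e-12),
               0.5)
  # defaults consistent with the 2 pL / 60% geometry
  g <- compartment_geometry(1)
  expect_equal(g$cell_volume * g$cytosol_fraction, 1.2e-12)
  expect_error(single_cell_concentration(1, 5e-4, 0), "positive")
})
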