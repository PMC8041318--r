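test_that("generated bundle matches the assay designs", {
  b <- generate_scenario(scenario_config(seed = 5))
  expect_equal(nrow(b$rates_peptide), 20L)   # 5 substrate x 4 inhibitor
  expect_equal(nrow(b$rates_conjugate), 15L) # 5 substrate x 3 inhibitor
  expect_true(all(b$rates_peptide$dump_uM == 140))
  expect_equal(sort(unique(b$rates_conjugate$inhibitor_uM)), c(0, 20, 40))
  expect_equal(b$decay$time_min, c(20, 40, 60, 120, 240))
  expect_equal(nrow(b$fractions), 6L)
  expect_equal(nrow(b$binding), 2L)
})

test_that("every generated table passes its stage's validation", {
  b <- generate_scenario(scenario_config(seed = 6))
  expect_silent(folatekin:::validate_rate_table(b$rates_peptide))
  expect_silent(folatekin:::validate_rate_table(b$rates_conjugate))
  expect_s3_class(fit_inhibition(b$rates_peptide), "ts_inhibition")
  expect_s3_class(fit_decay(b$decay), "decay_fit")
  expect_true(all(b$combinations$inh_combined_pct >= 0 &
                    b$combinations$inh_combined_pct <= 100))
  expect_s3_class(cluster_sq(sq_matrix(b$combinations)), "sq_clustering")
})

test_that("same seed gives identical bundles", {
  b1 <- generate_scenario(scenario_config(seed = 21))
  b2 <- generate_scenario(scenario_config(seed = 21))
  expect_identical(b1, b2)
  b3 <- generate_scenario(scenario_config(seed = 22))
  expect_false(identical(b1$rates_peptide$rate, b3$rates_peptide$rate))
})

test_that("zero-noise bundle lets the pipeline recover all truths", {
  b <- generate_scenario(scenario_config(seed = 1), noise_free = TRUE)
  fitp <- suppressWarnings(fit_inhibition(b$rates_peptide))
  expect_identical(fitp$mode, "competitive")
  expect_equal(fitp$Ki_app, 90, tolerance = 1e-6)
  fitc <- suppressWarnings(fit_inhibition(b$rates_conjugate))
  expect_identical(fitc$mode, "mixed")
  expect_equal(fitc$Ki_app, 38, tolerance = 1e-6)
  expect_equal(fitc$Kip_app, 44, tolerance = 1e-6)
  fd <- fit_decay(b$decay)
  expect_equal(fd$k, 3.5e-3, tolerance = 1e-10)
  truth <- attr(b$combinations, "truth")
  sq <- synergism_quotient(b$combinations$inh_a_pct,
                           b$combinations$inh_b_pct,
                           b$combinations$inh_combined_pct)
  expect_equal(sq, truth$sq, tolerance = 1e-12)
  expect_identical(classify_sq(sq), truth$class)
})

test_that("end-to-end recovery over seeds is essentially unbiased", {
  # 100 seeds at the default bench-noise levels
  ki <- k <- numeric(100)
  cls_hit <- cls_n <- 0
  for (s in 1:100) {
    b <- generate_scenario(scenario_config(seed = s))
    ki[s] <- fit_inhibition(b$rates_peptide)$Ki_app
    k[s] <- fit_decay(b$decay)$k
    truth <- attr(b$combinations, "truth")
    sq <- synergism_quotient(b$combinations$inh_a_pct,
                             b$combinations$inh_b_pct,
                             b$combinations$inh_combined_pct)
    # classes away from the thresholds should survive 5-point noise
    clear <- truth$sq >= 1.25 | truth$sq <= 0.8
    cls_hit <- cls_hit + sum(classify_sq(sq)[clear] == truth$class[clear])
    cls_n <- cls_n + sum(clear)
  }
  expect_lt(abs(stats::median(ki) / 90 - 1), 0.05)
  expect_lt(abs(stats::median(k) / 3.5e-3 - 1), 0.05)
  expect_gt(cls_hit / cls_n, 0.8)
})
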