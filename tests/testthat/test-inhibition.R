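test_that("simulate_rates is reproducible and noise-free on the law", {
  p <- conjugate_params()
  d0 <- simulate_rates(p, S_GRID, I_CONJ)
  expect_equal(d0$rate,
               ts_rate(d0$substrate_uM, d0$inhibitor_uM, 140, p))
  expect_equal(nrow(simulate_rates(peptide_params(), S_GRID, I_PEPTIDE)),
               20L)
  a <- simulate_rates(p, S_GRID, I_CONJ, noise_cv = 0.05, seed = 11)
  b <- simulate_rates(p, S_GRID, I_CONJ, noise_cv = 0.05, seed = 11)
  expect_identical(a, b)
  expect_error(simulate_rates(p, numeric(0), I_CONJ), "empty")
  expect_error(simulate_rates(p, S_GRID, I_CONJ, noise_cv = -1), ">= 0")
})

test_that("noise-free competitive data give common reciprocal intercepts", {
  fit <- suppressWarnings(
    fit_inhibition(simulate_rates(peptide_params(), S_GRID, I_PEPTIDE)))
  ints <- fit$primary$intercept
  expect_lt(max(abs(ints / ints[1] - 1)), 1e-9)
  expect_identical(fit$mode, "competitive")
  expect_true(is.na(fit$Kip_app))
})

test_that("noise-free mixed data yield inhibitor-dependent intercepts", {
  fit <- suppressWarnings(
    fit_inhibition(simulate_rates(conjugate_params(), S_GRID, I_CONJ)))
  expect_identical(fit$mode, "mixed")
  expect_gt(coef(fit$secondary$intercept)[[2]], 0)
})

test_that("noise-free roundtrip recovers generating apparent constants", {
  cases <- list(list(Ki = 90, Kip = Inf, mode = "competitive"),
                list(Ki = 38, Kip = 44, mode = "mixed"),
                list(Ki = 40, Kip = 44, mode = "mixed"))
  for (cs in cases) {
    p <- params_from_apparent(Km_app = 15, Ki = cs$Ki, Kip = cs$Kip)
    ilev <- if (is.finite(cs$Kip)) I_CONJ else I_PEPTIDE
    fit <- suppressWarnings(fit_inhibition(simulate_rates(p, S_GRID, ilev)))
    expect_identical(fit$mode, cs$mode)
    expect_equal(fit$Ki_app, cs$Ki, tolerance = 1e-6)
    if (is.finite(cs$Kip))
      expect_equal(fit$Kip_app, cs$Kip, tolerance = 1e-6)
  }
})

test_that("fits are invariant to record order", {
  d <- simulate_rates(conjugate_params(), S_GRID, I_CONJ,
                      noise_cv = 0.05, seed = 3)
  f1 <- fit_inhibition(d)
  f2 <- fit_inhibition(d[sample(nrow(d)), ])
  expect_equal(coef(f1), coef(f2))
  expect_identical(f1$mode, f2$mode)
})

test_that("degenerate observations and designs are handled", {
  d <- simulate_rates(conjugate_params(), S_GRID, I_CONJ)
  d$rate[1] <- 0
  expect_warning(fit_inhibition(d), "non-positive rate")
  d2 <- d[d$substrate_uM > 20 | d$inhibitor_uM > 0, ]
  expect_error(suppressWarnings(fit_inhibition(d2)),
               "fewer than 3 substrate levels")
  d3 <- d; d3$dump_uM[1] <- 99
  expect_error(fit_inhibition(d3), "one dUMP")
  flat <- data.frame(substrate_uM = rep(S_GRID, 2),
                     inhibitor_uM = rep(c(0, 50), each = 5),
                     dump_uM = 140,
                     rate = rep(ts_rate(S_GRID, 0, 140,
                                        peptide_params()), 2))
  expect_identical(suppressWarnings(fit_inhibition(flat))$mode,
                   "no inhibition detected")
})

test_that("two inhibitor levels fall back to low-confidence rule", {
  fit <- suppressWarnings(fit_inhibition(
    simulate_rates(conjugate_params(), S_GRID, c(0, 40))))
  expect_true(fit$low_confidence)
  expect_identical(fit$mode, "mixed")
  fit2 <- suppressWarnings(fit_inhibition(
    simulate_rates(peptide_params(), S_GRID, c(0, 40))))
  expect_identical(fit2$mode, "competitive")
})

test_that("model methods are mutually consistent", {
  d <- simulate_rates(conjugate_params(), S_GRID, I_CONJ,
                      noise_cv = 0.05, seed = 5)
  fit <- fit_inhibition(d)
  expect_equal(residuals(fit), d$rate - predict(fit))
  expect_named(coef(fit),
               c("Ki_app", "Ki_app_se", "Kip_app", "Kip_app_se"))
  expect_output(print(summary(fit)), "Secondary fit")
  grDevices::pdf(NULL); on.exit(grDevices::dev.off())
  expect_invisible(plot(fit))
})

test_that("stochastic recovery: median Ki within 10% at 5% rate noise", {
  set.seed(101)
  p <- peptide_params()
  ki <- replicate(200, {
    d <- simulate_rates(p, S_GRID, I_PEPTIDE, noise_cv = 0.05)
    fit_inhibition(d)$Ki_app
  })
  expect_lt(abs(stats::median(ki) / 90 - 1), 0.10)
})
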