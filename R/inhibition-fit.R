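#' Simulate an initial-rate dataset on a substrate x inhibitor grid
#'
#' Generates a fixed-dUMP initial-rate table from the coupled-equilibrium
#' rate law, optionally perturbed by multiplicative Gaussian noise with a
#' given coefficient of variation -- the structure of the double-reciprocal
#' inhibition assays (substrate grid crossed with a few inhibitor levels
#' at dUMP = 140 muM).
#'
#' @param p a [mechanism_params()] object.
#' @param s substrate levels, muM.
#' @param i inhibitor levels, muM.
#' @param d dUMP concentration, muM (single value; the assay design keeps
#'   it fixed).
#' @param noise_cv coefficient of variation of multiplicative Gaussian
#'   noise on the rates; 0 gives noise-free data.
#' @param seed optional integer seed for reproducibility.
#' @return data.frame with columns `substrate_uM`, `inhibitor_uM`,
#'   `dump_uM`, `rate`; attribute `"truth"` carries the generating
#'   parameters and apparent constants.
#' @examples
#' p <- params_from_apparent(Km_app = 15, Ki = 38, Kip = 44)
#' d <- simulate_rates(p, s = c(5, 10, 20, 50, 100), i = c(0, 20, 40))
#' head(d)
#' @export
simulate_rates <- function(p, s, i, d = 140, noise_cv = 0, seed = NULL) {
  stopifnot(inherits(p, "mechanism_params"))
  if (length(s) == 0L || length(i) == 0L) stop("empty assay design")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (length(d) != 1L) stop("the design uses a single fixed dUMP level")
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(substrate_uM = s, inhibitor_uM = i,
                      KEEP.OUT.ATTRS = FALSE)
  v <- ts_rate(grid$substrate_uM, grid$inhibitor_uM, d, p)
  if (noise_cv > 0)
    v <- v * (1 + stats::rnorm(length(v), sd = noise_cv))
  out <- data.frame(substrate_uM = grid$substrate_uM,
                    inhibitor_uM = grid$inhibitor_uM,
                    dump_uM = d, rate = v)
  attr(out, "truth") <- c(list(params = p, noise_cv = noise_cv,
                               seed = seed),
                          apparent_constants(p, d))
  out
}

validate_rate_table <- function(data) {
  need <- c("substrate_uM", "inhibitor_uM", "dump_uM", "rate")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("rate table is missing column(s): ", paste(miss, collapse = ", "))
  if (length(unique(data$dump_uM)) != 1L)
    stop("all records in a rate dataset must share one dUMP level")
  if (any(data$substrate_uM <= 0))
    stop("substrate concentrations must be positive for reciprocal fits")
  data
}

#' Fit the double-reciprocal (Lineweaver-Burk) inhibition model
#'
#' Per inhibitor level, fits the ordinary least-squares line of `1/v` on
#' `1/s` (primary fits), then regresses the primary slopes and intercepts
#' on inhibitor concentration (secondary fits). For linear mixed-type
#' inhibition the primary slope is `Km_app (1 + i/Ki) / Vmax` and the
#' intercept `(1 + i/Kip) / Vmax`, so the apparent constants follow as
#' the x-axis intercepts of the secondary lines:
#' `Ki_app = intercept/slope` of the slope-vs-i line, and `Kip_app`
#' analogously from the intercept-vs-i line.
#'
#' Classification: the fit is called mixed when the intercept-vs-i slope
#' differs from zero in a two-sided test at level `alpha`. Because the
#' primary fits supply known standard errors for their intercepts, the
#' test statistic is the variance-weighted secondary slope over its
#' propagated standard error (normal reference); an OLS residual t-test
#' over 3-4 inhibitor levels has almost no degrees of freedom and would
#' miss even a doubling of the intercepts. With only two inhibitor
#' levels a relative-change criterion is used instead (intercept change
#' exceeding 5 percent of baseline, flagged low-confidence). Otherwise
#' the inhibition is competitive.
#'
#' @param data a rate table as produced by [simulate_rates()] or read
#'   from a delimited file: columns `substrate_uM`, `inhibitor_uM`,
#'   `dump_uM`, `rate`.
#' @param alpha two-sided significance level for the mixed-vs-competitive
#'   decision.
#' @param weighted if `TRUE`, primary fits are weighted by `v^4`
#'   (inverse-variance weighting of `1/v` under constant-CV noise);
#'   default is the unweighted least-squares line.
#' @return an object of class `"ts_inhibition"` with components
#'   `primary` (per-level slope/intercept table), `secondary` (the two
#'   `lm` fits), `mode` (`"competitive"`, `"mixed"` or
#'   `"no inhibition detected"`), `Ki_app`, `Ki_app_se`, `Kip_app`,
#'   `Kip_app_se`, `d`, `alpha`, `low_confidence`.
#' @examples
#' p <- params_from_apparent(Km_app = 15, Ki = 38, Kip = 44)
#' fit <- fit_inhibition(simulate_rates(p, c(5, 10, 20, 50, 100),
#'                                      c(0, 20, 40)))
#' fit
#' @export
fit_inhibition <- function(data, alpha = 0.05, weighted = FALSE) {
  data <- validate_rate_table(data)
  bad <- data$rate <= 0
  if (any(bad)) {
    warning(sprintf("excluding %d record(s) with non-positive rate",
                    sum(bad)))
    data <- data[!bad, , drop = FALSE]
  }
  levels_i <- sort(unique(data$inhibitor_uM))
  if (length(levels_i) < 2L)
    stop("need at least 2 inhibitor levels")

  primary <- do.call(rbind, lapply(levels_i, function(ii) {
    sub <- data[data$inhibitor_uM == ii, , drop = FALSE]
    if (length(unique(sub$substrate_uM)) < 3L)
      stop(sprintf("inhibitor level %g muM has fewer than 3 substrate levels",
                   ii))
    w <- if (weighted) sub$rate^4 else NULL
    fit <- stats::lm(I(1 / rate) ~ I(1 / substrate_uM), data = sub,
                     weights = w)
    cf <- summary(fit)$coefficients
    data.frame(inhibitor_uM = ii,
               slope = cf[2, 1], slope_se = cf[2, 2],
               intercept = cf[1, 1], intercept_se = cf[1, 2],
               r_squared = summary(fit)$r.squared,
               n = nrow(sub))
  }))

  slope_fit <- stats::lm(slope ~ inhibitor_uM, data = primary)
  int_fit   <- stats::lm(intercept ~ inhibitor_uM, data = primary)

  ratio_with_se <- function(fit) {
    ## x-intercept magnitude a/b of line a + b i, delta-method SE
    cf <- stats::coef(fit); V <- stats::vcov(fit)
    a <- cf[[1]]; b <- cf[[2]]
    k <- a / b
    se <- abs(k) * sqrt(V[1, 1] / a^2 + V[2, 2] / b^2 -
                        2 * V[1, 2] / (a * b))
    c(value = k, se = se)
  }

  two_levels <- length(levels_i) == 2L

  ## two-sided test of a secondary slope against zero. The primary fits
  ## carry known standard errors, so the default statistic is the
  ## variance-weighted slope over its propagated error (z-test) -- with
  ## only 3-4 inhibitor levels the OLS residual t-test has almost no
  ## residual df and misses even a doubling of the intercepts. Falls
  ## back to the OLS t-test when a primary SE is zero (noise-free data).
  slope_test <- function(y, se) {
    if (any(se <= 0)) {
      fit <- stats::lm(y ~ levels_i)
      cf <- summary(fit)$coefficients
      p <- if (nrow(cf) < 2L || is.na(cf[2, 4])) NA_real_ else cf[2, 4]
      return(list(slope = cf[2, 1], p = p))
    }
    w <- 1 / se^2
    xb <- sum(w * levels_i) / sum(w)
    sxx <- sum(w * (levels_i - xb)^2)
    b <- sum(w * (levels_i - xb) * y) / sxx
    list(slope = b, p = 2 * stats::pnorm(-abs(b) * sqrt(sxx)))
  }

  slope_b <- stats::coef(slope_fit)[[2]]
  int_b   <- stats::coef(int_fit)[[2]]

  ## no inhibition: non-positive, or numerically negligible, dependence
  ## of the primary slopes on inhibitor concentration
  negligible <- slope_b * max(levels_i) <
    1e-9 * abs(stats::coef(slope_fit)[[1]])
  if (slope_b <= 0 || negligible) {
    mode <- "no inhibition detected"
    Ki <- c(value = NA_real_, se = NA_real_)
    Kip <- c(value = NA_real_, se = NA_real_)
    low_conf <- FALSE
  } else {
    Ki <- ratio_with_se(slope_fit)
    if (two_levels) {
      base <- primary$intercept[primary$inhibitor_uM == levels_i[1]]
      rel <- abs(diff(primary$intercept)) / abs(base)
      mixed <- rel > 0.05
      low_conf <- TRUE
    } else {
      tst <- slope_test(primary$intercept, primary$intercept_se)
      ## statistical and practical significance: the implied intercept
      ## change across the design must exceed numerical noise
      practical <- tst$slope * max(levels_i) >
        1e-6 * abs(primary$intercept[1])
      mixed <- is.finite(tst$p) && tst$p < alpha && tst$slope > 0 &&
        practical
      low_conf <- FALSE
    }
    if (mixed) {
      mode <- "mixed"
      Kip <- ratio_with_se(int_fit)
    } else {
      mode <- "competitive"
      Kip <- c(value = NA_real_, se = NA_real_)
    }
  }

  structure(list(primary = primary,
                 secondary = list(slope = slope_fit, intercept = int_fit),
                 mode = mode,
                 Ki_app = Ki[["value"]], Ki_app_se = Ki[["se"]],
                 Kip_app = Kip[["value"]], Kip_app_se = Kip[["se"]],
                 d = data$dump_uM[1], alpha = alpha,
                 low_confidence = low_conf,
                 data = data),
            class = "ts_inhibition")
}

#' @export
print.ts_inhibition <- function(x, ...) {
  cat("Double-reciprocal inhibition analysis\n")
  cat(sprintf("  dUMP = %g muM, %d inhibitor levels, %d rates\n",
              x$d, nrow(x$primary), nrow(x$data)))
  cat(sprintf("  mode: %s%s\n", x$mode,
              if (x$low_confidence) " (low confidence: 2 levels)" else ""))
  if (is.finite(x$Ki_app))
    cat(sprintf("  Ki_app  = %.4g +/- %.2g muM\n", x$Ki_app, x$Ki_app_se))
  if (is.finite(x$Kip_app))
    cat(sprintf("  Ki'_app = %.4g +/- %.2g muM\n", x$Kip_app, x$Kip_app_se))
  invisible(x)
}

#' @export
summary.ts_inhibition <- function(object, ...) {
  structure(list(fit = object,
                 primary = object$primary,
                 secondary_slope = summary(object$secondary$slope),
                 secondary_intercept = summary(object$secondary$intercept)),
            class = "summary.ts_inhibition")
}

#' @export
print.summary.ts_inhibition <- function(x, ...) {
  print(x$fit)
  cat("\nPrimary fits (1/v vs 1/s):\n")
  print(x$primary, row.names = FALSE)
  cat("\nSecondary fit, slope ~ i:\n")
  print(x$secondary_slope$coefficients)
  cat("\nSecondary fit, intercept ~ i:\n")
  print(x$secondary_intercept$coefficients)
  invisible(x)
}

#' @export
coef.ts_inhibition <- function(object, ...) {
  c(Ki_app = object$Ki_app, Ki_app_se = object$Ki_app_se,
    Kip_app = object$Kip_app, Kip_app_se = object$Kip_app_se)
}

#' @export
predict.ts_inhibition <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  ## reconstruct 1/v from the per-level primary lines
  pr <- object$primary
  idx <- match(newdata$inhibitor_uM, pr$inhibitor_uM)
  if (anyNA(idx))
    stop("newdata contains inhibitor levels not present in the fit")
  inv <- pr$intercept[idx] + pr$slope[idx] / newdata$substrate_uM
  1 / inv
}

#' @export
residuals.ts_inhibition <- function(object, ...) {
  object$data$rate - predict(object)
}

#' Double-reciprocal plot of a fitted inhibition model
#'
#' Plots `1/v` against `1/s` with one least-squares line per inhibitor
#' level -- the standard Lineweaver-Burk display in which competitive
#' inhibition shows common intercepts and mixed inhibition does not.
#'
#' @param x a `"ts_inhibition"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ts_inhibition <- function(x, ...) {
  d <- x$data
  cols <- seq_len(nrow(x$primary))
  lev <- x$primary$inhibitor_uM
  graphics::plot(1 / d$substrate_uM, 1 / d$rate,
                 col = cols[match(d$inhibitor_uM, lev)],
                 xlab = "1/[s] (1/muM)", ylab = "1/v",
                 main = "Double-reciprocal plot", ...)
  for (k in seq_along(lev))
    graphics::abline(x$primary$intercept[k], x$primary$slope[k],
                     col = cols[k])
  graphics::legend("topleft", legend = sprintf("[i] = %g muM", lev),
                   col = cols, lty = 1, bty = "n")
  invisible(x)
}
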