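#' Simulate a first-order concentration decay series
#'
#' Generates `C(t) = C0 exp(-k t)` at the given timepoints, optionally
#' with multiplicative log-normal noise of a given coefficient of
#' variation (mean-corrected so the expected concentration equals the
#' noise-free curve). The biostability assays sample at 20, 40, 60, 120
#' and 240 minutes after administration.
#'
#' @param C0 initial concentration, muM.
#' @param k first-order rate constant, 1/min.
#' @param times sampling times, minutes.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param n_replicates number of replicate series.
#' @param seed optional integer seed.
#' @return data.frame with columns `time_min`, `concentration_uM`,
#'   `replicate`; attribute `"truth"` carries `C0` and `k`.
#' @examples
#' simulate_decay(18.5, 3.5e-3, c(20, 40, 60, 120, 240))
#' @export
simulate_decay <- function(C0, k, times, noise_cv = 0, n_replicates = 1,
                           seed = NULL) {
  if (length(times) == 0L) stop("empty time vector")
  stopifnot(C0 > 0, k >= 0, noise_cv >= 0, n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    conc <- C0 * exp(-k * times)
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      conc <- conc * exp(stats::rnorm(length(times), -sdlog^2 / 2, sdlog))
    }
    data.frame(time_min = times, concentration_uM = conc, replicate = r)
  }))
  attr(out, "truth") <- list(C0 = C0, k = k, noise_cv = noise_cv)
  out
}

#' Fit first-order degradation kinetics
#'
#' Log-linear ordinary least squares of `ln C` on time: for first-order
#' decay `ln C(t) = ln C0 - k t`, so `k` is minus the slope and the
#' half-life is `t_half = ln(2)/k`. Replicates are pooled into a single
#' fit by default (`per_replicate = TRUE` fits each series separately
#' and returns a list of fits). A direct nonlinear exponential fit
#' (`method = "nls"`, via [stats::nls()]) is available; the log-linear
#' route is the default because the assay-scale data are few points with
#' roughly constant relative error.
#'
#' @param series data.frame with columns `time_min`, `concentration_uM`
#'   and optionally `replicate` (as from [simulate_decay()]).
#' @param method `"loglinear"` (default) or `"nls"`.
#' @param per_replicate fit each replicate separately?
#' @return an object of class `"decay_fit"`: `k` (1/min), `k_se`, `C0`,
#'   `t_half` (min), `r_squared`, `n`, and the underlying `lm`/`nls`
#'   fit. A non-decaying series yields `k = 0` (or slightly negative
#'   slope magnitudes reported as-is) with `t_half = Inf`.
#' @examples
#' s <- simulate_decay(18.5, 3.5e-3, c(20, 40, 60, 120, 240))
#' fit_decay(s)
#' @export
fit_decay <- function(series, method = c("loglinear", "nls"),
                      per_replicate = FALSE) {
  method <- match.arg(method)
  need <- c("time_min", "concentration_uM")
  miss <- setdiff(need, names(series))
  if (length(miss))
    stop("decay series is missing column(s): ", paste(miss, collapse = ", "))
  if (per_replicate && "replicate" %in% names(series)) {
    fits <- lapply(split(series, series$replicate), fit_decay,
                   method = method)
    return(fits)
  }
  bad <- series$concentration_uM <= 0
  if (any(bad)) {
    warning(sprintf("excluding %d non-positive concentration(s)", sum(bad)))
    series <- series[!bad, , drop = FALSE]
  }
  if (nrow(series) < 3L)
    stop("need at least 3 positive-concentration timepoints")
  loglin <- stats::lm(log(concentration_uM) ~ time_min, data = series)
  if (method == "loglinear") {
    fit <- loglin
    cf <- summary(fit)$coefficients
    k <- -cf[2, 1]; k_se <- cf[2, 2]
    C0 <- exp(cf[1, 1])
    r2 <- summary(fit)$r.squared
  } else {
    start <- list(C0 = exp(stats::coef(loglin)[[1]]),
                  k = max(-stats::coef(loglin)[[2]], 1e-6))
    fit <- stats::nls(concentration_uM ~ C0 * exp(-k * time_min),
                      data = series, start = start,
                      control = stats::nls.control(maxiter = 200))
    cf <- summary(fit)$coefficients
    C0 <- cf["C0", 1]; k <- cf["k", 1]; k_se <- cf["k", 2]
    res <- stats::resid(fit)
    r2 <- 1 - sum(res^2) /
      sum((series$concentration_uM - mean(series$concentration_uM))^2)
  }
  if (abs(k) < 1e-12) k <- 0    # numerically flat series
  structure(list(k = k, k_se = k_se, C0 = C0,
                 t_half = if (k > 0) log(2) / k else Inf,
                 r_squared = r2, n = nrow(series),
                 method = method, fit = fit, data = series),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("First-order decay fit (", x$method, ", n = ", x$n, ")\n", sep = "")
  cat(sprintf("  k      = %.4g +/- %.2g per min\n", x$k, x$k_se))
  cat(sprintf("  t_half = %.4g min\n", x$t_half))
  cat(sprintf("  C0     = %.4g muM,  R^2 = %.4f\n", x$C0, x$r_squared))
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying fit:\n")
  print(summary(object$fit))
  invisible(object)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(k = object$k, k_se = object$k_se, C0 = object$C0,
    t_half = object$t_half)
}

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_min else newdata$time_min
  object$C0 * exp(-object$k * t)
}

#' @export
residuals.decay_fit <- function(object, ...) {
  object$data$concentration_uM - predict(object)
}

#' @export
plot.decay_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$time_min, d$concentration_uM, log = "y",
                 xlab = "time (min)", ylab = "concentration (muM)",
                 main = sprintf("First-order decay: t1/2 = %.3g min",
                                x$t_half), ...)
  tt <- seq(min(d$time_min), max(d$time_min), length.out = 100)
  graphics::lines(tt, x$C0 * exp(-x$k * tt))
  invisible(x)
}
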