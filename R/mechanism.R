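#' Microscopic equilibrium constants for the hTS inhibition mechanism
#'
#' Constructs and validates the parameter set of the coupled-equilibrium
#' model of human thymidylate synthase (hTS) inhibition by difunctional
#' folate-peptide inhibitors. The enzyme is a homodimer that equilibrates
#' between an inactive conformation (`II`) and the active dimer-dUMP
#' complex (`AA`); the inhibitor can bind the monomer-monomer interface of
#' the inactive dimer (`IiI`), the catalytic pocket of the dUMP-occupied
#' monomer (`AAi`), or the other monomer's pocket (`iAA`), and the folate
#' substrate can still bind the latter complex to give a non-productive
#' ternary species (`iAAs`).
#'
#' The six equilibria, written with dissociation-style constants in
#' micromolar so that larger values mean weaker binding:
#'
#' 1. `II + d = AA`, `K1 = [II][d]/[AA]` (dUMP-linked inactive/active
#'    coupling; at fixed dUMP `[II]/[AA] = K1/d`)
#' 2. `II + i = IiI`, `K2` (interface binding of the peptidic moiety)
#' 3. `AA + i = AAi`, `K3` (catalytic pocket of the dUMP-bound monomer)
#' 4. `AA + i = iAA`, `K4` (catalytic pocket of the other monomer)
#' 5. `AA + s = AAs`, `K5` (productive substrate binding; half-saturation
#'    of the productive step, so `Ks` is accepted as an alias)
#' 6. `iAA + s = iAAs`, `K6` (substrate binding to the inhibited complex)
#'
#' Only the ratio `K4*K6/K5` is identifiable from steady-state rate data
#' (it is the apparent uncompetitive constant Ki'); `K6 = Inf` expresses
#' the purely competitive limit in which `iAAs` never forms.
#'
#' @param K1,K2,K3,K4,K5,K6 equilibrium constants, micromolar (muM);
#'   strictly positive, `K6` may be `Inf`.
#' @param Vmax maximal initial rate at saturating substrate and zero
#'   inhibitor, in the rate units of the assay.
#' @param Ks alias for `K5` (productive-step half-saturation); supply one
#'   of `K5`/`Ks`, or both if equal.
#' @return an object of class `"mechanism_params"` (a named list).
#' @seealso [ts_rate()], [apparent_constants()], [species_balance()]
#' @examples
#' p <- mechanism_params(K1 = 140 / 15, K2 = 6, K3 = 260, K4 = 260,
#'                       K5 = 14, K6 = 2.4, Vmax = 1)
#' p
#' @export
mechanism_params <- function(K1, K2, K3, K4, K5 = NULL, K6 = Inf, Vmax = 1,
                             Ks = NULL) {
  if (is.null(K5) && is.null(Ks))
    stop("supply the productive substrate constant as `K5` (or `Ks`)")
  if (is.null(K5)) K5 <- Ks
  if (!is.null(Ks) && !isTRUE(all.equal(Ks, K5)))
    stop("`Ks` is an alias for `K5`; the two values differ")
  p <- list(K1 = K1, K2 = K2, K3 = K3, K4 = K4, K5 = K5, K6 = K6,
            Vmax = Vmax)
  for (nm in names(p)) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
      stop(sprintf("`%s` must be a single strictly positive number", nm))
  }
  finite <- setdiff(names(p), "K6")
  if (any(!is.finite(unlist(p[finite]))))
    stop("all constants except `K6` must be finite")
  structure(p, class = "mechanism_params")
}

#' @export
print.mechanism_params <- function(x, ...) {
  cat("hTS coupled-equilibrium mechanism parameters (muM):\n")
  cat(sprintf("  K1 = %g  K2 = %g  K3 = %g  K4 = %g  K5 = %g  K6 = %g\n",
              x$K1, x$K2, x$K3, x$K4, x$K5, x$K6))
  cat(sprintf("  Vmax = %g\n", x$Vmax))
  invisible(x)
}

#' Apparent inhibition constants implied by the microscopic mechanism
#'
#' Collapses the six-equilibrium scheme to the linear mixed-inhibition
#' form `v = Vmax s / (Km_app (1 + i/Ki) + s (1 + i/Kip))` at dUMP
#' concentration `d`. Exactly:
#' `Km_app = K5 (1 + K1/d)`,
#' `1/Ki = (1/K3 + 1/K4 + K1/(d K2)) / (1 + K1/d)`,
#' `Kip = K4 K6 / K5`.
#' For `d >> K1` (the assay regime, `d/K1` about 15) the slope constant
#' reduces to the composite relation `1/Ki = 1/K3 + 1/K4 + K1/(d K2)` used
#' by [infer_micro_constants()].
#'
#' @param p a [mechanism_params()] object.
#' @param d dUMP concentration, muM.
#' @return named list with `Km_app`, `Ki`, `Kip` (muM; `Kip = Inf` in the
#'   competitive limit) and `Vmax`.
#' @export
apparent_constants <- function(p, d) {
  stopifnot(inherits(p, "mechanism_params"), is.numeric(d), d > 0)
  A <- 1 + p$K1 / d
  B <- 1 / p$K3 + 1 / p$K4 + p$K1 / (d * p$K2)
  list(Km_app = p$K5 * A,
       Ki     = A / B,
       Kip    = if (is.finite(p$K6)) p$K4 * p$K6 / p$K5 else Inf,
       Vmax   = p$Vmax)
}

#' Build a mechanism realizing prescribed apparent constants
#'
#' Convenience inverse of [apparent_constants()]: returns a
#' [mechanism_params()] object whose apparent Michaelis constant, slope
#' inhibition constant and intercept inhibition constant at dUMP
#' concentration `d` are exactly the requested values. The interface
#' equilibrium is made negligible (`K2` huge) and `K3 = K4`, so the choice
#' is one of the many micro-parameterizations consistent with the same
#' apparent behaviour -- sufficient for simulation and roundtrip testing.
#'
#' @param Km_app apparent Michaelis constant of the substrate, muM.
#' @param Ki apparent (slope-derived) inhibition constant, muM.
#' @param Kip apparent (intercept-derived) inhibition constant, muM;
#'   `Inf` gives purely competitive behaviour.
#' @param Vmax maximal rate.
#' @param d dUMP concentration, muM.
#' @param d_over_K1 ratio of dUMP concentration to the coupling constant
#'   `K1`; the assays run near 15.
#' @return a [mechanism_params()] object.
#' @export
params_from_apparent <- function(Km_app, Ki, Kip = Inf, Vmax = 1,
                                 d = 140, d_over_K1 = 15) {
  stopifnot(Km_app > 0, Ki > 0, Kip > 0, Vmax > 0, d > 0, d_over_K1 > 0)
  A  <- 1 + 1 / d_over_K1
  K1 <- d / d_over_K1
  K2 <- 1e12                       # interface path switched off
  K3 <- K4 <- 2 * Ki / (A - Ki * K1 / (d * K2))
  K5 <- Km_app / A
  K6 <- if (is.finite(Kip)) Kip * K5 / K4 else Inf
  mechanism_params(K1 = K1, K2 = K2, K3 = K3, K4 = K4, K5 = K5, K6 = K6,
                   Vmax = Vmax)
}

#' Closed-form initial rate of the inhibited hTS reaction
#'
#' Evaluates the steady-state initial rate of the coupled-equilibrium
#' mechanism in the fast-equilibration, tracer-enzyme limit. Derived by
#' expressing every species relative to the active complex `AA`:
#'
#' `v = Vmax (s/K5) / [(1 + K1/d) + i (1/K3 + 1/K4 + K1/(d K2)) +
#'  (s/K5) (1 + i K5/(K4 K6))]`
#'
#' which is the linear mixed-inhibition form (see
#' [apparent_constants()]); at `i = 0` it reduces to the
#' Michaelis-Menten law `v = Vmax s / (Km_app + s)`, and for `K6 = Inf`
#' the maximal rate is independent of inhibitor (competitive limit,
#' common intercepts in double-reciprocal plots).
#'
#' @param s substrate (mTHF) concentration, muM; vectorized.
#' @param i inhibitor concentration, muM; vectorized.
#' @param d dUMP concentration, muM.
#' @param p a [mechanism_params()] object.
#' @return initial rate(s), same units as `Vmax`.
#' @examples
#' p <- params_from_apparent(Km_app = 15, Ki = 90)
#' ts_rate(s = c(5, 20, 100), i = 0, d = 140, p)
#' @export
ts_rate <- function(s, i, d, p) {
  stopifnot(inherits(p, "mechanism_params"))
  if (any(s < 0) || any(i < 0) || any(d <= 0))
    stop("require s >= 0, i >= 0, d > 0")
  A  <- 1 + p$K1 / d
  B  <- 1 / p$K3 + 1 / p$K4 + p$K1 / (d * p$K2)
  su <- s / p$K5
  unc <- if (is.finite(p$K6)) p$K5 / (p$K4 * p$K6) else 0
  p$Vmax * su / (A + i * B + su * (1 + i * unc))
}

#' Numerical species-balance solution of the full mechanism
#'
#' Independent check of the closed form [ts_rate()]: solves the general
#' mass balance of the six equilibria for a finite total enzyme
#' concentration, conserving enzyme, inhibitor and substrate (dUMP is
#' treated as a buffered free concentration, matching the assay where
#' dUMP is in vast excess over enzyme). No tracer-enzyme assumption is
#' made; in the limit `E0 -> 0` the returned rate converges to
#' [ts_rate()].
#'
#' The two free-ligand unknowns are found by a damped Newton iteration in
#' log space; convergence requires relative residuals below `tol`.
#'
#' @param s,i,d total substrate, total inhibitor and (free) dUMP
#'   concentrations, muM.
#' @param p a [mechanism_params()] object.
#' @param E0 total enzyme (dimer) concentration, muM.
#' @param tol relative residual tolerance for the conservation equations.
#' @param maxit maximum Newton iterations.
#' @return list with `species` (named fractional abundances of `II`,
#'   `AA`, `AAs`, `IiI`, `AAi`, `iAA`, `iAAs`, summing to 1), `rate`,
#'   `free` (free `s` and `i`) and `residual`.
#' @export
species_balance <- function(s, i, d, p, E0 = 1e-6, tol = 1e-10,
                            maxit = 200L) {
  stopifnot(inherits(p, "mechanism_params"),
            length(s) == 1L, length(i) == 1L, length(d) == 1L,
            s >= 0, i >= 0, d > 0, E0 > 0)

  ## species concentrations relative to [AA], at free ligand (sf, if)
  coefs <- function(sf, if_) {
    k6 <- if (is.finite(p$K6)) p$K6 else Inf
    c(II   = p$K1 / d,
      AA   = 1,
      AAs  = sf / p$K5,
      IiI  = (p$K1 / d) * if_ / p$K2,
      AAi  = if_ / p$K3,
      iAA  = if_ / p$K4,
      iAAs = if (is.finite(k6)) if_ * sf / (p$K4 * k6) else 0)
  }
  balance <- function(sf, if_) {
    cf <- coefs(sf, if_)
    AA <- E0 / sum(cf)
    sp <- cf * AA
    c(s_res = sf + sp[["AAs"]] + sp[["iAAs"]] - s,
      i_res = if_ + sp[["IiI"]] + sp[["AAi"]] + sp[["iAA"]] +
              sp[["iAAs"]] - i)
  }

  ## trivial axes: no substrate and/or no inhibitor need no iteration
  sf <- if (s > 0) min(s, s / (1 + E0 / p$K5)) else 0
  if_ <- if (i > 0) i else 0
  if (s > 0 || i > 0) {
    x <- log(pmax(c(sf, if_), 1e-300))
    active <- c(s > 0, i > 0)
    scale <- pmax(c(s, i), 1)
    for (it in seq_len(maxit)) {
      r <- balance(exp(x)[1], exp(x)[2])
      if (max(abs(r) / scale) < tol) break
      ## numerical Jacobian wrt active log-unknowns
      J <- matrix(0, 2, 2)
      h <- 1e-7
      for (j in 1:2) {
        if (!active[j]) { J[j, j] <- 1; next }
        xp <- x; xp[j] <- xp[j] + h
        J[, j] <- (balance(exp(xp)[1], exp(xp)[2]) - r) / h
      }
      step <- tryCatch(solve(J, r), error = function(e) r / diag(J))
      step[!active] <- 0
      step <- pmin(pmax(step, -2), 2)   # damp in log space
      x <- x - step
      if (it == maxit)
        stop(sprintf(
          "species balance did not converge: residuals %.3g, %.3g",
          r[1], r[2]))
    }
    sf <- exp(x)[1] * (s > 0)
    if_ <- exp(x)[2] * (i > 0)
  }

  cf <- coefs(sf, if_)
  frac <- cf / sum(cf)
  res <- balance(sf, if_)
  list(species  = frac,
       rate     = p$Vmax * frac[["AAs"]],
       free     = c(s = sf, i = if_),
       residual = max(abs(res) / pmax(c(s, i), 1)))
}
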