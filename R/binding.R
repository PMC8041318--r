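#' Equilibrium bound-tracer fraction in a two-ligand competition
#'
#' Solves the full mass balance of one receptor with a labelled tracer
#' and an unlabelled competitor (`R + T = RT`, `R + C = RC`) with ligand
#' depletion: the free-receptor concentration is the root of
#' `R0 = r (1 + T0/(KdT + r) + C0/(KdC + r))`, bracketed on `(0, R0)`
#' and found with [stats::uniroot()]. In the tracer limit (receptor and
#' tracer well below every Kd) the bound-tracer fraction relative to the
#' competitor-free system reduces to `1 / (1 + C0/KdC)`.
#'
#' @param Kd_tracer,Kd_competitor dissociation constants, any common
#'   concentration unit.
#' @param tracer_conc,competitor_conc,receptor_total total concentrations
#'   in the same unit.
#' @param tol relative tolerance of the root find.
#' @return list with `bound_fraction` (fraction of tracer bound),
#'   `displacement` (fractional loss of tracer binding relative to the
#'   competitor-free system) and `free_receptor`.
#' @examples
#' bound_tracer_fraction(Kd_tracer = 1, Kd_competitor = 10,
#'                       tracer_conc = 1e-4, competitor_conc = 40,
#'                       receptor_total = 1e-4)$displacement  # ~0.8
#' @export
bound_tracer_fraction <- function(Kd_tracer, Kd_competitor, tracer_conc,
                                  competitor_conc, receptor_total,
                                  tol = 1e-12) {
  stopifnot(Kd_tracer > 0, Kd_competitor > 0, tracer_conc > 0,
            competitor_conc >= 0, receptor_total > 0)
  free_receptor <- function(C0) {
    f <- function(r)
      r * (1 + tracer_conc / (Kd_tracer + r) +
             C0 / (Kd_competitor + r)) - receptor_total
    stats::uniroot(f, c(receptor_total * 1e-16, receptor_total),
                   tol = receptor_total * tol)$root
  }
  r  <- free_receptor(competitor_conc)
  r0 <- free_receptor(0)
  fb  <- r / (Kd_tracer + r)     # fraction of tracer bound
  fb0 <- r0 / (Kd_tracer + r0)
  list(bound_fraction = fb,
       displacement = 1 - fb / fb0,
       free_receptor = r)
}

#' Ratio of competitor binding constants from paired displacements
#'
#' Two competitors at the same concentration displace fractions `fa` and
#' `fb` of a surface-bound tracer. In the tracer limit each displacement
#' satisfies `f/(1-f) = C0/Kd`, so the ratio of association constants
#' (inverse Kd ratio) is the odds ratio
#' `[fa/(1-fa)] / [fb/(1-fb)]`. When receptor and tracer concentrations
#' are supplied, the full mass-balance model is inverted numerically for
#' each competitor's Kd instead.
#'
#' @param fa,fb displaced fractions in (0, 1).
#' @param competitor_conc competitor concentration (same for both), any
#'   unit; required only for the full route.
#' @param receptor_total,tracer_conc,Kd_tracer optional concentrations
#'   enabling the full mass-balance inversion.
#' @return list with `ratio` (binding-constant ratio, competitor a over
#'   competitor b) and `route` (`"tracer-limit"` or `"mass-balance"`).
#' @examples
#' infer_K_ratio(0.80, 0.40)   # odds ratio 6
#' @export
infer_K_ratio <- function(fa, fb, competitor_conc = NULL,
                          receptor_total = NULL, tracer_conc = NULL,
                          Kd_tracer = NULL) {
  stopifnot(fa > 0, fb > 0)
  if (fa >= 1 || fb >= 1)
    stop("displacement of 1 implies an unbounded binding-constant ratio")
  full <- !is.null(receptor_total) && !is.null(tracer_conc) &&
    !is.null(Kd_tracer) && !is.null(competitor_conc)
  if (!full) {
    ratio <- (fa / (1 - fa)) / (fb / (1 - fb))
    return(list(ratio = ratio, route = "tracer-limit"))
  }
  solve_Kd <- function(f) {
    g <- function(logKd)
      bound_tracer_fraction(Kd_tracer, exp(logKd), tracer_conc,
                            competitor_conc, receptor_total)$displacement - f
    exp(stats::uniroot(g, log(competitor_conc) + c(-25, 25),
                       tol = 1e-12)$root)
  }
  list(ratio = solve_Kd(fb) / solve_Kd(fa), route = "mass-balance")
}

#' Free-energy difference from a binding-constant ratio
#'
#' `ddG = R T ln(ratio)` with the gas constant
#' `R = 8.314 J / (mol K)`; a ratio of 5 at 298.15 K gives about
#' 4 kJ/mol.
#'
#' @param ratio ratio of binding equilibrium constants (> 0).
#' @param temperature_K absolute temperature, K.
#' @return free-energy difference, kJ/mol.
#' @examples
#' delta_G_from_ratio(5)        # ~3.99 kJ/mol
#' delta_G_from_ratio(1)        # 0
#' @export
delta_G_from_ratio <- function(ratio, temperature_K = 298.15) {
  if (any(ratio <= 0)) stop("ratio must be positive")
  stopifnot(temperature_K > 0)
  8.314 * temperature_K * log(ratio) / 1000
}
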