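#' Subcellular compartment geometry
#'
#' Geometry of a lysed-cell fractionation experiment: number of cells,
#' mean single-cell volume, and the volume fractions of the cytosol and
#' the endocytic vesicles. Defaults are the values used for IGROV-1
#' ovarian cancer cells: 2 pL per cell, cytosol 60 percent and vesicles
#' 2.5 percent of the cellular volume.
#'
#' @param n_cells number of lysed cells.
#' @param cell_volume mean single-cell volume, litres.
#' @param cytosol_fraction,vesicle_fraction volume fractions in (0, 1),
#'   summing to less than 1.
#' @param external_volume extracellular medium volume, litres.
#' @return object of class `"compartment_geometry"`.
#' @examples
#' compartment_geometry(n_cells = 2e6)
#' @export
compartment_geometry <- function(n_cells, cell_volume = 2e-12,
                                 cytosol_fraction = 0.60,
                                 vesicle_fraction = 0.025,
                                 external_volume = 3e-3) {
  stopifnot(n_cells >= 1, cell_volume > 0, external_volume > 0,
            cytosol_fraction > 0, cytosol_fraction < 1,
            vesicle_fraction > 0, vesicle_fraction < 1)
  if (cytosol_fraction + vesicle_fraction >= 1)
    stop("cytosol and vesicle fractions must sum to less than 1")
  structure(list(n_cells = n_cells, cell_volume = cell_volume,
                 cytosol_fraction = cytosol_fraction,
                 vesicle_fraction = vesicle_fraction,
                 external_volume = external_volume),
            class = "compartment_geometry")
}

#' @export
print.compartment_geometry <- function(x, ...) {
  cat(sprintf(
    "Compartment geometry: %.3g cells x %.3g L (cytosol %g%%, vesicles %g%%)\n",
    x$n_cells, x$cell_volume, 100 * x$cytosol_fraction,
    100 * x$vesicle_fraction))
  cat(sprintf("  extracellular volume %.3g L\n", x$external_volume))
  invisible(x)
}

#' Total volume of a subcellular compartment
#'
#' @param geom a [compartment_geometry()] object.
#' @param fraction one of `"extracellular"`, `"cytosolic"`, `"vesicles"`.
#' @return volume in litres.
#' @examples
#' g <- compartment_geometry(2e6)
#' compartment_volume(g, "cytosolic")   # 2.4e-6 L
#' compartment_volume(g, "vesicles")    # 1.0e-7 L
#' @export
compartment_volume <- function(geom, fraction) {
  stopifnot(inherits(geom, "compartment_geometry"))
  fraction <- match.arg(fraction,
                        c("extracellular", "cytosolic", "vesicles"))
  switch(fraction,
         extracellular = geom$external_volume,
         cytosolic = geom$n_cells * geom$cell_volume * geom$cytosol_fraction,
         vesicles  = geom$n_cells * geom$cell_volume * geom$vesicle_fraction)
}

## monoisotopic proton mass, Da
PROTON_DA <- 1.00728

#' Neutral mass from a multiply protonated m/z
#'
#' For a peptide observed as `[M + zH]^z+`, `M = z (m/z - m_H)`.
#'
#' @param mz observed mass-to-charge ratio, Th.
#' @param z positive integer charge state.
#' @param proton_mass proton mass in Da (monoisotopic by default;
#'   override for average-mass workflows).
#' @return neutral mass, Da.
#' @examples
#' neutral_mass_from_mz(478.5515, 3)   # 1432.63 Da
#' @export
neutral_mass_from_mz <- function(mz, z, proton_mass = PROTON_DA) {
  if (any(z < 1) || any(z != round(z))) stop("z must be a positive integer")
  if (any(mz <= proton_mass)) stop("m/z must exceed the proton mass")
  z * (mz - proton_mass)
}

#' Predicted m/z of a neutral mass at a given charge state
#'
#' Inverse of [neutral_mass_from_mz()]: `(M + z m_H) / z`.
#'
#' @param M neutral mass, Da.
#' @param z positive integer charge state.
#' @param proton_mass proton mass, Da.
#' @return m/z, Th.
#' @examples
#' predict_mz(neutral_mass_from_mz(478.5, 3), 2)   # ~717.25
#' @export
predict_mz <- function(M, z, proton_mass = PROTON_DA) {
  if (any(z < 1) || any(z != round(z))) stop("z must be a positive integer")
  if (any(M <= 0)) stop("neutral mass must be positive")
  (M + z * proton_mass) / z
}

#' Conjugate identity: neutral mass with consistent charge states
#'
#' @param neutral_mass neutral monoisotopic mass, Da; may be omitted if
#'   `charge_states` is given (it is then derived from the first state).
#' @param charge_states optional data.frame with columns `z` and `mz`;
#'   every state must be consistent with the neutral mass within `tol`.
#' @param tol consistency tolerance, Da.
#' @return object of class `"conjugate_identity"`.
#' @examples
#' conjugate_identity(charge_states = data.frame(z = 3, mz = 478.5515))
#' @export
conjugate_identity <- function(neutral_mass = NULL, charge_states = NULL,
                               tol = 0.05) {
  if (is.null(neutral_mass)) {
    if (is.null(charge_states) || nrow(charge_states) == 0L)
      stop("supply neutral_mass or at least one charge state")
    neutral_mass <- neutral_mass_from_mz(charge_states$mz[1],
                                         charge_states$z[1])
  }
  if (!is.null(charge_states)) {
    M <- neutral_mass_from_mz(charge_states$mz, charge_states$z)
    off <- abs(M - neutral_mass)
    if (any(off > tol))
      stop(sprintf(
        "charge state z=%d (m/z %.4f) implies M = %.4f Da, %.3f Da from %.4f",
        charge_states$z[which.max(off)], charge_states$mz[which.max(off)],
        M[which.max(off)], max(off), neutral_mass))
  }
  structure(list(neutral_mass = neutral_mass,
                 charge_states = charge_states),
            class = "conjugate_identity")
}

#' @export
print.conjugate_identity <- function(x, ...) {
  cat(sprintf("Conjugate: neutral mass %.4f Da\n", x$neutral_mass))
  if (!is.null(x$charge_states))
    for (k in seq_len(nrow(x$charge_states)))
      cat(sprintf("  [M+%dH]%d+  m/z %.4f\n", x$charge_states$z[k],
                  x$charge_states$z[k], x$charge_states$mz[k]))
  invisible(x)
}

#' Molar concentration of a conjugate in one compartment
#'
#' Converts a measured mass (ng) in a fraction into a molar
#' concentration over the compartment volume:
#' `C [muM] = (mass_ng / M_Da) / vol_L * 1e-3`
#' (ng/Da gives nanomoles; nmol/L is nM, so divide by 1000 for muM).
#'
#' @param mass_ng measured conjugate mass in the fraction, ng.
#' @param neutral_mass molar (neutral) mass, Da, or a
#'   [conjugate_identity()] object.
#' @param volume_L compartment volume, litres.
#' @return concentration, muM.
#' @examples
#' g <- compartment_geometry(2e6)
#' fraction_concentration(34.4, 1432.63, compartment_volume(g, "vesicles"))
#' @export
fraction_concentration <- function(mass_ng, neutral_mass, volume_L) {
  if (inherits(neutral_mass, "conjugate_identity"))
    neutral_mass <- neutral_mass$neutral_mass
  stopifnot(neutral_mass > 0)
  if (any(volume_L <= 0)) stop("compartment volume must be positive")
  if (any(mass_ng < 0)) stop("mass must be non-negative")
  (mass_ng * 1e-9 / neutral_mass) / volume_L * 1e6
}

#' Vesicle-to-cytosol concentration ratio from fraction masses
#'
#' The molar-mass and cell-count factors cancel, so the concentration
#' ratio reduces to `(m_ves / m_cyt) * (cytosol_fraction /
#' vesicle_fraction)` -- a mass-independent quantity. With the default
#' geometry (60 percent vs 2.5 percent) the 37 degree fractionation
#' masses 34.4 and 60.2 ng give 13.7.
#'
#' @param m_ves,m_cyt conjugate masses in the vesicular and cytosolic
#'   fractions, ng.
#' @param geom a [compartment_geometry()] object.
#' @return dimensionless concentration ratio.
#' @examples
#' vesicle_cytosol_ratio(34.4, 60.2, compartment_geometry(2e6))  # 13.7
#' @export
vesicle_cytosol_ratio <- function(m_ves, m_cyt, geom) {
  stopifnot(inherits(geom, "compartment_geometry"))
  if (any(m_cyt <= 0)) stop("undefined ratio: cytosolic mass is zero")
  (m_ves / m_cyt) * (geom$cytosol_fraction / geom$vesicle_fraction)
}

#' Cytosolic concentration from fluorometric difference signals
#'
#' The pteroate fluorescence difference between treated and control cell
#' lysates is proportional to the amount of conjugate taken up. With a
#' calibration factor expressed as kcounts per pmol of conjugate in the
#' lysate, the cytosolic concentration over all lysed cells is
#' `C [muM] = (signal_treated - signal_control) / cal / V_cytosol`
#' with the amount in pmol and the pooled cytosolic volume in litres.
#' Negative differences (blank variability) are clamped to zero with a
#' warning.
#'
#' @param treated,control signal intensities, kcounts; scalars or equal
#'   length vectors (e.g. one emission and one excitation channel).
#' @param calibration_factor instrument calibration, kcounts per pmol.
#' @param geom a [compartment_geometry()] object.
#' @return list with `difference_kcounts`, `amount_pmol` and
#'   `concentration_uM` per channel.
#' @examples
#' g <- compartment_geometry(6e6)
#' fluorometric_concentration(c(834, 1120), c(747, 994),
#'                            calibration_factor = 0.598, geom = g)
#' @export
fluorometric_concentration <- function(treated, control, calibration_factor,
                                       geom) {
  if (missing(calibration_factor) || !is.numeric(calibration_factor) ||
      calibration_factor <= 0)
    stop("a positive calibration_factor (kcounts per pmol) is required")
  stopifnot(inherits(geom, "compartment_geometry"),
            all(treated >= 0), all(control >= 0),
            length(treated) == length(control))
  diff <- treated - control
  if (any(diff < 0)) {
    warning("negative treated-control difference clamped to zero")
    diff <- pmax(diff, 0)
  }
  amount_pmol <- diff / calibration_factor
  vol <- compartment_volume(geom, "cytosolic")
  list(difference_kcounts = diff,
       amount_pmol = amount_pmol,
       concentration_uM = amount_pmol * 1e-12 / vol * 1e6)
}

#' Single-cell cytosolic concentration from an interpolated LC-MS value
#'
#' Implements the dilution-based back-calculation: the calibration-curve
#' concentration in the analysed sample is scaled by the final dilution
#' volume and divided by the number of cells times the single-cell
#' cytosol volume:
#' `C_cell = C_sample * V_dilution / (n_cells * v_cytosol)`.
#'
#' @param sample_conc_uM interpolated analyte concentration in the
#'   diluted sample, muM.
#' @param dilution_volume_L final dilution volume, litres (the assays use
#'   500 muL).
#' @param n_cells number of cells in the sample.
#' @param cytosol_volume_per_cell_L single-cell cytosol volume, litres
#'   (1.2 pL: 60 percent of a 2 pL cell).
#' @return single-cell cytosolic concentration, muM.
#' @examples
#' single_cell_concentration(2.4, 500e-6, 1e6, 1.2e-12)  # 1000 muM
#' @export
single_cell_concentration <- function(sample_conc_uM, dilution_volume_L,
                                      n_cells,
                                      cytosol_volume_per_cell_L = 1.2e-12) {
  stopifnot(dilution_volume_L > 0, cytosol_volume_per_cell_L > 0)
  if (any(n_cells <= 0)) stop("n_cells must be positive")
  sample_conc_uM * dilution_volume_L /
    (n_cells * cytosol_volume_per_cell_L)
}
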