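## delimited-table readers with schema validation; comma-separated,
## header required, '.' decimal, UTF-8 -- no locale inference.

read_checked <- function(file, required, what) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s '%s' is missing column(s): %s", what, file,
                 paste(miss, collapse = ", ")))
  df
}

#' Read an initial-rate table
#'
#' Comma-separated with header
#' `substrate_uM,inhibitor_uM,dump_uM,rate`.
#'
#' @param file path to a delimited text file.
#' @return validated data.frame.
#' @export
read_rate_table <- function(file) {
  validate_rate_table(
    read_checked(file, c("substrate_uM", "inhibitor_uM", "dump_uM",
                         "rate"), "rate table"))
}

#' Read a fraction-mass table
#'
#' Header `fraction,mass_ng,temperature_C`.
#'
#' @param file path to a delimited text file.
#' @return validated data.frame.
#' @export
read_fraction_table <- function(file) {
  df <- read_checked(file, c("fraction", "mass_ng", "temperature_C"),
                     "fraction table")
  ok <- c("extracellular", "cytosolic", "vesicles")
  bad <- setdiff(unique(df$fraction), ok)
  if (length(bad))
    stop("unknown fraction label(s): ", paste(bad, collapse = ", "))
  if (any(df$mass_ng < 0)) stop("masses must be non-negative")
  df
}

#' Read a decay series table
#'
#' Header `time_min,concentration_uM,replicate` (replicate optional).
#'
#' @param file path to a delimited text file.
#' @return validated data.frame.
#' @export
read_decay_table <- function(file) {
  read_checked(file, c("time_min", "concentration_uM"), "decay series")
}

#' Read a drug-combination table
#'
#' Header
#' `cell_line,drug_a,dose_a,drug_b,dose_b,inh_a_pct,inh_b_pct,inh_combined_pct`.
#'
#' @param file path to a delimited text file.
#' @return validated data.frame.
#' @export
read_combination_table <- function(file) {
  read_checked(file, c("cell_line", "drug_a", "dose_a", "drug_b",
                       "dose_b", "inh_a_pct", "inh_b_pct",
                       "inh_combined_pct"), "combination table")
}

#' Write an analysis report as JSON
#'
#' Serializes a (possibly nested) list of results with units and
#' provenance fields intact. Unboxed scalars, full precision.
#'
#' @param report named list.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_report <- function(report, file) {
  jsonlite::write_json(report, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(file)
}

#' Run the full analysis pipeline on a bundle of input tables
#'
#' Executes every stage the supplied bundle has inputs for, in
#' dependency order: double-reciprocal inhibition fits (peptide first,
#' whose inferred `K2` feeds the conjugate's microscopic-constant
#' inference), first-order decay, compartment quantification, binding
#' ratio and free-energy difference, and SQ scoring with clustering.
#' Unavailable stages are skipped silently; every numeric result is
#' returned with its units in the report structure.
#'
#' @param bundle named list as produced by [generate_scenario()], or
#'   assembled from the `read_*` functions; recognized elements:
#'   `rates_peptide`, `rates_conjugate`, `decay`, `fractions`,
#'   `binding`, `combinations`.
#' @param geom [compartment_geometry()] for the fraction table.
#' @param conjugate [conjugate_identity()] for concentration conversion.
#' @param d_over_K1 dUMP-to-K1 ratio for constant inference.
#' @param alpha significance level for the inhibition-mode test.
#' @param seed seed recorded in the report.
#' @return nested report list (class `"folatekin_report"`).
#' @examples
#' b <- generate_scenario(scenario_config(seed = 3), noise_free = TRUE)
#' rep <- run_pipeline(b, geom = compartment_geometry(2e6),
#'                     conjugate = conjugate_identity(1432.63))
#' names(rep)
#' @export
run_pipeline <- function(bundle, geom = compartment_geometry(2e6),
                         conjugate = conjugate_identity(1432.63),
                         d_over_K1 = 15, alpha = 0.05, seed = NULL) {
  rep <- list(provenance = list(
    package = "folatekin",
    version = as.character(utils::packageVersion("folatekin")),
    seed = seed))

  K2_ref <- NULL
  if (!is.null(bundle$rates_peptide)) {
    fit <- fit_inhibition(bundle$rates_peptide, alpha = alpha)
    mc <- infer_micro_constants(fit$Ki_app, fit$Ki_app_se,
                                d_over_K1 = d_over_K1)
    K2_ref <- mc$K2_est
    rep$peptide_inhibition <- list(
      mode = fit$mode, Ki_app_uM = fit$Ki_app, Ki_app_se_uM = fit$Ki_app_se,
      K2_est_uM = mc$K2_est,
      primary_fits = fit$primary)
  }
  if (!is.null(bundle$rates_conjugate)) {
    fit <- fit_inhibition(bundle$rates_conjugate, alpha = alpha)
    rep$conjugate_inhibition <- list(
      mode = fit$mode, Ki_app_uM = fit$Ki_app, Ki_app_se_uM = fit$Ki_app_se,
      Kip_app_uM = fit$Kip_app, Kip_app_se_uM = fit$Kip_app_se,
      primary_fits = fit$primary)
    if (!is.null(K2_ref) && is.finite(fit$Ki_app)) {
      mc <- infer_micro_constants(fit$Ki_app, fit$Ki_app_se,
                                  d_over_K1 = d_over_K1, K2_ref = K2_ref)
      rep$conjugate_inhibition$inv34_per_uM <- mc$inv34
      rep$conjugate_inhibition$hmean34_uM <- mc$hmean34
    }
  }
  if (!is.null(bundle$decay)) {
    fit <- fit_decay(bundle$decay)
    rep$decay <- list(k_per_min = fit$k, k_se_per_min = fit$k_se,
                      t_half_min = fit$t_half, C0_uM = fit$C0,
                      r_squared = fit$r_squared)
  }
  if (!is.null(bundle$fractions)) {
    fr <- bundle$fractions
    rep$compartments <- lapply(split(fr, fr$temperature_C), function(x) {
      conc <- vapply(seq_len(nrow(x)), function(j)
        fraction_concentration(x$mass_ng[j], conjugate,
                               compartment_volume(geom, x$fraction[j])),
        numeric(1))
      out <- list(concentrations_uM = stats::setNames(conc, x$fraction))
      if (all(c("vesicles", "cytosolic") %in% x$fraction))
        out$vesicle_cytosol_ratio <- vesicle_cytosol_ratio(
          x$mass_ng[x$fraction == "vesicles"],
          x$mass_ng[x$fraction == "cytosolic"], geom)
      out
    })
  }
  if (!is.null(bundle$binding)) {
    b <- bundle$binding
    r <- infer_K_ratio(b$displacement_fraction[1],
                       b$displacement_fraction[2])
    rep$binding <- list(ratio = r$ratio, route = r$route,
                        ddG_kJ_mol = delta_G_from_ratio(r$ratio))
  }
  if (!is.null(bundle$combinations)) {
    tab <- bundle$combinations
    sq <- synergism_quotient(tab$inh_a_pct, tab$inh_b_pct,
                             tab$inh_combined_pct)
    m <- sq_matrix(tab)
    rep$synergy <- list(sq = sq, class = classify_sq(sq))
    if (!anyNA(m) && nrow(m) >= 2) {
      cl <- cluster_sq(m)
      rep$synergy$leaf_order <- cl$order
      rep$synergy$newick <- sq_newick(cl)
    }
  }
  structure(rep, class = c("folatekin_report", "list"))
}

#' @export
print.folatekin_report <- function(x, ...) {
  cat("folatekin pipeline report -- stages:",
      paste(setdiff(names(x), "provenance"), collapse = ", "), "\n")
  invisible(x)
}
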