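#' Synergism quotient of a drug combination
#'
#' The synergism quotient (SQ) is the net growth-inhibitory effect of a
#' combination divided by the sum of the net single-agent effects:
#' `SQ = inhibition_combined / (inhibition_a + inhibition_b)`. Scale
#' invariant: multiplying all three inhibitions by a positive constant
#' leaves SQ unchanged.
#'
#' @param inhibition_a,inhibition_b single-agent growth inhibition,
#'   percent in \[0, 100\]; vectorized.
#' @param inhibition_combined combined-treatment growth inhibition,
#'   percent.
#' @return SQ, dimensionless.
#' @examples
#' synergism_quotient(20, 20, 50)   # 1.25
#' synergism_quotient(30, 30, 45)   # 0.75
#' @export
synergism_quotient <- function(inhibition_a, inhibition_b,
                               inhibition_combined) {
  chk <- c(inhibition_a, inhibition_b, inhibition_combined)
  if (any(chk < 0 | chk > 100))
    stop("inhibition percentages must lie in [0, 100]")
  denom <- inhibition_a + inhibition_b
  if (any(denom == 0))
    stop("undefined SQ: both single-agent inhibitions are zero")
  inhibition_combined / denom
}

#' Classify a synergism quotient
#'
#' SQ above 1.1 is synergism, below 0.9 antagonism, and the closed band
#' \[0.9, 1.1\] additivity. (Note the clustering transform
#' [transform_sq()] assigns exactly 1.1 to the synergistic shift, as its
#' rule is stated with a closed lower bound; the two published rules
#' disagree only at that single point.)
#'
#' @param sq synergism quotient(s), positive.
#' @return character vector: `"synergism"`, `"additivity"` or
#'   `"antagonism"`.
#' @examples
#' classify_sq(c(1.16, 1.02, 0.85))
#' @export
classify_sq <- function(sq) {
  if (any(sq <= 0)) stop("SQ must be positive")
  ifelse(sq > 1.1, "synergism",
         ifelse(sq < 0.9, "antagonism", "additivity"))
}

#' Class-separating transform of synergism quotients
#'
#' For clustering, the SQ scale is spread so interaction classes
#' dominate the distances: values below 0.9 have 10 subtracted, values
#' at or above 1.1 have 10 added, and the additive band is left
#' unchanged. Classes are thereby separated by at least 8.9 units.
#'
#' @param sq synergism quotient(s), positive.
#' @return transformed value(s).
#' @examples
#' transform_sq(c(0.85, 1.0, 1.16))   # -9.15, 1.0, 11.16
#' @export
transform_sq <- function(sq) {
  if (any(sq <= 0)) stop("SQ must be positive")
  ifelse(sq < 0.9, sq - 10, ifelse(sq >= 1.1, sq + 10, sq))
}

#' Build an SQ matrix from a combination table
#'
#' @param table data.frame with columns `cell_line`, `drug_a`, `dose_a`,
#'   `drug_b`, `dose_b`, `inh_a_pct`, `inh_b_pct`, `inh_combined_pct`.
#' @return numeric matrix, rows = combination labels
#'   (`drug_a+drug_b@dose_a/dose_b`), columns = cell lines.
#' @export
sq_matrix <- function(table) {
  need <- c("cell_line", "drug_a", "dose_a", "drug_b", "dose_b",
            "inh_a_pct", "inh_b_pct", "inh_combined_pct")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("combination table is missing column(s): ",
         paste(miss, collapse = ", "))
  sq <- synergism_quotient(table$inh_a_pct, table$inh_b_pct,
                           table$inh_combined_pct)
  combo <- sprintf("%s+%s@%s/%s", table$drug_a, table$drug_b,
                   table$dose_a, table$dose_b)
  rows <- unique(combo); cols <- unique(table$cell_line)
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  m[cbind(match(combo, rows), match(table$cell_line, cols))] <- sq
  m
}

#' Hierarchical clustering of a synergism-quotient matrix
#'
#' Clusters combinations (rows) of an SQ matrix by Euclidean distance
#' and complete linkage, after applying the class-separating
#' [transform_sq()] (disable with `transform = FALSE`). The transform
#' makes interaction class the dominant structure of the dendrogram.
#'
#' @param m numeric SQ matrix (combinations x cell lines), complete (no
#'   missing values), at least 2 rows.
#' @param transform apply [transform_sq()] before clustering?
#' @return object of class `"sq_clustering"`: the [stats::hclust()] tree
#'   (`hclust`), the transformed matrix (`values`), per-cell
#'   classifications (`classes`), and the leaf order.
#' @examples
#' m <- rbind(a = c(0.8, 0.85), b = c(1.2, 1.3), c = c(1.0, 1.02))
#' colnames(m) <- c("A2780", "IGROV1")
#' cluster_sq(m)
#' @export
cluster_sq <- function(m, transform = TRUE) {
  if (!is.matrix(m) || !is.numeric(m)) stop("m must be a numeric matrix")
  if (anyNA(m)) stop("SQ matrix must be complete for clustering")
  if (nrow(m) < 2L) stop("need at least 2 combinations to cluster")
  vals <- if (transform) transform_sq(m) else m
  hc <- stats::hclust(stats::dist(vals, method = "euclidean"),
                      method = "complete")
  structure(list(hclust = hc, values = vals,
                 classes = matrix(classify_sq(m), nrow(m),
                                  dimnames = dimnames(m)),
                 order = rownames(m)[hc$order],
                 transformed = transform),
            class = "sq_clustering")
}

#' @export
print.sq_clustering <- function(x, ...) {
  cat(sprintf("SQ clustering: %d combinations x %d cell lines (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$transformed) "class-separating transform" else
                "raw SQ values"))
  cat("  leaf order:", paste(x$order, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.sq_clustering <- function(x, ...) {
  graphics::plot(x$hclust, xlab = "combination",
                 main = "SQ complete-linkage clustering", sub = "", ...)
  invisible(x)
}

#' Export an SQ dendrogram as a Newick string
#'
#' @param x an `"sq_clustering"` object.
#' @param file optional path; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
sq_newick <- function(x, file = NULL) {
  stopifnot(inherits(x, "sq_clustering"))
  phy <- ape::as.phylo(x$hclust)
  if (is.null(file)) ape::write.tree(phy)
  else invisible(ape::write.tree(phy, file = file))
}
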