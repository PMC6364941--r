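#' Integrate the residual component over lipid regions
#'
#' Once the metabolic signal has been captured by the templates, the
#' residual component over broad, lipid-dominated windows approximates the
#' lipid concentrations. A warning flags regions where the metabolite fit
#' contributes more than 20% of the residual area — leakage of catalogued
#' metabolite signal into a lipid feature.
#'
#' @param fit a \linkS4class{DeconFit}.
#' @param lipid_table data.frame with columns
#'   \code{lipid_id,resonance_label,ppm_lo,ppm_hi} (see
#'   \code{\link{defaultLipidTable}}).
#' @param contamination_warn fraction of residual area above which metabolite
#'   contamination is reported.
#' @return named numeric vector of lipid features.
#' @export
integrateResidual <- function(fit, lipid_table, contamination_warn = 0.2) {
  x <- rev(fit@ppm)
  res <- rev(fit@residualFit)
  met <- rev(fit@metaboliteFit)
  rng <- range(x)
  outside <- lipid_table$ppm_hi <= rng[1] | lipid_table$ppm_lo >= rng[2]
  if (any(outside))
    stop("lipid region(s) outside the axis: ",
         paste(lipid_table$lipid_id[outside], collapse = ", "))
  v <- numeric(nrow(lipid_table))
  contaminated <- character(0)
  for (i in seq_len(nrow(lipid_table))) {
    win <- x >= lipid_table$ppm_lo[i] & x < lipid_table$ppm_hi[i]
    if (sum(win) > 1) {
      v[i] <- pracma::trapz(x[win], res[win])
      met_area <- pracma::trapz(x[win], met[win])
      if (v[i] > 0 && met_area > contamination_warn * v[i])
        contaminated <- c(contaminated, lipid_table$lipid_id[i])
    }
  }
  if (length(contaminated))
    warning("metabolite fit exceeds ", round(100 * contamination_warn),
            "% of the residual area in lipid region(s): ",
            paste(contaminated, collapse = ", "))
  setNames(v, lipid_table$lipid_id)
}

#' Assemble deconvolution features for a cohort
#'
#' Collects the fitted relative metabolite concentrations and/or the lipid
#' features integrated from the residual component into a labelled
#' \linkS4class{FeatureMatrix}. Metabolites flagged as excluded from
#' classification (betaine and choline in the 900 MHz catalogue) are
#' dropped. Coefficients are multiplied by each spectrum's stored
#' normalization constant's inverse already implicit in the fit; set
#' \code{denormalize = TRUE} to undo spectrum-level normalization using the
#' constants recorded in the processing logs.
#'
#' @param fits named list of \linkS4class{DeconFit} objects (one per
#'   sample).
#' @param catalogue the \linkS4class{MetaboliteCatalogue} fitted.
#' @param mode "metabolites", "lipids" or "both".
#' @param lipid_table required for lipid modes.
#' @param labels class labels in the order of \code{fits}.
#' @param norm_constants optional per-sample normalization constants to
#'   multiply features back to a common pre-normalization scale.
#' @return a \linkS4class{FeatureMatrix} with provenance "deconvolution".
#' @export
assembleFeatures <- function(fits, catalogue,
                             mode = c("both", "metabolites", "lipids"),
                             lipid_table = NULL, labels = NULL,
                             norm_constants = NULL) {
  mode <- match.arg(mode)
  miss <- vapply(fits, is.null, logical(1))
  if (any(miss))
    stop("missing fit for sample(s): ",
         paste(names(fits)[miss], collapse = ", "))
  ids <- names(fits)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(fits))
  blocks <- list()
  if (mode %in% c("both", "metabolites")) {
    keep <- metaboliteNames(catalogue, classificationOnly = TRUE)
    met <- t(vapply(fits, function(f) f@beta[keep], numeric(length(keep))))
    colnames(met) <- keep
    blocks$met <- met
  }
  if (mode %in% c("both", "lipids")) {
    if (is.null(lipid_table)) stop("lipid_table is required for lipid features")
    lip <- t(vapply(fits, integrateResidual, numeric(nrow(lipid_table)),
                    lipid_table = lipid_table))
    colnames(lip) <- lipid_table$lipid_id
    blocks$lip <- lip
  }
  vals <- do.call(cbind, blocks)
  rownames(vals) <- ids
  if (!is.null(norm_constants)) vals <- vals * norm_constants
  makeFeatureMatrix(vals, labels, provenance = "deconvolution")
}
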