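#' @rdname nmrsigex-accessors
#' @aliases ppm,NMRSpectrum-method
setMethod("ppm", "NMRSpectrum", function(object) object@ppm)

#' @rdname nmrsigex-accessors
setMethod("intensity", "NMRSpectrum", function(object) object@intensity)

#' @rdname nmrsigex-accessors
setMethod("fieldMHz", "NMRSpectrum", function(object) object@fieldMHz)

#' @rdname nmrsigex-accessors
setMethod("fieldMHz", "Fid", function(object) object@fieldMHz)

#' @rdname nmrsigex-accessors
setMethod("fieldMHz", "TemplateLibrary", function(object) object@fieldMHz)

#' @rdname nmrsigex-accessors
setMethod("exclusionMask", "NMRSpectrum", function(object) object@mask)

#' @rdname nmrsigex-accessors
setMethod("processingLog", "NMRSpectrum", function(object) object@meta)

#' @rdname nmrsigex-accessors
setMethod("processingLog", "Fid", function(object) object@meta)

#' @rdname nmrsigex-accessors
setMethod("multiplets", "TemplateLibrary", function(object) object@multiplets)

#' @rdname nmrsigex-accessors
setMethod("multiplets", "MetaboliteCatalogue",
          function(object) object@library@multiplets)

#' @param ... for \code{metaboliteNames}, \code{classificationOnly = FALSE}
#'   restricts to metabolites usable as classification features.
#' @rdname nmrsigex-accessors
setMethod("metaboliteNames", "MetaboliteCatalogue",
  function(object, classificationOnly = FALSE) {
    mt <- object@metabolites
    if (classificationOnly) mt$name[mt$in_classification] else mt$name
  })

#' @rdname nmrsigex-accessors
setMethod("lipidResonances", "MetaboliteCatalogue", function(object) object@lipids)

#' @rdname nmrsigex-accessors
setMethod("cohortLabels", "CohortTruth", function(object) object@labels)

#' @rdname nmrsigex-accessors
setMethod("concentrations", "CohortTruth", function(object) object@concentrations)

#' @rdname nmrsigex-accessors
setMethod("lipidLevels", "CohortTruth", function(object) object@lipidLevels)

#' @rdname nmrsigex-accessors
setMethod("shiftJitter", "CohortTruth", function(object) object@shifts)

#' @rdname nmrsigex-accessors
setMethod("coef", "DeconFit", function(object) object@beta)

#' @rdname nmrsigex-accessors
setMethod("coefficients95", "DeconFit", function(object) object@ci95)

#' @rdname nmrsigex-accessors
setMethod("metaboliteFit", "DeconFit", function(object) object@metaboliteFit)

#' @rdname nmrsigex-accessors
setMethod("residualFit", "DeconFit", function(object) object@residualFit)

#' @rdname nmrsigex-accessors
setMethod("fitSum", "DeconFit",
          function(object) object@metaboliteFit + object@residualFit)

#' @rdname nmrsigex-accessors
setMethod("ppm", "DeconFit", function(object) object@ppm)

#' @rdname nmrsigex-accessors
setMethod("featureValues", "FeatureMatrix",
          function(object) t(SummarizedExperiment::assay(object)))

#' @rdname nmrsigex-accessors
setMethod("sampleLabels", "FeatureMatrix",
          function(object) SummarizedExperiment::colData(object)$label)

#' @rdname nmrsigex-accessors
setMethod("provenance", "FeatureMatrix",
          function(object) S4Vectors::metadata(object)$provenance)

#' @rdname nmrsigex-accessors
setMethod("cvIterations", "CvResult", function(object) object@iterations)

#' @rdname nmrsigex-accessors
setMethod("cvProbabilities", "CvResult", function(object) object@probabilities)

setMethod("show", "Fid", function(object) {
  cat("Fid:", length(object@signal), "complex points, dwell",
      signif(object@dwellSec * 1e6, 4), "us,",
      object@fieldMHz, "MHz\n")
})

setMethod("show", "NMRSpectrum", function(object) {
  cat("NMRSpectrum:", length(object@ppm), "points,",
      signif(max(object@ppm), 4), "to", signif(min(object@ppm), 4), "ppm,",
      object@fieldMHz, "MHz;", sum(object@mask), "masked points\n")
  if (length(object@meta))
    cat("  history:", paste(names(object@meta), collapse = " -> "), "\n")
})

setMethod("show", "TemplateLibrary", function(object) {
  cat("TemplateLibrary:", nrow(object@multiplets), "multiplets for",
      length(unique(object@multiplets$metabolite)), "metabolites at",
      object@fieldMHz, "MHz\n")
})

setMethod("show", "MetaboliteCatalogue", function(object) {
  cat("MetaboliteCatalogue:", nrow(object@metabolites), "metabolites (",
      sum(object@metabolites$in_classification), "classification features ),",
      nrow(object@lipids), "lipid resonances,",
      object@library@fieldMHz, "MHz\n")
})

setMethod("show", "CohortTruth", function(object) {
  cat("CohortTruth:", length(object@labels), "samples (",
      sum(object@labels == "case"), "cases /",
      sum(object@labels == "control"), "controls ),",
      ncol(object@concentrations), "metabolites,",
      ncol(object@lipidLevels), "lipid resonances\n")
})

setMethod("show", "DeconFit", function(object) {
  cat("DeconFit:", length(object@beta), "metabolites on",
      length(object@ppm), "points; converged:",
      isTRUE(object@convergence$converged), "(",
      object@convergence$iterations, "iterations )\n")
  top <- sort(object@beta, decreasing = TRUE)
  top <- head(top, 5)
  cat("  largest coefficients:",
      paste(sprintf("%s=%.3g", names(top), top), collapse = ", "), "\n")
})

setMethod("show", "ModeratedTResult", function(object) {
  cat("ModeratedTResult:", nrow(object@table), "features; d0 =",
      signif(object@d0, 4), ", s0^2 =", signif(object@s02, 4), "\n")
})

setMethod("show", "CvResult", function(object) {
  it <- object@iterations
  cat("CvResult:", nrow(it), "iterations (",
      length(unique(it$repetition)), "repetitions x",
      length(unique(it$fold)), "folds )\n")
  if (nrow(it))
    cat(sprintf("  mean error %.3f, sensitivity %.3f, specificity %.3f\n",
                mean(it$error), mean(it$sensitivity), mean(it$specificity)))
})
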