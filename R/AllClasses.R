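#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats approx fft median optim quantile rnorm runif rlnorm sd var
#'   setNames coef predict mad smooth.spline fitted cor
#' @importFrom graphics hist
#' @importFrom utils read.csv write.csv head modifyList
NULL

#' Time-domain NMR signal (free induction decay)
#'
#' Holds the complex time-domain samples emitted by resonating nuclei after
#' the radio-frequency pulse, together with the acquisition metadata needed to
#' map the Fourier-transformed signal onto a chemical-shift (ppm) axis.
#'
#' @slot signal complex vector of time-domain samples.
#' @slot dwellSec sampling interval in seconds (inverse spectral width).
#' @slot fieldMHz spectrometer proton resonance frequency in MHz.
#' @slot carrierPpm chemical shift (ppm) of the carrier (centre) frequency;
#'   frequencies in the FID are offsets from this position.
#' @slot meta list of processing history entries.
#' @exportClass Fid
setClass("Fid", representation(
  signal = "complex",
  dwellSec = "numeric",
  fieldMHz = "numeric",
  carrierPpm = "numeric",
  meta = "list"
))

setValidity("Fid", function(object) {
  msg <- character()
  if (length(object@signal) < 2L) msg <- c(msg, "signal must have length >= 2")
  if (length(object@dwellSec) != 1L || object@dwellSec <= 0)
    msg <- c(msg, "dwellSec must be a single positive number")
  if (length(object@fieldMHz) != 1L || object@fieldMHz <= 0)
    msg <- c(msg, "fieldMHz must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Frequency-domain 1D NMR spectrum
#'
#' A real-valued intensity trace on a strictly descending chemical-shift axis,
#' optionally retaining the complex representation (needed for phase
#' correction) and a logical exclusion mask (water/TSP windows).
#'
#' @slot ppm strictly descending chemical-shift axis (ppm).
#' @slot intensity real intensities, same length as \code{ppm}.
#' @slot cplx complex spectrum before/after phasing; may be length zero once
#'   the spectrum is finalized.
#' @slot mask logical; \code{TRUE} marks points excluded from normalization
#'   and integration (e.g. the water window).
#' @slot fieldMHz spectrometer frequency (MHz).
#' @slot meta list of processing history entries (apodization, normalization
#'   constant, referencing shift, ...).
#' @exportClass NMRSpectrum
setClass("NMRSpectrum", representation(
  ppm = "numeric",
  intensity = "numeric",
  cplx = "complex",
  mask = "logical",
  fieldMHz = "numeric",
  meta = "list"
))

setValidity("NMRSpectrum", function(object) {
  msg <- character()
  n <- length(object@ppm)
  if (n < 2L) msg <- c(msg, "ppm axis must have length >= 2")
  if (length(object@intensity) != n)
    msg <- c(msg, "intensity and ppm must have equal length")
  if (n >= 2L && any(diff(object@ppm) >= 0))
    msg <- c(msg, "ppm axis must be strictly decreasing")
  if (length(object@cplx) && length(object@cplx) != n)
    msg <- c(msg, "cplx must be empty or match ppm length")
  if (length(object@mask) != n)
    msg <- c(msg, "mask must match ppm length")
  if (length(msg)) msg else TRUE
})

#' Library of multiplet templates
#'
#' Prior knowledge about each metabolite's spectral signature: one row per
#' multiplet with its centre position, J-coupling pattern, coupling constants,
#' proton count and (optionally empirical) relative peak intensities. Complex
#' multiplets may instead carry a raster curve, a non-parametric template cut
#' from a pure-compound spectrum.
#'
#' @slot multiplets data.frame with columns \code{metabolite},
#'   \code{multiplet_id}, \code{center_ppm}, \code{pattern}, \code{j_hz}
#'   (list column, Hz), \code{protons}, \code{rel_intensities} (list column,
#'   sums to protons), \code{shift_tolerance_ppm}.
#' @slot rasters named list (by \code{multiplet_id}) of data.frames with
#'   columns \code{ppm}, \code{intensity} for raster multiplets.
#' @slot fieldMHz field strength the positions were calibrated at (MHz).
#' @exportClass TemplateLibrary
setClass("TemplateLibrary", representation(
  multiplets = "data.frame",
  rasters = "list",
  fieldMHz = "numeric"
))

.template_patterns <- c("singlet", "doublet", "triplet", "quartet",
                        "double_doublet", "raster")

setValidity("TemplateLibrary", function(object) {
  m <- object@multiplets
  req <- c("metabolite", "multiplet_id", "center_ppm", "pattern", "j_hz",
           "protons", "rel_intensities", "shift_tolerance_ppm")
  msg <- character()
  if (!all(req %in% names(m)))
    return(paste("multiplets must have columns:", paste(req, collapse = ", ")))
  if (anyDuplicated(m$multiplet_id))
    msg <- c(msg, "multiplet_id values must be unique")
  if (!all(m$pattern %in% .template_patterns))
    msg <- c(msg, "unknown pattern value")
  if (any(m$protons <= 0 | m$protons != round(m$protons)))
    msg <- c(msg, "protons must be positive integers")
  bad <- vapply(seq_len(nrow(m)), function(i) {
    h <- m$rel_intensities[[i]]
    length(h) > 0 && abs(sum(h) - m$protons[i]) > 1e-9
  }, logical(1))
  if (any(bad))
    msg <- c(msg, paste("rel_intensities must sum to protons; offending multiplet(s):",
                        paste(m$multiplet_id[bad], collapse = ", ")))
  ras <- m$pattern == "raster"
  if (!all(m$multiplet_id[ras] %in% names(object@rasters)))
    msg <- c(msg, "raster multiplets must have a raster curve attached")
  if (length(msg)) msg else TRUE
})

#' Catalogue of plasma metabolites and lipid resonances for simulation
#'
#' Bundles a \linkS4class{TemplateLibrary} with metabolite-level bookkeeping
#' (total protons, typical plasma concentration, whether the metabolite is
#' used as a classification feature) and a table of broad lipid resonances.
#'
#' @slot library the multiplet \linkS4class{TemplateLibrary}.
#' @slot metabolites data.frame with columns \code{name}, \code{protons_total},
#'   \code{mean_conc} (relative units), \code{in_classification} (logical).
#' @slot lipids data.frame with columns \code{lipid_id}, \code{label},
#'   \code{center_ppm}, \code{fwhm_hz}, \code{mean_level}.
#' @exportClass MetaboliteCatalogue
setClass("MetaboliteCatalogue", representation(
  library = "TemplateLibrary",
  metabolites = "data.frame",
  lipids = "data.frame"
))

setValidity("MetaboliteCatalogue", function(object) {
  msg <- character()
  mt <- object@metabolites
  if (anyDuplicated(mt$name)) msg <- c(msg, "metabolite names must be unique")
  cp <- object@library@multiplets$center_ppm
  if (length(cp) && (any(cp <= -0.5) || any(cp >= 10)))
    msg <- c(msg, "multiplet centres must lie in (-0.5, 10) ppm")
  if (!all(object@library@multiplets$metabolite %in% mt$name))
    msg <- c(msg, "every multiplet must belong to a catalogued metabolite")
  if (any(mt$protons_total <= 0 | mt$protons_total != round(mt$protons_total)))
    msg <- c(msg, "protons_total must be positive integers")
  if (length(msg)) msg else TRUE
})

#' Ground truth for a simulated two-class cohort
#'
#' @slot labels factor with levels \code{control}, \code{case}.
#' @slot concentrations samples x metabolites matrix of true relative
#'   concentrations (non-negative).
#' @slot lipidLevels samples x lipid-resonance matrix of true lipid levels.
#' @slot shifts samples x multiplets matrix of per-spectrum chemical-shift
#'   jitter (ppm).
#' @slot design list echoing the \code{cohortDesign()} used.
#' @exportClass CohortTruth
setClass("CohortTruth", representation(
  labels = "factor",
  concentrations = "matrix",
  lipidLevels = "matrix",
  shifts = "matrix",
  design = "list"
))

setValidity("CohortTruth", function(object) {
  msg <- character()
  n <- length(object@labels)
  if (nrow(object@concentrations) != n || nrow(object@lipidLevels) != n ||
      nrow(object@shifts) != n)
    msg <- c(msg, "all per-sample matrices must have one row per label")
  if (any(object@concentrations < 0))
    msg <- c(msg, "concentrations must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Result of a two-component spectral deconvolution
#'
#' The fitted decomposition of a spectrum into a metabolite component (sum of
#' scaled, locally shifted multiplet templates) and a wavelet-regularized
#' residual component, plus convergence diagnostics and optional 95% credible
#' intervals for the metabolite coefficients.
#'
#' @slot beta named non-negative metabolite coefficients (relative
#'   concentrations).
#' @slot delta named per-multiplet fitted local shifts (ppm).
#' @slot fwhmHz fitted Lorentzian linewidth (Hz).
#' @slot ppm the axis the fit lives on (descending).
#' @slot metaboliteFit fitted metabolite component.
#' @slot residualFit fitted residual (wavelet) component.
#' @slot ci95 two-column matrix (lo, hi) per metabolite, or 0-row if not
#'   computed.
#' @slot noiseSdEst noise standard deviation estimated from a signal-free
#'   window.
#' @slot convergence list with \code{iterations}, \code{rel_change},
#'   \code{converged}.
#' @slot details internal per-multiplet bookkeeping (template supports and
#'   fitted contributions) used by diagnostics and interval estimation.
#' @exportClass DeconFit
setClass("DeconFit", representation(
  beta = "numeric",
  delta = "numeric",
  fwhmHz = "numeric",
  ppm = "numeric",
  metaboliteFit = "numeric",
  residualFit = "numeric",
  ci95 = "matrix",
  noiseSdEst = "numeric",
  convergence = "list",
  details = "list"
))

setValidity("DeconFit", function(object) {
  msg <- character()
  if (any(object@beta < 0)) msg <- c(msg, "beta must be non-negative")
  if (length(object@metaboliteFit) != length(object@ppm) ||
      length(object@residualFit) != length(object@ppm))
    msg <- c(msg, "fit curves must match the ppm axis")
  if (length(msg)) msg else TRUE
})

#' Samples-by-features matrix with class labels
#'
#' A thin \linkS4class{SummarizedExperiment} subclass: features are rows,
#' samples are columns, the class label lives in \code{colData()$label} and
#' the provenance ("binning" or "deconvolution") in \code{metadata()}.
#'
#' @exportClass FeatureMatrix
setClass("FeatureMatrix", contains = "SummarizedExperiment")

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (!"label" %in% names(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'label' column")
  if (any(is.na(SummarizedExperiment::assay(object))))
    msg <- c(msg, "feature values must not contain NA")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "feature ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Moderated t-statistics with empirical-Bayes variance shrinkage
#'
#' @slot table data.frame with one row per feature: \code{feature},
#'   \code{mean_diff}, \code{t_ordinary}, \code{t_moderated}, \code{s2},
#'   \code{s2_shrunk}, \code{rank}.
#' @slot d0 prior degrees of freedom (may be \code{Inf}).
#' @slot s02 prior variance.
#' @slot dg residual degrees of freedom per feature (n1 + n2 - 2).
#' @exportClass ModeratedTResult
setClass("ModeratedTResult", representation(
  table = "data.frame",
  d0 = "numeric",
  s02 = "numeric",
  dg = "numeric"
))

#' Repeated cross-validation result
#'
#' @slot iterations data.frame with one row per (repetition, fold):
#'   \code{repetition}, \code{fold}, \code{error}, \code{sensitivity},
#'   \code{specificity}.
#' @slot probabilities data.frame of pooled out-of-fold case probabilities:
#'   \code{sample_id}, \code{label}, \code{repetition}, \code{prob}.
#' @slot selection list (one character vector per iteration) of the features
#'   retained by the in-fold selector; empty when no selection was applied.
#' @slot config the cross-validation configuration used.
#' @exportClass CvResult
setClass("CvResult", representation(
  iterations = "data.frame",
  probabilities = "data.frame",
  selection = "list",
  config = "list"
))

setValidity("CvResult", function(object) {
  it <- object@iterations
  msg <- character()
  if (nrow(it)) {
    if (any(it$error < 0 | it$error > 1, na.rm = TRUE))
      msg <- c(msg, "error rates must lie in [0, 1]")
    if (any(it$sensitivity < 0 | it$sensitivity > 1, na.rm = TRUE) ||
        any(it$specificity < 0 | it$specificity > 1, na.rm = TRUE))
      msg <- c(msg, "sensitivity/specificity must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
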