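# nmrsigex

Metabolic signal extraction from 1D ¹H-NMR blood-plasma spectra: spectral
binning versus two-component template deconvolution, evaluated by repeated
cross-validated classification.

## The problem

A single 1D proton-NMR spectrum of blood plasma encodes the concentrations
of dozens of metabolites as overlapping multiplets on a chemical-shift (ppm)
axis, sitting on broad lipid and macromolecule resonances. Two routes lead
from such spectra to features for case/control classification:

* **Spectral binning** — integrate the spectrum over predefined ppm regions
  ("integrated spectral regions", ISRs). Simple and fast, but a region that
  contains two metabolites moving in opposite directions between classes can
  lose its discriminative signal, and a discriminative region cannot be
  attributed to a single compound.
* **Template deconvolution** — model the spectrum as

  S(x) = Σ_m β_m T_m(x; δ) + r(x) + ε(x),

  where each metabolite template `T_m` is a sum of Lorentzian multiplets
  whose positions, J-coupling patterns and relative peak intensities are
  prior knowledge, `β_m ≥ 0` are relative concentrations, `δ` are small
  per-multiplet position shifts, and the residual component `r` captures
  everything uncatalogued — notably broad lipid resonances, which can then
  be integrated over lipid-specific windows to give lipid features.

This package implements both routes end to end for synthetic cohorts whose
ground truth is known: a plasma-like spectrum generator, the preprocessing
chain (apodization, zero-filling, Fourier transformation, phasing,
asymmetric-least-squares baseline correction, TSP referencing at 0.015 ppm,
monotone warping alignment, normalization), the multiplet template library
(33 target metabolites at 400 MHz; betaine and choline added at 900 MHz but
excluded from classification), region tables (110/105/103 bins for the
400 MHz, manual 900 MHz and automated 900 MHz protocols), the deconvolution
solver with 95% credible intervals, and a repeated stratified three-fold
cross-validation harness (333 repetitions = 999 classifier fits) with
in-fold moderated-t feature selection and a pluggable classifier contract
(elastic-net logistic regression as the reference).

Relative peak intensities for multiplets with roofing are normalized to the
proton count (`h_i = p·y_i/Σy_i`); first-order patterns place peaks at
offsets derived from the coupling constants (a double doublet's outer peaks
sit at half the sum of the two J values from the centre).

## Worked example

```r
library(nmrsigex)

catalogue <- buildCatalogue(400)
design <- cohortDesign(n_cases = 8, n_controls = 8, seed = 42)
truth <- simulateCohort(design, catalogue)
truth
#> CohortTruth: 16 samples ( 8 cases / 8 controls ), 33 metabolites, 9 lipid resonances

acq <- acquisitionParams(400)
fid <- synthesizeFid(concentrations(truth)[1, ], lipidLevels(truth)[1, ],
                     shiftJitter(truth)[1, ], catalogue, acq)
spectrum <- preprocessFid(fid, phi0_deg = 0)
spectrum
#> NMRSpectrum: 16384 points, 12.25 to -2.75 ppm, 400 MHz; 1093 masked points
#>   history: synthesized -> ... -> baseline -> reference -> excluded_windows -> normalize

# binning features (total-area-normalized region integrals)
isr <- integrateRegions(spectrum, defaultRegionTable(400))
round(head(isr, 3), 5)
#>    R001    R002    R003
#> 0.00097 0.00253 0.00291

# two-component deconvolution
fit <- deconvolve(spectrum, catalogue@library)
fit
#> DeconFit: 33 metabolites on 16384 points; converged: TRUE ( 16 iterations )
#>   largest coefficients: beta-D-glucopyranose=0.0511, alpha-D-glucopyranose=0.0381,
#>   lactate=0.0321, glutamine=0.0156, alanine=0.0107
```

The coefficients are relative concentrations in the normalized-intensity
scale; glucose anomers and lactate dominating a fasting-plasma profile is
exactly what the generator encodes. Lipid features come from the residual
component (`integrateResidual(fit, defaultLipidTable(400))`); a warning
flags lipid windows where catalogued metabolite signal leaks in, which is
common in crowded regions and mirrors practice.

Classification of a binning feature matrix with in-fold moderated-t
selection and an elastic net:

```r
mt <- moderatedT(bins)          # bins: a labelled FeatureMatrix
mt
#> ModeratedTResult: 110 features; d0 = 680.8 , s0^2 = 1.003
cv <- runRepeatedCv(bins, cvConfig(k_folds = 3, repetitions = 25,
                                   selector = "moderated_t_top_k", top_k = 15,
                                   classifier = "elastic_net", seed = 9))
summarizeCv(list(`binning ISRs` = cv))
#>       features     error    error_se sensitivity specificity
#> 1 binning ISRs 0.3409161 0.006785431   0.6255072   0.6904667
```

The mean error, sensitivity and specificity are averages over all
repetition × fold iterations with their standard errors — the same summary
layout used for the five predictor sets that `runStudy()` produces
(binning at 400 MHz, deconvolution at 400 MHz, binning on the automated and
manual-style 900 MHz preprocessing, deconvolution at 900 MHz, with
metabolites-only / lipids-only / combined deconvolution sub-results).

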