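---
title: "Extracting metabolic signal from 1D 1H-NMR plasma spectra: binning and template deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting metabolic signal from 1D 1H-NMR plasma spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrsigex)
```

# Overview

`nmrsigex` compares two routes from one-dimensional proton-NMR blood-plasma
spectra to classifier-ready features. The first, spectral binning,
integrates each spectrum over a fixed table of chemical-shift regions. The
second, two-component template deconvolution, explains the spectrum as a
non-negative combination of metabolite multiplet templates plus a flexible
residual, yielding one relative concentration per metabolite and, from the
residual, a small set of broad lipid features. Because the study that
motivates this comparison rests on patient spectra that cannot be packaged,
the package ships a synthetic-cohort generator whose ground truth makes
every downstream stage testable.

# The spectrum model and the generator

A damped oscillation at frequency $f$ with apparent transverse decay $T_2$
contributes $a\,e^{i2\pi f t}e^{-t/T_2}$ to the free induction decay; its
Fourier transform is a Lorentzian of full width at half maximum
$1/(\pi T_2)$ Hz and area proportional to $a$. The generator builds each
synthetic FID as a sum of such peaks:

* **Metabolites.** Each catalogue multiplet places peaks at
  `center_ppm + offset/field`, where the offsets follow the first-order
  J-coupling rules (doublet $\pm J/2$; triplet $-J, 0, +J$ at 1:2:1;
  quartet $\pm 3J/2, \pm J/2$ at 1:3:3:1; double doublet
  $\pm(J_1+J_2)/2, \pm(J_1-J_2)/2$). Peak amplitudes are concentration
  times the relative intensity $h_i$; for multiplets with second-order
  roofing the $h_i$ are empirical, normalized so $\sum_i h_i$ equals the
  proton count.
* **Lipids.** Broad resonances (full widths 25–40 Hz) at the standard
  plasma positions: the fatty-acid chain methyl and methylene envelopes,
  allylic and diallylic methylenes, the resonances alpha and beta to the
  carbonyl, the lysyl signal, the olefinic protons, and the cholesterol
  C18 methyl.
* **Artifacts.** A residual water hump near 4.79 ppm (1% of a nominal
  pre-suppression amplitude by default), a sharp TSP reference singlet, a
  smooth baseline drift emulated by ultra-fast-decaying components, an
  optional zero/first-order phase error, and complex white noise.

The packaged catalogue covers the 33 target metabolites of the 400 MHz
analysis; at 900 MHz betaine and choline are added but flagged as excluded
from classification, so 33 classification features remain at either field.
Multiplet positions and couplings follow standard plasma assignments
(HMDB-style) because the original assignment tables are not published; they
ship as editable CSVs under `inst/extdata/`.

## Cohort design defaults

`cohortDesign()` encodes the study conditions: 69 cases and 74 controls;
per-sample concentrations log-normal about the class mean with a
coefficient of variation of 0.2 (a typical between-subject spread for
plasma metabolites); per-spectrum multiplet position jitter with SD
0.002 ppm, within the warp and shift-fitting tolerances; six metabolites
and two lipid resonances perturbed at fold changes between 1.2 and 2 —
large enough to be detectable, small enough that classification stays
imperfect. The acquisition defaults mirror a CPMG plasma experiment:
spectral widths of 6000 Hz (400 MHz) and 14423 Hz (900 MHz), 1.2 s of
acquisition, natural linewidths of about 1.5 Hz and 1.0 Hz, and a
time-domain noise level chosen so that major metabolite peaks appear with
the high signal-to-noise (a few hundred for the lactate doublet) typical of
averaged plasma spectra. These are the generator's fixed study conditions,
not tuning knobs.

The generator does not attempt T1 relaxation, solvent exchange, CPMG
editing physics, radiation damping, or 2D experiments, and its class
effects are illustrative rather than estimates of any real cohort's
biology. Tests passing on these cohorts therefore demonstrate that the
algorithms recover a known truth under realistic widths, overlap, drift and
noise — not that the defaults reproduce any particular patient dataset.

# Preprocessing

The automated-style chain is `apodize` (exponential line broadening,
default 0.7 Hz) → `zeroFillTransform` (zero-fill to the next power of two
at least twice the acquired length, discrete Fourier transform scaled by
the dwell time, frequency axis mapped to ppm via
$(f - f_{ref})/f_{field}$) → `phaseCorrect`/`autophase` → `baselineCorrect`
→ `referenceToTsp` → `excludeRegions` → `normalizeSpectrum`, with
`warpAlign` as a cohort-level step between referencing and normalization.

Numerical choices worth recording:

* **Autophase objective.** The squared negative-intensity penalty
  $\sum \min(I, 0)^2$, minimized by Nelder-Mead from four zero-order
  starting angles. A well-phased absorption spectrum is non-negative up to
  noise and baseline, so the objective has its minimum at the true angles;
  the multi-start guards against the 180-degree ambiguity.
* **Baseline.** Asymmetric least squares with asymmetry 0.01: points above
  the baseline get weight 0.01, points below 0.99, iterated until fewer
  than 0.5% of weights change. The smoothness penalty defaults to
  $\lambda = 2\times 10^9 (n/8192)^4$. The fourth-power scaling keeps the
  *physical* stiffness of the baseline constant across axis lengths
  (the index-space second difference of a fixed curve shrinks
  quadratically as points are added); the constant was chosen so that a
  Lorentzian riding on a linear drift loses less than 2% of its area,
  which materially smaller penalties fail by absorbing peak tails into the
  baseline.
* **Referencing.** The TSP apex is located in a window around 0 ppm by
  parabolic interpolation through the discrete maximum and the axis is
  translated so it sits at 0.015 ppm; an apex less than five robust noise
  SDs above the window median is rejected as undetectable.
* **Warping.** A strictly monotone piecewise-linear map (default 64
  segments, ±0.01 ppm node limit) maximizes local correlation with a
  reference; under the "after" policy every candidate reference is tried
  and the one minimizing the total post-warp sum of squared differences
  wins. Monotonicity is enforced by construction; candidate maps that
  would fold the axis are repaired, never returned. Because the full
  policy costs a quadratic number of warps, the study pipeline restricts
  the candidate set (default eight evenly spaced spectra) — a speed/
  optimality trade the user can override. Cohorts are warped separately
  per class, since class differences are expected signal.
* **Masking and normalization.** The residual water window (4.50–5.10 ppm)
  and the TSP window (±0.20 ppm) are masked; masked points contribute
  nothing to normalization or integration. Total-area normalization uses
  the trapezoid area over unmasked points; median normalization divides by
  the median positive intensity.

# Binning

Regions are half-open intervals $[lo, hi)$ in ascending ppm so adjacent
regions partition the axis exactly; integrals interpolate the intensity at
the region boundaries, making a split region's halves sum to the whole to
machine precision. The packaged tables (110 regions at 400 MHz, 105 and
103 for the manual- and automated-style 900 MHz protocols) were generated
from the catalogue's multiplet positions with linewidth margins, then split
at the widest regions to the protocol counts; the originals are not
published, so these stand-ins are deliberately overridable via
`readRegionTable()`.

# Deconvolution

The fit minimizes
$\lVert S - \sum_m \beta_m T_m(\delta) - r \rVert^2$ with $\beta \ge 0$ and
per-multiplet shifts $|\delta| \le$ tolerance (±0.005 ppm at 400 MHz,
±0.003 ppm at 900 MHz). The residual $r$ has two parts with distinct
roles:

* a **smooth background** spanned by a cubic B-spline basis with knots
  every 18 Hz (capped at 400 columns), fitted *jointly* with the templates
  by profiling it out of the non-negative least squares step — this is
  what absorbs broad lipid humps and leftover baseline;
* a **fine-scale component** obtained by soft-thresholding the Daubechies-4
  wavelet detail coefficients of the post-fit leftover at the universal
  threshold $\hat\sigma\sqrt{2\log n}$ (robust MAD noise scale, decomposition
  to level $\log_2 n - 4$), capturing uncatalogued sharp structure while
  suppressing noise.

The alternation is: non-negative least squares for $\beta$ (Lawson-Hanson on
the Cholesky-reduced normal equations, with the background profiled out) →
per-multiplet shift grid search at axis-step resolution with sub-grid
parabolic refinement, ties broken toward zero shift → repeat until the
relative change of the fitting error drops below $10^{-6}$ or 50
iterations. Two ordering decisions were forced by failure modes observed on
synthetic fixtures, and are deliberate design features:

* The wavelet part is extracted **once, after** the template/shift
  alternation has converged. If it is updated inside the loop with a
  noise-scaled threshold, the alternation becomes degenerate — in the
  noise-free limit any $(\beta, r = S - T\beta)$ is a fixed point — and
  template misfit leaks into the residual before the shifts settle.
* The linewidth is refined **after** the shifts converge (coarse grid then
  parabolic refinement on the log-width scale, starting from the natural
  width plus the apodization broadening read from the processing log).
  Scoring candidate widths against still-unaligned peaks systematically
  prefers too-broad templates, which biases every coefficient in that
  spectrum by a common factor.

Degenerate inputs: an empty library is an error; two templates whose
discretized curves correlate above 0.99999 are rejected as a singular
design; masked points are zero-weighted rather than dropped so the wavelet
step keeps its power-of-two length; on non-power-of-two axes the wavelet
part is skipped and the background alone forms the residual.

Credible intervals come from a random-walk Metropolis sampler over the
coefficients with a Gaussian likelihood whose scale is the noise SD
estimated from a signal-free window (9.3–10.3 ppm by default), a flat
prior truncated at zero, and the smooth background marginalized by
projecting both data and templates onto its orthogonal complement —
conditioning on the fitted background curve instead demonstrably
undercovers. Proposal scales start at the conditional posterior SD and
adapt once mid-burn-in; an acceptance rate outside [0.05, 0.8] triggers a
warning.

`fitDiagnostics()` reports, per multiplet, the integral of the original
spectrum over the multiplet's window against the integral of the
metabolite fit, plus a crowding score (the fraction of the window's fitted
area attributed to other templates and the residual). The comparison is
only informative for isolated multiplets; a high crowding score marks the
windows where the two integrals legitimately disagree.

# Features and classification

Lipid features are trapezoid integrals of the residual component over the
packaged lipid windows (9 at 400 MHz; 10 at 900 MHz, where the methylene
envelope is split in two); a warning reports windows in which the
metabolite fit exceeds 20% of the residual area, the leakage caveat that
accompanies imperfect template fits. Deconvolution features are multiplied
back by each spectrum's stored normalization constant so that samples share
a scale; metabolites flagged as non-classification features are dropped at
assembly.

The moderated t-statistic shrinks each feature's pooled variance toward a
prior estimated by the empirical-Bayes moment method on the log sample
variances (delegated to `limma::fitFDist`);
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, reducing to the
ordinary pooled t at $d_0 = 0$ and pinning all variances at $s_0^2$ when
$d_0$ is infinite. Ranking ties break by feature order for determinism.

The harness runs repeated stratified k-fold cross-validation (defaults: 3
folds, 333 repetitions, hence 999 classifier fits). The selector and the
classifier see only training folds; a sample is called a case when its
predicted probability exceeds 0.5; sensitivity is the fraction of cases
classified correctly. The master seed spawns one substream per repetition,
so repetitions are independent yet the whole result is reproducible. The
classifier contract is any `fit`/`predict_prob` pair; packaged options are
the elastic-net reference (penalized logistic regression, mixing value 0.5,
regularization strength by inner 5-fold cross-validation on the training
folds), the lasso (mixing 1), random forest and SVM wrappers, and a fast
diagonal nearest-centroid classifier used where hundreds of repetitions
matter more than classifier sophistication. In-fold selection keeps the
top 15 features by absolute moderated t by default — the size of the
top-variable lists the study design reports — and is intended for binning
features; deconvolution feature sets are classified without selection.

# Problem sizes in the tests

The suite exercises full-scale single spectra (16384-point axes at
400 MHz) for recovery checks, and scales the cohort-level fixtures to keep
the whole suite comfortably interactive: six full-scale spectra for the
cohort recovery property, 200 replicates of a 1024-point single-template
spectrum for interval coverage, a 30-sample 4096-point cohort for the
opposite-effect scenario, and a 12-sample short-acquisition study for the
end-to-end pipeline. These sizes are the package's own choices for a
readable, repeatable test suite; every fixture is generated in code.

# Known limitations

* Template shapes are first-order Lorentzian multiplets or raster curves;
  higher-order coupling patterns must be supplied as rasters.
* The packaged region/lipid tables and chemical shifts are standard-
  assignment stand-ins, not the original study's unpublished tables.
* The point-estimate solver is a deterministic MAP-style alternation; only
  the intervals are sampled. Joint posterior structure across metabolites
  (e.g. anti-correlation of overlapping templates) is visible to the
  sampler only through one-coefficient moves with the others fixed.
* Warping optimality degrades when the candidate reference set is
  restricted for speed.
* Absolute (mM) quantification, lipoprotein subclasses and vendor binary
  formats are out of scope; spectra enter as plain-text ppm/intensity or
  FID tables.
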