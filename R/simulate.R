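.extdata <- function(file) {
  path <- system.file("extdata", file, package = "nmrsigex")
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}

# run code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Packaged catalogue of plasma metabolite signatures
#'
#' Returns the default target catalogue used throughout the package: 33
#' metabolites at 400 MHz; at 900 MHz betaine and choline are added (35
#' entries) but flagged as excluded from classification, leaving 33 usable
#' classification features. Multiplet positions and couplings follow standard
#' plasma assignments and are shipped as editable CSVs (see
#' \code{system.file("extdata", package = "nmrsigex")}).
#'
#' @param field_mhz spectrometer frequency; 400 or 900 for the packaged
#'   defaults. Other fields require a user template library.
#' @param template_csv,metabolite_csv,lipid_csv optional paths overriding the
#'   packaged tables (same CSV dialects).
#' @return a \linkS4class{MetaboliteCatalogue}.
#' @export
buildCatalogue <- function(field_mhz = 400, template_csv = NULL,
                           metabolite_csv = NULL, lipid_csv = NULL) {
  packaged <- is.null(template_csv) && is.null(metabolite_csv)
  if (packaged && !field_mhz %in% c(400, 900))
    stop("no packaged catalogue for field ", field_mhz,
         " MHz; supply a user template_csv/metabolite_csv")
  lib <- readTemplateCsv(
    if (is.null(template_csv)) .extdata("plasma_multiplets.csv") else template_csv,
    field_mhz = field_mhz)
  mt <- read.csv(
    if (is.null(metabolite_csv)) .extdata("plasma_metabolites.csv") else metabolite_csv,
    stringsAsFactors = FALSE)
  if (packaged) {
    keep_col <- if (field_mhz == 900) "field_900" else "field_400"
    mt <- mt[mt[[keep_col]] == 1, ]
  }
  mt <- data.frame(name = mt$name, protons_total = NA_integer_,
                   mean_conc = mt$mean_conc,
                   in_classification = as.logical(mt$in_classification),
                   stringsAsFactors = FALSE)
  m <- lib@multiplets[lib@multiplets$metabolite %in% mt$name, , drop = FALSE]
  rownames(m) <- NULL
  if (field_mhz >= 700) m$shift_tolerance_ppm <- pmin(m$shift_tolerance_ppm, 0.003)
  lib@multiplets <- m
  mt$protons_total <- vapply(mt$name, function(nm)
    as.integer(sum(m$protons[m$metabolite == nm])), integer(1))
  lp <- read.csv(
    if (is.null(lipid_csv)) .extdata("plasma_lipids.csv") else lipid_csv,
    stringsAsFactors = FALSE)
  new("MetaboliteCatalogue", library = lib, metabolites = mt, lipids = lp)
}

#' Metabolites covered by the spiking experiments
#'
#' The 37 compounds for which spiked spectra pin down chemical-shift
#' positions (the target catalogue plus acetone, glycerol, methanol, and
#' glucose counted once rather than per anomer).
#'
#' @return character vector of 37 metabolite names.
#' @export
spikingMetabolites <- function() {
  c("alanine", "arginine", "asparagine", "aspartate", "cysteine",
    "glutamine", "glutamate", "glycine", "histidine", "isoleucine",
    "leucine", "lysine", "methionine", "phenylalanine", "proline",
    "serine", "threonine", "tryptophan", "tyrosine", "valine",
    "glucose", "myo-inositol", "acetate", "acetoacetate",
    "alpha-ketoglutarate", "beta-hydroxybutyrate", "citrate", "lactate",
    "pyruvate", "succinate", "creatine", "creatinine", "acetone",
    "betaine", "choline", "glycerol", "methanol")
}

#' Acquisition parameters for simulated spectra
#'
#' Defaults mirror a CPMG plasma acquisition: spectral width 6000 Hz at
#' 400 MHz and 14423 Hz at 900 MHz, 1.2 s acquisition time, apparent
#' transverse decay giving a ~1.5 Hz (400) / ~1.0 Hz (900) natural linewidth,
#' and complex white noise at a level typical of high signal-to-noise plasma
#' spectra.
#'
#' @param field_mhz spectrometer frequency (MHz).
#' @param spectral_width_hz sweep width (Hz).
#' @param acq_time_s acquisition time (s); sets the number of complex points.
#' @param t2_s apparent transverse decay constant (s).
#' @param noise_sd time-domain noise standard deviation per channel.
#' @param carrier_ppm chemical shift at the centre of the sweep.
#' @return list of acquisition parameters.
#' @export
acquisitionParams <- function(field_mhz = 400,
                              spectral_width_hz = if (field_mhz >= 700) 14423 else 6000,
                              acq_time_s = 1.2,
                              t2_s = if (field_mhz >= 700) 1 / (pi * 1.0) else 1 / (pi * 1.5),
                              noise_sd = if (field_mhz >= 700) 0.08 else 0.10,
                              carrier_ppm = 4.75) {
  stopifnot(field_mhz > 0, spectral_width_hz > 0, acq_time_s > 0, t2_s > 0,
            noise_sd >= 0)
  n <- round(spectral_width_hz * acq_time_s)
  list(field_mhz = field_mhz, spectral_width_hz = spectral_width_hz,
       n_points = n, dwell_s = 1 / spectral_width_hz, t2_s = t2_s,
       noise_sd = noise_sd, carrier_ppm = carrier_ppm)
}

#' Two-class cohort design for the synthetic study
#'
#' Describes the simulated case/control cohort: sample sizes (defaults 69
#' lung-cancer-like cases and 74 controls), which metabolites and lipid
#' resonances differ between classes and by how much (log fold changes),
#' between-sample biological variation, per-spectrum chemical-shift jitter
#' and baseline drift amplitude.
#'
#' The default effects perturb six metabolites and two lipid resonances at
#' fold changes between 1.2 and 2, a regime that yields informative but
#' imperfect classification.
#'
#' @param n_cases,n_controls class sizes.
#' @param effects named numeric, metabolite log fold changes (case vs
#'   control).
#' @param lipid_effects named numeric, lipid-resonance log fold changes.
#' @param biological_cv coefficient of variation of per-sample true levels.
#' @param shift_jitter_ppm SD of per-spectrum multiplet position jitter.
#' @param baseline_amplitude scale of the simulated baseline drift.
#' @param seed integer seed making the cohort reproducible.
#' @return list describing the design.
#' @export
cohortDesign <- function(n_cases = 69, n_controls = 74,
                         effects = c(lactate = log(1.8),
                                     alanine = log(1.5),
                                     glycine = log(1.25),
                                     citrate = -log(1.6),
                                     glutamate = -log(1.4),
                                     valine = -log(1.3)),
                         lipid_effects = c(lip_ch2n = log(1.5),
                                           lip_vinyl = -log(1.3)),
                         biological_cv = 0.2,
                         shift_jitter_ppm = 0.002,
                         baseline_amplitude = 1,
                         seed = 20260101) {
  stopifnot(n_cases >= 1, n_controls >= 1, biological_cv >= 0,
            shift_jitter_ppm >= 0)
  list(n_cases = n_cases, n_controls = n_controls, effects = effects,
       lipid_effects = lipid_effects, biological_cv = biological_cv,
       shift_jitter_ppm = shift_jitter_ppm,
       baseline_amplitude = baseline_amplitude, seed = seed)
}

#' Draw the ground truth for a synthetic cohort
#'
#' Per-sample metabolite concentrations are log-normal around the class mean
#' (case mean = control mean times \code{exp(effect)}) with the design's
#' coefficient of variation; lipid levels are drawn the same way per
#' resonance; per-spectrum multiplet shifts are Normal(0, jitter). The draw
#' is reproducible under the design seed and leaves the caller's RNG state
#' untouched.
#'
#' @param design a \code{\link{cohortDesign}}.
#' @param catalogue a \linkS4class{MetaboliteCatalogue}.
#' @return a \linkS4class{CohortTruth}.
#' @export
simulateCohort <- function(design, catalogue) {
  mt <- catalogue@metabolites
  lp <- catalogue@lipids
  unknown <- setdiff(names(design$effects), mt$name)
  if (length(unknown))
    stop("effect specified for metabolite(s) not in catalogue: ",
         paste(unknown, collapse = ", "))
  unknown_l <- setdiff(names(design$lipid_effects), lp$lipid_id)
  if (length(unknown_l))
    stop("effect specified for lipid resonance(s) not in catalogue: ",
         paste(unknown_l, collapse = ", "))
  n <- design$n_cases + design$n_controls
  labels <- factor(rep(c("control", "case"),
                       c(design$n_controls, design$n_cases)),
                   levels = c("control", "case"))
  cv <- design$biological_cv
  sdlog <- sqrt(log1p(cv^2))
  draw <- function(means, effects, ids) {
    lfc <- setNames(rep(0, length(ids)), ids)
    lfc[names(effects)] <- effects
    out <- matrix(0, n, length(ids), dimnames = list(NULL, ids))
    for (j in seq_along(ids)) {
      mu <- means[j] * ifelse(labels == "case", exp(lfc[j]), 1)
      out[, j] <- if (sdlog > 0)
        rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
      else mu
    }
    out
  }
  .with_seed(design$seed, {
    conc <- draw(mt$mean_conc, design$effects, mt$name)
    lip <- draw(lp$mean_level, design$lipid_effects, lp$lipid_id)
    mult_ids <- catalogue@library@multiplets$multiplet_id
    shifts <- matrix(rnorm(n * length(mult_ids), 0, design$shift_jitter_ppm),
                     n, length(mult_ids), dimnames = list(NULL, mult_ids))
    sample_ids <- sprintf("S%03d", seq_len(n))
    rownames(conc) <- rownames(lip) <- rownames(shifts) <- sample_ids
    new("CohortTruth", labels = labels, concentrations = conc,
        lipidLevels = lip, shifts = shifts, design = design)
  })
}

#' Artifact settings for spectrum synthesis
#'
#' @param water_amplitude amplitude of the (pre-suppression) water hump.
#' @param water_residual_frac fraction of the hump surviving suppression.
#' @param water_ppm,water_fwhm_hz position and width of the residual hump.
#' @param tsp_amplitude amplitude of the TSP reference singlet.
#' @param tsp_ppm where the TSP apex is placed (offset it to exercise
#'   referencing).
#' @param baseline smooth baseline drift on/off (scaled by the design's
#'   \code{baseline_amplitude}).
#' @param phi0_deg,phi1_deg zero/first-order phase error applied at the
#'   transform stage.
#' @return list of artifact settings.
#' @export
simArtifacts <- function(water_amplitude = 100, water_residual_frac = 0.01,
                         water_ppm = 4.79, water_fwhm_hz = 40,
                         tsp_amplitude = 1.5, tsp_ppm = 0.015,
                         baseline = TRUE, phi0_deg = 0, phi1_deg = 0) {
  list(water_amplitude = water_amplitude,
       water_residual_frac = water_residual_frac, water_ppm = water_ppm,
       water_fwhm_hz = water_fwhm_hz, tsp_amplitude = tsp_amplitude,
       tsp_ppm = tsp_ppm, baseline = baseline, phi0_deg = phi0_deg,
       phi1_deg = phi1_deg)
}

# accumulate damped complex exponentials: sum_k a_k exp((i 2 pi f_k - 1/T2_k) t)
.fid_peaks <- function(t, amps, freqs, t2s) {
  z <- complex(real = rep(0, length(t)))
  for (k in seq_along(amps)) {
    if (amps[k] == 0) next
    z <- z + amps[k] * exp(complex(real = -t / t2s[k],
                                   imaginary = 2 * pi * freqs[k] * t))
  }
  z
}

#' Synthesize the FID of one plasma-like sample
#'
#' Builds the time-domain signal as a sum of damped complex exponentials:
#' each multiplet contributes peaks at the frequencies implied by its centre
#' (plus the sample's jitter for that multiplet) and its J-coupling offsets,
#' with amplitudes proportional to concentration times relative intensity.
#' Lipid resonances enter as fast-decaying (broad) components. Optional
#' artifacts add a residual water hump, the TSP reference singlet, a smooth
#' baseline drift (ultra-fast-decaying components) and a recorded phase
#' error applied at the transform stage.
#'
#' @param conc named metabolite concentrations (relative units).
#' @param lipid named lipid resonance levels.
#' @param shifts named per-multiplet ppm displacements (default none).
#' @param catalogue a \linkS4class{MetaboliteCatalogue}.
#' @param acq an \code{\link{acquisitionParams}} list.
#' @param artifacts a \code{\link{simArtifacts}} list, or \code{NULL} for a
#'   clean signal.
#' @param baseline_amplitude scale of the baseline drift components.
#' @param noise logical; add complex white noise at \code{acq$noise_sd}.
#' @return a \linkS4class{Fid}.
#' @export
synthesizeFid <- function(conc, lipid = NULL, shifts = NULL, catalogue, acq,
                          artifacts = simArtifacts(), baseline_amplitude = 1,
                          noise = TRUE) {
  m <- catalogue@library@multiplets
  t <- acq$dwell_s * (seq_len(acq$n_points) - 1L)
  amps <- c(); freqs <- c(); t2s <- c()
  half_sw <- acq$spectral_width_hz / 2
  for (i in seq_len(nrow(m))) {
    cc <- conc[[m$metabolite[i]]]
    if (is.null(cc) || is.na(cc)) cc <- 0
    if (cc == 0) next
    sh <- if (!is.null(shifts) && m$multiplet_id[i] %in% names(shifts))
      shifts[[m$multiplet_id[i]]] else 0
    pk <- .multiplet_peaks(m[i, ])
    f <- (m$center_ppm[i] + sh - acq$carrier_ppm) * acq$field_mhz + pk$offset_hz
    if (any(abs(f) > half_sw))
      stop("peak frequency outside spectral width for multiplet ",
           m$multiplet_id[i])
    amps <- c(amps, cc * pk$h)
    freqs <- c(freqs, f)
    t2s <- c(t2s, rep(acq$t2_s, nrow(pk)))
  }
  if (!is.null(lipid)) {
    lp <- catalogue@lipids
    for (i in seq_len(nrow(lp))) {
      lv <- lipid[[lp$lipid_id[i]]]
      if (is.null(lv) || is.na(lv) || lv == 0) next
      amps <- c(amps, lv)
      freqs <- c(freqs, (lp$center_ppm[i] - acq$carrier_ppm) * acq$field_mhz)
      t2s <- c(t2s, 1 / (pi * lp$fwhm_hz[i]))
    }
  }
  meta <- list(synthesized = TRUE)
  if (!is.null(artifacts)) {
    if (artifacts$water_amplitude > 0 && artifacts$water_residual_frac > 0) {
      amps <- c(amps, artifacts$water_amplitude * artifacts$water_residual_frac)
      freqs <- c(freqs, (artifacts$water_ppm - acq$carrier_ppm) * acq$field_mhz)
      t2s <- c(t2s, 1 / (pi * artifacts$water_fwhm_hz))
    }
    if (artifacts$tsp_amplitude > 0) {
      amps <- c(amps, artifacts$tsp_amplitude)
      freqs <- c(freqs, (artifacts$tsp_ppm - acq$carrier_ppm) * acq$field_mhz)
      t2s <- c(t2s, 0.5)
    }
    if (isTRUE(artifacts$baseline) && baseline_amplitude > 0) {
      # ultra-fast decays render as very broad humps, i.e. baseline drift
      for (bp in c(2.5, 6.5)) {
        amps <- c(amps, 0.15 * baseline_amplitude)
        freqs <- c(freqs, (bp - acq$carrier_ppm) * acq$field_mhz)
        t2s <- c(t2s, 0.002)
      }
    }
    meta$phi0_deg <- artifacts$phi0_deg
    meta$phi1_deg <- artifacts$phi1_deg
  }
  z <- .fid_peaks(t, amps, freqs, t2s)
  if (noise && acq$noise_sd > 0)
    z <- z + complex(real = rnorm(length(t), 0, acq$noise_sd),
                     imaginary = rnorm(length(t), 0, acq$noise_sd))
  new("Fid", signal = z, dwellSec = acq$dwell_s, fieldMHz = acq$field_mhz,
      carrierPpm = acq$carrier_ppm, meta = meta)
}

#' Write a simulated cohort to disk
#'
#' Synthesizes one file per sample (frequency-domain \code{ppm,intensity}
#' spectra or time-domain \code{t,re,im} FIDs) plus a cohort manifest CSV
#' with columns \code{sample_id,label,path,field_mhz}. The ground truth is
#' stored alongside for testing.
#'
#' @param truth a \linkS4class{CohortTruth}.
#' @param catalogue the \linkS4class{MetaboliteCatalogue} used to draw it.
#' @param dir output directory (created if needed).
#' @param acq acquisition parameters.
#' @param artifacts artifact settings (see \code{\link{simArtifacts}}).
#' @param format "fid" (default) or "spectrum" (transformed with default
#'   settings, no phase error).
#' @return the manifest data.frame, invisibly written to
#'   \code{dir/manifest.csv}.
#' @export
writeCohort <- function(truth, catalogue, dir,
                        acq = acquisitionParams(),
                        artifacts = simArtifacts(), format = c("fid", "spectrum")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(truth@labels)
  ids <- rownames(truth@concentrations)
  paths <- character(n)
  .with_seed(truth@design$seed + 1L, {
    for (i in seq_len(n)) {
      fid <- synthesizeFid(conc = truth@concentrations[i, ],
                           lipid = truth@lipidLevels[i, ],
                           shifts = truth@shifts[i, ],
                           catalogue = catalogue, acq = acq,
                           artifacts = artifacts,
                           baseline_amplitude = truth@design$baseline_amplitude)
      if (format == "fid") {
        paths[i] <- file.path(dir, paste0(ids[i], "_fid.csv"))
        writeFidFile(fid, paths[i])
      } else {
        sp <- zeroFillTransform(fid)
        paths[i] <- file.path(dir, paste0(ids[i], "_spec.csv"))
        writeSpectrumFile(sp, paths[i])
      }
    }
  })
  manifest <- data.frame(sample_id = ids, label = as.character(truth@labels),
                         path = paths, field_mhz = acq$field_mhz,
                         stringsAsFactors = FALSE)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(data.frame(sample_id = ids, truth@concentrations),
            file.path(dir, "truth_concentrations.csv"), row.names = FALSE)
  write.csv(data.frame(sample_id = ids, truth@lipidLevels),
            file.path(dir, "truth_lipid_levels.csv"), row.names = FALSE)
  manifest
}

#' Plain-text spectrum and FID file I/O
#'
#' Spectrum files are two-column CSV \code{ppm,intensity} with a strictly
#' descending ppm axis; FID files are three-column CSV \code{t,re,im}.
#'
#' @param path file path.
#' @param field_mhz,carrier_ppm acquisition metadata not stored in the FID
#'   file itself.
#' @return \code{readSpectrumFile}: an \linkS4class{NMRSpectrum};
#'   \code{readFidFile}: a \linkS4class{Fid}.
#' @name spectrum-io
NULL

#' @rdname spectrum-io
#' @param spectrum an \linkS4class{NMRSpectrum}.
#' @export
writeSpectrumFile <- function(spectrum, path) {
  write.csv(data.frame(ppm = spectrum@ppm, intensity = spectrum@intensity),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname spectrum-io
#' @export
readSpectrumFile <- function(path, field_mhz = NA_real_) {
  d <- read.csv(path)
  new("NMRSpectrum", ppm = d$ppm, intensity = d$intensity,
      cplx = complex(0), mask = rep(FALSE, nrow(d)), fieldMHz = field_mhz,
      meta = list(source = path))
}

#' @rdname spectrum-io
#' @param fid a \linkS4class{Fid}.
#' @export
writeFidFile <- function(fid, path) {
  t <- fid@dwellSec * (seq_along(fid@signal) - 1L)
  write.csv(data.frame(t = t, re = Re(fid@signal), im = Im(fid@signal)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname spectrum-io
#' @export
readFidFile <- function(path, field_mhz, carrier_ppm = 4.75) {
  d <- read.csv(path)
  new("Fid", signal = complex(real = d$re, imaginary = d$im),
      dwellSec = d$t[2] - d$t[1], fieldMHz = field_mhz,
      carrierPpm = carrier_ppm, meta = list(source = path))
}

#' @rdname spectrum-io
#' @export
readManifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "label", "path", "field_mhz")
  if (!all(req %in% names(m)))
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  m
}
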