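# shared in-code fixtures; everything is generated, nothing is stored

# descending ppm axis mimicking a transformed spectrum
fix_axis <- function(n = 4096, field = 400, sw_hz = 6000, carrier = 4.75) {
  f <- (seq_len(n) - 1 - n / 2) / n * sw_hz
  rev(carrier + f / field)
}

fix_spectrum <- function(y, ppm, field = 400, cplx = complex(0)) {
  new("NMRSpectrum", ppm = ppm, intensity = y, cplx = cplx,
      mask = rep(FALSE, length(ppm)), fieldMHz = field, meta = list())
}

# spectrum made of Lorentzians with the given total areas (ppm units)
fix_lorentz_spectrum <- function(centers, areas, fwhm_ppm = 0.006,
                                 n = 4096, field = 400) {
  ppm <- fix_axis(n, field)
  y <- rep(0, n)
  for (i in seq_along(centers))
    y <- y + areas[i] * nmrsigex:::lorentzian(ppm, centers[i], fwhm_ppm)
  fix_spectrum(y, ppm, field)
}

# minimal multiplet table row constructor
fix_multiplet <- function(metabolite, id, center, pattern = "singlet",
                          j = numeric(), protons = 1L, h = numeric(),
                          tol = 0.005) {
  out <- data.frame(metabolite = metabolite, multiplet_id = id,
                    center_ppm = center, pattern = pattern,
                    protons = protons, shift_tolerance_ppm = tol,
                    stringsAsFactors = FALSE)
  out$j_hz <- list(j)
  out$rel_intensities <- list(h)
  out
}

fix_library <- function(rows, field = 400) {
  new("TemplateLibrary", multiplets = do.call(rbind, rows), rasters = list(),
      fieldMHz = field)
}

# tiny user catalogue built from a library (equal unit mean concentrations)
fix_catalogue <- function(lib, mean_conc = NULL, lipids = NULL) {
  mets <- unique(lib@multiplets$metabolite)
  if (is.null(mean_conc)) mean_conc <- rep(1, length(mets))
  mt <- data.frame(name = mets,
                   protons_total = vapply(mets, function(nm)
                     as.integer(sum(lib@multiplets$protons[
                       lib@multiplets$metabolite == nm])), integer(1)),
                   mean_conc = mean_conc,
                   in_classification = TRUE, stringsAsFactors = FALSE)
  if (is.null(lipids))
    lipids <- data.frame(lipid_id = character(), label = character(),
                         center_ppm = numeric(), fwhm_hz = numeric(),
                         mean_level = numeric())
  new("MetaboliteCatalogue", library = lib, metabolites = mt, lipids = lipids)
}

# labelled gaussian feature matrix with optional mean shifts on some columns
fix_features <- function(n_case = 20, n_control = 20, p = 10,
                         shift = numeric(p), sd = 1, seed = 1) {
  set.seed(seed)
  labels <- factor(rep(c("control", "case"), c(n_control, n_case)),
                   levels = c("control", "case"))
  X <- matrix(rnorm((n_case + n_control) * p, 0, sd), ncol = p,
              dimnames = list(sprintf("S%03d", seq_len(n_case + n_control)),
                              sprintf("F%02d", seq_len(p))))
  X[labels == "case", ] <- X[labels == "case", ] +
    matrix(shift, nrow = n_case, ncol = p, byrow = TRUE)
  makeFeatureMatrix(X, labels)
}
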