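#' Proton-normalized relative peak intensities for an empirical multiplet
#'
#' Multiplets that exhibit second-order roofing/leaning are described
#' empirically by the observed peak intensities of a pure-compound (or
#' spiked) spectrum, rescaled so that they sum to the number of resonating
#' protons: \eqn{h_i = p \, y_i / \sum_j y_j}. A citrate doublet arising from
#' a CH2 group (two protons) with observed intensities in ratio 3:2 yields
#' relative intensities 1.2 and 0.8.
#'
#' @param y observed peak intensities (all positive).
#' @param p number of protons associated with the multiplet.
#' @return numeric vector \code{h} with \code{sum(h) == p}.
#' @export
#' @examples
#' relativeIntensities(c(0.6, 0.4), p = 2)  # 1.2 0.8
relativeIntensities <- function(y, p) {
  if (any(!is.finite(y)) || any(y <= 0))
    stop("all observed intensities must be positive")
  if (length(p) != 1L || p < 1 || p != round(p))
    stop("p must be a positive integer proton count")
  p * y / sum(y)
}

#' Peak offsets and binomial intensity ratios for first-order patterns
#'
#' First-order J-coupling patterns place peaks symmetrically about the
#' multiplet centre at offsets determined by the coupling constants: a
#' doublet at \eqn{\pm J/2}, a triplet at \eqn{(-J, 0, +J)} with 1:2:1
#' intensities, a quartet at \eqn{\pm 3J/2, \pm J/2} (1:3:3:1) and a double
#' doublet at \eqn{\pm(J_1+J_2)/2} and \eqn{\pm(J_1-J_2)/2} — the outermost
#' peak sits half the sum of the two couplings away from the centre. The
#' returned intensity ratios are the defaults; empirical ratios from
#' \code{\link{relativeIntensities}} override them to model roofing.
#'
#' @param pattern one of \code{"singlet"}, \code{"doublet"}, \code{"triplet"},
#'   \code{"quartet"}, \code{"double_doublet"}.
#' @param j_hz coupling constant(s) in Hz; none for a singlet, one for
#'   doublet/triplet/quartet, two for a double doublet.
#' @return list with \code{offsets_hz} (ascending) and \code{ratios}
#'   (normalized to sum to 1).
#' @export
#' @examples
#' patternOffsets("double_doublet", c(8, 4))$offsets_hz  # -6 -2  2  6
patternOffsets <- function(pattern, j_hz = numeric()) {
  pattern <- match.arg(pattern, c("singlet", "doublet", "triplet", "quartet",
                                  "double_doublet"))
  need <- c(singlet = 0L, doublet = 1L, triplet = 1L, quartet = 1L,
            double_doublet = 2L)[[pattern]]
  if (length(j_hz) != need)
    stop(sprintf("pattern '%s' requires %d coupling constant(s), got %d",
                 pattern, need, length(j_hz)))
  res <- switch(pattern,
    singlet = list(offsets_hz = 0, ratios = 1),
    doublet = list(offsets_hz = c(-1, 1) * j_hz / 2, ratios = c(1, 1) / 2),
    triplet = list(offsets_hz = c(-j_hz, 0, j_hz), ratios = c(1, 2, 1) / 4),
    quartet = list(offsets_hz = c(-3, -1, 1, 3) * j_hz / 2,
                   ratios = c(1, 3, 3, 1) / 8),
    double_doublet = {
      s <- sum(j_hz) / 2; d <- abs(diff(j_hz)) / 2
      list(offsets_hz = c(-s, -d, d, s), ratios = rep(0.25, 4))
    })
  ord <- order(res$offsets_hz)
  list(offsets_hz = res$offsets_hz[ord], ratios = res$ratios[ord])
}

#' Lorentzian line with unit area
#'
#' @param x evaluation points.
#' @param x0 centre.
#' @param fwhm full width at half maximum (same units as \code{x}).
#' @return intensities integrating to 1 over the real line.
#' @keywords internal
lorentzian <- function(x, x0, fwhm) {
  g <- fwhm / 2
  (g / pi) / ((x - x0)^2 + g^2)
}

.unwrap <- function(x) if (is.list(x)) x[[1]] else x

.multiplet_peaks <- function(spec_row) {
  # spec_row: one-row slice of a TemplateLibrary multiplets data.frame
  po <- patternOffsets(spec_row$pattern, .unwrap(spec_row$j_hz))
  h <- .unwrap(spec_row$rel_intensities)
  if (!length(h)) h <- po$ratios * spec_row$protons
  if (length(h) != length(po$offsets_hz))
    stop(sprintf("multiplet '%s': %d relative intensities for %d peaks",
                 spec_row$multiplet_id, length(h), length(po$offsets_hz)))
  data.frame(offset_hz = po$offsets_hz, h = h)
}

#' Discretize a multiplet template on a ppm grid
#'
#' Renders one multiplet as a sum of Lorentzians centred at
#' \code{center_ppm + offset_hz / field_mhz}, with heights proportional to the
#' relative intensities and a common linewidth, then rescales so the total
#' area (trapezoid rule on the grid) equals the proton count. Raster
#' multiplets are interpolated from their stored curve instead, shifted to
#' the requested centre.
#'
#' @param spec a one-row multiplet specification (a slice of
#'   \code{multiplets(library)}) or a list with the same fields.
#' @param grid_ppm ppm axis (ascending or descending) to discretize on.
#' @param field_mhz spectrometer frequency (MHz), used to convert Hz offsets
#'   to ppm.
#' @param fwhm_hz Lorentzian full width at half maximum (Hz).
#' @param shift_ppm optional local displacement added to the centre.
#' @return numeric intensities on \code{grid_ppm} whose trapezoid integral is
#'   the multiplet's proton count.
#' @export
buildTemplate <- function(spec, grid_ppm, field_mhz, fwhm_hz = 1.5,
                          shift_ppm = 0) {
  if (is.data.frame(spec)) {
    stopifnot(nrow(spec) == 1L)
    spec <- as.list(spec)
  }
  asc <- grid_ppm
  rev_out <- FALSE
  if (length(asc) > 1 && asc[2] < asc[1]) { asc <- rev(asc); rev_out <- TRUE }
  centre <- spec$center_ppm + shift_ppm
  if (identical(spec$pattern, "raster")) {
    ras <- .unwrap(spec$raster)
    if (is.null(ras)) stop("raster multiplet without a raster curve")
    y <- approx(ras$ppm - mean(range(ras$ppm)) + centre, ras$intensity,
                xout = asc, yleft = 0, yright = 0)$y
  } else {
    pk <- .multiplet_peaks(spec)
    fw_ppm <- fwhm_hz / field_mhz
    pos <- centre + pk$offset_hz / field_mhz
    if (any(pos < min(asc)) || any(pos > max(asc)))
      stop(sprintf("multiplet '%s' has peaks outside the grid",
                   spec$multiplet_id))
    y <- rep(0, length(asc))
    for (i in seq_along(pos))
      y <- y + pk$h[i] * lorentzian(asc, pos[i], fw_ppm)
  }
  area <- pracma::trapz(asc, y)
  if (area <= 0) stop("template has non-positive area on the grid")
  y <- y * (spec$protons / area)
  if (rev_out) rev(y) else y
}

#' Build a raster template from a measured spectrum segment
#'
#' Complex multiplets whose coupling pattern cannot be written down as a
#' first-order formula can be represented non-parametrically by a segment of
#' a pure-compound (or spiked) spectrum. The segment is clipped at zero and
#' rescaled so its area equals the proton count.
#'
#' @param spectrum an \linkS4class{NMRSpectrum} (baseline corrected).
#' @param ppm_window numeric length-2, the window to cut (any order).
#' @param p proton count the raster represents.
#' @param metabolite,multiplet_id identifiers for the resulting entry.
#' @param shift_tolerance_ppm allowed local displacement when fitting.
#' @return a one-row multiplets data.frame (with the raster attached as a
#'   list column) suitable for \code{rbind}-ing into a library.
#' @export
loadRaster <- function(spectrum, ppm_window, p, metabolite = "raster",
                       multiplet_id = paste0(metabolite, "_raster"),
                       shift_tolerance_ppm = 0.005) {
  stopifnot(is(spectrum, "NMRSpectrum"), length(ppm_window) == 2L)
  lo <- min(ppm_window); hi <- max(ppm_window)
  sel <- spectrum@ppm >= lo & spectrum@ppm <= hi
  if (sum(sel) < 3L) stop("ppm window contains fewer than 3 points")
  x <- rev(spectrum@ppm[sel])
  y <- pmax(rev(spectrum@intensity[sel]), 0)
  area <- pracma::trapz(x, y)
  if (area <= 0) stop("segment is all zero after clipping at 0")
  ras <- data.frame(ppm = x, intensity = y * p / area)
  out <- data.frame(metabolite = metabolite, multiplet_id = multiplet_id,
                    center_ppm = mean(c(lo, hi)), pattern = "raster",
                    protons = p, shift_tolerance_ppm = shift_tolerance_ppm,
                    stringsAsFactors = FALSE)
  out$j_hz <- list(numeric())
  out$rel_intensities <- list(numeric())
  out$raster <- list(ras)
  out
}

.parse_semi <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(numeric())
  as.numeric(strsplit(trimws(x), ";")[[1]])
}

.fmt_semi <- function(v) paste(format(v, digits = 10, trim = TRUE),
                               collapse = ";")

#' Read / write a multiplet template library as CSV
#'
#' The CSV dialect has one row per multiplet with columns
#' \code{metabolite,multiplet_id,center_ppm,pattern,j_hz,protons,rel_intensities,raster_file,shift_tolerance_ppm};
#' \code{j_hz} and \code{rel_intensities} are semicolon-separated lists, the
#' latter optional (defaulted from the first-order pattern ratios). Raster
#' curves are stored in side files of two columns \code{ppm,intensity}.
#'
#' @param path CSV file path.
#' @param field_mhz field strength to record in the library.
#' @return \code{readTemplateCsv}: a \linkS4class{TemplateLibrary}.
#' @export
readTemplateCsv <- function(path, field_mhz = NA_real_) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("metabolite", "multiplet_id", "center_ppm", "pattern", "j_hz",
           "protons")
  if (!all(req %in% names(raw)))
    stop("template CSV must have columns: ", paste(req, collapse = ", "))
  if (!"rel_intensities" %in% names(raw)) raw$rel_intensities <- ""
  if (!"shift_tolerance_ppm" %in% names(raw))
    raw$shift_tolerance_ppm <- 0.005
  if (!"raster_file" %in% names(raw)) raw$raster_file <- ""
  n <- nrow(raw)
  j <- lapply(raw$j_hz, .parse_semi)
  h <- lapply(raw$rel_intensities, .parse_semi)
  rasters <- list()
  for (i in seq_len(n)) {
    need <- c(singlet = 0L, doublet = 1L, triplet = 1L, quartet = 1L,
              double_doublet = 2L, raster = 0L)[[raw$pattern[i]]]
    if (is.null(need))
      stop(sprintf("row %d: unknown pattern '%s'", i, raw$pattern[i]))
    if (raw$pattern[i] != "raster" && length(j[[i]]) != need)
      stop(sprintf("row %d (%s): pattern '%s' requires %d J value(s), got %d",
                   i, raw$multiplet_id[i], raw$pattern[i], need,
                   length(j[[i]])))
    if (length(h[[i]]) && abs(sum(h[[i]]) - raw$protons[i]) > 1e-6)
      stop(sprintf("row %d (%s): relative intensities sum to %g, not protons %d",
                   i, raw$multiplet_id[i], sum(h[[i]]), raw$protons[i]))
    if (raw$pattern[i] == "raster") {
      rf <- raw$raster_file[i]
      if (!nzchar(rf)) stop(sprintf("row %d: raster multiplet needs raster_file", i))
      rp <- if (file.exists(rf)) rf else file.path(dirname(path), rf)
      rasters[[raw$multiplet_id[i]]] <- read.csv(rp)
    }
  }
  m <- raw[, c("metabolite", "multiplet_id", "center_ppm", "pattern",
               "protons", "shift_tolerance_ppm")]
  m$j_hz <- j
  m$rel_intensities <- h
  new("TemplateLibrary", multiplets = m, rasters = rasters,
      fieldMHz = field_mhz)
}

#' @rdname readTemplateCsv
#' @param lib a \linkS4class{TemplateLibrary}.
#' @export
writeTemplateCsv <- function(lib, path) {
  m <- lib@multiplets
  out <- data.frame(
    metabolite = m$metabolite,
    multiplet_id = m$multiplet_id,
    center_ppm = m$center_ppm,
    pattern = m$pattern,
    j_hz = vapply(m$j_hz, .fmt_semi, character(1)),
    protons = m$protons,
    rel_intensities = vapply(m$rel_intensities, .fmt_semi, character(1)),
    raster_file = "",
    shift_tolerance_ppm = m$shift_tolerance_ppm,
    stringsAsFactors = FALSE)
  for (id in names(lib@rasters)) {
    rf <- paste0("raster_", id, ".csv")
    write.csv(lib@rasters[[id]], file.path(dirname(path), rf),
              row.names = FALSE)
    out$raster_file[out$multiplet_id == id] <- rf
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
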