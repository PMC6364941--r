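# trapezoid integral on a descending-ppm spectrum honouring the mask:
# intervals touching a masked point contribute nothing
.trapz_masked <- function(ppm_desc, y, mask = NULL) {
  x <- rev(ppm_desc); v <- rev(y)
  keep_pt <- if (is.null(mask)) rep(TRUE, length(v)) else rev(!mask)
  dx <- diff(x)
  ok <- keep_pt[-length(v)] & keep_pt[-1]
  sum(dx[ok] * (v[-length(v)][ok] + v[-1][ok]) / 2)
}

.log_step <- function(meta, name, value = TRUE) {
  meta[[name]] <- value
  meta
}

#' Exponential apodization (line broadening)
#'
#' Multiplies FID sample \eqn{k} by \eqn{\exp(-\pi \cdot lb \cdot t_k)},
#' which convolves the spectrum with a Lorentzian of width \code{lb_hz},
#' trading resolution for signal-to-noise. The protocol default is 0.7 Hz.
#'
#' @param fid a \linkS4class{Fid}.
#' @param lb_hz line broadening in Hz (>= 0); 0 is the identity.
#' @return the apodized \linkS4class{Fid}.
#' @export
apodize <- function(fid, lb_hz = 0.7) {
  stopifnot(is(fid, "Fid"), lb_hz >= 0)
  t <- fid@dwellSec * (seq_along(fid@signal) - 1L)
  fid@signal <- fid@signal * exp(-pi * lb_hz * t)
  fid@meta <- .log_step(fid@meta, "apodize_lb_hz", lb_hz)
  fid
}

#' Zero-fill and Fourier transform a FID
#'
#' Pads the FID with zeros to \code{zero_fill_to} points (default: the next
#' power of two at least twice the acquired length, which halves the
#' frequency-domain point spacing), applies the discrete Fourier transform
#' scaled by the dwell time, and maps the frequency axis to chemical shift
#' via \eqn{ppm = carrier + f / field}. Any phase error recorded on the FID
#' (synthetic acquisition artifact) is applied to the complex spectrum here;
#' the result still needs phasing before the real part is a pure absorption
#' spectrum.
#'
#' @param fid a \linkS4class{Fid}.
#' @param zero_fill_to target length (power of two, >= length of the FID).
#' @return an \linkS4class{NMRSpectrum} retaining its complex representation.
#' @export
zeroFillTransform <- function(fid, zero_fill_to = NULL) {
  stopifnot(is(fid, "Fid"))
  n0 <- length(fid@signal)
  if (is.null(zero_fill_to)) zero_fill_to <- 2^ceiling(log2(2 * n0))
  if (zero_fill_to < n0)
    stop("zero_fill_to must be at least the acquired length ", n0)
  if (abs(log2(zero_fill_to) - round(log2(zero_fill_to))) > 1e-9)
    stop("zero_fill_to must be a power of two")
  z <- c(fid@signal, complex(real = rep(0, zero_fill_to - n0)))
  N <- zero_fill_to
  Z <- fft(z) * fid@dwellSec
  # ascending frequency axis: negative half first
  Z <- c(Z[(N / 2 + 1):N], Z[1:(N / 2)])
  f <- (seq_len(N) - 1 - N / 2) / (N * fid@dwellSec)
  ppm_asc <- fid@carrierPpm + f / fid@fieldMHz
  # descending storage order
  Z <- rev(Z); ppm <- rev(ppm_asc)
  meta <- .log_step(fid@meta, "transform", list(n_acquired = n0, n_fft = N))
  sp <- new("NMRSpectrum", ppm = ppm, intensity = Re(Z), cplx = Z,
            mask = rep(FALSE, N), fieldMHz = fid@fieldMHz, meta = meta)
  phi0 <- fid@meta$phi0_deg; phi1 <- fid@meta$phi1_deg
  if (!is.null(phi0) && (phi0 != 0 || (!is.null(phi1) && phi1 != 0))) {
    # inject the recorded acquisition phase error (inverse of phaseCorrect)
    frac <- (sp@ppm - mean(range(sp@ppm))) / diff(range(sp@ppm))
    rot <- exp(1i * (phi0 + if (is.null(phi1)) 0 else phi1 * frac) * pi / 180)
    sp@cplx <- sp@cplx * rot
    sp@intensity <- Re(sp@cplx)
  }
  sp
}

#' Zero- and first-order phase correction
#'
#' Rotates the complex spectrum by
#' \eqn{\exp(-i(\phi_0 + \phi_1 (x - x_{pivot})/span))} and takes the real
#' part as the new intensity. \code{autophase} searches for the angles that
#' minimize the squared negative-intensity penalty
#' \eqn{\sum \min(I, 0)^2}, the criterion that a well-phased absorption
#' spectrum is non-negative up to noise and baseline.
#'
#' @param spectrum an \linkS4class{NMRSpectrum} retaining its complex
#'   representation.
#' @param phi0_deg,phi1_deg zero/first-order angles in degrees.
#' @param pivot_ppm pivot for the first-order term (default: axis centre).
#' @return \code{phaseCorrect}: the phased \linkS4class{NMRSpectrum};
#'   \code{autophase}: list with \code{spectrum}, \code{phi0_deg},
#'   \code{phi1_deg}.
#' @export
phaseCorrect <- function(spectrum, phi0_deg, phi1_deg = 0, pivot_ppm = NULL) {
  stopifnot(is(spectrum, "NMRSpectrum"))
  if (!length(spectrum@cplx))
    stop("spectrum no longer holds a complex representation; phase before baseline/normalization")
  if (is.null(pivot_ppm)) pivot_ppm <- mean(range(spectrum@ppm))
  frac <- (spectrum@ppm - pivot_ppm) / diff(range(spectrum@ppm))
  rot <- exp(-1i * (phi0_deg + phi1_deg * frac) * pi / 180)
  spectrum@cplx <- spectrum@cplx * rot
  spectrum@intensity <- Re(spectrum@cplx)
  spectrum@meta <- .log_step(spectrum@meta, "phase",
                             c(phi0 = phi0_deg, phi1 = phi1_deg))
  spectrum
}

#' @rdname phaseCorrect
#' @export
autophase <- function(spectrum) {
  stopifnot(is(spectrum, "NMRSpectrum"))
  obj <- function(phi) {
    s <- phaseCorrect(spectrum, phi[1], phi[2])
    sum(pmin(s@intensity, 0)^2)
  }
  best <- NULL
  for (start0 in c(0, 90, 180, 270)) {
    fit <- optim(c(start0, 0), obj, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (best$convergence != 0)
    warning("autophase did not fully converge; returning best angles found")
  phi <- best$par
  phi[1] <- ((phi[1] + 180) %% 360) - 180
  list(spectrum = phaseCorrect(spectrum, phi[1], phi[2]),
       phi0_deg = phi[1], phi1_deg = phi[2])
}

# asymmetric-least-squares baseline: penalized smooth curve with weight
# `asymmetry` above the baseline and 1 - asymmetry below it
.asls_baseline <- function(y, asymmetry, smoothness, max_iter = 20) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  P <- smoothness * Matrix::crossprod(D)
  w <- rep(1, n)
  b <- y
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    W <- Matrix::Diagonal(n, w)
    b_new <- as.numeric(Matrix::solve(W + P, w * y))
    w_new <- ifelse(y > b_new, asymmetry, 1 - asymmetry)
    # a handful of points flickering across the baseline is convergence in
    # practice; insisting on exact weight stability cycles forever
    done <- sum(w_new != w) <= max(1, 5e-3 * n)
    b <- b_new; w <- w_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged)
    warning("baseline correction reached the iteration limit; using last iterate")
  b
}

#' Asymmetric-least-squares baseline correction
#'
#' Estimates a smooth baseline with asymmetric weights (small weight
#' \code{asymmetry} where the residual is positive, i.e. under peaks, and
#' \code{1 - asymmetry} elsewhere), iterated to convergence, and subtracts
#' it. A small asymmetry (protocol value 0.01) keeps the number of spectral
#' points with negative intensities to a minimum; the fraction of negative
#' points after correction is recorded in the processing log.
#'
#' @param spectrum an \linkS4class{NMRSpectrum}.
#' @param asymmetry weight in (0, 1) for points above the baseline.
#' @param smoothness roughness penalty lambda on the second differences;
#'   \code{NULL} picks \code{2e9 * (n/8192)^4}, which keeps the baseline's
#'   physical stiffness constant across axis lengths (the index-space
#'   second-difference penalty scales as the fourth power of the point
#'   count).
#' @param max_iter iteration cap for the reweighting loop.
#' @return the baseline-corrected \linkS4class{NMRSpectrum} (the complex
#'   representation is dropped).
#' @export
baselineCorrect <- function(spectrum, asymmetry = 0.01, smoothness = NULL,
                            max_iter = 30) {
  stopifnot(is(spectrum, "NMRSpectrum"), asymmetry > 0, asymmetry < 1)
  if (is.null(smoothness))
    smoothness <- 2e9 * (length(spectrum@intensity) / 8192)^4
  b <- .asls_baseline(spectrum@intensity, asymmetry, smoothness, max_iter)
  spectrum@intensity <- spectrum@intensity - b
  spectrum@cplx <- complex(0)
  spectrum@meta <- .log_step(spectrum@meta, "baseline",
                             list(asymmetry = asymmetry,
                                  smoothness = smoothness,
                                  negative_fraction =
                                    mean(spectrum@intensity < 0)))
  spectrum
}

# parabolic interpolation of an apex given the discrete maximum and its
# neighbours; returns the sub-step offset in index units
.parabolic_offset <- function(y_m1, y_0, y_p1) {
  den <- y_m1 - 2 * y_0 + y_p1
  if (den == 0) return(0)
  0.5 * (y_m1 - y_p1) / den
}

#' Reference the chemical-shift axis to the TSP singlet
#'
#' Locates the TSP apex in a search window around 0 ppm (parabolic
#' interpolation of the discrete maximum) and translates the ppm axis so the
#' apex sits at the target position, 0.015 ppm by convention for plasma.
#'
#' @param spectrum an \linkS4class{NMRSpectrum}.
#' @param tsp_target_ppm where the apex should end up.
#' @param search_window ppm interval to look in.
#' @param snr_min minimum apex height in robust noise units; below it the
#'   reference peak is declared undetectable.
#' @return the re-referenced \linkS4class{NMRSpectrum}; the applied shift is
#'   recorded in the processing log.
#' @export
referenceToTsp <- function(spectrum, tsp_target_ppm = 0.015,
                           search_window = c(-0.2, 0.2), snr_min = 5) {
  stopifnot(is(spectrum, "NMRSpectrum"))
  sel <- which(spectrum@ppm >= min(search_window) &
               spectrum@ppm <= max(search_window))
  if (length(sel) < 3L) stop("TSP search window outside the spectrum axis")
  y <- spectrum@intensity[sel]
  noise <- mad(y)
  i <- which.max(y)
  if (noise > 0 && (y[i] - median(y)) / noise < snr_min)
    stop("no peak apex above the noise threshold in the TSP search window")
  i_glob <- sel[i]
  off <- if (i_glob > 1 && i_glob < length(spectrum@ppm))
    .parabolic_offset(spectrum@intensity[i_glob - 1], spectrum@intensity[i_glob],
                      spectrum@intensity[i_glob + 1]) else 0
  step <- spectrum@ppm[i_glob] - spectrum@ppm[min(i_glob + 1, length(spectrum@ppm))]
  apex <- spectrum@ppm[i_glob] - off * step  # descending axis: +index = -ppm
  shift <- apex - tsp_target_ppm
  spectrum@ppm <- spectrum@ppm - shift
  spectrum@meta <- .log_step(spectrum@meta, "reference",
                             c(shift_ppm = shift, apex_ppm = apex))
  spectrum
}

#' Mask spectral windows from downstream analysis
#'
#' Marks the points inside the given ppm windows (typically the residual
#' water region and the TSP region) as excluded; masked points contribute
#' nothing to normalization or region integration.
#'
#' @param spectrum an \linkS4class{NMRSpectrum}.
#' @param windows list of length-2 numeric vectors (ppm intervals).
#' @return the spectrum with an updated exclusion mask.
#' @export
excludeRegions <- function(spectrum,
                           windows = list(c(4.50, 5.10), c(-0.20, 0.20))) {
  stopifnot(is(spectrum, "NMRSpectrum"))
  for (w in windows) {
    stopifnot(length(w) == 2L)
    spectrum@mask <- spectrum@mask |
      (spectrum@ppm >= min(w) & spectrum@ppm <= max(w))
  }
  if (all(spectrum@mask)) stop("masking removed the entire axis")
  spectrum@meta <- .log_step(spectrum@meta, "excluded_windows", windows)
  spectrum
}

#' Normalize a spectrum
#'
#' \code{"total_area_excluding"} divides by the trapezoid area over unmasked
#' points (the manual-protocol normalization, computed without the water and
#' TSP signal once those windows are masked); \code{"median"} divides by the
#' median positive intensity. The constant is stored in the processing log.
#'
#' @param spectrum an \linkS4class{NMRSpectrum}.
#' @param method normalization method.
#' @return the normalized \linkS4class{NMRSpectrum}.
#' @export
normalizeSpectrum <- function(spectrum,
                              method = c("total_area_excluding", "median")) {
  method <- match.arg(method)
  stopifnot(is(spectrum, "NMRSpectrum"))
  const <- switch(method,
    total_area_excluding = .trapz_masked(spectrum@ppm, spectrum@intensity,
                                         spectrum@mask),
    median = median(spectrum@intensity[spectrum@intensity > 0]))
  if (!is.finite(const) || const <= 0)
    stop("normalization constant is not positive")
  spectrum@intensity <- spectrum@intensity / const
  spectrum@cplx <- complex(0)
  spectrum@meta <- .log_step(spectrum@meta, "normalize",
                             list(method = method, constant = const))
  spectrum
}

# warp one spectrum onto a reference with a piecewise-linear monotone ppm map
.warp_one <- function(y, ref, x_asc, segments, max_shift_pts) {
  n <- length(y)
  bounds <- round(seq(1, n + 1, length.out = segments + 1))
  shifts <- numeric(segments)
  cand <- -max_shift_pts:max_shift_pts
  for (s in seq_len(segments)) {
    i0 <- bounds[s]; i1 <- bounds[s + 1] - 1
    seg_ref <- ref[i0:i1]
    if (sd(seg_ref) == 0) { shifts[s] <- 0; next }
    best <- 0; best_cor <- -Inf
    for (d in cand) {
      j0 <- i0 + d; j1 <- i1 + d
      if (j0 < 1 || j1 > n) next
      seg <- y[j0:j1]
      if (sd(seg) == 0) next
      r <- sum((seg - mean(seg)) * (seg_ref - mean(seg_ref)))
      r <- r / (sd(seg) * sd(seg_ref))
      if (r > best_cor) { best_cor <- r; best <- d }
    }
    shifts[s] <- best
  }
  # node shifts: mean of adjacent segment shifts, clamped so the map stays
  # strictly monotone
  node_idx <- bounds
  node_shift <- c(shifts[1],
                  (shifts[-segments] + shifts[-1]) / 2,
                  shifts[segments])
  pos <- node_idx + node_shift
  pos <- cummax_strict(pos)
  map <- approx(node_idx, pos, xout = seq_len(n), rule = 2)$y
  approx(seq_len(n), y, xout = map, rule = 2)$y
}

# enforce strict monotonicity with a minimal forward adjustment
cummax_strict <- function(x, eps = 1e-6) {
  for (i in seq_along(x)[-1]) if (x[i] <= x[i - 1]) x[i] <- x[i - 1] + eps
  x
}

#' Align spectra by piecewise-linear warping
#'
#' Each spectrum is warped onto a reference by a strictly monotone
#' piecewise-linear map of the ppm axis, with per-segment shifts chosen to
#' maximize the local correlation with the reference. Under the
#' \code{"after"} reference policy every candidate reference is tried and
#' the one minimizing the total post-warp sum of squared differences is
#' kept; \code{"fixed"} uses the supplied reference index. Groups (e.g. the
#' two cohorts) may be warped separately.
#'
#' @param spectra list of \linkS4class{NMRSpectrum} objects on a common axis.
#' @param policy reference selection policy.
#' @param reference index of the reference when \code{policy = "fixed"}.
#' @param segments number of piecewise-linear segments.
#' @param max_shift_ppm largest per-node displacement allowed.
#' @param groups optional factor; warping is performed separately per level.
#' @param candidates maximum number of (evenly spaced) spectra tried as
#'   reference under the \code{"after"} policy; \code{NULL} tries every
#'   spectrum. Restricting the candidate set trades reference optimality for
#'   speed on large cohorts.
#' @return list with \code{spectra} (warped), \code{reference} (chosen
#'   index/indices), \code{ssd_before}, \code{ssd_after}.
#' @export
warpAlign <- function(spectra, policy = c("after", "fixed"), reference = 1L,
                      segments = 64, max_shift_ppm = 0.01, groups = NULL,
                      candidates = NULL) {
  policy <- match.arg(policy)
  stopifnot(length(spectra) >= 2L)
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    stopifnot(length(groups) == length(spectra))
    out <- spectra; refs <- integer(0); sb <- sa <- 0
    for (g in levels(groups)) {
      idx <- which(groups == g)
      if (length(idx) < 2L) next
      w <- warpAlign(spectra[idx], policy = policy, reference = 1L,
                     segments = segments, max_shift_ppm = max_shift_ppm,
                     candidates = candidates)
      out[idx] <- w$spectra
      refs <- c(refs, idx[w$reference])
      sb <- sb + w$ssd_before; sa <- sa + w$ssd_after
    }
    return(list(spectra = out, reference = refs, ssd_before = sb,
                ssd_after = sa))
  }
  x_desc <- spectra[[1]]@ppm
  for (s in spectra)
    if (!isTRUE(all.equal(s@ppm, x_desc)))
      stop("all spectra must share a common ppm axis")
  x_asc <- rev(x_desc)
  Y <- vapply(spectra, function(s) rev(s@intensity), numeric(length(x_asc)))
  step <- mean(diff(x_asc))
  max_shift_pts <- max(1L, round(max_shift_ppm / step))
  ssd <- function(M) {
    mu <- rowMeans(M)
    sum((M - mu)^2)
  }
  ssd_before <- ssd(Y)
  warp_to <- function(ref_idx) {
    W <- Y
    for (j in seq_len(ncol(Y)))
      if (j != ref_idx)
        W[, j] <- .warp_one(Y[, j], Y[, ref_idx], x_asc, segments,
                            max_shift_pts)
    W
  }
  cands <- if (policy == "after") {
    if (is.null(candidates) || candidates >= length(spectra))
      seq_along(spectra)
    else unique(round(seq(1, length(spectra), length.out = candidates)))
  } else reference
  best <- NULL
  for (r in cands) {
    W <- warp_to(r)
    v <- sum((W - W[, r])^2)
    if (is.null(best) || v < best$v) best <- list(r = r, W = W, v = v)
  }
  out <- spectra
  for (j in seq_along(out)) {
    out[[j]]@intensity <- rev(best$W[, j])
    out[[j]]@cplx <- complex(0)
    out[[j]]@meta <- .log_step(out[[j]]@meta, "warp",
                               list(reference = best$r, policy = policy))
  }
  list(spectra = out, reference = best$r, ssd_before = ssd_before,
       ssd_after = ssd(best$W))
}

#' Resample a spectrum onto a common ppm axis
#'
#' Linear interpolation onto a target descending axis; needed after
#' referencing (which translates each spectrum's own axis) and before
#' cohort-level operations such as warping or binning on shared boundaries.
#'
#' @param spectrum an \linkS4class{NMRSpectrum}.
#' @param ppm_axis target strictly descending axis.
#' @return the resampled \linkS4class{NMRSpectrum}.
#' @export
resampleToAxis <- function(spectrum, ppm_axis) {
  stopifnot(is(spectrum, "NMRSpectrum"), all(diff(ppm_axis) < 0))
  y <- approx(rev(spectrum@ppm), rev(spectrum@intensity), xout = rev(ppm_axis),
              rule = 2)$y
  m <- approx(rev(spectrum@ppm), rev(as.numeric(spectrum@mask)),
              xout = rev(ppm_axis), method = "constant", rule = 2)$y > 0
  new("NMRSpectrum", ppm = ppm_axis, intensity = rev(y), cplx = complex(0),
      mask = rev(m), fieldMHz = spectrum@fieldMHz,
      meta = .log_step(spectrum@meta, "resample", length(ppm_axis)))
}

#' One-spectrum preprocessing chain
#'
#' Convenience wrapper running the automated-style protocol on a single FID:
#' apodization, zero-filling + Fourier transformation, phasing (automatic
#' unless angles are given), baseline correction, TSP referencing, masking
#' of the water and TSP windows, and normalization. Warping is a
#' cohort-level operation and is applied separately.
#'
#' @param fid a \linkS4class{Fid}.
#' @param lb_hz apodization line broadening (Hz).
#' @param zero_fill_to transform length (default: next power of two at least
#'   twice the acquired length).
#' @param phi0_deg,phi1_deg phase angles; \code{NULL} triggers autophasing.
#' @param asymmetry,smoothness baseline parameters.
#' @param tsp_target_ppm referencing target.
#' @param exclude windows to mask.
#' @param normalization normalization method.
#' @return a preprocessed \linkS4class{NMRSpectrum}.
#' @export
preprocessFid <- function(fid, lb_hz = 0.7, zero_fill_to = NULL,
                          phi0_deg = NULL, phi1_deg = 0,
                          asymmetry = 0.01, smoothness = NULL,
                          tsp_target_ppm = 0.015,
                          exclude = list(c(4.50, 5.10), c(-0.20, 0.20)),
                          normalization = "total_area_excluding") {
  sp <- zeroFillTransform(apodize(fid, lb_hz), zero_fill_to)
  sp <- if (is.null(phi0_deg)) autophase(sp)$spectrum
        else phaseCorrect(sp, phi0_deg, phi1_deg)
  sp <- baselineCorrect(sp, asymmetry, smoothness)
  sp <- referenceToTsp(sp, tsp_target_ppm)
  sp <- excludeRegions(sp, exclude)
  normalizeSpectrum(sp, normalization)
}
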