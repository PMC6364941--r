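make_fid <- function(freq_hz = 200, amp = 1, t2 = 0.2, n = 2048, sw = 4000,
                     phi0 = 0, phi1 = 0) {
  t <- (seq_len(n) - 1) / sw
  z <- amp * exp(complex(imaginary = 2 * pi * freq_hz * t) - t / t2)
  new("Fid", signal = z, dwellSec = 1 / sw, fieldMHz = 400, carrierPpm = 4.75,
      meta = list(phi0_deg = phi0, phi1_deg = phi1))
}

test_that("apodization multiplies by the exponential window", {
  fid <- make_fid()
  expect_equal(apodize(fid, 0)@signal, fid@signal)
  ap <- apodize(fid, 0.7)
  t <- (seq_along(fid@signal) - 1) * fid@dwellSec
  expect_equal(Mod(ap@signal), Mod(fid@signal) * exp(-pi * 0.7 * t),
               tolerance = 1e-12)
  # a 2 Hz line broadening widens the Lorentzian by exactly 2 Hz
  fwhm_of <- function(f) {
    sp <- zeroFillTransform(f, 2^17)
    i <- which.max(sp@intensity)
    above <- range(which(sp@intensity > sp@intensity[i] / 2))
    abs(sp@ppm[above[1]] - sp@ppm[above[2]]) * 400
  }
  w0 <- fwhm_of(make_fid(t2 = 0.15, n = 4096))
  w2 <- fwhm_of(apodize(make_fid(t2 = 0.15, n = 4096), 2))
  expect_equal(w2 - w0, 2, tolerance = 0.05)
})

test_that("zero-fill transform maps frequency to chemical shift", {
  z <- make_fid(freq_hz = 200)
  sp <- zeroFillTransform(z)
  expect_equal(sp@ppm[which.max(sp@intensity)], 4.75 + 200 / 400,
               tolerance = 1e-3)
  expect_true(all(diff(sp@ppm) < 0))
  # doubling the transform length halves the point spacing
  sp2 <- zeroFillTransform(z, 2^13)
  expect_equal(mean(-diff(sp2@ppm)), mean(-diff(zeroFillTransform(z, 2^12)@ppm)) / 2,
               tolerance = 1e-9)

  zero <- make_fid(amp = 0)
  expect_true(all(zeroFillTransform(zero)@intensity == 0))

  # energy conservation: integral |S(f)|^2 df = integral |s(t)|^2 dt
  sp3 <- zeroFillTransform(z, 2^11)  # no padding: n already 2048
  e_t <- sum(Mod(z@signal)^2) * z@dwellSec
  df <- 4000 / 2^11
  e_f <- sum(Mod(sp3@cplx)^2) * df
  expect_equal(e_f, e_t, tolerance = 1e-9)

  expect_error(zeroFillTransform(z, 1024), "at least")
  expect_error(zeroFillTransform(z, 3000), "power of two")
})

test_that("phase correction rotates and autophase recovers injected errors", {
  sp <- zeroFillTransform(make_fid())
  expect_equal(phaseCorrect(sp, 0, 0)@intensity, sp@intensity)

  # a 90 degree rotation turns absorption into dispersion: near-zero at the
  # apex and antisymmetric flanks
  spf <- zeroFillTransform(make_fid(), 2^15)
  apex <- which.max(spf@intensity)
  disp <- phaseCorrect(spf, 90)
  expect_lt(abs(disp@intensity[apex]), 0.05 * spf@intensity[apex])
  expect_lt(disp@intensity[apex + 8] * disp@intensity[apex - 8], 0)

  err <- zeroFillTransform(make_fid(phi0 = 40, phi1 = 25))
  rec <- autophase(err)
  expect_equal(rec$phi0_deg %% 360, 40, tolerance = 1)
  expect_equal(rec$phi1_deg, 25, tolerance = 1)
})

test_that("asymmetric least squares removes drift but not peak area", {
  n <- 8192
  ppm <- fix_axis(n)
  peak <- nmrsigex:::lorentzian(ppm, 3.0, 0.02)
  drift <- 0.3 * (ppm - min(ppm)) / diff(range(ppm)) + 0.1
  sp <- fix_spectrum(peak + drift, ppm)
  bc <- baselineCorrect(sp, asymmetry = 0.01)
  win <- ppm > 2.8 & ppm < 3.2
  a_true <- pracma::trapz(rev(ppm[win]), rev(peak[win]))
  a_rec <- pracma::trapz(rev(ppm[win]), rev(bc@intensity[win]))
  expect_equal(a_rec, a_true, tolerance = 0.02)
  expect_true(is.numeric(bc@meta$baseline$negative_fraction))

  # an identically zero spectrum yields an identically zero baseline
  zero <- fix_spectrum(rep(0, n), ppm)
  bzero <- baselineCorrect(zero, 0.01)
  expect_lt(max(abs(bzero@intensity)), 1e-12)

  # flat spectrum: estimated baseline is (numerically) the signal itself
  flat <- fix_spectrum(rep(0.5, n), ppm)
  bflat <- baselineCorrect(flat, 0.01)
  expect_lt(max(abs(bflat@intensity)), 1e-4 * 0.5)

  # smaller asymmetry never increases the count of negative points
  negs <- vapply(c(0.05, 0.01, 0.001), function(p)
    sum(baselineCorrect(sp, p)@intensity < 0), numeric(1))
  expect_true(all(diff(negs) <= 0))

  # near idempotence: a second pass changes little
  bc2 <- baselineCorrect(bc, 0.01)
  expect_lt(max(abs(bc2@intensity - bc@intensity)), 0.01 * max(bc@intensity))
})

test_that("TSP referencing moves the apex to the target", {
  n <- 8192
  ppm <- fix_axis(n)
  y <- nmrsigex:::lorentzian(ppm, 0.030, 0.004) +
    nmrsigex:::lorentzian(ppm, 3.0, 0.01)
  sp <- fix_spectrum(y, ppm)
  ref <- referenceToTsp(sp)
  step <- abs(mean(diff(ppm)))
  sel <- ref@ppm > -0.1 & ref@ppm < 0.1
  apex <- ref@ppm[sel][which.max(ref@intensity[sel])]
  expect_lt(abs(apex - 0.015), step)
  expect_lt(abs(ref@meta$reference[["shift_ppm"]] - 0.015), step)

  # referencing an already-referenced spectrum is a no-op within one step
  ref2 <- referenceToTsp(ref)
  expect_lt(abs(ref2@meta$reference[["shift_ppm"]]), step)

  noise_only <- fix_spectrum(rnorm(n, 0, 1e-3), ppm)
  expect_error(referenceToTsp(noise_only), "noise threshold")
})

test_that("window masking excludes exactly the requested points", {
  sp <- fix_lorentz_spectrum(c(3.0, 4.8), c(1, 5), n = 4096)
  expect_equal(excludeRegions(sp, list())@mask, sp@mask)
  masked <- excludeRegions(sp, list(c(4.5, 5.1)))
  expect_equal(masked@mask, sp@ppm >= 4.5 & sp@ppm <= 5.1)
  a_all <- nmrsigex:::.trapz_masked(sp@ppm, sp@intensity)
  a_keep <- nmrsigex:::.trapz_masked(masked@ppm, masked@intensity, masked@mask)
  a_cut <- nmrsigex:::.trapz_masked(sp@ppm[masked@mask],
                                    sp@intensity[masked@mask])
  # additivity up to the two trapezoids straddling the mask boundary
  expect_equal(a_keep + a_cut, a_all, tolerance = 1e-3)
  expect_error(excludeRegions(sp, list(range(sp@ppm) + c(-1, 1))), "entire")
})

test_that("normalization fixes the area or median and is scale invariant", {
  sp <- fix_lorentz_spectrum(c(1.5, 3.0), c(2, 1), n = 4096)
  nm <- normalizeSpectrum(sp)
  expect_equal(nmrsigex:::.trapz_masked(nm@ppm, nm@intensity, nm@mask), 1,
               tolerance = 1e-9)
  sp10 <- fix_spectrum(sp@intensity * 10, sp@ppm)
  nm10 <- normalizeSpectrum(sp10)
  expect_equal(nm10@intensity, nm@intensity, tolerance = 1e-9)
  md <- normalizeSpectrum(sp, "median")
  expect_equal(median(md@intensity[md@intensity > 0]), 1, tolerance = 1e-12)
  expect_error(normalizeSpectrum(fix_spectrum(rep(-1, 10), fix_axis(10))),
               "not positive")
})

test_that("warping recovers a rigid shift and reduces cohort disagreement", {
  n <- 4096
  ppm <- fix_axis(n)
  base <- nmrsigex:::lorentzian(ppm, 1.33, 0.01) +
    0.7 * nmrsigex:::lorentzian(ppm, 3.2, 0.012)
  shifted <- approx(rev(ppm) + 0.004, rev(base), xout = rev(ppm), rule = 2)$y
  s1 <- fix_spectrum(base, ppm)
  s2 <- fix_spectrum(rev(shifted), ppm)

  ident <- warpAlign(list(s1, s1, s1))
  expect_equal(ident$ssd_after, 0, tolerance = 1e-20)
  expect_equal(ident$spectra[[2]]@intensity, s1@intensity)

  w <- warpAlign(list(s1, s2), segments = 16, max_shift_ppm = 0.01)
  expect_lt(w$ssd_after, 0.1 * w$ssd_before)

  # scaling intensities commutes with warping
  s2b <- fix_spectrum(s2@intensity * 10, ppm)
  wb <- warpAlign(list(fix_spectrum(base * 10, ppm), s2b), segments = 16)
  expect_equal(wb$spectra[[2]]@intensity, w$spectra[[2]]@intensity * 10,
               tolerance = 1e-8)

  # grouped warping picks a reference per group
  g <- warpAlign(list(s1, s2, s1, s2), groups = c("a", "a", "b", "b"),
                 segments = 16)
  expect_length(g$reference, 2L)
})

test_that("simulated cohort preprocessing preserves isolated area ratios", {
  lib <- fix_library(list(fix_multiplet("a", "a_s", 2.5, "singlet"),
                          fix_multiplet("b", "b_s", 6.8, "singlet")))
  cat_ <- fix_catalogue(lib)
  acq <- acquisitionParams(400, acq_time_s = 0.5, noise_sd = 0.01)
  arts <- simArtifacts(baseline = TRUE)
  conc <- list(c(a = 1.0, b = 2.0), c(a = 2.0, b = 1.0))
  set.seed(99)
  sp <- lapply(conc, function(cc) {
    fid <- synthesizeFid(cc, catalogue = cat_, acq = acq, artifacts = arts,
                         baseline_amplitude = 0.5)
    preprocessFid(fid, phi0_deg = 0)
  })
  area <- function(s, c0) {
    win <- s@ppm > c0 - 0.05 & s@ppm < c0 + 0.05
    nmrsigex:::.trapz_masked(s@ppm[win], s@intensity[win])
  }
  # ratio of metabolite a between the two samples, corrected for the
  # normalization constants, recovers the simulated 1:2
  r_a <- (area(sp[[1]], 2.5) * sp[[1]]@meta$normalize$constant) /
         (area(sp[[2]], 2.5) * sp[[2]]@meta$normalize$constant)
  expect_equal(r_a, 0.5, tolerance = 0.03)
})
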