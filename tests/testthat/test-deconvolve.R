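# three well-separated multiplets on a small power-of-two axis
fix_decon_library <- function() {
  fix_library(list(
    fix_multiplet("alaxine", "alx_d", 1.45, "doublet", j = 7.2, protons = 3L),
    fix_multiplet("glyxine", "glx_s", 3.56, "singlet", protons = 2L),
    fix_multiplet("citrene", "cit_dd", 2.60, "double_doublet", j = c(16, 8),
                  protons = 2L)))
}

test_that("an exactly representable spectrum is recovered to ~1e-6", {
  lib <- fix_decon_library()
  ppm <- fix_axis(4096)
  Tm <- templateMatrix(lib, ppm, 400, fwhm_hz = 2.0)
  beta0 <- c(alaxine = 0.8, citrene = 0.25, glyxine = 1.7)
  y <- as.numeric(Tm[, names(beta0)] %*% beta0)
  sp <- fix_spectrum(y, ppm)
  fit <- deconvolve(sp, lib, deconOptions(fwhm_hz = 2.0, refine_fwhm = FALSE))
  expect_lt(max(abs(coef(fit)[names(beta0)] - beta0) / beta0), 1e-6)
  expect_true(fit@convergence$converged)
  # decomposition identity: the two components add up to the stored fit sum
  expect_lt(max(abs(fitSum(fit) - fit@metaboliteFit - fit@residualFit)), 1e-12)
  # and the fit error does not exceed a template-free (background-only) fit
  err_fit <- sum((sp@intensity - fitSum(fit))^2)
  fit0 <- deconvolve(fix_spectrum(y, ppm),
                     fix_library(list(fix_multiplet("dummy", "d_s", 8.5,
                                                    "singlet"))),
                     deconOptions(fwhm_hz = 2.0, refine_fwhm = FALSE))
  err_bg <- sum((sp@intensity - fitSum(fit0))^2)
  expect_lte(err_fit, err_bg)
})

test_that("isolated peaks with noise agree with a per-peak area oracle", {
  lib <- fix_decon_library()
  ppm <- fix_axis(4096)
  Tm <- templateMatrix(lib, ppm, 400, fwhm_hz = 2.0)
  beta0 <- c(alaxine = 1.0, citrene = 0.5, glyxine = 2.0)
  sigma <- 0.02
  set.seed(3)
  y <- as.numeric(Tm[, names(beta0)] %*% beta0) + rnorm(4096, 0, sigma)
  sp <- fix_spectrum(y, ppm)
  fit <- deconvolve(sp, lib, deconOptions(fwhm_hz = 2.0, refine_fwhm = FALSE,
                                          fit_shift = FALSE))
  step <- abs(mean(diff(ppm)))
  for (met in names(beta0)) {
    win <- switch(met, alaxine = c(1.30, 1.60), citrene = c(2.45, 2.75),
                  glyxine = c(3.41, 3.71))
    sel <- ppm >= win[1] & ppm <= win[2]
    protons <- sum(lib@multiplets$protons[lib@multiplets$metabolite == met])
    area <- pracma::trapz(rev(ppm[sel]), rev(y[sel]))
    oracle <- area / protons
    se <- sigma * sqrt(sum(sel)) * step / protons
    expect_lt(abs(coef(fit)[[met]] - oracle), 3 * se + 0.02 * oracle)
  }
})

test_that("a broad hump is captured by the residual, not the templates", {
  lib <- fix_decon_library()
  ppm <- fix_axis(4096)
  hump <- 5 * nmrsigex:::lorentzian(ppm, 2.6, 40 / 400)  # 40 Hz wide
  sp <- fix_spectrum(hump, ppm)
  fit <- deconvolve(sp, lib, deconOptions(fwhm_hz = 2.0, refine_fwhm = FALSE))
  protons <- setNames(c(3, 2, 2), c("alaxine", "glyxine", "citrene"))
  met_area <- sum(coef(fit) * protons[names(coef(fit))])
  expect_lt(met_area, 0.01 * 5)
  # the residual holds the hump
  res_area <- pracma::trapz(rev(ppm), rev(fit@residualFit))
  expect_equal(res_area, 5, tolerance = 0.1)
})

test_that("injected local shifts within tolerance are recovered", {
  lib <- fix_decon_library()
  ppm <- fix_axis(8192)
  true_shift <- c(alx_d = 0.003, glx_s = -0.002, cit_dd = 0.0035)
  m <- lib@multiplets
  y <- rep(0, length(ppm))
  for (k in seq_len(nrow(m)))
    y <- y + buildTemplate(m[k, ], ppm, 400, 2.0,
                           shift_ppm = true_shift[[m$multiplet_id[k]]])
  sp <- fix_spectrum(y, ppm)
  fit <- deconvolve(sp, lib, deconOptions(fwhm_hz = 2.0, refine_fwhm = FALSE))
  rmse <- sqrt(mean((fit@delta[names(true_shift)] - true_shift)^2))
  expect_lt(rmse, 0.001)
})

test_that("credible intervals degenerate without noise and are seed-stable", {
  lib <- fix_library(list(fix_multiplet("solo", "solo_s", 2.5, "singlet")))
  ppm <- fix_axis(1024)
  Tm <- templateMatrix(lib, ppm, 400, 2.0)
  sp <- fix_spectrum(as.numeric(Tm * 1.3), ppm)
  fit <- deconvolve(sp, lib, deconOptions(fwhm_hz = 2.0, refine_fwhm = FALSE,
                                          fit_shift = FALSE))
  fit <- credibleIntervals(fit, n_iter = 500, burn_in = 200, seed = 4)
  ci <- coefficients95(fit)
  expect_lt(ci["solo", "hi"] - ci["solo", "lo"], 1e-3 * coef(fit)[["solo"]])

  # interval width grows monotonically with the noise level
  widths <- vapply(c(0.005, 0.02), function(s) {
    set.seed(11)
    spn <- fix_spectrum(as.numeric(Tm * 1.3) + rnorm(1024, 0, s), ppm)
    f <- deconvolve(spn, lib, deconOptions(fwhm_hz = 2.0,
                                           refine_fwhm = FALSE,
                                           fit_shift = FALSE,
                                           noise_window_ppm = c(8, 11)))
    f <- credibleIntervals(f, n_iter = 800, burn_in = 300, seed = 5)
    diff(as.numeric(coefficients95(f)["solo", ]))
  }, numeric(1))
  expect_lt(widths[1], widths[2])
})

test_that("diagnostics separate isolated from crowded multiplets", {
  lib <- fix_library(list(
    fix_multiplet("lone", "lone_s", 1.5, "singlet", protons = 2L),
    fix_multiplet("crowded", "crw_q", 3.8, "quartet", j = 7.2, protons = 1L)))
  ppm <- fix_axis(8192)
  Tm <- templateMatrix(lib, ppm, 400, 2.0)
  # a cluster of unmodelled resonances swamps the quartet's neighbourhood
  clutter <- 6 * nmrsigex:::lorentzian(ppm, 3.77, 0.015) +
    5 * nmrsigex:::lorentzian(ppm, 3.84, 0.012)
  y <- as.numeric(Tm %*% c(0.8, 0.6)) + clutter
  sp <- fix_spectrum(y, ppm)
  fit <- deconvolve(sp, lib, deconOptions(fwhm_hz = 2.0, refine_fwhm = FALSE))
  d <- fitDiagnostics(fit, sp)
  lone <- d[d$multiplet_id == "lone_s", ]
  crw <- d[d$multiplet_id == "crw_q", ]
  expect_equal(lone$bin_integral, lone$fit_integral, tolerance = 1e-3)
  expect_gt(crw$crowding, 0.3)
  expect_gt(crw$bin_integral / crw$fit_integral, 1.5)
  expect_lt(lone$crowding, 0.2)
})

test_that("duplicate templates are rejected as a singular design", {
  lib <- fix_library(list(fix_multiplet("a", "a_s", 2.5, "singlet"),
                          fix_multiplet("b", "b_s", 2.5, "singlet")))
  sp <- fix_lorentz_spectrum(2.5, 1, n = 1024)
  expect_error(deconvolve(sp, lib, deconOptions(fwhm_hz = 2.0,
                                                refine_fwhm = FALSE)),
               "singular")
})
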