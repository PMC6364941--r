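test_that("packaged catalogues carry the expected metabolite sets", {
  c400 <- buildCatalogue(400)
  expect_equal(nrow(c400@metabolites), 33L)
  expect_equal(sum(c400@metabolites$in_classification), 33L)
  c900 <- buildCatalogue(900)
  expect_equal(nrow(c900@metabolites), 35L)
  excl <- c900@metabolites$name[!c900@metabolites$in_classification]
  expect_setequal(excl, c("betaine", "choline"))
  expect_equal(length(metaboliteNames(c900, classificationOnly = TRUE)), 33L)
  expect_length(spikingMetabolites(), 37L)
  expect_error(buildCatalogue(600), "no packaged catalogue")
  # every metabolite has at least one multiplet with positive protons
  m <- multiplets(c900)
  expect_true(all(metaboliteNames(c900) %in% m$metabolite))
  expect_true(all(m$protons >= 1))
})

test_that("a user catalogue passes through unchanged", {
  dir <- tempdir()
  tpl <- file.path(dir, "user_multiplets.csv")
  met <- file.path(dir, "user_metabolites.csv")
  write.csv(data.frame(metabolite = "widgetate", multiplet_id = "w_s",
                       center_ppm = 2.5, pattern = "singlet", j_hz = "",
                       protons = 3, rel_intensities = "", raster_file = "",
                       shift_tolerance_ppm = 0.005),
            tpl, row.names = FALSE)
  write.csv(data.frame(name = "widgetate", mean_conc = 1, field_400 = 1,
                       field_900 = 1, in_classification = 1),
            met, row.names = FALSE)
  cat_ <- buildCatalogue(500, template_csv = tpl, metabolite_csv = met)
  expect_equal(metaboliteNames(cat_), "widgetate")
  expect_equal(multiplets(cat_)$center_ppm, 2.5)
  expect_equal(cat_@metabolites$protons_total, 3L)
})

test_that("cohort draws respect the design and are seed-reproducible", {
  cat_ <- buildCatalogue(400)
  design <- cohortDesign(seed = 7)
  truth <- simulateCohort(design, cat_)
  expect_length(cohortLabels(truth), 143L)
  expect_equal(sum(cohortLabels(truth) == "case"), 69L)
  expect_equal(sum(cohortLabels(truth) == "control"), 74L)
  truth2 <- simulateCohort(design, cat_)
  expect_identical(concentrations(truth), concentrations(truth2))
  expect_identical(shiftJitter(truth), shiftJitter(truth2))

  # noiseless effect of log(2) on lactate doubles the case mean exactly
  d0 <- cohortDesign(n_cases = 5, n_controls = 5,
                     effects = c(lactate = log(2)), lipid_effects = NULL,
                     biological_cv = 0, seed = 1)
  t0 <- simulateCohort(d0, cat_)
  lac <- concentrations(t0)[, "lactate"]
  expect_equal(mean(lac[cohortLabels(t0) == "case"]) /
               mean(lac[cohortLabels(t0) == "control"]), 2, tolerance = 1e-12)

  # null effects: both classes share the generative law (equal means here)
  dn <- cohortDesign(n_cases = 4, n_controls = 4, effects = NULL,
                     lipid_effects = NULL, biological_cv = 0, seed = 1)
  tn <- simulateCohort(dn, cat_)
  expect_equal(concentrations(tn)[1, ], concentrations(tn)[8, ])

  expect_error(simulateCohort(
    cohortDesign(effects = c(unobtainium = 1)), cat_), "unobtainium")
})

test_that("synthesized FIDs obey the damped-exponential peak model", {
  lib <- fix_library(list(fix_multiplet("glyx", "glyx_s", 3.5, "singlet",
                                        protons = 1L)))
  cat_ <- fix_catalogue(lib)
  acq <- acquisitionParams(400, acq_time_s = 0.8)

  z <- synthesizeFid(c(glyx = 0), catalogue = cat_, acq = acq,
                     artifacts = NULL, noise = FALSE)
  expect_true(all(z@signal == 0))

  fid <- synthesizeFid(c(glyx = 1), catalogue = cat_, acq = acq,
                       artifacts = NULL, noise = FALSE)
  spw <- zeroFillTransform(fid, 2^17)  # dense axis to resolve the linewidth
  i <- which.max(spw@intensity)
  expect_equal(spw@ppm[i], 3.5, tolerance = 1e-3)
  # Lorentzian FWHM of a damped exponential is 1/(pi T2)
  half <- spw@intensity[i] / 2
  above <- range(which(spw@intensity > half))
  fw_hz <- abs(spw@ppm[above[1]] - spw@ppm[above[2]]) * 400
  expect_equal(fw_hz, 1 / (pi * acq$t2_s), tolerance = 0.05)
  sp <- zeroFillTransform(fid)

  fid2 <- synthesizeFid(c(glyx = 2), catalogue = cat_, acq = acq,
                        artifacts = NULL, noise = FALSE)
  sp2 <- zeroFillTransform(fid2)
  a1 <- pracma::trapz(rev(sp@ppm), rev(sp@intensity))
  a2 <- pracma::trapz(rev(sp2@ppm), rev(sp2@intensity))
  expect_equal(a2 / a1, 2, tolerance = 1e-9)

  # linearity: a mixture is the sum of the single-compound signals
  lib2 <- fix_library(list(fix_multiplet("a", "a_s", 3.5, "singlet"),
                           fix_multiplet("b", "b_d", 1.3, "doublet", j = 7,
                                         protons = 3L)))
  cat2 <- fix_catalogue(lib2)
  fa <- synthesizeFid(c(a = 1, b = 0), catalogue = cat2, acq = acq,
                      artifacts = NULL, noise = FALSE)
  fb <- synthesizeFid(c(a = 0, b = 2), catalogue = cat2, acq = acq,
                      artifacts = NULL, noise = FALSE)
  fab <- synthesizeFid(c(a = 1, b = 2), catalogue = cat2, acq = acq,
                       artifacts = NULL, noise = FALSE)
  expect_lt(max(abs(fab@signal - fa@signal - fb@signal)), 1e-9)

  # a resonance beyond the sweep width is refused by name
  lib3 <- fix_library(list(fix_multiplet("far", "far_s", 9.9, "singlet")))
  expect_error(synthesizeFid(c(far = 1), catalogue = fix_catalogue(lib3),
                             acq = acquisitionParams(400, spectral_width_hz = 2000,
                                                     acq_time_s = 0.5),
                             artifacts = NULL, noise = FALSE),
               "far_s")
})

test_that("isolated multiplet area is proportional to concentration", {
  lib <- fix_library(list(fix_multiplet("a", "a_s", 3.5, "singlet")))
  cat_ <- fix_catalogue(lib)
  acq <- acquisitionParams(400, acq_time_s = 0.6)
  areas <- vapply(c(0.5, 1, 2, 5), function(cc) {
    sp <- zeroFillTransform(synthesizeFid(c(a = cc), catalogue = cat_,
                                          acq = acq, artifacts = NULL,
                                          noise = FALSE))
    pracma::trapz(rev(sp@ppm), rev(sp@intensity))
  }, numeric(1))
  r <- areas / c(0.5, 1, 2, 5)
  expect_lt(max(abs(r / r[1] - 1)), 1e-6)
})

test_that("cohorts round-trip through disk", {
  lib <- fix_library(list(fix_multiplet("a", "a_s", 3.5, "singlet"),
                          fix_multiplet("b", "b_s", 1.9, "singlet")))
  cat_ <- fix_catalogue(lib)
  design <- cohortDesign(n_cases = 3, n_controls = 2, effects = NULL,
                         lipid_effects = NULL, seed = 11)
  truth <- simulateCohort(design, cat_)
  dir <- file.path(tempdir(), "cohort_rt")
  acq <- acquisitionParams(400, acq_time_s = 0.4)
  manifest <- writeCohort(truth, cat_, dir, acq, artifacts = NULL,
                          format = "spectrum")
  expect_equal(nrow(manifest), 5L)
  expect_equal(manifest$label, as.character(cohortLabels(truth)))
  expect_true(all(file.exists(manifest$path)))

  m2 <- readManifest(file.path(dir, "manifest.csv"))
  expect_equal(m2$sample_id, manifest$sample_id)

  # write -> read round-trips a FID-format cohort to numerical precision
  dir2 <- file.path(tempdir(), "cohort_rt_fid")
  mf <- writeCohort(truth, cat_, dir2, acq, artifacts = NULL, format = "fid")
  fid <- readFidFile(mf$path[1], field_mhz = 400, carrier_ppm = acq$carrier_ppm)
  sp_disk <- zeroFillTransform(fid)
  sp_ref <- readSpectrumFile(manifest$path[1], field_mhz = 400)
  expect_equal(length(fid@signal), acq$n_points)
  rel <- max(abs(sp_disk@intensity - sp_ref@intensity)) /
    max(abs(sp_ref@intensity))
  expect_lt(rel, 1e-6)
})
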