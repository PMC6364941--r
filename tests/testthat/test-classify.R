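test_that("moderated t reduces to the ordinary t when d0 = 0", {
  fm <- fix_features(n_case = 15, n_control = 12, p = 30,
                     shift = c(rep(1, 5), rep(0, 25)), seed = 2)
  mt <- moderatedT(fm, d0 = 0)
  expect_lt(max(abs(mt@table$t_moderated - mt@table$t_ordinary)), 1e-12)
  # and agrees with a textbook pooled two-sample t for one feature
  X <- featureValues(fm); lab <- sampleLabels(fm)
  tt <- t.test(X[lab == "case", 1], X[lab == "control", 1], var.equal = TRUE)
  expect_equal(mt@table$t_ordinary[1], unname(tt$statistic), tolerance = 1e-9)
})

test_that("moderated t shrinks variances toward the prior", {
  fm <- fix_features(n_case = 10, n_control = 10, p = 200, seed = 3)
  mt <- moderatedT(fm)
  expect_gt(mt@d0, 0)
  # shrunken variances lie between the per-feature and prior variances
  lo <- pmin(mt@table$s2, mt@s02); hi <- pmax(mt@table$s2, mt@s02)
  expect_true(all(mt@table$s2_shrunk >= lo - 1e-12 &
                  mt@table$s2_shrunk <= hi + 1e-12))
  # infinite prior df pins every variance at the prior
  mt_inf <- moderatedT(fm, d0 = Inf)
  expect_true(all(abs(mt_inf@table$s2_shrunk - mt_inf@s02) < 1e-12))
  # features sharing a common variance are essentially unshrunk
  X <- featureValues(fm)[, 1, drop = FALSE]
  Xc <- X[, rep(1, 8)] + matrix(seq(0, 7), nrow(X), 8, byrow = TRUE)
  colnames(Xc) <- paste0("C", 1:8)
  mtc <- moderatedT(list(X = Xc, labels = sampleLabels(fm)))
  expect_equal(mtc@table$t_moderated, mtc@table$t_ordinary, tolerance = 1e-6)

  # cross-check against the reference empirical-Bayes implementation
  design <- cbind(1, sampleLabels(fm) == "case")
  ef <- limma::eBayes(limma::lmFit(t(featureValues(fm)), design))
  expect_equal(mt@d0, ef$df.prior, tolerance = 1e-6)
  expect_equal(unname(mt@table$t_moderated),
               unname(ef$t[, 2]) * sign(1), tolerance = 1e-6)

  expect_error(moderatedT(fix_features(n_case = 1, n_control = 5, p = 4)),
               "at least 2")
})

test_that("null moderated t attains its nominal type-I rate", {
  n_feat <- 200
  fm <- fix_features(n_case = 20, n_control = 20, p = n_feat, seed = 8)
  mt <- moderatedT(fm)
  crit <- qt(0.975, df = mt@d0 + mt@dg)
  hits <- sum(abs(mt@table$t_moderated) > crit)
  # 95% binomial band around 5% of 200
  expect_gte(hits, qbinom(0.025, n_feat, 0.05))
  expect_lte(hits, qbinom(0.975, n_feat, 0.05))
})

test_that("stratified folds balance classes to within one sample", {
  labels <- factor(rep(c("case", "control"), c(69, 74)))
  folds <- stratifiedFolds(labels, 3, seed = 9)
  tab <- table(labels, folds)
  expect_true(all(tab["case", ] == 23))
  expect_true(all(tab["control", ] %in% c(24, 25)))
  expect_identical(folds, stratifiedFolds(labels, 3, seed = 9))
  expect_false(identical(folds, stratifiedFolds(labels, 3, seed = 10)))
  expect_error(stratifiedFolds(labels, 1), "at least 2")
  expect_error(stratifiedFolds(factor(rep(c("a", "b"), c(2, 50))), 3),
               "smallest class")
})

test_that("the harness fits k x repetitions classifiers without leakage", {
  fm <- fix_features(n_case = 12, n_control = 12, p = 6,
                     shift = c(2, rep(0, 5)), seed = 4)
  seen <- new.env(); seen$train <- list(); seen$test <- list()
  spy <- list(
    fit = function(X, y) {
      seen$train[[length(seen$train) + 1L]] <- rownames(X)
      makeClassifier("centroid")$fit(X, y)
    },
    predict_prob = function(model, X) {
      seen$test[[length(seen$test) + 1L]] <- rownames(X)
      makeClassifier("centroid")$predict_prob(model, X)
    })
  cfg <- cvConfig(k_folds = 3, repetitions = 4, classifier = spy, seed = 21)
  res <- runRepeatedCv(fm, cfg)
  it <- cvIterations(res)
  expect_equal(nrow(it), 12L)
  for (i in seq_along(seen$train)) {
    expect_length(intersect(seen$train[[i]], seen$test[[i]]), 0L)
    expect_length(union(seen$train[[i]], seen$test[[i]]), 24L)
  }
  # each repetition tests every sample exactly once
  pr <- cvProbabilities(res)
  expect_true(all(table(pr$sample_id, pr$repetition) == 1L))
  # rerunning with the same seed reproduces the result exactly
  res2 <- runRepeatedCv(fm, cfg)
  expect_identical(cvIterations(res2), it)
})

test_that("in-fold selection keeps only the top-k features by |t|", {
  fm <- fix_features(n_case = 15, n_control = 15, p = 20,
                     shift = c(3, 3, rep(0, 18)), seed = 6)
  cfg <- cvConfig(k_folds = 3, repetitions = 2,
                  selector = "moderated_t_top_k", top_k = 4,
                  classifier = "centroid", seed = 2)
  res <- runRepeatedCv(fm, cfg)
  expect_true(all(lengths(res@selection) == 4L))
  expect_true(all(vapply(res@selection, function(s)
    all(c("F01", "F02") %in% s), logical(1))))
  expect_error(runRepeatedCv(fm, cvConfig(selector = "moderated_t_top_k",
                                          top_k = 50)),
               "exceeds")
})

test_that("summaries report means with standard errors", {
  fm <- fix_features(n_case = 10, n_control = 10, p = 4,
                     shift = c(4, 0, 0, 0), seed = 5)
  res <- runRepeatedCv(fm, cvConfig(k_folds = 2, repetitions = 10,
                                    classifier = "centroid", seed = 3))
  sm <- summarizeCv(list(fixture = res))
  it <- cvIterations(res)
  expect_equal(sm$error, mean(it$error), tolerance = 1e-12)
  expect_equal(sm$error_se, sd(it$error) / sqrt(nrow(it)), tolerance = 1e-12)
  expect_equal(sm$features, "fixture")
  # identical iterations give an SE of zero
  res0 <- res
  res0@iterations$error <- 0.25
  res0@iterations$sensitivity <- 0.8
  res0@iterations$specificity <- 0.7
  sm0 <- summarizeCv(list(const = res0))
  expect_equal(sm0$error_se, 0)
  # one row per feature set
  expect_equal(nrow(summarizeCv(list(a = res, b = res0))), 2L)
})

test_that("probability histograms separate what the classifier separates", {
  sep <- fix_features(n_case = 15, n_control = 15, p = 5,
                      shift = c(5, 5, rep(0, 3)), seed = 7)
  res <- runRepeatedCv(sep, cvConfig(k_folds = 3, repetitions = 5,
                                     classifier = "centroid", seed = 1))
  h <- probabilityHistogram(res)
  case_mass <- sum(h$prop[h$class == "case" & h$bin_lo >= 0.5])
  ctrl_mass <- sum(h$prop[h$class == "control" & h$bin_hi <= 0.5])
  expect_gt(case_mass, 0.9)
  expect_gt(ctrl_mass, 0.9)
  expect_true(all(res@probabilities$prob >= 0 & res@probabilities$prob <= 1))
})

test_that("top-feature frequencies find a dominant effect", {
  fm <- fix_features(n_case = 15, n_control = 15, p = 12,
                     shift = c(6, rep(0, 11)), seed = 10)
  res <- runRepeatedCv(fm, cvConfig(k_folds = 3, repetitions = 5,
                                    classifier = "centroid", seed = 2))
  freq <- topFeatureFrequency(res, n_top = 3, features = fm)
  expect_equal(freq$frequency[freq$feature == "F01"], 1.0)
  expect_true(all(freq$frequency >= 0 & freq$frequency <= 1))
  expect_lte(nrow(freq), 12L)
  # with the moderated-t selector the stored logs are reused
  res_sel <- runRepeatedCv(fm, cvConfig(k_folds = 3, repetitions = 5,
                                        selector = "moderated_t_top_k",
                                        top_k = 5, classifier = "centroid",
                                        seed = 2))
  freq2 <- topFeatureFrequency(res_sel, n_top = 3)
  expect_equal(freq2$frequency[freq2$feature == "F01"], 1.0)
})

test_that("elastic net and lasso plug-ins train and predict probabilities", {
  fm <- fix_features(n_case = 20, n_control = 20, p = 10,
                     shift = c(3, 3, rep(0, 8)), seed = 12)
  res <- runRepeatedCv(fm, cvConfig(k_folds = 2, repetitions = 2,
                                    classifier = "elastic_net", seed = 6))
  expect_lt(mean(cvIterations(res)$error), 0.2)
  lasso <- makeClassifier("lasso")
  X <- featureValues(fm)
  model <- lasso$fit(X, sampleLabels(fm))
  p <- lasso$predict_prob(model, X)
  expect_true(all(p >= 0 & p <= 1))
})
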