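.feature_input <- function(features) {
  if (is(features, "FeatureMatrix")) {
    list(X = featureValues(features), labels = sampleLabels(features),
         provenance = provenance(features))
  } else if (is.list(features) && all(c("X", "labels") %in% names(features))) {
    list(X = as.matrix(features$X),
         labels = factor(as.character(features$labels),
                         levels = c("control", "case")),
         provenance = features$provenance %||% "unknown")
  } else stop("features must be a FeatureMatrix or a list(X, labels)")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Moderated two-sample t-statistics
#'
#' For each feature, the pooled two-sample variance \eqn{s_g^2} (with
#' \eqn{d_g = n_1 + n_2 - 2} degrees of freedom) is shrunk toward a prior
#' variance \eqn{s_0^2} estimated together with the prior degrees of freedom
#' \eqn{d_0} by an empirical-Bayes moment fit on the log sample variances:
#' \eqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}. The
#' moderated statistic is the mean difference (case minus control) divided
#' by \eqn{\tilde{s}_g \sqrt{1/n_1 + 1/n_2}}. With \eqn{d_0 = 0} it reduces
#' to the ordinary pooled t; with infinite \eqn{d_0} all variances equal
#' \eqn{s_0^2}.
#'
#' @param features a \linkS4class{FeatureMatrix} or \code{list(X, labels)}
#'   with samples in rows.
#' @param d0 optional override of the prior degrees of freedom (e.g. 0 for
#'   the ordinary t limit); \code{NULL} estimates it.
#' @return a \linkS4class{ModeratedTResult}.
#' @export
moderatedT <- function(features, d0 = NULL) {
  fi <- .feature_input(features)
  X <- fi$X; labels <- fi$labels
  if (nlevels(droplevels(labels)) != 2L)
    stop("two classes are required")
  n1 <- sum(labels == "case"); n2 <- sum(labels == "control")
  if (n1 < 2L || n2 < 2L) stop("each class needs at least 2 samples")
  Xc <- X[labels == "case", , drop = FALSE]
  Xk <- X[labels == "control", , drop = FALSE]
  m1 <- colMeans(Xc); m2 <- colMeans(Xk)
  dg <- n1 + n2 - 2
  s2 <- ((n1 - 1) * apply(Xc, 2, var) + (n2 - 1) * apply(Xk, 2, var)) / dg
  if (is.null(d0)) {
    fd <- limma::fitFDist(pmax(s2, 1e-300), df1 = dg)
    d0 <- fd$df2
    s02 <- fd$scale
  } else if (d0 == 0) {
    s02 <- mean(s2)
  } else {
    fd <- limma::fitFDist(pmax(s2, 1e-300), df1 = dg)
    s02 <- fd$scale
  }
  s2_shrunk <- if (is.infinite(d0)) rep(s02, length(s2))
               else (d0 * s02 + dg * s2) / (d0 + dg)
  se_fac <- sqrt(1 / n1 + 1 / n2)
  diff <- m1 - m2
  t_ord <- diff / (sqrt(s2) * se_fac)
  t_mod <- diff / (sqrt(s2_shrunk) * se_fac)
  ord <- order(-abs(t_mod), seq_along(t_mod))  # ties by feature order
  rank_ <- integer(length(t_mod)); rank_[ord] <- seq_along(t_mod)
  tab <- data.frame(feature = colnames(X) %||% paste0("F", seq_along(t_mod)),
                    mean_diff = diff, t_ordinary = t_ord, t_moderated = t_mod,
                    s2 = s2, s2_shrunk = s2_shrunk, rank = rank_,
                    row.names = NULL)
  new("ModeratedTResult", table = tab, d0 = d0, s02 = s02, dg = dg)
}

#' Stratified fold assignment
#'
#' Assigns samples to \code{k} folds so that within each class the fold
#' sizes differ by at most one; reproducible under the seed.
#'
#' @param labels class labels.
#' @param k number of folds (>= 2, at most the smaller class size).
#' @param seed RNG seed.
#' @return integer fold assignment in 1..k.
#' @export
stratifiedFolds <- function(labels, k = 3, seed = 1) {
  labels <- as.factor(labels)
  if (k < 2) stop("k must be at least 2")
  if (k > min(table(labels)))
    stop("k exceeds the size of the smallest class")
  folds <- integer(length(labels))
  .with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  })
  folds
}

#' Classifier plug-in constructor
#'
#' Returns the fit/predict pair used by the cross-validation harness. Any
#' list with elements \code{fit(X, y)} returning a model and
#' \code{predict_prob(model, X)} returning case probabilities can be slotted
#' in. The reference implementation is a penalized (elastic net) logistic
#' regression with the regularization strength chosen by inner
#' cross-validation on the training folds; \code{"lasso"} is the mixing
#' value 1 special case. \code{"centroid"} is a fast diagonal
#' nearest-centroid classifier useful for large repetition counts.
#'
#' @param name one of \code{"elastic_net"}, \code{"lasso"},
#'   \code{"random_forest"}, \code{"svm"}, \code{"centroid"}.
#' @param params list of classifier parameters (\code{alpha}, mixing value
#'   for the penalized models, default 0.5; \code{inner_folds}, default 5;
#'   passed through otherwise).
#' @return list with \code{fit} and \code{predict_prob}.
#' @export
makeClassifier <- function(name = c("elastic_net", "lasso", "random_forest",
                                    "svm", "centroid"),
                           params = list()) {
  name <- match.arg(name)
  if (name %in% c("elastic_net", "lasso")) {
    alpha <- if (name == "lasso") 1 else params$alpha %||% 0.5
    nf <- params$inner_folds %||% 5
    list(
      fit = function(X, y) {
        # glmnet advises on small inner folds; routine at CV training sizes
        suppressWarnings(
          glmnet::cv.glmnet(X, y == "case", family = "binomial",
                            alpha = alpha, nfolds = nf, standardize = TRUE))
      },
      predict_prob = function(model, X)
        as.numeric(predict(model, X, s = "lambda.min", type = "response")))
  } else if (name == "random_forest") {
    if (!requireNamespace("randomForest", quietly = TRUE))
      stop("the random_forest classifier needs the randomForest package")
    nt <- params$ntree %||% 500
    list(
      fit = function(X, y) randomForest::randomForest(X, droplevels(y),
                                                      ntree = nt),
      predict_prob = function(model, X)
        predict(model, X, type = "prob")[, "case"])
  } else if (name == "svm") {
    if (!requireNamespace("e1071", quietly = TRUE))
      stop("the svm classifier needs the e1071 package")
    list(
      fit = function(X, y) e1071::svm(X, droplevels(y), probability = TRUE,
                                      kernel = params$kernel %||% "radial"),
      predict_prob = function(model, X) {
        p <- predict(model, X, probability = TRUE)
        attr(p, "probabilities")[, "case"]
      })
  } else {
    # diagonal nearest-centroid with logistic link on the discriminant
    list(
      fit = function(X, y) {
        mu1 <- colMeans(X[y == "case", , drop = FALSE])
        mu0 <- colMeans(X[y == "control", , drop = FALSE])
        s <- apply(X, 2, sd); s[s == 0] <- 1
        list(mu1 = mu1, mu0 = mu0, s = s)
      },
      predict_prob = function(model, X) {
        d1 <- sweep(sweep(X, 2, model$mu1), 2, model$s, "/")^2
        d0 <- sweep(sweep(X, 2, model$mu0), 2, model$s, "/")^2
        z <- rowSums(d0) - rowSums(d1)
        1 / (1 + exp(-z / max(ncol(X), 1)))
      })
  }
}

#' Cross-validation configuration
#'
#' @param k_folds folds per repetition (default 3).
#' @param repetitions number of repeated splits (default 333, giving 999
#'   classifier fits with 3 folds).
#' @param selector in-fold feature selection: \code{"none"} or
#'   \code{"moderated_t_top_k"} (rank by absolute moderated t on the
#'   training folds and keep the top \code{top_k}).
#' @param top_k number of features kept by the selector (default 15).
#' @param classifier plug-in name (see \code{\link{makeClassifier}}) or a
#'   fit/predict list.
#' @param classifier_params passed to \code{\link{makeClassifier}}.
#' @param seed master seed; it spawns one substream per repetition so
#'   repetitions are independent but reproducible.
#' @return config list for \code{\link{runRepeatedCv}}.
#' @export
cvConfig <- function(k_folds = 3, repetitions = 333,
                     selector = c("none", "moderated_t_top_k"), top_k = 15,
                     classifier = "elastic_net", classifier_params = list(),
                     seed = 1) {
  selector <- match.arg(selector)
  stopifnot(k_folds >= 2, repetitions >= 1)
  list(k_folds = k_folds, repetitions = repetitions, selector = selector,
       top_k = top_k, classifier = classifier,
       classifier_params = classifier_params, seed = seed)
}

#' Repeated stratified k-fold cross-validation
#'
#' For every repetition the samples are split into stratified folds; for
#' every fold the selector (if any) and the classifier are fitted on the
#' training folds only and evaluated on the held-out fold. A sample is
#' predicted a case when its probability exceeds 0.5. Sensitivity is the
#' fraction of cases classified correctly, specificity the fraction of
#' controls. With the defaults (3 folds, 333 repetitions) the summary
#' averages 999 classifier fits.
#'
#' @param features a \linkS4class{FeatureMatrix} or \code{list(X, labels)}.
#' @param config see \code{\link{cvConfig}}.
#' @return a \linkS4class{CvResult}.
#' @export
runRepeatedCv <- function(features, config = cvConfig()) {
  fi <- .feature_input(features)
  X <- fi$X; labels <- fi$labels
  stopifnot(!anyNA(labels))
  if (config$selector != "none" && config$top_k > ncol(X))
    stop("top_k exceeds the number of features")
  if (config$selector != "none" && identical(fi$provenance, "deconvolution"))
    warning("moderated-t selection is intended for binning features; ",
            "deconvolution feature sets are usually classified without selection")
  clf <- if (is.list(config$classifier)) config$classifier
         else makeClassifier(config$classifier, config$classifier_params)
  ids <- rownames(X) %||% sprintf("S%03d", seq_len(nrow(X)))
  rep_seeds <- .with_seed(config$seed,
                          sample.int(.Machine$integer.max - 1L,
                                     config$repetitions))
  iter_rows <- vector("list", config$repetitions * config$k_folds)
  prob_rows <- vector("list", length(iter_rows))
  selection <- vector("list", length(iter_rows))
  row_i <- 0L
  for (r in seq_len(config$repetitions)) {
    folds <- stratifiedFolds(labels, config$k_folds, rep_seeds[r])
    for (f in seq_len(config$k_folds)) {
      train <- folds != f
      Xtr <- X[train, , drop = FALSE]; ytr <- labels[train]
      Xte <- X[!train, , drop = FALSE]; yte <- labels[!train]
      keep <- colnames(X)
      if (config$selector == "moderated_t_top_k") {
        mt <- moderatedT(list(X = Xtr, labels = ytr))
        keep <- mt@table$feature[order(mt@table$rank)][seq_len(config$top_k)]
        Xtr <- Xtr[, keep, drop = FALSE]
        Xte <- Xte[, keep, drop = FALSE]
      }
      prob <- .with_seed(rep_seeds[r] + f, {
        model <- clf$fit(Xtr, ytr)
        as.numeric(clf$predict_prob(model, Xte))
      })
      pred <- ifelse(prob > 0.5, "case", "control")
      row_i <- row_i + 1L
      iter_rows[[row_i]] <- data.frame(
        repetition = r, fold = f,
        error = mean(pred != as.character(yte)),
        sensitivity = if (any(yte == "case"))
          mean(pred[yte == "case"] == "case") else NA_real_,
        specificity = if (any(yte == "control"))
          mean(pred[yte == "control"] == "control") else NA_real_)
      prob_rows[[row_i]] <- data.frame(
        sample_id = ids[!train], label = as.character(yte),
        repetition = r, prob = prob)
      selection[[row_i]] <- if (config$selector == "none") character(0) else keep
    }
  }
  new("CvResult",
      iterations = do.call(rbind, iter_rows),
      probabilities = do.call(rbind, prob_rows),
      selection = selection, config = config)
}

#' Summarize repeated cross-validation results
#'
#' Mean and standard error (SD over iterations divided by the square root of
#' the iteration count) of the error rate, sensitivity and specificity, one
#' row per result.
#'
#' @param results a \linkS4class{CvResult} or a named list of them.
#' @return data.frame with columns \code{features}, \code{error},
#'   \code{error_se}, \code{sensitivity}, \code{sensitivity_se},
#'   \code{specificity}, \code{specificity_se} and a formatted
#'   \code{display} column in the style "mean (se)".
#' @export
summarizeCv <- function(results) {
  if (is(results, "CvResult")) results <- list(result = results)
  rows <- lapply(names(results), function(nm) {
    it <- results[[nm]]@iterations
    stat <- function(v) c(mean(v, na.rm = TRUE),
                          sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
    e <- stat(it$error); s <- stat(it$sensitivity); p <- stat(it$specificity)
    data.frame(features = nm, error = e[1], error_se = e[2],
               sensitivity = s[1], sensitivity_se = s[2],
               specificity = p[1], specificity_se = p[2],
               display = sprintf("%.3f (%.3f) / %.3f (%.3f) / %.3f (%.3f)",
                                 e[1], e[2], s[1], s[2], p[1], p[2]),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Distribution of out-of-fold case probabilities per true class
#'
#' Pools the out-of-fold predicted probabilities over all repetitions and
#' bins them separately for true cases and true controls — the data behind
#' a probability histogram of the classifier.
#'
#' @param result a \linkS4class{CvResult}.
#' @param breaks histogram break points on [0, 1].
#' @return data.frame with \code{class}, \code{bin_lo}, \code{bin_hi},
#'   \code{count}, \code{prop}.
#' @export
probabilityHistogram <- function(result, breaks = seq(0, 1, by = 0.05)) {
  pr <- result@probabilities
  if (!nrow(pr)) stop("no pooled probabilities in the result")
  stopifnot(all(pr$prob >= 0 & pr$prob <= 1))
  out <- lapply(c("control", "case"), function(cl) {
    p <- pr$prob[pr$label == cl]
    cnt <- hist(p, breaks = breaks, plot = FALSE)$counts
    data.frame(class = cl, bin_lo = breaks[-length(breaks)],
               bin_hi = breaks[-1], count = cnt,
               prop = if (length(p)) cnt / length(p) else 0)
  })
  do.call(rbind, out)
}

#' Frequency of features among the top-ranked discriminators
#'
#' How often each feature appears among the \code{n_top} largest absolute
#' moderated t-statistics across cross-validation iterations. Uses the
#' selection logs when the result was run with the moderated-t selector and
#' \code{top_k >= n_top}; otherwise recomputes the ranking on each
#' iteration's training folds from the supplied features.
#'
#' @param result a \linkS4class{CvResult}.
#' @param n_top size of the top list (default 15).
#' @param features the features the result was computed from (needed when
#'   selection logs are absent or too short).
#' @return data.frame with \code{feature} and \code{frequency} (fraction of
#'   iterations), sorted decreasing.
#' @export
topFeatureFrequency <- function(result, n_top = 15, features = NULL) {
  cfg <- result@config
  logs <- result@selection
  have_logs <- length(logs) && all(lengths(logs) >= n_top)
  if (!have_logs) {
    if (is.null(features))
      stop("selection logs absent; supply the features to recompute rankings")
    fi <- .feature_input(features)
    rep_seeds <- .with_seed(cfg$seed,
                            sample.int(.Machine$integer.max - 1L,
                                       cfg$repetitions))
    logs <- list(); i <- 0L
    for (r in seq_len(cfg$repetitions)) {
      folds <- stratifiedFolds(fi$labels, cfg$k_folds, rep_seeds[r])
      for (f in seq_len(cfg$k_folds)) {
        mt <- moderatedT(list(X = fi$X[folds != f, , drop = FALSE],
                              labels = fi$labels[folds != f]))
        i <- i + 1L
        logs[[i]] <- mt@table$feature[order(mt@table$rank)][seq_len(n_top)]
      }
    }
  } else {
    logs <- lapply(logs, function(v) v[seq_len(n_top)])
  }
  tab <- table(unlist(logs)) / length(logs)
  out <- data.frame(feature = names(tab), frequency = as.numeric(tab),
                    row.names = NULL)
  out[order(-out$frequency, out$feature), , drop = FALSE]
}
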