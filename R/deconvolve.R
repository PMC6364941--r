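#' Options for the two-component deconvolution fit
#'
#' @param fwhm_hz prior Lorentzian linewidth; \code{NULL} selects 1.5 Hz
#'   below 700 MHz and 1.0 Hz above, before any refinement.
#' @param refine_fwhm refine the linewidth by a coarse grid search on the
#'   first iteration.
#' @param max_iter cap on the alternating updates.
#' @param tol stop when the relative change of the fitting error drops below
#'   this.
#' @param background_knot_hz knot spacing (Hz) of the smooth-background part
#'   of the residual component.
#' @param wavelet_threshold_factor multiplier on the universal soft
#'   threshold for the fine-scale (wavelet) part of the residual.
#' @param noise_window_ppm signal-free window used to estimate the noise SD.
#' @param fit_shift fit per-multiplet local shifts (grid search at axis-step
#'   resolution within each multiplet's tolerance; ties broken toward zero).
#' @return list of options for \code{\link{deconvolve}}.
#' @export
deconOptions <- function(fwhm_hz = NULL, refine_fwhm = TRUE, max_iter = 50,
                         tol = 1e-6, background_knot_hz = 18,
                         wavelet_threshold_factor = 1.0,
                         noise_window_ppm = c(9.3, 10.3),
                         fit_shift = TRUE) {
  list(fwhm_hz = fwhm_hz, refine_fwhm = refine_fwhm, max_iter = max_iter,
       tol = tol, background_knot_hz = background_knot_hz,
       wavelet_threshold_factor = wavelet_threshold_factor,
       noise_window_ppm = noise_window_ppm, fit_shift = fit_shift)
}

# sparse representation of one multiplet template on the ascending grid:
# support indices at shift 0 plus the curve values; shifting by k grid steps
# is an index translation
.sparse_template <- function(spec_row, lib, x_asc, field, fwhm_hz,
                             keep_frac = 1e-5) {
  row <- as.list(spec_row)
  if (identical(row$pattern[[1]], "raster"))
    row$raster <- list(lib@rasters[[row$multiplet_id[[1]]]])
  y <- buildTemplate(row, x_asc, field, fwhm_hz)
  thr <- keep_frac * max(y)
  idx <- which(y > thr)
  idx <- seq(min(idx), max(idx))
  list(idx = idx, val = y[idx])
}

.place <- function(n, sp, shift_steps = 0, scale = 1) {
  v <- numeric(n)
  k <- floor(shift_steps)
  f <- shift_steps - k
  idx <- sp$idx + k
  ok <- idx >= 1 & idx <= n
  if (f == 0) {
    v[idx[ok]] <- sp$val[ok] * scale
  } else {
    # fractional shift by linear interpolation between grid translates
    v[idx[ok]] <- v[idx[ok]] + (1 - f) * sp$val[ok] * scale
    idx2 <- idx + 1L
    ok2 <- idx2 >= 1 & idx2 <= n
    v[idx2[ok2]] <- v[idx2[ok2]] + f * sp$val[ok2] * scale
  }
  v
}

# metabolite design matrix: one column per metabolite, the sum of its
# (shifted) multiplet curves
.assemble_T <- function(n, sparse_list, mult_meta, shifts_steps, mets) {
  T <- matrix(0, n, length(mets), dimnames = list(NULL, mets))
  for (k in seq_along(sparse_list)) {
    j <- match(mult_meta$metabolite[k], mets)
    T[, j] <- T[, j] + .place(n, sparse_list[[k]], shifts_steps[k])
  }
  T
}

# orthonormal basis for the smooth background on an n-point axis spanning
# `span_ppm`, with knots every `knot_ppm`; masked points are zeroed.
# The basis size is capped: beyond ~400 columns the QR dominates the fit
# cost while the background gains no useful flexibility.
.bg_basis <- function(n, w_keep, span_ppm, knot_ppm) {
  nknots <- max(8L, round(span_ppm / knot_ppm))
  B <- splines::bs(seq_len(n), df = min(nknots, n %/% 8, 400L), degree = 3,
                   intercept = TRUE)
  qr.Q(qr(B * w_keep))
}

# non-negative least squares via Cholesky reduction of the normal equations
.nnls <- function(A, b) {
  G <- crossprod(A)
  G <- G + diag(1e-10 * mean(diag(G)), ncol(G))
  R <- chol(G)
  c_ <- backsolve(R, crossprod(A, b), transpose = TRUE)
  fit <- pracma::lsqnonneg(R, as.numeric(c_))
  fit$x
}

#' Template matrix for a library on a given axis
#'
#' One column per metabolite: the sum of its multiplet template curves
#' (unit concentration, area = protons per multiplet) discretized on the
#' axis. Useful for constructing exactly-representable test spectra and for
#' inspecting the fit design.
#'
#' @param lib a \linkS4class{TemplateLibrary}.
#' @param ppm_axis spectrum axis (descending or ascending).
#' @param field_mhz spectrometer frequency (MHz).
#' @param fwhm_hz template linewidth.
#' @return numeric matrix, length(ppm_axis) x metabolites.
#' @export
templateMatrix <- function(lib, ppm_axis, field_mhz, fwhm_hz = 1.5) {
  desc <- length(ppm_axis) > 1 && ppm_axis[2] < ppm_axis[1]
  x_asc <- if (desc) rev(ppm_axis) else ppm_axis
  m <- lib@multiplets
  mets <- unique(m$metabolite)
  sp <- lapply(seq_len(nrow(m)), function(i)
    .sparse_template(m[i, ], lib, x_asc, field_mhz, fwhm_hz))
  T <- .assemble_T(length(x_asc), sp, m, rep(0L, nrow(m)), mets)
  if (desc) T <- T[nrow(T):1, , drop = FALSE]
  T
}

.noise_sd_est <- function(x_asc, y_asc, window) {
  sel <- x_asc >= min(window) & x_asc <= max(window)
  if (sum(sel) < 16) sel <- seq_len(min(256L, length(y_asc)))
  v <- y_asc[sel]
  sd(v - stats::fitted(stats::smooth.spline(seq_along(v), v, df = 4)))
}

#' Two-component spectral deconvolution
#'
#' Decomposes a preprocessed spectrum into (i) a metabolite component, the
#' sum of catalogue multiplet templates scaled by non-negative coefficients
#' with per-multiplet local shifts inside their tolerances, and (ii) a
#' residual component capturing everything the templates do not explain —
#' a smooth background (coarse B-spline basis fitted jointly with the
#' templates) plus wavelet-thresholded fine structure. The alternating
#' MAP-style solver iterates non-negative least squares for the
#' coefficients, grid-search shift refinement, and the residual update,
#' stopping when the relative change of the fitting error falls below
#' \code{tol} (default 1e-6) or after \code{max_iter} iterations.
#'
#' @param spectrum a preprocessed \linkS4class{NMRSpectrum}.
#' @param lib a \linkS4class{TemplateLibrary} (e.g.
#'   \code{buildCatalogue(400)@library}).
#' @param options see \code{\link{deconOptions}}.
#' @return a \linkS4class{DeconFit}.
#' @export
deconvolve <- function(spectrum, lib, options = deconOptions()) {
  stopifnot(is(spectrum, "NMRSpectrum"))
  m <- lib@multiplets
  if (!nrow(m)) stop("template library is empty")
  field <- spectrum@fieldMHz
  x_asc <- rev(spectrum@ppm)
  y <- rev(spectrum@intensity)
  w_keep <- rev(!spectrum@mask)
  y_fit <- ifelse(w_keep, y, 0)
  n <- length(y)
  step <- mean(diff(x_asc))
  mets <- unique(m$metabolite)

  fwhm <- options$fwhm_hz
  if (is.null(fwhm)) {
    fwhm <- if (field >= 700) 1.0 else 1.5
    # apodization broadens every line by the exponential width
    lb <- spectrum@meta$apodize_lb_hz
    if (!is.null(lb)) fwhm <- fwhm + lb
  }

  noise_sd <- .noise_sd_est(x_asc, y, options$noise_window_ppm)

  # smooth-background basis (zeroed at masked points, like the data)
  QB <- .bg_basis(n, w_keep, diff(range(x_asc)),
                  options$background_knot_hz / field)
  proj_out <- function(M) M - QB %*% crossprod(QB, M)

  build_all <- function(fw) lapply(seq_len(nrow(m)), function(i)
    .sparse_template(m[i, ], lib, x_asc, field, fw))

  sparse_list <- build_all(fwhm)
  Tm0 <- .assemble_T(n, sparse_list, m, rep(0, nrow(m)), mets) * w_keep
  cc <- suppressWarnings(stats::cor(Tm0))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 0
  if (any(cc > 0.99999))
    stop("singular design: duplicate or indistinguishable templates")

  max_steps <- pmax(0L, as.integer(floor(m$shift_tolerance_ppm / abs(step))))
  pow2 <- abs(log2(n) - round(log2(n))) < 1e-9

  # alternate NNLS for the coefficients (smooth background profiled out)
  # with per-multiplet shift refinement; the fine-scale wavelet part of the
  # residual is extracted once at the very end so that template misfit
  # cannot leak into it while the shifts are still settling
  run_main <- function(sparse_list, shift_steps, iter_offset = 0L) {
    Tm <- .assemble_T(n, sparse_list, m, shift_steps, mets) * w_keep
    beta <- rep(0, length(mets))
    met_fit <- bg <- numeric(n)
    err_prev <- Inf
    conv <- list(iterations = iter_offset, rel_change = NA_real_,
                 converged = FALSE)
    for (it in seq_len(options$max_iter)) {
      PT <- proj_out(Tm)
      beta <- .nnls(PT, as.numeric(proj_out(cbind(y_fit))))
      met_fit <- as.numeric(Tm %*% beta)
      gamma <- crossprod(QB, y_fit - met_fit)
      bg <- as.numeric(QB %*% gamma)

      if (isTRUE(options$fit_shift)) {
        changed <- FALSE
        for (k in seq_len(nrow(m))) {
          if (max_steps[k] == 0L) next
          j <- match(m$metabolite[k], mets)
          if (beta[j] <= 0) next
          cur <- .place(n, sparse_list[[k]], shift_steps[k], beta[j]) * w_keep
          target <- y_fit - bg - (met_fit - cur)
          cands <- seq(-max_steps[k], max_steps[k])
          cands <- cands[order(abs(cands), cands)]  # prefer smaller |shift|
          sse_at <- function(d) {
            v <- .place(n, sparse_list[[k]], d, beta[j]) * w_keep
            sum((target - v)^2)
          }
          sse <- vapply(cands, sse_at, numeric(1))
          best <- cands[which.min(sse)]
          # sub-grid refinement: parabola through the best point's neighbours
          if (abs(best) < max_steps[k]) {
            s0 <- sse[match(best, cands)]
            sm <- sse[match(best - 1L, cands)]
            sp_ <- sse[match(best + 1L, cands)]
            den <- sm - 2 * s0 + sp_
            if (is.finite(den) && den > 0) {
              frac <- 0.5 * (sm - sp_) / den
              frac <- max(-0.5, min(0.5, frac))
              if (sse_at(best + frac) < s0) best <- best + frac
            }
          }
          if (abs(best - shift_steps[k]) > 1e-3) {
            shift_steps[k] <- best
            changed <- TRUE
          }
        }
        if (changed) {
          Tm <- .assemble_T(n, sparse_list, m, shift_steps, mets) * w_keep
          met_fit <- as.numeric(Tm %*% beta)
          gamma <- crossprod(QB, y_fit - met_fit)
          bg <- as.numeric(QB %*% gamma)
        }
      }

      err <- sum((y_fit - met_fit - bg)^2)
      rel <- if (is.finite(err_prev) && err_prev > 0)
        abs(err_prev - err) / err_prev else 1
      conv <- list(iterations = iter_offset + it, rel_change = rel,
                   converged = rel < options$tol)
      if (conv$converged) break
      err_prev <- err
    }
    list(beta = beta, shift_steps = shift_steps, met_fit = met_fit, bg = bg,
         conv = conv, err = sum((y_fit - met_fit - bg)^2))
  }

  st <- run_main(sparse_list, rep(0, nrow(m)))

  if (isTRUE(options$refine_fwhm)) {
    # refine the linewidth only after the shifts have settled: scoring a
    # candidate width against unaligned peaks systematically prefers
    # too-broad templates
    fw_score <- function(fw) {
      Tw <- .assemble_T(n, build_all(fw), m, st$shift_steps, mets) * w_keep
      b <- .nnls(proj_out(Tw), as.numeric(proj_out(cbind(y_fit))))
      sum((proj_out(cbind(y_fit - Tw %*% b)))^2)
    }
    cand <- fwhm * c(0.8, 0.9, 1, 1.12, 1.25)
    score <- vapply(cand, fw_score, numeric(1))
    b <- which.min(score)
    fw_new <- cand[b]
    if (b > 1 && b < length(cand)) {
      lx <- log(cand[(b - 1):(b + 1)]); sy <- score[(b - 1):(b + 1)]
      den <- (sy[1] - 2 * sy[2] + sy[3])
      if (is.finite(den) && den > 0) {
        off <- 0.5 * (sy[1] - sy[3]) / den
        fw_try <- exp(lx[2] + off * (lx[3] - lx[2]))
        if (fw_score(fw_try) < sy[2]) fw_new <- fw_try
      }
    }
    if (abs(fw_new - fwhm) / fwhm > 0.02) {
      fwhm <- fw_new
      sparse_list <- build_all(fwhm)
      st <- run_main(sparse_list, st$shift_steps,
                     iter_offset = st$conv$iterations)
    }
  }

  beta <- st$beta; shift_steps <- st$shift_steps
  met_fit <- st$met_fit; bg <- st$bg; conv <- st$conv
  wav <- numeric(n)

  # fine-scale residual: universal soft threshold at the robust noise scale
  leftover <- y_fit - met_fit - bg
  if (pow2 && any(leftover != 0)) {
    sig <- max(.wavelet_noise_sd(leftover), 1e-300)
    lambda <- options$wavelet_threshold_factor * sig * sqrt(2 * log(n))
    wav <- .wavelet_denoise(leftover, lambda)
  }

  resid_fit <- bg + wav
  names(beta) <- mets
  delta <- setNames(shift_steps * step, m$multiplet_id)
  new("DeconFit",
      beta = beta, delta = delta, fwhmHz = fwhm, ppm = spectrum@ppm,
      metaboliteFit = rev(met_fit), residualFit = rev(resid_fit),
      ci95 = matrix(numeric(0), 0, 2), noiseSdEst = noise_sd,
      convergence = conv,
      details = list(sparse = sparse_list, mult = m,
                     shift_steps = shift_steps, mets = mets,
                     x_asc = x_asc, y_fit = y_fit, w_keep = w_keep,
                     step = step, bg = bg, wav = wav,
                     span_ppm = diff(range(x_asc)),
                     knot_ppm = options$background_knot_hz / field))
}

#' Credible intervals for deconvolution coefficients
#'
#' Random-walk Metropolis over the metabolite coefficients (and optionally
#' the multiplet shifts) with a Gaussian likelihood whose scale is the noise
#' SD estimated from a signal-free window, and a flat non-negative
#' (half-unbounded) prior truncating the coefficients at zero. The residual
#' component is held at its fitted value. Returns the central 95% posterior
#' interval per metabolite.
#'
#' @param fit a converged \linkS4class{DeconFit}.
#' @param n_iter Metropolis iterations after burn-in.
#' @param burn_in adaptation/burn-in iterations.
#' @param seed RNG seed for reproducibility.
#' @param sample_shifts also update the local shifts by one-step moves.
#' @return the \linkS4class{DeconFit} with its \code{ci95} slot filled.
#' @export
credibleIntervals <- function(fit, n_iter = 2000, burn_in = 500, seed = 1,
                              sample_shifts = FALSE) {
  d <- fit@details
  if (!length(d)) stop("fit does not carry the details needed for intervals")
  n <- length(d$y_fit)
  mets <- d$mets
  M <- length(mets)
  Tm <- .assemble_T(n, d$sparse, d$mult, d$shift_steps, mets) * d$w_keep
  # marginalize the smooth background (flat prior): work with the data and
  # templates projected onto the background's orthogonal complement, rather
  # than conditioning on the fitted background curve
  QB <- .bg_basis(n, d$w_keep, d$span_ppm, d$knot_ppm)
  proj <- function(M_) M_ - QB %*% crossprod(QB, M_)
  Tm <- proj(Tm)
  y_p <- as.numeric(proj(cbind(d$y_fit - d$wav)))
  # floor far below any realistic noise level but above double underflow
  sigma <- max(fit@noiseSdEst, 1e-9 * max(abs(d$y_fit)), 1e-12)
  beta <- fit@beta
  resid <- y_p - as.numeric(Tm %*% beta)
  csq <- colSums(Tm^2)
  step_sd <- pmax(sigma / sqrt(pmax(csq, 1e-300)), 1e-12)
  .with_seed(seed, {
    draws <- matrix(NA_real_, n_iter, M, dimnames = list(NULL, mets))
    acc <- 0L; tries <- 0L
    for (it in seq_len(burn_in + n_iter)) {
      for (j in seq_len(M)) {
        prop <- beta[j] + rnorm(1, 0, step_sd[j])
        tries <- tries + 1L
        if (prop < 0) next  # flat prior truncated at zero
        dbeta_ <- prop - beta[j]
        # change in SSE from moving one coefficient
        dsse <- dbeta_^2 * csq[j] - 2 * dbeta_ * sum(resid * Tm[, j])
        if (log(runif(1)) < -dsse / (2 * sigma^2)) {
          resid <- resid - dbeta_ * Tm[, j]
          beta[j] <- prop
          acc <- acc + 1L
        }
      }
      if (it == burn_in %/% 2 && burn_in > 0) {
        # crude adaptation toward a workable acceptance rate
        rate <- acc / max(tries, 1L)
        step_sd <- step_sd * ifelse(rate < 0.15, 0.4,
                                    ifelse(rate > 0.6, 2.5, 1))
        acc <- 0L; tries <- 0L
      }
      if (it > burn_in) draws[it - burn_in, ] <- beta
    }
    rate <- acc / max(tries, 1L)
    if (rate < 0.05 || rate > 0.8)
      warning(sprintf("Metropolis acceptance rate %.2f outside [0.05, 0.8]",
                      rate))
    ci <- t(apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
    colnames(ci) <- c("lo", "hi")
    fit@ci95 <- ci
    fit
  })
}

#' Per-multiplet fit diagnostics
#'
#' For each multiplet, compares the integral of the original spectrum over
#' the multiplet's window with the integral of the fitted metabolite
#' component over the same window, and reports a crowding score: the
#' fraction of the window's fitted area attributed to other templates plus
#' the residual component. In crowded regions the bin integral is dominated
#' by neighbours, so agreement between the two integrals is only informative
#' for isolated multiplets.
#'
#' @param fit a \linkS4class{DeconFit}.
#' @param spectrum the spectrum that was fitted.
#' @param margin_ppm half-width added around the multiplet peak span.
#' @return data.frame with one row per multiplet: window bounds, spectrum
#'   integral, metabolite-fit integral, own-template integral and crowding
#'   score.
#' @export
fitDiagnostics <- function(fit, spectrum, margin_ppm = 0.01) {
  d <- fit@details
  m <- d$mult
  n <- length(d$y_fit)
  x <- d$x_asc
  Tm_cols <- lapply(seq_len(nrow(m)), function(k)
    .place(n, d$sparse[[k]], d$shift_steps[k],
           fit@beta[[m$metabolite[k]]]))
  met_fit <- rev(fit@metaboliteFit)
  res_fit <- rev(fit@residualFit)
  y <- rev(spectrum@intensity)
  out <- lapply(seq_len(nrow(m)), function(k) {
    own <- Tm_cols[[k]]
    if (any(own > 0)) {
      core <- own > 0.05 * max(own)
      lo <- min(x[core]) - margin_ppm; hi <- max(x[core]) + margin_ppm
    } else {
      lo <- m$center_ppm[k] - margin_ppm; hi <- m$center_ppm[k] + margin_ppm
    }
    win <- x >= lo & x <= hi
    intg <- function(v) if (sum(win) > 1) pracma::trapz(x[win], v[win]) else 0
    bin_i <- intg(y)
    fit_i <- intg(met_fit)
    own_i <- intg(own)
    other <- intg(met_fit) - own_i + intg(res_fit)
    tot <- own_i + other
    data.frame(multiplet_id = m$multiplet_id[k], metabolite = m$metabolite[k],
               ppm_lo = lo, ppm_hi = hi, bin_integral = bin_i,
               fit_integral = fit_i, own_integral = own_i,
               crowding = if (tot > 0) max(0, min(1, other / tot)) else 0)
  })
  do.call(rbind, out)
}
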