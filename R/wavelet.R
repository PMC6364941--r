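# Daubechies-4 discrete wavelet transform with periodic boundaries.
# Hand-rolled because the residual model needs only this one filter pair;
# coefficients are the standard D4 quadrature mirror filters.

.d4_h <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
.d4_g <- c(.d4_h[4], -.d4_h[3], .d4_h[2], -.d4_h[1])

.dwt_step <- function(a) {
  n <- length(a)
  idx <- function(k, m) ((2 * (k - 1) + m) %% n) + 1
  k <- seq_len(n / 2)
  ap <- dp <- numeric(n / 2)
  for (m in 0:3) {
    ap <- ap + .d4_h[m + 1] * a[idx(k, m)]
    dp <- dp + .d4_g[m + 1] * a[idx(k, m)]
  }
  list(a = ap, d = dp)
}

.idwt_step <- function(a, d) {
  n2 <- length(a)
  out <- numeric(2 * n2)
  k <- seq_len(n2)
  for (m in 0:3) {
    j <- (2 * (k - 1) + m) %% (2 * n2) + 1
    out[j] <- out[j] + .d4_h[m + 1] * a + .d4_g[m + 1] * d
  }
  out
}

# full pyramid to `levels` levels; returns list(approx, details = list from
# finest to coarsest)
.dwt <- function(x, levels) {
  d <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    s <- .dwt_step(a)
    d[[l]] <- s$d
    a <- s$a
  }
  list(approx = a, details = d)
}

.idwt <- function(w) {
  a <- w$approx
  for (l in rev(seq_along(w$details)))
    a <- .idwt_step(a, w$details[[l]])
  a
}

.soft <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)

# wavelet shrinkage: soft-threshold all detail coefficients at `lambda`,
# keep the coarse approximation untouched
.wavelet_denoise <- function(x, lambda, levels = NULL) {
  n <- length(x)
  if (abs(log2(n) - round(log2(n))) > 1e-9)
    stop("wavelet residual update requires a power-of-two length")
  if (is.null(levels)) levels <- max(1L, as.integer(log2(n)) - 4L)
  w <- .dwt(x, levels)
  w$details <- lapply(w$details, .soft, lambda = lambda)
  .idwt(w)
}

# robust noise scale from the finest-detail coefficients
.wavelet_noise_sd <- function(x) {
  s <- .dwt_step(x)
  median(abs(s$d)) / 0.6745
}
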