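#' Complex first-harmonic Fourier coefficient of a time course
#'
#' Computes the (optionally weighted) complex coefficient of the first
#' harmonic of period `period` from values `b` observed at times `t`:
#' \deqn{F = \frac{2}{\sum_j u_j} \sum_j u_j b_j e^{-i 2\pi t_j / period}}
#' with weights `u` (all 1 when unweighted). For a pure cosine
#' `b = A cos(2*pi*(t - t0)/period)` sampled at equispaced times covering the
#' period, `F = A exp(-i 2*pi*t0/period)` exactly, so `Mod(F)` is the cosine
#' amplitude and the peak time is `-Arg(F) * period / (2*pi)` modulo the
#' period.
#'
#' @param b numeric values (one per time point).
#' @param t times, same units as `period` (hours by convention, ZT).
#' @param u non-negative weights; default equal weights.
#' @param period oscillation period (default 24 h).
#' @return complex scalar `F`.
#' @keywords internal
fourier_coefficient <- function(b, t, u = rep(1, length(b)), period = 24) {
  stopifnot(length(b) == length(t), length(u) == length(b), all(u >= 0))
  theta <- 2 * pi * t / period
  (2 / sum(u)) * sum(u * b * complex(real = cos(theta), imaginary = -sin(theta)))
}

#' Peak phase from a complex Fourier coefficient
#'
#' @param F complex first-harmonic coefficient as returned by
#'   [fourier_coefficient()].
#' @param period oscillation period.
#' @return peak time in `[0, period)`.
#' @keywords internal
phase_from_coefficient <- function(F, period = 24) {
  (-Arg(F) * period / (2 * pi)) %% period
}

#' Unweighted harmonic regression at a fixed period
#'
#' Fits `y = m + A*cos(2*pi*t/period) + B*sin(2*pi*t/period)` by ordinary
#' least squares and tests the joint null `A = B = 0` with the exact
#' F(2, n - 3) test. This is the small-sample-correct form used for binned
#' genomic tracks and expression time courses, where the residual variance is
#' estimated from only a handful of residual degrees of freedom; the
#' chi-square(2) form with a plug-in variance is reserved for the LWMR rhythm
#' test where uncertainties are propagated from a large local fit.
#'
#' Replicated time points are supported (each observation enters the
#' regression individually).
#'
#' @param y numeric response values.
#' @param t times of each observation (hours).
#' @param period oscillation period in the same units as `t` (default 24).
#' @return list with `amplitude` (cosine amplitude `sqrt(A^2+B^2)`), `phase`
#'   (time of fitted maximum in `[0, period)`), `mesor` (fitted mean `m`),
#'   `p` (F-test p-value), `fstat`, `df` (residual df `n - 3`).
#' @examples
#' t <- seq(0, 20, by = 4)
#' fit <- harmonic_regression(2 + cos(2 * pi * (t - 8) / 24), t)
#' round(c(fit$amplitude, fit$phase), 6)  # 1, 8
#' @export
harmonic_regression <- function(y, t, period = 24) {
  stopifnot(length(y) == length(t))
  ok <- is.finite(y) & is.finite(t)
  y <- y[ok]; t <- t[ok]
  n <- length(y)
  if (n < 4L || length(unique(t %% period)) < 3L) {
    stop("harmonic_regression() needs >= 4 observations at >= 3 distinct phases")
  }
  theta <- 2 * pi * t / period
  X <- cbind(1, cos(theta), sin(theta))
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  A <- cf[2L]; B <- cf[3L]
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  df2 <- n - 3L
  if (tss <= .Machine$double.eps * n || df2 < 1L) {
    # constant input (or saturated fit): no rhythm detectable
    return(list(amplitude = 0, phase = 0, mesor = mean(y), p = 1,
                fstat = 0, df = df2))
  }
  fstat <- ((tss - rss) / 2) / (rss / df2)
  p <- stats::pf(fstat, 2, df2, lower.tail = FALSE)
  amplitude <- sqrt(A^2 + B^2)
  phase <- if (amplitude > 0) (atan2(B, A) * period / (2 * pi)) %% period else 0
  list(amplitude = unname(amplitude), phase = unname(phase),
       mesor = unname(cf[1L]), p = unname(p), fstat = unname(fstat), df = df2)
}

#' Circular difference of two phases
#'
#' Returns `a - b` mapped to `(-period/2, period/2]`, the signed shortest
#' displacement around the clock. Antisymmetric: `circular_diff(a, b) ==
#' -circular_diff(b, a)` except at the exact antipode.
#'
#' @param a,b phases in hours.
#' @param period clock period (default 24).
#' @export
circular_diff <- function(a, b, period = 24) {
  d <- (a - b) %% period
  ifelse(d > period / 2, d - period, d)
}
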