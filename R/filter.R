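# Butterworth band-pass design via the bilinear transform, plus zero-phase
# (forward-backward) application. Designed here because no DSP package is a
# declared dependency; validated in the tests by FFT gain checks.

# Polynomial coefficients (highest order first) from complex roots.
poly_from_roots <- function(roots) {
  p <- 1 + 0i
  for (r in roots) p <- c(p, 0i) - c(0i, p * r)
  p
}

#' Design a digital Butterworth band-pass filter
#'
#' Analog low-pass prototype of the given order, low-pass-to-band-pass
#' transformed and discretized with the bilinear transform (frequencies
#' prewarped), as in any standard DSP text. The returned transfer function has
#' `2 * order + 1` numerator and denominator coefficients.
#'
#' @param low,high band edges in Hz.
#' @param rate sampling rate in Hz; must exceed `2 * high`.
#' @param order analog prototype order (the digital filter has twice this).
#' @return list with numeric `b`, `a` (denominator normalized to `a[1] = 1`).
#' @export
butter_bandpass <- function(low, high, rate, order = 4) {
  rm_assert(low > 0 && high > low, "need 0 < low < high")
  rm_assert(rate > 2 * high,
            sprintf("high edge %g Hz is at or above Nyquist (%g Hz)",
                    high, rate / 2))
  k <- seq_len(order)
  theta <- pi * (2 * k - 1) / (2 * order)
  proto <- complex(real = -sin(theta), imaginary = cos(theta))
  fs2 <- 2 * rate
  w1 <- fs2 * tan(pi * low / rate)
  w2 <- fs2 * tan(pi * high / rate)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  # low-pass -> band-pass: each prototype pole spawns a conjugate pair
  poles <- unlist(lapply(proto, function(p) {
    b <- p * bw / 2
    d <- sqrt(b^2 - w0^2 + 0i)
    c(b + d, b - d)
  }))
  zeros <- rep(0 + 0i, order) # plus `order` zeros at infinity
  gain <- bw^order
  # bilinear transform
  zd <- (fs2 + poles) / (fs2 - poles)
  zn <- c((fs2 + zeros) / (fs2 - zeros), rep(-1 + 0i, order))
  gd <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  b <- Re(poly_from_roots(zn)) * gd
  a <- Re(poly_from_roots(zd))
  list(b = b, a = a / a[1])
}

# Steady-state initial filter state for a step input of unit height
# (direct-form II transposed), so the forward pass starts without a transient
# when the state is scaled by the first sample.
filter_initial_state <- function(b, a) {
  n <- length(a) - 1
  A <- rbind(-a[-1], cbind(diag(1, n - 1), 0)) # companion matrix of a
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n) - t(A), B)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters forward then backward (squaring the magnitude response and
#' cancelling the phase), after extending the signal at both ends by an odd
#' reflection so edge transients fall on the padding. Output has the same
#' length as the input; a band-interior sinusoid keeps its peak positions.
#'
#' @param signal numeric sample vector.
#' @param rate sampling rate in Hz.
#' @param low,high band edges in Hz (defaults 1 and 16).
#' @param order Butterworth prototype order (default 4).
#' @return filtered numeric vector, same length as `signal`.
#' @examples
#' t <- seq(0, 15, by = 1 / 50)
#' filtered <- bandpass(sin(2 * pi * 8 * t), rate = 50)
#' @export
bandpass <- function(signal, rate, low = 1, high = 16, order = 4) {
  n <- length(signal)
  coef <- butter_bandpass(low, high, rate, order)
  rm_assert(n > 3 * (length(coef$a) - 1),
            "signal shorter than the filter warm-up length",
            "restmotion_shape_error")
  # padding: at least three time constants of the slow (low-edge) dynamics
  pad <- min(n - 1, max(3 * (length(coef$a) - 1), ceiling(3 * rate / low)))
  left <- 2 * signal[1] - signal[seq(pad + 1, 2)]
  right <- 2 * signal[n] - signal[seq(n - 1, n - pad)]
  ext <- c(left, signal, right)
  zi <- filter_initial_state(coef$b, coef$a)
  fwd <- iir_filter_cpp(coef$b, coef$a, ext, zi * ext[1])
  rev1 <- rev(fwd)
  bwd <- iir_filter_cpp(coef$b, coef$a, rev1, zi * rev1[1])
  rev(bwd)[seq(pad + 1, pad + n)]
}
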