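#' One-sided power spectrum of a signal
#'
#' Default estimator is the raw periodogram of the full record, no windowing,
#' scaled so that the bin powers sum to the signal's mean square (Parseval);
#' a Welch estimator (Hann window, 50% overlap) is available as an
#' alternative for smoother spectra.
#'
#' @param signal numeric vector (a `resultant_signal`'s samples, typically).
#' @param rate sampling rate in Hz.
#' @param method `"periodogram"` (default) or `"welch"`.
#' @param welch_segment segment length for the Welch estimator.
#' @return list of class `spectral_estimate` with `frequencies` (Hz, 0 to
#'   Nyquist, strictly increasing) and `power` (non-negative, same length).
#' @export
power_spectrum <- function(signal, rate,
                           method = c("periodogram", "welch"),
                           welch_segment = 256) {
  method <- match.arg(method)
  n <- length(signal)
  rm_assert(n >= 2, "need at least 2 samples", "restmotion_shape_error")
  if (method == "periodogram") {
    p <- Mod(fft(signal))^2 / n^2
    half <- seq_len(floor(n / 2) + 1)
    power <- p[half]
    # fold negative frequencies onto interior bins
    interior <- seq(2, length(half) - if (n %% 2 == 0) 1 else 0)
    power[interior] <- 2 * power[interior]
    freq <- (half - 1) * rate / n
  } else {
    seg <- min(welch_segment, n)
    step <- max(1, floor(seg / 2))
    starts <- seq(1, n - seg + 1, by = step)
    win <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg - 1) / seg) # Hann
    wnorm <- sum(win^2)
    acc <- 0
    for (s in starts) {
      x <- signal[s:(s + seg - 1)] * win
      acc <- acc + Mod(fft(x))^2 / (seg * wnorm)
    }
    p <- acc / length(starts)
    half <- seq_len(floor(seg / 2) + 1)
    power <- p[half]
    interior <- seq(2, length(half) - if (seg %% 2 == 0) 1 else 0)
    power[interior] <- 2 * power[interior]
    freq <- (half - 1) * rate / seg
  }
  structure(list(frequencies = freq, power = power),
            class = "spectral_estimate")
}
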