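# The 18 per-sensor features, in their canonical report order. Names are the
# lower-case identifiers used in feature-table columns `<sensor>.<feature>`.
FEATURE_ORDER <- c("rms", "peak", "mav", "mavfd", "mavsd", "fmean", "zc",
                   "fpeak", "f50", "f80", "power35_75", "apen", "fuzzyen",
                   "var", "range", "intla", "skewness", "kurtosis")

#' Entropy parameters for ApEn / FuzzyEn
#'
#' @param m embedding (comparison window) length.
#' @param r tolerance as a multiple of the signal's standard deviation; the
#'   absolute tolerance used is `r * sd(signal)`.
#' @param fuzzy_power exponent of the fuzzy membership `exp(-(d/r)^n)`.
#' @return list of class `entropy_params`.
#' @export
entropy_params <- function(m = 2, r = 0.2, fuzzy_power = 2) {
  rm_assert(m >= 1 && r > 0 && fuzzy_power >= 1,
            "need m >= 1, r > 0, fuzzy_power >= 1")
  structure(list(m = as.integer(m), r = r, fuzzy_power = fuzzy_power),
            class = "entropy_params")
}

#' @rdname signal_features
#' @export
rms <- function(signal) {
  check_len(signal, 1)
  sqrt(mean(signal^2))
}

#' @rdname signal_features
#' @export
peak <- function(signal) {
  check_len(signal, 1)
  max(signal)
}

#' Amplitude and variability features of a signal
#'
#' Scalar features of a (typically detrended resultant) sample vector:
#' root mean square (`rms`), maximum (`peak`), mean absolute value (`mav`,
#' computed over the whole record: a single rest trial has no event structure
#' to window over), mean absolute first/second difference (`mavfd`,
#' `mavsd`), count of strict sign changes (`zero_crossing`; zeros inherit the
#' preceding sign), sample variance (`variance`, n-1 denominator), min-max
#' `range_`, interquartile range (`intla`, linearly interpolated quartiles),
#' and the moment-based `skewness` and (non-excess) `kurtosis`.
#'
#' @param signal numeric sample vector.
#' @return a single numeric value (`zero_crossing`: an integer count).
#' @name signal_features
#' @export
mav <- function(signal) {
  check_len(signal, 1)
  mean(abs(signal))
}

#' @rdname signal_features
#' @export
mavfd <- function(signal) {
  check_len(signal, 2)
  mean(abs(diff(signal)))
}

#' @rdname signal_features
#' @export
mavsd <- function(signal) {
  check_len(signal, 3)
  mean(abs(diff(signal, lag = 2)))
}

#' @rdname signal_features
#' @export
zero_crossing <- function(signal) {
  check_len(signal, 1)
  s <- sign(signal)
  # zeros attach to the preceding sign
  for (i in seq_along(s)) {
    if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  }
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

#' @rdname signal_features
#' @export
variance <- function(signal) {
  check_len(signal, 2)
  var(signal)
}

#' @rdname signal_features
#' @export
range_ <- function(signal) {
  check_len(signal, 1)
  max(signal) - min(signal)
}

#' @rdname signal_features
#' @export
intla <- function(signal) {
  check_len(signal, 1)
  unname(diff(quantile(signal, c(0.25, 0.75), type = 7)))
}

#' @rdname signal_features
#' @export
skewness <- function(signal) {
  check_len(signal, 2)
  s <- sd(signal)
  if (s == 0) return(NA_real_)
  mean((signal - mean(signal))^3) / s^3
}

#' @rdname signal_features
#' @export
kurtosis <- function(signal) {
  check_len(signal, 2)
  s <- sd(signal)
  if (s == 0) return(NA_real_)
  mean((signal - mean(signal))^4) / s^4
}

check_len <- function(signal, minimum) {
  if (length(signal) < minimum) {
    rm_stop(sprintf("signal must have at least %d sample(s)", minimum),
            "restmotion_shape_error")
  }
  invisible(TRUE)
}

#' Spectral summary features
#'
#' Computed on a `spectral_estimate` from [power_spectrum()]: power-weighted
#' mean frequency (`fmean`), frequency of maximum power (`fpeak`), the first
#' grid frequencies at which cumulative power reaches 50% / 80% of the total
#' (`f50`, `f80`), and the power summed over a band (`power_band`, default
#' 3.5-7.5 Hz, band edges inclusive). The quantile and peak features are
#' undefined (`NA`) on a zero-power spectrum.
#'
#' @param spec a `spectral_estimate`.
#' @param low,high band edges in Hz for `power_band`.
#' @return a single numeric value (Hz for the frequency features).
#' @name spectral_features
#' @export
fmean <- function(spec) {
  total <- sum(spec$power)
  if (total <= 0) return(NA_real_)
  sum(spec$power * spec$frequencies) / total
}

#' @rdname spectral_features
#' @export
fpeak <- function(spec) {
  if (sum(spec$power) <= 0) return(NA_real_)
  spec$frequencies[which.max(spec$power)]
}

cumulative_frequency <- function(spec, fraction) {
  total <- sum(spec$power)
  if (total <= 0) return(NA_real_)
  idx <- which(cumsum(spec$power) >= fraction * total)[1]
  spec$frequencies[idx]
}

#' @rdname spectral_features
#' @export
f50 <- function(spec) cumulative_frequency(spec, 0.5)

#' @rdname spectral_features
#' @export
f80 <- function(spec) cumulative_frequency(spec, 0.8)

#' @rdname spectral_features
#' @export
power_band <- function(spec, low = 3.5, high = 7.5) {
  sum(spec$power[spec$frequencies >= low & spec$frequencies <= high])
}

#' Approximate entropy
#'
#' Regularity statistic `ApEn(m, r, N) = Phi^m(r) - Phi^(m+1)(r)` built from
#' the log-frequencies of template matches within Chebyshev tolerance
#' `r * sd(signal)`; self-matches are included. A constant signal has zero
#' approximate entropy.
#'
#' @param signal numeric vector of length `> m + 1`.
#' @param params an [entropy_params()].
#' @return non-negative scalar (up to floating error).
#' @export
apen <- function(signal, params = entropy_params()) {
  n <- length(signal)
  if (n <= params$m + 1) {
    rm_stop("signal too short for ApEn", "restmotion_shape_error")
  }
  s <- sd(signal)
  if (s == 0) return(0) # all distances zero: every template matches
  apen_cpp(signal, params$m, params$r * s)
}

#' Fuzzy entropy
#'
#' Like [apen()] but each comparison window has its own mean removed before
#' the Chebyshev distance, similarity is the fuzzy membership
#' `exp(-(d / (r * sd))^n)` instead of a hard threshold, and self-matches are
#' excluded. Invariant to adding a constant to the signal.
#'
#' @inheritParams apen
#' @return non-negative scalar (up to floating error).
#' @export
fuzzyen <- function(signal, params = entropy_params()) {
  n <- length(signal)
  if (n <= params$m + 1) {
    rm_stop("signal too short for FuzzyEn", "restmotion_shape_error")
  }
  s <- sd(signal)
  if (s == 0) return(0) # all windows identical after baseline removal
  fuzzyen_cpp(signal, params$m, params$r * s, params$fuzzy_power)
}

# All 18 features of one detrended resultant, in FEATURE_ORDER.
sensor_features <- function(rs, params = entropy_params(),
                            spectrum_method = "periodogram") {
  x <- rs$samples
  spec <- power_spectrum(x, rs$sampling_rate, method = spectrum_method)
  vals <- c(
    rms = rms(x), peak = peak(x), mav = mav(x), mavfd = mavfd(x),
    mavsd = mavsd(x), fmean = fmean(spec), zc = as.numeric(zero_crossing(x)),
    fpeak = fpeak(spec), f50 = f50(spec), f80 = f80(spec),
    power35_75 = power_band(spec), apen = apen(x, params),
    fuzzyen = fuzzyen(x, params), var = variance(x), range = range_(x),
    intla = intla(x), skewness = skewness(x), kurtosis = kurtosis(x)
  )
  vals[FEATURE_ORDER]
}

#' Names of the 108 features in canonical order
#'
#' Six sensors in analysis order (gyr1, gyr2, acc1, acc2, mag1, mag2) times
#' 18 features in report order, named `<sensor>.<feature>`.
#'
#' @return character vector of length 108.
#' @export
feature_names <- function() {
  as.vector(t(outer(SENSOR_ANALYSIS_ORDER, FEATURE_ORDER, paste, sep = ".")))
}

#' Extract the 108-feature vector of one recording
#'
#' Preprocesses the recording ([preprocess_recording()]) and computes the 18
#' features for each of the six sensors. Undefined features (possible only on
#' degenerate, e.g. all-zero, signals) are returned as `NA` with a warning.
#'
#' @param rec an `imu_recording`.
#' @param params an [entropy_params()].
#' @param low,high band-pass edges in Hz.
#' @param spectrum_method passed to [power_spectrum()].
#' @return named numeric vector of length 108 with attributes `subject_id`,
#'   `label` and `hy`.
#' @export
extract_features <- function(rec, params = entropy_params(),
                             low = 1, high = 16,
                             spectrum_method = "periodogram") {
  signals <- preprocess_recording(rec, low = low, high = high)
  vals <- unlist(lapply(signals, sensor_features, params = params,
                        spectrum_method = spectrum_method))
  names(vals) <- feature_names()
  if (anyNA(vals)) {
    warning(sprintf("recording %s/trial %d: %d undefined feature(s) flagged NA",
                    rec$metadata$subject_id, rec$metadata$trial,
                    sum(is.na(vals))))
  }
  attr(vals, "subject_id") <- rec$metadata$subject_id
  attr(vals, "label") <- rec$metadata$group
  attr(vals, "hy") <- rec$metadata$hy
  vals
}

#' Build the subject-level feature table of a cohort
#'
#' Features are computed per trial and averaged per subject (the default),
#' or kept as one row per trial.
#'
#' @param cohort an `rm_cohort` from [generate_cohort()].
#' @param params an [entropy_params()].
#' @param aggregate `"mean"` (one row per subject, trials averaged) or
#'   `"trial"` (one row per trial).
#' @param low,high band-pass edges in Hz.
#' @param spectrum_method passed to [power_spectrum()].
#' @return data.frame with columns `subject_id`, `label`, `hy` and the 108
#'   feature columns, of class `feature_table`.
#' @export
cohort_features <- function(cohort, params = entropy_params(),
                            aggregate = c("mean", "trial"),
                            low = 1, high = 16,
                            spectrum_method = "periodogram") {
  aggregate <- match.arg(aggregate)
  rows <- list()
  for (subject in cohort) {
    mat <- do.call(rbind, lapply(subject$recordings, function(r) {
      extract_features(r, params, low = low, high = high,
                       spectrum_method = spectrum_method)
    }))
    if (aggregate == "mean") {
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = subject$spec$subject_id,
        label = subject$spec$group, hy = subject$spec$hy_score,
        t(colMeans(mat)), check.names = FALSE)
    } else {
      for (k in seq_len(nrow(mat))) {
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sprintf("%s.t%d", subject$spec$subject_id, k),
          label = subject$spec$group, hy = subject$spec$hy_score,
          t(mat[k, ]), check.names = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

# Columns of a feature table that hold features (not identifiers).
feature_columns <- function(table) {
  setdiff(colnames(table), c("subject_id", "label", "hy"))
}

#' Write / read a feature table as CSV
#'
#' One row per subject: `subject_id,label,hy,<feature columns>`; missing
#' (undefined) features serialize as empty cells.
#'
#' @param table a `feature_table`.
#' @param path file path.
#' @return `path` (write) or the table (read), invisibly for write.
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- read.csv(path, check.names = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}
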