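#' Per-sample resultant (Euclidean magnitude) of three axis series
#'
#' `R = sqrt(x^2 + y^2 + z^2)` elementwise; invariant to any rotation applied
#' jointly to the three axes.
#'
#' @param x,y,z equal-length numeric vectors.
#' @return non-negative numeric vector of the same length.
#' @export
resultant <- function(x, y, z) {
  if (length(x) != length(y) || length(x) != length(z)) {
    rm_stop("x, y, z must have equal length", "restmotion_shape_error")
  }
  sqrt(x^2 + y^2 + z^2)
}

#' Subtract the mean from a signal
#'
#' @param signal non-empty numeric vector.
#' @return zero-mean vector of the same length.
#' @export
detrend_mean <- function(signal) {
  if (length(signal) < 1) {
    rm_stop("cannot detrend an empty signal", "restmotion_shape_error")
  }
  signal - mean(signal)
}

new_resultant_signal <- function(samples, sensor_name, sampling_rate,
                                 detrended = TRUE) {
  structure(list(sensor_name = sensor_name, samples = samples,
                 sampling_rate = sampling_rate, detrended = detrended),
            class = "resultant_signal")
}

#' Preprocess a two-IMU recording into six detrended resultant signals
#'
#' Each axis series is band-pass filtered ([bandpass()]), the per-sensor
#' resultant is computed ([resultant()]) and mean-subtracted
#' ([detrend_mean()]). Sensors are returned in the fixed analysis order
#' gyr1, gyr2, acc1, acc2, mag1, mag2.
#'
#' @param rec an `imu_recording`.
#' @param low,high band-pass edges in Hz.
#' @param order Butterworth prototype order.
#' @return named list of six `resultant_signal` objects.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_pd = 1, n_healthy = 0, n_hy1 = 1,
#'                                         seed = 3))
#' sigs <- preprocess_recording(cohort[[1]]$recordings[[1]])
#' names(sigs)
#' @export
preprocess_recording <- function(rec, low = 1, high = 16, order = 4) {
  rm_assert(inherits(rec, "imu_recording"), "rec must be an imu_recording",
            "restmotion_shape_error")
  lens <- unlist(lapply(rec$series, function(m) nrow(m)))
  rm_assert(length(unique(lens)) == 1 && lens[1] >= 2,
            "all axis series must share one length >= 2",
            "restmotion_shape_error")
  out <- lapply(SENSOR_ANALYSIS_ORDER, function(sensor) {
    m <- rec$series[[sensor]]
    filtered <- apply(m, 2, bandpass, rate = rec$sampling_rate,
                      low = low, high = high, order = order)
    r <- resultant(filtered[, "x"], filtered[, "y"], filtered[, "z"])
    new_resultant_signal(detrend_mean(r), sensor, rec$sampling_rate)
  })
  names(out) <- SENSOR_ANALYSIS_ORDER
  out
}
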