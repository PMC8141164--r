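# Sensor naming: two IMUs (1 = hand, 2 = forearm), each with accelerometer,
# gyroscope, magnetometer. File-column order follows the recording dialect;
# analysis order (gyroscopes first) is fixed by preprocess_recording().
SENSOR_FILE_ORDER <- c("acc1", "gyr1", "mag1", "acc2", "gyr2", "mag2")
SENSOR_ANALYSIS_ORDER <- c("gyr1", "gyr2", "acc1", "acc2", "mag1", "mag2")
AXES <- c("x", "y", "z")

# Relative coupling of the common kinematic oscillation into each sensor
# channel. The forearm IMU sees an attenuated version of the hand motion;
# magnetometers pick up only a weak orientation-driven trace of it, which is
# what lets a ranking reproduce the accelerometer/gyroscope dominance seen on
# real data.
SENSOR_TREMOR_GAIN <- c(acc1 = 1, gyr1 = 1, mag1 = 0.1,
                        acc2 = 0.6, gyr2 = 0.6, mag2 = 0.06)
GRAVITY <- 9.81

#' Cohort configuration for the synthetic two-IMU generator
#'
#' Defaults mirror the study cohort this generator emulates: 27 subjects
#' (15 PD, 12 healthy), 11 of the PD subjects at Hoehn & Yahr stage 1 with
#' sub-visual tremor, three 15-second trials per subject at 50 Hz.
#'
#' @param n_pd number of PD-like subjects.
#' @param n_healthy number of healthy-like subjects.
#' @param n_hy1 number of PD subjects at HY stage 1 (the rest are stage 2).
#' @param sampling_rate sampling rate in Hz.
#' @param trial_duration trial length in seconds; `sampling_rate *
#'   trial_duration` must be a whole number of samples.
#' @param n_trials trials per subject.
#' @param seed master seed; identical seed gives a bit-identical cohort.
#' @param amp_hy1,amp_hy2 length-2 ranges (multiples of the per-axis noise SD)
#'   from which HY-1 and HY-2 tremor amplitudes are drawn. Defaults: HY 1 is
#'   sub-visual (0.2-0.6x noise floor), HY 2 clearly visible (2-5x).
#' @param noise_sd per-axis Gaussian noise SD (the "noise floor"), arbitrary
#'   sensor units.
#' @param tremor_band length-2 Hz range tremor frequencies are drawn from.
#' @return a validated list of class `cohort_config`.
#' @examples
#' cohort_config(seed = 7)
#' @export
cohort_config <- function(n_pd = 15, n_healthy = 12, n_hy1 = 11,
                          sampling_rate = 50, trial_duration = 15,
                          n_trials = 3, seed = 1,
                          amp_hy1 = c(0.2, 0.6), amp_hy2 = c(2, 5),
                          noise_sd = 1, tremor_band = c(3.5, 7.5)) {
  rm_assert(n_pd >= 0 && n_healthy >= 0 && n_pd + n_healthy > 0,
            "cohort must contain at least one subject")
  rm_assert(n_hy1 <= n_pd, "n_hy1 cannot exceed n_pd")
  rm_assert(sampling_rate > 0 && trial_duration > 0,
            "sampling rate and trial duration must be positive")
  rm_assert(n_trials >= 1, "n_trials must be positive")
  n_samples <- sampling_rate * trial_duration
  rm_assert(abs(n_samples - round(n_samples)) < 1e-9,
            "sampling_rate * trial_duration must be an integer sample count")
  rm_assert(length(amp_hy1) == 2 && length(amp_hy2) == 2 &&
              all(amp_hy1 >= 0) && all(amp_hy2 >= 0),
            "amplitude ranges must be non-negative length-2 vectors")
  rm_assert(noise_sd > 0, "noise_sd must be positive")
  rm_assert(length(tremor_band) == 2 && tremor_band[1] < tremor_band[2],
            "tremor_band must be an increasing length-2 Hz range")
  structure(list(
    n_pd = as.integer(n_pd), n_healthy = as.integer(n_healthy),
    n_hy1 = as.integer(n_hy1), sampling_rate = sampling_rate,
    trial_duration = trial_duration, n_trials = as.integer(n_trials),
    seed = as.integer(seed), amp_hy1 = sort(amp_hy1), amp_hy2 = sort(amp_hy2),
    noise_sd = noise_sd, tremor_band = tremor_band
  ), class = "cohort_config")
}

new_imu_recording <- function(series, sampling_rate, metadata) {
  structure(list(series = series, sampling_rate = sampling_rate,
                 metadata = metadata),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  n <- nrow(x$series[[1]])
  cat(sprintf(
    "<imu_recording> subject=%s trial=%d group=%s hy=%d  %d sensors x 3 axes x %d samples @ %g Hz (%.1f s)\n",
    x$metadata$subject_id, x$metadata$trial, x$metadata$group,
    x$metadata$hy, length(x$series), n, x$sampling_rate,
    n / x$sampling_rate))
  invisible(x)
}

# Slow positive amplitude-modulation envelope: rectified white noise smoothed
# with a one-second moving average, normalized to unit mean.
tremor_envelope <- function(n, rate) {
  w <- max(3L, as.integer(round(rate)))
  raw <- abs(rnorm(n + w))
  sm <- as.numeric(stats::filter(raw, rep(1 / w, w), sides = 2))
  sm <- sm[!is.na(sm)][seq_len(n)]
  sm / mean(sm)
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

simulate_trial <- function(spec, config, trial_idx, dirs) {
  n <- as.integer(round(config$sampling_rate * config$trial_duration))
  t <- (seq_len(n) - 1) / config$sampling_rate
  osc <- if (spec$tremor_amp > 0) {
    phase <- runif(1, 0, 2 * pi)
    env <- tremor_envelope(n, config$sampling_rate)
    spec$tremor_amp * config$noise_sd * env *
      sin(2 * pi * spec$tremor_freq * t + phase)
  } else {
    numeric(n)
  }
  series <- lapply(SENSOR_FILE_ORDER, function(sensor) {
    imu <- substring(sensor, 4)
    u <- dirs[[imu]]
    gain <- SENSOR_TREMOR_GAIN[[sensor]]
    m <- matrix(rnorm(3 * n, sd = config$noise_sd), ncol = 3,
                dimnames = list(NULL, AXES))
    if (spec$tremor_amp > 0) m <- m + outer(osc * gain, u)
    if (startsWith(sensor, "acc")) m[, "z"] <- m[, "z"] + GRAVITY
    m
  })
  names(series) <- SENSOR_FILE_ORDER
  new_imu_recording(series, config$sampling_rate,
                    list(subject_id = spec$subject_id, trial = trial_idx,
                         group = spec$group, hy = spec$hy_score))
}

#' Generate a synthetic two-IMU resting-hand cohort
#'
#' Each PD-like subject carries an amplitude-modulated sinusoid at a
#' subject-specific frequency in the tremor band, projected onto the three
#' axes by a per-IMU random unit direction and coupled into every sensor with
#' a fixed per-sensor gain; independent Gaussian noise is added to every axis
#' and a gravity-like constant offset to each accelerometer z axis. Healthy
#' subjects are noise only. HY-2 amplitudes strictly dominate HY-1 amplitudes
#' under the default ranges.
#'
#' @param config a [cohort_config()].
#' @return a list of class `rm_cohort`; one element per subject, each a list
#'   with `$spec` (subject_id, group, hy_score, tremor_freq, tremor_amp,
#'   n_trials) and `$recordings` (list of `imu_recording`).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_pd = 1, n_healthy = 1, n_hy1 = 1,
#'                                         seed = 7))
#' length(cohort)
#' @export
generate_cohort <- function(config) {
  rm_assert(inherits(config, "cohort_config"),
            "config must be built with cohort_config()")
  with_substream(config$seed, "cohort", {
    groups <- c(rep("PD", config$n_pd), rep("healthy", config$n_healthy))
    hy <- c(rep(1L, config$n_hy1), rep(2L, config$n_pd - config$n_hy1),
            rep(0L, config$n_healthy))
    subjects <- lapply(seq_along(groups), function(i) {
      amp <- switch(as.character(hy[i]),
                    "0" = 0,
                    "1" = runif(1, config$amp_hy1[1], config$amp_hy1[2]),
                    "2" = runif(1, config$amp_hy2[1], config$amp_hy2[2]))
      spec <- list(
        subject_id = sprintf("S%02d", i),
        group = groups[i],
        hy_score = hy[i],
        tremor_freq = runif(1, config$tremor_band[1], config$tremor_band[2]),
        tremor_amp = amp,
        n_trials = config$n_trials
      )
      dirs <- list(`1` = random_unit_vector(), `2` = random_unit_vector())
      recordings <- lapply(seq_len(config$n_trials), function(k) {
        simulate_trial(spec, config, k, dirs)
      })
      list(spec = spec, recordings = recordings)
    })
    structure(subjects, class = "rm_cohort", config = config)
  })
}

#' @export
print.rm_cohort <- function(x, ...) {
  groups <- vapply(x, function(s) s$spec$group, character(1))
  cat(sprintf("<rm_cohort> %d subjects (%d PD, %d healthy), %d recordings\n",
              length(x), sum(groups == "PD"), sum(groups == "healthy"),
              sum(vapply(x, function(s) length(s$recordings), integer(1)))))
  invisible(x)
}
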