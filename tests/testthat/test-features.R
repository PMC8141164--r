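# Closed forms on whole-period unit sinusoids, plus loop oracles on random
# input, for the amplitude/variability features.

test_that("amplitude features match closed forms on whole-period sinusoids", {
  s <- sine_signal(2) # 30 whole periods at 50 Hz
  expect_lt(abs(rms(s) - 1 / sqrt(2)) / (1 / sqrt(2)), 0.01)
  expect_lt(abs(peak(s) - 1), 0.01)
  expect_lt(abs(range_(s) - 2) / 2, 0.01)
  expect_lt(abs(mav(s) - 2 / pi) / (2 / pi), 0.01)
  expect_lte(abs(zero_crossing(s) - 2 * 2 * 15), 1) # 2 f T, +/- 1 boundary
})

test_that("amplitude features match simple arithmetic cases", {
  expect_equal(peak(c(-3, 2)), 2)
  expect_equal(mavfd(c(0, 1, 0, 1)), 1)
  ramp <- seq(0, 10, by = 0.5) # step d = 0.5
  expect_equal(mavsd(ramp), 1)
  expect_equal(variance(c(1, 2, 3)), 1)
  expect_equal(skewness(c(-1, 1, -1, 1)), 0)
  expect_equal(zero_crossing(rep(4, 20)), 0)
})

test_that("amplitude features match loop oracles on random input", {
  set.seed(31)
  x <- rnorm(200)
  expect_equal(rms(x), sqrt(sum(x^2) / length(x)))
  expect_equal(peak(x), max(x))
  expect_equal(mav(x), sum(abs(x)) / length(x))
  fd <- 0; for (i in 1:199) fd <- fd + abs(x[i + 1] - x[i])
  expect_equal(mavfd(x), fd / 199)
  sd2 <- 0; for (i in 1:198) sd2 <- sd2 + abs(x[i + 2] - x[i])
  expect_equal(mavsd(x), sd2 / 198)
  sgn <- sign(x); zc <- sum(sgn[-1] != sgn[-200])
  expect_equal(zero_crossing(x), zc)
  m <- mean(x); s <- sd(x)
  expect_equal(skewness(x), mean((x - m)^3) / s^3)
  expect_equal(kurtosis(x), mean((x - m)^4) / s^4)
  q <- quantile(x, c(0.25, 0.75), type = 7)
  expect_equal(intla(x), unname(q[2] - q[1]))
})

test_that("kurtosis is non-excess: a large Gaussian sample gives ~3", {
  set.seed(5)
  expect_equal(kurtosis(rnorm(1e5)), 3, tolerance = 0.1)
})

test_that("the periodogram satisfies Parseval and localizes pure tones", {
  s <- sine_signal(8)
  spec <- power_spectrum(s, 50)
  expect_equal(spec$frequencies[1], 0)
  expect_equal(spec$frequencies[length(spec$frequencies)], 25)
  expect_true(all(diff(spec$frequencies) > 0))
  expect_true(all(spec$power >= 0))
  expect_equal(sum(spec$power), mean(s^2), tolerance = 0.01)
  expect_equal(spec$frequencies[which.max(spec$power)], 8)
  # zero signal -> all-zero spectrum
  expect_equal(power_spectrum(numeric(750), 50)$power,
               numeric(length(spec$power)))
  # white noise: flat in the mean sense
  set.seed(9)
  w <- power_spectrum(rnorm(750), 50)
  lowhalf <- w$power[w$frequencies > 0 & w$frequencies <= 12.5]
  highhalf <- w$power[w$frequencies > 12.5]
  expect_lt(abs(sum(lowhalf) - sum(highhalf)) / sum(w$power), 0.2)
})

test_that("spectral features match single- and two-line spectra", {
  spec8 <- power_spectrum(sine_signal(8), 50)
  grid_step <- diff(spec8$frequencies[1:2])
  for (f in list(fmean, fpeak, f50, f80)) {
    expect_lt(abs(f(spec8) - 8), grid_step + 1e-9)
  }
  spec5 <- power_spectrum(sine_signal(5), 50)
  expect_gte(power_band(spec5) / sum(spec5$power), 0.95)
  two <- power_spectrum(sine_signal(4) + sine_signal(12), 50)
  expect_equal(fmean(two), 8, tolerance = 0.01)
  # ordering and band bound hold on an arbitrary signal
  set.seed(12)
  sp <- power_spectrum(rnorm(750), 50)
  expect_lte(f50(sp), f80(sp))
  expect_lte(f80(sp), 25)
  expect_lte(power_band(sp), sum(sp$power))
})

test_that("F50/F80 equal a first-crossing loop oracle", {
  set.seed(44)
  sp <- power_spectrum(rnorm(500), 50)
  crossing <- function(frac) {
    tot <- sum(sp$power); acc <- 0
    for (i in seq_along(sp$power)) {
      acc <- acc + sp$power[i]
      if (acc >= frac * tot) return(sp$frequencies[i])
    }
  }
  expect_equal(f50(sp), crossing(0.5))
  expect_equal(f80(sp), crossing(0.8))
})

test_that("ApEn equals its brute-force oracle and behaves on edge cases", {
  params <- entropy_params()
  expect_equal(apen(rep(2.5, 50), params), 0)
  set.seed(61)
  for (n in c(30, 50, 100)) {
    x <- rnorm(n)
    r_abs <- params$r * sd(x)
    expect_lt(abs(apen(x, params) - apen_oracle(x, 2, r_abs)), 1e-10)
  }
  expect_error(apen(c(1, 2, 3), entropy_params(m = 2)),
               class = "restmotion_shape_error")
})

test_that("FuzzyEn equals its brute-force oracle and is offset-invariant", {
  params <- entropy_params()
  set.seed(62)
  for (n in c(30, 50, 100)) {
    x <- rnorm(n)
    r_abs <- params$r * sd(x)
    expect_lt(abs(fuzzyen(x, params) -
                    fuzzyen_oracle(x, 2, r_abs, 2)), 1e-10)
  }
  x <- rnorm(80)
  expect_equal(fuzzyen(x, params), fuzzyen(x + 100, params))
})

test_that("entropies rank a sine as more regular than its shuffle", {
  params <- entropy_params()
  s <- sine_signal(4, duration = 4) # 200 samples
  for (seed in 1:10) {
    set.seed(seed)
    shuffled <- sample(s)
    expect_lt(apen(s, params), apen(shuffled, params))
    expect_lt(fuzzyen(s, params), fuzzyen(shuffled, params))
  }
})

test_that("extract_features yields 108 deterministically named values", {
  cohort <- generate_cohort(cohort_config(n_pd = 1, n_healthy = 0, n_hy1 = 1,
                                          seed = 23))
  rec <- cohort[[1]]$recordings[[1]]
  fv <- extract_features(rec)
  expect_length(fv, 108)
  expect_equal(names(fv), feature_names())
  expect_false(any(duplicated(names(fv))))
  expect_equal(sum(startsWith(names(fv), "acc")), 36)
  expect_equal(sum(startsWith(names(fv), "gyr")), 36)
  expect_equal(sum(startsWith(names(fv), "mag")), 36)
  # 18 features per sensor, in the fixed report order per sensor
  expect_equal(sub("^gyr1\\.", "", names(fv)[1:18]),
               c("rms", "peak", "mav", "mavfd", "mavsd", "fmean", "zc",
                 "fpeak", "f50", "f80", "power35_75", "apen", "fuzzyen",
                 "var", "range", "intla", "skewness", "kurtosis"))
  expect_identical(fv, extract_features(rec)) # deterministic
})

test_that("degenerate all-zero recordings flag undefined features", {
  expect_warning(fv <- extract_features(make_zero_recording()),
                 "undefined")
  amp <- fv[grep("\\.(rms|peak|mav|mavfd|mavsd|zc|power35_75|var|range|intla|apen|fuzzyen)$",
                 names(fv))]
  expect_true(all(amp == 0))
  quantile_freq <- fv[grep("\\.(fmean|fpeak|f50|f80)$", names(fv))]
  expect_true(all(is.na(quantile_freq)))
})

test_that("cohort feature tables aggregate trials per subject", {
  cohort <- generate_cohort(cohort_config(n_pd = 1, n_healthy = 1, n_hy1 = 1,
                                          seed = 29))
  tab <- cohort_features(cohort)
  expect_equal(dim(tab), c(2, 3 + 108))
  expect_equal(tab$label, c("PD", "healthy"))
  per_trial <- cohort_features(cohort, aggregate = "trial")
  expect_equal(nrow(per_trial), 6)
  f <- feature_names()[1]
  expect_equal(tab[[f]][1], mean(per_trial[[f]][1:3]))
  # CSV round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(back$subject_id, tab$subject_id)
  expect_equal(as.matrix(back[f]), as.matrix(tab[f]), tolerance = 1e-12)
})

test_that("PD cohorts carry more tremor-band power than healthy ones", {
  tab <- cached_default_table()
  bp <- rowMeans(tab[paste0(c("acc1", "gyr1"), ".power35_75")])
  expect_gt(mean(bp[tab$label == "PD"]), mean(bp[tab$label == "healthy"]))
})
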