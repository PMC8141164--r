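# Brute-force oracles, written as plain double loops straight from the
# definitions so they stay independent of the package's vectorized / C++
# implementations.

apen_oracle <- function(x, m, r_abs) {
  n <- length(x)
  phi <- function(mm) {
    M <- n - mm + 1
    logc <- numeric(M)
    for (i in seq_len(M)) {
      cnt <- 0
      for (j in seq_len(M)) {
        d <- 0
        for (k in 0:(mm - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d <= r_abs) cnt <- cnt + 1
      }
      logc[i] <- log(cnt / M)
    }
    mean(logc)
  }
  phi(m) - phi(m + 1)
}

fuzzyen_oracle <- function(x, m, r_abs, p) {
  n <- length(x)
  M <- n - m
  phase <- function(mm) {
    w <- matrix(0, M, mm)
    for (i in seq_len(M)) {
      seg <- x[i:(i + mm - 1)]
      w[i, ] <- seg - mean(seg)
    }
    pi_ <- numeric(M)
    for (i in seq_len(M)) {
      s <- 0
      for (j in seq_len(M)) {
        if (j == i) next
        d <- max(abs(w[i, ] - w[j, ]))
        s <- s + exp(-(d / r_abs)^p)
      }
      pi_[i] <- s / (M - 1)
    }
    log(mean(pi_))
  }
  phase(m) - phase(m + 1)
}

# ReliefF by the book: min-max scale, Manhattan nearest hit/miss, one
# deterministic pass over every row.
relieff_oracle <- function(x, labels, k = 1) {
  n <- nrow(x); p <- ncol(x)
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  xs <- x
  for (j in seq_len(p)) xs[, j] <- (x[, j] - lo[j]) / rng[j]
  w <- numeric(p)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sum(abs(xs[i, ] - xs[j, ]))
    d[i] <- Inf
    hit_pool <- setdiff(which(labels == labels[i]), i)
    miss_pool <- which(labels != labels[i])
    hits <- hit_pool[order(d[hit_pool])][seq_len(k)]
    misses <- miss_pool[order(d[miss_pool])][seq_len(k)]
    for (h in hits) for (f in seq_len(p)) {
      w[f] <- w[f] - abs(xs[i, f] - xs[h, f]) / (n * k)
    }
    for (mi in misses) for (f in seq_len(p)) {
      w[f] <- w[f] + abs(xs[i, f] - xs[mi, f]) / (n * k)
    }
  }
  w
}

# Whole-period sinusoid at 50 Hz.
sine_signal <- function(freq, duration = 15, rate = 50, amplitude = 1) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  amplitude * sin(2 * pi * freq * t)
}

make_feature_table <- function(x, labels,
                               ids = sprintf("S%02d", seq_len(nrow(x)))) {
  cn <- colnames(x) %||% rep("", ncol(x))
  fill <- which(is.na(cn) | cn == "")
  cn[fill] <- sprintf("f%02d", fill)
  colnames(x) <- cn
  df <- data.frame(subject_id = ids, label = labels, hy = 0L,
                   as.data.frame(x), check.names = FALSE)
  class(df) <- c("feature_table", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two well-separated Gaussian blobs as a normalized-looking feature table.
make_blob_table <- function(n_per_class = 20, p = 5, sep = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p, -sep / 2), ncol = p),
             matrix(rnorm(n_per_class * p, sep / 2), ncol = p))
  make_feature_table(x, rep(c("healthy", "PD"), each = n_per_class))
}

make_zero_recording <- function(n = 750, rate = 50) {
  series <- lapply(seq_len(6), function(i) {
    matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  })
  names(series) <- c("acc1", "gyr1", "mag1", "acc2", "gyr2", "mag2")
  structure(list(series = series, sampling_rate = rate,
                 metadata = list(subject_id = "Z0", trial = 1L,
                                 group = "healthy", hy = 0L)),
            class = "imu_recording")
}

# Default-size cohort feature table, computed once per test run.
.fixture_cache <- new.env(parent = emptyenv())
cached_default_table <- function() {
  if (is.null(.fixture_cache$table)) {
    cohort <- generate_cohort(cohort_config(seed = 42))
    .fixture_cache$cohort <- cohort
    .fixture_cache$table <- cohort_features(cohort)
  }
  .fixture_cache$table
}

strong_config <- function(seed) {
  cohort_config(amp_hy1 = c(3, 5), amp_hy2 = c(3, 5), seed = seed)
}

null_config <- function(seed) {
  cohort_config(amp_hy1 = c(0, 0), amp_hy2 = c(0, 0), seed = seed)
}
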