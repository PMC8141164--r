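# Recording text dialect: UTF-8 CSV, one metadata comment line
#   # rate_hz=50 subject=S01 trial=1 group=PD hy=2
# followed by a header line
#   time,acc1_x,acc1_y,acc1_z,gyr1_x,...,mag2_z   (19 columns)
# and one row per sample.

recording_columns <- function() {
  c("time", as.vector(t(outer(SENSOR_FILE_ORDER, AXES, paste, sep = "_"))))
}

#' Write an IMU recording to a CSV file
#'
#' @param rec an `imu_recording`.
#' @param path destination file path.
#' @return `path`, invisibly usable in pipelines.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path) {
  rm_assert(inherits(rec, "imu_recording"), "rec must be an imu_recording")
  n <- nrow(rec$series[[1]])
  df <- data.frame(time = (seq_len(n) - 1) / rec$sampling_rate)
  for (sensor in SENSOR_FILE_ORDER) {
    for (ax in AXES) df[[paste(sensor, ax, sep = "_")]] <- rec$series[[sensor]][, ax]
  }
  meta <- rec$metadata
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%g subject=%s trial=%d group=%s hy=%d",
                     rec$sampling_rate, meta$subject_id, meta$trial,
                     meta$group, meta$hy), con)
  write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_meta_line <- function(line, path) {
  body <- sub("^#\\s*", "", line)
  kv <- strsplit(strsplit(body, "\\s+")[[1]], "=")
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) {
    rm_stop(sprintf("%s: line 1: malformed metadata comment", path),
            "restmotion_parse_error")
  }
  vals <- vapply(kv, `[`, character(1), 2)
  names(vals) <- vapply(kv, `[`, character(1), 1)
  need <- c("rate_hz", "subject", "trial", "group", "hy")
  missing <- setdiff(need, names(vals))
  if (length(missing)) {
    rm_stop(sprintf("%s: line 1: metadata missing key(s): %s",
                    path, paste(missing, collapse = ", ")),
            "restmotion_parse_error")
  }
  vals
}

#' Read an IMU recording written by [write_recording()]
#'
#' Malformed headers, ragged rows and non-numeric cells raise a parse error
#' naming the offending line.
#'
#' @param path file path.
#' @return an `imu_recording`.
#' @export
read_recording <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  rm_assert(length(lines) >= 3, sprintf("%s: file too short", path),
            "restmotion_parse_error")
  if (!startsWith(lines[1], "#")) {
    rm_stop(sprintf("%s: line 1: expected metadata comment line", path),
            "restmotion_parse_error")
  }
  meta <- parse_meta_line(lines[1], path)
  header <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  expected <- recording_columns()
  if (!identical(header, expected)) {
    rm_stop(sprintf("%s: line 2: header must be '%s'", path,
                    paste(expected, collapse = ",")),
            "restmotion_parse_error")
  }
  body <- lines[-(1:2)]
  cells <- strsplit(body, ",", fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != length(expected))) {
    bad <- which(widths != length(expected))[1]
    rm_stop(sprintf("%s: line %d: expected %d columns, found %d",
                    path, bad + 2L, length(expected), widths[bad]),
            "restmotion_parse_error")
  }
  m <- suppressWarnings(
    matrix(as.numeric(unlist(cells)), nrow = length(body), byrow = TRUE)
  )
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    rm_stop(sprintf("%s: line %d: non-numeric cell", path, bad + 2L),
            "restmotion_parse_error")
  }
  colnames(m) <- expected
  series <- lapply(SENSOR_FILE_ORDER, function(sensor) {
    sub <- m[, paste(sensor, AXES, sep = "_"), drop = FALSE]
    colnames(sub) <- AXES
    sub
  })
  names(series) <- SENSOR_FILE_ORDER
  new_imu_recording(series, as.numeric(meta[["rate_hz"]]),
                    list(subject_id = meta[["subject"]],
                         trial = as.integer(meta[["trial"]]),
                         group = meta[["group"]],
                         hy = as.integer(meta[["hy"]])))
}

#' Duration of a recording in seconds
#' @param rec an `imu_recording`.
#' @return seconds, `n_samples / sampling_rate`.
#' @export
recording_duration <- function(rec) {
  nrow(rec$series[[1]]) / rec$sampling_rate
}
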