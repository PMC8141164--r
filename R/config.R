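# Experiment configuration: one YAML document drives the whole pipeline.

default_config_list <- function() {
  list(
    cohort = list(n_pd = 15, n_healthy = 12, n_hy1 = 11, sampling_rate = 50,
                  trial_duration = 15, n_trials = 3,
                  amp_hy1 = c(0.2, 0.6), amp_hy2 = c(2, 5), noise_sd = 1,
                  tremor_band = c(3.5, 7.5)),
    entropy = list(m = 2, r = 0.2, fuzzy_power = 2),
    filter_band = c(1, 16),
    classifiers = c("KNN", "SVM", "RF", "NB"),
    percentages = seq(10, 100, by = 10),
    folds = 10,
    train_fraction = 0.5,
    aggregate = "mean",
    rank_on = "train",
    seed = 1,
    out_dir = "restmotion-out"
  )
}

#' Build a validated experiment configuration
#'
#' @param ... overrides of the default fields (`cohort`, `entropy`,
#'   `filter_band`, `classifiers`, `percentages`, `folds`,
#'   `train_fraction`, `aggregate`, `rank_on`, `seed`, `out_dir`). Unknown
#'   keys are rejected.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(...) {
  cfg <- default_config_list()
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  rm_assert(length(unknown) == 0,
            sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  for (key in names(override)) {
    if (is.list(cfg[[key]]) && is.list(override[[key]]) && key != "classifiers") {
      sub_unknown <- setdiff(names(override[[key]]), names(cfg[[key]]))
      rm_assert(length(sub_unknown) == 0,
                sprintf("unknown %s key(s): %s", key,
                        paste(sub_unknown, collapse = ", ")))
      cfg[[key]][names(override[[key]])] <- override[[key]]
    } else {
      cfg[[key]] <- override[[key]]
    }
  }
  # normalize shapes so configs round-trip through YAML unchanged
  cfg$classifiers <- toupper(unlist(cfg$classifiers))
  cfg$percentages <- as.numeric(unlist(cfg$percentages))
  cfg$filter_band <- as.numeric(unlist(cfg$filter_band))
  validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

validate_config <- function(cfg) {
  band <- unlist(cfg$filter_band)
  rm_assert(length(band) == 2 && band[1] > 0 && band[2] > band[1],
            "filter_band must be an increasing positive Hz pair")
  rm_assert(band[2] < cfg$cohort$sampling_rate / 2,
            sprintf("filter high edge %g Hz is at or above Nyquist (%g Hz)",
                    band[2], cfg$cohort$sampling_rate / 2))
  kinds <- toupper(unlist(cfg$classifiers))
  rm_assert(all(kinds %in% CLASSIFIER_KINDS),
            "classifiers must be among KNN, SVM, RF, NB")
  rm_assert(all(unlist(cfg$percentages) %in% seq(10, 100, by = 10)),
            "percentages must lie on the 10..100 grid")
  rm_assert(cfg$folds >= 2, "folds must be at least 2")
  rm_assert(cfg$train_fraction > 0 && cfg$train_fraction < 1,
            "train_fraction must be in (0, 1)")
  invisible(cfg)
}

#' Read / write an experiment configuration as YAML
#'
#' The configuration round-trips unchanged through serialization.
#'
#' @param cfg an [experiment_config()].
#' @param path YAML file path.
#' @return `path` (write); an `experiment_config` (read).
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(experiment_config, raw)
}

# Small content hash (djb2) for artifact provenance headers; the output
# directory is not part of the scientific configuration.
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  s <- yaml::as.yaml(cfg)
  h <- 5381
  for (c in utf8ToInt(s)) h <- (h * 33 + c) %% 2147483647
  sprintf("%08x", h)
}

#' Run the entire pipeline from one configuration
#'
#' simulate -> preprocess -> extract -> select -> classify -> evaluate.
#' Writes `features.csv`, `ranking.csv`, `report.csv` and `splits.json` into
#' `cfg$out_dir`, each stamped with the seed and a config hash, and returns
#' the evaluation report.
#'
#' @param cfg an [experiment_config()].
#' @param write_artifacts write the output files (default TRUE).
#' @return an `evaluation_report` (invisibly when writing artifacts).
#' @export
run_all <- function(cfg, write_artifacts = TRUE) {
  rm_assert(inherits(cfg, "experiment_config"),
            "cfg must come from experiment_config()")
  cohort_args <- c(cfg$cohort, list(seed = cfg$seed))
  cohort <- generate_cohort(do.call(cohort_config, cohort_args))
  band <- unlist(cfg$filter_band)
  params <- do.call(entropy_params, cfg$entropy)
  table <- cohort_features(cohort, params, aggregate = cfg$aggregate,
                           low = band[1], high = band[2])
  report <- run_experiment(table,
                           classifiers = toupper(unlist(cfg$classifiers)),
                           percentages = unlist(cfg$percentages),
                           folds = cfg$folds, seed = cfg$seed,
                           rank_on = cfg$rank_on,
                           train_fraction = cfg$train_fraction)
  if (write_artifacts) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- sprintf("# seed=%d config_hash=%s", cfg$seed, config_hash(cfg))
    write_stamped <- function(df, file) {
      path <- file.path(cfg$out_dir, file)
      con <- file(path, "w")
      writeLines(stamp, con)
      write.csv(df, con, row.names = FALSE)
      close(con)
      path
    }
    write_stamped(table, "features.csv")
    ranked <- attr(report, "ranking")
    write_stamped(data.frame(feature = ranked$order,
                             weight = ranked$scores[ranked$order],
                             rank = seq_along(ranked$order)), "ranking.csv")
    write_stamped(report, "report.csv")
    jsonlite::write_json(
      c(list(seed = cfg$seed, config_hash = config_hash(cfg)),
        attr(report, "split")),
      file.path(cfg$out_dir, "splits.json"), auto_unbox = TRUE)
    return(invisible(report))
  }
  report
}
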