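#' Z-score normalize the feature columns of a table
#'
#' Each feature column is centred on its mean and divided by its sample
#' standard deviation (n-1 denominator), `ZS = (value - mu) / sigma`.
#' Constant columns cannot be scaled; they are dropped with a warning.
#'
#' @param table a `feature_table` (columns `subject_id`, `label`, `hy` are
#'   passed through untouched).
#' @return the normalized table; attribute `dropped` lists removed columns.
#' @export
zscore_normalize <- function(table) {
  feats <- feature_columns(table)
  rm_assert(nrow(table) >= 2, "need at least 2 rows to normalize",
            "restmotion_shape_error")
  sds <- vapply(table[feats], sd, numeric(1))
  constant <- feats[!is.na(sds) & sds == 0]
  if (length(constant)) {
    warning(sprintf("dropping %d constant column(s): %s",
                    length(constant),
                    paste(head(constant, 5), collapse = ", ")))
    table <- table[, !(colnames(table) %in% constant), drop = FALSE]
    feats <- setdiff(feats, constant)
  }
  for (f in feats) table[[f]] <- (table[[f]] - mean(table[[f]])) / sd(table[[f]])
  class(table) <- c("feature_table", "data.frame")
  attr(table, "dropped") <- constant
  table
}

#' Rank features with ReliefF
#'
#' Deterministic ReliefF for two classes: every row is visited once; for each
#' row the `k` nearest same-class rows (hits) and `k` nearest other-class
#' rows (misses) are found by Manhattan distance on min-max scaled features,
#' and each feature's weight accumulates
#' `diff(feature, row, miss) - diff(feature, row, hit)`, with
#' `diff = |a - b| / (max - min)` and averaging over rows and neighbors.
#' Ties in weight are broken by column position (earlier column ranks first).
#'
#' @param table a `feature_table` with both class labels present.
#' @param k number of nearest hits/misses per visited row.
#' @return list of class `ranked_features`: `scores` (named weights, table
#'   column order), `order` (feature names by descending weight),
#'   `tie_break = "column index"`.
#' @export
relieff_rank <- function(table, k = 1) {
  feats <- feature_columns(table)
  labels <- table$label
  classes <- unique(labels)
  if (length(classes) < 2) {
    rm_stop("ReliefF needs both classes present", "restmotion_ranking_error")
  }
  rm_assert(k >= 1 && k < min(table(labels)),
            "k must be below the size of the smaller class")
  x <- as.matrix(table[feats])
  rng <- apply(x, 2, function(col) diff(range(col)))
  rng[rng == 0] <- 1 # constant feature: diffs are all zero anyway
  xs <- sweep(sweep(x, 2, apply(x, 2, min)), 2, rng, "/")
  n <- nrow(xs)
  w <- numeric(length(feats))
  for (i in seq_len(n)) {
    d <- rowSums(abs(sweep(xs, 2, xs[i, ])))
    d[i] <- Inf
    hits <- which(labels == labels[i])
    misses <- which(labels != labels[i])
    hits <- hits[order(d[hits])][seq_len(k)]
    misses <- misses[order(d[misses])][seq_len(k)]
    for (h in hits) w <- w - abs(xs[i, ] - xs[h, ]) / (n * k)
    for (m in misses) w <- w + abs(xs[i, ] - xs[m, ]) / (n * k)
  }
  names(w) <- feats
  ord <- feats[order(-w, seq_along(w))]
  structure(list(scores = w, order = ord, k = k,
                 tie_break = "column index"),
            class = "ranked_features")
}

#' Top percentage subset of ranked features
#'
#' Returns the `round(pct / 100 * total)` best-ranked feature names,
#' round-half-up (10% of 108 features gives 11).
#'
#' @param ranked a `ranked_features` from [relieff_rank()].
#' @param pct percentage in `{10, 20, ..., 100}`.
#' @param total total feature count the percentage refers to (defaults to
#'   the number of ranked features).
#' @return character vector of feature names.
#' @export
percent_subset <- function(ranked, pct, total = length(ranked$order)) {
  rm_assert(length(pct) == 1 && pct %in% seq(10, 100, by = 10),
            "pct must be one of 10, 20, ..., 100")
  n <- floor(pct / 100 * total + 0.5) # round half up
  ranked$order[seq_len(min(n, length(ranked$order)))]
}

#' Write a ReliefF ranking report as CSV
#'
#' Columns `feature,weight,rank` in rank order.
#'
#' @param ranked a `ranked_features`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranked, path) {
  df <- data.frame(feature = ranked$order,
                   weight = ranked$scores[ranked$order],
                   rank = seq_along(ranked$order))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
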