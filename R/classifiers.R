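# Four classifiers behind one train/predict contract. None of the usual R
# machine-learning packages are available offline, so KNN, Gaussian naive
# Bayes and the polynomial-kernel SVM (a deterministic SMO solver) live here
# in R, and the random forest (120 CART trees) in src/forest.cpp.

CLASSIFIER_KINDS <- c("KNN", "SVM", "RF", "NB")

#' Specify a classifier
#'
#' Hyperparameter defaults follow the benchmarked configuration: KNN with
#' `k = 3` (Euclidean, majority vote, hypothetical ties broken toward the
#' single nearest neighbor); SVM with a polynomial kernel
#' `(gamma * <u, v> + coef0)^degree` (degree 3, cost 1,
#' `gamma = 1 / n_features`, `coef0 = 1`); random forest with 120 trees and
#' `floor(sqrt(p))` features per split; naive Bayes with Gaussian (normal)
#' class-conditional densities.
#'
#' @param method one of `"KNN"`, `"SVM"`, `"RF"`, `"NB"` (named `method`
#'   rather than `kind` so that the KNN parameter `k` cannot partially match
#'   it).
#' @param ... overrides of the method's parameters (`k`; `degree`, `cost`,
#'   `gamma`, `coef0`; `n_trees`, `mtry`), all named.
#' @param seed integer; fixes the forest (the other methods are
#'   deterministic).
#' @return list of class `classifier_spec`; the method is stored as `$kind`.
#' @export
classifier_spec <- function(method, ..., seed = 1) {
  kind <- match.arg(toupper(method), CLASSIFIER_KINDS)
  defaults <- switch(kind,
    KNN = list(k = 3),
    SVM = list(degree = 3, cost = 1, gamma = NULL, coef0 = 1),
    RF  = list(n_trees = 120, mtry = NULL),
    NB  = list(distribution = "normal"))
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  rm_assert(length(unknown) == 0,
            sprintf("unknown %s parameter(s): %s", kind,
                    paste(unknown, collapse = ", ")))
  defaults[names(override)] <- override
  structure(list(kind = kind, params = defaults, seed = as.integer(seed)),
            class = "classifier_spec")
}

table_xy <- function(table) {
  feats <- feature_columns(table)
  x <- as.matrix(table[feats])
  rm_assert(!anyNA(x), "feature table contains missing values",
            "restmotion_data_error")
  list(x = x, y = table$label, feats = feats)
}

#' Train a classifier on a normalized feature table
#'
#' @param spec a [classifier_spec()].
#' @param table a `feature_table` with no missing values and both classes
#'   present; features are assumed already Z-scored.
#' @param positive_label label treated as the positive class (used only to
#'   orient the SVM decision value).
#' @return a fitted model handle of class `rm_model` for
#'   [predict_classifier()].
#' @export
train_classifier <- function(spec, table, positive_label = "PD") {
  rm_assert(inherits(spec, "classifier_spec"),
            "spec must come from classifier_spec()")
  d <- table_xy(table)
  classes <- sort(unique(d$y))
  if (length(classes) < 2) {
    rm_stop("training table has a single class", "restmotion_fit_error")
  }
  fit <- switch(spec$kind,
    KNN = {
      if (spec$params$k > nrow(d$x) - 1) {
        rm_stop(sprintf("KNN k=%d needs more than %d training rows",
                        spec$params$k, nrow(d$x)), "restmotion_fit_error")
      }
      list(x = d$x, y = d$y)
    },
    NB = nb_fit(d$x, d$y),
    SVM = svm_fit(d$x, d$y, positive_label, spec$params),
    RF = list(x = d$x,
              y01 = as.integer(d$y == positive_label),
              seed = derive_seed(spec$seed, "forest"),
              n_trees = spec$params$n_trees,
              mtry = spec$params$mtry %||%
                       max(1L, floor(sqrt(ncol(d$x))))))
  structure(list(spec = spec, fit = fit, feats = d$feats,
                 classes = classes, positive = positive_label),
            class = "rm_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict class labels for a feature table
#'
#' @param model an `rm_model` from [train_classifier()].
#' @param table a `feature_table` whose feature columns match the training
#'   columns in name and order.
#' @return data.frame of class `rm_predictions` with columns `subject_id`,
#'   `predicted`, `truth`.
#' @export
predict_classifier <- function(model, table) {
  rm_assert(inherits(model, "rm_model"), "model must come from train_classifier()")
  if (nrow(table) == 0) {
    return(structure(data.frame(subject_id = character(),
                                predicted = character(),
                                truth = character()),
                     class = c("rm_predictions", "data.frame")))
  }
  feats <- feature_columns(table)
  if (!identical(feats, model$feats)) {
    rm_stop("feature columns do not match the training columns",
            "restmotion_schema_error")
  }
  x <- as.matrix(table[feats])
  rm_assert(!anyNA(x), "feature table contains missing values",
            "restmotion_data_error")
  pred <- switch(model$spec$kind,
    KNN = knn_predict(model$fit, x, model$spec$params$k),
    NB = nb_predict(model$fit, x),
    SVM = svm_predict(model$fit, x),
    RF = {
      votes <- rf_votes_cpp(model$fit$x, model$fit$y01, x,
                            model$fit$n_trees, model$fit$mtry,
                            model$fit$seed)
      ifelse(votes >= 0.5, model$positive,
             setdiff(model$classes, model$positive))
    })
  structure(data.frame(subject_id = table$subject_id,
                       predicted = as.character(pred),
                       truth = as.character(table$label)),
            class = c("rm_predictions", "data.frame"))
}

# ---- KNN ------------------------------------------------------------------

knn_predict <- function(fit, x, k) {
  apply(x, 1, function(row) {
    d <- sqrt(colSums((t(fit$x) - row)^2))
    ord <- order(d)
    nn <- fit$y[ord[seq_len(k)]]
    tab <- table(nn)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) > 1) fit$y[ord[1]] else winners
  })
}

# ---- Gaussian naive Bayes -------------------------------------------------

nb_fit <- function(x, y) {
  classes <- sort(unique(y))
  stats <- lapply(classes, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    mu <- colMeans(xc)
    sigma <- apply(xc, 2, sd)
    sigma[!is.finite(sigma) | sigma < 1e-9] <- 1e-9
    list(mu = mu, sigma = sigma, logprior = log(nrow(xc) / nrow(x)))
  })
  names(stats) <- classes
  list(classes = classes, stats = stats)
}

nb_predict <- function(fit, x) {
  scores <- sapply(fit$classes, function(cl) {
    s <- fit$stats[[cl]]
    apply(x, 1, function(row) {
      s$logprior + sum(stats::dnorm(row, s$mu, s$sigma, log = TRUE))
    })
  })
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  fit$classes[max.col(scores, ties.method = "first")]
}

# ---- Polynomial-kernel SVM via deterministic SMO --------------------------

poly_kernel <- function(a, b, gamma, coef0, degree) {
  (gamma * tcrossprod(a, b) + coef0)^degree
}

svm_fit <- function(x, y, positive_label, params) {
  yy <- ifelse(y == positive_label, 1, -1)
  gamma <- params$gamma %||% (1 / ncol(x))
  K <- poly_kernel(x, x, gamma, params$coef0, params$degree)
  n <- nrow(x)
  C <- params$cost
  alpha <- numeric(n)
  b <- 0
  decision <- function() as.numeric(K %*% (alpha * yy)) + b
  tol <- 1e-3
  for (pass in seq_len(200)) {
    changed <- 0
    E <- decision() - yy
    for (i in seq_len(n)) {
      Ei <- sum(K[i, ] * alpha * yy) + b - yy[i]
      if ((yy[i] * Ei < -tol && alpha[i] < C) ||
          (yy[i] * Ei > tol && alpha[i] > 0)) {
        E <- as.numeric(K %*% (alpha * yy)) + b - yy
        j <- which.max(abs(Ei - E) * (seq_len(n) != i))
        Ej <- E[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (yy[i] != yy[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - yy[j] * (Ei - Ej) / eta
        aj <- min(H, max(L, aj))
        if (abs(aj - aj_old) < 1e-7) next
        ai <- ai_old + yy[i] * yy[j] * (aj_old - aj)
        b1 <- b - Ei - yy[i] * (ai - ai_old) * K[i, i] -
          yy[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - yy[i] * (ai - ai_old) * K[i, j] -
          yy[j] * (aj - aj_old) * K[j, j]
        alpha[i] <- ai; alpha[j] <- aj
        b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else
          (b1 + b2) / 2
        changed <- changed + 1
      }
    }
    if (changed == 0) break
  }
  sv <- alpha > 1e-8
  list(sv_x = x[sv, , drop = FALSE], sv_coef = (alpha * yy)[sv], b = b,
       gamma = gamma, coef0 = params$coef0, degree = params$degree,
       positive = positive_label,
       negative = setdiff(unique(y), positive_label))
}

svm_predict <- function(fit, x) {
  f <- if (nrow(fit$sv_x) == 0) {
    rep(fit$b, nrow(x))
  } else {
    as.numeric(poly_kernel(x, fit$sv_x, fit$gamma, fit$coef0, fit$degree) %*%
                 fit$sv_coef) + fit$b
  }
  ifelse(f >= 0, fit$positive, fit$negative)
}
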