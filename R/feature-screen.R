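#' Robust scaling of a feature matrix
#'
#' Per feature: subtract the median and divide by the interquartile range
#' (quartiles by linear interpolation, the convention of the usual robust
#' scaler). Features with zero IQR are centered only and flagged, never
#' divided by zero.
#'
#' @param m Numeric matrix, subjects in rows, features in columns.
#' @return Scaled matrix with a logical `"zero_iqr"` attribute marking the
#'   flagged features.
#' @examples
#' robust_scale(cbind(a = c(1, 2, 3, 100)))
#' @export
robust_scale <- function(m) {
  m <- as.matrix(m)
  med <- apply(m, 2, stats::median)
  q <- apply(m, 2, stats::quantile, probs = c(0.25, 0.75), type = 7)
  iqr <- q[2L, ] - q[1L, ]
  zero <- stats::setNames(iqr == 0, colnames(m))
  centered <- sweep(m, 2, med, "-")
  scale_by <- ifelse(zero, 1, iqr)
  out <- sweep(centered, 2, scale_by, "/")
  attr(out, "zero_iqr") <- zero
  out
}

#' Screening configuration
#'
#' Settings for the nested cross-validated importance screen: `repeats`
#' outer repetitions of `folds`-fold cross-validation (default the 5 x
#' twofold scheme), a randomized hyperparameter search of `n_search`
#' candidates judged by inner `folds`-fold CV mean-squared error, and the
#' importance significance threshold.
#'
#' @param repeats Outer CV repetitions, default 5.
#' @param folds Folds per repetition (outer and inner), default 2.
#' @param n_search Randomized hyperparameter candidates per outer fold,
#'   default 5.
#' @param threshold Mean normalized impurity-decrease importance above which
#'   a feature is flagged significant, default 0.01.
#' @param num_trees_max Upper bound for ensemble size in the search,
#'   default 300.
#' @param max_depth_max Upper bound for tree depth in the search, default 8.
#' @param seed Integer seed controlling folds and search.
#' @return List of class `screen_config`.
#' @export
screen_config <- function(repeats = 5L, folds = 2L, n_search = 5L,
                          threshold = 0.01, num_trees_max = 300L,
                          max_depth_max = 8L, seed = 1L) {
  stopifnot(repeats >= 1L, folds >= 2L, n_search >= 1L, threshold > 0)
  structure(list(repeats = as.integer(repeats), folds = as.integer(folds),
                 n_search = as.integer(n_search), threshold = threshold,
                 num_trees_max = as.integer(num_trees_max),
                 max_depth_max = as.integer(max_depth_max),
                 seed = as.integer(seed)),
            class = "screen_config")
}

draw_rf_params <- function(cfg, p) {
  # regression forests consider most features per split (the regressor
  # convention); the search samples the considered fraction, size and depth
  list(num.trees = sample(50:cfg$num_trees_max, 1L),
       mtry = max(1L, ceiling(p * stats::runif(1L, 0.3, 1))),
       max.depth = sample(3:cfg$max_depth_max, 1L))
}

draw_gbdt_params <- function(cfg) {
  list(nrounds = sample(50:min(cfg$num_trees_max, 200L), 1L),
       max_depth = sample(2:cfg$max_depth_max, 1L),
       eta = stats::runif(1L, 0.05, 0.3),
       subsample = stats::runif(1L, 0.6, 1))
}

fit_rf <- function(x, y, params) {
  ranger::ranger(x = x, y = y, num.trees = params$num.trees,
                 mtry = min(params$mtry, ncol(x)),
                 max.depth = params$max.depth,
                 importance = "impurity", num.threads = 1L,
                 verbose = FALSE)
}

fit_gbdt <- function(x, y, params) {
  xgboost::xgboost(x, y, nrounds = params$nrounds,
                   max_depth = params$max_depth,
                   learning_rate = params$eta,
                   subsample = params$subsample,
                   objective = "reg:squarederror",
                   nthreads = 1L, verbosity = 0L)
}

normalized_importance <- function(model, feature_names) {
  if (inherits(model, "ranger")) {
    imp <- model$variable.importance[feature_names]
    imp[is.na(imp)] <- 0
  } else {
    tab <- xgboost::xgb.importance(model = model)
    imp <- stats::setNames(rep(0, length(feature_names)), feature_names)
    imp[tab$Feature] <- tab$Gain
  }
  imp <- pmax(imp, 0)
  s <- sum(imp)
  if (s > 0) imp / s else imp
}

cv_mse <- function(x, y, params, fitter, folds, fold_id) {
  errs <- vapply(seq_len(folds), function(k) {
    tr <- fold_id != k
    model <- fitter(x[tr, , drop = FALSE], y[tr], params)
    pred <- if (inherits(model, "ranger"))
      stats::predict(model, data = x[!tr, , drop = FALSE])$predictions
    else
      stats::predict(model, newdata = x[!tr, , drop = FALSE])
    mean((pred - y[!tr])^2)
  }, numeric(1L))
  mean(errs)
}

#' Rank metabolite features by impurity-decrease importance
#'
#' Fits bagged (random forest) and boosted (gradient-boosted decision tree)
#' regression ensembles of the numeric phenotype code on the scaled feature
#' matrix under repeated nested cross-validation: in each outer training
#' fold a randomized hyperparameter search is scored by inner CV
#' mean-squared error, the winning configuration is refitted on the outer
#' training data, and its normalized impurity-decrease importances are
#' recorded. Importances are averaged over all outer folds and repeats;
#' features whose mean importance exceeds the threshold in either family are
#' flagged significant. A full-data refit importance is also reported for
#' reference.
#'
#' For regression trees "impurity" is the variance reduction at each split -
#' the regression analogue of the Gini impurity decrease used for
#' classification trees. Within any single fitted ensemble the normalized
#' importances are non-negative and sum to one.
#'
#' @param m Numeric feature matrix (subjects x features), typically already
#'   passed through [robust_scale()]. Column names identify features.
#' @param target Numeric phenotype codes (see [phenotype_code()]), one per
#'   subject, with at least two distinct values.
#' @param cfg A [screen_config()].
#' @return Object of class `importance_table`: data frame with per-feature
#'   mean CV importances (`imp_rf`, `imp_gbdt`), full-data refit importances
#'   (`imp_rf_full`, `imp_gbdt_full`), and logical `significant_rf`,
#'   `significant_gbdt`, `significant` (either family) columns, sorted by
#'   max importance.
#' @export
rank_importance <- function(m, target, cfg = screen_config()) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("feature_", seq_len(ncol(m)))
  stopifnot(length(target) == nrow(m))
  if (length(unique(target)) < 2L)
    stop("target must take at least two distinct values")
  n <- nrow(m); p <- ncol(m)
  feats <- colnames(m)
  families <- list(rf = list(fit = fit_rf, draw = function() draw_rf_params(cfg, p)),
                   gbdt = list(fit = fit_gbdt, draw = function() draw_gbdt_params(cfg)))

  set.seed(cfg$seed)
  acc <- list(rf = numeric(p), gbdt = numeric(p))
  n_fits <- 0L
  for (r in seq_len(cfg$repeats)) {
    fold_id <- sample(rep_len(seq_len(cfg$folds), n))
    for (k in seq_len(cfg$folds)) {
      tr <- fold_id != k
      x_tr <- m[tr, , drop = FALSE]; y_tr <- target[tr]
      inner_id <- sample(rep_len(seq_len(cfg$folds), sum(tr)))
      for (fam in names(families)) {
        cand <- replicate(cfg$n_search, families[[fam]]$draw(), simplify = FALSE)
        scores <- vapply(cand, function(par)
          cv_mse(x_tr, y_tr, par, families[[fam]]$fit, cfg$folds, inner_id),
          numeric(1L))
        best <- cand[[which.min(scores)]]
        model <- families[[fam]]$fit(x_tr, y_tr, best)
        acc[[fam]] <- acc[[fam]] + normalized_importance(model, feats)
      }
      n_fits <- n_fits + 1L
    }
  }
  imp_rf <- acc$rf / n_fits
  imp_gbdt <- acc$gbdt / n_fits

  # full-data refit with mid-range defaults, reported alongside the CV average
  full_rf <- normalized_importance(
    fit_rf(m, target, list(num.trees = cfg$num_trees_max,
                           mtry = max(1L, floor(sqrt(p))),
                           max.depth = cfg$max_depth_max)), feats)
  full_gbdt <- normalized_importance(
    fit_gbdt(m, target, list(nrounds = 100L, max_depth = 4L, eta = 0.1,
                             subsample = 1)), feats)

  out <- data.frame(feature = feats,
                    imp_rf = unname(imp_rf), imp_gbdt = unname(imp_gbdt),
                    imp_rf_full = unname(full_rf),
                    imp_gbdt_full = unname(full_gbdt))
  out$significant_rf <- out$imp_rf > cfg$threshold
  out$significant_gbdt <- out$imp_gbdt > cfg$threshold
  out$significant <- out$significant_rf | out$significant_gbdt
  out <- out[order(-pmax(out$imp_rf, out$imp_gbdt)), ]
  rownames(out) <- NULL
  structure(out, class = c("importance_table", "data.frame"),
            threshold = cfg$threshold, config = cfg)
}

#' @export
print.importance_table <- function(x, n = 10L, ...) {
  cat("Feature importance screen (impurity decrease, nested CV average)\n")
  cat("  significance threshold:", attr(x, "threshold"),
      "| significant features:", sum(x$significant), "of", nrow(x), "\n\n")
  df <- utils::head(as.data.frame(x), n)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], signif, digits = 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
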