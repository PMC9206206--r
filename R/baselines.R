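#' Default hyperparameter grids for the baseline classifiers
#'
#' The packaged grids, searched by grouped nested cross-validation in
#' [tune_and_fit_baseline()]:
#' * logistic: inverse regularization strength `C` in {0.1, 1.0, 10.0}
#'   (ridge penalty, `lambda = 1 / (C * n)`);
#' * random forest: trees {300, 500, 800} x max depth {8, 15, 25} x
#'   min samples to split {5, 10} x min samples per leaf {2, 5} x
#'   max features {sqrt, log2, none} — 108 combinations;
#' * gradient boosting: learning rate {0.01, 0.05, 0.10} x trees
#'   {300, 500, 800} x max features {sqrt, log2, none} — 27 combinations.
#'
#' `"none"` for max features means all features are candidates at each
#' split.
#'
#' @return Named list of tibbles, one grid per classifier kind.
#' @export
default_grids <- function() {
  list(
    logistic = tibble(C = c(0.1, 1.0, 10.0)),
    random_forest = tidyr::expand_grid(
      n_trees = c(300, 500, 800),
      max_depth = c(8, 15, 25),
      min_samples_split = c(5, 10),
      min_samples_leaf = c(2, 5),
      max_features = c("sqrt", "log2", "none")
    ),
    gradient_boosting = tidyr::expand_grid(
      learning_rate = c(0.01, 0.05, 0.10),
      n_trees = c(300, 500, 800),
      max_features = c("sqrt", "log2", "none")
    )
  )
}

mtry_from <- function(max_features, p) {
  switch(max_features,
         sqrt = max(1L, floor(sqrt(p))),
         log2 = max(1L, floor(log2(p))),
         none = p,
         abort(paste0("unknown max_features: ", max_features)))
}

fit_one_baseline <- function(kind, X, y, params, seed) {
  p <- ncol(X)
  if (kind == "logistic") {
    fit <- glmnet::glmnet(X, factor(y, levels = c(FALSE, TRUE)),
                          family = "binomial", alpha = 0,
                          lambda = 1 / (params$C * nrow(X)),
                          standardize = FALSE)
    list(kind = kind, fit = fit, features = colnames(X))
  } else if (kind == "random_forest") {
    fit <- ranger::ranger(
      x = X, y = factor(ifelse(y, "abnormal", "normal"),
                        levels = c("normal", "abnormal")),
      num.trees = params$n_trees, max.depth = params$max_depth,
      min.node.size = params$min_samples_split,
      min.bucket = params$min_samples_leaf,
      mtry = mtry_from(params$max_features, p),
      probability = TRUE, importance = "impurity",
      seed = seed, num.threads = 1
    )
    list(kind = kind, fit = fit, features = colnames(X))
  } else if (kind == "gradient_boosting") {
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    eta = params$learning_rate, max_depth = 3,
                    colsample_bytree = mtry_from(params$max_features, p) / p,
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = as.numeric(y), nthread = 1),
      nrounds = params$n_trees, verbose = 0
    )
    list(kind = kind, fit = fit, features = colnames(X))
  } else {
    abort(paste0("unknown classifier kind: ", kind))
  }
}

#' Tune and fit a baseline classifier under grouped inner cross-validation
#'
#' Searches the hyperparameter grid with admission-grouped inner
#' cross-validation (default 3 folds), selecting the grid point with the
#' highest mean inner AUROC (ties: first point in grid order), then refits
#' on the full training set. A one-point grid skips the inner loop. Features
#' are expected pre-scaled ([minmax_scale()]).
#'
#' @param kind `"logistic"`, `"random_forest"` or `"gradient_boosting"`.
#' @param newdata Training data frame of features.
#' @param labels Logical vector, `TRUE` = abnormal.
#' @param groups Admission identifier per row.
#' @param grid Hyperparameter tibble (default: the packaged grid for
#'   `kind`).
#' @param inner_k Inner folds (default 3).
#' @param seed Integer seed (inner fold assignment and stochastic fits).
#' @return A `baseline_model`; score new data with [predict_baseline()].
#' @export
tune_and_fit_baseline <- function(kind, newdata, labels, groups,
                                  grid = NULL, inner_k = 3, seed = 1) {
  kinds <- c("logistic", "random_forest", "gradient_boosting")
  if (!kind %in% kinds) abort(paste0("unknown classifier kind: ", kind))
  if (is.null(grid)) grid <- default_grids()[[kind]]
  if (nrow(grid) == 0) abort("tune_and_fit_baseline: empty grid")
  X <- as.matrix(as.data.frame(newdata))
  if (nrow(grid) == 1) {
    best <- 1L
  } else {
    folds <- assign_folds(unique(groups), k = inner_k, seed = seed)
    fold_of <- folds$fold[match(groups, folds$admission_id)]
    mean_auc <- vapply(seq_len(nrow(grid)), function(g) {
      aucs <- vapply(0:(inner_k - 1), function(f) {
        tr <- fold_of != f
        m <- fit_one_baseline(kind, X[tr, , drop = FALSE], labels[tr],
                              grid[g, ], seed)
        auroc(labels[!tr],
              baseline_scores(m, X[!tr, , drop = FALSE]))
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }, numeric(1))
    best <- which.max(mean_auc)  # first max wins ties
  }
  model <- fit_one_baseline(kind, X, labels, grid[best, ], seed)
  model$params <- grid[best, ]
  class(model) <- "baseline_model"
  model
}

baseline_scores <- function(model, X) {
  if (model$kind == "logistic") {
    as.vector(predict(model$fit, newx = X, type = "response"))
  } else if (model$kind == "random_forest") {
    predict(model$fit, data = X, num.threads = 1)$predictions[, "abnormal"]
  } else {
    predict(model$fit, newdata = xgboost::xgb.DMatrix(X, nthread = 1))
  }
}

#' Abnormality scores from a fitted baseline model
#'
#' @param model A `baseline_model` from [tune_and_fit_baseline()].
#' @param newdata Data frame of (pre-scaled) features.
#' @return Numeric vector of P(abnormal) scores.
#' @export
predict_baseline <- function(model, newdata) {
  stopifnot(inherits(model, "baseline_model"))
  baseline_scores(model, as.matrix(as.data.frame(newdata)))
}

#' Feature relevance ranks of a fitted model
#'
#' Ranks features by model-specific relevance, 1 = most relevant: absolute
#' coefficient for the logistic model, impurity importance for the random
#' forest, gain for gradient boosting. For the fuzzy classifier, relevance
#' is the wrapper selection order; unselected features share the worst rank
#' (number of candidates + 1). Ties get the average rank.
#'
#' @param model A `baseline_model` or `fuzzy_rulebase`.
#' @param features Character vector of all candidate feature names.
#' @return Tibble `feature`, `rank`.
#' @export
feature_ranks <- function(model, features) {
  if (inherits(model, "fuzzy_rulebase")) {
    sel <- model$selected_features
    if (is.null(sel)) sel <- model$features
    rk <- rep(length(features) + 1, length(features))
    names(rk) <- features
    rk[sel] <- seq_along(sel)
    return(tibble(feature = features, rank = unname(rk[features])))
  }
  stopifnot(inherits(model, "baseline_model"))
  imp <- if (model$kind == "logistic") {
    co <- as.matrix(coef(model$fit))[, 1]
    abs(co[setdiff(names(co), "(Intercept)")])
  } else if (model$kind == "random_forest") {
    ranger::importance(model$fit)
  } else {
    it <- xgboost::xgb.importance(model = model$fit)
    v <- setNames(rep(0, length(model$features)), model$features)
    v[it$Feature] <- it$Gain
    v
  }
  v <- setNames(rep(0, length(features)), features)
  v[names(imp)] <- imp
  tibble(feature = features, rank = rank(-v, ties.method = "average"))
}
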