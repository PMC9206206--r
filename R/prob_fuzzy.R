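#' Probabilistic Takagi-Sugeno fuzzy classifier
#'
#' The classifier is a small base of fuzzy rules. Each rule has one Gaussian
#' membership function per selected feature (antecedent) and a probabilistic
#' consequent: a probability per class. A sample's degree of activation of a
#' rule is the product t-norm of its per-feature memberships; the class
#' score is the activation-weighted average of the rule consequents, which
#' always sums to 1 across classes. Rule antecedents come from fuzzy c-means
#' clustering; the antecedent features come from wrapper forward selection.
#'
#' @name prob_fuzzy
NULL

# numeric floor keeping activations strictly positive under underflow
.activation_floor <- 1e-300

as_feature_matrix <- function(x, features) {
  x <- as.data.frame(x)
  missing_f <- setdiff(features, names(x))
  if (length(missing_f) > 0) {
    abort(paste0("feature vector is missing feature(s): ",
                 paste(missing_f, collapse = ", ")))
  }
  as.matrix(x[, features, drop = FALSE])
}

#' Degree of activation of fuzzy rules
#'
#' For each sample and rule, the product over the rule's features of the
#' Gaussian membership `exp(-(x - center)^2 / (2 * spread^2))`. The degree
#' lies in `(0, 1]`: Gaussians are strictly positive, and a tiny numeric
#' floor guards against underflow for extreme inputs.
#'
#' @param rules A rule set (from [induce_rules()] or a fitted
#'   `fuzzy_rulebase`).
#' @param newdata Data frame (or matrix) supplying all rule features.
#' @return Matrix of activations, samples x rules.
#' @export
rule_activation <- function(rules, newdata) {
  X <- as_feature_matrix(newdata, rules$features)
  k <- nrow(rules$centers)
  A <- matrix(0, nrow(X), k)
  for (j in seq_len(k)) {
    z <- sweep(X, 2, rules$centers[j, ], "-")
    z <- sweep(z, 2, rules$spreads[j, ], "/")
    A[, j] <- exp(-rowSums(z^2) / 2)
  }
  pmax(A, .activation_floor)
}

#' Induce rule antecedents by fuzzy c-means clustering
#'
#' Clusters the training samples with fuzzy c-means (fuzzifier 2, relative
#' tolerance 1e-5, at most 300 iterations, seeded initialization). Each
#' cluster becomes one rule: per feature, the center is the cluster's
#' membership-weighted mean and the spread the membership-weighted standard
#' deviation, floored at 1e-3 of the feature's training span so memberships
#' stay proper even on degenerate (e.g. all-duplicate) data. `k_rules = 1`
#' degenerates to the overall mean and standard deviation.
#'
#' @param newdata Training data frame/matrix.
#' @param features Feature columns to use (default: all columns).
#' @param k_rules Number of rules (clusters), `1 <= k_rules <= n`.
#' @param seed Integer seed for the clustering initialization.
#' @return A rule set: list with `features`, `centers` (k x p), `spreads`
#'   (k x p).
#' @export
induce_rules <- function(newdata, features = NULL, k_rules = 3, seed = 1) {
  if (is.null(features)) features <- colnames(as.data.frame(newdata))
  X <- as_feature_matrix(newdata, features)
  n <- nrow(X)
  if (k_rules < 1) abort("induce_rules: k_rules must be >= 1")
  if (k_rules > n) abort("induce_rules: k_rules exceeds the number of samples")
  span <- apply(X, 2, function(col) diff(range(col)))
  floor_s <- pmax(1e-3 * span, 1e-3 * ifelse(span == 0, 1, span))
  floor_s[span == 0] <- 1e-3
  n_distinct_rows <- nrow(unique(X))
  if (k_rules == 1 || n_distinct_rows < 2) {
    centers <- matrix(colMeans(X), 1, ncol(X),
                      dimnames = list(NULL, features))
    spreads <- matrix(pmax(apply(X, 2, stats::sd), floor_s), 1, ncol(X),
                      dimnames = list(NULL, features))
    if (k_rules > 1) {  # duplicate degenerate rule to the requested size
      centers <- centers[rep(1, k_rules), , drop = FALSE]
      spreads <- spreads[rep(1, k_rules), , drop = FALSE]
    }
    spreads[is.na(spreads)] <- floor_s[is.na(spreads[1, ])]
    return(list(features = features, centers = centers, spreads = spreads))
  }
  k_eff <- min(k_rules, n_distinct_rows)
  set.seed(seed)
  cm <- e1071::cmeans(X, centers = k_eff, m = 2, iter.max = 300,
                      control = list(reltol = 1e-5))
  w <- cm$membership^2                      # fuzzifier-weighted memberships
  centers <- matrix(NA_real_, k_rules, ncol(X),
                    dimnames = list(NULL, features))
  spreads <- matrix(NA_real_, k_rules, ncol(X),
                    dimnames = list(NULL, features))
  for (j in seq_len(k_eff)) {
    wj <- w[, j] / sum(w[, j])
    cj <- colSums(X * wj)
    vj <- colSums(sweep(X, 2, cj, "-")^2 * wj)
    centers[j, ] <- cj
    spreads[j, ] <- pmax(sqrt(vj), floor_s)
  }
  if (k_eff < k_rules) {  # recycle when distinct rows limit the clusters
    extra <- ((k_eff):(k_rules - 1)) %% k_eff + 1
    centers[(k_eff + 1):k_rules, ] <- centers[extra, , drop = FALSE]
    spreads[(k_eff + 1):k_rules, ] <- spreads[extra, , drop = FALSE]
  }
  list(features = features, centers = centers, spreads = spreads)
}

#' Estimate probabilistic rule consequents
#'
#' Per rule, the consequent probability of class C is the share of the
#' rule's total training activation mass contributed by samples of class C:
#' `sum over {i : y_i = C} of activation_i / sum over i of activation_i`.
#' Consequents therefore sum to 1 per rule and are invariant to rescaling
#' all activations. Rules with total activation below 1e-12 fall back to the
#' class priors and are flagged.
#'
#' @param rules A rule set from [induce_rules()].
#' @param newdata Training data.
#' @param labels Logical vector, `TRUE` = abnormal (positive class).
#' @return The rule set with a `consequents` matrix (k x 2, columns
#'   `normal`, `abnormal`), `priors`, and `degenerate_rules` flags.
#' @export
fit_consequents <- function(rules, newdata, labels) {
  if (length(labels) == 0) abort("fit_consequents: no training samples")
  A <- rule_activation(rules, newdata)
  tot <- colSums(A)
  pos <- colSums(A[labels, , drop = FALSE])
  priors <- c(normal = mean(!labels), abnormal = mean(labels))
  degenerate <- tot < 1e-12
  p_ab <- ifelse(degenerate, priors[["abnormal"]], pos / tot)
  rules$consequents <- cbind(normal = 1 - p_ab, abnormal = p_ab)
  rules$priors <- priors
  rules$degenerate_rules <- degenerate
  if (any(degenerate)) {
    warn(paste0("fit_consequents: ", sum(degenerate),
                " rule(s) had no activation mass; consequents set to priors"))
  }
  rules
}

#' Fit a probabilistic Takagi-Sugeno fuzzy classifier
#'
#' Induces `k_rules` rule antecedents by fuzzy c-means on the given features
#' and estimates probabilistic consequents on the training labels.
#'
#' @param newdata Training data frame.
#' @param labels Logical vector, `TRUE` = abnormal.
#' @param features Antecedent features (default: all columns of `newdata`).
#' @param k_rules Number of rules (default 3; keep small for interpretable
#'   rules).
#' @param seed Seed for the clustering initialization.
#' @return A `fuzzy_rulebase`.
#' @export
fit_fuzzy <- function(newdata, labels, features = NULL, k_rules = 3,
                      seed = 1) {
  if (is.null(features)) features <- colnames(as.data.frame(newdata))
  rules <- induce_rules(newdata, features, k_rules = k_rules, seed = seed)
  rules <- fit_consequents(rules, newdata, labels)
  structure(rules, class = "fuzzy_rulebase")
}

#' Class scores of the fuzzy classifier
#'
#' The score of class C is the activation-weighted average of the rule
#' consequents: `sum_k a_k * consequent_k(C) / sum_k a_k`. Scores sum to 1
#' across classes. Samples activating no rule (total activation below
#' 1e-12) receive the class priors.
#'
#' @param rule_base A fitted `fuzzy_rulebase`.
#' @param newdata Data to score.
#' @return Tibble with columns `normal`, `abnormal` (scores summing to 1)
#'   and `predicted` (`"abnormal"` iff its score >= 0.5; ties go to
#'   abnormal).
#' @export
predict_scores <- function(rule_base, newdata) {
  if (is.null(rule_base$consequents)) {
    abort("predict_scores: rule base has no consequents; fit it first")
  }
  A <- rule_activation(rule_base, newdata)
  denom <- rowSums(A)
  p_ab <- as.vector(A %*% rule_base$consequents[, "abnormal"]) / denom
  dead <- denom < 1e-12
  if (any(dead)) p_ab[dead] <- rule_base$priors[["abnormal"]]
  tibble(normal = 1 - p_ab, abnormal = p_ab,
         predicted = ifelse(p_ab >= 0.5, "abnormal", "normal"))
}

#' @export
predict.fuzzy_rulebase <- function(object, newdata, ...) {
  predict_scores(object, newdata)
}

#' Wrapper forward selection of antecedent features
#'
#' Greedy forward selection on a grouped inner validation split: admissions
#' (groups) are shuffled with the given seed and one third held out for
#' validation. Starting from the empty set, each step adds the candidate
#' whose inclusion maximizes validation AUROC (ties broken by candidate
#' order). The first step always accepts the best single feature; later
#' steps stop when the best improvement is below `epsilon`.
#'
#' @param newdata Training data frame containing the candidate features.
#' @param labels Logical vector, `TRUE` = abnormal.
#' @param groups Admission identifier per row (grouping unit of the split).
#' @param candidates Candidate feature names (default: all columns).
#' @param k_rules Rules per fitted model.
#' @param epsilon Minimum AUROC improvement to keep adding (default 0.005).
#' @param seed Seed for the inner split and clustering.
#' @return Character vector of selected features, in selection order.
#' @export
wrapper_select <- function(newdata, labels, groups, candidates = NULL,
                           k_rules = 3, epsilon = 0.005, seed = 1) {
  if (is.null(candidates)) candidates <- colnames(as.data.frame(newdata))
  if (length(candidates) < 1) abort("wrapper_select: no candidate features")
  ids <- unique(groups)
  set.seed(seed)
  ids <- sample(ids)
  n_val <- max(1L, floor(length(ids) / 3))
  val_ids <- ids[seq_len(n_val)]
  in_val <- groups %in% val_ids
  if (length(unique(labels[in_val])) < 2 || length(unique(labels[!in_val])) < 2) {
    abort("wrapper_select: degenerate inner split (a side has a single class)")
  }
  train <- as.data.frame(newdata)[!in_val, , drop = FALSE]
  val <- as.data.frame(newdata)[in_val, , drop = FALSE]
  y_tr <- labels[!in_val]
  y_va <- labels[in_val]
  selected <- character(0)
  current <- -Inf
  remaining <- candidates
  while (length(remaining) > 0) {
    scores <- vapply(remaining, function(f) {
      rb <- fit_fuzzy(train, y_tr, features = c(selected, f),
                      k_rules = k_rules, seed = seed)
      auroc(y_va, predict_scores(rb, val)$abnormal)
    }, numeric(1))
    best <- which.max(scores)  # first max wins ties (candidate order)
    if (length(selected) == 0) {
      selected <- remaining[best]
      current <- scores[best]
    } else if (scores[best] - current >= epsilon) {
      selected <- c(selected, remaining[best])
      current <- scores[best]
    } else {
      break
    }
    remaining <- setdiff(remaining, selected)
  }
  selected
}

#' Fit the fuzzy classifier with wrapper feature selection
#'
#' Convenience wrapper: selects antecedent features with [wrapper_select()]
#' on the training data, then fits the final rule base on all training rows
#' with the selected features.
#'
#' @inheritParams wrapper_select
#' @return A `fuzzy_rulebase` with an extra `selected_features` element (in
#'   selection order).
#' @export
fit_fuzzy_classifier <- function(newdata, labels, groups, candidates = NULL,
                                 k_rules = 3, epsilon = 0.005, seed = 1) {
  sel <- wrapper_select(newdata, labels, groups, candidates,
                        k_rules = k_rules, epsilon = epsilon, seed = seed)
  rb <- fit_fuzzy(newdata, labels, features = sel, k_rules = k_rules,
                  seed = seed)
  rb$selected_features <- sel
  rb
}

#' @export
print.fuzzy_rulebase <- function(x, ...) {
  cat("<fuzzy_rulebase> ", nrow(x$centers), " rules over features: ",
      paste(x$features, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize a fitted rule base to JSON
#'
#' Writes features, per-rule Gaussian centers and spreads, probabilistic
#' consequents and class priors so fitted rules can be inspected or audited.
#'
#' @param rule_base A fitted `fuzzy_rulebase`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_rulebase <- function(rule_base, path) {
  obj <- list(
    features = rule_base$features,
    rules = lapply(seq_len(nrow(rule_base$centers)), function(j) {
      list(centers = as.list(setNames(rule_base$centers[j, ],
                                      rule_base$features)),
           spreads = as.list(setNames(rule_base$spreads[j, ],
                                      rule_base$features)),
           consequents = as.list(rule_base$consequents[j, ]))
    }),
    priors = as.list(rule_base$priors)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @exportS3Method generics::tidy
tidy.fuzzy_rulebase <- function(x, ...) {
  k <- nrow(x$centers)
  purrr::map(seq_len(k), function(j) {
    tibble(rule = j, feature = x$features,
           center = unname(x$centers[j, ]), spread = unname(x$spreads[j, ]),
           consequent_normal = unname(x$consequents[j, "normal"]),
           consequent_abnormal = unname(x$consequents[j, "abnormal"]))
  }) |> purrr::list_rbind()
}

#' @exportS3Method generics::glance
glance.fuzzy_rulebase <- function(x, ...) {
  tibble(n_rules = nrow(x$centers), n_features = length(x$features),
         prior_abnormal = unname(x$priors[["abnormal"]]))
}
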