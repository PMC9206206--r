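#' Assign admissions to cross-validation folds
#'
#' Seeded shuffle followed by round-robin assignment, so every admission
#' lands in exactly one fold, all events of an admission share its fold, and
#' fold sizes differ by at most one admission.
#'
#' @param admission_ids Admission identifiers (duplicates collapsed).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Tibble `admission_id`, `fold` (`0 .. k-1`).
#' @export
assign_folds <- function(admission_ids, k = 10, seed = 1) {
  ids <- unique(admission_ids)
  if (length(ids) < k) {
    abort(paste0("assign_folds: ", length(ids), " admissions cannot fill ",
                 k, " folds"))
  }
  set.seed(seed)
  ids <- sample(ids)
  tibble(admission_id = ids, fold = (seq_along(ids) - 1L) %% as.integer(k))
}

#' Min-max scaling with training-set statistics
#'
#' Scales each numeric column of `newdata` as
#' `(x - min_train) / (max_train - min_train)` using the training column's
#' minimum and maximum. Held-out values may fall outside `[0, 1]` (no
#' clipping). Constant training columns scale to all zeros.
#'
#' @param train Training data frame (numeric columns).
#' @param newdata Data to scale (default: the training data).
#' @return `newdata` with scaled numeric columns.
#' @export
minmax_scale <- function(train, newdata = train) {
  num_cols <- names(train)[vapply(train, is.numeric, logical(1))]
  out <- newdata
  for (cn in num_cols) {
    lo <- min(train[[cn]])
    hi <- max(train[[cn]])
    out[[cn]] <- if (hi > lo) (newdata[[cn]] - lo) / (hi - lo)
                 else rep(0, nrow(newdata))
  }
  out
}

#' Area under the ROC curve by rank statistic
#'
#' The probability that a uniformly chosen positive (abnormal) sample
#' outscores a uniformly chosen negative one, with ties counting one half —
#' the Mann-Whitney form of the AUROC.
#'
#' @param labels Logical vector, `TRUE` = abnormal (positive class).
#' @param scores Numeric scores, larger = more abnormal.
#' @return AUROC in `[0, 1]`, or `NA` if a class is absent.
#' @export
auroc <- function(labels, scores) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)  # midranks: ties count 1/2
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Interpolation-free summation over score thresholds (average precision):
#' thresholds sweep the distinct scores from most to least abnormal and each
#' recall increment contributes its precision,
#' `AP = sum_i (R_i - R_{i-1}) * P_i`.
#'
#' @inheritParams auroc
#' @return PR-AUC in `[0, 1]`, or `NA` if a class is absent.
#' @export
pr_auc <- function(labels, scores) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  if (n1 == 0 || sum(!labels) == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  s <- scores[o]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied block
  precision <- tp[keep] / (tp[keep] + fp[keep])
  recall <- tp[keep] / n1
  sum(diff(c(0, recall)) * precision)
}

#' Compute the full performance metric panel
#'
#' Confusion-based metrics (abnormal = positive class): specificity
#' `TN/(FP+TN)`, sensitivity `TP/(FN+TP)`, accuracy, precision `TP/(FP+TP)`,
#' negative predictive value `TN/(FN+TN)`, F1 (harmonic mean of precision
#' and sensitivity), mean G `sqrt(sensitivity * specificity)` and index
#' balanced accuracy `(mean G)^2 * (1 + sensitivity - specificity)`; plus
#' the threshold-free AUROC and PR-AUC from the scores. Ratios with a zero
#' denominator (and rank metrics on single-class labels) are `NA`.
#'
#' @param labels Logical vector, `TRUE` = abnormal.
#' @param predicted Predicted classes: logical, or `"abnormal"`/`"normal"`.
#' @param scores Numeric abnormality scores.
#' @return One-row tibble with the 10 metrics and the confusion counts.
#' @export
compute_metrics <- function(labels, predicted, scores) {
  labels <- as.logical(labels)
  if (is.character(predicted) || is.factor(predicted)) {
    predicted <- as.character(predicted) == "abnormal"
  }
  tp <- sum(labels & predicted)
  fp <- sum(!labels & predicted)
  tn <- sum(!labels & !predicted)
  fn <- sum(labels & !predicted)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- div(tp, fn + tp)
  spec <- div(tn, fp + tn)
  prec <- div(tp, fp + tp)
  npv <- div(tn, fn + tn)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  mg <- if (is.na(sens) || is.na(spec)) NA_real_ else sqrt(sens * spec)
  iba <- if (is.na(mg)) NA_real_ else mg^2 * (1 + sens - spec)
  tibble(
    specificity = spec, sensitivity = sens,
    accuracy = div(tp + tn, tp + tn + fp + fn),
    precision = prec, npv = npv, f1 = f1,
    auroc = auroc(labels, scores), pr_auc = pr_auc(labels, scores),
    mean_g = mg, iba = iba,
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

metric_names <- function() {
  c("specificity", "sensitivity", "accuracy", "precision", "npv", "f1",
    "auroc", "pr_auc", "mean_g", "iba")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null distribution when both samples are small (fewer than 50 per
#' side) and tie-free; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param values_a,values_b Numeric samples (e.g. 10 fold-level metric
#'   values per approach).
#' @return Two-sided p-value.
#' @export
wilcoxon_ranksum_2sided <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    abort("wilcoxon_ranksum_2sided: empty sample")
  }
  suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                       correct = TRUE)$p.value
  )
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjustment: `adjusted_i = min over j >= rank(i) of m * p_(j) / j`
#' capped at 1 (the cumulative-minimum form computed by
#' `stats::p.adjust(method = "BH")`); a result is significant iff its
#' adjusted p-value is at most `fdr`.
#'
#' @param p_values Raw p-values in `[0, 1]`.
#' @param fdr False discovery rate (default 0.05).
#' @return Tibble `p_value`, `p_adjusted`, `significant`.
#' @export
benjamini_hochberg <- function(p_values, fdr = 0.05) {
  if (length(p_values) < 1) abort("benjamini_hochberg: no p-values")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("benjamini_hochberg: p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  tibble(p_value = p_values, p_adjusted = adj, significant = adj <= fdr)
}

#' Aggregate per-fold, per-classifier feature ranks
#'
#' Mean rank per feature across folds within each classifier, then mean of
#' those across classifiers; the final ordering is ascending by mean rank
#' with ties broken alphabetically by feature name. Every classifier must
#' rank every feature in every fold.
#'
#' @param ranks Tibble with columns `classifier`, `fold`, `feature`, `rank`.
#' @return Tibble `feature`, `mean_rank`, `rank` (final 1-based position).
#' @export
aggregate_feature_ranks <- function(ranks) {
  need <- c("classifier", "fold", "feature", "rank")
  if (!all(need %in% names(ranks))) {
    abort("aggregate_feature_ranks: need columns classifier, fold, feature, rank")
  }
  n_feat <- dplyr::n_distinct(ranks$feature)
  complete <- ranks |>
    dplyr::count(classifier, fold) |>
    dplyr::pull(n)
  if (any(complete != n_feat)) {
    abort("aggregate_feature_ranks: some (classifier, fold) is missing features")
  }
  ranks |>
    dplyr::group_by(classifier, feature) |>
    dplyr::summarise(fold_mean = mean(rank), .groups = "drop") |>
    dplyr::group_by(feature) |>
    dplyr::summarise(mean_rank = mean(.data$fold_mean), .groups = "drop") |>
    dplyr::arrange(mean_rank, feature) |>
    dplyr::mutate(rank = dplyr::row_number())
}
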