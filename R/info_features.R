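#' Binary Shannon entropy in bits
#'
#' `-p*log2(p) - (1-p)*log2(1-p)` with the convention `0*log2(0) = 0`.
#' Vectorized.
#'
#' @param p Probability (or vector of probabilities) of the normal class.
#' @return Entropy in `[0, 1]` bits.
#' @export
binary_entropy <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  term <- function(q) ifelse(q <= 0, 0, -q * log2(q))
  term(p) + term(1 - p)
}

#' Estimate the pretest probability table
#'
#' For each run length M (the count of immediately preceding consecutive
#' normal same-test results within an admission), estimates the probability
#' that the next result is normal as the pooled ratio
#' `count(normal at M) / count(tested at M)` across the supplied (training)
#' events. If the events carry a `test_type` column the table is estimated
#' per test type.
#'
#' @param events Tibble with columns `run_length_M`, `is_normal` and
#'   optionally `test_type`. Must contain training admissions only.
#' @return A `pretest_table` tibble: `test_type` (if supplied), `M`,
#'   `n_normal`, `n_total`, `probability`.
#' @export
#' @examples
#' ev <- tibble::tibble(run_length_M = c(0, 1, 2, 0, 0, 1, 2),
#'                      is_normal = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
#' estimate_pretest_table(ev)
estimate_pretest_table <- function(events) {
  if (!all(c("run_length_M", "is_normal") %in% names(events))) {
    abort("estimate_pretest_table: need columns run_length_M and is_normal")
  }
  if (nrow(events) == 0) abort("estimate_pretest_table: empty training set")
  keys <- if ("test_type" %in% names(events)) c("test_type", "M") else "M"
  tab <- events |>
    dplyr::mutate(M = as.integer(run_length_M)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_normal = sum(is_normal), n_total = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(probability = n_normal / n_total) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
  class(tab) <- c("pretest_table", class(tab))
  tab
}

#' Look up pretest probabilities for new events
#'
#' Returns the training estimate for each requested run length. Run lengths
#' not observed in training are clamped to the largest observed M (the
#' least-biased available estimate under monotone run-length persistence).
#'
#' @param table A `pretest_table` from [estimate_pretest_table()].
#' @param M Integer run length(s).
#' @param test_type Test type(s), required iff the table is per-test.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
lookup_pretest <- function(table, M, test_type = NULL) {
  if (nrow(table) == 0) abort("lookup_pretest: empty pretest table")
  per_test <- "test_type" %in% names(table)
  if (per_test && is.null(test_type)) {
    tts <- unique(table$test_type)
    if (length(tts) > 1) {
      abort("lookup_pretest: table covers several test types; supply test_type")
    }
    test_type <- tts  # unambiguous single-test table
  }
  n <- length(M)
  tt <- if (per_test) rep_len(test_type, n) else rep_len("", n)
  out <- numeric(n)
  groups <- if (per_test) split(seq_len(n), tt) else list(all = seq_len(n))
  for (g in names(groups)) {
    idx <- groups[[g]]
    sub <- if (per_test) table[table$test_type == g, ] else table
    if (nrow(sub) == 0) {
      abort(paste0("lookup_pretest: no entries for test type '", g, "'"))
    }
    hit <- match(M[idx], sub$M)
    hit[is.na(hit)] <- which.max(sub$M)  # clamp to max observed M
    out[idx] <- sub$probability[hit]
  }
  out
}

#' Freedman-Diaconis histogram bin width
#'
#' `2 * IQR / N^(1/3)`. When the IQR is zero (heavily tied data) the rule is
#' undefined and a Sturges-style fallback is used instead: the data span
#' divided into `ceiling(log2(N)) + 1` equal-width bins; a zero span yields
#' width 0, which downstream binning treats as a single bin.
#'
#' @param values Numeric vector (>= 2 finite values).
#' @return Scalar bin width.
#' @export
fd_bin_width <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) abort("fd_bin_width: need at least 2 finite values")
  iqr <- stats::IQR(values)
  if (iqr > 0) return(2 * iqr / n^(1 / 3))
  span <- max(values) - min(values)
  if (span == 0) return(0)
  span / (ceiling(log2(n)) + 1)
}

#' Estimate a conditional-entropy table for one feature
#'
#' Bins a continuous feature with the Freedman-Diaconis width (categorical
#' features use their categories as bins) over the training span and, per
#' bin, records the share of normal outcomes and the binary entropy of the
#' outcome in bits. Values most associated with one outcome get low entropy;
#' uncertain values get entropy near 1 bit. The pooled (marginal) outcome
#' entropy is stored as the fallback for values outside the training
#' support, empty bins and unseen categories.
#'
#' @param values Training feature values (numeric, or character/factor for
#'   `kind = "categorical"`).
#' @param labels Logical training outcomes (`TRUE` = normal).
#' @param kind `"continuous"` or `"categorical"`.
#' @return An `entropy_table` object.
#' @export
estimate_entropy_table <- function(values, labels,
                                   kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (length(values) == 0) abort("estimate_entropy_table: empty training set")
  if (length(values) != length(labels)) {
    abort("estimate_entropy_table: values and labels differ in length")
  }
  marginal_p <- mean(labels)
  marginal_h <- binary_entropy(marginal_p)
  if (kind == "categorical") {
    values <- as.character(values)
    bins <- tibble(category = values, is_normal = labels) |>
      dplyr::group_by(.data$category) |>
      dplyr::summarise(n_obs = dplyr::n(), p_normal = mean(is_normal),
                       .groups = "drop") |>
      dplyr::mutate(entropy_bits = binary_entropy(p_normal))
    edges <- NULL
  } else {
    if (any(!is.finite(values))) {
      abort("estimate_entropy_table: non-finite continuous values")
    }
    lo <- min(values)
    hi <- max(values)
    width <- if (length(values) >= 2) fd_bin_width(values) else 0
    if (width <= 0 || hi == lo) {
      edges <- c(lo, hi)             # single degenerate bin
    } else {
      n_bins <- max(1L, ceiling((hi - lo) / width))
      edges <- lo + width * (0:n_bins)
    }
    idx <- bin_index(values, edges)
    n_bins_total <- length(edges) - 1L
    counts <- tabulate(idx, nbins = n_bins_total)
    normals <- vapply(seq_len(n_bins_total),
                      function(b) sum(labels[idx == b]), numeric(1))
    p <- ifelse(counts > 0, normals / counts, NA_real_)
    bins <- tibble(
      bin = seq_len(n_bins_total),
      lower = edges[-length(edges)],
      upper = edges[-1],
      n_obs = counts,
      p_normal = p,
      entropy_bits = ifelse(counts > 0, binary_entropy(ifelse(is.na(p), 0, p)),
                            NA_real_)
    )
  }
  structure(list(kind = kind, edges = edges, bins = bins,
                 marginal_p_normal = marginal_p,
                 marginal_entropy_bits = marginal_h),
            class = "entropy_table")
}

# bin assignment over closed-right-at-the-top edges: bin i covers
# [edges[i], edges[i+1]), the last bin is closed; outside -> NA
bin_index <- function(x, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx[x < edges[1] | x > edges[length(edges)]] <- NA_integer_
  idx[idx == 0L] <- NA_integer_
  pmin(idx, length(edges) - 1L)
}

#' @export
print.entropy_table <- function(x, ...) {
  cat("<entropy_table> kind=", x$kind, ", ", nrow(x$bins), " bins, marginal ",
      round(x$marginal_entropy_bits, 4), " bits\n", sep = "")
  invisible(x)
}

#' Evaluate the conditional-entropy feature for new values
#'
#' Maps each raw value to the training entropy (bits) of the bin or category
#' containing it. Values outside the training bins, values landing in empty
#' bins, and unseen categories all fall back to the marginal training
#' entropy.
#'
#' @param table An `entropy_table` from [estimate_entropy_table()] or an
#'   encoder from [encode_categorical()].
#' @param values Raw feature values.
#' @return Numeric vector of entropies in `[0, 1]` bits.
#' @export
entropy_feature <- function(table, values) {
  stopifnot(inherits(table, "entropy_table"))
  if (table$kind == "categorical") {
    hit <- match(as.character(values), table$bins$category)
    out <- table$bins$entropy_bits[hit]
  } else {
    idx <- bin_index(values, table$edges)
    out <- table$bins$entropy_bits[idx]
  }
  ifelse(is.na(out), table$marginal_entropy_bits, out)
}

#' Entropy encoding for categorical features
#'
#' Maps each category to the conditional binary entropy of the outcome given
#' that category, `H(is_normal | Z = c)` in bits, estimated on the training
#' folds. Unseen categories at apply time map to the marginal training
#' entropy. This numeric coding is used for sex and admission diagnosis.
#'
#' @param categories Training category values.
#' @param labels Logical training outcomes (`TRUE` = normal).
#' @return An `entropy_table` of kind `"categorical"`; apply it with
#'   [entropy_feature()].
#' @export
encode_categorical <- function(categories, labels) {
  if (length(categories) == 0) abort("encode_categorical: empty category set")
  estimate_entropy_table(categories, labels, kind = "categorical")
}

approach1_features <- function() {
  c(icu_vital_names(), "sex_encoded", "age", "diagnosis_encoded",
    "first_lab_of_day_value")
}

# Base (raw) per-event table for one test type: prediction targets plus the
# raw columns every feature is derived from. Kept internal.
base_event_table <- function(cohort, aligned, test_type, targets_only = TRUE) {
  labs <- cohort$labs
  need <- c("is_normal", "run_length_M", "day_index", "is_first_of_day")
  if (!all(need %in% names(labs))) {
    abort("cohort labs are not annotated; run annotate_sequences() first")
  }
  ev <- labs |>
    dplyr::filter(test_type == !!test_type) |>
    dplyr::left_join(cohort$admissions, by = "admission_id") |>
    dplyr::left_join(aligned,
                     by = c("admission_id", "test_type", "time_h"),
                     relationship = "many-to-many")
  firsts <- ev |>
    dplyr::filter(is_first_of_day) |>
    dplyr::select(admission_id, day_index,
                  first_lab_of_day_value = value)
  ev <- ev |>
    dplyr::left_join(firsts, by = c("admission_id", "day_index"))
  if (targets_only) {
    ev <- ev |>
      dplyr::filter(!is_first_of_day) |>
      dplyr::filter(!is.na(first_lab_of_day_value))
  }
  ev
}

#' Fit the per-fold feature estimators on training admissions
#'
#' Fits, for one test type and using training admissions only: the pretest
#' probability table (over all annotated training events of the test), the
#' entropy encoders for sex and diagnosis, and one conditional-entropy table
#' per base feature (the six aligned vitals, encoded sex and diagnosis, age
#' and the first-lab-of-day value), each estimated on the training
#' prediction-target events.
#'
#' @param cohort An annotated `icu_cohort` restricted to training admissions.
#' @param aligned Aligned vitals for the same admissions ([align_cohort()]).
#' @param test_type The test type being predicted.
#' @return A `feature_maker` object; use with [assemble_features()].
#' @export
fit_feature_maker <- function(cohort, aligned, test_type) {
  all_ev <- base_event_table(cohort, aligned, test_type, targets_only = FALSE)
  if (nrow(all_ev) == 0) {
    abort(paste0("fit_feature_maker: no training events for '", test_type, "'"))
  }
  pretest <- estimate_pretest_table(
    dplyr::select(all_ev, run_length_M, is_normal))
  targets <- base_event_table(cohort, aligned, test_type, targets_only = TRUE)
  if (nrow(targets) == 0) {
    abort(paste0("fit_feature_maker: no prediction-target events for '",
                 test_type, "'"))
  }
  sex_enc <- encode_categorical(targets$sex, targets$is_normal)
  diag_enc <- encode_categorical(targets$diagnosis, targets$is_normal)
  base <- targets |>
    dplyr::mutate(sex_encoded = entropy_feature(sex_enc, sex),
                  diagnosis_encoded = entropy_feature(diag_enc, diagnosis))
  ent <- list()
  for (f in approach1_features()) {
    kind <- if (f %in% c("sex_encoded", "diagnosis_encoded")) "categorical"
            else "continuous"
    raw <- if (f == "sex_encoded") targets$sex
           else if (f == "diagnosis_encoded") targets$diagnosis
           else base[[f]]
    ent[[f]] <- estimate_entropy_table(raw, targets$is_normal, kind = kind)
  }
  structure(list(test_type = test_type, pretest = pretest,
                 sex_encoder = sex_enc, diagnosis_encoder = diag_enc,
                 entropy_tables = ent),
            class = "feature_maker")
}

#' @export
print.feature_maker <- function(x, ...) {
  cat("<feature_maker> test_type=", x$test_type, ", pretest M in [",
      min(x$pretest$M), ", ", max(x$pretest$M), "], ",
      length(x$entropy_tables), " entropy tables\n", sep = "")
  invisible(x)
}

#' Assemble a feature matrix for one approach
#'
#' Builds the per-event feature matrix for the given approach using
#' estimators fitted on training folds only:
#' * `"1"`: the 10 baseline features — six aligned vitals, entropy-encoded
#'   sex and diagnosis, age, and the value of the day's first same-test
#'   result.
#' * `"2"`: the 10 baseline features plus the pretest probability and the
#'   conditional-entropy variant of each baseline feature (21 columns).
#' * `"1+pretest"` / `"1+entropy"`: ablations adding only the named family.
#'
#' Rows are the prediction targets: annotated events of the test type that
#' are not the first of their day. Events on a day whose only result is the
#' first one contribute no rows (the first of the day is a feature source,
#' never a target).
#'
#' @param maker A `feature_maker` fitted on the training folds.
#' @param cohort Annotated `icu_cohort` holding the events to featurize.
#' @param aligned Aligned vitals for the same events.
#' @param approach `"1"`, `"2"`, `"1+pretest"` or `"1+entropy"`.
#' @return A tibble with identifier columns `admission_id`, `time_h`, the
#'   label `is_normal`, and the feature columns.
#' @export
assemble_features <- function(maker, cohort, aligned,
                              approach = c("1", "2", "1+pretest", "1+entropy")) {
  stopifnot(inherits(maker, "feature_maker"))
  approach <- match.arg(approach)
  ev <- base_event_table(cohort, aligned, maker$test_type, targets_only = TRUE)
  out <- ev |>
    dplyr::mutate(
      sex_encoded = entropy_feature(maker$sex_encoder, sex),
      diagnosis_encoded = entropy_feature(maker$diagnosis_encoder, diagnosis)
    )
  feats <- approach1_features()
  if (approach %in% c("2", "1+pretest")) {
    out$pretest_probability <- lookup_pretest(maker$pretest, ev$run_length_M)
    feats <- c(feats, "pretest_probability")
  }
  if (approach %in% c("2", "1+entropy")) {
    for (f in approach1_features()) {
      raw <- if (f == "sex_encoded") ev$sex
             else if (f == "diagnosis_encoded") ev$diagnosis
             else out[[f]]
      out[[paste0("entropy_", f)]] <-
        entropy_feature(maker$entropy_tables[[f]], raw)
    }
    feats <- c(feats, paste0("entropy_", approach1_features()))
  }
  res <- out[, c("admission_id", "time_h", "is_normal", feats)]
  if (anyNA(res[feats])) {
    abort("assemble_features: missing values in assembled features")
  }
  as_tibble(res)
}
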