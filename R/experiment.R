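#' Configure a full comparison experiment
#'
#' Bundles everything [run_experiment()] needs: the synthetic cohort
#' configuration, the test types to predict, the classifiers and feature
#' approaches to compare, the cross-validation depth, the hyperparameter
#' grids and the false discovery rate.
#'
#' @param simulation A [sim_config()] describing the cohort.
#' @param test_types Test types to evaluate (default: the simulated ones).
#' @param classifiers Subset of `{"fuzzy", "logistic", "random_forest",
#'   "gradient_boosting"}`.
#' @param approaches Subset of `{"1", "2", "1+pretest", "1+entropy"}`.
#'   `"1"` must be present when more than one approach is compared (it is
#'   the reference).
#' @param k_folds Outer folds, grouped by admission (default 10).
#' @param grids Hyperparameter grids (default [default_grids()]).
#' @param fdr False discovery rate for the approach comparison.
#' @param k_rules Rules in the fuzzy classifier.
#' @param epsilon Wrapper-selection stopping threshold.
#' @param inner_k Inner folds for the baseline grid search.
#' @param seed Experiment seed: governs fold assignment and all model
#'   randomness through derived streams (the simulation uses
#'   `simulation$seed`).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(simulation = sim_config(),
                              test_types = simulation$test_types,
                              classifiers = c("fuzzy", "logistic",
                                              "random_forest",
                                              "gradient_boosting"),
                              approaches = c("1", "2"),
                              k_folds = 10, grids = default_grids(),
                              fdr = 0.05, k_rules = 3, epsilon = 0.005,
                              inner_k = 3, seed = 1L) {
  stopifnot(inherits(simulation, "sim_config"))
  known_cls <- c("fuzzy", "logistic", "random_forest", "gradient_boosting")
  known_app <- c("1", "2", "1+pretest", "1+entropy")
  if (length(classifiers) < 1 || !all(classifiers %in% known_cls)) {
    abort("experiment_config: classifiers must be a nonempty subset of fuzzy, logistic, random_forest, gradient_boosting")
  }
  if (length(approaches) < 1 || !all(approaches %in% known_app)) {
    abort("experiment_config: approaches must be a nonempty subset of 1, 2, 1+pretest, 1+entropy")
  }
  if (length(approaches) > 1 && !"1" %in% approaches) {
    abort("experiment_config: approach comparisons use approach 1 as the reference; include it")
  }
  if (k_folds < 2) abort("experiment_config: k_folds must be >= 2")
  if (!all(test_types %in% simulation$test_types)) {
    abort("experiment_config: test_types must be simulated by the cohort config")
  }
  structure(list(simulation = simulation, test_types = test_types,
                 classifiers = classifiers, approaches = approaches,
                 k_folds = as.integer(k_folds), grids = grids, fdr = fdr,
                 k_rules = k_rules, epsilon = epsilon,
                 inner_k = as.integer(inner_k), seed = as.integer(seed)),
            class = "experiment_config")
}

fit_any_classifier <- function(kind, train_x, labels, groups, config, seed) {
  if (kind == "fuzzy") {
    fit_fuzzy_classifier(train_x, labels, groups,
                         k_rules = config$k_rules, epsilon = config$epsilon,
                         seed = seed)
  } else {
    tune_and_fit_baseline(kind, train_x, labels, groups,
                          grid = config$grids[[kind]],
                          inner_k = config$inner_k, seed = seed)
  }
}

score_any_classifier <- function(model, newdata) {
  if (inherits(model, "fuzzy_rulebase")) predict_scores(model, newdata)$abnormal
  else predict_baseline(model, newdata)
}

#' Run the full approach-comparison experiment
#'
#' Simulates the cohort, applies the inclusion criteria, annotates and
#' aligns it, then runs admission-grouped k-fold cross-validation: for each
#' fold and test type, every estimator (pretest table, entropy tables,
#' categorical encoders, min-max scaler, classifiers) is fitted on the
#' training folds only and scored on the held-out fold. Fold-level metric
#' panels are compared between approach 1 and each other approach with
#' two-sided Wilcoxon rank-sum tests under Benjamini-Hochberg correction,
#' and feature relevance ranks are aggregated across folds and classifiers.
#'
#' @param config An [experiment_config()].
#' @param cohort Optional pre-built annotated cohort (for reusing one
#'   simulation across experiments); by default the cohort is generated
#'   from `config$simulation`.
#' @return An `icu_experiment` report: tibbles `metrics` (one row per
#'   approach x test type x classifier x fold), `comparison`,
#'   `feature_ranks`, and a `manifest` list.
#' @export
run_experiment <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- Sys.time()
  set.seed(config$seed)
  fold_seed <- sample.int(2^31 - 2, 1)
  model_seed_base <- sample.int(2^31 - 2, 1)

  if (is.null(cohort)) {
    cohort <- generate_cohort(config$simulation)
    cohort <- apply_inclusion_criteria(cohort)
    cohort <- annotate_sequences(cohort)
  }
  aligned <- align_cohort(cohort)
  folds <- assign_folds(cohort$admissions$admission_id,
                        k = config$k_folds, seed = fold_seed)

  subset_cohort <- function(ids) {
    new_icu_cohort(
      dplyr::filter(cohort$admissions, admission_id %in% ids),
      dplyr::filter(cohort$vitals, admission_id %in% ids),
      dplyr::filter(cohort$labs, admission_id %in% ids)
    )
  }

  metrics_rows <- list()
  rank_rows <- list()
  for (tt in config$test_types) {
    for (f in 0:(config$k_folds - 1)) {
      train_ids <- folds$admission_id[folds$fold != f]
      test_ids <- folds$admission_id[folds$fold == f]
      maker <- fit_feature_maker(subset_cohort(train_ids),
                                 dplyr::filter(aligned, admission_id %in% train_ids),
                                 tt)
      for (ap in config$approaches) {
        tr <- assemble_features(maker, subset_cohort(train_ids),
                                dplyr::filter(aligned, admission_id %in% train_ids),
                                approach = ap)
        te <- assemble_features(maker, subset_cohort(test_ids),
                                dplyr::filter(aligned, admission_id %in% test_ids),
                                approach = ap)
        feat_cols <- setdiff(names(tr), c("admission_id", "time_h", "is_normal"))
        tr_x <- minmax_scale(tr[feat_cols], tr[feat_cols])
        te_x <- minmax_scale(tr[feat_cols], te[feat_cols])
        y_tr <- !tr$is_normal   # abnormal = positive class
        y_te <- !te$is_normal
        for (ci in seq_along(config$classifiers)) {
          cl <- config$classifiers[ci]
          seed_m <- (model_seed_base + 131 * f + 17 * ci +
                       7919 * match(ap, config$approaches)) %% (2^31 - 2) + 1
          model <- fit_any_classifier(cl, tr_x, y_tr, tr$admission_id,
                                      config, seed_m)
          s <- score_any_classifier(model, te_x)
          panel <- compute_metrics(y_te, s >= 0.5, s)
          metrics_rows[[length(metrics_rows) + 1]] <-
            dplyr::bind_cols(tibble(approach = ap, test_type = tt,
                                    classifier = cl, fold = f,
                                    seed = config$seed), panel)
          rank_rows[[length(rank_rows) + 1]] <-
            feature_ranks(model, feat_cols) |>
            dplyr::mutate(approach = ap, test_type = tt, classifier = cl,
                          fold = f)
        }
      }
    }
  }
  metrics <- dplyr::bind_rows(metrics_rows)
  ranks_raw <- dplyr::bind_rows(rank_rows)
  comparison <- compare_approaches(metrics, fdr = config$fdr)
  feature_rank_tbl <- ranks_raw |>
    dplyr::group_by(approach, test_type) |>
    dplyr::group_modify(~ aggregate_feature_ranks(.x)) |>
    dplyr::ungroup()

  manifest <- list(
    config = list(
      simulation = unclass(config$simulation),
      test_types = config$test_types, classifiers = config$classifiers,
      approaches = config$approaches, k_folds = config$k_folds,
      fdr = config$fdr, k_rules = config$k_rules, epsilon = config$epsilon,
      inner_k = config$inner_k
    ),
    seed = config$seed,
    n_admissions_included = nrow(cohort$admissions),
    n_events = nrow(cohort$labs),
    package_version = as.character(utils::packageVersion("icupretest")),
    r_version = as.character(getRversion()),
    wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  structure(list(metrics = metrics, comparison = comparison,
                 feature_ranks = feature_rank_tbl, raw_ranks = ranks_raw,
                 manifest = manifest),
            class = "icu_experiment")
}

#' Compare approaches metric-by-metric across folds
#'
#' For each (comparison approach, test type, classifier, metric), tests the
#' fold-level values of the approach against approach 1 with a two-sided
#' Wilcoxon rank-sum test and reports the percent change of the fold means.
#' p-values are Benjamini-Hochberg adjusted within each comparison approach
#' (one correction per family of test x classifier x metric comparisons).
#'
#' @param metrics The `metrics` tibble of an experiment (fold-level rows).
#' @param fdr False discovery rate (default 0.05).
#' @return Tibble with one row per comparison: means for both approaches,
#'   `pct_change`, `p_value`, `p_adjusted`, `significant`.
#' @export
compare_approaches <- function(metrics, fdr = 0.05) {
  others <- setdiff(unique(metrics$approach), "1")
  if (length(others) == 0 || !"1" %in% metrics$approach) {
    return(tibble(approach = character(), test_type = character(),
                  classifier = character(), metric = character(),
                  mean_ref = numeric(), mean_alt = numeric(),
                  pct_change = numeric(), p_value = numeric(),
                  p_adjusted = numeric(), significant = logical()))
  }
  long <- metrics |>
    dplyr::select(approach, test_type, classifier, fold,
                  dplyr::all_of(metric_names())) |>
    tidyr::pivot_longer(dplyr::all_of(metric_names()),
                        names_to = "metric", values_to = "value")
  out <- list()
  for (ap in others) {
    comp <- long |>
      dplyr::filter(approach %in% c("1", ap)) |>
      dplyr::group_by(test_type, classifier, metric) |>
      dplyr::group_modify(function(d, key) {
        a <- d$value[d$approach == "1"]
        b <- d$value[d$approach == ap]
        a <- a[is.finite(a)]
        b <- b[is.finite(b)]
        if (length(a) == 0 || length(b) == 0) {
          return(tibble(mean_ref = NA_real_, mean_alt = NA_real_,
                        pct_change = NA_real_, p_value = NA_real_))
        }
        tibble(mean_ref = mean(a), mean_alt = mean(b),
               pct_change = 100 * (mean(b) - mean(a)) / mean(a),
               p_value = wilcoxon_ranksum_2sided(b, a))
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(approach = ap, .before = 1)
    ok <- !is.na(comp$p_value)
    comp$p_adjusted <- NA_real_
    comp$significant <- NA
    if (any(ok)) {
      bh <- benjamini_hochberg(comp$p_value[ok], fdr = fdr)
      comp$p_adjusted[ok] <- bh$p_adjusted
      comp$significant[ok] <- bh$significant
    }
    out[[ap]] <- comp
  }
  dplyr::bind_rows(out)
}

#' @export
print.icu_experiment <- function(x, ...) {
  cat("<icu_experiment> ", nrow(x$metrics), " metric rows (",
      paste(unique(x$metrics$approach), collapse = ", "), ") over ",
      dplyr::n_distinct(x$metrics$test_type), " test type(s), ",
      dplyr::n_distinct(x$metrics$classifier), " classifier(s), ",
      dplyr::n_distinct(x$metrics$fold), " folds\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.icu_experiment <- function(x, ...) x$metrics

#' @exportS3Method generics::glance
glance.icu_experiment <- function(x, ...) {
  x$metrics |>
    dplyr::group_by(approach) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metric_names()),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
}

#' Render an experiment report to files
#'
#' Writes `metrics_by_fold.csv`, `comparison.csv`, `feature_ranks.csv`, a
#' JSON `manifest.json` echoing the configuration and seed, and a
#' plain-text `summary.txt` with per-approach metric means and the count of
#' significant improvements per metric and classifier.
#'
#' @param report An `icu_experiment`.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
render_report <- function(report, directory) {
  stopifnot(inherits(report, "icu_experiment"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(directory, c("metrics_by_fold.csv", "comparison.csv",
                                  "feature_ranks.csv", "manifest.json",
                                  "summary.txt"))
  readr::write_csv(report$metrics, paths[1])
  readr::write_csv(report$comparison, paths[2])
  readr::write_csv(report$feature_ranks, paths[3])
  jsonlite::write_json(report$manifest, paths[4], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  means <- glance(report)
  sig <- report$comparison |>
    dplyr::filter(!is.na(significant), significant) |>
    dplyr::count(approach, classifier, metric, name = "n_significant")
  con <- file(paths[5], "w")
  on.exit(close(con))
  writeLines(c(
    paste0("experiment seed: ", report$manifest$seed),
    paste0("admissions included: ", report$manifest$n_admissions_included),
    "", "per-approach metric means (across folds, tests, classifiers):",
    utils::capture.output(print(as.data.frame(means), digits = 4)),
    "", "significant improvements (BH-adjusted) by approach/classifier/metric:",
    if (nrow(sig) > 0) utils::capture.output(print(as.data.frame(sig)))
    else "  none"
  ), con)
  invisible(paths)
}
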