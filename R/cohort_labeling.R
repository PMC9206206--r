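#' Apply the cohort inclusion criteria
#'
#' An admission is retained iff (in this order of reporting): age is
#' strictly greater than 18 years; every one of the six vitals has at least
#' one measurement; and at least one test type has two or more orders.
#' Excluded admissions are recorded with the first failed criterion
#' (`"age"`, `"vitals"` or `"orders"`). The operation is idempotent.
#'
#' @param cohort An `icu_cohort`.
#' @return The filtered `icu_cohort` with an `excluded` tibble
#'   (`admission_id`, `reason`).
#' @export
apply_inclusion_criteria <- function(cohort) {
  stopifnot(inherits(cohort, "icu_cohort"))
  adm <- cohort$admissions
  vit_count <- cohort$vitals |>
    dplyr::distinct(admission_id, variable) |>
    dplyr::count(admission_id, name = "n_vitals")
  max_orders <- cohort$labs |>
    dplyr::count(admission_id, test_type) |>
    dplyr::group_by(admission_id) |>
    dplyr::summarise(max_orders = max(n), .groups = "drop")
  status <- adm |>
    dplyr::left_join(vit_count, by = "admission_id") |>
    dplyr::left_join(max_orders, by = "admission_id") |>
    dplyr::mutate(
      n_vitals = dplyr::coalesce(.data$n_vitals, 0L),
      max_orders = dplyr::coalesce(.data$max_orders, 0L),
      reason = dplyr::case_when(
        age <= 18 ~ "age",
        n_vitals < 6L ~ "vitals",
        max_orders < 2L ~ "orders",
        TRUE ~ NA_character_
      )
    )
  excluded <- status |>
    dplyr::filter(!is.na(reason)) |>
    dplyr::select(admission_id, reason)
  keep <- status$admission_id[is.na(status$reason)]
  prior_excluded <- if (is.null(cohort$excluded)) NULL else cohort$excluded
  new_icu_cohort(
    admissions = dplyr::filter(adm, admission_id %in% keep),
    vitals = dplyr::filter(cohort$vitals, admission_id %in% keep),
    labs = dplyr::filter(cohort$labs, admission_id %in% keep),
    truth = if (is.null(cohort$truth)) NULL else
      dplyr::filter(cohort$truth, admission_id %in% keep),
    excluded = dplyr::bind_rows(prior_excluded, excluded)
  )
}

# run length of the all-normal suffix strictly before each event
run_length_before <- function(is_normal) {
  n <- length(is_normal)
  M <- integer(n)
  if (n > 1) {
    for (i in 2:n) M[i] <- if (is_normal[i - 1]) M[i - 1] + 1L else 0L
  }
  M
}

#' Label results and annotate run lengths, day indices and first-of-day flags
#'
#' Assigns `is_normal` from the sex/age-conditional reference ranges, then,
#' per (admission, test type) in time order (ties broken by input record
#' order): `run_length_M` = number of immediately preceding consecutive
#' normal results (0 for the first event and immediately after an abnormal;
#' the count spans day boundaries); `day_index` = admission-relative 24-hour
#' block (`floor(time_h / 24)`); `is_first_of_day` marks the earliest event
#' of each (test type, day). Non-first-of-day events are the prediction
#' targets downstream — the first result of the day is used as a feature,
#' not predicted.
#'
#' @param cohort An `icu_cohort` (typically post
#'   [apply_inclusion_criteria()]).
#' @param ranges Reference ranges; defaults to the packaged table.
#' @return The cohort with `labs` gaining `is_normal`, `run_length_M`,
#'   `day_index`, `is_first_of_day`.
#' @export
annotate_sequences <- function(cohort, ranges = load_reference_ranges()) {
  stopifnot(inherits(cohort, "icu_cohort"))
  labs <- cohort$labs |>
    dplyr::left_join(dplyr::select(cohort$admissions, admission_id, sex, age),
                     by = "admission_id")
  if (any(is.na(labs$sex) | is.na(labs$age))) {
    abort("annotate_sequences: lab events reference admissions absent from the cohort")
  }
  labs <- labs |>
    dplyr::mutate(.record = dplyr::row_number()) |>
    dplyr::mutate(is_normal = label_event(value, test_type, sex, age, ranges)) |>
    dplyr::arrange(admission_id, test_type, time_h, .record) |>
    dplyr::group_by(admission_id, test_type) |>
    dplyr::mutate(run_length_M = run_length_before(is_normal),
                  day_index = as.integer(floor(time_h / 24))) |>
    dplyr::group_by(admission_id, test_type, day_index) |>
    dplyr::mutate(is_first_of_day = dplyr::row_number() == 1L) |>
    dplyr::ungroup() |>
    dplyr::select(-sex, -age, -.record)
  out <- cohort
  out$labs <- labs
  out
}
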