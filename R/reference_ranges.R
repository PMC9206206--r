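#' The 18 laboratory blood tests covered by the packaged reference ranges
#'
#' Short machine-friendly names for the blood gas, chemistry, hematology and
#' liver-panel tests the package ships sex/age-conditional normal ranges for:
#' arterial pH, PaO2, PCO2, potassium, hemoglobin, sodium, hematocrit, white
#' blood cells, total CO2 content, creatinine, urea, random glucose, alanine
#' transaminase, total bilirubin, alkaline phosphatase, albumin, aspartate
#' aminotransferase and gamma-glutamyl transferase.
#'
#' @return Character vector of 18 test-type names.
#' @export
icu_test_types <- function() {
  c("ph", "pao2", "pco2", "potassium", "hemoglobin", "sodium", "hematocrit",
    "wbc", "co2_total", "creatinine", "urea", "glucose", "alt", "bilirubin",
    "alp", "albumin", "ast", "ggt")
}

#' Load sex- and age-conditional normal reference ranges
#'
#' Reads a reference-range table and validates it. Each row gives the normal
#' interval `[low, high]` (bounds inclusive) for one test under a sex
#' condition (`male`, `female` or `any`) and a half-open age condition
#' `[age_low, age_high)` in completed years. The packaged default covers the
#' 18 ICU blood tests returned by [icu_test_types()].
#'
#' Validation enforces the partition property: for every test, every sex and
#' every age from 18 to 110, exactly one row applies. Overlapping or gapped
#' conditions raise an error listing the offending test.
#'
#' @param path Path to a CSV with columns `test_type`, `sex`, `age_low`,
#'   `age_high`, `low`, `high`. `NULL` (default) loads the packaged table.
#' @return A tibble of class `reference_ranges`.
#' @export
#' @examples
#' ranges <- load_reference_ranges()
#' dplyr::filter(ranges, test_type == "potassium")
load_reference_ranges <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_ranges.csv",
                        package = "icupretest", mustWork = TRUE)
  }
  rr <- readr::read_csv(path, col_types = readr::cols(
    test_type = readr::col_character(),
    sex = readr::col_character(),
    age_low = readr::col_double(),
    age_high = readr::col_double(),
    low = readr::col_double(),
    high = readr::col_double()
  ))
  required <- c("test_type", "sex", "age_low", "age_high", "low", "high")
  missing_cols <- setdiff(required, names(rr))
  if (length(missing_cols) > 0) {
    abort(paste0("reference range table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(rr$sex %in% c("male", "female", "any"))) {
    abort("reference range sex condition must be one of male, female, any")
  }
  if (any(!is.finite(rr$low) | !is.finite(rr$high) | rr$low >= rr$high)) {
    bad <- which(!is.finite(rr$low) | !is.finite(rr$high) | rr$low >= rr$high)
    abort(paste0("invalid reference interval (need low < high) in row(s): ",
                 paste(bad, collapse = ", ")))
  }
  validate_range_partition(rr)
  class(rr) <- c("reference_ranges", class(rr))
  rr
}

# Every (test, sex, age in 18..110) must match exactly one row.
validate_range_partition <- function(rr) {
  ages <- 18:110
  for (tt in unique(rr$test_type)) {
    sub <- rr[rr$test_type == tt, ]
    for (sx in c("male", "female")) {
      applicable <- sub[sub$sex %in% c("any", sx), ]
      n_match <- vapply(ages, function(a) {
        sum(applicable$age_low <= a & a < applicable$age_high)
      }, integer(1))
      if (any(n_match != 1L)) {
        bad_age <- ages[which(n_match != 1L)[1]]
        abort(paste0(
          "reference ranges for test '", tt, "' do not partition: sex=", sx,
          ", age=", bad_age, " matches ", n_match[which(n_match != 1L)[1]],
          " rows (rows: ",
          paste(which(rr$test_type == tt), collapse = ", "), ")"
        ))
      }
    }
  }
  invisible(rr)
}

# Resolve the single applicable interval per (test_type, sex, age).
# All arguments vectorized and recycled to a common length.
applicable_range <- function(ranges, test_type, sex, age) {
  n <- max(length(test_type), length(sex), length(age))
  test_type <- rep_len(test_type, n)
  sex <- rep_len(sex, n)
  age <- rep_len(age, n)
  low <- numeric(n)
  high <- numeric(n)
  # resolve per distinct (test, sex, age) combination, then spread
  key <- paste(test_type, sex, age, sep = "\r")
  for (k in unique(key)) {
    i <- which(key == k)[1]
    hit <- ranges$test_type == test_type[i] &
      (ranges$sex == "any" | ranges$sex == sex[i]) &
      ranges$age_low <= age[i] & age[i] < ranges$age_high
    if (sum(hit) != 1L) {
      abort(paste0("no unique reference range for (test_type=", test_type[i],
                   ", sex=", sex[i], ", age=", age[i], ")"))
    }
    sel <- key == k
    low[sel] <- ranges$low[hit]
    high[sel] <- ranges$high[hit]
  }
  tibble(low = low, high = high)
}

#' Label a laboratory result as normal or abnormal
#'
#' A value is normal iff it lies inside the applicable reference interval,
#' bounds inclusive. All arguments are vectorized.
#'
#' @param value Numeric result value(s) in the test's units.
#' @param test_type Test name(s), see [icu_test_types()].
#' @param sex `"male"` or `"female"`.
#' @param age Age in completed years at admission.
#' @param ranges A `reference_ranges` table from [load_reference_ranges()].
#' @return Logical vector: `TRUE` for normal.
#' @export
#' @examples
#' rr <- load_reference_ranges()
#' label_event(4.2, "potassium", "female", 40, rr)  # TRUE
#' label_event(120, "hemoglobin", "male", 40, rr)   # FALSE
label_event <- function(value, test_type, sex, age, ranges) {
  iv <- applicable_range(ranges, test_type, sex, age)
  value >= iv$low & value <= iv$high
}
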