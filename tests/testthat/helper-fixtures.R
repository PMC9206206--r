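# Hand-built cohort fixtures. Potassium (normal range 3.5-5.0 for everyone)
# is the workhorse test: 4.2 encodes a normal result, 5.5 an abnormal one.

normal_value <- 4.2
abnormal_value <- 5.5

# one observation of each vital at t = 1 h, plus optional extras
basic_vitals <- function(id) {
  tibble::tibble(
    admission_id = id,
    variable = icu_vital_names(),
    time_h = 1,
    value = c(80, 97, 16, 37, 85, 50)
  )
}

# seqs: named list admission_id -> character vector of "N"/"A";
# times: list of time vectors (defaults to 1, 2, 3, ... hours)
cohort_from_sequences <- function(seqs, times = NULL, test_type = "potassium",
                                  age = 50, sex = "male",
                                  diagnosis = "cardiac") {
  adm <- tibble::tibble(admission_id = names(seqs), age = age, sex = sex,
                        diagnosis = diagnosis)
  labs <- purrr::imap(seqs, function(s, id) {
    tt <- if (is.null(times[[id]])) seq_along(s) else times[[id]]
    tibble::tibble(admission_id = id, test_type = test_type, time_h = tt,
                   value = ifelse(s == "N", normal_value, abnormal_value))
  }) |> purrr::list_rbind()
  vitals <- purrr::map(names(seqs), basic_vitals) |> purrr::list_rbind()
  icupretest:::new_icu_cohort(adm, vitals, labs)
}

# a small annotated + aligned simulated cohort shared by feature tests
small_sim_cohort <- function(n = 60, seed = 42, ...) {
  sim <- sim_config(n_admissions = n, test_types = "potassium",
                    mean_labs_per_admission = 12,
                    vitals_sampling_rate = 0.3,
                    stay_length_hours = c(24, 72), seed = seed, ...)
  annotate_sequences(apply_inclusion_criteria(generate_cohort(sim)))
}
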