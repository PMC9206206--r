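#' Configuration for the synthetic ICU cohort generator
#'
#' Bundles and validates the parameters of the synthetic electronic medical
#' record generator. The normality of consecutive same-test results follows a
#' two-state Markov chain with persistence `p_stay_normal` = P(next normal |
#' previous normal) and recovery `p_recover` = P(next normal | previous
#' abnormal), modulated on the log-odds scale by a latent severity process
#' (weight `vitals_effect`) and a per-diagnosis offset.
#'
#' @param n_admissions Number of ICU admissions to simulate.
#' @param mean_labs_per_admission Mean number of orders per test type per
#'   admission (Poisson).
#' @param test_types Character vector, subset of [icu_test_types()].
#' @param p_stay_normal P(next result normal | previous normal), in `[0, 1]`.
#' @param p_recover P(next result normal | previous abnormal), in `[0, 1]`.
#' @param vitals_effect Log-odds weight of the latent severity on the
#'   probability of an abnormal result (larger = sicker patients have more
#'   abnormal labs and visibly deranged vitals).
#' @param diagnosis_effects Named numeric vector mapping admission diagnosis
#'   to a log-odds offset on the probability of a normal result.
#' @param vitals_sampling_rate Mean vitals samples per hour (exponential
#'   inter-arrival times, per variable).
#' @param stay_length_hours Length-2 numeric range for the ICU stay in hours.
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_admissions = 200,
                       mean_labs_per_admission = 20,
                       test_types = c("potassium", "hemoglobin"),
                       p_stay_normal = 0.9,
                       p_recover = 0.3,
                       vitals_effect = 0.4,
                       diagnosis_effects = c(cardiac = 0, sepsis = -0.5,
                                             trauma = 0.3, respiratory = -0.2,
                                             renal = -0.4),
                       vitals_sampling_rate = 1,
                       stay_length_hours = c(24, 120),
                       seed = 1L) {
  check_num <- function(x, field, lo = -Inf, hi = Inf) {
    if (length(x) != 1 || !is.numeric(x) || !is.finite(x) || x < lo || x > hi) {
      abort(paste0("invalid sim_config field '", field, "': must be a finite ",
                   "number in [", lo, ", ", hi, "]"))
    }
  }
  check_num(n_admissions, "n_admissions", lo = 1)
  check_num(mean_labs_per_admission, "mean_labs_per_admission", lo = 0)
  check_num(p_stay_normal, "p_stay_normal", 0, 1)
  check_num(p_recover, "p_recover", 0, 1)
  check_num(vitals_effect, "vitals_effect")
  check_num(vitals_sampling_rate, "vitals_sampling_rate", lo = 1e-6)
  check_num(seed, "seed")
  if (!is.numeric(diagnosis_effects) || length(diagnosis_effects) < 1 ||
      is.null(names(diagnosis_effects)) || any(!is.finite(diagnosis_effects))) {
    abort("invalid sim_config field 'diagnosis_effects': need a named finite numeric vector")
  }
  if (!is.numeric(stay_length_hours) || length(stay_length_hours) != 2 ||
      any(!is.finite(stay_length_hours)) || any(stay_length_hours <= 0) ||
      stay_length_hours[1] > stay_length_hours[2]) {
    abort("invalid sim_config field 'stay_length_hours': need 0 < lo <= hi")
  }
  if (length(test_types) < 1 || !all(test_types %in% icu_test_types())) {
    abort(paste0("invalid sim_config field 'test_types': must be a nonempty ",
                 "subset of icu_test_types()"))
  }
  structure(list(
    n_admissions = as.integer(n_admissions),
    mean_labs_per_admission = mean_labs_per_admission,
    test_types = test_types,
    p_stay_normal = p_stay_normal,
    p_recover = p_recover,
    vitals_effect = vitals_effect,
    diagnosis_effects = diagnosis_effects,
    vitals_sampling_rate = vitals_sampling_rate,
    stay_length_hours = stay_length_hours,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Names of the six vital-sign variables
#'
#' Heart rate (beats/min), oxygen saturation (%), respiration rate
#' (breaths/min), temperature (deg C), blood pressure (mean arterial
#' pressure, mm Hg) and urine output (mL).
#'
#' @return Character vector of length 6.
#' @export
icu_vital_names <- function() c("hr", "spo2", "rr", "temp", "bp", "urine")

# baseline + severity loading + noise per vital
vital_profiles <- function() {
  tibble(
    variable = icu_vital_names(),
    baseline = c(80, 97, 16, 37, 85, 50),
    loading  = c(8, -1.5, 3, 0.45, -6, -12),
    noise_sd = c(5, 1, 2, 0.3, 5, 15)
  )
}

# Markov stationary probability of the normal state; 0.5 when degenerate.
stationary_p_normal <- function(p_stay, p_recover) {
  denom <- 1 - p_stay + p_recover
  if (denom <= 0) return(0.5)
  p_recover / denom
}

#' Generate a seeded synthetic ICU cohort
#'
#' Simulates `n_admissions` ICU stays with demographics, an admission
#' diagnosis, irregularly sampled vitals and timestamped laboratory results.
#' A per-admission latent severity (hourly AR(1), coefficient 0.9, unit
#' innovation variance, linearly interpolated) drives both the vitals and —
#' through `vitals_effect` on the log-odds scale — the probability that each
#' successive lab result is abnormal, on top of the two-state normal/abnormal
#' Markov chain and the diagnosis offset. Normal values are drawn uniformly
#' inside the applicable reference interval; abnormal values uniformly in an
#' excursion of 30% of the interval width beyond the bound on the side
#' matching the severity sign (the high side when the low excursion would be
#' negative).
#'
#' Every admission receives at least one sample of each of the six vitals and
#' at least two orders of the first configured test type, so the default
#' cohort passes [apply_inclusion_criteria()] by construction.
#'
#' @param config A [sim_config()].
#' @param ranges Reference ranges used to draw values consistent with the
#'   intended normality; defaults to the packaged table.
#' @return An `icu_cohort`: a list of tibbles `admissions` (admission_id,
#'   age, sex, diagnosis), `vitals` (admission_id, variable, time_h, value),
#'   `labs` (admission_id, test_type, time_h, value), plus a `truth` tibble
#'   (admission_id, test_type, time_h, severity, is_normal) holding the
#'   simulation ground truth at each lab event. `truth` is simulation
#'   metadata: it is not written by [write_cohort()] and never enters the
#'   analysis pipeline.
#' @export
#' @examples
#' coh <- generate_cohort(sim_config(n_admissions = 5, seed = 7))
#' coh$admissions
generate_cohort <- function(config, ranges = load_reference_ranges()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  prof <- vital_profiles()
  diagnoses <- names(config$diagnosis_effects)
  p_init <- stationary_p_normal(config$p_stay_normal, config$p_recover)

  adm_rows <- vector("list", config$n_admissions)
  vit_rows <- vector("list", config$n_admissions)
  lab_rows <- vector("list", config$n_admissions)
  tru_rows <- vector("list", config$n_admissions)

  for (a in seq_len(config$n_admissions)) {
    id <- sprintf("adm%05d", a)
    age <- sample(19:95, 1)
    sex <- sample(c("male", "female"), 1)
    dx <- sample(diagnoses, 1)
    dx_off <- unname(config$diagnosis_effects[[dx]])
    stay <- runif(1, config$stay_length_hours[1], config$stay_length_hours[2])

    # latent severity: hourly AR(1), phi = 0.9, unit innovations,
    # stationary start; linear interpolation between hours
    hours <- 0:ceiling(stay)
    phi <- 0.9
    sev <- numeric(length(hours))
    sev[1] <- rnorm(1, 0, 1 / sqrt(1 - phi^2))
    for (h in seq_along(hours)[-1]) sev[h] <- phi * sev[h - 1] + rnorm(1)
    sev_at <- approxfun(hours, sev, rule = 2)

    # vitals at exponential inter-arrival times, >= 1 sample per variable
    vlist <- vector("list", nrow(prof))
    for (v in seq_len(nrow(prof))) {
      times <- cumsum(rexp(ceiling(stay * config$vitals_sampling_rate * 3) + 5,
                           rate = config$vitals_sampling_rate))
      times <- times[times < stay]
      if (length(times) == 0) times <- runif(1, 0, stay)
      vals <- prof$baseline[v] + prof$loading[v] * sev_at(times) +
        rnorm(length(times), 0, prof$noise_sd[v])
      if (prof$variable[v] == "spo2") vals <- pmin(vals, 100)
      if (prof$variable[v] %in% c("rr", "urine")) vals <- pmax(vals, 0)
      vlist[[v]] <- tibble(admission_id = id, variable = prof$variable[v],
                           time_h = times, value = vals)
    }

    llist <- list()
    tlist <- list()
    for (ti in seq_along(config$test_types)) {
      tt <- config$test_types[ti]
      n_orders <- rpois(1, config$mean_labs_per_admission)
      if (ti == 1) n_orders <- max(n_orders, 2L)  # inclusion by construction
      if (n_orders == 0) next
      times <- sort(runif(n_orders, 0, stay))
      iv <- applicable_range(ranges, tt, sex, age)[1, ]
      width <- iv$high - iv$low
      sev_t <- sev_at(times)
      normal <- logical(n_orders)
      vals <- numeric(n_orders)
      prev_normal <- NA
      for (i in seq_len(n_orders)) {
        base <- if (i == 1) p_init else if (prev_normal) config$p_stay_normal else config$p_recover
        logit <- qlogis(base) + dx_off - config$vitals_effect * sev_t[i]
        # degenerate chain probabilities (0 or 1) stay degenerate
        p <- if (is.infinite(qlogis(base))) base else plogis(logit)
        normal[i] <- runif(1) < p
        prev_normal <- normal[i]
        if (normal[i]) {
          vals[i] <- runif(1, iv$low, iv$high)
        } else {
          lo_side <- sev_t[i] < 0 && (iv$low - 0.3 * width) >= 0
          vals[i] <- if (lo_side) runif(1, iv$low - 0.3 * width, iv$low)
                     else runif(1, iv$high, iv$high + 0.3 * width)
        }
      }
      llist[[tt]] <- tibble(admission_id = id, test_type = tt,
                            time_h = times, value = vals)
      tlist[[tt]] <- tibble(admission_id = id, test_type = tt,
                            time_h = times, severity = sev_t,
                            is_normal = normal)
    }

    adm_rows[[a]] <- tibble(admission_id = id, age = age, sex = sex,
                            diagnosis = dx)
    vit_rows[[a]] <- dplyr::bind_rows(vlist)
    lab_rows[[a]] <- dplyr::bind_rows(llist)
    tru_rows[[a]] <- dplyr::bind_rows(tlist)
  }

  new_icu_cohort(
    admissions = dplyr::bind_rows(adm_rows),
    vitals = dplyr::bind_rows(vit_rows),
    labs = dplyr::bind_rows(lab_rows),
    truth = dplyr::bind_rows(tru_rows)
  )
}

new_icu_cohort <- function(admissions, vitals, labs, truth = NULL,
                           excluded = NULL) {
  structure(list(admissions = as_tibble(admissions),
                 vitals = as_tibble(vitals),
                 labs = as_tibble(labs),
                 truth = truth,
                 excluded = excluded),
            class = "icu_cohort")
}

#' @export
print.icu_cohort <- function(x, ...) {
  cat("<icu_cohort> ", nrow(x$admissions), " admissions, ",
      nrow(x$vitals), " vitals samples, ", nrow(x$labs), " lab events\n",
      sep = "")
  if (!is.null(x$excluded) && nrow(x$excluded) > 0) {
    cat("  excluded by inclusion criteria: ", nrow(x$excluded), "\n", sep = "")
  }
  invisible(x)
}

#' Write a cohort to a directory of CSV files
#'
#' Writes `admissions.csv`, `vitals.csv` and `labs.csv`. Values round-trip
#' exactly through [read_cohort()] (readr writes shortest round-trippable
#' decimal representations). The simulation `truth` table, if present, is
#' not written: on-disk cohorts look like de-identified EMR extracts.
#'
#' @param cohort An `icu_cohort`.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "icu_cohort"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(directory, c("admissions.csv", "vitals.csv", "labs.csv"))
  readr::write_csv(cohort$admissions, paths[1])
  readr::write_csv(cohort$vitals, paths[2])
  readr::write_csv(cohort$labs, paths[3])
  invisible(paths)
}

#' Read a cohort from a directory of CSV files
#'
#' Inverse of [write_cohort()]: `read_cohort(write_cohort(x))` reproduces the
#' three tables exactly, including column order. Missing files, missing
#' required columns or duplicated `admission_id`s in `admissions.csv` raise
#' an error naming the offender.
#'
#' @param directory Directory containing `admissions.csv`, `vitals.csv`,
#'   `labs.csv`.
#' @return An `icu_cohort` (without simulation truth).
#' @export
read_cohort <- function(directory) {
  specs <- list(
    admissions = list(cols = c("admission_id", "age", "sex", "diagnosis"),
                      numeric = "age"),
    vitals = list(cols = c("admission_id", "variable", "time_h", "value"),
                  numeric = c("time_h", "value")),
    labs = list(cols = c("admission_id", "test_type", "time_h", "value"),
                numeric = c("time_h", "value"))
  )
  out <- list()
  for (nm in names(specs)) {
    path <- file.path(directory, paste0(nm, ".csv"))
    if (!file.exists(path)) abort(paste0("missing cohort file: ", path))
    # read everything as character and convert numerics with the base
    # parser, which is correctly rounded, so doubles round-trip exactly
    df <- readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_character()))
    missing_cols <- setdiff(specs[[nm]]$cols, names(df))
    if (length(missing_cols) > 0) {
      abort(paste0(path, " is missing required column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    for (cn in specs[[nm]]$numeric) df[[cn]] <- as.numeric(df[[cn]])
    if (nm == "admissions") df$age <- as.integer(df$age)  # completed years
    out[[nm]] <- df[, specs[[nm]]$cols]
  }
  if (anyDuplicated(out$admissions$admission_id)) {
    dup <- out$admissions$admission_id[duplicated(out$admissions$admission_id)][1]
    abort(paste0("duplicate admission_id in admissions.csv: ", dup))
  }
  new_icu_cohort(out$admissions, out$vitals, out$labs)
}
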