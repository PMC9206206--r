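#' Interpolate one vital-sign series at query times
#'
#' Fits a natural cubic spline through the observations (duplicate
#' timestamps are averaged first) and evaluates it at the query times.
#' Queries outside the observed span are clamped to the nearest boundary
#' observation — cubic extrapolation on sparse clinical series is
#' numerically explosive. Degenerate inputs degrade gracefully: a single
#' observation yields a constant; two observations a straight line (the
#' natural spline reduces to it).
#'
#' @param times Observation times (hours since admission).
#' @param values Observed values.
#' @param query_times Times at which to estimate the vital.
#' @return Numeric vector, one value per query time.
#' @export
#' @examples
#' fit_and_query_spline(c(0, 1, 2), c(60, 70, 80), 1.5)
fit_and_query_spline <- function(times, values, query_times) {
  if (length(times) == 0 || length(values) == 0) {
    abort("fit_and_query_spline: no observations")
  }
  if (length(times) != length(values)) {
    abort("fit_and_query_spline: times and values differ in length")
  }
  if (any(!is.finite(times)) || any(!is.finite(values))) {
    abort("fit_and_query_spline: non-finite observation")
  }
  # average duplicate timestamps, then sort
  if (anyDuplicated(times)) {
    agg <- tapply(values, times, mean)
    times <- as.numeric(names(agg))
    values <- as.numeric(agg)
  }
  o <- order(times)
  times <- times[o]
  values <- values[o]
  if (length(times) == 1) {
    return(rep(values, length(query_times)))
  }
  f <- stats::splinefun(times, values, method = "natural")
  q <- pmin(pmax(query_times, times[1]), times[length(times)])
  f(q)
}

#' Estimate all six vitals at every lab-event time
#'
#' For each admission and each vital, fits the interpolant of
#' [fit_and_query_spline()] on that admission's observations only and
#' evaluates it at the admission's lab-event times. The procedure uses
#' neither lab values nor normality labels, so no information can leak from
#' the prediction target into the aligned features, and admissions never
#' share information.
#'
#' @param cohort An `icu_cohort` (labs may or may not be annotated).
#' @return A tibble with one row per lab event: `admission_id`, `test_type`,
#'   `time_h` and one column per vital (`hr`, `spo2`, `rr`, `temp`, `bp`,
#'   `urine`).
#' @export
align_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "icu_cohort"))
  vit_split <- split(cohort$vitals, cohort$vitals$admission_id)
  lab_split <- split(cohort$labs, cohort$labs$admission_id)
  vnames <- icu_vital_names()
  out <- vector("list", length(lab_split))
  for (i in seq_along(lab_split)) {
    labs <- lab_split[[i]]
    id <- labs$admission_id[1]
    vit <- vit_split[[id]]
    res <- labs[, c("admission_id", "test_type", "time_h")]
    for (v in vnames) {
      obs <- vit[!is.null(vit) & vit$variable == v, , drop = FALSE]
      if (is.null(vit) || nrow(obs) == 0) {
        abort(paste0("align_cohort: admission ", id, " has no '", v,
                     "' measurements (inclusion criteria not applied?)"))
      }
      res[[v]] <- fit_and_query_spline(obs$time_h, obs$value, labs$time_h)
    }
    out[[i]] <- res
  }
  dplyr::bind_rows(out)
}
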