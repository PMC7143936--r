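#' Canonical covariate order
#'
#' The seven binary covariates of the progression model, in reporting order:
#' gender (1 = male), age (1 = over 65 at first stroke), then the five
#' district-level environmental indicators (1 = high divorce rate, high
#' unemployment rate, high elderly-living-alone rate, low winter temperature,
#' high fraction of PSI > 100 days). The base group is the all-zero vector.
#'
#' @return Character vector of covariate column names.
#' @export
covariate_names <- function() {
  c("gender", "age", "divorce", "unemployment", "elderly_alone",
    "temperature", "air_pollution")
}

#' Compute district-level environmental rates from raw counts
#'
#' Rates are `100 * numerator / denominator`: divorce rate over the
#' population aged 15+, unemployment rate over the labor force,
#' PSI-exceedance as the percentage of monitored days with PSI above 100, and
#' elderly-living-alone rate over the population aged 65+. Winter temperature
#' is the unweighted mean of the January, February and December means.
#'
#' @param raw Data frame with columns `district`, `divorced_pop`,
#'   `adult_pop`, `unemployed`, `labor_force`, `psi_exceed_days`,
#'   `psi_monitor_days`, `elderly_alone`, `elderly_pop`, `temp_jan`,
#'   `temp_feb`, `temp_dec`.
#' @return A tibble with columns `district`, `divorce_rate`,
#'   `unemployment_rate`, `air_pollution`, `elderly_alone_rate`,
#'   `winter_temp`.
#' @export
compute_rates <- function(raw) {
  raw <- tibble::as_tibble(raw)
  denoms <- c(divorce_rate = "adult_pop", unemployment_rate = "labor_force",
              air_pollution = "psi_monitor_days",
              elderly_alone_rate = "elderly_pop")
  for (measure in names(denoms)) {
    bad <- raw[[denoms[[measure]]]] <= 0
    if (any(bad)) {
      rlang::abort(paste0("zero denominator for ", measure, " in district(s) ",
                          paste(raw$district[bad], collapse = ", ")))
    }
  }
  tibble::tibble(
    district = raw$district,
    divorce_rate = 100 * raw$divorced_pop / raw$adult_pop,
    unemployment_rate = 100 * raw$unemployed / raw$labor_force,
    air_pollution = 100 * raw$psi_exceed_days / raw$psi_monitor_days,
    elderly_alone_rate = 100 * raw$elderly_alone / raw$elderly_pop,
    winter_temp = (raw$temp_jan + raw$temp_feb + raw$temp_dec) / 3
  )
}

#' One-standard-deviation dichotomization of district profiles
#'
#' A district is flagged high-incidence for divorce, unemployment,
#' elderly-living-alone and air pollution when its value lies strictly above
#' the cross-district mean plus one standard deviation; temperature is
#' flagged when strictly below the mean minus one standard deviation (low
#' winter temperature). The SD is normalized by `n - 1`; boundary ties are
#' not flagged.
#'
#' @param profiles Tibble from [compute_rates()] (at least 2 districts).
#' @return A tibble with columns `district` and binary indicators `divorce`,
#'   `unemployment`, `elderly_alone`, `temperature`, `air_pollution`.
#' @export
dichotomize <- function(profiles) {
  profiles <- tibble::as_tibble(profiles)
  if (nrow(profiles) < 2) {
    rlang::abort("dichotomization needs at least 2 districts (SD undefined)")
  }
  high <- function(x) as.integer(x > mean(x) + stats::sd(x))
  low <- function(x) as.integer(x < mean(x) - stats::sd(x))
  tibble::tibble(
    district = profiles$district,
    divorce = high(profiles$divorce_rate),
    unemployment = high(profiles$unemployment_rate),
    elderly_alone = high(profiles$elderly_alone_rate),
    temperature = low(profiles$winter_temp),
    air_pollution = high(profiles$air_pollution)
  )
}

#' Attach the seven-covariate binary vector to trajectories
#'
#' Links each patient to their district's environmental indicators through
#' the registered residence and adds the individual bits: `gender` (1 =
#' male) and `age` (1 = older than 65 at first stroke).
#'
#' @param trajectories Trajectory tibble (needs `sex`, `age_at_stroke`,
#'   `district`).
#' @param indicators District indicator tibble from [dichotomize()].
#' @return The trajectory tibble with the seven binary covariate columns of
#'   [covariate_names()] appended.
#' @export
attach_covariates <- function(trajectories, indicators) {
  trajectories <- tibble::as_tibble(trajectories)
  unknown <- setdiff(unique(trajectories$district), indicators$district)
  if (length(unknown) > 0) {
    bad <- trajectories$patient_id[trajectories$district %in% unknown]
    rlang::abort(paste0("district(s) without environmental indicators for patient(s): ",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  out <- trajectories %>%
    dplyr::mutate(
      gender = as.integer(.data$sex == "male"),
      age = as.integer(.data$age_at_stroke > 65)
    ) %>%
    dplyr::left_join(
      indicators[c("district", "divorce", "unemployment", "elderly_alone",
                   "temperature", "air_pollution")],
      by = "district"
    )
  out
}
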