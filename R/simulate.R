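#' Default data-generating model for synthetic cohorts
#'
#' A fully parameterized nine-state model whose magnitudes are realistic for
#' chronic-disease to stroke to dementia progression: chronic-to-stroke mean
#' sojourns of roughly 2-5 years, stroke-to-dementia sojourns of roughly
#' 1.5-3 years, ischemic stroke more frequent than hemorrhagic, and a
#' handful of nonzero covariate effects of plausible size (relative risks
#' between about 0.4 and 1.7) spread over both layers.
#'
#' @return An `smp_model`.
#' @export
default_true_model <- function() {
  edges <- tibble::tribble(
    ~from, ~to, ~p, ~sigma, ~v, ~beta,
    1L, 6L, 0.40, 3.0, 1.25, c(gender = 0.21, temperature = 0.24),
    1L, 7L, 0.60, 2.8, 1.20, c(age = -0.30, unemployment = -0.37),
    2L, 6L, 0.40, 2.5, 1.30, c(divorce = 0.55),
    2L, 7L, 0.60, 2.0, 1.15, c(temperature = 0.54),
    3L, 6L, 0.40, 3.0, 1.25, c(gender = 0.49),
    3L, 7L, 0.60, 2.7, 1.20, c(unemployment = -0.49),
    4L, 6L, 0.40, 4.5, 1.40, numeric(0),
    4L, 7L, 0.60, 4.8, 1.45, c(air_pollution = 0.27),
    5L, 6L, 0.40, 3.5, 1.10, c(age = -0.60),
    5L, 7L, 0.60, 3.8, 1.10, numeric(0),
    6L, 8L, 0.45, 2.0, 1.00, numeric(0),
    6L, 9L, 0.55, 1.4, 0.95, c(age = -0.39),
    7L, 8L, 0.45, 2.6, 1.05, c(temperature = -0.32),
    7L, 9L, 0.55, 2.8, 1.10, c(age = -0.37, temperature = -0.44)
  )
  smp_model(edges)
}

#' Scenario configuration for the synthetic-cohort generator
#'
#' Bundles every knob of the generator: the true model, cohort size, the
#' five-state chronic entry mixture, district count, individual covariate
#' prevalences, optional extra patient-level binary covariates (e.g.
#' medication or rehabilitation indicators, with their own true effects set
#' on the model), calendar placement and the administrative censoring
#' window.
#'
#' @param seed Integer master seed; all randomness derives from it through
#'   per-patient substreams, so enlarging the cohort does not perturb
#'   earlier patients.
#' @param n_patients Number of patients.
#' @param n_districts Number of administrative districts (default 22).
#' @param mixture Probabilities of the five chronic entry states (sum 1).
#' @param model True `smp_model` (default [default_true_model()]).
#' @param p_male,p_age Prevalence of the male and over-65 bits.
#' @param extra_covariates Named numeric vector of prevalences for
#'   additional patient-level binary covariates (default none).
#' @param entry_start,entry_end Calendar range over which chronic entries are
#'   drawn uniformly (a pre-window lead-in keeps most strokes inside the
#'   study window).
#' @param study_start,study_end Study window; follow-up is administratively
#'   censored at `study_end`.
#' @return A list of class `smp_scenario`.
#' @export
scenario_config <- function(seed = 1L,
                            n_patients = 2000L,
                            n_districts = 22L,
                            mixture = rep(0.2, 5),
                            model = default_true_model(),
                            p_male = 0.5,
                            p_age = 0.4,
                            extra_covariates = NULL,
                            entry_start = as.Date("1995-01-01"),
                            entry_end = as.Date("2008-12-31"),
                            study_start = as.Date("2000-01-01"),
                            study_end = as.Date("2010-12-31")) {
  if (abs(sum(mixture) - 1) > 1e-9 || length(mixture) != 5) {
    rlang::abort("`mixture` must be 5 probabilities summing to 1")
  }
  if (n_patients <= 0) rlang::abort("`n_patients` must be positive")
  if (as.Date(entry_start) > as.Date(study_end)) {
    rlang::abort("entry range must not start after the study end")
  }
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 n_districts = as.integer(n_districts), mixture = mixture,
                 model = model, p_male = p_male, p_age = p_age,
                 extra_covariates = extra_covariates,
                 entry_start = as.Date(entry_start),
                 entry_end = as.Date(entry_end),
                 study_start = as.Date(study_start),
                 study_end = as.Date(study_end)),
            class = "smp_scenario")
}

# deterministic substream seed, kept below 2^31
substream_seed <- function(seed, i) {
  as.integer(((seed %% 100000) * 20011 + i * 7 + 3) %% 2147483647)
}

#' Generate district-level environmental raw counts and truth flags
#'
#' Draws raw numerators/denominators per district (rates lognormal, winter
#' temperatures normal), from which [compute_rates()] reproduces the five
#' environmental measures. The columns prefixed `truth_` record which
#' districts the one-standard-deviation rule flags, computed directly from
#' the realized rates, so the covariate pipeline can be truth-checked.
#'
#' @param cfg An `smp_scenario`.
#' @return A tibble with one row per district: raw count columns consumed by
#'   [compute_rates()] plus `truth_divorce`, `truth_unemployment`,
#'   `truth_elderly_alone`, `truth_temperature`, `truth_air_pollution`.
#' @export
generate_districts <- function(cfg) {
  if (cfg$n_districts < 2) rlang::abort("need at least 2 districts")
  withr::with_seed(substream_seed(cfg$seed, 0), {
    n <- cfg$n_districts
    adult_pop <- round(stats::rlnorm(n, log(2e5), 0.4))
    labor_force <- round(adult_pop * stats::runif(n, 0.45, 0.6))
    elderly_pop <- round(adult_pop * stats::runif(n, 0.10, 0.18))
    divorce_rate <- stats::rlnorm(n, log(5), 0.35)
    unemp_rate <- stats::rlnorm(n, log(4), 0.30)
    psi_rate <- stats::rlnorm(n, log(6), 0.60)
    alone_rate <- stats::rlnorm(n, log(10), 0.30)
    temp_base <- stats::rnorm(n, 16, 1.8)
    raw <- tibble::tibble(
      district = sprintf("D%02d", seq_len(n)),
      divorced_pop = round(divorce_rate / 100 * adult_pop),
      adult_pop = adult_pop,
      unemployed = round(unemp_rate / 100 * labor_force),
      labor_force = labor_force,
      psi_exceed_days = round(psi_rate / 100 * 365),
      psi_monitor_days = 365L,
      elderly_alone = round(alone_rate / 100 * elderly_pop),
      elderly_pop = elderly_pop,
      temp_jan = temp_base - 0.6 + stats::rnorm(n, 0, 0.3),
      temp_feb = temp_base + stats::rnorm(n, 0, 0.3),
      temp_dec = temp_base + 0.9 + stats::rnorm(n, 0, 0.3)
    )
  })
  rates <- compute_rates(raw)
  flag_high <- function(x) as.integer(x > mean(x) + stats::sd(x))
  raw$truth_divorce <- flag_high(rates$divorce_rate)
  raw$truth_unemployment <- flag_high(rates$unemployment_rate)
  raw$truth_elderly_alone <- flag_high(rates$elderly_alone_rate)
  raw$truth_temperature <- as.integer(
    rates$winter_temp < mean(rates$winter_temp) - stats::sd(rates$winter_temp))
  raw$truth_air_pollution <- flag_high(rates$air_pollution)
  raw
}

# conditional Weibull draw under the PH effect: scale sigma * exp(-lp / v)
draw_sojourn <- function(sigma, v, lp) {
  stats::rweibull(1, shape = v, scale = sigma * exp(-lp / v))
}

# redraw until the sojourn is at least one day (claims carry day-resolution
# dates, and the ordering rules need strictly increasing dates)
draw_sojourn_min1d <- function(sigma, v, lp) {
  for (k in 1:100) {
    d <- draw_sojourn(sigma, v, lp)
    if (round(d * 365.25) >= 1) return(d)
  }
  1 / 365.25
}

#' Simulate ground-truth patient trajectories
#'
#' For each patient: a district (hence environmental indicator bits), sex
#' and age bits, a chronic entry state from the mixture and a uniform entry
#' date; then the semi-Markov path is sampled forward - next state from the
#' embedded chain, sojourn from the edge's covariate-conditional Weibull -
#' until a dementia state is reached or the study window ends, in which case
#' the patient is right-censored in their current state. Dates are stored at
#' day resolution and durations recomputed from them. Birth year is set
#' consistently with the drawn over-65 bit.
#'
#' @param cfg An `smp_scenario`.
#' @return A trajectory tibble (same layout as [build_cohort()]) with the
#'   seven covariate bit columns, any extra covariates, and attributes
#'   `districts` (the [generate_districts()] table) and `config`.
#' @export
simulate_trajectories <- function(cfg) {
  districts <- generate_districts(cfg)
  indicators <- dichotomize(compute_rates(districts))
  model <- cfg$model
  edges <- model$edges
  extra_names <- names(cfg$extra_covariates)

  entry_days <- as.numeric(cfg$entry_end - cfg$entry_start)
  rows <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    rows[[i]] <- withr::with_seed(substream_seed(cfg$seed, i), {
      district <- districts$district[sample.int(nrow(districts), 1)]
      ind <- indicators[indicators$district == district, ]
      bits <- c(
        gender = stats::rbinom(1, 1, cfg$p_male),
        age = stats::rbinom(1, 1, cfg$p_age),
        divorce = ind$divorce, unemployment = ind$unemployment,
        elderly_alone = ind$elderly_alone, temperature = ind$temperature,
        air_pollution = ind$air_pollution
      )
      if (length(extra_names) > 0) {
        extra <- stats::rbinom(length(extra_names), 1, cfg$extra_covariates)
        names(extra) <- extra_names
        bits <- c(bits, extra)
      }
      chronic_state <- sample.int(5, 1, prob = cfg$mixture)
      entry <- cfg$entry_start + round(stats::runif(1, 0, entry_days))

      lp_edge <- function(k) {
        b <- edges$beta[[k]]
        if (length(b) == 0) 0 else sum(b * bits[names(b)])
      }
      # chronic -> stroke
      out <- edges[edges$from == chronic_state, ]
      k1 <- which(edges$from == chronic_state)[
        sample.int(nrow(out), 1, prob = out$p)]
      d1 <- draw_sojourn_min1d(edges$sigma[k1], edges$v[k1], lp_edge(k1))
      stroke_date <- entry + max(1, round(d1 * 365.25))

      stroke_state <- NA_integer_; dementia_state <- NA_integer_
      dementia_date <- as.Date(NA); censored <- TRUE
      if (stroke_date <= cfg$study_end) {
        stroke_state <- edges$to[k1]
        out2 <- edges[edges$from == stroke_state, ]
        k2 <- which(edges$from == stroke_state)[
          sample.int(nrow(out2), 1, prob = out2$p)]
        d2 <- draw_sojourn_min1d(edges$sigma[k2], edges$v[k2], lp_edge(k2))
        dem_date <- stroke_date + max(1, round(d2 * 365.25))
        if (dem_date <= cfg$study_end) {
          dementia_state <- edges$to[k2]
          dementia_date <- dem_date
          censored <- FALSE
        }
      } else {
        stroke_date <- as.Date(NA)
      }

      ref_year <- as.integer(format(
        if (!is.na(stroke_date)) stroke_date else cfg$study_end, "%Y"))
      age_target <- if (bits[["age"]] == 1) sample(67:85, 1) else sample(32:64, 1)
      birth_year <- ref_year - age_target

      dplyr::bind_cols(
        tibble::tibble(
          patient_id = sprintf("S%06d", i),
          sex = if (bits[["gender"]] == 1) "male" else "female",
          birth_year = birth_year, district = district,
          chronic_state = chronic_state, chronic_date = entry,
          stroke_state = stroke_state, stroke_date = stroke_date,
          dementia_state = dementia_state, dementia_date = dementia_date,
          censored = censored,
          censor_date = if (censored) cfg$study_end else as.Date(NA),
          age_at_stroke = if (!is.na(stroke_date)) age_target else NA_integer_
        ),
        tibble::as_tibble(as.list(bits))
      )
    })
  }
  traj <- dplyr::bind_rows(rows)
  traj <- traj %>%
    dplyr::mutate(
      d_cs = as.numeric(dplyr::coalesce(.data$stroke_date, cfg$study_end) -
                          .data$chronic_date) / 365.25,
      d_sd = dplyr::if_else(
        is.na(.data$stroke_state), NA_real_,
        as.numeric(dplyr::coalesce(.data$dementia_date, cfg$study_end) -
                     .data$stroke_date) / 365.25),
      ambiguous = FALSE,
      .after = "censor_date"
    )
  attr(traj, "districts") <- districts
  attr(traj, "config") <- cfg
  traj
}

# per-state chronic ICD codes used when rendering trajectories as claims
chronic_codes <- list(
  `1` = "4019", `2` = "250", `3` = "2724", `4` = "2740", `5` = character(0)
)
stroke_codes <- c(`6` = "430", `7` = "433")
dementia_codes <- c(`8` = "2904", `9` = "2941")
state4_extras <- c("250", "2720", "4019", "4280", "42731")

#' Render trajectories as an ICD-coded claims event stream
#'
#' Inverse of the cohort builder: each trajectory becomes an enrollment
#' marker (an unmapped general-examination code at the chronic entry date),
#' the chronic diagnosis code(s) implied by the entry state (for state 4, an
#' index diagnosis followed by five further chronic diagnoses so that the
#' more-than-four-factors rule is recoverable), stroke diagnosis events
#' (one hospitalization, or three distinct-date clinic visits within the
#' 365-day confirmation rule), and the dementia diagnosis where one
#' occurred. Optionally injects noise patients that each violate one
#' inclusion rule, labelled with the exclusion reason the cohort builder is
#' expected to emit.
#'
#' @param trajectories Output of [simulate_trajectories()].
#' @param cfg The same `smp_scenario`.
#' @param violations Character vector of violation kinds to inject (each
#'   adds one synthetic patient): any of `"age"`, `"same_day_dual"`,
#'   `"no_stroke"`, `"unconfirmed"`, `"stroke_outside_window"`,
#'   `"zero_sojourn"`. Default none.
#' @return A list with `events` (diagnosis-event tibble in [read_claims()]
#'   layout) and `truth` (tibble `patient_id`, `kind`, `expected_reason`).
#' @export
emit_claims <- function(trajectories, cfg, violations = character(0)) {
  ev <- vector("list", nrow(trajectories))
  for (i in seq_len(nrow(trajectories))) {
    tr <- trajectories[i, ]
    ev[[i]] <- withr::with_seed(substream_seed(cfg$seed + 1L, i), {
      render_patient(tr)
    })
  }
  truth <- tibble::tibble(patient_id = trajectories$patient_id,
                          kind = "clean",
                          expected_reason = NA_character_)
  if (length(violations) > 0) {
    inj <- purrr::imap(violations, function(kind, j) {
      violation_patient(kind, j, cfg)
    })
    ev <- c(ev, purrr::map(inj, "events"))
    truth <- dplyr::bind_rows(truth, purrr::map_dfr(inj, "truth"))
  }
  events <- dplyr::bind_rows(ev)
  list(events = events, truth = truth)
}

render_patient <- function(tr) {
  base <- function(icd9, date, encounter = "clinic") {
    tibble::tibble(patient_id = tr$patient_id, sex = tr$sex,
                   birth_year = tr$birth_year, district = tr$district,
                   icd9 = icd9, date = date, encounter = encounter)
  }
  out <- list(base("V700", tr$chronic_date))  # enrollment marker, unmapped
  cs <- as.character(tr$chronic_state)
  end_date <- min(tr$stroke_date, tr$censor_date, na.rm = TRUE)
  gap <- as.numeric(end_date - tr$chronic_date)
  if (length(chronic_codes[[cs]]) > 0) {
    out <- c(out, list(base(chronic_codes[[cs]], tr$chronic_date)))
    if (tr$chronic_state == 4) {
      # five further distinct chronic diagnoses strictly inside the spell
      offs <- pmin(pmax(round(seq_len(5) * gap / 6), 1), gap - 1)
      out <- c(out, list(base(state4_extras, tr$chronic_date + offs)))
    } else if (tr$chronic_state %in% c(1, 3) && gap >= 2 &&
                 stats::runif(1) < 0.3) {
      # optionally one additional metabolic risk factor (still states 1/3)
      extra <- if (tr$chronic_state == 1) "250" else "4019"
      off <- max(1, min(round(gap / 2), gap - 1))
      out <- c(out, list(base(extra, tr$chronic_date + off)))
    }
  }
  if (!is.na(tr$stroke_state)) {
    code <- stroke_codes[[as.character(tr$stroke_state)]]
    if (stats::runif(1) < 0.4) {
      out <- c(out, list(base(code, tr$stroke_date, "hospitalization")))
    } else {
      out <- c(out, list(base(code, tr$stroke_date + c(0, 45, 120))))
    }
    if (!is.na(tr$dementia_state)) {
      dcode <- dementia_codes[[as.character(tr$dementia_state)]]
      out <- c(out, list(base(dcode, tr$dementia_date)))
    }
  }
  dplyr::bind_rows(out)
}

violation_patient <- function(kind, j, cfg) {
  id <- sprintf("V_%s_%02d", kind, j)
  base <- function(icd9, date, encounter = "hospitalization",
                   birth_year = 1940L) {
    tibble::tibble(patient_id = id, sex = "female", birth_year = birth_year,
                   district = "D01", icd9 = icd9, date = as.Date(date),
                   encounter = encounter)
  }
  events <- switch(
    kind,
    age = dplyr::bind_rows(
      base("4019", "2001-03-01", "clinic", birth_year = 1980L),
      base("433", "2005-06-01", birth_year = 1980L)
    ),
    same_day_dual = dplyr::bind_rows(
      base("4019", "2001-03-01", "clinic"),
      base("430", "2005-06-01"),
      base("433", "2005-06-01")
    ),
    no_stroke = base("4019", "2001-03-01", "clinic"),
    unconfirmed = dplyr::bind_rows(
      base("4019", "2001-03-01", "clinic"),
      base("433", "2005-06-01", "clinic"),
      base("433", "2005-07-01", "clinic")
    ),
    stroke_outside_window = dplyr::bind_rows(
      base("4019", "1996-03-01", "clinic"),
      base("433", "1998-06-01")
    ),
    zero_sojourn = dplyr::bind_rows(
      base("4019", "2005-06-01", "clinic"),
      base("433", "2005-06-01")
    ),
    rlang::abort(paste0("unknown violation kind: ", kind))
  )
  expected <- if (kind == "zero_sojourn") "zero_sojourn" else kind
  list(events = events,
       truth = tibble::tibble(patient_id = id, kind = kind,
                              expected_reason = expected))
}
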