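#' ICD-9-CM code table of the eleven chronic diseases, stroke and dementia
#'
#' One row per code prefix. Range entries (e.g. hypertension 401-405) are
#' expanded to their three-digit category prefixes; listed four- and
#' five-digit codes (e.g. atrial fibrillation 42731, peripheral artery
#' disease 437.3) are kept at full length so that [map_icd()] can resolve
#' overlaps by longest-prefix match.
#'
#' @return A tibble with columns `prefix`, `disease` and `group`
#'   (`"chronic"`, `"stroke"`, `"dementia"`).
#' @export
icd_table <- function() {
  tibble::tribble(
    ~prefix, ~disease, ~group,
    "401", "hypertension", "chronic",
    "402", "hypertension", "chronic",
    "403", "hypertension", "chronic",
    "404", "hypertension", "chronic",
    "405", "hypertension", "chronic",
    "250", "diabetes", "chronic",
    "272", "hyperlipidemia", "chronic",
    "490", "chronic_lung", "chronic",
    "491", "chronic_lung", "chronic",
    "492", "chronic_lung", "chronic",
    "493", "chronic_lung", "chronic",
    "494", "chronic_lung", "chronic",
    "495", "chronic_lung", "chronic",
    "496", "chronic_lung", "chronic",
    "242", "hyperthyroidism", "chronic",
    "585", "chronic_kidney", "chronic",
    "428", "heart_failure", "chronic",
    "42731", "atrial_fibrillation", "chronic",
    "78051", "sleep_apnea", "chronic",
    "78053", "sleep_apnea", "chronic",
    "78057", "sleep_apnea", "chronic",
    "274", "gout", "chronic",
    "4373", "peripheral_artery", "chronic",
    "440", "peripheral_artery", "chronic",
    "441", "peripheral_artery", "chronic",
    "4431", "peripheral_artery", "chronic",
    "4432", "peripheral_artery", "chronic",
    "4438", "peripheral_artery", "chronic",
    "4439", "peripheral_artery", "chronic",
    "4471", "peripheral_artery", "chronic",
    "4478", "peripheral_artery", "chronic",
    "4479", "peripheral_artery", "chronic",
    "445", "peripheral_artery", "chronic",
    "430", "hemorrhagic_stroke", "stroke",
    "432", "hemorrhagic_stroke", "stroke",
    "433", "ischemic_stroke", "stroke",
    "437", "ischemic_stroke", "stroke",
    "2904", "vascular_dementia", "dementia",
    "294", "nonvascular_dementia", "dementia",
    "337", "nonvascular_dementia", "dementia"
  )
}

# priority used to break ties when two chronic diseases share the earliest
# diagnosis date: the three index diseases first, then Table-1 order
chronic_priority <- c(
  "hypertension", "diabetes", "hyperlipidemia", "chronic_lung",
  "hyperthyroidism", "chronic_kidney", "heart_failure",
  "atrial_fibrillation", "sleep_apnea", "gout", "peripheral_artery"
)

#' Map ICD-9-CM codes to disease labels
#'
#' Codes are normalized (dots stripped) and matched by longest prefix against
#' [icd_table()], so `"4031"` falls under the hypertension 401-405 range and
#' `"43730"` resolves to peripheral artery disease (437.3) rather than the
#' three-digit ischemic-stroke category 437. Unlisted codes map to `NA`.
#'
#' @param code Character vector of ICD-9-CM codes (with or without dots).
#' @return Character vector of disease labels, `NA` where unmapped.
#' @export
#' @examples
#' map_icd(c("4031", "430", "43730", "79999"))
map_icd <- function(code) {
  tbl <- icd_table()
  norm <- gsub("[. ]", "", as.character(code))
  out <- rep(NA_character_, length(norm))
  for (len in sort(unique(nchar(tbl$prefix)), decreasing = TRUE)) {
    sub <- tbl[nchar(tbl$prefix) == len, ]
    idx <- is.na(out) & nchar(norm) >= len
    if (!any(idx)) next
    hit <- match(substr(norm[idx], 1, len), sub$prefix)
    out[idx][!is.na(hit)] <- sub$disease[hit[!is.na(hit)]]
  }
  out
}

icd_group <- function(disease) {
  tbl <- icd_table()
  tbl$group[match(disease, tbl$disease)]
}

normalize_events <- function(events) {
  events <- tibble::as_tibble(events)
  required <- c("patient_id", "sex", "birth_year", "district", "icd9",
                "date", "encounter")
  missing <- setdiff(required, names(events))
  if (length(missing) > 0) {
    rlang::abort(paste0("`events` is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  events$date <- as.Date(events$date)
  events$disease <- map_icd(events$icd9)
  events$group <- icd_group(events$disease)
  dplyr::arrange(events, .data$patient_id, .data$date, .data$icd9,
                 .data$encounter)
}

#' Read a claims-style diagnosis event table
#'
#' @param path CSV/TSV file with header
#'   `patient_id,sex,birth_year,district,icd9,date,encounter`; ISO-8601 dates.
#' @return A tibble of diagnosis events.
#' @export
read_claims <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  ev <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character")
  tibble::tibble(
    patient_id = ev$patient_id,
    sex = ev$sex,
    birth_year = as.integer(ev$birth_year),
    district = ev$district,
    icd9 = ev$icd9,
    date = as.Date(ev$date),
    encounter = ev$encounter
  )
}

age_at <- function(date, birth_year) {
  as.integer(format(date, "%Y")) - birth_year
}

#' Screen patients against the cohort inclusion rules
#'
#' A patient is included when their first stroke diagnosis falls inside the
#' study window and is confirmed by at least three distinct-date clinic
#' visits carrying a stroke code (no consecutive gap above 365 days) or by at
#' least one hospitalization with a stroke code; patients younger than 30 at
#' first stroke and patients whose first hemorrhagic and first ischemic
#' diagnoses share a date are excluded. Every exclusion carries a reason code
#' (`no_stroke`, `same_day_dual`, `stroke_outside_window`, `unconfirmed`,
#' `age`).
#'
#' @param events Diagnosis-event tibble (see [read_claims()] for columns).
#' @param study_start,study_end Study window (dates); defaults 2000-01-01 to
#'   2010-12-31.
#' @return A tibble with one row per patient: `patient_id`, `included`,
#'   `reason` (`NA` when included), `stroke_date`, `stroke_state`
#'   (6 hemorrhagic / 7 ischemic), `age_at_stroke`.
#' @export
apply_inclusion <- function(events,
                            study_start = as.Date("2000-01-01"),
                            study_end = as.Date("2010-12-31")) {
  events <- normalize_events(events)
  events %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::group_modify(~ screen_patient(.x, study_start, study_end)) %>%
    dplyr::ungroup()
}

screen_patient <- function(ev, study_start, study_end) {
  out <- tibble::tibble(included = FALSE, reason = NA_character_,
                        stroke_date = as.Date(NA), stroke_state = NA_integer_,
                        age_at_stroke = NA_integer_)
  stroke_ev <- ev[!is.na(ev$group) & ev$group == "stroke", ]
  if (nrow(stroke_ev) == 0) {
    out$reason <- "no_stroke"
    return(out)
  }
  first_hem <- suppressWarnings(min(stroke_ev$date[stroke_ev$disease == "hemorrhagic_stroke"]))
  first_isc <- suppressWarnings(min(stroke_ev$date[stroke_ev$disease == "ischemic_stroke"]))
  if (is.finite(first_hem) && is.finite(first_isc) && first_hem == first_isc) {
    out$reason <- "same_day_dual"
    return(out)
  }
  stroke_date <- min(stroke_ev$date)
  stroke_type <- stroke_ev$disease[stroke_ev$date == stroke_date][1]
  out$stroke_date <- stroke_date
  out$stroke_state <- if (stroke_type == "hemorrhagic_stroke") 6L else 7L
  out$age_at_stroke <- age_at(stroke_date, ev$birth_year[1])
  if (stroke_date < study_start || stroke_date > study_end) {
    out$reason <- "stroke_outside_window"
    return(out)
  }
  if (!stroke_confirmed(stroke_ev)) {
    out$reason <- "unconfirmed"
    return(out)
  }
  if (out$age_at_stroke < 30) {
    out$reason <- "age"
    return(out)
  }
  out$included <- TRUE
  out
}

# >= 1 hospitalization with a stroke code, or >= 3 distinct-date clinic
# visits with a stroke code where consecutive gaps are <= 365 days
stroke_confirmed <- function(stroke_ev) {
  if (any(stroke_ev$encounter == "hospitalization")) return(TRUE)
  d <- sort(unique(stroke_ev$date[stroke_ev$encounter == "clinic"]))
  if (length(d) < 3) return(FALSE)
  gaps <- as.numeric(diff(d))
  any(gaps[-length(gaps)] <= 365 & gaps[-1] <= 365)
}

#' Assign the five-category chronic entry state
#'
#' Classifies each included patient's pre-stroke chronic history into the
#' five entry states: hypertension first with at most one further metabolic
#' risk factor (state 1), diabetes mellitus only (state 2), hyperlipidemia
#' first with at most one further factor (state 3), more than four metabolic
#' risk factors after an initial other chronic disease (state 4), and no
#' chronic disease among the eleven before stroke (state 5). A "metabolic
#' risk factor" is any additional distinct chronic diagnosis on or after the
#' index diagnosis date. Histories that fit none of the four patterns are
#' assigned the nearest category and flagged `ambiguous`; ties between
#' hypertension and hyperlipidemia on the same first date resolve to
#' hypertension.
#'
#' @param events Diagnosis-event tibble.
#' @param inclusion Output of [apply_inclusion()] (included rows are used).
#' @return A tibble: `patient_id`, `chronic_state` (1-5), `chronic_date`
#'   (index diagnosis date; first-ever event date for state 5), `ambiguous`.
#' @export
assign_chronic_state <- function(events, inclusion) {
  events <- normalize_events(events)
  inc <- inclusion[inclusion$included, c("patient_id", "stroke_date")]
  events %>%
    dplyr::inner_join(inc, by = "patient_id") %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::group_modify(~ classify_chronic(.x)) %>%
    dplyr::ungroup()
}

classify_chronic <- function(ev) {
  pre <- ev[!is.na(ev$group) & ev$group == "chronic" &
              ev$date < ev$stroke_date[1], ]
  if (nrow(pre) == 0) {
    return(tibble::tibble(chronic_state = 5L,
                          chronic_date = min(ev$date),
                          ambiguous = FALSE))
  }
  first_dates <- tapply(pre$date, pre$disease, min)
  diseases <- names(first_dates)
  first_dates <- as.Date(first_dates, origin = "1970-01-01")
  ord <- order(first_dates, match(diseases, chronic_priority))
  index <- diseases[ord[1]]
  index_date <- first_dates[ord[1]]
  n_extra <- sum(diseases != index & first_dates >= index_date)
  if (index == "hypertension") {
    state <- 1L; ambiguous <- n_extra > 1
  } else if (index == "diabetes") {
    state <- 2L; ambiguous <- n_extra > 0
  } else if (index == "hyperlipidemia") {
    state <- 3L; ambiguous <- n_extra > 1
  } else {
    state <- 4L; ambiguous <- n_extra <= 4
  }
  tibble::tibble(chronic_state = state, chronic_date = index_date,
                 ambiguous = ambiguous)
}

#' Build state trajectories from screened events
#'
#' Combines inclusion screening, chronic-state assignment and dementia
#' follow-up into one trajectory per included patient. Dementia diagnoses
#' must fall strictly after the stroke date (earlier dementia codes are
#' dropped with a warning); ICD 290.4 maps to vascular dementia (state 8) and
#' 294/337 to non-vascular dementia (state 9). Patients without dementia by
#' the study end are censored in their stroke state at the study end date.
#' Patients whose chronic index date equals the stroke date are excluded with
#' reason `zero_sojourn` (a zero sojourn has no Weibull likelihood).
#'
#' @inheritParams apply_inclusion
#' @return A list with `trajectories` (tibble, one row per included patient)
#'   and `exclusions` (tibble `patient_id`, `reason`). Durations `d_cs`
#'   (chronic to stroke) and `d_sd` (stroke to dementia or censoring) are in
#'   years (365.25 days).
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   patient_id = "p1", sex = "male", birth_year = 1940L, district = "d1",
#'   icd9 = c("4019", "433", "433", "433", "2904"),
#'   date = as.Date(c("2001-05-01", "2004-02-01", "2004-03-01",
#'                    "2004-04-01", "2006-06-30")),
#'   encounter = "clinic"
#' )
#' build_cohort(ev)$trajectories
build_cohort <- function(events,
                         study_start = as.Date("2000-01-01"),
                         study_end = as.Date("2010-12-31")) {
  events <- normalize_events(events)
  inclusion <- apply_inclusion(events, study_start, study_end)
  chronic <- assign_chronic_state(events, inclusion)

  meta <- events %>%
    dplyr::distinct(.data$patient_id, .keep_all = TRUE) %>%
    dplyr::select("patient_id", "sex", "birth_year", "district")

  dem <- events %>%
    dplyr::filter(!is.na(.data$group), .data$group == "dementia") %>%
    dplyr::inner_join(inclusion[inclusion$included,
                                c("patient_id", "stroke_date")],
                      by = "patient_id")
  n_dropped <- sum(dem$date <= dem$stroke_date)
  if (n_dropped > 0) {
    warning(n_dropped, " dementia event(s) on or before the stroke date were dropped",
            call. = FALSE)
  }
  dem <- dem %>%
    dplyr::filter(.data$date > .data$stroke_date) %>%
    dplyr::mutate(dem_state = ifelse(.data$disease == "vascular_dementia", 8L, 9L)) %>%
    dplyr::group_by(.data$patient_id) %>%
    # earliest dementia diagnosis; a same-day tie resolves to vascular (8)
    dplyr::arrange(.data$date, .data$dem_state, .by_group = TRUE) %>%
    dplyr::summarise(dementia_date = dplyr::first(.data$date),
                     dementia_state = dplyr::first(.data$dem_state))

  traj <- inclusion %>%
    dplyr::filter(.data$included) %>%
    dplyr::select("patient_id", "stroke_date", "stroke_state",
                  "age_at_stroke") %>%
    dplyr::left_join(chronic, by = "patient_id") %>%
    dplyr::left_join(dem, by = "patient_id") %>%
    dplyr::left_join(meta, by = "patient_id")

  zero <- traj$chronic_date >= traj$stroke_date
  exclusions <- dplyr::bind_rows(
    inclusion %>% dplyr::filter(!.data$included) %>%
      dplyr::select("patient_id", "reason"),
    traj %>% dplyr::filter(zero) %>%
      dplyr::transmute(.data$patient_id, reason = "zero_sojourn")
  )
  traj <- traj[!zero, ]

  traj <- traj %>%
    dplyr::mutate(
      censored = is.na(.data$dementia_state),
      censor_date = dplyr::if_else(.data$censored, study_end, as.Date(NA)),
      d_cs = as.numeric(.data$stroke_date - .data$chronic_date) / 365.25,
      d_sd = dplyr::if_else(
        .data$censored,
        as.numeric(study_end - .data$stroke_date) / 365.25,
        as.numeric(.data$dementia_date - .data$stroke_date) / 365.25
      )
    ) %>%
    dplyr::select("patient_id", "sex", "birth_year", "district",
                  "chronic_state", "chronic_date", "stroke_state",
                  "stroke_date", "dementia_state", "dementia_date",
                  "censored", "censor_date", "d_cs", "d_sd",
                  "age_at_stroke", "ambiguous")
  list(trajectories = traj, exclusions = exclusions)
}

#' Write / read trajectory tables
#'
#' Plain-CSV persistence for the one-row-per-patient trajectory table.
#'
#' @param trajectories Trajectory tibble from [build_cohort()] or
#'   [simulate_trajectories()].
#' @param path CSV file path.
#' @return `path` invisibly ([write_trajectories()]) or a tibble
#'   ([read_trajectories()]).
#' @export
write_trajectories <- function(trajectories, path) {
  utils::write.csv(trajectories, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (col in intersect(c("chronic_date", "stroke_date", "dementia_date",
                          "censor_date"), names(df))) {
    df[[col]] <- as.Date(df[[col]])
  }
  if ("censored" %in% names(df)) df$censored <- as.logical(df$censored)
  tibble::as_tibble(df)
}
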