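test_that("ICD-9-CM mapping follows the code table with longest-prefix matching", {
  expect_equal(map_icd("4031"), "hypertension")
  expect_equal(map_icd("430"), "hemorrhagic_stroke")
  expect_true(is.na(map_icd("79999")))
  expect_equal(map_icd("2500"), "diabetes")
  expect_equal(map_icd("272"), "hyperlipidemia")
  expect_equal(map_icd("4931"), "chronic_lung")
  expect_equal(map_icd("42731"), "atrial_fibrillation")
  expect_true(is.na(map_icd("4270")))       # other 427.x not listed
  expect_equal(map_icd("780.51"), "sleep_apnea")
  expect_true(is.na(map_icd("78052")))
  # 437.3 is peripheral artery disease, any other 437.x ischemic stroke
  expect_equal(map_icd("4373"), "peripheral_artery")
  expect_equal(map_icd("43730"), "peripheral_artery")
  expect_equal(map_icd("4371"), "ischemic_stroke")
  expect_equal(map_icd("2904"), "vascular_dementia")
  expect_true(is.na(map_icd("290")))
  expect_equal(map_icd("3371"), "nonvascular_dementia")
})

test_that("inclusion screen emits the documented reason codes", {
  ev <- dplyr::bind_rows(
    clean_patient_events("ok"),
    event_row("nostroke", "4019", "2003-01-01"),
    # hemorrhagic and ischemic first diagnosed the same day
    event_row("dual", c("430", "433"), "2005-06-01", "hospitalization"),
    # only two clinic visits, no hospitalization
    event_row("unconf", "433", c("2005-06-01", "2005-07-01")),
    # confirmed stroke but before the window opens
    event_row("early", "433", "1999-06-01", "hospitalization"),
    # age 28 at stroke
    event_row("young", "433", "2005-06-01", "hospitalization",
              birth_year = 1977L)
  )
  inc <- apply_inclusion(ev)
  reason <- setNames(inc$reason, inc$patient_id)
  expect_true(inc$included[inc$patient_id == "ok"])
  expect_equal(reason[["nostroke"]], "no_stroke")
  expect_equal(reason[["dual"]], "same_day_dual")
  expect_equal(reason[["unconf"]], "unconfirmed")
  expect_equal(reason[["early"]], "stroke_outside_window")
  expect_equal(reason[["young"]], "age")
})

test_that("three clinic visits confirm a stroke only within the 365-day rule", {
  gap_ok <- event_row("a", "433", c("2004-01-01", "2004-11-01", "2005-09-01"))
  expect_true(apply_inclusion(gap_ok)$included)
  gap_bad <- event_row("b", "433", c("2004-01-01", "2005-06-01", "2006-11-01"))
  expect_equal(apply_inclusion(gap_bad)$reason, "unconfirmed")
  hosp <- event_row("c", "433", "2004-01-01", "hospitalization")
  expect_true(apply_inclusion(hosp)$included)
})

test_that("chronic-state classification implements the five-category scheme", {
  cases <- list(
    # hypertension alone -> state 1
    list(ev = event_row("p", "4019", "2001-01-01"), state = 1L, amb = FALSE),
    # hypertension plus one further factor -> still state 1
    list(ev = event_row("p", c("4019", "250"), c("2001-01-01", "2002-01-01")),
         state = 1L, amb = FALSE),
    # diabetes only -> state 2
    list(ev = event_row("p", "250", "2001-01-01"), state = 2L, amb = FALSE),
    # hyperlipidemia plus one factor -> state 3
    list(ev = event_row("p", c("2720", "4280"), c("2001-01-01", "2002-01-01")),
         state = 3L, amb = FALSE),
    # gout then five further factors -> state 4
    list(ev = event_row("p", c("2740", "250", "4019", "2720", "4280", "42731"),
                        c("2001-01-01", "2001-06-01", "2001-07-01",
                          "2001-08-01", "2001-09-01", "2001-10-01")),
         state = 4L, amb = FALSE),
    # no chronic history -> state 5
    list(ev = event_row("p", "V700", "2001-01-01"), state = 5L, amb = FALSE),
    # hypertension/hyperlipidemia tie on the same first date -> state 1
    list(ev = event_row("p", c("4019", "2720"), "2001-01-01"),
         state = 1L, amb = FALSE),
    # diabetes with an extra factor fits no pattern -> flagged ambiguous
    list(ev = event_row("p", c("250", "4280"), c("2001-01-01", "2002-01-01")),
         state = 2L, amb = TRUE),
    # other-chronic with too few factors for state 4 -> flagged ambiguous
    list(ev = event_row("p", c("2740", "250"), c("2001-01-01", "2002-01-01")),
         state = 4L, amb = TRUE)
  )
  for (cs in cases) {
    ev <- dplyr::bind_rows(cs$ev,
                           event_row("p", "433", "2005-06-01", "hospitalization"))
    got <- assign_chronic_state(ev, apply_inclusion(ev))
    expect_equal(got$chronic_state, cs$state)
    expect_equal(got$ambiguous, cs$amb)
  }
})

test_that("chronic diagnoses on or after the stroke date do not count", {
  ev <- dplyr::bind_rows(
    event_row("p", "433", "2005-06-01", "hospitalization"),
    event_row("p", "4019", "2005-06-01"),   # same day as stroke
    event_row("p", "250", "2006-01-01")     # after stroke
  )
  got <- assign_chronic_state(ev, apply_inclusion(ev))
  expect_equal(got$chronic_state, 5L)
})

test_that("trajectories carry state sequence, sojourns and censoring", {
  ev <- dplyr::bind_rows(
    event_row("p", "2724", "2002-01-01"),
    event_row("p", "433", c("2004-01-01", "2004-02-01", "2004-03-01")),
    event_row("p", "2904", "2006-06-30")
  )
  tr <- build_cohort(ev)$trajectories
  expect_equal(tr$chronic_state, 3L)
  expect_equal(tr$stroke_state, 7L)
  expect_equal(tr$dementia_state, 8L)
  expect_false(tr$censored)
  expect_equal(tr$d_cs, 2.0, tolerance = 0.01)
  expect_equal(tr$d_sd, 2.5, tolerance = 0.01)

  # stroke-only patient is censored at study end
  ev2 <- dplyr::bind_rows(
    event_row("q", "4019", "2002-01-01"),
    event_row("q", "430", "2004-01-01", "hospitalization")
  )
  tr2 <- build_cohort(ev2)$trajectories
  expect_true(tr2$censored)
  expect_equal(tr2$censor_date, as.Date("2010-12-31"))
  expect_equal(tr2$d_sd, as.numeric(as.Date("2010-12-31") -
                                      as.Date("2004-01-01")) / 365.25)
  expect_equal(tr2$stroke_state, 6L)
})

test_that("dementia events on or before the stroke date are dropped with a warning", {
  ev <- dplyr::bind_rows(
    event_row("p", "2904", "2003-01-01"),
    event_row("p", "4019", "2002-01-01"),
    event_row("p", "433", "2004-01-01", "hospitalization")
  )
  expect_warning(res <- build_cohort(ev), "dropped")
  expect_true(res$trajectories$censored)
})

test_that("zero chronic-to-stroke sojourns are excluded with a reason code", {
  ev <- dplyr::bind_rows(
    event_row("p", "4019", "2004-01-01"),
    event_row("p", "433", "2004-01-01", "hospitalization")
  )
  res <- build_cohort(ev)
  expect_equal(nrow(res$trajectories), 0)
  expect_equal(res$exclusions$reason, "zero_sojourn")
})

test_that("cohort construction conserves patients and is order independent", {
  cfg <- scenario_config(seed = 21, n_patients = 120)
  cl <- emit_claims(simulate_trajectories(cfg), cfg,
                    violations = c("age", "no_stroke"))
  res <- build_cohort(cl$events)
  n_patients <- dplyr::n_distinct(cl$events$patient_id)
  expect_equal(nrow(res$trajectories) + nrow(res$exclusions), n_patients)

  shuffled <- withr::with_seed(5, cl$events[sample(nrow(cl$events)), ])
  res2 <- build_cohort(shuffled)
  expect_equal(res2$trajectories, res$trajectories)
  expect_equal(dplyr::arrange(res2$exclusions, patient_id),
               dplyr::arrange(res$exclusions, patient_id))
})

test_that("trajectory tables round-trip through CSV", {
  cfg <- scenario_config(seed = 22, n_patients = 40)
  tr <- simulate_trajectories(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(tr, path)
  back <- read_trajectories(path)
  expect_equal(back$d_cs, tr$d_cs, tolerance = 1e-12)
  expect_equal(back$chronic_date, tr$chronic_date)
  expect_equal(back$censored, tr$censored)
  expect_equal(back$gender, tr$gender)
})
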