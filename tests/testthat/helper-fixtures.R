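# shared fixtures built in code

# minimal valid model: default structure, balanced chains, simple Weibulls
toy_model <- function(p16 = 0.4, sigma16 = 2, v16 = 1) {
  edges <- smp_edges()
  edges$p <- ifelse(edges$from <= 5, 0.5, 0.5)
  edges$p[edges$from == 1 & edges$to == 6] <- p16
  edges$p[edges$from == 1 & edges$to == 7] <- 1 - p16
  edges$sigma <- 2
  edges$v <- 1.2
  edges$sigma[edges$from == 1 & edges$to == 6] <- sigma16
  edges$v[edges$from == 1 & edges$to == 6] <- v16
  smp_model(edges)
}

# the default generating model with every covariate effect removed
null_true_model <- function() {
  m <- default_true_model()
  m$edges$beta <- rep(list(numeric(0)), nrow(m$edges))
  m
}

# trajectory table holding a single fitted edge 1 -> 6 with optional
# censoring (censored rows stay in state 1) and optional covariate columns
single_edge_traj <- function(durations, status = rep(TRUE, length(durations)),
                             covariates = NULL) {
  n <- length(durations)
  traj <- tibble::tibble(
    patient_id = sprintf("p%04d", seq_len(n)),
    chronic_state = 1L,
    stroke_state = ifelse(status, 6L, NA_integer_),
    dementia_state = NA_integer_,
    censored = TRUE,
    d_cs = durations,
    d_sd = NA_real_
  )
  if (!is.null(covariates)) traj <- dplyr::bind_cols(traj, covariates)
  traj
}

# diagnosis-event row builder
event_row <- function(patient_id, icd9, date, encounter = "clinic",
                      sex = "female", birth_year = 1945L, district = "D01") {
  tibble::tibble(patient_id = patient_id, sex = sex, birth_year = birth_year,
                 district = district, icd9 = icd9, date = as.Date(date),
                 encounter = encounter)
}

# a patient that passes every inclusion rule: hypertension 2001, three
# confirmed clinic ischemic-stroke visits from 2004, vascular dementia 2006
clean_patient_events <- function(id = "ok1") {
  dplyr::bind_rows(
    event_row(id, "4019", "2001-05-01"),
    event_row(id, "433", c("2004-02-01", "2004-03-01", "2004-04-01")),
    event_row(id, "2904", "2006-06-30")
  )
}
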