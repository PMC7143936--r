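#' Covariate-conditional sojourn-time prediction
#'
#' Under the proportional-hazards construction the conditional sojourn law
#' of an edge stays Weibull with scale `sigma * exp(-beta'z / v)` and
#' unchanged shape `v`; the predicted mean and standard deviation are its
#' moments. The all-zero (base group) vector returns the baseline edge
#' moments. Increasing `beta'z` (hazard up) strictly decreases the
#' predicted mean.
#'
#' @param model An `smp_model` with fitted parameters.
#' @param from,to State indices of a fitted edge.
#' @param z Covariate values: `NULL` (base group), a named vector, or a data
#'   frame with one row per subject whose columns cover the edge's
#'   coefficient names.
#' @return A tibble with columns `mean` and `sd` (years), one row per row
#'   of `z`.
#' @export
#' @examples
#' m <- smp_model(dplyr::mutate(smp_edges(), p = 0.5, sigma = 2, v = 1.2))
#' predict_sojourn(m, 1, 6)
predict_sojourn <- function(model, from, to, z = NULL) {
  e <- edge_params(model, from, to)
  beta <- e$beta[[1]]
  if (is.null(z)) {
    lp <- 0
  } else if (is.numeric(z)) {
    miss <- setdiff(names(beta), names(z))
    if (length(beta) > 0 && (is.null(names(z)) || length(miss) > 0)) {
      rlang::abort("`z` must be named and cover all edge coefficients")
    }
    lp <- if (length(beta)) sum(beta * z[names(beta)]) else 0
  } else {
    z <- as.data.frame(z)
    miss <- setdiff(names(beta), names(z))
    if (length(miss) > 0) {
      rlang::abort(paste0("`z` is missing covariate column(s): ",
                          paste(miss, collapse = ", ")))
    }
    lp <- if (length(beta)) {
      drop(as.matrix(z[names(beta)]) %*% beta)
    } else {
      rep(0, nrow(z))
    }
  }
  sojourn_moments(e$sigma * exp(-lp / e$v), e$v)
}

#' Adjusted R-squared of sojourn-time predictions
#'
#' `R^2 = 1 - SS_res / SS_tot` on observed versus predicted durations,
#' adjusted for the number of regressors:
#' `adjusted R^2 = 1 - (1 - R^2) * (n - 1) / (n - p - 1)`.
#'
#' @param observed Observed (uncensored) durations.
#' @param predicted Predicted conditional mean durations, same length.
#' @param p Number of regressors used by the prediction.
#' @return Adjusted R-squared (scalar). Always `<= R^2`, with equality iff
#'   `p = 0`.
#' @export
#' @examples
#' adjusted_r2(c(1, 2, 3), c(1.1, 1.9, 3.2), p = 1)
adjusted_r2 <- function(observed, predicted, p) {
  n <- length(observed)
  if (length(predicted) != n) {
    rlang::abort("`observed` and `predicted` must have the same length")
  }
  if (n <= p + 1) rlang::abort("need n > p + 1 observations")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    rlang::abort("`observed` is constant: R-squared is undefined")
  }
  r2 <- 1 - sum((observed - predicted)^2) / ss_tot
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Per-edge sojourn report for one fitted model
#'
#' For every fitted edge, predicts each uncensored subject's conditional
#' mean sojourn from their covariates and reports: the model-implied mean
#' (average of conditional means) and standard deviation (mixture over the
#' subjects' covariate distribution), and the adjusted R-squared of the
#' per-subject predictions against observed durations with `p` equal to the
#' number of covariates active on the edge. Censored spells are excluded
#' (their durations are lower bounds).
#'
#' @param fit An `smp_fit`.
#' @param trajectories The trajectory tibble the model was fitted to.
#' @return A tibble with columns `from`, `to`, `mean_years`, `sd_years`,
#'   `adj_r2`, `p`, `n`.
#' @export
evaluate_sojourn <- function(fit, trajectories) {
  spells <- traj_spells(trajectories)
  obs <- spells[!is.na(spells$to), ]
  edges <- fit$model$edges
  purrr::map_dfr(seq_len(nrow(edges)), function(k) {
    from <- edges$from[k]; to <- edges$to[k]
    rows <- obs[obs$from == from & obs$to == to, ]
    if (nrow(rows) == 0) return(NULL)
    mom <- predict_sojourn(fit$model, from, to, z = rows)
    n_cov <- length(edges$beta[[k]])
    adj <- if (nrow(rows) > n_cov + 1 && stats::sd(rows$duration) > 0) {
      adjusted_r2(rows$duration, mom$mean, n_cov)
    } else {
      NA_real_
    }
    tibble::tibble(
      from = from, to = to,
      mean_years = mean(mom$mean),
      sd_years = sqrt(mean(mom$sd^2) + stats::var(mom$mean) * (nrow(rows) - 1) / nrow(rows)),
      adj_r2 = adj, p = n_cov, n = nrow(rows)
    )
  })
}

#' Compare covariate models on sojourn-time prediction
#'
#' Runs [evaluate_sojourn()] for each fitted covariate model on the same
#' cohort and stacks the per-edge reports.
#'
#' @param fits Named list of `smp_fit` objects (e.g. the `fits` element of an
#'   [model_protocol()] result).
#' @param trajectories The common trajectory tibble.
#' @return A tibble with columns `model`, `from`, `to`, `mean_years`,
#'   `sd_years`, `adj_r2`, `p`, `n`.
#' @export
evaluate_models <- function(fits, trajectories) {
  dplyr::bind_rows(purrr::imap(fits, function(fit, name) {
    dplyr::mutate(evaluate_sojourn(fit, trajectories), model = name,
                  .before = 1)
  }))
}
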