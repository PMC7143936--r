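#' Weibull sojourn-time hazard
#'
#' The conditional sojourn time of each transition follows a Weibull law
#' `W(sigma, v)` with hazard `alpha(t) = v * (1/sigma)^v * t^(v-1)`. With
#' `v = 1` this is the constant exponential hazard `1/sigma`. For `v < 1`
#' the hazard diverges at `t = 0`; the value `Inf` is returned there so
#' integrals and plots can handle the singularity explicitly.
#'
#' @param t Duration in years, `>= 0` (vectorized).
#' @param sigma Weibull scale, years, `> 0`.
#' @param v Weibull shape, `> 0`.
#' @return Hazard rate per year, same length as `t`.
#' @export
#' @examples
#' sojourn_hazard(5, sigma = 2, v = 1)    # exponential: 1/2
#' sojourn_hazard(1, sigma = 1, v = 2)    # 2
sojourn_hazard <- function(t, sigma, v) {
  check_sojourn_args(t, sigma, v)
  out <- v * (1 / sigma)^v * t^(v - 1)
  # t = 0: limit is 0 for v > 1, 1/sigma for v = 1, +Inf for v < 1
  if (any(t == 0)) {
    out[t == 0] <- if (v > 1) 0 else if (v == 1) 1 / sigma else Inf
  }
  out
}

#' Weibull sojourn-time survival function
#'
#' `S(t) = exp(-(t/sigma)^v)`, the probability that the conditional sojourn
#' on an edge exceeds `t`.
#'
#' @inheritParams sojourn_hazard
#' @return Survival probability, same length as `t`.
#' @export
sojourn_survival <- function(t, sigma, v) {
  check_sojourn_args(t, sigma, v)
  exp(-(t / sigma)^v)
}

#' Weibull sojourn-time density
#'
#' `f(t) = alpha(t) * S(t)`; integrates to one over `[0, Inf)`.
#'
#' @inheritParams sojourn_hazard
#' @return Density per year, same length as `t`.
#' @export
sojourn_density <- function(t, sigma, v) {
  check_sojourn_args(t, sigma, v)
  sojourn_hazard(t, sigma, v) * sojourn_survival(t, sigma, v)
}

#' Mean and standard deviation of a Weibull sojourn
#'
#' Standard Weibull moments: `mean = sigma * gamma(1 + 1/v)` and
#' `var = sigma^2 * (gamma(1 + 2/v) - gamma(1 + 1/v)^2)`. For `v = 1`
#' (exponential) mean and sd both equal `sigma`.
#'
#' @param sigma Weibull scale, years, `> 0`.
#' @param v Weibull shape, `> 0`.
#' @return A tibble with columns `mean` and `sd` (years).
#' @export
#' @examples
#' sojourn_moments(sigma = 2, v = 1)
sojourn_moments <- function(sigma, v) {
  if (any(sigma <= 0) || any(v <= 0)) {
    rlang::abort("`sigma` and `v` must be strictly positive")
  }
  g1 <- gamma(1 + 1 / v)
  g2 <- gamma(1 + 2 / v)
  tibble::tibble(mean = sigma * g1, sd = sigma * sqrt(g2 - g1^2))
}

#' Covariate-adjusted sojourn hazard (proportional hazards)
#'
#' Cox-type effect on the conditional sojourn hazard of one transition:
#' `h(t, z) = alpha(t) * exp(beta' z)`. With the all-zero covariate vector
#' (the base group) this is the baseline Weibull hazard; the hazard ratio
#' between any two covariate vectors is constant in `t`.
#'
#' @inheritParams sojourn_hazard
#' @param beta Numeric coefficient vector.
#' @param z Binary covariate vector (0/1), same length as `beta`.
#' @return Hazard rate per year.
#' @export
#' @examples
#' covariate_hazard(1, sigma = 2, v = 1, beta = 0.214, z = 1)
covariate_hazard <- function(t, sigma, v, beta, z) {
  if (length(beta) != length(z)) {
    rlang::abort("`beta` and `z` must have the same length")
  }
  if (length(z) > 0 && !all(z %in% c(0, 1))) {
    rlang::abort("covariates `z` must be binary 0/1")
  }
  sojourn_hazard(t, sigma, v) * exp(sum(beta * z))
}

#' Relative risk of each covariate
#'
#' Exponentiates Cox coefficients into multiplicative hazard ratios against
#' the base group, `RR = exp(beta)`. Tabular reports conventionally round
#' these to two decimals.
#'
#' @param beta Numeric vector of Cox coefficients (names retained).
#' @return `exp(beta)`.
#' @export
#' @examples
#' relative_risk(c(gender = 0.214, age = -0.117))
relative_risk <- function(beta) {
  exp(beta)
}

#' Conditional transition-time distribution of one edge
#'
#' For an edge `(i, j)` of the model, returns the conditional cumulative
#' distribution `F_ij(t) = P(sojourn <= t | next state j)` together with the
#' joint kernel `Q_ij(t) = P_ij * F_ij(t)`; `Q_ij(Inf) = P_ij` and the
#' kernels of a state sum to one in the limit.
#'
#' @param model An `smp_model`.
#' @param from,to State indices of the transition.
#' @param t Duration in years, `>= 0` (vectorized).
#' @return A tibble with columns `t`, `cdf` (`F_ij`) and `q` (`Q_ij`).
#' @export
transition_cdf <- function(model, from, to, t) {
  e <- edge_params(model, from, to)
  if (any(t < 0)) rlang::abort("durations `t` must be nonnegative")
  cdf <- 1 - sojourn_survival(t, e$sigma, e$v)
  tibble::tibble(t = t, cdf = cdf, q = e$p * cdf)
}

#' Waiting-time survival of a state
#'
#' `S_i(t) = sum_j P_ij * (1 - F_ij(t))`: the probability of still being in
#' state `i` at duration `t`, mixing the conditional sojourn survivals over
#' the embedded chain. For an absorbing state (no outgoing edges) the
#' convention `S_i(t) = 1` for all `t` is used.
#'
#' @param model An `smp_model`.
#' @param state State index.
#' @param t Duration in years, `>= 0` (vectorized).
#' @return Survival probability, same length as `t`.
#' @export
state_waiting_survival <- function(model, state, t) {
  if (!state %in% model$states$state) {
    rlang::abort(paste0("unknown state ", state))
  }
  if (any(t < 0)) rlang::abort("durations `t` must be nonnegative")
  out_edges <- model$edges[model$edges$from == state, ]
  if (nrow(out_edges) == 0) return(rep(1, length(t)))
  s <- rep(0, length(t))
  for (k in seq_len(nrow(out_edges))) {
    s <- s + out_edges$p[k] *
      sojourn_survival(t, out_edges$sigma[k], out_edges$v[k])
  }
  s
}

#' Semi-Markov hazard between two states
#'
#' The hazard of moving to state `j` at duration `t` in state `i`:
#' `lambda_ij(t) = P_ij * f_ij(t) / S_i(t)` for a permitted edge, 0 for any
#' other off-diagonal pair, and the diagonal convention
#' `lambda_ii(t) = -sum_{j != i} lambda_ij(t)` so hazard-matrix rows sum to
#' zero.
#'
#' @param model An `smp_model`.
#' @param from,to State indices (`from` must be non-absorbing).
#' @param t Duration in years (vectorized).
#' @return Hazard rate per year, same length as `t`.
#' @seealso [smp_hazard_matrix()]
#' @export
smp_hazard <- function(model, from, to, t) {
  if (!from %in% model$edges$from) {
    rlang::abort(paste0("state ", from, " is absorbing or unknown; its semi-Markov hazard is undefined"))
  }
  s_i <- state_waiting_survival(model, from, t)
  if (any(s_i == 0)) {
    rlang::abort("waiting-time survival underflowed to 0: `t` is beyond the numerical support of state ",
                 call = NULL)
  }
  if (from == to) {
    out_edges <- model$edges[model$edges$from == from, ]
    tot <- rep(0, length(t))
    for (k in seq_len(nrow(out_edges))) {
      tot <- tot + out_edges$p[k] *
        sojourn_density(t, out_edges$sigma[k], out_edges$v[k]) / s_i
    }
    return(-tot)
  }
  hit <- model$edges$from == from & model$edges$to == to
  if (!any(hit)) return(rep(0, length(t)))
  e <- model$edges[hit, ]
  e$p * sojourn_density(t, e$sigma, e$v) / s_i
}

#' Full semi-Markov hazard matrix at one duration
#'
#' @param model An `smp_model`.
#' @param t Single duration in years.
#' @return A k x k matrix of `lambda_ij(t)`; rows of non-absorbing states sum
#'   to zero, rows of absorbing states are all zero.
#' @export
smp_hazard_matrix <- function(model, t) {
  if (length(t) != 1) rlang::abort("`t` must be a single duration")
  k <- nrow(model$states)
  lam <- matrix(0, k, k, dimnames = list(model$states$state, model$states$state))
  for (i in model$states$state) {
    if (!i %in% model$edges$from) next
    for (j in model$states$state) {
      lam[i, j] <- smp_hazard(model, i, j, t)
    }
  }
  lam
}

check_sojourn_args <- function(t, sigma, v) {
  if (length(sigma) != 1 || length(v) != 1 || !is.finite(sigma) || !is.finite(v)) {
    rlang::abort("`sigma` and `v` must be finite scalars")
  }
  if (sigma <= 0 || v <= 0) {
    rlang::abort("`sigma` and `v` must be strictly positive")
  }
  if (any(t < 0)) rlang::abort("durations `t` must be nonnegative")
  invisible(TRUE)
}
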