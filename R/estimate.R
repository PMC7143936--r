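#' Expand trajectories into at-risk spells
#'
#' One row per observed state occupancy: the chronic spell (chronic state to
#' stroke, or censored in the chronic state) and, where a stroke occurred,
#' the stroke spell (stroke state to dementia, or censored in the stroke
#' state). Covariate columns present on the trajectory table are carried
#' along.
#'
#' @param trajectories Trajectory tibble.
#' @return A tibble with columns `patient_id`, `from`, `to` (`NA` when
#'   censored), `duration` (years) plus any covariate columns.
#' @export
traj_spells <- function(trajectories) {
  trajectories <- tibble::as_tibble(trajectories)
  covs <- setdiff(names(trajectories),
                  c("patient_id", "sex", "birth_year", "district",
                    "chronic_state", "chronic_date", "stroke_state",
                    "stroke_date", "dementia_state", "dementia_date",
                    "censored", "censor_date", "d_cs", "d_sd",
                    "age_at_stroke", "ambiguous"))
  chronic <- trajectories %>%
    dplyr::transmute(.data$patient_id, from = .data$chronic_state,
                     to = .data$stroke_state, duration = .data$d_cs)
  stroke <- trajectories %>%
    dplyr::filter(!is.na(.data$stroke_state)) %>%
    dplyr::transmute(.data$patient_id, from = .data$stroke_state,
                     to = .data$dementia_state, duration = .data$d_sd)
  spells <- dplyr::bind_rows(
    dplyr::bind_cols(chronic, trajectories[covs]),
    dplyr::bind_cols(stroke,
                     trajectories[!is.na(trajectories$stroke_state), covs])
  )
  spells <- spells[!is.na(spells$duration) & spells$duration > 0, ]
  # canonical order: likelihood sums become invariant to input row order
  # and patient relabeling (floating-point addition is order sensitive)
  dplyr::arrange(spells, .data$from, .data$to, .data$duration,
                 dplyr::across(dplyr::all_of(covs)))
}

#' Estimate the embedded transition chain by counts
#'
#' `P_ij = N_ij / sum_j N_ij` over observed (uncensored) transitions.
#' States with outgoing edges but no observed exits get `NA` probabilities
#' and are flagged rather than silently zeroed.
#'
#' @param trajectories Trajectory tibble.
#' @param edges Permitted transitions (default [smp_edges()]).
#' @return A tibble with columns `from`, `to`, `n` and `p`; rows sum to one
#'   within each `from` state that has observed exits.
#' @export
#' @examples
#' cfg <- scenario_config(seed = 1, n_patients = 200)
#' estimate_embedded(simulate_trajectories(cfg))
estimate_embedded <- function(trajectories, edges = smp_edges()) {
  spells <- traj_spells(trajectories)
  obs <- spells[!is.na(spells$to), ]
  if (nrow(obs) == 0) rlang::abort("no observed transitions in `trajectories`")
  counts <- obs %>%
    dplyr::count(.data$from, .data$to, name = "n")
  out <- edges %>%
    dplyr::left_join(counts, by = c("from", "to")) %>%
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) %>%
    dplyr::group_by(.data$from) %>%
    dplyr::mutate(p = if (sum(.data$n) > 0) .data$n / sum(.data$n) else NA_real_) %>%
    dplyr::ungroup()
  occupied <- unique(out$from[is.na(out$p) & out$from %in% spells$from])
  if (length(occupied) > 0) {
    warning("state(s) ", paste(occupied, collapse = ", "),
            " are occupied but have no observed exits; their transition row is undefined",
            call. = FALSE)
  }
  out
}

#' Wald test of a Cox coefficient
#'
#' `statistic = (beta / se)^2` against a chi-square distribution with one
#' degree of freedom.
#'
#' @param beta Estimated coefficient(s).
#' @param se Standard error(s), strictly positive.
#' @return A tibble with columns `statistic` and `p_value`.
#' @export
#' @examples
#' wald_test(0.5, 0.1)
wald_test <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    rlang::abort("`se` must be strictly positive")
  }
  stat <- (beta / se)^2
  tibble::tibble(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

canonical_cov_map <- function(covariate_map, edges) {
  if (is.null(covariate_map)) {
    return(tibble::tibble(from = integer(0), to = integer(0),
                          covariate = character(0)))
  }
  if (is.character(covariate_map)) {
    return(tidyr::expand_grid(edges[c("from", "to")],
                              covariate = covariate_map))
  }
  tibble::as_tibble(covariate_map)[c("from", "to", "covariate")]
}

fit_control <- function(control = list()) {
  utils::modifyList(list(maxit = 1000, reltol = 1e-10, n_starts = 3,
                         start_seed = 101, low_count = 10), control)
}

#' Fit Weibull sojourn distributions with Cox covariate effects
#'
#' Maximum-likelihood fit of the parametric semi-Markov model: every
#' observed transition `i -> j` with duration `d` and covariates `z`
#' contributes `log P_ij + log f_ij(d | z)` and every spell censored in
#' state `i` contributes `log S_i(d | z)`, where `f_ij` is the Weibull
#' density under the edge-specific proportional-hazards effect and
#' `S_i(d | z) = sum_j P_ij S_ij(d | z)`. The embedded chain `P` is fixed at
#' its count estimate. Censored spells couple the outgoing edges of a state,
#' so optimization runs jointly per origin state on the unconstrained scale
#' `(log sigma, log v, beta)` with an analytic gradient, three fixed-seed
#' starts and observed-information standard errors.
#'
#' @param trajectories Trajectory tibble (with covariate columns when
#'   `covariate_map` names any).
#' @param covariate_map Covariates per edge: `NULL` (none), a character
#'   vector applied to every edge, or a data frame with columns `from`,
#'   `to`, `covariate`.
#' @param edges Permitted transitions (default [smp_edges()]).
#' @param embedded Optional precomputed [estimate_embedded()] table.
#' @param states State space (default [smp_states()]).
#' @param control List: `maxit` (1000), `reltol` (1e-10), `n_starts` (3),
#'   `start_seed` (101), `low_count` (10).
#' @return An object of class `smp_fit`: the fitted `smp_model` plus tidy
#'   parameter, standard-error and Wald-test tables; see [tidy.smp_fit()].
#' @export
fit_smp <- function(trajectories, covariate_map = NULL, edges = smp_edges(),
                    embedded = NULL, states = smp_states(),
                    control = list()) {
  ctl <- fit_control(control)
  cov_map <- canonical_cov_map(covariate_map, edges)
  missing_cov <- setdiff(unique(cov_map$covariate), names(trajectories))
  if (length(missing_cov) > 0) {
    rlang::abort(paste0("covariate column(s) not in `trajectories`: ",
                        paste(missing_cov, collapse = ", ")))
  }
  spells <- traj_spells(trajectories)
  if (is.null(embedded)) embedded <- estimate_embedded(trajectories, edges)

  results <- list()
  for (i in sort(unique(spells$from))) {
    sp_i <- spells[spells$from == i, ]
    emb_i <- embedded[embedded$from == i & embedded$n > 0, ]
    if (nrow(emb_i) == 0) next
    cov_i <- cov_map[cov_map$from == i, ]
    results[[as.character(i)]] <- fit_state_block(sp_i, emb_i, cov_i, ctl)
  }

  params <- dplyr::bind_rows(purrr::map(results, "params"))
  empty_coef <- tibble::tibble(
    from = integer(0), to = integer(0), covariate = character(0),
    estimate = double(0), std_error = double(0), statistic = double(0),
    p_value = double(0), relative_risk = double(0)
  )
  coefs <- dplyr::bind_rows(c(list(empty_coef), purrr::map(results, "coef")))
  loglik_sojourn <- sum(purrr::map_dbl(results, "loglik"))
  loglik_embedded <- sum(embedded$n[embedded$n > 0] *
                           log(embedded$p[embedded$n > 0]))

  fitted_edges <- embedded %>%
    dplyr::left_join(params, by = c("from", "to")) %>%
    dplyr::mutate(low_count = .data$n < ctl$low_count)
  beta_list <- purrr::map2(fitted_edges$from, fitted_edges$to, function(f, t) {
    rows <- coefs[coefs$from == f & coefs$to == t, ]
    stats::setNames(rows$estimate, rows$covariate)
  })
  model_edges <- fitted_edges %>%
    dplyr::filter(!is.na(.data$sigma)) %>%
    dplyr::select("from", "to", "p", "sigma", "v")
  model_edges$beta <- beta_list[!is.na(fitted_edges$sigma)]
  # renormalize in case undefined edges were dropped from the model object
  model_edges <- model_edges %>%
    dplyr::group_by(.data$from) %>%
    dplyr::mutate(p = .data$p / sum(.data$p)) %>%
    dplyr::ungroup()

  structure(list(
    model = smp_model(model_edges, states = states),
    embedded = embedded,
    params = fitted_edges,
    coef = coefs,
    covariate_map = cov_map,
    loglik = loglik_sojourn + loglik_embedded,
    n = nrow(trajectories),
    converged = all(purrr::map_lgl(results, "converged")),
    max_grad = max(purrr::map_dbl(results, ~ max(abs(.x$grad))))
  ), class = "smp_fit")
}

# joint likelihood block for one origin state ------------------------------

fit_state_block <- function(sp_i, emb_i, cov_i, ctl) {
  edges_to <- emb_i$to
  p_hat <- emb_i$p / sum(emb_i$p)
  m <- purrr::map(edges_to, ~ cov_i$covariate[cov_i$to == .x])
  obs <- sp_i[!is.na(sp_i$to), ]
  cens <- sp_i[is.na(sp_i$to), ]

  # design pieces per edge
  d_obs <- purrr::map(edges_to, ~ obs$duration[obs$to == .x])
  z_obs <- purrr::map2(edges_to, m, function(to, mv) {
    as.matrix(obs[obs$to == to, mv, drop = FALSE])
  })
  d_cens <- cens$duration
  z_cens <- purrr::map(m, ~ as.matrix(cens[, .x, drop = FALSE]))

  k <- length(edges_to)
  npar_edge <- 2 + lengths(m)
  offsets <- cumsum(c(0, npar_edge[-k]))

  unpack <- function(theta) {
    purrr::map(seq_len(k), function(e) {
      th <- theta[(offsets[e] + 1):(offsets[e] + npar_edge[e])]
      list(lsig = th[1], lv = th[2], beta = th[-(1:2)])
    })
  }

  negll <- function(theta) {
    pars <- unpack(theta)
    ll <- 0
    for (e in seq_len(k)) {
      p <- pars[[e]]; d <- d_obs[[e]]
      if (length(d) > 0) {
        v <- exp(p$lv)
        lp <- if (length(p$beta)) drop(z_obs[[e]] %*% p$beta) else 0
        logu <- v * (log(d) - p$lsig)
        w <- exp(pmin(logu + lp, 700))
        ll <- ll + sum(p$lv - v * p$lsig + (v - 1) * log(d) + lp - w)
      }
    }
    if (length(d_cens) > 0) {
      s <- rep(0, length(d_cens))
      for (e in seq_len(k)) {
        p <- pars[[e]]; v <- exp(p$lv)
        lp <- if (length(p$beta)) drop(z_cens[[e]] %*% p$beta) else 0
        w <- exp(pmin(v * (log(d_cens) - p$lsig) + lp, 700))
        s <- s + p_hat[e] * exp(-w)
      }
      ll <- ll + sum(log(pmax(s, 1e-300)))
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  grad_negll <- function(theta) {
    pars <- unpack(theta)
    g <- numeric(length(theta))
    cens_s <- NULL
    cens_terms <- vector("list", k)
    if (length(d_cens) > 0) {
      cens_s <- rep(0, length(d_cens))
      for (e in seq_len(k)) {
        p <- pars[[e]]; v <- exp(p$lv)
        lp <- if (length(p$beta)) drop(z_cens[[e]] %*% p$beta) else 0
        logd_ls <- log(d_cens) - p$lsig
        w <- exp(pmin(v * logd_ls + lp, 700))
        sv <- p_hat[e] * exp(-w)
        cens_s <- cens_s + sv
        cens_terms[[e]] <- list(sw = sv * w, v = v, logd_ls = logd_ls)
      }
      cens_s <- pmax(cens_s, 1e-300)
    }
    for (e in seq_len(k)) {
      p <- pars[[e]]; v <- exp(p$lv)
      idx <- offsets[e]
      d <- d_obs[[e]]
      g_lsig <- 0; g_lv <- 0; g_beta <- numeric(length(p$beta))
      if (length(d) > 0) {
        lp <- if (length(p$beta)) drop(z_obs[[e]] %*% p$beta) else 0
        logd_ls <- log(d) - p$lsig
        w <- exp(pmin(v * logd_ls + lp, 700))
        g_lsig <- sum(-v + v * w)
        g_lv <- sum(1 + v * logd_ls * (1 - w))
        if (length(p$beta)) g_beta <- drop(crossprod(z_obs[[e]], 1 - w))
      }
      if (length(d_cens) > 0) {
        ct <- cens_terms[[e]]
        ratio <- ct$sw / cens_s
        g_lsig <- g_lsig + sum(ratio * v)
        g_lv <- g_lv - sum(ratio * v * ct$logd_ls)
        if (length(p$beta)) {
          g_beta <- g_beta - drop(crossprod(z_cens[[e]], ratio))
        }
      }
      g[idx + 1] <- g_lsig
      g[idx + 2] <- g_lv
      if (length(p$beta)) g[idx + 2 + seq_along(p$beta)] <- g_beta
    }
    -g
  }

  # log-scale method-of-moments starting values per edge
  start0 <- unlist(purrr::map(seq_len(k), function(e) {
    d <- d_obs[[e]]
    if (length(d) >= 2 && stats::sd(log(d)) > 0) {
      shape <- min(max(1.2825 / stats::sd(log(d)), 0.2), 10)
      scale <- exp(mean(log(d)) + 0.5772 / shape)
    } else {
      shape <- 1
      scale <- max(mean(d), 0.1)
    }
    c(log(scale), log(shape), rep(0, length(m[[e]])))
  }))

  best <- NULL
  for (s in seq_len(ctl$n_starts)) {
    start <- if (s == 1) start0 else {
      withr::with_seed(ctl$start_seed + s,
                       start0 + stats::rnorm(length(start0), 0, 0.3))
    }
    opt <- tryCatch(
      stats::optim(start, negll, grad_negll, method = "BFGS",
                   control = list(maxit = ctl$maxit, reltol = ctl$reltol)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) rlang::abort("optimization failed for a state block")

  # Newton polish: BFGS stops on relative function change; a few damped
  # Newton steps drive the score to machine-level zero
  hess <- NULL
  for (it in 1:10) {
    g <- grad_negll(best$par)
    if (max(abs(g)) < 1e-7) break
    h <- tryCatch(stats::optimHess(best$par, negll, grad_negll),
                  error = function(e) NULL)
    step <- if (is.null(h)) NULL else tryCatch(solve(h, g), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    improved <- FALSE
    for (half in 1:6) {
      cand <- best$par - lambda * step
      val <- negll(cand)
      if (is.finite(val) && val <= best$value + 1e-12) {
        best$par <- cand; best$value <- val
        hess <- NULL
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }

  hess <- tryCatch(
    stats::optimHess(best$par, negll, grad_negll),
    error = function(e) NULL
  )
  se <- rep(NA_real_, length(best$par))
  if (!is.null(hess)) {
    vcov <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vcov)) {
      dg <- diag(vcov)
      se[dg > 0] <- sqrt(dg[dg > 0])
    }
  }

  pars <- unpack(best$par)
  ses <- unpack(se)
  params <- purrr::map_dfr(seq_len(k), function(e) {
    tibble::tibble(
      from = sp_i$from[1], to = edges_to[e],
      sigma = exp(pars[[e]]$lsig), v = exp(pars[[e]]$lv),
      sigma_se = exp(pars[[e]]$lsig) * ses[[e]]$lsig,
      v_se = exp(pars[[e]]$lv) * ses[[e]]$lv,
      n_obs = length(d_obs[[e]])
    )
  })
  coef <- purrr::map_dfr(seq_len(k), function(e) {
    if (length(m[[e]]) == 0) return(NULL)
    est <- pars[[e]]$beta
    s <- ses[[e]]$beta
    stat <- (est / s)^2
    tibble::tibble(
      from = sp_i$from[1], to = edges_to[e], covariate = m[[e]],
      estimate = est, std_error = s, statistic = stat,
      p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
      relative_risk = exp(est)
    )
  })
  list(params = params, coef = coef, loglik = -best$value,
       converged = best$convergence == 0,
       grad = grad_negll(best$par), n_cens = length(d_cens))
}

#' @export
print.smp_fit <- function(x, ...) {
  cat("<smp_fit> ", nrow(x$params), " edges, n = ", x$n,
      ", log-likelihood = ", format(x$loglik, digits = 8),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  print(tidy(x), n = 20)
  invisible(x)
}

#' Tidy a fitted semi-Markov model
#'
#' One row per parameter: Weibull `sigma` and `v` per edge plus one row per
#' Cox coefficient with its Wald test and relative risk.
#'
#' @param x An `smp_fit`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`, `relative_risk`.
#' @export
tidy.smp_fit <- function(x, ...) {
  sojourn <- x$params %>%
    dplyr::filter(!is.na(.data$sigma)) %>%
    dplyr::select("from", "to", "sigma", "v", "sigma_se", "v_se") %>%
    tidyr::pivot_longer(c("sigma", "v"), names_to = "term",
                        values_to = "estimate") %>%
    dplyr::mutate(std_error = ifelse(.data$term == "sigma",
                                     .data$sigma_se, .data$v_se),
                  statistic = NA_real_, p_value = NA_real_,
                  relative_risk = NA_real_) %>%
    dplyr::select("from", "to", "term", "estimate", "std_error",
                  "statistic", "p_value", "relative_risk")
  coefs <- x$coef %>%
    dplyr::rename(term = "covariate")
  dplyr::bind_rows(sojourn, coefs) %>%
    dplyr::arrange(.data$from, .data$to)
}

#' One-row summary of a fitted semi-Markov model
#' @param x An `smp_fit`.
#' @param ... Unused.
#' @return A tibble: `n`, `n_edges`, `n_coef`, `loglik`, `converged`.
#' @export
glance.smp_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_edges = sum(!is.na(x$params$sigma)),
    n_coef = nrow(x$coef),
    loglik = x$loglik,
    converged = x$converged
  )
}
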