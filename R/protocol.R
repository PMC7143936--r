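#' Enumerate the univariate covariate-test grid
#'
#' One univariate Wald test per (edge, covariate) pair. With the default
#' 14-edge structure (10 chronic-to-stroke plus 4 stroke-to-dementia
#' transitions) and 7 covariates the screen comprises 98 tests.
#'
#' @param edges Transition tibble (default [smp_edges()]).
#' @param covariates Character vector of covariate names.
#' @return A tibble with columns `from`, `to`, `covariate`.
#' @export
#' @examples
#' nrow(univariate_grid(smp_edges(), covariate_names()))  # 98
univariate_grid <- function(edges = smp_edges(), covariates = covariate_names()) {
  tidyr::expand_grid(edges[c("from", "to")], covariate = covariates)
}

#' Univariate screening then multivariate covariate models
#'
#' Reproduces the two-stage inference protocol. Stage 1 fits every covariate
#' of every group alone on every edge and records its Wald p-value. Stage 2
#' refits each edge with all covariates whose univariate p-value fell below
#' `alpha`, once per covariate group: model A (gender, age and the five
#' environmental indicators), model B (gender, age and
#' medication/rehabilitation indicators), and model C starting from the
#' union of A's and B's selections. Edges with no selected covariate are
#' reported without covariate rows.
#'
#' @param trajectories Trajectory tibble carrying all covariate columns named
#'   by `groups`.
#' @param groups Named list of covariate-name vectors for models `A` and `B`
#'   (model `C` is derived as their union). Defaults to model A =
#'   [covariate_names()] only, in which case only model A is fitted.
#' @param alpha Wald significance threshold (default 0.05).
#' @param edges Transition structure (default [smp_edges()]).
#' @param ... Passed to [fit_smp()].
#' @return An object of class `smp_protocol`: list with `univariate` (the
#'   stage-1 test table), `selection` (per model/edge selected covariates),
#'   `fits` (named list of `smp_fit`) and `alpha`.
#' @export
model_protocol <- function(trajectories, groups = list(A = covariate_names()),
                           alpha = 0.05, edges = smp_edges(), ...) {
  if (is.null(names(groups)) || any(names(groups) == "")) {
    rlang::abort("`groups` must be a named list of covariate vectors")
  }
  derive_c <- all(c("A", "B") %in% names(groups)) && !"C" %in% names(groups)

  embedded <- estimate_embedded(trajectories, edges)
  spells <- traj_spells(trajectories)
  ctl <- fit_control(list(...)$control %||% list())

  # stage 1: univariate fits, deduplicated across groups; only the state
  # block containing the tested edge needs refitting
  pairs <- dplyr::distinct(
    dplyr::bind_rows(purrr::map(groups, ~ univariate_grid(edges, .x)))
  )
  uni <- purrr::pmap_dfr(pairs, function(from, to, covariate) {
    sp_i <- spells[spells$from == from, ]
    emb_i <- embedded[embedded$from == from & embedded$n > 0, ]
    na_row <- tibble::tibble(from = from, to = to, covariate = covariate,
                             estimate = NA_real_, std_error = NA_real_,
                             p_value = NA_real_)
    if (!to %in% emb_i$to) return(na_row)
    cov_i <- tibble::tibble(from = from, to = to, covariate = covariate)
    block <- fit_state_block(sp_i, emb_i, cov_i, ctl)
    row <- block$coef[block$coef$to == to, ]
    if (nrow(row) == 0) return(na_row)
    row[c("from", "to", "covariate", "estimate", "std_error", "p_value")]
  })

  selection_for <- function(covs) {
    uni %>%
      dplyr::filter(.data$covariate %in% covs,
                    !is.na(.data$p_value), .data$p_value < alpha) %>%
      dplyr::select("from", "to", "covariate")
  }
  selections <- purrr::map(groups, selection_for)
  if (derive_c) {
    selections$C <- dplyr::distinct(
      dplyr::bind_rows(selections[["A"]], selections[["B"]])
    )
  }

  fits <- purrr::map(selections, function(sel) {
    fit_smp(trajectories, covariate_map = sel, edges = edges,
            embedded = embedded, ...)
  })

  selection <- dplyr::bind_rows(
    purrr::imap(selections, ~ dplyr::mutate(.x, model = .y, .before = 1))
  )
  structure(list(univariate = uni, selection = selection, fits = fits,
                 alpha = alpha),
            class = "smp_protocol")
}

#' @export
print.smp_protocol <- function(x, ...) {
  cat("<smp_protocol> ", nrow(x$univariate), " univariate tests, models: ",
      paste(names(x$fits), collapse = ", "), "\n", sep = "")
  print(protocol_report(x), n = 15)
  invisible(x)
}

#' Multivariate covariate-model report
#'
#' Tabulates the multivariate fits of an [model_protocol()] result in the
#' conventional layout: one row per model, covariate and transition, with
#' the coefficient, the relative risk `exp(beta)` rounded to two decimals
#' and the Wald p-value.
#'
#' @param protocol An `smp_protocol`.
#' @return A tibble with columns `model`, `covariate`, `transition`, `beta`,
#'   `relative_risk`, `p_value`.
#' @export
protocol_report <- function(protocol) {
  dplyr::bind_rows(purrr::imap(protocol$fits, function(fit, name) {
    if (nrow(fit$coef) == 0) return(NULL)
    fit$coef %>%
      dplyr::transmute(
        model = name,
        covariate = .data$covariate,
        transition = paste0(.data$from, "->", .data$to),
        beta = .data$estimate,
        relative_risk = round(relative_risk(.data$estimate), 2),
        p_value = .data$p_value
      )
  }))
}

#' @rdname protocol_report
#' @param x An `smp_protocol`.
#' @param ... Unused.
#' @export
tidy.smp_protocol <- function(x, ...) {
  protocol_report(x)
}
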