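#' State space of the three-layer progression model
#'
#' The progression model has nine states in three layers: five chronic-disease
#' entry states, two stroke states (hemorrhagic, ischemic) and two absorbing
#' dementia states (vascular, non-vascular). Patients enter in a chronic
#' state, may transition to a stroke state and from there to a dementia state.
#'
#' @return A tibble with columns `state` (integer index 1-9), `layer`
#'   (`"chronic"`, `"stroke"` or `"dementia"`) and `label`.
#' @export
#' @examples
#' smp_states()
smp_states <- function() {
  tibble::tibble(
    state = 1:9,
    layer = c(rep("chronic", 5), rep("stroke", 2), rep("dementia", 2)),
    label = c(
      "Diagnosed only with hypertension or with one metabolic risk factor after having hypertension",
      "Diagnosed only with diabetes mellitus",
      "Diagnosed only with hyperlipidemia or with one metabolic risk factor after having hyperlipidemia",
      "Diagnosed with more than four metabolic risk factors after having other 8 chronic diseases",
      "Diagnosed other than 11 types of chronic disease or without chronic",
      "Hemorrhagic stroke",
      "Ischemic stroke",
      "Vascular dementia",
      "Non-vascular dementia"
    )
  )
}

#' Permitted transitions of the layered progression model
#'
#' Every chronic state can move to either stroke state and every stroke state
#' to either dementia state, giving the default 14-edge structure
#' (5 x 2 + 2 x 2). Dementia states are absorbing.
#'
#' @param states State-space tibble as returned by [smp_states()].
#' @return A tibble with columns `from` and `to` (integer state indices).
#' @export
#' @examples
#' smp_edges()
smp_edges <- function(states = smp_states()) {
  chronic <- states$state[states$layer == "chronic"]
  stroke <- states$state[states$layer == "stroke"]
  dementia <- states$state[states$layer == "dementia"]
  dplyr::bind_rows(
    tidyr::expand_grid(from = chronic, to = stroke),
    tidyr::expand_grid(from = stroke, to = dementia)
  )
}

state_layer <- function(state, states = smp_states()) {
  states$layer[match(state, states$state)]
}

#' Construct a parametric semi-Markov model
#'
#' Bundles the embedded transition chain `P_ij`, per-edge Weibull sojourn
#' distributions `W(sigma_ij, v_ij)` and optional per-edge Cox
#' proportional-hazards coefficient vectors `beta_ij` into a single model
#' object. Covariates act multiplicatively on the conditional sojourn hazard
#' of each edge (`alpha_ij(t) * exp(beta' z)`); the embedded chain is
#' covariate-free.
#'
#' @param edges A data frame with one row per permitted transition and columns
#'   `from`, `to`, `p` (embedded transition probability), `sigma` (Weibull
#'   scale, years), `v` (Weibull shape) and optionally `beta`, a list-column
#'   of named numeric coefficient vectors (may be `NULL`/empty per edge).
#' @param states State-space tibble; defaults to the nine-state space of
#'   [smp_states()].
#' @return An object of class `smp_model`.
#' @export
#' @examples
#' edges <- dplyr::mutate(smp_edges(), p = ifelse(from <= 5, 0.5, 0.5),
#'                        sigma = 2.5, v = 1.2)
#' m <- smp_model(edges)
#' m
smp_model <- function(edges, states = smp_states()) {
  edges <- tibble::as_tibble(edges)
  required <- c("from", "to", "p", "sigma", "v")
  missing <- setdiff(required, names(edges))
  if (length(missing) > 0) {
    rlang::abort(paste0("`edges` is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (!"beta" %in% names(edges)) {
    edges$beta <- rep(list(numeric(0)), nrow(edges))
  }
  edges$beta <- purrr::map(edges$beta, function(b) {
    if (is.null(b) || length(b) == 0) return(numeric(0))
    b <- unlist(b)
    if (is.null(names(b)) || any(names(b) == "")) {
      rlang::abort("every `beta` coefficient must be named after its covariate")
    }
    b
  })
  x <- structure(list(states = tibble::as_tibble(states),
                      edges = edges[c("from", "to", "p", "sigma", "v", "beta")]),
                 class = "smp_model")
  validate_smp_model(x)
  x
}

#' Validate a semi-Markov model object
#'
#' Checks the structural invariants: exactly one row per edge, all edges step
#' forward by exactly one layer, strictly positive Weibull parameters,
#' probabilities in \[0, 1\] and outgoing probabilities summing to one
#' (tolerance 1e-9) for every state with outgoing edges.
#'
#' @param x An `smp_model`.
#' @return `x`, invisibly, or an error describing the violated invariant.
#' @export
validate_smp_model <- function(x) {
  states <- x$states
  edges <- x$edges
  if (anyDuplicated(edges[c("from", "to")]) > 0) {
    rlang::abort("duplicate edges in model")
  }
  layer_rank <- c(chronic = 1, stroke = 2, dementia = 3)
  lf <- layer_rank[state_layer(edges$from, states)]
  lt <- layer_rank[state_layer(edges$to, states)]
  if (anyNA(lf) || anyNA(lt)) rlang::abort("edge references unknown state")
  if (any(lt - lf != 1)) {
    rlang::abort("every edge must step forward by exactly one layer")
  }
  if (any(!is.finite(edges$sigma)) || any(edges$sigma <= 0)) {
    rlang::abort("Weibull scale `sigma` must be strictly positive")
  }
  if (any(!is.finite(edges$v)) || any(edges$v <= 0)) {
    rlang::abort("Weibull shape `v` must be strictly positive")
  }
  if (any(edges$p < 0 | edges$p > 1)) {
    rlang::abort("transition probabilities must lie in [0, 1]")
  }
  sums <- tapply(edges$p, edges$from, sum)
  bad <- names(sums)[abs(sums - 1) > 1e-9]
  if (length(bad) > 0) {
    rlang::abort(paste0("outgoing transition probabilities of state(s) ",
                        paste(bad, collapse = ", "), " do not sum to 1"))
  }
  invisible(x)
}

#' @export
print.smp_model <- function(x, ...) {
  cat("<smp_model> ", nrow(x$states), " states, ", nrow(x$edges),
      " transitions\n", sep = "")
  n_beta <- sum(lengths(x$edges$beta) > 0)
  if (n_beta > 0) cat("covariate effects on ", n_beta, " edge(s)\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' Look up the parameters of one edge
#' @param model An `smp_model`.
#' @param from,to State indices of the transition.
#' @return One-row tibble with the edge's parameters.
#' @keywords internal
edge_params <- function(model, from, to) {
  row <- model$edges[model$edges$from == from & model$edges$to == to, ]
  if (nrow(row) == 0) {
    rlang::abort(paste0("transition ", from, "->", to, " is not in the model"))
  }
  row
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-edge parameters of a semi-Markov model
#'
#' @param x An `smp_model`.
#' @param ... Unused.
#' @return A tibble with one row per edge: `from`, `to`, `p`, `sigma`, `v`
#'   and `n_covariates`.
#' @export
tidy.smp_model <- function(x, ...) {
  dplyr::mutate(
    x$edges[c("from", "to", "p", "sigma", "v")],
    n_covariates = lengths(x$edges$beta)
  )
}

#' One-line model summary
#' @param x An `smp_model`.
#' @param ... Unused.
#' @return A one-row tibble: `n_states`, `n_edges`, `n_absorbing`,
#'   `n_covariate_edges`.
#' @export
glance.smp_model <- function(x, ...) {
  tibble::tibble(
    n_states = nrow(x$states),
    n_edges = nrow(x$edges),
    n_absorbing = sum(!x$states$state %in% x$edges$from),
    n_covariate_edges = sum(lengths(x$edges$beta) > 0)
  )
}

#' Write a semi-Markov model to JSON
#'
#' The on-disk representation keeps full double precision so that a
#' write/read round trip is lossless.
#'
#' @param model An `smp_model`.
#' @param path File path to write to.
#' @return `path`, invisibly.
#' @export
write_smp_model <- function(model, path) {
  edges <- purrr::pmap(model$edges, function(from, to, p, sigma, v, beta) {
    list(from = from, to = to, p = p, sigma = sigma, v = v,
         beta = if (length(beta) == 0) stats::setNames(list(), character(0)) else as.list(beta))
  })
  states <- purrr::pmap(model$states, function(state, layer, label) {
    list(index = state, layer = layer, label = label)
  })
  json <- jsonlite::toJSON(list(states = states, edges = edges),
                           auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a semi-Markov model from JSON
#'
#' @param path File path written by [write_smp_model()].
#' @return An `smp_model`.
#' @export
read_smp_model <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  states <- purrr::map_dfr(raw$states, function(s) {
    tibble::tibble(state = as.integer(s$index), layer = s$layer, label = s$label)
  })
  edges <- purrr::map_dfr(raw$edges, function(e) {
    tibble::tibble(from = as.integer(e$from), to = as.integer(e$to),
                   p = e$p, sigma = e$sigma, v = e$v,
                   beta = list(unlist(e$beta) %||% numeric(0)))
  })
  edges$beta <- purrr::map(edges$beta, function(b) {
    if (length(b) == 0) numeric(0) else b
  })
  smp_model(edges, states = states)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
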