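#' Plot the per-edge sojourn distributions of a model
#'
#' Draws the baseline sojourn density, hazard or survival curve of every
#' edge, facetted by origin state.
#'
#' @param object An `smp_model`.
#' @param fun Which curve to draw: `"density"`, `"hazard"` or `"survival"`.
#' @param t_max Upper end of the duration grid in years (default: 3 times
#'   the largest edge mean).
#' @param n Grid resolution.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.smp_model <- function(object, fun = c("density", "hazard", "survival"),
                               t_max = NULL, n = 200, ...) {
  fun <- match.arg(fun)
  f <- switch(fun, density = sojourn_density, hazard = sojourn_hazard,
              survival = sojourn_survival)
  if (is.null(t_max)) {
    mom <- sojourn_moments(object$edges$sigma, object$edges$v)
    t_max <- 3 * max(mom$mean)
  }
  grid <- seq(t_max / n, t_max, length.out = n)
  df <- purrr::pmap_dfr(object$edges[c("from", "to", "sigma", "v")],
                        function(from, to, sigma, v) {
                          tibble::tibble(from = from, to = to, t = grid,
                                         y = f(grid, sigma, v))
                        })
  df$edge <- paste0(df$from, "→", df$to)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$y,
                                   colour = .data$edge)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~from, scales = "free", labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sojourn time (years)", y = fun, colour = "transition") +
    ggplot2::theme_minimal()
}

#' Forest plot of fitted relative risks
#'
#' Shows `exp(beta)` with Wald 95% confidence intervals for every covariate
#' on every edge of a fitted model.
#'
#' @param object An `smp_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.smp_fit <- function(object, ...) {
  df <- object$coef
  if (nrow(df) == 0) {
    rlang::abort("the fit has no covariate effects to plot")
  }
  df <- df %>%
    dplyr::mutate(
      edge = paste0(.data$from, "→", .data$to),
      rr = exp(.data$estimate),
      lo = exp(.data$estimate - 1.96 * .data$std_error),
      hi = exp(.data$estimate + 1.96 * .data$std_error)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rr, y = .data$covariate)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::facet_wrap(~edge) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "relative risk (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
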