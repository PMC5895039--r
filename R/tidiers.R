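# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @describeIn fit_probit_lasso Tidy the fitted weights (one row per term).
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.probit_fit <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef),
         penalized = names(x$coef) != "(Intercept)")
}

#' @describeIn fit_probit_lasso One-row fit summary.
#' @export
glance.probit_fit <- function(x, ...) {
  tibble(lambda = x$lambda, nll = x$nll, n_train = x$n_train,
         iterations = x$iterations, converged = x$converged,
         n_zero = sum(x$coef[-1] == 0))
}

#' @describeIn fit_poisson_glm Tidy the fitted weights.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.spike_fit <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @describeIn fit_poisson_glm One-row fit summary.
#' @export
glance.spike_fit <- function(x, ...) {
  tibble(n_train = x$n_train, converged = x$converged,
         gp_tau = if (is.null(x$gp)) NA_real_ else x$gp$tau,
         gp_amplitude = if (is.null(x$gp)) NA_real_ else x$gp$amplitude,
         gp_latent_sd = if (is.null(x$g)) NA_real_ else sd(x$g))
}

#' @describeIn ar_params Tidy the parameters of a fitted AR model.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.ar_fit <- function(x, ...) {
  p <- x$params
  tibble(
    term = c("alpha", "beta",
             if (p$model %in% c("CM1", "ICM2")) "omega" else "gamma",
             "sigma1", "sigma2", "mu"),
    estimate = c(p$alpha, p$beta, p$coupling, p$sigma1, p$sigma2, p$mu)
  )
}

#' @describeIn ar_params One-row summary of a fitted AR model.
#' @export
glance.ar_fit <- function(x, ...) {
  tibble(model = x$model, objective = x$objective, converged = x$converged,
         n_sim = x$n_sim)
}

#' Plot cumulative prediction increments
#'
#' Bar chart of the per-covariate increments (choice correlation or Pearson
#' cc) from [cumulative_cpp()] / [cumulative_cc()], marking significant
#' increments.
#'
#' @param object A `cp_cumulative` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cp_cumulative <- function(object, ...) {
  df <- as_tibble(object)
  df$covariate <- factor(df$covariate, levels = df$covariate)
  df$significant <- df$p_value < 0.05
  ggplot2::ggplot(df, ggplot2::aes(x = .data$covariate, y = .data$mean_increment,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "covariate added", y = "increment",
                  fill = "p < 0.05") +
    ggplot2::theme_minimal()
}

#' Plot raw versus semipartial choice probabilities
#'
#' Scatter of each unit's semipartial CP (history regressed out) against its
#' raw CP, with the identity line; points near the diagonal indicate CPs
#' unaffected by history.
#'
#' @param object A `cp_results` tibble from [cp_summary()].
#' @param which Which semipartial variant to plot against the raw CP.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cp_results <- function(object, which = c("history", "choice", "full"),
                                ...) {
  which <- match.arg(which)
  ycol <- paste0("semipartial_cp_", which)
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$raw_cp, y = .data[[ycol]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal(xlim = c(0.2, 0.9), ylim = c(0.2, 0.9)) +
    ggplot2::labs(x = "raw CP", y = sprintf("semipartial CP (%s removed)", which)) +
    ggplot2::theme_minimal()
}

#' Plot a power-analysis result
#'
#' Histogram of the population-mean semipartial CP across repetitions, with
#' the 0.5 reference.
#'
#' @param object A `cp_power` tibble from [power_analysis()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cp_power <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$mean_semi_cp)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "mean semipartial CP per repetition", y = "repetitions") +
    ggplot2::theme_minimal()
}

#' Plot fitted psychometric functions
#'
#' Cumulative-Gaussian curves for each fitted group of [fit_psychometric()],
#' averaged across sessions.
#'
#' @param object The tibble returned by [fit_psychometric()].
#' @param signal_range Range of signed signal strengths to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_psychometric <- function(object, signal_range = c(-0.3, 0.3), ...) {
  grid <- seq(signal_range[1], signal_range[2], length.out = 101)
  curves <- object %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(mu = mean(.data$mu), sigma = mean(.data$sigma),
                     .groups = "drop") %>%
    dplyr::reframe(signal = grid,
                   p = pnorm((grid - .data$mu) / .data$sigma),
                   .by = "group")
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$signal, y = .data$p,
                                       colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3, colour = "grey70") +
    ggplot2::labs(x = "signal strength (preferred +)",
                  y = "P(preferred choice)") +
    ggplot2::theme_minimal()
}
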