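#' Posterior histogram of the Homeric age
#'
#' Frequency histogram of the posterior draws for one node age, on the BCE
#' calendar scale by default, with the posterior mean marked — the standard
#' way to display the dating result.
#'
#' @param object A `homer_chain` from [run_mcmc()].
#' @param parameter Which age to plot; default `"age_homer"`.
#' @param bce Plot calendar dates BCE (default) rather than years BP.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.homer_chain <- function(object, parameter = "age_homer",
                                 bce = TRUE, bins = 60, ...) {
  ref <- attr(object, "priors")$reference_year %||% 2000
  x <- object[[parameter]]
  if (bce) x <- x - ref
  lab <- if (bce) "Date (BCE)" else "Age (years BP)"
  df <- tibble::tibble(x = x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = mean(x), colour = "white",
                        linewidth = 1.2) +
    ggplot2::labs(x = lab, y = "Posterior frequency",
                  title = sprintf("Posterior of %s (mean %.0f)",
                                  parameter, mean(x))) +
    ggplot2::theme_minimal()
}

#' Plot the composite log-likelihood surface over the Homeric age
#'
#' Evaluates [loglik_grid()] and plots the resulting surface; a quick visual
#' check that the likelihood is unimodal in the Homeric age and where its
#' maximum falls relative to the posterior.
#'
#' @param table A filtered cognacy tibble.
#' @param age_hittite,age_root Fixed ages for the other nodes, years BP.
#' @param from,to,by Grid over the Homeric age, years BP.
#' @return A ggplot object.
#' @export
plot_likelihood_surface <- function(table, age_hittite = 3400, age_root = 9000,
                                    from = 100, to = 6000, by = 50) {
  grid <- loglik_grid(table, seq(from, to, by = by), age_hittite, age_root)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$age_homer, y = .data$loglik)) +
    ggplot2::geom_line(colour = "grey25") +
    ggplot2::geom_vline(xintercept = grid$age_homer[which.max(grid$loglik)],
                        linetype = 2) +
    ggplot2::labs(x = "Homeric age (years BP)",
                  y = "Composite log-likelihood") +
    ggplot2::theme_minimal()
}
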