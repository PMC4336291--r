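#' Plot a reliability envelope
#'
#' Min-max ribbon over perturbation replicates with the mean as a line and
#' the unperturbed evaluation as points, faceted by metric; multiple
#' predictors (row-bound envelopes) are distinguished by colour. Mirrors the
#' usual presentation of perturbation benchmarks for critical-residue
#' predictors.
#'
#' @param object A `"reliability_envelope"` (or several combined with
#'   [dplyr::bind_rows()]).
#' @param metrics Metrics to facet over.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reliability_envelope <- function(object,
                                          metrics = c("sensitivity",
                                                      "specificity", "mcc"),
                                          ...) {
  sm <- tidy.reliability_envelope(object) |>
    dplyr::filter(.data$metric %in% metrics)
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$threshold,
                                   colour = .data$predictor,
                                   fill = .data$predictor)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$unperturbed), size = 0.8) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "top fraction of ranked residues called critical",
                  y = "metric value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot ISPA calls against the error budget
#'
#' Minority-phenotype proportion versus per-variant read depth for every
#' both-phenotype variant, coloured by the BiM call, with the expected error
#' rate mu and the per-depth one-sided rejection boundary drawn as reference
#' lines.
#'
#' @param result An `"ispa_result"` from [classify_table()].
#' @param alpha Test level used for the boundary line (read from the result
#'   summary by default).
#' @return A ggplot object.
#' @export
plot_ispa_calls <- function(result, alpha = NULL) {
  stopifnot(inherits(result, "ispa_result"))
  if (nrow(result$calls) == 0L) {
    stop("no both-phenotype variants to plot", call. = FALSE)
  }
  mu <- result$summary$mu
  if (is.null(alpha)) alpha <- result$summary$alpha
  crit <- stats::qnorm(1 - alpha)
  calls <- dplyr::mutate(result$calls,
                         minority_prop = .data$minority_count / .data$total)
  grid <- tibble::tibble(
    total = seq(min(calls$total), max(calls$total), length.out = 200),
  )
  grid$boundary <- mu + crit * sqrt(mu * (1 - mu) / grid$total)
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$total,
                                      y = .data$minority_prop)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$bim_call), alpha = 0.7) +
    ggplot2::geom_hline(yintercept = mu, linetype = "dashed") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$boundary),
                       linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "reads per variant (both pools)",
                  y = "minority-phenotype proportion",
                  colour = "BiM call") +
    ggplot2::theme_minimal()
}
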