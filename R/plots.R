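#' Scree plot of ranked triad distances
#'
#' Ranked mean taxonomic distances with, when a fit is supplied, the
#' broken-stick fit overlaid and the change-point marked.
#'
#' @param object An `ms_scree`.
#' @param fit Optional `segmented_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ms_scree
#' @export
autoplot.ms_scree <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$rank, y = .data$mean_distance)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::labs(x = "Triad rank", y = "Mean taxonomic distance") +
    ggplot2::theme_minimal()
  if (!is.null(fit) && !fit$degenerate) {
    fitted_df <- tibble(rank = fit$x, fitted = predict(fit))
    p <- p +
      ggplot2::geom_line(data = fitted_df,
                         ggplot2::aes(y = .data$fitted), colour = "red") +
      ggplot2::geom_vline(xintercept = fit$change_point,
                          linetype = "dashed", colour = "red")
  }
  p
}

#' @rdname autoplot.ms_scree
#' @param scree An `ms_scree`.
#' @export
plot_scree <- function(scree, fit = NULL) autoplot(scree, fit = fit)

#' Kaplan-Meier curve plot
#'
#' Step survival curve with the pointwise confidence band.
#'
#' @param object A `km_estimate`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot km_estimate
#' @export
autoplot.km_estimate <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(time = 0, survival = 1, ci_lower = NA_real_, ci_upper = NA_real_),
    as_tibble(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = .data$ci_lower),
                       linetype = "dotted", na.rm = TRUE) +
    ggplot2::geom_step(ggplot2::aes(y = .data$ci_upper),
                       linetype = "dotted", na.rm = TRUE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Days since admission", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.km_estimate
#' @param km A `km_estimate`.
#' @export
plot_km <- function(km) autoplot(km)

#' Enrichment chi-square bar plot
#'
#' Per-variable segment-enrichment statistics coloured by pattern class.
#'
#' @param object An `ms_enrichment`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ms_enrichment
#' @export
autoplot.ms_enrichment <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::mutate(variable = factor(.data$variable,
                                    levels = rev(.data$variable)),
                  pattern = factor(.data$pattern, levels = 1:3,
                                   labels = c("1: random",
                                              "2: segment-1 predominant",
                                              "3: segment-2 overrepresented")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chi2, y = .data$variable,
                                   fill = .data$pattern)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Chi-square", y = NULL, fill = "Pattern") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ms_enrichment
#' @param enrichment An `ms_enrichment`.
#' @export
plot_enrichment <- function(enrichment) autoplot(enrichment)
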