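#' Plot the distribution of the nine accessibility measures
#'
#' Histograms of each measure column, free scales, one facet per measure.
#'
#' @param object An `access_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.access_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as.data.frame(object)[intersect(measure_names(), names(object))],
    dplyr::everything(), names_to = "measure", values_to = "value")
  long$measure <- factor(long$measure, levels = measure_names())
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey30") +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::labs(x = NULL, y = "block groups",
                  title = "Distribution of accessibility measures")
}

#' Heatmap of pairwise weighted kappa between measures
#'
#' @param object An `agreement_matrix`.
#' @param what `"kappa"` (default) or `"rho"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_matrix <- function(object, what = c("kappa", "rho"), ...) {
  what <- match.arg(what)
  m <- object[[what]]
  long <- tibble::as_tibble(m, rownames = "measure_a") |>
    tidyr::pivot_longer(-"measure_a", names_to = "measure_b",
                        values_to = "value")
  long$measure_a <- factor(long$measure_a, levels = object$measures)
  long$measure_b <- factor(long$measure_b, levels = rev(object$measures))
  ggplot2::ggplot(long, ggplot2::aes(.data$measure_a, .data$measure_b,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$value), "", sprintf("%.2f", .data$value))),
      size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), na.value = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = what,
                  title = paste("Pairwise", what, "between measures"))
}

#' Map of local Moran's I cluster/outlier classes
#'
#' @param local Tibble from [local_morans_i()] (optionally with a `measure`
#'   column from [run_all()]).
#' @param centroids Tibble `bg_id`, `x`, `y`.
#' @return A ggplot object.
#' @export
plot_local_moran <- function(local, centroids) {
  d <- dplyr::left_join(local, centroids, by = c(id = "bg_id"))
  pal <- c(HH = "#b2182b", LL = "#2166ac", HL = "#ef8a62", LH = "#67a9cf",
           `not-significant` = "grey80")
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y,
                                       colour = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = pal) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Local spatial clusters and outliers",
                  colour = NULL)
  if ("measure" %in% names(d)) p <- p + ggplot2::facet_wrap(~measure)
  p
}

#' Forest plot of odds ratios for the low-accessibility exposure
#'
#' @param validity Tibble from [run_validity_suite()].
#' @param form Which model form to show (default `"III"`).
#' @return A ggplot object.
#' @export
plot_validity_or <- function(validity, form = "III") {
  d <- dplyr::filter(validity, .data$form == !!form,
                     .data$term == "low_access")
  d$measure <- factor(d$measure, levels = rev(measure_names()))
  ggplot2::ggplot(d, ggplot2::aes(.data$or, .data$measure)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (low vs high accessibility)", y = NULL,
                  title = paste("Late-stage odds ratios, model", form))
}
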