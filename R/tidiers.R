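#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a validity model fit
#'
#' One row per model term with odds ratio and Wald 95 percent CI.
#'
#' @param x A `validity_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `se`, `or`, `lower`, `upper`.
#' @export
tidy.validity_fit <- function(x, ...) x$terms

#' One-row summary of a validity model fit
#'
#' @param x A `validity_fit`.
#' @param ... Unused.
#' @return Tibble `form`, `n`, `re_variance`, `scaled_deviance`, `deviance`.
#' @export
glance.validity_fit <- function(x, ...) {
  tibble::tibble(form = x$form, n = x$n, re_variance = x$re_variance,
                 scaled_deviance = x$scaled_deviance, deviance = x$deviance)
}

#' Tidy a deprivation factor fit
#'
#' @param x A `deprivation_fit`.
#' @param ... Unused.
#' @return Tibble `variable`, `loading`.
#' @export
tidy.deprivation_fit <- function(x, ...) {
  tibble::tibble(variable = names(x$loadings), loading = unname(x$loadings))
}

#' One-row summary of a deprivation factor fit
#'
#' @param x A `deprivation_fit`.
#' @param ... Unused.
#' @return Tibble `n_factors`, `variance_explained`.
#' @export
glance.deprivation_fit <- function(x, ...) {
  tibble::tibble(n_factors = x$n_factors,
                 variance_explained = x$variance_explained)
}

#' Tidy an agreement battery
#'
#' @param x An `agreement_matrix`.
#' @param ... Unused.
#' @return The long pairs tibble (`measure_a`, `measure_b`, `rho`, `kappa`,
#'   CI bounds, Landis-Koch label).
#' @export
tidy.agreement_matrix <- function(x, ...) x$pairs
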