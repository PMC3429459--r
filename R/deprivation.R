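#' Fit the block-group deprivation factor by common factor analysis
#'
#' Columns are standardized, factors are extracted by the principal-factor
#' method (eigendecomposition of the correlation matrix with prior
#' communalities on the diagonal: 1 by default, or squared multiple
#' correlations with `priors = "smc"`), factors with eigenvalue above 1 are
#' retained and varimax-rotated when more than one is kept. The factor with
#' the largest absolute loading on the poverty variable is taken as the
#' deprivation factor, with its sign flipped if poverty loads negatively so
#' that deprivation-increasing variables load positively.
#'
#' @param covariates Tibble of numeric covariate columns, optionally with a
#'   `bg_id` column (at least 22 rows; no constant columns).
#' @param priors `"one"` (principal components extraction, default) or
#'   `"smc"` (squared multiple correlations as prior communalities).
#' @param anchor Name of the poverty-type variable that orients and selects
#'   the deprivation factor (default `"pct_below_poverty"`; falls back to the
#'   first column if absent).
#' @return Object of class `deprivation_fit`: `loadings` (named vector on
#'   the deprivation factor), `all_loadings` (rotated loading matrix),
#'   `variance_explained` (deprivation-factor sum of squared loadings over
#'   the number of variables), `n_factors`, `scores` (regression-method
#'   factor scores on the deprivation factor), `center`/`scale` used for
#'   standardization.
#' @export
fit_deprivation_factor <- function(covariates, priors = c("one", "smc"),
                                   anchor = "pct_below_poverty") {
  priors <- match.arg(priors)
  x <- as.data.frame(covariates)
  if ("bg_id" %in% names(x)) x$bg_id <- NULL
  x <- as.matrix(x)
  stopifnot(is.numeric(x))
  if (nrow(x) < ncol(x) + 1) {
    stop("need more block groups than variables (at least ", ncol(x) + 1, ")",
         call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  if (!anchor %in% colnames(x)) anchor <- colnames(x)[1]

  z <- scale(x)
  r <- stats::cor(x)
  if (priors == "smc") {
    rin <- tryCatch(solve(r), error = function(e)
      stop("correlation matrix is singular; cannot compute SMC priors",
           call. = FALSE))
    diag(r) <- 1 - 1 / diag(rin)
  }
  eig <- eigen(r, symmetric = TRUE)
  keep <- which(eig$values > 1)
  if (length(keep) == 0) keep <- 1L
  load <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(pmax(eig$values[keep], 0)), length(keep))
  rownames(load) <- colnames(x)

  if (ncol(load) > 1) {
    rot <- stats::varimax(load)
    load <- load %*% rot$rotmat
  }
  dep <- which.max(abs(load[anchor, ]))
  if (load[anchor, dep] < 0) load[, dep] <- -load[, dep]

  # regression-method factor scores on the deprivation factor; fall back to
  # the least-squares projection when the correlation matrix is singular
  # (e.g. collinear covariates)
  coef <- tryCatch(solve(stats::cor(x), load[, dep]),
                   error = function(e) load[, dep] / sum(load[, dep]^2))
  scores <- as.numeric(z %*% coef)

  structure(
    list(loadings = stats::setNames(load[, dep], colnames(x)),
         all_loadings = load,
         variance_explained = sum(load[, dep]^2) / ncol(x),
         n_factors = ncol(load),
         scores = scores,
         anchor = anchor,
         center = attr(z, "scaled:center"),
         scale = attr(z, "scaled:scale")),
    class = "deprivation_fit"
  )
}

#' @export
print.deprivation_fit <- function(x, ...) {
  cat("<deprivation_fit> ", x$n_factors, "factor(s) retained;",
      sprintf("deprivation factor explains %.1f%% of total variance\n",
              100 * x$variance_explained))
  invisible(x)
}

#' Select deprivation-index variables by loading magnitude
#'
#' @param loadings Named numeric vector of loadings on the deprivation
#'   factor (or a `deprivation_fit`).
#' @param threshold Absolute-loading cutoff in (0, 1); default 0.60.
#' @return Character vector of selected variable names.
#' @export
select_variables <- function(loadings, threshold = 0.60) {
  if (inherits(loadings, "deprivation_fit")) loadings <- loadings$loadings
  stopifnot(threshold > 0, threshold < 1, !is.null(names(loadings)))
  sel <- names(loadings)[abs(loadings) >= threshold]
  if (length(sel) == 0) {
    stop("no variable reaches |loading| >= ", threshold,
         "; lower the threshold", call. = FALSE)
  }
  sel
}

#' Cronbach's alpha of a set of standardized items
#'
#' `alpha = k/(k-1) * (1 - sum of item variances / variance of the item
#' sum)`, computed on column-standardized items. Items are sign-aligned with
#' their loading orientation before summation when `orientation` is given.
#'
#' @param items Tibble or matrix of at least two numeric item columns
#'   (a `bg_id` column is dropped).
#' @param orientation Optional named sign vector (+1/-1) applied to items
#'   before scoring.
#' @return Alpha (scalar, <= 1).
#' @export
cronbach_alpha <- function(items, orientation = NULL) {
  x <- as.data.frame(items)
  if ("bg_id" %in% names(x)) x$bg_id <- NULL
  x <- as.matrix(x)
  k <- ncol(x)
  if (k < 2) stop("need at least 2 items", call. = FALSE)
  z <- scale(x)
  if (!is.null(orientation)) {
    z <- z %*% diag(sign(orientation[colnames(x)]), k)
  }
  total_var <- stats::var(rowSums(z))
  k / (k - 1) * (1 - sum(apply(z, 2, stats::var)) / total_var)
}

#' Composite deprivation score from selected covariates
#'
#' Mean of the column-wise z-scores of the selected variables, each oriented
#' by the sign of its loading so that higher scores mean more deprivation.
#' The score is invariant to affine transforms of any input column.
#'
#' @param covariates Tibble of covariates (with optional `bg_id`).
#' @param selected Character vector of selected variable names.
#' @param loadings Named loadings used only for sign orientation (default:
#'   all positive).
#' @return Tibble `bg_id` (if present), `deprivation` score per block group.
#' @export
deprivation_score <- function(covariates, selected, loadings = NULL) {
  stopifnot(length(selected) >= 1)
  x <- as.data.frame(covariates)
  ids <- if ("bg_id" %in% names(x)) x$bg_id else NULL
  missing <- setdiff(selected, names(x))
  if (length(missing)) {
    stop("selected variables not in the table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  z <- scale(as.matrix(x[selected]))
  s <- if (is.null(loadings)) rep(1, length(selected)) else
    sign(loadings[selected])
  score <- as.numeric(z %*% s) / length(selected)
  out <- tibble::tibble(deprivation = score)
  if (!is.null(ids)) out <- dplyr::bind_cols(tibble::tibble(bg_id = ids), out)
  out
}

#' Build the full deprivation index in one call
#'
#' Convenience wrapper: fit the factor, select variables at the loading
#' threshold, assess internal consistency, and compute the composite score.
#'
#' @inheritParams fit_deprivation_factor
#' @inheritParams select_variables
#' @return List: `fit` (`deprivation_fit`), `selected`, `alpha`, `scores`
#'   (tibble from [deprivation_score()]).
#' @export
deprivation_index <- function(covariates, threshold = 0.60,
                              priors = "one", anchor = "pct_below_poverty") {
  fit <- fit_deprivation_factor(covariates, priors = priors, anchor = anchor)
  selected <- select_variables(fit, threshold = threshold)
  x <- as.data.frame(covariates)
  alpha <- cronbach_alpha(x[selected], orientation = sign(fit$loadings[selected]))
  scores <- deprivation_score(covariates, selected, loadings = fit$loadings)
  list(fit = fit, selected = selected, alpha = alpha, scores = scores)
}
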