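#' Spearman rank correlation matrix of accessibility measures
#'
#' Rank correlations (average ranks for ties) between every pair of measure
#' columns, with p-values from [stats::cor.test()]. Constant columns give NA
#' cells and a warning.
#'
#' @param access An `access_table` (or any tibble); non-numeric and id
#'   columns are dropped.
#' @return List of class `spearman_matrix`: `rho` and `p` matrices.
#' @export
spearman_matrix <- function(access) {
  x <- as.data.frame(access)
  x <- x[vapply(x, is.numeric, logical(1))]
  if (nrow(x) < 3) stop("need at least 3 block groups", call. = FALSE)
  constant <- vapply(x, function(v) stats::sd(v) == 0, logical(1))
  if (any(constant)) {
    warning("constant column(s), correlations undefined: ",
            paste(names(x)[constant], collapse = ", "), call. = FALSE)
  }
  k <- ncol(x)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(names(x), names(x)))
  diag(rho) <- 1
  diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (constant[i] || constant[j]) next
    ct <- suppressWarnings(
      stats::cor.test(x[[i]], x[[j]], method = "spearman", exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  structure(list(rho = rho, p = p), class = "spearman_matrix")
}

#' Categorize a measure into quartiles
#'
#' Cuts at the 25th, 50th and 75th percentiles (linear-interpolation
#' quantiles, type 7), with intervals closed on the right: a value exactly at
#' a cut point takes the lower category.
#'
#' @param values Numeric vector with at least 4 distinct values.
#' @return Integer vector of categories 1-4.
#' @export
quartile_categorize <- function(values) {
  if (length(unique(values)) < 4) {
    stop("need at least 4 distinct values to form quartiles", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  1L + (values > q[1]) + (values > q[2]) + (values > q[3])
}

#' Weighted kappa between two ordinal categorizations
#'
#' Chance-corrected agreement `kappa = 1 - sum(w * O) / sum(w * E)` with
#' disagreement weights `w_ij = |i - j|` (linear, the default) or
#' `(i - j)^2` (quadratic); expected proportions come from the marginal
#' products. The 95 percent confidence interval is a seeded nonparametric
#' bootstrap (percentile method) over paired resamples.
#'
#' @param cat_a,cat_b Integer categories of equal length (e.g. quartiles
#'   1-4).
#' @param scheme `"linear"` or `"quadratic"` disagreement weights.
#' @param n_boot Bootstrap resamples for the CI (default 1000); 0 skips the
#'   CI.
#' @param seed Seed for the bootstrap.
#' @return Tibble `kappa`, `lower`, `upper`.
#' @export
weighted_kappa <- function(cat_a, cat_b, scheme = c("linear", "quadratic"),
                           n_boot = 1000, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(length(cat_a) == length(cat_b))
  if (length(unique(cat_a)) < 2 || length(unique(cat_b)) < 2) {
    warning("a rater uses a single category; kappa undefined", call. = FALSE)
    return(tibble::tibble(kappa = NA_real_, lower = NA_real_,
                          upper = NA_real_))
  }
  k <- kappa_point(cat_a, cat_b, scheme)
  if (n_boot <= 0) {
    return(tibble::tibble(kappa = k, lower = NA_real_, upper = NA_real_))
  }
  n <- length(cat_a)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(cat_a[idx])) < 2 || length(unique(cat_b[idx])) < 2) {
        return(NA_real_)
      }
      kappa_point(cat_a[idx], cat_b[idx], scheme)
    }, numeric(1))
  })
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  tibble::tibble(kappa = k, lower = ci[1], upper = ci[2])
}

kappa_point <- function(cat_a, cat_b, scheme) {
  levels_all <- sort(unique(c(cat_a, cat_b)))
  m <- length(levels_all)
  o <- table(factor(cat_a, levels_all), factor(cat_b, levels_all)) /
    length(cat_a)
  e <- outer(rowSums(o), colSums(o))
  d <- abs(outer(seq_len(m), seq_len(m), "-"))
  w <- if (scheme == "linear") d else d^2
  1 - sum(w * o) / sum(w * e)
}

#' Interpret a kappa coefficient on the Landis-Koch scale
#'
#' Labels: `<= 0` no agreement; `(0, 0.20]` slight; `(0.20, 0.40]` fair;
#' `(0.40, 0.60]` moderate; `(0.60, 0.80]` substantial; `> 0.80` perfect.
#'
#' @param kappa Numeric vector in \[-1, 1\].
#' @return Character vector of agreement labels.
#' @export
interpret_kappa <- function(kappa) {
  if (any(kappa < -1 | kappa > 1, na.rm = TRUE)) {
    stop("kappa must lie in [-1, 1]", call. = FALSE)
  }
  cut_lab <- function(k) {
    if (is.na(k)) return(NA_character_)
    if (k <= 0) "no agreement"
    else if (k <= 0.20) "slight agreement"
    else if (k <= 0.40) "fair agreement"
    else if (k <= 0.60) "moderate agreement"
    else if (k <= 0.80) "substantial agreement"
    else "perfect agreement"
  }
  vapply(kappa, cut_lab, character(1))
}

#' Full measure-agreement battery
#'
#' Spearman correlations of the raw measures plus pairwise weighted kappa
#' (with bootstrap CIs and Landis-Koch labels) of their quartile
#' categorizations.
#'
#' @inheritParams spearman_matrix
#' @inheritParams weighted_kappa
#' @return List of class `agreement_matrix`: `measures`, `rho`, `kappa`,
#'   `kappa_lower`, `kappa_upper`, `labels` (matrices), and `pairs` (long
#'   tibble, upper triangle).
#' @export
agreement_matrix <- function(access, scheme = "linear", n_boot = 1000,
                             seed = 1) {
  x <- as.data.frame(access)
  x <- x[vapply(x, is.numeric, logical(1))]
  sp <- spearman_matrix(x)
  cats <- lapply(x, quartile_categorize)
  k <- ncol(x)
  nm <- names(x)
  kap <- lo <- hi <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(kap) <- 1
  pairs <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    wk <- weighted_kappa(cats[[i]], cats[[j]], scheme = scheme,
                         n_boot = n_boot, seed = seed + i * k + j)
    kap[i, j] <- kap[j, i] <- wk$kappa
    lo[i, j] <- lo[j, i] <- wk$lower
    hi[i, j] <- hi[j, i] <- wk$upper
    pairs[[length(pairs) + 1]] <- tibble::tibble(
      measure_a = nm[i], measure_b = nm[j],
      rho = sp$rho[i, j], kappa = wk$kappa,
      lower = wk$lower, upper = wk$upper,
      label = interpret_kappa(wk$kappa)
    )
  }
  structure(
    list(measures = nm, rho = sp$rho, kappa = kap,
         kappa_lower = lo, kappa_upper = hi,
         labels = matrix(interpret_kappa(as.vector(kap)), k, k,
                         dimnames = list(nm, nm)),
         pairs = dplyr::bind_rows(pairs)),
    class = "agreement_matrix"
  )
}
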