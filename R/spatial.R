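#' Inverse-distance spatial weights
#'
#' `w_ij = 1 / d_ij^power` for `d_ij <= threshold` (threshold infinite by
#' default, so every pair of units interacts and influence simply fades with
#' distance), zero diagonal, optionally row-standardized so each row sums
#' to 1.
#'
#' @param centroids Tibble with `bg_id` (or `id`) and coordinates `x`, `y`;
#'   centroids must be distinct.
#' @param power Distance exponent (default 1).
#' @param threshold Distance beyond which weights are zero (default `Inf`).
#' @param row_standardize Scale each row to sum 1 (default `TRUE`).
#' @return Object of class `spatial_weights`: `ids`, `w` (matrix), `meta`.
#' @export
inverse_distance_weights <- function(centroids, power = 1, threshold = Inf,
                                     row_standardize = TRUE) {
  ids <- if ("bg_id" %in% names(centroids)) centroids$bg_id else centroids$id
  d <- as.matrix(stats::dist(cbind(centroids$x, centroids$y)))
  off <- d[upper.tri(d)]
  if (any(off == 0)) {
    stop("coincident centroids give infinite weights", call. = FALSE)
  }
  w <- 1 / d^power
  diag(w) <- 0
  w[d > threshold] <- 0
  isolated <- rowSums(w) == 0
  if (any(isolated)) {
    warning("isolated unit(s) with no neighbours: ",
            paste(ids[isolated], collapse = ", "), call. = FALSE)
  }
  if (row_standardize) {
    rs <- rowSums(w)
    w <- sweep(w, 1, ifelse(rs == 0, 1, rs), "/")
  }
  dimnames(w) <- list(ids, ids)
  structure(
    list(ids = as.character(ids), w = w,
         meta = list(power = power, threshold = threshold,
                     row_standardized = row_standardize)),
    class = "spatial_weights"
  )
}

#' Binary contiguity weights from an adjacency matrix (testing helper)
#'
#' @param adj Symmetric 0/1 adjacency matrix (zero diagonal).
#' @param row_standardize Scale rows to sum 1.
#' @return A `spatial_weights` object.
#' @export
contiguity_weights <- function(adj, row_standardize = FALSE) {
  stopifnot(is.matrix(adj), all(diag(adj) == 0))
  ids <- rownames(adj)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(adj)))
  w <- adj * 1
  if (row_standardize) {
    rs <- rowSums(w)
    w <- sweep(w, 1, ifelse(rs == 0, 1, rs), "/")
  }
  dimnames(w) <- list(ids, ids)
  structure(list(ids = ids, w = w,
                 meta = list(power = NA, threshold = NA,
                             row_standardized = row_standardize)),
            class = "spatial_weights")
}

#' Global Moran's I with randomization inference
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the deviations
#' from the mean. The expectation `E[I] = -1/(n-1)` and variance follow the
#' randomization (permutation) assumption; the normal-approximation z score,
#' p-value and a symmetric 95 percent CI are reported.
#'
#' @param values Numeric vector, one per unit (non-constant).
#' @param weights A `spatial_weights` object aligned to `values`.
#' @return Tibble `i`, `expected`, `variance`, `z`, `p`, `lower`, `upper`.
#' @export
global_morans_i <- function(values, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  w <- weights$w
  n <- length(values)
  stopifnot(nrow(w) == n)
  if (stats::sd(values) == 0) {
    stop("constant values: spatial autocorrelation undefined", call. = FALSE)
  }
  z <- values - mean(values)
  s0 <- sum(w)
  i <- (n / s0) * sum(w * outer(z, z)) / sum(z^2)

  # randomization moments
  s1 <- 0.5 * sum((w + t(w))^2)
  s2 <- sum((rowSums(w) + colSums(w))^2)
  b2 <- n * sum(z^4) / sum(z^2)^2
  ei <- -1 / (n - 1)
  ei2 <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
            b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * s0^2)
  v <- ei2 - ei^2
  zscore <- (i - ei) / sqrt(v)
  tibble::tibble(
    i = i, expected = ei, variance = v, z = zscore,
    p = 2 * stats::pnorm(-abs(zscore)),
    lower = i - 1.96 * sqrt(v), upper = i + 1.96 * sqrt(v)
  )
}

#' Local Moran's I (LISA) with conditional permutation inference
#'
#' `I_i = (z_i / m2) * sum_j w_ij z_j` with `m2 = sum(z^2) / n`. For each
#' unit the value is held fixed while the others are permuted (`n_perm`
#' draws) to obtain a one-sided pseudo p-value in the direction of the
#' observed statistic. Units with `pseudo_p < alpha` are classified by the
#' quadrant of `(z_i, spatial lag of z)`: HH or LL clusters when the signs
#' agree, HL or LH outliers when they differ; all others are
#' `"not-significant"`.
#'
#' @inheritParams global_morans_i
#' @param n_perm Conditional permutations (default 999).
#' @param alpha Significance level for classification (default 0.05).
#' @param seed Seed for the permutations.
#' @return Tibble `id`, `local_i`, `lag`, `pseudo_p`, `class`.
#' @export
local_morans_i <- function(values, weights, n_perm = 999, alpha = 0.05,
                           seed = 1) {
  stopifnot(inherits(weights, "spatial_weights"))
  w <- weights$w
  n <- length(values)
  stopifnot(nrow(w) == n)
  if (stats::sd(values) == 0) {
    stop("constant values: spatial autocorrelation undefined", call. = FALSE)
  }
  z <- values - mean(values)
  m2 <- sum(z^2) / n
  lag <- as.numeric(w %*% z)
  li <- z * lag / m2

  pseudo_p <- withr::with_seed(seed, {
    vapply(seq_len(n), function(k) {
      wk <- w[k, -k]
      perm <- vapply(seq_len(n_perm), function(b) {
        zb <- sample(z[-k])
        z[k] * sum(wk * zb) / m2
      }, numeric(1))
      if (li[k] >= 0) (sum(perm >= li[k]) + 1) / (n_perm + 1)
      else (sum(perm <= li[k]) + 1) / (n_perm + 1)
    }, numeric(1))
  })

  cls <- rep("not-significant", n)
  sig <- pseudo_p < alpha
  cls[sig & z > 0 & lag > 0] <- "HH"
  cls[sig & z < 0 & lag < 0] <- "LL"
  cls[sig & z > 0 & lag <= 0] <- "HL"
  cls[sig & z < 0 & lag >= 0] <- "LH"
  tibble::tibble(id = weights$ids, local_i = li, lag = lag,
                 pseudo_p = pseudo_p, class = cls)
}
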