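#' Distance-decay specification for floating-catchment accessibility
#'
#' A decay spec describes how the interaction between a block group and a
#' facility is down-weighted with travel time inside the catchment limit
#' `t0`. Three kinds are supported:
#'
#' * `"none"` — weight 1 for all times up to `t0` (the original, unweighted
#'   two-step floating catchment area model);
#' * `"zonal"` — a stepwise weight per travel-time band: zone i covers the
#'   half-open interval `((i-1) * zone_width, i * zone_width]`, with `t = 0`
#'   falling in zone 1. `length(weights) * zone_width` must equal `t0`, the
#'   first weight must be 1 and weights must be non-increasing;
#' * `"continuous"` — a truncated, normalized Gaussian,
#'   `(exp(-t^2 / (2 beta^2)) - exp(-t0^2 / (2 beta^2))) /
#'    (1 - exp(-t0^2 / (2 beta^2)))`,
#'   which is 1 at `t = 0` and falls to 0 at `t = t0`.
#'
#' Beyond `t0` the weight is 0 for every kind.
#'
#' @param kind One of `"none"`, `"zonal"`, `"continuous"`.
#' @param t0 Catchment limit in minutes (default 30).
#' @param zone_width Minutes per zone (zonal only; e.g. 10 or 5).
#' @param weights Per-zone weights in (0, 1], non-increasing, first element 1
#'   (zonal only).
#' @param beta Gaussian decay parameter in minutes (continuous only; default
#'   15).
#' @return An object of class `decay_spec`.
#' @examples
#' decay_spec("zonal", zone_width = 10, weights = c(1.00, 0.51, 0.07))
#' decay_spec("continuous", beta = 15)
#' @export
decay_spec <- function(kind = c("none", "zonal", "continuous"), t0 = 30,
                       zone_width = NULL, weights = NULL, beta = 15) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(t0), length(t0) == 1, t0 > 0)
  if (kind == "zonal") {
    if (is.null(zone_width) || is.null(weights)) {
      stop("zonal decay requires `zone_width` and `weights`", call. = FALSE)
    }
    if (length(weights) * zone_width != t0) {
      stop("length(weights) * zone_width must equal t0", call. = FALSE)
    }
    if (any(weights <= 0) || any(weights > 1)) {
      stop("zonal weights must lie in (0, 1]", call. = FALSE)
    }
    if (weights[1] != 1) stop("the first zonal weight must be 1", call. = FALSE)
    if (is.unsorted(rev(weights))) {
      stop("zonal weights must be non-increasing", call. = FALSE)
    }
  }
  if (kind == "continuous" && (!is.numeric(beta) || beta <= 0)) {
    stop("`beta` must be a positive number of minutes", call. = FALSE)
  }
  structure(
    list(kind = kind, t0 = t0, zone_width = zone_width,
         weights = weights, beta = beta),
    class = "decay_spec"
  )
}

#' @export
print.decay_spec <- function(x, ...) {
  cat("<decay_spec>", x$kind, " t0 =", x$t0, "min")
  if (x$kind == "zonal") {
    cat("  zones:", paste(format(x$weights), collapse = ", "),
        sprintf("(%d-min bands)", x$zone_width))
  }
  if (x$kind == "continuous") cat("  beta =", x$beta, "min")
  cat("\n")
  invisible(x)
}

#' Evaluate a decay weight at given travel times
#'
#' @param t Vector of travel times in minutes (non-negative; `Inf` allowed
#'   and yields weight 0).
#' @param spec A [decay_spec()].
#' @return Numeric vector of weights in \[0, 1\].
#' @examples
#' quick3 <- decay_spec("zonal", zone_width = 10, weights = c(1.00, 0.51, 0.07))
#' decay_weight(c(7, 12, 28, 31), quick3)
#' @export
decay_weight <- function(t, spec) {
  stopifnot(inherits(spec, "decay_spec"))
  if (any(t < 0, na.rm = TRUE)) {
    stop("travel times must be non-negative", call. = FALSE)
  }
  w <- numeric(length(t))
  inside <- is.finite(t) & t <= spec$t0
  if (!any(inside)) return(w)
  ti <- t[inside]
  w[inside] <- switch(
    spec$kind,
    none = 1,
    zonal = {
      zone <- pmax(1L, ceiling(ti / spec$zone_width))
      spec$weights[zone]
    },
    continuous = {
      tail <- exp(-spec$t0^2 / (2 * spec$beta^2))
      (exp(-ti^2 / (2 * spec$beta^2)) - tail) / (1 - tail)
    }
  )
  w
}

#' The six decay specifications of the standard measure battery
#'
#' Returns the decay specs behind the six floating-catchment accessibility
#' scores: unweighted (`SAU`), continuous Gaussian (`SAC`), and the four
#' zonal schemes — three 10-minute zones with quick (1.00, 0.51, 0.07) or
#' slow (1.00, 0.75, 0.32) decay (`SA3Q`, `SA3S`) and six 5-minute zones
#' with quick (1.00, 0.82, 0.45, 0.17, 0.04, 0.01) or slow
#' (1.00, 0.96, 0.85, 0.70, 0.53, 0.37) decay (`SA6Q`, `SA6S`).
#'
#' @param t0 Catchment limit in minutes (default 30).
#' @param beta Gaussian parameter for the continuous spec (default 15).
#' @return Named list of six [decay_spec()] objects.
#' @export
decay_presets <- function(t0 = 30, beta = 15) {
  list(
    SAU  = decay_spec("none", t0 = t0),
    SAC  = decay_spec("continuous", t0 = t0, beta = beta),
    SA3Q = decay_spec("zonal", t0 = t0, zone_width = t0 / 3,
                      weights = c(1.00, 0.51, 0.07)),
    SA3S = decay_spec("zonal", t0 = t0, zone_width = t0 / 3,
                      weights = c(1.00, 0.75, 0.32)),
    SA6Q = decay_spec("zonal", t0 = t0, zone_width = t0 / 6,
                      weights = c(1.00, 0.82, 0.45, 0.17, 0.04, 0.01)),
    SA6S = decay_spec("zonal", t0 = t0, zone_width = t0 / 6,
                      weights = c(1.00, 0.96, 0.85, 0.70, 0.53, 0.37))
  )
}
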