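#' Service density: machines reachable within the catchment per capita
#'
#' For each block group, sums the machines at all facilities reachable within
#' `t0` minutes and divides by the block group's eligible population
#' (women aged 40 and above), scaled to a per-`scale` rate.
#'
#' @param od Long OD tibble from [od_matrix()] or a minutes matrix.
#' @param machines Tibble `facility_id`, `machines` (a single year), or a
#'   named numeric vector keyed by facility id.
#' @param populations Tibble `bg_id`, `pop_women40`, or a named numeric
#'   vector keyed by block-group id. All populations must be positive.
#' @param t0 Catchment limit in minutes (default 30, inclusive).
#' @param scale Rate multiplier (default `1e4`: machines per 10,000 women
#'   40+).
#' @return Tibble `bg_id`, `des`.
#' @export
service_density <- function(od, machines, populations, t0 = 30, scale = 1e4) {
  tt <- as_od_times(od)
  s <- align_supply(machines, colnames(tt))
  p <- align_population(populations, rownames(tt))
  reach <- is.finite(tt) & tt <= t0
  tibble::tibble(
    bg_id = rownames(tt),
    des = scale * as.numeric(reach %*% s) / p
  )
}

#' Two-step floating catchment area accessibility score
#'
#' Step 1 computes each facility's supply-to-weighted-demand ratio
#' `R_j = S_j / sum_k W(t_kj) P_k` over the block groups whose centroids fall
#' within the facility's `t0`-minute catchment. Step 2 sums the ratios,
#' decay-weighted, over the facilities reachable from each block group:
#' `A_k = scale * sum_j W(t_kj) R_j`. A facility whose catchment contains no
#' population contributes nothing (and is reported via a message).
#'
#' @inheritParams service_density
#' @param decay A [decay_spec()]; its `t0` defines the catchment.
#' @return Tibble `bg_id`, `score`.
#' @export
two_step_fca <- function(od, machines, populations, decay, scale = 1e4) {
  stopifnot(inherits(decay, "decay_spec"))
  tt <- as_od_times(od)
  s <- align_supply(machines, colnames(tt))
  p <- align_population(populations, rownames(tt))

  w <- matrix(decay_weight(as.vector(tt), decay),
              nrow(tt), ncol(tt), dimnames = dimnames(tt))
  demand <- as.numeric(p %*% w)              # per facility: sum_k W(t_kj) P_k
  empty <- demand <= 0
  if (any(empty)) {
    message(sum(empty), " facility(ies) with empty catchment contribute nothing")
  }
  ratio <- ifelse(empty, 0, s / ifelse(empty, 1, demand))
  tibble::tibble(
    bg_id = rownames(tt),
    score = scale * as.numeric(w %*% ratio)
  )
}

#' Element-wise multi-year average of accessibility tables
#'
#' Averages the density and floating-catchment columns of per-year access
#' tables; travel-time columns (`dst`, `dst5`), which do not vary by year,
#' are passed through after an identity check.
#'
#' @param tables List of per-year access tibbles with identical `bg_id`
#'   columns (same order) and identical numeric column sets.
#' @return One tibble of the same shape with year-averaged values.
#' @export
multi_year_average <- function(tables) {
  stopifnot(length(tables) >= 1)
  ids <- tables[[1]]$bg_id
  for (t in tables) {
    if (!identical(t$bg_id, ids)) {
      stop("block-group ids are misaligned across years", call. = FALSE)
    }
  }
  num_cols <- setdiff(names(tables[[1]]), "bg_id")
  out <- tables[[1]]
  for (col in num_cols) {
    if (col %in% c("dst", "dst5")) {
      vals <- vapply(tables, function(t) t[[col]], numeric(length(ids)))
      if (!all(abs(vals - vals[, 1]) < 1e-12)) {
        stop("travel-time columns must not vary across years", call. = FALSE)
      }
      next
    }
    out[[col]] <- rowMeans(
      vapply(tables, function(t) t[[col]], numeric(length(ids)))
    )
  }
  out
}

#' Compute the full nine-measure accessibility table
#'
#' Produces, per block group: shortest travel time (`dst`), mean time to the
#' five nearest facilities (`dst5`), service density (`des`), and the six
#' floating-catchment scores (`sau`, `sac`, `sa3q`, `sa3s`, `sa6q`, `sa6s`)
#' under the unweighted, continuous-Gaussian and four zonal decay schemes.
#' Density and floating-catchment scores are computed per facility-year and
#' averaged across years; travel-time measures use the year-invariant
#' network.
#'
#' @inheritParams service_density
#' @param machines_by_year Tibble `facility_id`, `year`, `machines`.
#' @param beta Gaussian parameter for the continuous scheme (minutes).
#' @return An `access_table` tibble: `bg_id` plus the nine measure columns.
#' @export
compute_all_measures <- function(od, machines_by_year, populations,
                                 t0 = 30, scale = 1e4, beta = 15) {
  tt <- as_od_times(od)
  specs <- decay_presets(t0 = t0, beta = beta)
  years <- sort(unique(machines_by_year$year))

  base <- dplyr::left_join(dst(tt), dst5(tt), by = "bg_id")
  yearly <- purrr::map(years, function(yr) {
    m <- dplyr::filter(machines_by_year, .data$year == yr)
    out <- base
    out$des <- service_density(tt, m, populations, t0 = t0, scale = scale)$des
    for (nm in names(specs)) {
      out[[tolower(nm)]] <-
        two_step_fca(tt, m, populations, specs[[nm]], scale = scale)$score
    }
    out
  })
  out <- multi_year_average(yearly)
  class(out) <- c("access_table", class(out))
  out
}

#' The nine accessibility measure names, in canonical order
#' @return Character vector of column names used in an `access_table`.
#' @export
measure_names <- function() {
  c("dst", "dst5", "des", "sau", "sac", "sa3q", "sa3s", "sa6q", "sa6s")
}

# --- input alignment helpers -------------------------------------------------

align_supply <- function(machines, facility_ids) {
  if (is.data.frame(machines)) {
    stopifnot(all(c("facility_id", "machines") %in% names(machines)))
    s <- machines$machines[match(facility_ids, as.character(machines$facility_id))]
  } else if (is.null(names(machines))) {
    stopifnot(length(machines) == length(facility_ids))
    s <- machines
  } else {
    s <- machines[facility_ids]
  }
  if (anyNA(s)) stop("missing machine counts for some facilities", call. = FALSE)
  if (any(s < 0)) stop("machine counts must be non-negative", call. = FALSE)
  as.numeric(s)
}

align_population <- function(populations, bg_ids) {
  if (is.data.frame(populations)) {
    stopifnot(all(c("bg_id", "pop_women40") %in% names(populations)))
    p <- populations$pop_women40[match(bg_ids, as.character(populations$bg_id))]
  } else if (is.null(names(populations))) {
    stopifnot(length(populations) == length(bg_ids))
    p <- populations
  } else {
    p <- populations[bg_ids]
  }
  if (anyNA(p)) stop("missing populations for some block groups", call. = FALSE)
  if (any(p <= 0)) stop("all block-group populations must be positive", call. = FALSE)
  as.numeric(p)
}
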