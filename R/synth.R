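#' Specification of a synthetic study region
#'
#' Describes the synthetic geography the generator emulates: a square region
#' with block-group centroids, spatially clustered facilities, a connected
#' planar road network, heterogeneous eligible populations (women aged 40+,
#' lognormal), and per-facility-year machine counts.
#'
#' @param n_blockgroups Number of block groups (>= 3).
#' @param n_facilities Number of facilities (>= 1).
#' @param region_extent Side of the square region in km.
#' @param network_style `"grid"` (jittered lattice) or `"random-planar"`
#'   (random nodes joined by nearest-neighbour edges plus a spanning tree).
#' @param mean_speed Travel speed in km per minute used for edge times
#'   (default 0.6, i.e. 36 km/h urban driving).
#' @param pop_log_mean,pop_log_sd Lognormal parameters for the women-40+
#'   population per block group (defaults 5.7 and 0.5, median about 300).
#' @param machines_mean Poisson mean for machines per facility; counts are
#'   floored at 1.
#' @param n_years Number of facility-years of machine counts (default 5).
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(n_blockgroups = 200, n_facilities = 20,
                        region_extent = 30, network_style = c("grid", "random-planar"),
                        mean_speed = 0.6, pop_log_mean = 5.7, pop_log_sd = 0.5,
                        machines_mean = 2, n_years = 5, seed = 1) {
  network_style <- match.arg(network_style)
  stopifnot(n_blockgroups >= 3, n_facilities >= 1,
            region_extent > 0, mean_speed > 0, pop_log_sd > 0,
            machines_mean > 0, n_years >= 1)
  structure(
    list(n_blockgroups = as.integer(n_blockgroups),
         n_facilities = as.integer(n_facilities),
         region_extent = region_extent, network_style = network_style,
         mean_speed = mean_speed, pop_log_mean = pop_log_mean,
         pop_log_sd = pop_log_sd, machines_mean = machines_mean,
         n_years = as.integer(n_years), seed = as.integer(seed)),
    class = "region_spec"
  )
}

#' Generate a synthetic region: block groups, facilities and road network
#'
#' Block-group centroids are uniform over the region with distinct
#' positions and integer lognormal populations (floored at 1). Facilities
#' cluster around three attraction centers (Gaussian scatter, sd = extent/10,
#' clipped to the region), mimicking urban service concentration. Each
#' facility carries a machine count per year: a Poisson draw floored at 1,
#' then perturbed by +/-1 (probability 0.1, refloored) across years to mimic
#' slight year-to-year change in capacity. The road network is connected;
#' edge weights are minutes (`length / mean_speed`). If a draw yields a
#' disconnected network it is redrawn up to 5 times before failing.
#'
#' @param spec A [region_spec()].
#' @return List with `blockgroups` (tibble `bg_id`, `x`, `y`,
#'   `pop_women40`), `facilities` (tibble `facility_id`, `x`, `y`, `year`,
#'   `machines`; one row per facility-year) and `network` (list of `nodes`
#'   and `edges` tibbles).
#' @export
generate_region <- function(spec) {
  stopifnot(inherits(spec, "region_spec"))
  withr::with_seed(spec$seed, {
    ext <- spec$region_extent

    net <- NULL
    for (try in 1:5) {
      cand <- make_network(spec)
      g <- igraph::graph_from_data_frame(cand$edges[, c("from", "to")],
                                         directed = FALSE,
                                         vertices = data.frame(name = as.character(cand$nodes$node)))
      if (igraph::components(g)$no == 1) { net <- cand; break }
    }
    if (is.null(net)) {
      stop("failed to generate a connected road network after 5 attempts",
           call. = FALSE)
    }

    repeat {
      bx <- stats::runif(spec$n_blockgroups, 0, ext)
      by <- stats::runif(spec$n_blockgroups, 0, ext)
      if (!anyDuplicated(cbind(bx, by))) break
    }
    blockgroups <- tibble::tibble(
      bg_id = sprintf("bg%03d", seq_len(spec$n_blockgroups)),
      x = bx, y = by,
      pop_women40 = pmax(1L, as.integer(round(
        stats::rlnorm(spec$n_blockgroups, spec$pop_log_mean, spec$pop_log_sd))))
    )

    centers <- cbind(stats::runif(3, 0.25 * ext, 0.75 * ext),
                     stats::runif(3, 0.25 * ext, 0.75 * ext))
    which_c <- sample.int(3, spec$n_facilities, replace = TRUE)
    fx <- pmin(ext, pmax(0, centers[which_c, 1] +
                           stats::rnorm(spec$n_facilities, 0, ext / 10)))
    fy <- pmin(ext, pmax(0, centers[which_c, 2] +
                           stats::rnorm(spec$n_facilities, 0, ext / 10)))
    base_machines <- pmax(1L, stats::rpois(spec$n_facilities, spec$machines_mean))
    facilities <- tidyr::expand_grid(
      facility_id = sprintf("fac%02d", seq_len(spec$n_facilities)),
      year = seq_len(spec$n_years)
    )
    facilities$x <- fx[match(facilities$facility_id,
                             sprintf("fac%02d", seq_len(spec$n_facilities)))]
    facilities$y <- fy[match(facilities$facility_id,
                             sprintf("fac%02d", seq_len(spec$n_facilities)))]
    perturb <- ifelse(stats::runif(nrow(facilities)) < 0.1,
                      sample(c(-1L, 1L), nrow(facilities), replace = TRUE), 0L)
    facilities$machines <- pmax(
      1L, base_machines[match(facilities$facility_id,
                              sprintf("fac%02d", seq_len(spec$n_facilities)))] + perturb)

    list(blockgroups = blockgroups, facilities = facilities, network = net)
  })
}

# Connected planar-ish network over the region. Grid: jittered lattice with
# 4-neighbour edges. Random-planar: uniform nodes, 3-nearest-neighbour edges
# plus a Euclidean minimum spanning tree to guarantee connectivity.
make_network <- function(spec) {
  ext <- spec$region_extent
  if (spec$network_style == "grid") {
    m <- max(3L, ceiling(sqrt(2 * spec$n_blockgroups)))
    step <- ext / (m - 1)
    grid <- expand.grid(i = seq_len(m), j = seq_len(m))
    nx <- (grid$i - 1) * step + stats::rnorm(m * m, 0, step / 10)
    ny <- (grid$j - 1) * step + stats::rnorm(m * m, 0, step / 10)
    id <- function(i, j) (j - 1) * m + i
    e <- list()
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i < m) e[[length(e) + 1]] <- c(id(i, j), id(i + 1, j))
      if (j < m) e[[length(e) + 1]] <- c(id(i, j), id(i, j + 1))
    }
    em <- do.call(rbind, e)
    nodes <- tibble::tibble(node = seq_len(m * m), x = nx, y = ny)
  } else {
    n <- max(20L, spec$n_blockgroups)
    nodes <- tibble::tibble(node = seq_len(n),
                            x = stats::runif(n, 0, ext),
                            y = stats::runif(n, 0, ext))
    d <- as.matrix(stats::dist(cbind(nodes$x, nodes$y)))
    knn <- do.call(rbind, lapply(seq_len(n), function(i) {
      nb <- order(d[i, ])[2:4]
      cbind(i, nb)
    }))
    g_full <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                                  weighted = TRUE)
    mst <- igraph::mst(g_full)
    mst_e <- igraph::as_edgelist(mst, names = FALSE)
    em <- unique(t(apply(rbind(knn, mst_e), 1, sort)))
  }
  dx <- nodes$x[em[, 1]] - nodes$x[em[, 2]]
  dy <- nodes$y[em[, 1]] - nodes$y[em[, 2]]
  edges <- tibble::tibble(from = em[, 1], to = em[, 2],
                          minutes = sqrt(dx^2 + dy^2) / spec$mean_speed)
  list(nodes = nodes, edges = edges)
}

#' The 21 census deprivation covariates
#'
#' Variable names for the six socioeconomic domains (education, occupation,
#' housing, income and poverty, racial composition, residential stability)
#' used to build the block-group deprivation index.
#'
#' @return Character vector of 21 variable names.
#' @export
deprivation_variables <- function() {
  c("pct_less_than_hs", "pct_college",
    "pct_unemployed", "pct_white_collar",
    "pct_renter_hh", "pct_vacant_hh", "pct_crowded_hh", "median_home_value",
    "pct_female_headed_hh", "pct_public_assistance", "pct_no_vehicle",
    "pct_no_kitchen", "pct_no_phone", "pct_incomplete_plumbing",
    "median_family_income", "pct_high_income_hh", "pct_below_poverty",
    "pct_nh_african_american", "pct_foreign_born",
    "pct_same_house_5yr", "pct_age_65_plus")
}

#' Reference single-factor loadings for the 21 deprivation covariates
#'
#' Published factor loadings of the 21 census variables on a block-group
#' deprivation factor; used as default generator parameters for synthetic
#' covariates and as a fixture for variable selection. Nine variables load
#' at 0.62 or above (unemployment, vacant housing, crowding, female-headed
#' households, public assistance, no vehicle, no phone, poverty, percent
#' non-Hispanic African American).
#'
#' @return Named numeric vector of 21 loadings in \[-1, 1\].
#' @export
reference_loadings <- function() {
  stats::setNames(
    c(0.46353, -0.42384,
      0.79788, -0.46336,
      0.58504, 0.81785, 0.61979, -0.19721,
      0.67542, 0.81928, 0.82504,
      0.10527, 0.63371, 0.20827,
      -0.42799, -0.03565, 0.86242,
      0.75122, -0.19410,
      -0.25038, -0.15917),
    deprivation_variables()
  )
}

#' Generate synthetic deprivation covariates with one latent factor
#'
#' Draws one standard-normal latent deprivation factor per block group and
#' sets covariate `i = loading_i * factor + noise`. By default the noise
#' standard deviation is `sqrt(1 - loading_i^2)` so each covariate has unit
#' total variance; a scalar `noise_sd` overrides it for all covariates.
#'
#' @param blockgroups Tibble with `bg_id` (other columns ignored).
#' @param loadings Numeric 21-vector in \[-1, 1\] (default
#'   [reference_loadings()]).
#' @param noise_sd Optional positive scalar noise standard deviation.
#' @param seed Integer seed.
#' @return Tibble `bg_id` plus the 21 named covariate columns; the true
#'   latent factor is attached as attribute `"latent_factor"`.
#' @export
generate_deprivation_covariates <- function(blockgroups,
                                            loadings = reference_loadings(),
                                            noise_sd = NULL, seed = 1) {
  vars <- deprivation_variables()
  if (length(loadings) != length(vars)) {
    stop("`loadings` must have length ", length(vars), call. = FALSE)
  }
  if (any(abs(loadings) > 1)) {
    stop("loadings must lie in [-1, 1]", call. = FALSE)
  }
  if (!is.null(noise_sd) && (!is.numeric(noise_sd) || noise_sd <= 0)) {
    stop("`noise_sd` must be a positive number", call. = FALSE)
  }
  n <- nrow(blockgroups)
  withr::with_seed(seed, {
    f <- stats::rnorm(n)
    sd_i <- if (is.null(noise_sd)) sqrt(pmax(0, 1 - loadings^2)) else
      rep(noise_sd, length(vars))
    x <- outer(f, unname(loadings)) +
      matrix(stats::rnorm(n * length(vars)), n) %*% diag(sd_i)
    colnames(x) <- vars
    out <- dplyr::bind_cols(tibble::tibble(bg_id = blockgroups$bg_id),
                            tibble::as_tibble(x))
    attr(out, "latent_factor") <- f
    out
  })
}

#' Specification of the synthetic late-stage outcome model
#'
#' Cases are assigned to block groups in proportion to the eligible
#' population; the late-stage indicator follows a logistic model in
#' dichotomized accessibility (1 = below-median, i.e. low access) and
#' deprivation (1 = above-median, i.e. more deprived), age group and race
#' group, with a Gaussian block-group random intercept.
#'
#' @param intercept Log-odds intercept (default `qlogis(0.4)`, a 40 percent
#'   baseline late-stage fraction).
#' @param beta_access Log odds ratio for low accessibility (default
#'   `log(1.2)`).
#' @param beta_deprivation Log odds ratio for high deprivation (default
#'   `log(1.2)`).
#' @param beta_age Length-3 coefficients for age groups `<50`, `50-64`,
#'   `65+` (first is the reference and must be 0).
#' @param beta_race Length-3 coefficients for race groups `NH-White`,
#'   `African American`, `Other` (first is the reference and must be 0).
#' @param random_intercept_sd Between-block-group SD on the log-odds scale
#'   (>= 0).
#' @param n_cases Number of cases to draw.
#' @param seed Integer seed.
#' @return An object of class `outcome_model_spec`.
#' @export
outcome_model_spec <- function(intercept = stats::qlogis(0.4),
                               beta_access = log(1.2),
                               beta_deprivation = log(1.2),
                               beta_age = c(0, log(0.9), log(1.1)),
                               beta_race = c(0, log(1.3), 0),
                               random_intercept_sd = 0.3,
                               n_cases = 4000, seed = 1) {
  stopifnot(random_intercept_sd >= 0, n_cases >= 1,
            length(beta_age) == 3, length(beta_race) == 3,
            beta_age[1] == 0, beta_race[1] == 0)
  structure(
    list(intercept = intercept, beta_access = beta_access,
         beta_deprivation = beta_deprivation, beta_age = beta_age,
         beta_race = beta_race, random_intercept_sd = random_intercept_sd,
         n_cases = as.integer(n_cases), seed = as.integer(seed)),
    class = "outcome_model_spec"
  )
}

#' Generate synthetic case records with a multilevel logistic outcome
#'
#' @param blockgroups Tibble `bg_id`, `pop_women40`.
#' @param access Per-block-group accessibility scores aligned to
#'   `blockgroups` (numeric vector).
#' @param deprivation Per-block-group deprivation scores aligned to
#'   `blockgroups` (numeric vector).
#' @param spec An [outcome_model_spec()].
#' @param age_probs,race_probs Marginal sampling probabilities for the three
#'   age and race groups.
#' @return Tibble `case_id`, `bg_id`, `age_group`, `race_group`,
#'   `late_stage`.
#' @export
generate_cases <- function(blockgroups, access, deprivation, spec,
                           age_probs = c(0.25, 0.35, 0.40),
                           race_probs = c(0.60, 0.35, 0.05)) {
  stopifnot(inherits(spec, "outcome_model_spec"),
            length(access) == nrow(blockgroups),
            length(deprivation) == nrow(blockgroups))
  if (all(blockgroups$pop_women40 == 0)) {
    stop("all block-group populations are zero", call. = FALSE)
  }
  low_access <- dichotomize_at_median(access)
  # above-median deprivation, ties to the less-deprived reference side
  high_dep <- dichotomize_at_median(-deprivation)
  age_levels <- c("<50", "50-64", "65+")
  race_levels <- c("NH-White", "African American", "Other")

  withr::with_seed(spec$seed, {
    bg_idx <- sample.int(nrow(blockgroups), spec$n_cases, replace = TRUE,
                         prob = blockgroups$pop_women40)
    age <- sample(age_levels, spec$n_cases, replace = TRUE, prob = age_probs)
    race <- sample(race_levels, spec$n_cases, replace = TRUE, prob = race_probs)
    b <- stats::rnorm(nrow(blockgroups), 0, spec$random_intercept_sd)
    eta <- spec$intercept +
      spec$beta_access * low_access[bg_idx] +
      spec$beta_deprivation * high_dep[bg_idx] +
      spec$beta_age[match(age, age_levels)] +
      spec$beta_race[match(race, race_levels)] +
      b[bg_idx]
    tibble::tibble(
      case_id = sprintf("case%06d", seq_len(spec$n_cases)),
      bg_id = blockgroups$bg_id[bg_idx],
      age_group = factor(age, levels = age_levels),
      race_group = factor(race, levels = race_levels),
      late_stage = stats::rbinom(spec$n_cases, 1, stats::plogis(eta))
    )
  })
}
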