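#' Configuration for an end-to-end pipeline run
#'
#' Bundles the region spec, outcome-model spec and analysis options under a
#' single master seed. Stage seeds are derived deterministically from the
#' master seed and the stage name (see [stage_seed()]), so each stage is
#' reproducible independently of execution order.
#'
#' @param region A [region_spec()].
#' @param outcome An [outcome_model_spec()].
#' @param t0 Catchment limit in minutes (default 30).
#' @param scale Accessibility score scale (default `1e4`).
#' @param beta Continuous-Gaussian decay parameter (default 15 minutes).
#' @param kappa_scheme `"linear"` or `"quadratic"` kappa weights.
#' @param n_boot Bootstrap resamples for kappa CIs.
#' @param n_perm Conditional permutations for local Moran's I.
#' @param moran_power,moran_threshold,moran_row_standardize Inverse-distance
#'   weight options.
#' @param dep_threshold Loading threshold for deprivation variable
#'   selection.
#' @param seed Master seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(region = region_spec(), outcome = outcome_model_spec(),
                       t0 = 30, scale = 1e4, beta = 15,
                       kappa_scheme = "linear", n_boot = 200, n_perm = 199,
                       moran_power = 1, moran_threshold = Inf,
                       moran_row_standardize = TRUE,
                       dep_threshold = 0.60, seed = 1) {
  structure(
    list(region = region, outcome = outcome, t0 = t0, scale = scale,
         beta = beta, kappa_scheme = kappa_scheme, n_boot = n_boot,
         n_perm = n_perm, moran_power = moran_power,
         moran_threshold = moran_threshold,
         moran_row_standardize = moran_row_standardize,
         dep_threshold = dep_threshold, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Deterministic per-stage seed from the master seed
#'
#' `stage_seed = (master * 1000003 + sum of the stage name's character
#' codes) mod (2^31 - 1)`: a documented rule, not hidden global state.
#'
#' @param master Integer master seed.
#' @param stage Stage name (character).
#' @return Integer seed below 2^31.
#' @export
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 1000003 + h) %% (2^31 - 1))
}

#' Run the whole pipeline: simulate, measure, compare, validate
#'
#' Generates a synthetic region, computes the nine-measure access table and
#' its summary distribution, the deprivation index, the agreement battery,
#' global and local Moran's I per measure, simulates case records, and fits
#' the predictive-validity models. When `out_dir` is given, every table is
#' written as CSV (plus JSON sidecars and a run manifest).
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return Invisible list: `region`, `od`, `access`, `summary`,
#'   `deprivation`, `agreement`, `moran_global`, `moran_local`, `cases`,
#'   `validity`, `manifest`.
#' @export
run_all <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))

  stage <- function(name) stage_seed(config$seed, name)

  # simulate ------------------------------------------------------------
  region <- generate_region(
    utils::modifyList(config$region, list(seed = stage("region"))) |>
      (\(x) { class(x) <- "region_spec"; x })()
  )
  covars <- generate_deprivation_covariates(region$blockgroups,
                                            seed = stage("covariates"))

  # travel + access -----------------------------------------------------
  od <- od_matrix(region$network, region$blockgroups,
                  dplyr::distinct(region$facilities, .data$facility_id,
                                  .keep_all = TRUE))
  access <- compute_all_measures(
    od, region$facilities[, c("facility_id", "year", "machines")],
    region$blockgroups, t0 = config$t0, scale = config$scale,
    beta = config$beta)
  summary_tbl <- summarize_access(access)

  # deprivation ----------------------------------------------------------
  dep <- deprivation_index(covars, threshold = config$dep_threshold)

  # agreement ------------------------------------------------------------
  agree <- agreement_matrix(access[measure_names()],
                            scheme = config$kappa_scheme,
                            n_boot = config$n_boot,
                            seed = stage("agreement"))

  # spatial pattern -------------------------------------------------------
  wts <- inverse_distance_weights(region$blockgroups,
                                  power = config$moran_power,
                                  threshold = config$moran_threshold,
                                  row_standardize = config$moran_row_standardize)
  moran_global <- purrr::map_dfr(measure_names(), function(m) {
    dplyr::mutate(global_morans_i(access[[m]], wts), measure = m,
                  .before = 1)
  })
  moran_local <- purrr::map_dfr(measure_names(), function(m) {
    dplyr::mutate(
      local_morans_i(access[[m]], wts, n_perm = config$n_perm,
                     seed = stage(paste0("local_", m))),
      measure = m, .before = 1)
  })

  # cases + validity ------------------------------------------------------
  outcome <- config$outcome
  outcome$seed <- stage("cases")
  class(outcome) <- "outcome_model_spec"
  cases <- generate_cases(region$blockgroups, access$sa6s,
                          dep$scores$deprivation, outcome)
  validity <- run_validity_suite(cases, access, dep$scores)

  manifest <- list(
    package_version = as.character(utils::packageVersion("floatcatch")),
    seed = config$seed,
    config_hash = config_hash(config),
    n_blockgroups = nrow(region$blockgroups),
    n_facilities = length(unique(region$facilities$facility_id)),
    n_cases = nrow(cases),
    measures = measure_names()
  )

  result <- list(region = region, od = od, access = access,
                 summary = summary_tbl, deprivation = dep, agreement = agree,
                 moran_global = moran_global, moran_local = moran_local,
                 cases = cases, validity = validity, manifest = manifest)
  if (!is.null(out_dir)) write_run(result, out_dir, config)
  invisible(result)
}

#' Summary distribution of the nine measures
#'
#' Mean, SD, min, quartiles, max, IQR and range per measure column.
#'
#' @param access An `access_table`.
#' @return Tibble with one row per measure.
#' @export
summarize_access <- function(access) {
  purrr::map_dfr(intersect(measure_names(), names(access)), function(m) {
    v <- access[[m]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(measure = m, mean = mean(v), sd = stats::sd(v),
                   min = min(v), p25 = q[1], median = q[2], p75 = q[3],
                   max = max(v), iqr = q[3] - q[1], range = max(v) - min(v))
  })
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  # small rolling hash; stable across sessions, no external dependency
  v <- utf8ToInt(s)
  h <- 0
  for (ch in v) h <- (h * 31 + ch) %% (2^31 - 1)
  sprintf("%d", h)
}

write_run <- function(result, out_dir, config) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wcsv <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(result$region$blockgroups, "blockgroups.csv")
  wcsv(result$region$facilities, "facilities.csv")
  wcsv(result$od, "od_matrix.csv")
  wcsv(result$access, "access.csv")
  wcsv(result$summary, "access_summary.csv")
  wcsv(result$deprivation$scores, "deprivation_scores.csv")
  wcsv(result$agreement$pairs, "agreement_pairs.csv")
  wcsv(as.data.frame(result$agreement$rho), "spearman_matrix.csv")
  wcsv(as.data.frame(result$agreement$kappa), "kappa_matrix.csv")
  wcsv(result$moran_global, "moran_global.csv")
  wcsv(result$moran_local, "moran_local.csv")
  wcsv(result$cases, "cases.csv")
  wcsv(result$validity, "validity.csv")
  jsonlite::write_json(
    list(selected = result$deprivation$selected,
         alpha = result$deprivation$alpha,
         variance_explained = result$deprivation$fit$variance_explained,
         loadings = as.list(result$deprivation$fit$loadings)),
    file.path(out_dir, "deprivation.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
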