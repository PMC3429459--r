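#' Dichotomize a score at its median
#'
#' Returns 1 for values strictly below the median (the "low" exposure side,
#' e.g. lower accessibility) and 0 otherwise; values exactly at the median
#' go to the reference (0) side.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return Integer 0/1 vector.
#' @export
dichotomize_at_median <- function(values) {
  if (length(unique(values)) < 2) {
    stop("constant input cannot be dichotomized", call. = FALSE)
  }
  as.integer(values < stats::median(values))
}

#' Multilevel logistic regression of late-stage odds on an exposure
#'
#' Fits `logit P(late_stage) = fixed effects + block-group random intercept`
#' by approximate maximum (marginal) likelihood (Laplace, via
#' [lme4::glmer()]). The accessibility exposure and the deprivation score
#' are dichotomized at their overall medians before fitting (below-median
#' accessibility and above-median deprivation are the indicator levels;
#' higher accessibility and less deprivation are the references). Model
#' forms:
#'
#' * `"I"` — low accessibility + age;
#' * `"II"` — low accessibility + age + race;
#' * `"III"` — low accessibility + high deprivation + age + race;
#' * `"joint"` — a four-level accessibility-by-deprivation factor
#'   (reference: more accessible and less deprived) + age + race;
#' * `"stratified"` — form II fit separately within each deprivation stratum
#'   (accessibility dichotomized at the overall median).
#'
#' @param cases Tibble `bg_id`, `age_group`, `race_group`, `late_stage`.
#' @param exposure Tibble `bg_id` plus one numeric score column (or a named
#'   vector keyed by block group): the accessibility measure.
#' @param deprivation Like `exposure`, for the deprivation score (required
#'   for forms `"III"`, `"joint"`, `"stratified"`).
#' @param form One of `"I"`, `"II"`, `"III"`, `"joint"`, `"stratified"`.
#' @param random_intercept `TRUE` for a block-group random intercept
#'   (default); `FALSE` fixes its variance at zero, reducing the fit to
#'   ordinary logistic regression.
#' @return Object of class `validity_fit` (or a list of them for
#'   `"stratified"`, one per stratum): `terms` tibble (`term`, `or`,
#'   `lower`, `upper`, `estimate`, `se`), `form`, `exposure`,
#'   `re_variance`, `scaled_deviance`, `n`.
#' @export
fit_multilevel_logistic <- function(cases, exposure, deprivation = NULL,
                                    form = c("I", "II", "III", "joint",
                                             "stratified"),
                                    random_intercept = TRUE) {
  form <- match.arg(form)
  if (form %in% c("III", "joint", "stratified") && is.null(deprivation)) {
    stop("form \"", form, "\" requires a deprivation score", call. = FALSE)
  }
  dat <- cases
  acc <- score_lookup(exposure)
  if (anyNA(acc[as.character(dat$bg_id)])) {
    stop("cases reference block groups missing from the exposure table",
         call. = FALSE)
  }
  dat$low_access <- dichotomize_at_median(acc)[
    match(as.character(dat$bg_id), names(acc))]
  if (!is.null(deprivation)) {
    dep <- score_lookup(deprivation)
    dat$high_dep <- dichotomize_at_median(-dep)[
      match(as.character(dat$bg_id), names(dep))]
  }
  if (length(unique(dat$bg_id)) < 2) {
    stop("need cases in at least 2 block groups", call. = FALSE)
  }

  if (form == "stratified") {
    fits <- lapply(split(dat, dat$high_dep), function(d) {
      if (length(unique(d$late_stage)) < 2) {
        warning("stratum with a single outcome class skipped", call. = FALSE)
        return(NULL)
      }
      fit_one(d, late_stage ~ low_access + age_group + race_group,
              random_intercept, form, "low_access")
    })
    names(fits) <- ifelse(names(fits) == "1", "more_deprived", "less_deprived")
    return(fits[!vapply(fits, is.null, logical(1))])
  }

  fml <- switch(form,
    I = late_stage ~ low_access + age_group,
    II = late_stage ~ low_access + age_group + race_group,
    III = late_stage ~ low_access + high_dep + age_group + race_group,
    joint = {
      dat$joint <- factor(
        paste0(ifelse(dat$low_access == 1, "low_access", "high_access"), ".",
               ifelse(dat$high_dep == 1, "more_deprived", "less_deprived")),
        levels = c("high_access.less_deprived", "low_access.less_deprived",
                   "high_access.more_deprived", "low_access.more_deprived"))
      late_stage ~ joint + age_group + race_group
    }
  )
  fit_one(dat, fml, random_intercept, form,
          if (form == "joint") "joint" else "low_access")
}

score_lookup <- function(x) {
  if (is.data.frame(x)) {
    num <- setdiff(names(x)[vapply(x, is.numeric, logical(1))], "bg_id")
    stats::setNames(x[[num[1]]], as.character(x$bg_id))
  } else {
    stopifnot(!is.null(names(x)))
    x
  }
}

fit_one <- function(dat, fml, random_intercept, form, exposure_name) {
  dat <- droplevels(dat)
  # drop factor covariates that are constant in this (sub)sample
  for (v in c("age_group", "race_group")) {
    if (v %in% all.vars(fml) && is.factor(dat[[v]]) &&
        nlevels(dat[[v]]) < 2) {
      fml <- stats::update(fml, stats::as.formula(paste(". ~ . -", v)))
    }
  }
  if (random_intercept) {
    fml_re <- stats::update(fml, . ~ . + (1 | bg_id))
    fit <- lme4::glmer(fml_re, data = dat, family = stats::binomial())
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    re_var <- as.numeric(lme4::VarCorr(fit)$bg_id[1])
    dev <- stats::deviance(fit)
  } else {
    fit <- stats::glm(fml, data = dat, family = stats::binomial())
    if (any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
      stop("apparent complete separation: |log-odds coefficient| > 15",
           call. = FALSE)
    }
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    re_var <- 0
    dev <- stats::deviance(fit)
  }
  terms <- tibble::tibble(
    term = names(beta), estimate = unname(beta), se = unname(se),
    or = exp(unname(beta)),
    lower = exp(unname(beta) - 1.96 * unname(se)),
    upper = exp(unname(beta) + 1.96 * unname(se))
  )
  structure(
    list(terms = terms, form = form, exposure = exposure_name,
         re_variance = re_var,
         scaled_deviance = dev / stats::df.residual(fit),
         deviance = dev, n = nrow(dat), fit = fit),
    class = "validity_fit"
  )
}

#' @export
print.validity_fit <- function(x, ...) {
  cat("<validity_fit> form", x$form, " n =", x$n,
      sprintf(" RE variance = %.4f\n", x$re_variance))
  print(x$terms)
  invisible(x)
}

#' Run the full predictive-validity battery
#'
#' For each of the nine accessibility measures fits model forms I, II and
#' III plus the jointly-classified and stratified forms, and returns one
#' long tibble of odds ratios.
#'
#' @param cases Case tibble (see [fit_multilevel_logistic()]).
#' @param access An `access_table` with `bg_id` and the nine measure
#'   columns.
#' @param deprivation Tibble `bg_id`, `deprivation`.
#' @param measures Which measure columns to analyse (default all nine).
#' @param random_intercept Passed through to the fits.
#' @return Tibble `measure`, `form`, `stratum`, `term`, `or`, `lower`,
#'   `upper`, `re_variance`, `scaled_deviance`.
#' @export
run_validity_suite <- function(cases, access, deprivation,
                               measures = measure_names(),
                               random_intercept = TRUE) {
  rows <- list()
  for (m in measures) {
    expo <- tibble::tibble(bg_id = access$bg_id, score = access[[m]])
    # travel-time measures: larger is worse, so flip sign before the
    # below-median split so that "low access" always means worse access
    if (m %in% c("dst", "dst5")) expo$score <- -expo$score
    for (f in c("I", "II", "III", "joint")) {
      fit <- fit_multilevel_logistic(cases, expo, deprivation, form = f,
                                     random_intercept = random_intercept)
      rows[[length(rows) + 1]] <- dplyr::mutate(
        fit$terms, measure = m, form = f, stratum = NA_character_,
        re_variance = fit$re_variance, scaled_deviance = fit$scaled_deviance)
    }
    strat <- fit_multilevel_logistic(cases, expo, deprivation,
                                     form = "stratified",
                                     random_intercept = random_intercept)
    for (s in names(strat)) {
      rows[[length(rows) + 1]] <- dplyr::mutate(
        strat[[s]]$terms, measure = m, form = "stratified", stratum = s,
        re_variance = strat[[s]]$re_variance,
        scaled_deviance = strat[[s]]$scaled_deviance)
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::select("measure", "form", "stratum", "term", "or", "lower",
                  "upper", "re_variance", "scaled_deviance")
}
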