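test_that("median dichotomization puts ties on the reference side", {
  expect_equal(sum(dichotomize_at_median(1:10)), 5)
  v <- c(1, 2, 3, 4, 5)
  expect_equal(dichotomize_at_median(v), c(1L, 1L, 0L, 0L, 0L))  # 3 = median
  expect_identical(dichotomize_at_median(v), dichotomize_at_median(exp(v)))
  expect_error(dichotomize_at_median(rep(2, 5)), "constant")
})

make_sim <- function(beta_access, n_cases, n_bg, re_sd, seed,
                     beta_dep = 0) {
  reg <- generate_region(region_spec(n_blockgroups = n_bg, seed = seed))
  access <- withr::with_seed(seed + 1, rnorm(n_bg))
  dep <- withr::with_seed(seed + 2, rnorm(n_bg))
  spec <- outcome_model_spec(beta_access = beta_access,
                             beta_deprivation = beta_dep,
                             beta_age = c(0, 0, 0), beta_race = c(0, 0, 0),
                             random_intercept_sd = re_sd,
                             n_cases = n_cases, seed = seed + 3)
  list(cases = generate_cases(reg$blockgroups, access, dep, spec),
       access = tibble::tibble(bg_id = reg$blockgroups$bg_id,
                               score = access),
       dep = tibble::tibble(bg_id = reg$blockgroups$bg_id,
                            deprivation = dep))
}

test_that("without a random intercept the fit matches the 2x2 cross-product", {
  # synthetic 2x2 table: exposed (20 late, 80 early), unexposed (10, 90)
  cases <- tibble::tibble(
    bg_id = rep(c("b1", "b2"), each = 100),
    age_group = factor("<50", levels = c("<50", "50-64", "65+")),
    race_group = factor("NH-White",
                        levels = c("NH-White", "African American", "Other")),
    late_stage = c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90))
  )
  expo <- tibble::tibble(bg_id = c("b1", "b2"), score = c(1, 2))  # b1 low
  fit <- fit_multilevel_logistic(cases, expo, form = "I",
                                 random_intercept = FALSE)
  or <- fit$terms$or[fit$terms$term == "low_access"]
  expect_equal(or, (20 * 90) / (80 * 10), tolerance = 1e-6)
  expect_equal(fit$re_variance, 0)
})

test_that("zero-variance generator: mixed fit agrees with the plain-logistic oracle", {
  sim <- make_sim(log(1.5), n_cases = 3000, n_bg = 100, re_sd = 0, seed = 3)
  plain <- fit_multilevel_logistic(sim$cases, sim$access, sim$dep,
                                   form = "III", random_intercept = FALSE)
  # independent oracle: direct glm on the same design
  acc <- stats::setNames(sim$access$score, sim$access$bg_id)
  dep <- stats::setNames(sim$dep$deprivation, sim$dep$bg_id)
  d <- dplyr::mutate(
    sim$cases,
    low_access = as.integer(acc[bg_id] < median(acc)),
    high_dep = as.integer(dep[bg_id] > median(dep)))
  oracle <- stats::glm(late_stage ~ low_access + high_dep + age_group +
                         race_group, family = binomial(), data = d)
  expect_equal(plain$terms$estimate, unname(coef(oracle)), tolerance = 1e-6)

  mixed <- fit_multilevel_logistic(sim$cases, sim$access, sim$dep,
                                   form = "III", random_intercept = TRUE)
  expect_equal(
    mixed$terms$estimate[mixed$terms$term == "low_access"],
    plain$terms$estimate[plain$terms$term == "low_access"],
    tolerance = 0.05)
  expect_lt(mixed$re_variance, 0.05)
})

test_that("the generating odds ratio is recovered at large n", {
  sim <- make_sim(log(1.2), n_cases = 50000, n_bg = 500, re_sd = 0, seed = 11)
  fit <- fit_multilevel_logistic(sim$cases, sim$access, form = "I",
                                 random_intercept = FALSE)
  or <- fit$terms$or[fit$terms$term == "low_access"]
  expect_gt(or, 1.1)
  expect_lt(or, 1.3)
})

test_that("joint classification nests the stratified low-access contrast", {
  sim <- make_sim(log(1.6), n_cases = 20000, n_bg = 300, re_sd = 0,
                  seed = 17, beta_dep = 0)
  joint <- fit_multilevel_logistic(sim$cases, sim$access, sim$dep,
                                   form = "joint", random_intercept = FALSE)
  strat <- fit_multilevel_logistic(sim$cases, sim$access, sim$dep,
                                   form = "stratified",
                                   random_intercept = FALSE)
  or_joint <- joint$terms$or[
    joint$terms$term == "jointlow_access.less_deprived"]
  or_strat <- strat$less_deprived$terms$or[
    strat$less_deprived$terms$term == "low_access"]
  expect_equal(log(or_joint), log(or_strat), tolerance = 0.1)
})

test_that("model forms expose the expected terms", {
  sim <- make_sim(log(1.2), n_cases = 1500, n_bg = 80, re_sd = 0.2, seed = 23)
  f1 <- fit_multilevel_logistic(sim$cases, sim$access, form = "I")
  expect_true(all(c("(Intercept)", "low_access") %in% f1$terms$term))
  expect_false(any(grepl("race", f1$terms$term)))
  f3 <- fit_multilevel_logistic(sim$cases, sim$access, sim$dep, form = "III")
  expect_true(all(c("low_access", "high_dep") %in% f3$terms$term))
  expect_true(any(grepl("race_group", f3$terms$term)))
  expect_true(all(f3$terms$lower <= f3$terms$or & f3$terms$or <= f3$terms$upper))
  expect_error(fit_multilevel_logistic(sim$cases, sim$access, form = "III"),
               "deprivation")
  expect_identical(tidy(f3), f3$terms)
  expect_equal(glance(f3)$n, 1500)
})

test_that("the validity suite covers nine measures times five forms", {
  reg <- generate_region(region_spec(n_blockgroups = 60, n_facilities = 8,
                                     seed = 31))
  od <- od_matrix(reg$network, reg$blockgroups,
                  dplyr::distinct(reg$facilities, facility_id,
                                  .keep_all = TRUE))
  acc <- compute_all_measures(
    od, reg$facilities[, c("facility_id", "year", "machines")],
    reg$blockgroups)
  dep <- tibble::tibble(bg_id = reg$blockgroups$bg_id,
                        deprivation = withr::with_seed(1, rnorm(60)))
  spec <- outcome_model_spec(n_cases = 800, seed = 5)
  cases <- generate_cases(reg$blockgroups, acc$sa6s, dep$deprivation, spec)
  suite <- run_validity_suite(cases, acc, dep, random_intercept = FALSE)
  combos <- dplyr::distinct(suite, measure, form, stratum)
  # forms I, II, III, joint, plus two strata of the stratified form
  expect_equal(nrow(combos), 9 * 6)
  expect_true(all(measure_names() %in% combos$measure))
  expect_true(all(suite$or > 0))
  suite2 <- run_validity_suite(cases, acc, dep, random_intercept = FALSE)
  expect_identical(suite, suite2)  # deterministic on fixed input
})
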