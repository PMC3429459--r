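starred9 <- c("pct_unemployed", "pct_vacant_hh", "pct_crowded_hh",
              "pct_female_headed_hh", "pct_public_assistance",
              "pct_no_vehicle", "pct_no_phone", "pct_below_poverty",
              "pct_nh_african_american")

test_that("the 0.60 loading threshold selects exactly the nine index variables", {
  expect_setequal(select_variables(reference_loadings(), 0.60), starred9)
  expect_error(select_variables(reference_loadings(), 0.99), "lower the")
  lam <- stats::setNames(rep(0.7, 5), paste0("v", 1:5))
  expect_setequal(select_variables(lam, 0.6), names(lam))
})

test_that("single-factor synthetic data recovers the generating loadings", {
  reg <- generate_region(region_spec(n_blockgroups = 500, seed = 31))
  cors <- vapply(1:10, function(s) {
    cov <- generate_deprivation_covariates(reg$blockgroups, seed = s)
    fit <- fit_deprivation_factor(cov)
    stats::cor(fit$loadings, reference_loadings())
  }, numeric(1))
  expect_true(all(cors > 0.95))
})

test_that("principal-factor loadings agree with a maximum-likelihood fit", {
  reg <- generate_region(region_spec(n_blockgroups = 500, seed = 41))
  cov <- generate_deprivation_covariates(reg$blockgroups, seed = 41)
  ours <- fit_deprivation_factor(cov)$loadings
  ml <- stats::factanal(as.matrix(cov[deprivation_variables()]),
                        factors = 1)$loadings[, 1]
  if (stats::cor(ml, ours) < 0) ml <- -ml
  expect_gt(stats::cor(ours, ml), 0.98)
})

test_that("the fitted deprivation score tracks the true latent factor", {
  reg <- generate_region(region_spec(n_blockgroups = 500, seed = 13))
  cov <- generate_deprivation_covariates(reg$blockgroups, seed = 13)
  fit <- fit_deprivation_factor(cov)
  f <- attr(cov, "latent_factor")
  expect_gt(stats::cor(fit$scores, f), 0.9)
  sel <- select_variables(fit)
  score <- deprivation_score(cov, sel, loadings = fit$loadings)$deprivation
  expect_gt(stats::cor(score, f), 0.9)
})

test_that("varimax separates two independent variable blocks", {
  ok <- 0
  for (s in 1:20) {
    withr::with_seed(s, {
      n <- 400
      f1 <- rnorm(n); f2 <- rnorm(n)
      x <- cbind(
        sapply(1:10, function(i) 0.8 * f1 + 0.6 * rnorm(n)),
        sapply(1:11, function(i) 0.8 * f2 + 0.6 * rnorm(n)))
      colnames(x) <- deprivation_variables()
    })
    fit <- fit_deprivation_factor(tibble::as_tibble(x))
    if (fit$n_factors >= 2) {
      l <- fit$all_loadings[, 1:2]
      cross <- min(max(abs(l[1:10, 1])), max(abs(l[1:10, 2])))
      cross2 <- min(max(abs(l[11:21, 1])), max(abs(l[11:21, 2])))
      if (cross < 0.2 && cross2 < 0.2) ok <- ok + 1
    }
  }
  expect_gte(ok, 18)
})

test_that("noise-free covariates give variance explained near 1", {
  withr::with_seed(1, {
    f <- rnorm(300)
    x <- sapply(1:21, function(i) f * sample(c(-1, 1), 1))
  })
  colnames(x) <- deprivation_variables()
  # exact collinearity: perturb infinitesimally so the correlation matrix
  # is not singular
  x <- x + matrix(rnorm(300 * 21, 0, 1e-6), 300)
  fit <- fit_deprivation_factor(tibble::as_tibble(x))
  expect_gt(fit$variance_explained, 0.999)
  expect_gt(fit$loadings["pct_below_poverty"], 0)  # orientation
})

test_that("pure-noise covariates explain about 1/21 of the variance", {
  ve <- vapply(1:100, function(s) {
    withr::with_seed(1000 + s, {
      x <- matrix(rnorm(2000 * 21), 2000)
    })
    colnames(x) <- deprivation_variables()
    fit_deprivation_factor(tibble::as_tibble(x))$variance_explained
  }, numeric(1))
  expect_equal(mean(ve), 1 / 21, tolerance = 0.3)  # relative; ~0.048-0.062
  expect_lt(mean(ve), 0.1)
})

test_that("the deprivation factor is oriented so poverty loads positively", {
  reg <- generate_region(region_spec(n_blockgroups = 300, seed = 77))
  cov <- generate_deprivation_covariates(reg$blockgroups,
                                         loadings = -reference_loadings(),
                                         seed = 77)
  fit <- fit_deprivation_factor(cov)
  expect_gt(fit$loadings["pct_below_poverty"], 0)
})

test_that("constant columns are rejected by name", {
  reg <- generate_region(region_spec(n_blockgroups = 100, seed = 1))
  cov <- generate_deprivation_covariates(reg$blockgroups, seed = 1)
  cov$pct_no_kitchen <- 1
  expect_error(fit_deprivation_factor(cov), "pct_no_kitchen")
})

test_that("cronbach's alpha matches closed forms", {
  withr::with_seed(2, x <- rnorm(500))
  expect_equal(cronbach_alpha(cbind(a = x, b = 2 * x + 3)), 1)
  withr::with_seed(3, ind <- matrix(rnorm(10000 * 2), ncol = 2,
                                    dimnames = list(NULL, c("a", "b"))))
  expect_equal(cronbach_alpha(ind), 0, tolerance = 0.05)

  # k standardized items with uniform pairwise correlation r:
  # alpha = k * r / (1 + (k - 1) * r) (Spearman-Brown)
  k <- 9; r <- 0.59
  sigma <- matrix(r, k, k); diag(sigma) <- 1
  ch <- chol(sigma)
  withr::with_seed(4, z <- matrix(rnorm(200000 * k), ncol = k) %*% ch)
  colnames(z) <- paste0("v", 1:k)
  expect_equal(cronbach_alpha(z), k * r / (1 + (k - 1) * r),
               tolerance = 0.01)
  expect_error(cronbach_alpha(z[, 1, drop = FALSE]), "at least 2")
})

test_that("scores are invariant to affine transforms of input columns", {
  reg <- generate_region(region_spec(n_blockgroups = 200, seed = 6))
  cov <- generate_deprivation_covariates(reg$blockgroups, seed = 6)
  fit <- fit_deprivation_factor(cov)
  sel <- select_variables(fit)
  s1 <- deprivation_score(cov, sel, fit$loadings)$deprivation
  cov2 <- cov
  cov2$pct_below_poverty <- 100 * cov2$pct_below_poverty + 7
  cov2$pct_no_vehicle <- 2 * cov2$pct_no_vehicle
  s2 <- deprivation_score(cov2, sel, fit$loadings)$deprivation
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("deprivation_index composes fit, selection, alpha and scores", {
  reg <- generate_region(region_spec(n_blockgroups = 400, seed = 21))
  cov <- generate_deprivation_covariates(reg$blockgroups, seed = 21)
  idx <- deprivation_index(cov)
  expect_true(all(idx$selected %in% deprivation_variables()))
  expect_gt(idx$alpha, 0.8)   # strongly loading items are highly consistent
  expect_lte(idx$alpha, 1)
  expect_equal(nrow(idx$scores), 400)
})
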