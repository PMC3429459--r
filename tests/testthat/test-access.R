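pops3 <- c(b1 = 100, b2 = 100, b3 = 100)
mach2 <- c(f1 = 1, f2 = 1)

test_that("the worked toy example gives the hand-derived two-step scores", {
  a <- two_step_fca(toy_times(), mach2, pops3, decay_spec("none"))
  # R1 = 1/200, R2 = 1/300; A1 = A2 = R1 + R2, A3 = R2 (per 10,000)
  expect_equal(a$score, c(1e4 / 120, 1e4 / 120, 1e4 / 300), tolerance = 1e-12)
  d <- service_density(toy_times(), mach2, pops3)
  expect_equal(d$des, c(200, 200, 100))
})

test_that("service density thresholds at the catchment and errors on zero population", {
  tt <- matrix(c(5, 25, 35, 5), nrow = 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("f1", "f2")))
  d <- service_density(tt, mach2, c(a = 100, b = 100))
  expect_equal(d$des, c(200, 100))
  ttn <- matrix(c(35, 40), nrow = 1, dimnames = list("a", c("f1", "f2")))
  expect_equal(service_density(ttn, mach2, c(a = 100))$des, 0)
  expect_error(service_density(tt, mach2, c(a = 0, b = 100)), "positive")
})

test_that("a single pair within the catchment reduces the score to the density", {
  tt <- matrix(12, 1, 1, dimnames = list("b", "f"))
  a <- two_step_fca(tt, c(f = 3), c(b = 250), decay_spec("none"))
  expect_equal(a$score, 1e4 * 3 / 250)
  expect_equal(a$score, service_density(tt, c(f = 3), c(b = 250))$des)
})

test_that("implementation matches the literal triple-loop oracle on random instances", {
  specs <- decay_presets()
  for (seed in 1:25) {
    inst <- random_instance(n_bg = sample(3:20, 1), n_fac = sample(1:5, 1),
                            seed = seed)
    for (nm in names(specs)) {
      got <- suppressMessages(
        two_step_fca(inst$tt, inst$s, inst$p, specs[[nm]]))$score
      want <- oracle_2sfca(inst$tt, inst$s, inst$p,
                           function(t) decay_weight(t, specs[[nm]]))
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("population-weighted scores conserve total supply (unweighted, scale 1)", {
  for (seed in 1:20) {
    inst <- random_instance(n_bg = 15, n_fac = 4, seed = 100 + seed)
    a <- suppressMessages(
      two_step_fca(inst$tt, inst$s, inst$p, decay_spec("none"), scale = 1))
    reachable <- colSums(inst$tt <= 30) > 0
    expect_equal(sum(inst$p * a$score), sum(inst$s[reachable]),
                 tolerance = 1e-9)
  }
})

test_that("zonal weights of 1 reproduce the unweighted scores exactly", {
  inst <- random_instance(12, 4, seed = 5)
  all_one <- decay_spec("zonal", zone_width = 10, weights = c(1, 1, 1))
  expect_identical(
    suppressMessages(two_step_fca(inst$tt, inst$s, inst$p, all_one))$score,
    suppressMessages(two_step_fca(inst$tt, inst$s, inst$p,
                                  decay_spec("none")))$score)
})

test_that("incrementing a facility's supply never decreases downstream scores", {
  inst <- random_instance(15, 5, seed = 9)
  base <- suppressMessages(
    two_step_fca(inst$tt, inst$s, inst$p, decay_spec("none")))$score
  for (j in 1:5) {
    s2 <- inst$s
    s2[j] <- s2[j] + 1
    upd <- suppressMessages(
      two_step_fca(inst$tt, s2, inst$p, decay_spec("none")))$score
    shares <- inst$tt[, j] <= 30
    expect_true(all(upd[shares] >= base[shares] - 1e-12))
    expect_equal(upd[!shares], base[!shares], tolerance = 1e-12)
  }
})

test_that("facilities with empty catchments contribute nothing", {
  tt <- matrix(c(5, 45), nrow = 1, dimnames = list("b", c("f1", "f2")))
  expect_message(
    a <- two_step_fca(tt, c(f1 = 1, f2 = 9), c(b = 100), decay_spec("none")),
    "empty catchment")
  expect_equal(a$score, 1e4 / 100)
})

test_that("multi-year averaging is an element-wise mean and checks alignment", {
  t1 <- tibble::tibble(bg_id = c("a", "b"), dst = c(3, 4), des = c(10, 20),
                       sau = c(1, 2))
  t2 <- tibble::tibble(bg_id = c("a", "b"), dst = c(3, 4), des = c(20, 40),
                       sau = c(3, 6))
  avg <- multi_year_average(list(t1, t2))
  expect_equal(avg$des, c(15, 30))
  expect_equal(avg$sau, c(2, 4))
  expect_equal(avg$dst, c(3, 4))                      # passed through
  expect_equal(multi_year_average(list(t1, t1)), t1)  # idempotent

  yearly <- lapply(1:5, function(i) {
    tibble::tibble(bg_id = c("a", "b"),
                   des = runif(2), sau = runif(2))
  })
  avg5 <- multi_year_average(yearly)
  brute <- rowMeans(sapply(yearly, function(t) t$des))
  expect_equal(avg5$des, unname(brute))

  bad <- tibble::tibble(bg_id = c("b", "a"), dst = c(4, 3), des = c(1, 1),
                        sau = c(1, 1))
  expect_error(multi_year_average(list(t1, bad)), "misaligned")
})

test_that("compute_all_measures composes the nine columns from its parts", {
  inst <- random_instance(15, 5, seed = 21)
  machines_by_year <- dplyr::bind_rows(lapply(1:3, function(yr) {
    tibble::tibble(facility_id = names(inst$s), year = yr,
                   machines = unname(inst$s) + (yr - 2))
  }))
  machines_by_year$machines <- pmax(1, machines_by_year$machines)
  pops <- tibble::tibble(bg_id = names(inst$p), pop_women40 = unname(inst$p))
  acc <- suppressMessages(
    compute_all_measures(inst$tt, machines_by_year, pops))
  expect_named(acc, c("bg_id", measure_names()))
  expect_true(all(vapply(acc[measure_names()],
                         function(v) all(v >= 0), logical(1))))

  # sau column equals the mean over years of the unweighted scores
  per_year <- sapply(1:3, function(yr) {
    m <- dplyr::filter(machines_by_year, year == yr)
    suppressMessages(
      two_step_fca(inst$tt, m, pops, decay_spec("none")))$score
  })
  expect_equal(acc$sau, unname(rowMeans(per_year)), tolerance = 1e-12)

  # triple-loop oracle for every floating-catchment column
  specs <- decay_presets()
  for (nm in names(specs)) {
    want <- rowMeans(sapply(1:3, function(yr) {
      m <- dplyr::filter(machines_by_year, year == yr)
      s <- stats::setNames(m$machines, m$facility_id)[colnames(inst$tt)]
      oracle_2sfca(inst$tt, s, inst$p,
                   function(t) decay_weight(t, specs[[nm]]))
    }))
    expect_equal(acc[[tolower(nm)]], unname(want), tolerance = 1e-12)
  }
})
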