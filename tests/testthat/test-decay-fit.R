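test_that("profile fit solves the constrained least squares exactly", {
  # noiseless 3-point series: exact interior solution, R^2 = 1
  s <- make_series(0.1, 1000, 500, c(0, 10, 20))
  f <- profile_fit(0.1, s)
  expect_equal(f$a1, 1000, tolerance = 1e-9)
  expect_equal(f$e1, 500, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  # zero-variance series is a degenerate fit
  expect_error(profile_fit(0.1, data.frame(day = c(0, 7, 14), alc = rep(800, 3))),
               "degenerate")

  # active plateau constraint: unconstrained e1 would go negative
  s <- data.frame(day = c(0, 20, 40), alc = c(1000, 10, 1))
  f <- profile_fit(0.2, s, e1_floor = 1)
  o <- oracle_profile(0.2, s$day, s$alc, e1_floor = 1)
  expect_equal(f$e1, 1)
  expect_equal(f$a1, o$a1, tolerance = 1e-6)
  expect_equal(f$r_squared, o$r_squared, tolerance = 1e-9)
})

test_that("constrained solutions match the optimisation oracle on random series", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    day <- sort(sample(0:56, n))
    y <- rlnorm(n, log(800 * exp(-0.05 * day) + 100), 0.5)
    alpha <- runif(1, 0.01, 0.2)
    f <- profile_fit(alpha, data.frame(day = day, alc = y))
    o <- oracle_profile(alpha, day, y)
    expect_equal(f$r_squared, o$r_squared, tolerance = 1e-7)
    expect_gte(f$a1, 0)
    expect_gte(f$e1, 1)
  }
})

test_that("grid selection recovers noiseless parameters on the grid", {
  days <- c(0, 3, 7, 10, 14, 17, 21, 24, 28, 31, 35)
  s <- make_series(0.10, 1500, 200, days)
  f <- fit_alpha(s)
  expect_equal(unname(coef(f)["alpha"]), 0.10, tolerance = 5e-4)
  expect_gte(f$r_squared, 0.999)
  # exact recovery at a grid alpha, tolerance 1e-6
  expect_equal(unname(coef(f)["a1"]), 1500, tolerance = 1e-3)
  expect_equal(unname(coef(f)["e1"]), 200, tolerance = 1e-3)
  # a2 identity holds exactly
  expect_identical(unname(coef(f)["a2"]),
                   unname(coef(f)["a1"] + coef(f)["e1"]))
})

test_that("selected rate is the lowest among the top candidates and within bounds", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    day <- sort(sample(0:56, n))
    y <- rlnorm(n, log(1200 * exp(-0.08 * day) + 150), 0.3)
    f <- fit_alpha(data.frame(day = day, alc = y))
    tied <- f$candidates$r_squared >= f$candidates$r_squared[1] - 1e-6
    expect_equal(unname(coef(f)["alpha"]), min(f$candidates$alpha[tied]))
    expect_gte(unname(coef(f)["alpha"]), 0.01)
    expect_lte(unname(coef(f)["alpha"]), 0.2)
    expect_equal(nrow(f$candidates), 10L)
  }
  # flat R^2 profile (2 informative points, curve plateaued at the 2nd):
  # many candidates fit equally well; the rule resolves to the smallest rate
  s <- data.frame(day = c(0, 55, 56), alc = c(1500, 200, 200))
  f <- fit_alpha(s)
  top <- f$candidates
  tied <- abs(top$r_squared - top$r_squared[1]) < 1e-6
  expect_gt(sum(tied), 1)           # genuinely flat across several candidates
  expect_equal(unname(coef(f)["alpha"]), min(top$alpha[tied]))
})

test_that("prediction follows the curve and its asymptotes", {
  s <- make_series(0.1, 1000, 500, c(0, 5, 10, 20, 30))
  f <- fit_alpha(s)
  expect_equal(predict(f, 0), unname(coef(f)["a2"]))
  expect_equal(predict(f, 10), 1000 * exp(-1) + 500, tolerance = 1e-3)
  expect_equal(predict(f, 1e6), unname(coef(f)["e1"]), tolerance = 1e-6)
  # strictly decreasing, bounded below by the plateau
  tt <- seq(0, 100, by = 0.5)
  p <- predict(f, tt)
  expect_true(all(diff(p) < 0))
  expect_true(all(p >= unname(coef(f)["e1"])))
  expect_error(predict(f, -1))
})

test_that("rescaling counts rescales amplitudes but not rate or R^2", {
  set.seed(3)
  day <- c(0, 7, 14, 21, 28, 42)
  y <- rlnorm(6, log(1400 * exp(-0.09 * day) + 180), 0.1)
  f1 <- fit_alpha(data.frame(day = day, alc = y))
  k <- 3.7
  f2 <- fit_alpha(data.frame(day = day, alc = k * y),
                  fit_config(e1_floor = k))   # floor scales with the data
  expect_equal(unname(coef(f2)["alpha"]), unname(coef(f1)["alpha"]))
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-9)
  expect_equal(unname(coef(f2)[c("a1", "e1", "a2")]),
               k * unname(coef(f1)[c("a1", "e1", "a2")]), tolerance = 1e-6)
})

test_that("cohort fitting tolerates degenerate patients and summarises", {
  sim <- simulate_cohort(sim_config(n_patients = 5, seed = 2))
  co <- sim$cohort
  # inject a flat series
  flat <- data.frame(patient_id = "FLAT", day = c(0, 7, 14), alc = rep(900, 3))
  co$alc <- rbind(co$alc, flat)
  extra <- co$clinical[1, ]
  extra$patient_id <- "FLAT"
  co$clinical <- rbind(co$clinical, extra)
  f <- fit_cohort(co)
  expect_equal(nrow(f$table), 6L)
  expect_match(f$table$flag[f$table$patient_id == "FLAT"], "degenerate")
  expect_true(all(f$table$flag[f$table$patient_id != "FLAT"] == ""))
  expect_true(is.null(f$fits[["FLAT"]]))
  # single-patient cohort
  sim1 <- simulate_cohort(sim_config(n_patients = 1, seed = 5))
  f1 <- fit_cohort(sim1$cohort)
  expect_equal(nrow(f1$table), 1L)
})
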