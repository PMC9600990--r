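test_that("the generator is deterministic under a fixed config", {
  cfg <- sim_config(n_patients = 20, seed = 99)
  s1 <- simulate_cohort(cfg, expression = TRUE)
  s2 <- simulate_cohort(cfg, expression = TRUE)
  expect_identical(s1$cohort$clinical, s2$cohort$clinical)
  expect_identical(s1$cohort$alc, s2$cohort$alc)
  expect_identical(s1$counts, s2$counts)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_cohort(cfg, write_dir = d1)
  simulate_cohort(cfg, write_dir = d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("noiseless series lie on the curve; noisy ones recover it", {
  cfg <- sim_config(noise_cv = 0, seed = 3)
  set.seed(3)
  s <- simulate_alc_series(cfg, alpha = 0.08, a1 = 1500, e1 = 150, n_meas = 8)
  expect_equal(s$alc, 1500 * exp(-0.08 * s$day) + 150, tolerance = 1e-3)
  expect_true(all(diff(s$day) > 0))

  # recovery at the study noise level: median absolute rate error < 0.02/day
  sim <- simulate_cohort(sim_config(n_patients = 200, seed = 31))
  ft <- fit_cohort(sim$cohort)$table
  err <- abs(ft$alpha - sim$truth$alpha_true[match(ft$patient_id,
                                                  sim$truth$patient_id)])
  expect_lt(median(err, na.rm = TRUE), 0.02)
})

test_that("marginal distributions sit at their clinical anchors", {
  sim <- simulate_cohort(sim_config(n_patients = 2000, seed = 4))
  clin <- sim$cohort$clinical
  expect_gt(median(sim$truth$alpha_true), 0.07)
  expect_lt(median(sim$truth$alpha_true), 0.09)
  expect_gt(median(clin$nlr), 2.2)
  expect_lt(median(clin$nlr), 2.7)
  n_meas <- as.integer(table(sim$cohort$alc$patient_id))
  expect_true(all(n_meas >= 3 & n_meas <= 18))
  expect_true(abs(median(n_meas) - 5) <= 1)
})

test_that("rate estimation error shrinks with cleaner, denser series", {
  med_err <- function(noise_cv, lambda, seed = 77) {
    sim <- simulate_cohort(sim_config(n_patients = 80, seed = seed,
                                      noise_cv = noise_cv,
                                      n_meas_lambda = lambda))
    ft <- fit_cohort(sim$cohort)$table
    median(abs(ft$alpha - sim$truth$alpha_true[match(ft$patient_id,
                                                     sim$truth$patient_id)]),
           na.rm = TRUE)
  }
  noise_grid <- c(0.02, 0.10, 0.30)
  errs_noise <- vapply(noise_grid, med_err, numeric(1), lambda = 4)
  expect_true(all(diff(errs_noise) > 0))
  dens_grid <- c(1, 5, 12)
  errs_dens <- vapply(dens_grid, function(l) med_err(0.15, l), numeric(1))
  expect_true(all(diff(errs_dens) < 0))
})

test_that("survival generation respects its hazard structure", {
  # all hazards zero: everyone censored
  cfg <- sim_config(n_patients = 50, seed = 6, h_early = 0, h_late = 0)
  set.seed(6)
  out <- simulate_outcomes(cfg, alpha = rlnorm(50, log(0.08), 0.5),
                           nlr = rlnorm(50, log(2.4), 0.6))
  expect_true(all(out$dsd == 0))
  expect_true(all(is.na(out$time_to_dsd_months)))
  expect_true(all(out$followup_months >= cfg$censor_min - 1e-9))

  # single-group constant hazard, no multipliers: KM tracks exp(-h t)
  h <- 0.02
  cfg <- sim_config(n_patients = 1000, seed = 8, h_early = h, h_late = h,
                    hr_low_alpha_early = 1, hr_high_nlr_early = 1,
                    hr_high_alpha_late = 1, censor_min = 96, censor_max = 96)
  set.seed(8)
  out <- simulate_outcomes(cfg, alpha = rlnorm(1000, log(0.08), 0.5),
                           nlr = rlnorm(1000, log(2.4), 0.6))
  cv <- km_estimate(out$followup_months, out$dsd)
  for (tq in c(12, 30, 60)) {
    s_hat <- km_at(cv, tq)
    s_true <- exp(-h * tq)
    se <- sqrt(s_true * (1 - s_true) / 1000)
    expect_lt(abs(s_hat - s_true), 3 * se + 0.01)
  }

  # event times never exceed follow-up; progression precedes death
  sim <- simulate_cohort(sim_config(n_patients = 300, seed = 13))
  clin <- sim$cohort$clinical
  dsd <- clin$dsd == 1
  expect_true(all(clin$time_to_dsd_months[dsd] <= clin$followup_months[dsd]))
  both <- dsd & clin$progression != "none"
  expect_true(all(clin$time_to_progression_months[both] <=
                    clin$time_to_dsd_months[both]))
})

test_that("planted expression signal is recoverable and nulls are calibrated", {
  cfg <- sim_config(n_patients = 39, seed = 19, n_genes = 200)
  sim <- simulate_cohort(cfg, expression = TRUE)
  clin <- sim$cohort$clinical
  flt <- filter_detected(sim$counts)
  fc <- paired_log2fc(flt$counts, sim$samples)
  idx <- match(colnames(fc), sim$truth$patient_id)
  screen <- correlation_screen(fc, sim$truth$alpha_true[idx],
                               clin$nlr[match(colnames(fc), clin$patient_id)],
                               clin$dsd[match(colnames(fc), clin$patient_id)])
  planted_alpha <- sim$planted$gene[sim$planted$covariate == "alpha"]
  hits <- screen$selected[screen$gene %in% planted_alpha]
  expect_gte(mean(hits), 0.75)

  # near-Poisson limit: variance/mean ratio of null-gene counts approaches 1
  cfg0 <- sim_config(n_patients = 60, seed = 23, n_genes = 100,
                     nb_dispersion = 1e-4, effect_slope = 0,
                     patient_effect_sd = 0)
  set.seed(23)
  expr <- simulate_expression(cfg0, alpha = rlnorm(60, log(0.08), 0.5),
                              nlr = rlnorm(60, log(2.4), 0.6))
  ctrl <- expr$counts[, expr$samples$role == "control"]
  # remove library-size variation before the dispersion check
  cpm <- sweep(ctrl, 2, colSums(ctrl), "/") * mean(colSums(ctrl))
  ratio <- apply(cpm, 1, var) / rowMeans(cpm)
  expect_lt(median(ratio), 2)
})
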