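#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate a chemoradiotherapy cervical-cancer cohort: the decay
#' rate, amplitude, plateau, NLR and measurement-count distributions are
#' anchored to the marginal medians and interquartile ranges such cohorts
#' report (decay rate median 0.08/day, IQR ~[0.055, 0.11]; plateau median
#' ~144 cells/uL; NLR median ~2.43; 3-18 counts per patient, median 5
#' over ~8 weeks). Survival is piecewise-exponential around the 30-month
#' split: before it, low decay rate and high NLR multiply the hazard;
#' after it, a high decay rate multiplies the hazard — the qualitative
#' reversal the endpoint framework is designed to detect. Expression is
#' negative-binomial with planted genes whose fold change loads on the
#' covariate z-scores plus a shared per-patient response factor.
#'
#' @param n_patients cohort size.
#' @param seed RNG seed; a fixed config reproduces the cohort exactly.
#' @param alpha_meanlog,alpha_sdlog log-normal decay-rate distribution (1/day).
#' @param a1_meanlog,a1_sdlog log-normal amplitude distribution (cells/uL).
#' @param e1_meanlog,e1_sdlog log-normal plateau distribution (cells/uL).
#' @param n_meas_lambda Poisson rate of extra measurements beyond 3
#'   (count capped at 18).
#' @param schedule_max_day last scheduled day of measurement.
#' @param schedule_jitter uniform jitter (days) around weekly draws.
#' @param noise_cv coefficient of variation of multiplicative log-normal
#'   measurement noise.
#' @param nlr_meanlog,nlr_sdlog log-normal NLR distribution.
#' @param pre_alc_cv log-scale noise linking reported pre-treatment ALC to
#'   the true curve value at day 0.
#' @param h_early,h_late baseline monthly hazards of disease-specific
#'   death before/after `split_months`.
#' @param hr_low_alpha_early hazard multiplier before the split for
#'   below-median decay rate.
#' @param hr_high_nlr_early hazard multiplier before the split for
#'   at-or-above-median NLR.
#' @param hr_high_alpha_late hazard multiplier after the split for
#'   at-or-above-median decay rate.
#' @param split_months boundary between the early and late hazard regimes.
#' @param censor_min,censor_max administrative censoring, uniform (months
#'   from end of treatment).
#' @param prog_frac_nodsd fraction of non-dying patients with progression.
#' @param prog_type_probs probabilities of LP, DM, LP+DM among progressors.
#' @param n_genes,n_planted_alpha,n_planted_nlr expression panel sizes.
#' @param effect_slope planted log2FC per covariate z-score unit.
#' @param patient_effect_sd sd of the shared per-patient fold-change
#'   response factor carried by planted genes.
#' @param nb_dispersion negative-binomial dispersion of counts.
#' @param mean_depth target library size.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 323, seed = 1,
                       alpha_meanlog = log(0.08), alpha_sdlog = 0.51,
                       a1_meanlog = log(1485), a1_sdlog = 0.40,
                       e1_meanlog = log(144), e1_sdlog = 1.0,
                       n_meas_lambda = 2, schedule_max_day = 56,
                       schedule_jitter = 2, noise_cv = 0.10,
                       nlr_meanlog = log(2.43), nlr_sdlog = 0.64,
                       pre_alc_cv = 0.20,
                       h_early = 0.0017, h_late = 0.0014,
                       hr_low_alpha_early = 2.5, hr_high_nlr_early = 2.5,
                       hr_high_alpha_late = 3.0, split_months = 30,
                       censor_min = 30, censor_max = 96,
                       prog_frac_nodsd = 0.12,
                       prog_type_probs = c(LP = 0.23, DM = 0.55, `LP+DM` = 0.22),
                       n_genes = 500, n_planted_alpha = 4, n_planted_nlr = 4,
                       effect_slope = 0.8, patient_effect_sd = 0.7,
                       nb_dispersion = 0.2, mean_depth = 2e5) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_patients >= 1, cfg$noise_cv >= 0, cfg$h_early >= 0,
            cfg$h_late >= 0, cfg$split_months > 0, cfg$nb_dispersion > 0,
            cfg$censor_min <= cfg$censor_max,
            cfg$n_planted_alpha + cfg$n_planted_nlr <= cfg$n_genes)
  structure(cfg, class = "sim_config")
}

#' Simulate one patient's serial lymphocyte counts
#'
#' Values follow `a1*exp(-alpha*day) + e1` with multiplicative log-normal
#' noise (mean-one), truncated below at 1 cell/uL. Measurement days are
#' weekly draws with jitter over the schedule window; with more than nine
#' measurements extra days are drawn uniformly. Uses the current RNG
#' stream.
#'
#' @param config a [sim_config()].
#' @param alpha,a1,e1 true curve parameters for this patient.
#' @param n_meas number of measurements (at least 3).
#' @return data frame with `day` (sorted, distinct) and `alc`.
#' @export
simulate_alc_series <- function(config, alpha, a1, e1, n_meas) {
  stopifnot(n_meas >= 3)
  weeks <- seq(0, config$schedule_max_day, by = 7)
  repeat {
    base <- sample(weeks, min(n_meas, length(weeks)))
    extra <- if (n_meas > length(weeks))
      stats::runif(n_meas - length(weeks), 0, config$schedule_max_day) else numeric(0)
    day <- c(base + stats::runif(length(base), -config$schedule_jitter,
                                 config$schedule_jitter), extra)
    day <- sort(unique(pmax(0, round(day))))
    if (length(day) >= min(n_meas, 3)) break
  }
  mu <- a1 * exp(-alpha * day) + e1
  if (config$noise_cv > 0) {
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    mu <- mu * stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog)
  }
  # 0.001 cells/uL resolution keeps CSV round-trips exact without
  # perturbing noiseless series beyond numerical tolerance
  data.frame(day = day, alc = pmax(1, round(mu, 3)))
}

#' Simulate survival outcomes from a piecewise-exponential hazard
#'
#' Before `split_months` the death hazard is `h_early` multiplied by
#' `hr_low_alpha_early` for below-median decay rates and by
#' `hr_high_nlr_early` for at-or-above-median NLR; after the split it is
#' `h_late` multiplied by `hr_high_alpha_late` for at-or-above-median
#' decay rates. Administrative censoring is uniform on
#' `[censor_min, censor_max]`. Dying patients receive a progression time
#' drawn as a Beta(2,3) fraction of the death time; a `prog_frac_nodsd`
#' share of the others progress at a uniform time before censoring. Uses
#' the current RNG stream.
#'
#' @param config a [sim_config()].
#' @param alpha,nlr per-patient covariates (medians are taken within the
#'   simulated sample).
#' @return data frame with `followup_months`, `dsd`,
#'   `time_to_dsd_months`, `progression`, `time_to_progression_months`.
#' @export
simulate_outcomes <- function(config, alpha, nlr) {
  n <- length(alpha)
  stopifnot(length(nlr) == n)
  low_alpha <- alpha < stats::median(alpha)
  high_nlr <- nlr >= stats::median(nlr)
  high_alpha <- !low_alpha
  he <- config$h_early * config$hr_low_alpha_early^low_alpha *
    config$hr_high_nlr_early^high_nlr
  hl <- config$h_late * config$hr_high_alpha_late^high_alpha
  E <- stats::rexp(n)
  brk <- he * config$split_months
  t_dsd <- ifelse(E < brk, E / he,
                  config$split_months + (E - brk) / hl)
  t_dsd[he == 0 & hl == 0] <- Inf
  cens <- stats::runif(n, config$censor_min, config$censor_max)
  dsd <- as.integer(t_dsd <= cens)
  fup <- round(ifelse(dsd == 1, t_dsd, cens), 1)
  t_dsd_obs <- ifelse(dsd == 1, fup, NA_real_)

  prog <- rep("none", n)
  t_prog <- rep(NA_real_, n)
  died <- dsd == 1
  t_prog[died] <- round(pmax(0.5, t_dsd_obs[died] * stats::rbeta(sum(died), 2, 3)), 1)
  t_prog[died] <- pmin(t_prog[died], t_dsd_obs[died])
  other <- which(!died)
  picks <- other[stats::runif(length(other)) < config$prog_frac_nodsd]
  t_prog[picks] <- round(stats::runif(length(picks), 1, pmax(1.5, fup[picks])), 1)
  t_prog[picks] <- pmin(t_prog[picks], fup[picks])
  has_prog <- !is.na(t_prog)
  prog[has_prog] <- sample(names(config$prog_type_probs), sum(has_prog),
                           replace = TRUE, prob = config$prog_type_probs)
  data.frame(followup_months = fup, dsd = dsd,
             time_to_dsd_months = t_dsd_obs, progression = prog,
             time_to_progression_months = t_prog,
             stringsAsFactors = FALSE)
}

#' Simulate a paired exosomal read-count matrix with planted genes
#'
#' Control counts are negative-binomial draws around log-normal gene
#' baselines scaled to the target depth. Treatment counts shift each
#' planted gene's mean by a true log2 fold change equal to `effect_slope`
#' times the z-score (log scale) of its covariate, plus a per-patient
#' shared response factor common to all planted genes; null genes have
#' zero true fold change. Uses the current RNG stream.
#'
#' @param config a [sim_config()].
#' @param alpha,nlr per-patient covariates.
#' @param patient_ids identifiers for the columns.
#' @return list with `counts` (genes x 2n matrix), `samples` (sample
#'   sheet) and `planted` (data frame `gene`, `covariate`, `effect`).
#' @export
simulate_expression <- function(config, alpha, nlr,
                                patient_ids = paste0("P", seq_along(alpha))) {
  n <- length(alpha)
  g <- config$n_genes
  genes <- sprintf("G%04d", seq_len(g))
  ia <- seq_len(config$n_planted_alpha)
  inl <- config$n_planted_alpha + seq_len(config$n_planted_nlr)
  z <- function(x) as.numeric(scale(log(x)))
  fc_true <- matrix(0, g, n)
  m <- stats::rnorm(n, 0, config$patient_effect_sd)
  if (length(ia))
    fc_true[ia, ] <- config$effect_slope * matrix(z(alpha), length(ia), n,
                                                  byrow = TRUE) +
      matrix(m, length(ia), n, byrow = TRUE)
  if (length(inl))
    fc_true[inl, ] <- config$effect_slope * matrix(z(nlr), length(inl), n,
                                                   byrow = TRUE) +
      matrix(m, length(inl), n, byrow = TRUE)
  base <- stats::rlnorm(g, log(100), 1.2)
  base <- base * config$mean_depth / sum(base)
  size <- 1 / config$nb_dispersion
  lib <- function() stats::rlnorm(n, 0, 0.2)
  mu_c <- outer(base, lib())
  mu_t <- outer(base, rep(1, n)) * 2^fc_true * rep(lib(), each = g)
  counts_c <- matrix(stats::rnbinom(g * n, mu = mu_c, size = size), g, n)
  counts_t <- matrix(stats::rnbinom(g * n, mu = mu_t, size = size), g, n)
  counts <- cbind(counts_c, counts_t)
  rownames(counts) <- genes
  colnames(counts) <- c(paste0(patient_ids, "_C"), paste0(patient_ids, "_T"))
  samples <- data.frame(
    sample_id = colnames(counts),
    patient_id = rep(patient_ids, 2),
    role = rep(c("control", "treatment"), each = n),
    stringsAsFactors = FALSE)
  planted <- data.frame(
    gene = genes[c(ia, inl)],
    covariate = c(rep("alpha", length(ia)), rep("nlr", length(inl))),
    effect = rep(config$effect_slope, length(ia) + length(inl)),
    stringsAsFactors = FALSE)
  list(counts = counts, samples = samples, planted = planted)
}

#' Simulate a complete cohort with known ground truth
#'
#' Composes the series, outcome and (optionally) expression generators
#' under a single seeded stream, builds a validated cohort object, and
#' optionally writes all interface files (`clinical.csv`, `alc.csv`,
#' `counts.tsv`, `samples.csv`, `truth_registry.csv`,
#' `planted_genes.csv`) to a directory.
#'
#' @param config a [sim_config()].
#' @param expression also simulate the paired count matrix.
#' @param write_dir optional output directory.
#' @return list with `cohort` (an `alc_cohort`), `truth` (data frame
#'   `patient_id`, `alpha_true`, `a1_true`, `e1_true`), and, when
#'   requested, `counts`, `samples`, `planted`.
#' @export
simulate_cohort <- function(config = sim_config(), expression = FALSE,
                            write_dir = NULL) {
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%04d", seq_len(n))
  alpha <- stats::rlnorm(n, config$alpha_meanlog, config$alpha_sdlog)
  a1 <- stats::rlnorm(n, config$a1_meanlog, config$a1_sdlog)
  e1 <- stats::rlnorm(n, config$e1_meanlog, config$e1_sdlog)
  n_meas <- pmin(18L, 3L + stats::rpois(n, config$n_meas_lambda))
  nlr <- round(stats::rlnorm(n, config$nlr_meanlog, config$nlr_sdlog), 2)

  alc <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- simulate_alc_series(config, alpha[i], a1[i], e1[i], n_meas[i])
    data.frame(patient_id = ids[i], s, stringsAsFactors = FALSE)
  }))

  outcomes <- simulate_outcomes(config, alpha, nlr)
  pre_alc <- round((a1 + e1) *
                     stats::rlnorm(n, 0, sqrt(log(1 + config$pre_alc_cv^2))))
  clinical <- data.frame(
    patient_id = ids,
    age = pmax(20, pmin(90, round(stats::rnorm(n, 57, 15)))),
    pathology = sample(c("squamous", "adenocarcinoma", "adenosquamous",
                         "carcinoma"), n, replace = TRUE,
                       prob = c(0.892, 0.062, 0.037, 0.009)),
    figo_stage = sample(c("IB-IIB", "IIIA-IIIC1", "IIIC2-IVB"), n,
                        replace = TRUE, prob = c(0.266, 0.588, 0.146)),
    rt_field = sample(c("pelvis", "pelvis+PALN"), n, replace = TRUE,
                      prob = c(0.805, 0.195)),
    ot_days = round(stats::rlnorm(n, log(53), 0.086)),
    td_eqd2 = round(stats::rlnorm(n, log(70.2), 0.027), 1),
    pre_alc = pre_alc,
    nlr = nlr,
    outcomes,
    stringsAsFactors = FALSE)

  cohort <- as_cohort(clinical, alc)
  truth <- data.frame(patient_id = ids, alpha_true = alpha, a1_true = a1,
                      e1_true = e1, stringsAsFactors = FALSE)
  out <- list(cohort = cohort, truth = truth, config = config)

  if (expression) {
    keep <- cohort$clinical$patient_id
    idx <- match(keep, ids)
    expr <- simulate_expression(config, alpha[idx], nlr[idx],
                                patient_ids = keep)
    out <- c(out, expr)
  }

  if (!is.null(write_dir)) {
    dir.create(write_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(write_dir, f)
    write_cohort(cohort, p("clinical.csv"), p("alc.csv"))
    utils::write.csv(truth, p("truth_registry.csv"), row.names = FALSE)
    if (nrow(cohort$exclusions))
      utils::write.csv(cohort$exclusions, p("exclusions.csv"), row.names = FALSE)
    if (expression) {
      utils::write.table(data.frame(gene = rownames(out$counts), out$counts,
                                    check.names = FALSE),
                         p("counts.tsv"), sep = "\t", row.names = FALSE,
                         quote = FALSE)
      utils::write.csv(out$samples, p("samples.csv"), row.names = FALSE)
      utils::write.csv(out$planted, p("planted_genes.csv"), row.names = FALSE)
    }
  }
  out
}
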