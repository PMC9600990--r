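#' Configuration of a full pipeline run
#'
#' Thresholds that clinical studies fix from cohort medians default to
#' `"median"`; fixed constants (for example decay rate 0.08 and NLR 2.43,
#' or 0.07 / 2.72 for a smaller expression cohort) can be supplied to
#' replicate a published stratification.
#'
#' @param clinical_path,alc_path cohort CSV inputs (see [read_cohort()]).
#' @param counts_path,samples_path optional paired count matrix inputs
#'   (see [read_counts()]); enables the exosome arm.
#' @param out_dir output directory for the report bundle.
#' @param fit a [fit_config()].
#' @param split_months endpoint split (months) or `"auto"`.
#' @param alpha_threshold,nlr_threshold `"median"` or fixed constants.
#' @param screen_p_threshold significance level of the correlation screen.
#' @param max_k best-subset size cap.
#' @param max_candidates cap on screened genes entering the exhaustive
#'   subset search (strongest associations kept), keeping the enumeration
#'   tractable.
#' @param seed RNG seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @return list of class `run_config`.
#' @export
run_config <- function(clinical_path, alc_path, counts_path = NULL,
                       samples_path = NULL, out_dir = "alcslope_run",
                       fit = fit_config(), split_months = 30,
                       alpha_threshold = "median", nlr_threshold = "median",
                       screen_p_threshold = 0.05, max_k = 15,
                       max_candidates = 15, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Reads and validates the cohort, median-imputes `pre_alc`/`nlr`, fits
#' the decay model per patient, builds the four survival endpoints,
#' compares the two decay-rate groups, runs Kaplan-Meier/log-rank analyses
#' and AIC-backward Cox models per endpoint, and (when count inputs are
#' configured) the exosome arm. All tables are written as CSVs into
#' `out_dir` together with a run log (package version, configuration
#' hash, seed).
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with all result tables.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  exo_enabled <- !is.null(config$counts_path)
  if (exo_enabled && (is.null(config$samples_path) ||
                      !file.exists(config$counts_path)))
    stop("configuration error: exosome arm enabled but counts matrix or ",
         "sample sheet is missing")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  stage <- "read_cohort"
  res <- tryCatch({
    cohort <- read_cohort(config$clinical_path, config$alc_path)
    if (nrow(cohort$exclusions))
      utils::write.csv(cohort$exclusions, p("exclusions.csv"), row.names = FALSE)
    cohort <- impute_median(cohort)$cohort

    stage <- "fit_cohort"
    fits <- fit_cohort(cohort, config$fit)
    utils::write.csv(fits$table, p("fits.csv"), row.names = FALSE)
    ok <- fits$table$flag == ""
    clin <- cohort$clinical[ok, , drop = FALSE]
    ftab <- fits$table[ok, , drop = FALSE]

    stage <- "endpoints"
    sp <- split_dsd(clin, config$split_months)
    endpoints <- lapply(c(dss = "dss", dss_a = "dss_a", dss_na = "dss_na",
                          pfs = "pfs"), function(k)
      build_endpoints(clin, sp$labels, k, threshold = sp$threshold))
    ep_all <- do.call(rbind, endpoints)
    utils::write.csv(ep_all, p("endpoints.csv"), row.names = FALSE)

    stage <- "survival"
    grp_alpha <- dichotomize(ftab$alpha, config$alpha_threshold)
    grp_nlr <- dichotomize(clin$nlr, config$nlr_threshold)
    in_clin <- cohort$alc$patient_id %in% clin$patient_id
    clin$min_alc <- vapply(split(cohort$alc[in_clin, c("day", "alc")],
                                 factor(cohort$alc$patient_id[in_clin],
                                        levels = clin$patient_id)),
                           derive_min_alc, numeric(1))
    cmp_data <- data.frame(age = clin$age, pathology = clin$pathology,
                           figo_stage = clin$figo_stage,
                           rt_field = clin$rt_field, ot_days = clin$ot_days,
                           td_eqd2 = clin$td_eqd2, pre_alc = clin$pre_alc,
                           min_alc = clin$min_alc, nlr = clin$nlr,
                           a2 = ftab$a2, e1 = ftab$e1)
    comparison <- group_compare(cmp_data, grp_alpha$labels)
    utils::write.csv(comparison, p("group_comparison.csv"), row.names = FALSE)

    km_rows <- list(); lr_rows <- list(); cox_rows <- list(); cox_fail <- list()
    covars <- data.frame(
      low_alpha = as.integer(grp_alpha$labels == "low"),
      high_nlr = as.integer(grp_nlr$labels == "high"),
      non_squamous = as.integer(clin$pathology != "squamous"),
      figo_stage = clin$figo_stage, age = clin$age)
    for (k in names(endpoints)) {
      ep <- endpoints[[k]]
      for (gname in c("alpha", "nlr")) {
        g <- if (gname == "alpha") grp_alpha$labels else grp_nlr$labels
        for (lv in levels(g)) {
          if (!any(g == lv)) next
          cv <- km_estimate(ep$time[g == lv], ep$event[g == lv])
          if (length(cv$time) == 0L) next   # no events in this group
          km_rows[[length(km_rows) + 1L]] <- data.frame(
            endpoint = k, group = paste0(gname, "_", lv), time = cv$time,
            survival = cv$survival, at_risk = cv$at_risk, events = cv$events)
        }
        lr <- logrank_test(ep$time, ep$event, g)
        lr_rows[[length(lr_rows) + 1L]] <- data.frame(
          endpoint = k, group = gname, statistic = lr$statistic,
          p = lr$p_value)
      }
      if (sum(ep$event) >= 5) {
        # sparse endpoints can separate on a rare covariate; record the
        # failed model and keep the run going
        cx <- tryCatch(cox_backward(covars, ep$time, ep$event, names(covars)),
                       error = function(e) e)
        if (inherits(cx, "error")) {
          cox_fail[[length(cox_fail) + 1L]] <- data.frame(
            endpoint = k, error = conditionMessage(cx))
        } else if (nrow(cx$terms)) {
          cox_rows[[length(cox_rows) + 1L]] <- data.frame(endpoint = k,
                                                          cx$terms,
                                                          aic = cx$aic)
        }
      }
    }
    utils::write.csv(do.call(rbind, km_rows), p("km_curves.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, lr_rows), p("logrank.csv"),
                     row.names = FALSE)
    if (length(cox_rows))
      utils::write.csv(do.call(rbind, cox_rows), p("cox_models.csv"),
                       row.names = FALSE)
    if (length(cox_fail))
      utils::write.csv(do.call(rbind, cox_fail), p("cox_failures.csv"),
                       row.names = FALSE)

    exo <- NULL
    if (exo_enabled) {
      stage <- "exosome"
      cm <- read_counts(config$counts_path, config$samples_path)
      flt <- filter_detected(cm$counts)
      fc <- paired_log2fc(flt$counts, cm$samples)
      common <- intersect(colnames(fc), clin$patient_id)
      if (length(common) < 3)
        stop("fewer than 3 patients shared between counts and cohort")
      fc <- fc[, common, drop = FALSE]
      idx <- match(common, clin$patient_id)
      screen <- correlation_screen(fc, ftab$alpha[idx], clin$nlr[idx],
                                   clin$dsd[idx],
                                   progression = clin$progression[idx] != "none",
                                   p_threshold = config$screen_p_threshold)
      utils::write.csv(screen, p("screen.csv"), row.names = FALSE)
      cand <- screen$gene[screen$selected]
      if (length(cand) > config$max_candidates) {
        strength <- pmin(screen$p_alpha, screen$p_dsd,
                         na.rm = TRUE)[screen$selected]
        cand <- cand[order(strength)][seq_len(config$max_candidates)]
      }
      subset_res <- NULL
      if (length(cand) >= 1) {
        subset_res <- best_subset(fc, cand, clin$dsd[idx],
                                  max_k = config$max_k)
        utils::write.csv(subset_res$trace, p("subset_trace.csv"),
                         row.names = FALSE)
        scores <- composite_score(fc, plus_genes = subset_res$selected_genes)
        utils::write.csv(data.frame(patient_id = names(scores),
                                    score = scores),
                         p("composite_scores.csv"), row.names = FALSE)
      }
      exo <- list(fc = fc, screen = screen, subset = subset_res)
    }

    list(cohort = cohort, fits = fits, endpoints = endpoints,
         comparison = comparison, logrank = do.call(rbind, lr_rows),
         cox = cox_rows, exosome = exo)
  }, error = function(e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))

  cfg_file <- tempfile()
  saveRDS(config[setdiff(names(config), "out_dir")], cfg_file)
  log_lines <- c(
    paste("alcslope version:", as.character(utils::packageVersion("alcslope"))),
    paste("config hash:", unname(tools::md5sum(cfg_file))),
    paste("seed:", config$seed),
    paste("run time:", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")))
  unlink(cfg_file)
  writeLines(log_lines, p("run_log.txt"))
  invisible(res)
}
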