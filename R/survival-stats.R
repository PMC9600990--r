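#' Kaplan-Meier product-limit estimate
#'
#' Thin structured wrapper around the product-limit estimator: returns the
#' step function as sorted event times with survival, at-risk and event
#' counts (tied events handled simultaneously).
#'
#' @param time follow-up times (months).
#' @param event logical or 0/1 event indicator.
#' @return An object of class `km_curve`: list with `time`, `survival`,
#'   `at_risk`, `events` (all restricted to event times) and `n`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1L, length(time) == length(event))
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  keep <- fit$n.event > 0
  structure(list(time = fit$time[keep], survival = fit$surv[keep],
                 at_risk = fit$n.risk[keep], events = fit$n.event[keep],
                 n = length(time), max_time = max(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, "with", sum(x$events),
      "events at", length(x$time), "distinct times\n")
  invisible(x)
}

#' Survival probability at a time point
#'
#' Evaluates the product-limit step function: the estimate at the last
#' event time at or before `t` (1 before the first event). Evaluation
#' beyond the last observed follow-up carries the last estimate forward
#' with an extrapolation warning.
#'
#' @param curve a [km_estimate()] result.
#' @param t months.
#' @return Survival proportion in `[0, 1]`.
#' @export
km_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), t >= 0)
  if (t > curve$max_time)
    warning("t = ", t, " is beyond the last observed time (", curve$max_time,
            "); carrying the last estimate forward")
  idx <- sum(curve$time <= t)
  if (idx == 0L) 1 else curve$survival[idx]
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank statistic summing observed-minus-expected
#' events over distinct event times, referred to chi-square with 1 df.
#' With zero events in both groups the statistic is 0 and p = 1.
#'
#' @param time,event follow-up times and event indicators.
#' @param group two-level grouping factor.
#' @return list with `statistic`, `p_value`, `df = 1`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  stopifnot(nlevels(droplevels(group)) == 2L, length(time) == length(group))
  if (sum(event) == 0)
    return(list(statistic = 0, p_value = 1, df = 1L))
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Cox proportional-hazards model with AIC backward elimination
#'
#' Fits the full Cox model (Efron tie handling), then repeatedly removes
#' the term whose removal most decreases the AIC until no removal
#' decreases it. Terms aliased by collinearity (undetermined coefficients)
#' are dropped before elimination starts. Hazard ratios carry 95% Wald
#' confidence intervals.
#'
#' @param data data frame of covariates.
#' @param time,event follow-up times (months) and event indicators.
#' @param terms character vector of covariate names (columns of `data`)
#'   entering the full model.
#' @return An object of class `cox_backward`: list with `terms` (data
#'   frame `term`, `coef`, `hr`, `ci_low`, `ci_high`, `p_value`), `aic`,
#'   `n_events`, `aic_trace` (AIC after each elimination, full model
#'   first), `eliminated`, `aliased` and the final `fit`.
#' @export
cox_backward <- function(data, time, event, terms) {
  stopifnot(all(terms %in% names(data)), sum(event) >= 1)
  df <- data.frame(.time = time, .event = as.integer(event),
                   data[terms], check.names = FALSE)

  fit_terms <- function(tt) {
    fml <- stats::as.formula(paste(
      "survival::Surv(.time, .event) ~",
      if (length(tt)) paste(sprintf("`%s`", tt), collapse = " + ") else "1"))
    f <- withCallingHandlers(
      survival::coxph(fml, data = df, ties = "efron", model = TRUE),
      warning = function(w) {
        if (grepl("infinite|did not converge|out of iterations",
                  conditionMessage(w)))
          stop("Cox fit did not converge with terms: ",
               paste(tt, collapse = ", "), " (", conditionMessage(w), ")",
               call. = FALSE)
        invokeRestart("muffleWarning")
      })
    f
  }
  aic_of <- function(f) {
    ll <- f$loglik[length(f$loglik)]
    k <- sum(!is.na(stats::coef(f)))
    -2 * ll + 2 * k
  }

  current <- terms
  fit <- fit_terms(current)
  aliased <- character(0)
  if (anyNA(stats::coef(fit))) {
    bad <- gsub("`", "", names(stats::coef(fit))[is.na(stats::coef(fit))])
    # attribute each undetermined coefficient to the longest matching term
    # (factor coefficients carry the term name as a prefix)
    aliased <- unique(vapply(bad, function(b) {
      hits <- current[b == current | startsWith(b, current)]
      hits[which.max(nchar(hits))]
    }, character(1)))
    current <- setdiff(current, aliased)
    fit <- fit_terms(current)
  }

  trace <- aic_of(fit)
  eliminated <- character(0)
  while (length(current) > 0L) {
    cand_aic <- vapply(current, function(tm)
      aic_of(fit_terms(setdiff(current, tm))), numeric(1))
    best <- which.min(cand_aic)
    if (cand_aic[best] >= trace[length(trace)] - 1e-8) break
    eliminated <- c(eliminated, current[best])
    current <- setdiff(current, current[best])
    fit <- fit_terms(current)
    trace <- c(trace, aic_of(fit))
  }

  cf <- stats::coef(fit)
  if (length(cf)) {
    se <- sqrt(diag(stats::vcov(fit)))
    term_tab <- data.frame(
      term = names(cf), coef = unname(cf), hr = exp(unname(cf)),
      ci_low = exp(unname(cf) - 1.96 * se), ci_high = exp(unname(cf) + 1.96 * se),
      p_value = 2 * stats::pnorm(-abs(unname(cf) / se)),
      stringsAsFactors = FALSE)
  } else {
    term_tab <- data.frame(term = character(0), coef = numeric(0),
                           hr = numeric(0), ci_low = numeric(0),
                           ci_high = numeric(0), p_value = numeric(0))
  }
  structure(list(terms = term_tab, aic = trace[length(trace)],
                 n_events = sum(event), aic_trace = trace,
                 eliminated = eliminated, aliased = aliased, fit = fit,
                 retained = current),
            class = "cox_backward")
}

#' @export
print.cox_backward <- function(x, digits = 3, ...) {
  cat("Cox model after AIC backward elimination\n")
  cat("  events:", x$n_events, "  AIC:", format(x$aic, digits = 6), "\n")
  if (length(x$aliased))
    cat("  dropped as aliased:", paste(x$aliased, collapse = ", "), "\n")
  if (length(x$eliminated))
    cat("  eliminated:", paste(x$eliminated, collapse = ", "), "\n")
  if (nrow(x$terms)) print(format(x$terms, digits = digits), row.names = FALSE)
  else cat("  (no terms retained)\n")
  invisible(x)
}

#' Baseline-style comparison of two patient groups
#'
#' For each variable, categorical data are compared with the chi-square
#' test (uncorrected by default) and continuous data with the t-test when
#' both groups pass Shapiro-Wilk normality at 0.05, otherwise with the
#' Wilcoxon rank-sum test.
#'
#' @param data data frame of patient variables.
#' @param group two-level grouping factor.
#' @param vars variables to compare; default all columns of `data`.
#' @param correct apply Yates continuity correction to chi-square tests.
#' @return data frame `variable`, `test_used`, `statistic`, `p_value`.
#' @export
group_compare <- function(data, group, vars = names(data), correct = FALSE) {
  group <- droplevels(as.factor(group))
  stopifnot(nlevels(group) == 2L, nrow(data) == length(group))
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    if (is.numeric(x) && length(unique(x)) > 2L) {
      norm_p <- vapply(levels(group), function(g) {
        xs <- x[group == g]
        if (length(xs) < 3 || length(xs) > 5000 || stats::var(xs) == 0) 0
        else stats::shapiro.test(xs)$p.value
      }, numeric(1))
      if (all(norm_p >= 0.05)) {
        tt <- stats::t.test(x ~ group)
        data.frame(variable = v, test_used = "t_test",
                   statistic = unname(tt$statistic), p_value = tt$p.value)
      } else {
        wt <- stats::wilcox.test(x ~ group, exact = FALSE)
        data.frame(variable = v, test_used = "wilcoxon",
                   statistic = unname(wt$statistic), p_value = wt$p.value)
      }
    } else {
      tab <- table(x, group)
      ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
      flag <- any(ct$expected == 0)
      data.frame(variable = v, test_used = if (flag) "chi_square_flagged" else "chi_square",
                 statistic = unname(ct$statistic), p_value = ct$p.value)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
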