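#' Configuration of the decay-rate fit
#'
#' The lymphocyte series of one patient is fitted to
#' `ALC(t) = a1 * exp(-alpha * t) + e1` with `a1 >= 0` and `e1 >= e1_floor`.
#' The decay rate `alpha` is profiled over a dense grid; among the `top_k`
#' grid candidates with the highest coefficient of determination the lowest
#' decay rate is selected.
#'
#' @param alpha_min,alpha_max bounds of the decay-rate grid, 1/day.
#' @param grid_step grid resolution, 1/day. The default 5e-4 yields 381
#'   candidates over the default range.
#' @param top_k number of top-ranked candidates entering the lowest-rate
#'   selection rule.
#' @param e1_floor lower bound for the plateau (estimated nadir), cells/uL;
#'   strict positivity of the plateau is enforced through this floor.
#' @param tie_tol two candidates are considered equally good fits when
#'   their R-squared values differ by at most this amount; the lowest-rate
#'   selection only moves between equally good candidates. Without the
#'   tolerance a dense grid would systematically bias the selected rate
#'   low, because the best `top_k` candidates straddle the optimum.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(alpha_min = 0.01, alpha_max = 0.2, grid_step = 5e-4,
                       top_k = 10L, e1_floor = 1, tie_tol = 1e-6) {
  stopifnot(alpha_min > 0, alpha_min < alpha_max, grid_step > 0,
            top_k >= 1, e1_floor > 0, tie_tol >= 0)
  structure(list(alpha_min = alpha_min, alpha_max = alpha_max,
                 grid_step = grid_step, top_k = as.integer(top_k),
                 e1_floor = e1_floor, tie_tol = tie_tol),
            class = "fit_config")
}

# Exact constrained least squares for a batch of fixed decay rates.
# For each alpha, minimises ||y - a1*exp(-alpha*d) - e1||^2 subject to
# a1 >= 0, e1 >= floor. The 2-D quadratic programme is solved by active-set
# enumeration: the optimum is the interior stationary point when feasible,
# otherwise the best of the two clamped edge solutions (each edge solution
# already covers its corner).
.profile_grid <- function(alphas, day, y, e1_floor) {
  n <- length(y)
  sy <- sum(y)
  syy <- sum(y^2)
  sst <- syy - sy^2 / n
  X <- exp(-outer(alphas, day))          # n_alpha x n
  sx <- rowSums(X)
  sxx <- rowSums(X^2)
  sxy <- as.numeric(X %*% y)

  sse_of <- function(a1, e1)
    pmax(0, syy - 2 * (a1 * sxy + e1 * sy) + a1^2 * sxx +
           2 * a1 * e1 * sx + e1^2 * n)

  # interior stationary point
  det <- n * sxx - sx^2
  ok <- det > .Machine$double.eps * n * sxx
  a1_u <- ifelse(ok, (n * sxy - sx * sy) / det, NA_real_)
  e1_u <- ifelse(ok, (sy * sxx - sx * sxy) / det, NA_real_)
  feas <- ok & a1_u >= 0 & e1_u >= e1_floor
  sse_u <- ifelse(feas, sse_of(a1_u, e1_u), Inf)

  # edge e1 = floor, a1 clamped at 0
  a1_f <- pmax(0, (sxy - e1_floor * sx) / sxx)
  sse_f <- sse_of(a1_f, e1_floor)

  # edge a1 = 0, e1 clamped at floor
  e1_z <- max(e1_floor, sy / n)
  sse_z <- sse_of(0, e1_z)

  sse <- pmin(sse_u, sse_f, sse_z)
  a1 <- ifelse(sse_u <= sse, a1_u, ifelse(sse_f <= sse, a1_f, 0))
  e1 <- ifelse(sse_u <= sse, e1_u, ifelse(sse_f <= sse, e1_floor, e1_z))
  data.frame(alpha = alphas, a1 = a1, e1 = e1,
             r_squared = 1 - sse / sst, sse = sse)
}

.check_series <- function(series, min_points = 2L) {
  if (is.list(series) && !is.data.frame(series)) series <- as.data.frame(series)
  stopifnot(is.data.frame(series), all(c("day", "alc") %in% names(series)))
  series <- series[order(series$day), , drop = FALSE]
  stopifnot(nrow(series) >= min_points, all(series$day >= 0),
            all(series$alc > 0), !anyDuplicated(series$day))
  if (stats::var(series$alc) == 0)
    stop("degenerate fit: ALC series has zero variance (R^2 undefined)")
  series
}

#' Constrained least-squares fit at a fixed decay rate
#'
#' For a fixed `alpha`, estimates the amplitude `a1` and plateau `e1` of
#' `a1 * exp(-alpha * day) + e1` by least squares subject to `a1 >= 0` and
#' `e1 >= e1_floor`, and reports `r_squared = 1 - SSE/SST` (SST about the
#' mean; may be negative under the constraints and is deliberately not
#' clipped so candidate ranking stays well defined).
#'
#' @param alpha decay rate, 1/day.
#' @param series data frame with `day` and `alc` columns for one patient.
#' @param e1_floor plateau lower bound, cells/uL.
#' @return data frame row with `alpha`, `a1`, `e1`, `r_squared`.
#' @export
profile_fit <- function(alpha, series, e1_floor = 1) {
  series <- .check_series(series)
  out <- .profile_grid(alpha, series$day, series$alc, e1_floor)
  out[, c("alpha", "a1", "e1", "r_squared")]
}

#' Fit the lymphocyte decay model to one patient's serial counts
#'
#' Profiles the constrained exponential fit over the decay-rate grid,
#' ranks candidates by `r_squared` (ties broken toward the lower rate) and
#' selects, among the top `top_k` candidates, the lowest decay rate whose
#' fit is indistinguishable from the best (R-squared within `tie_tol`).
#' The selection rule is deliberately conservative: near-flat
#' goodness-of-fit profiles resolve to the slowest decay compatible with
#' the data, while a sharply peaked profile keeps its optimum.
#'
#' @param series data frame with `day` and `alc` columns; at least 3
#'   measurements with strictly increasing days.
#' @param config a [fit_config()].
#' @return An object of class `alc_decay_fit` with components
#'   `coefficients` (`alpha`, `a1`, `e1`, `a2 = a1 + e1`), `r_squared`,
#'   `candidates` (the ranked top-`top_k` grid candidates), `series` and
#'   `config`.
#' @seealso [predict.alc_decay_fit()], [fit_cohort()]
#' @export
fit_alpha <- function(series, config = fit_config()) {
  series <- .check_series(series, min_points = 3L)
  alphas <- seq(config$alpha_min, config$alpha_max, by = config$grid_step)
  top_k <- config$top_k
  if (length(alphas) < top_k) {
    warning("grid has fewer points (", length(alphas), ") than top_k (",
            top_k, "); truncating top_k")
    top_k <- length(alphas)
  }
  grid <- .profile_grid(alphas, series$day, series$alc, config$e1_floor)
  ord <- order(-grid$r_squared, grid$alpha)
  cand <- grid[ord[seq_len(top_k)], c("alpha", "a1", "e1", "r_squared")]
  rownames(cand) <- NULL
  tied <- cand$r_squared >= cand$r_squared[1] - config$tie_tol
  sel <- cand[tied, ][which.min(cand$alpha[tied]), ]
  structure(list(
    coefficients = c(alpha = sel$alpha, a1 = sel$a1, e1 = sel$e1,
                     a2 = sel$a1 + sel$e1),
    r_squared = sel$r_squared,
    candidates = cand,
    series = series,
    config = config
  ), class = "alc_decay_fit")
}

#' @export
print.alc_decay_fit <- function(x, digits = 4, ...) {
  cf <- x$coefficients
  cat("Lymphocyte decay fit: ALC(t) = a1*exp(-alpha*t) + e1\n")
  cat(sprintf("  alpha = %.*g /day   a1 = %.*g   e1 = %.*g   a2 = %.*g cells/uL\n",
              digits, cf["alpha"], digits, cf["a1"], digits, cf["e1"],
              digits, cf["a2"]))
  cat(sprintf("  R^2 = %.*g on %d measurements\n", digits, x$r_squared,
              nrow(x$series)))
  invisible(x)
}

#' @export
coef.alc_decay_fit <- function(object, ...) object$coefficients

#' Predicted lymphocyte count at given times
#'
#' Evaluates `a1 * exp(-alpha * t) + e1`; at `t = 0` this is `a2`, the
#' estimated pre-treatment count, and the `t -> Inf` asymptote is `e1`,
#' the estimated nadir under continued irradiation.
#'
#' @param object an `alc_decay_fit`.
#' @param t times in days since the first radiotherapy fraction; defaults
#'   to the observed measurement days.
#' @param ... unused.
#' @return Numeric vector of counts, cells/uL.
#' @export
predict.alc_decay_fit <- function(object, t = object$series$day, ...) {
  stopifnot(all(t >= 0))
  cf <- object$coefficients
  unname(cf["a1"] * exp(-cf["alpha"] * t) + cf["e1"])
}

#' @export
fitted.alc_decay_fit <- function(object, ...) predict(object)

#' @export
residuals.alc_decay_fit <- function(object, ...)
  object$series$alc - fitted(object)

#' @export
summary.alc_decay_fit <- function(object, ...) {
  out <- list(coefficients = object$coefficients,
              r_squared = object$r_squared,
              n = nrow(object$series),
              candidates = object$candidates,
              resid_range = range(residuals(object)))
  class(out) <- "summary.alc_decay_fit"
  out
}

#' @export
print.summary.alc_decay_fit <- function(x, ...) {
  cat("Lymphocyte decay fit on", x$n, "measurements\n\n")
  print(round(x$coefficients, 5))
  cat(sprintf("\nR^2 = %.5f; residual range [%.1f, %.1f]\n",
              x$r_squared, x$resid_range[1], x$resid_range[2]))
  cat("\nTop candidates (ranked by R^2; lowest alpha selected):\n")
  print(x$candidates, digits = 5)
  invisible(x)
}

#' @export
plot.alc_decay_fit <- function(x, ...) {
  s <- x$series
  tt <- seq(0, max(s$day), length.out = 200)
  graphics::plot(s$day, s$alc, xlab = "days since first RT fraction",
                 ylab = "ALC (cells/uL)", pch = 19, ...)
  graphics::lines(tt, predict(x, tt), col = "steelblue", lwd = 2)
  graphics::abline(h = x$coefficients["e1"], lty = 3, col = "grey40")
  invisible(x)
}

#' Simulate noisy series from a fitted decay curve
#'
#' Draws series at the observed measurement days with multiplicative
#' log-normal noise around the fitted curve, the same noise model as the
#' cohort generator.
#'
#' @param object an `alc_decay_fit`.
#' @param nsim number of series.
#' @param seed optional RNG seed.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param ... unused.
#' @return List of `nsim` data frames with `day` and `alc`.
#' @export
simulate.alc_decay_fit <- function(object, nsim = 1, seed = NULL,
                                   noise_cv = 0.1, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  day <- object$series$day
  sdlog <- sqrt(log(1 + noise_cv^2))
  lapply(seq_len(nsim), function(i)
    data.frame(day = day,
               alc = pmax(1, mu * stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog))))
}

#' Fit the decay model to every patient of a cohort
#'
#' Per-patient fits are collected into a table; degenerate series (zero
#' variance) are flagged and the cohort run continues.
#'
#' @param cohort an `alc_cohort` object (see [read_cohort()]).
#' @param config a [fit_config()].
#' @return An object of class `alc_cohort_fit`: list with `table` (one row
#'   per patient: `patient_id`, `alpha`, `a1`, `e1`, `a2`, `r_squared`,
#'   `n_points`, `flag`) and `fits` (named list of `alc_decay_fit`, `NULL`
#'   where flagged).
#' @export
fit_cohort <- function(cohort, config = fit_config()) {
  stopifnot(inherits(cohort, "alc_cohort"))
  ids <- cohort$clinical$patient_id
  series_list <- split(cohort$alc[c("day", "alc")],
                       factor(cohort$alc$patient_id, levels = ids))
  fits <- vector("list", length(ids))
  names(fits) <- ids
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    s <- series_list[[i]]
    f <- tryCatch(fit_alpha(s, config), error = function(e) e)
    if (inherits(f, "error")) {
      rows[[i]] <- data.frame(patient_id = ids[i], alpha = NA_real_,
                              a1 = NA_real_, e1 = NA_real_, a2 = NA_real_,
                              r_squared = NA_real_, n_points = nrow(s),
                              flag = conditionMessage(f),
                              stringsAsFactors = FALSE)
    } else {
      fits[[i]] <- f
      cf <- f$coefficients
      rows[[i]] <- data.frame(patient_id = ids[i], alpha = cf[["alpha"]],
                              a1 = cf[["a1"]], e1 = cf[["e1"]],
                              a2 = cf[["a2"]], r_squared = f$r_squared,
                              n_points = nrow(f$series), flag = "",
                              stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(table = table, fits = fits, config = config),
            class = "alc_cohort_fit")
}

#' @export
print.alc_cohort_fit <- function(x, ...) {
  tab <- x$table
  ok <- tab$flag == ""
  cat("Cohort decay fits:", sum(ok), "patients fitted",
      if (any(!ok)) paste0("(", sum(!ok), " flagged)") else "", "\n")
  if (any(ok)) {
    q <- stats::quantile(tab$alpha[ok], c(0.25, 0.5, 0.75))
    cat(sprintf("  alpha median [IQR]: %.3f [%.3f-%.3f] /day\n",
                q[2], q[1], q[3]))
    cat(sprintf("  a2 median: %.0f cells/uL   e1 median: %.0f cells/uL\n",
                stats::median(tab$a2[ok]), stats::median(tab$e1[ok])))
  }
  invisible(x)
}

#' @export
summary.alc_cohort_fit <- function(object, ...) {
  tab <- object$table
  ok <- tab$flag == ""
  list(n = nrow(tab), n_flagged = sum(!ok),
       alpha = stats::quantile(tab$alpha[ok], c(0.25, 0.5, 0.75)),
       a2 = stats::quantile(tab$a2[ok], c(0.25, 0.5, 0.75)),
       e1 = stats::quantile(tab$e1[ok], c(0.25, 0.5, 0.75)),
       r_squared = stats::quantile(tab$r_squared[ok], c(0.25, 0.5, 0.75)))
}

#' @export
as.data.frame.alc_cohort_fit <- function(x, ...) x$table

#' @export
coef.alc_cohort_fit <- function(object, ...) {
  m <- as.matrix(object$table[, c("alpha", "a1", "e1", "a2")])
  rownames(m) <- object$table$patient_id
  m
}
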