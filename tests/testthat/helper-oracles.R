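# Independent oracles used across the suite. Each recomputes the quantity
# under test by a different route (numerical optimisation, exhaustive
# enumeration, hand-rolled textbook formulas) and must stay independent of
# the package internals.

# Noiseless series on the decay curve.
make_series <- function(alpha, a1, e1, days)
  data.frame(day = days, alc = a1 * exp(-alpha * days) + e1)

# Constrained (a1 >= 0, e1 >= floor) least squares at fixed alpha via
# box-constrained quasi-Newton optimisation with analytic gradient.
oracle_profile <- function(alpha, day, y, e1_floor = 1, start = NULL) {
  x <- exp(-alpha * day)
  fn <- function(p) sum((y - p[1] * x - p[2])^2)
  gr <- function(p) {
    r <- y - p[1] * x - p[2]
    c(-2 * sum(r * x), -2 * sum(r))
  }
  if (is.null(start)) start <- c(max(mean(y) - min(y), 1), max(min(y), e1_floor))
  start <- pmax(start, c(0, e1_floor))
  opt <- stats::optim(start, fn, gr, method = "L-BFGS-B",
                      lower = c(0, e1_floor),
                      control = list(factr = 1e1, maxit = 500))
  sst <- sum((y - mean(y))^2)
  list(a1 = opt$par[1], e1 = opt$par[2], sse = opt$value,
       r_squared = 1 - opt$value / sst)
}

# Brute-force scan over a refined alpha grid with the same top-k-then-
# lowest-alpha selection rule (top_k scaled so the candidate window spans
# the same alpha range).
oracle_fit <- function(series, alpha_min = 0.01, alpha_max = 0.2,
                       grid_step = 5e-4, top_k = 10, e1_floor = 1,
                       tie_tol = 1e-6, refine = 10) {
  day <- series$day; y <- series$alc
  alphas <- seq(alpha_min, alpha_max, by = grid_step / refine)
  r2 <- numeric(length(alphas))
  a1 <- numeric(length(alphas)); e1 <- numeric(length(alphas))
  start <- NULL
  for (i in seq_along(alphas)) {
    o <- oracle_profile(alphas[i], day, y, e1_floor, start)
    r2[i] <- o$r_squared; a1[i] <- o$a1; e1[i] <- o$e1
    start <- c(o$a1, o$e1)
  }
  ord <- order(-r2, alphas)
  top <- ord[seq_len(top_k * refine)]
  tied <- top[r2[top] >= max(r2) - tie_tol]
  sel <- tied[which.min(alphas[tied])]
  list(alpha = alphas[sel], a1 = a1[sel], e1 = e1[sel], r_squared = r2[sel],
       profile = data.frame(alpha = alphas, r_squared = r2))
}

# Hand product-limit estimator.
km_hand <- function(time, event) {
  event <- as.integer(event)
  tt <- sort(unique(time[event == 1]))
  surv <- numeric(length(tt)); s <- 1
  for (i in seq_along(tt)) {
    d <- sum(time == tt[i] & event == 1)
    r <- sum(time >= tt[i])
    s <- s * (1 - d / r)
    surv[i] <- s
  }
  data.frame(time = tt, survival = surv)
}

# Per-event-time 2x2 hypergeometric log-rank statistic.
logrank_hand <- function(time, event, group) {
  group <- as.factor(group)
  g1 <- levels(group)[1]
  tt <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in tt) {
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (O - E)^2 / V
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

# Exhaustive two-sided rank-sum p by enumerating all group assignments.
wilcox_enum <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2   # Mann-Whitney U of x
  combs <- utils::combn(n + m, n)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p <- min(1, 2 * min(mean(u_all <= w_obs), mean(u_all >= w_obs)))
  list(statistic = w_obs, p_value = p)
}

# Naive all-subsets search with lm(), maximising adjusted R^2 per size and
# adjusted R^2 / k overall.
subset_enum <- function(fc, candidates, outcome, max_k = length(candidates)) {
  n <- ncol(fc)
  max_k <- min(max_k, length(candidates), n - 2)
  best_score <- -Inf; best <- NULL
  trace <- NULL
  for (k in seq_len(max_k)) {
    combs <- utils::combn(candidates, k, simplify = FALSE)
    best_adj <- -Inf; best_genes <- NULL; best_r2 <- NA
    for (s in combs) {
      d <- data.frame(y = as.numeric(outcome), t(fc[s, , drop = FALSE]))
      f <- stats::lm(y ~ ., data = d)
      sm <- summary(f)
      if (sm$adj.r.squared > best_adj) {
        best_adj <- sm$adj.r.squared; best_genes <- s; best_r2 <- sm$r.squared
      }
    }
    trace <- rbind(trace, data.frame(k = k, adj_r2 = best_adj, r2 = best_r2,
                                     genes = paste(best_genes, collapse = "+")))
    if (best_adj / k > best_score) {
      best_score <- best_adj / k
      best <- best_genes
    }
  }
  list(selected_genes = best, score = best_score, trace = trace)
}

# Published TMM recipe, step by step.
tmm_hand <- function(counts, logratioTrim = 0.3, sumTrim = 0.05) {
  lib <- colSums(counts)
  uq <- apply(sweep(counts, 2, lib, "/"), 2, quantile, p = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  one_factor <- function(obs, refv, nO, nR) {
    logR <- log2((obs / nO) / (refv / nR))
    absE <- (log2(obs / nO) + log2(refv / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refv) / nR / refv
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratioTrim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sumTrim) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    f <- sum(logR[keep] / v[keep]) / sum(1 / v[keep])
    2^f
  }
  f <- vapply(seq_len(ncol(counts)), function(j)
    one_factor(counts[, j], counts[, ref], lib[j], lib[ref]), numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# Small valid clinical/ALC tables for cohort tests.
toy_cohort_tables <- function() {
  clinical <- data.frame(
    patient_id = c("A", "B", "C"),
    age = c(55, 60, 48),
    pathology = c("squamous", "adenocarcinoma", "squamous"),
    figo_stage = c("IB-IIB", "IIIA-IIIC1", "IIIC2-IVB"),
    rt_field = c("pelvis", "pelvis", "pelvis+PALN"),
    ot_days = c(50, 53, 56),
    td_eqd2 = c(70, 68.5, 72),
    pre_alc = c(1800, NA, 2100),
    nlr = c(2.1, 3.4, NA),
    followup_months = c(60, 24, 80),
    dsd = c(0, 1, 0),
    time_to_dsd_months = c(NA, 24, NA),
    progression = c("none", "DM", "none"),
    time_to_progression_months = c(NA, 10, NA),
    stringsAsFactors = FALSE)
  alc <- data.frame(
    patient_id = rep(c("A", "B", "C"), each = 4),
    day = rep(c(0, 14, 28, 42), 3),
    alc = c(1800, 900, 500, 300, 2000, 1100, 600, 350, 2100, 1000, 450, 280),
    stringsAsFactors = FALSE)
  list(clinical = clinical, alc = alc)
}
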