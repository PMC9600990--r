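#' Read a paired count matrix and its sample sheet
#'
#' @param counts_path TSV, first column the gene identifier, remaining
#'   columns one sample each.
#' @param samples_path CSV with columns `sample_id`, `patient_id`, `role`
#'   (`control` = pre-treatment, `treatment` = week-2).
#' @return list with `counts` (integer matrix, genes x samples) and
#'   `samples` (data frame, one row per column of `counts`).
#' @export
read_counts <- function(counts_path, samples_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  validate_counts(counts, samples)
  list(counts = counts, samples = samples[match(colnames(counts),
                                                samples$sample_id), ])
}

validate_counts <- function(counts, samples) {
  stopifnot(all(c("sample_id", "patient_id", "role") %in% names(samples)),
            all(samples$role %in% c("control", "treatment")),
            setequal(colnames(counts), samples$sample_id),
            all(counts >= 0))
  roles <- table(samples$patient_id, samples$role)
  if (!all(roles == 1L))
    stop("every patient must have exactly one control and one treatment sample")
  invisible(TRUE)
}

#' Remove genes undetected in too many samples
#'
#' Keeps genes with a nonzero count in at least `min_detect_frac` of all
#' samples; a gene detected in exactly half of the samples is retained.
#' Idempotent.
#'
#' @param counts genes x samples count matrix.
#' @param min_detect_frac minimum detection fraction, default 0.5.
#' @return list with the filtered `counts` and `removed` gene identifiers.
#' @export
filter_detected <- function(counts, min_detect_frac = 0.5) {
  stopifnot(nrow(counts) >= 1L, ncol(counts) >= 1L)
  keep <- rowMeans(counts > 0) >= min_detect_frac
  list(counts = counts[keep, , drop = FALSE],
       removed = rownames(counts)[!keep])
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Between-sample normalization factors for read-count libraries computed
#' with the standard TMM recipe (reference column = library whose
#' upper-quartile count is closest to the mean upper quartile; 30% trim on
#' log-ratios, 5% on log-abundance; inverse-variance weighting), rescaled
#' so the factors multiply to 1.
#'
#' @param counts genes x samples count matrix with positive library sizes.
#' @return Named numeric vector of factors, one per sample.
#' @export
tmm_factors <- function(counts) {
  stopifnot(ncol(counts) >= 2L, all(colSums(counts) > 0))
  uq <- apply(sweep(counts, 2, colSums(counts), "/"), 2,
              stats::quantile, p = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  shared <- vapply(seq_len(ncol(counts)), function(j)
    any(counts[, j] > 0 & counts[, ref] > 0), logical(1))
  if (!all(shared))
    stop("sample(s) share no detected genes with the reference: ",
         paste(colnames(counts)[!shared], collapse = ", "))
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  names(f) <- colnames(counts)
  f
}

#' Per-patient paired log2 fold change
#'
#' Normalized counts are counts-per-million after TMM effective library
#' size correction; the per-gene, per-patient log2 fold change is
#' `log2((treatment + pc) / (control + pc))` with pseudocount `pc` on the
#' CPM scale guarding zeros.
#'
#' @param counts genes x samples count matrix.
#' @param samples sample sheet (see [read_counts()]).
#' @param factors TMM factors from [tmm_factors()]; computed when `NULL`.
#' @param pseudocount added to both normalized counts, default 0.5.
#' @return Matrix genes x patients of log2 fold changes.
#' @export
paired_log2fc <- function(counts, samples, factors = NULL, pseudocount = 0.5) {
  validate_counts(counts, samples)
  if (is.null(factors)) factors <- tmm_factors(counts)
  factors <- factors[colnames(counts)]
  cpm <- sweep(counts, 2, colSums(counts) * factors, "/") * 1e6
  patients <- unique(samples$patient_id)
  ctrl <- samples$sample_id[match(paste(patients, "control"),
                                  paste(samples$patient_id, samples$role))]
  trt <- samples$sample_id[match(paste(patients, "treatment"),
                                 paste(samples$patient_id, samples$role))]
  fc <- log2((cpm[, trt, drop = FALSE] + pseudocount) /
               (cpm[, ctrl, drop = FALSE] + pseudocount))
  colnames(fc) <- patients
  fc
}

#' Screen genes for association with the decay rate, NLR and outcome
#'
#' Pearson correlation of each gene's paired log2 fold change against the
#' per-patient decay rate, the neutrophil-to-lymphocyte ratio and the
#' disease-specific-death indicator (0/1). A gene is selected when it is
#' significantly associated with the decay rate, or with death, or with
#' both NLR and death; each selected gene is tagged with its justifying
#' covariates. Zero-variance genes are excluded with a flag.
#'
#' @param fc genes x patients log2 fold-change matrix.
#' @param alpha,nlr per-patient numeric covariates.
#' @param dsd per-patient logical/0-1 death indicator.
#' @param progression optional per-patient logical progression indicator,
#'   reported but not used in the selection rule.
#' @param p_threshold significance threshold, default 0.05.
#' @return data frame `gene`, correlations/p-values per covariate,
#'   `selected`, `tag`.
#' @export
correlation_screen <- function(fc, alpha, nlr, dsd, progression = NULL,
                               p_threshold = 0.05) {
  stopifnot(ncol(fc) >= 3L, length(alpha) == ncol(fc),
            length(nlr) == ncol(fc), length(dsd) == ncol(fc))
  dsd <- as.numeric(dsd)
  cors <- function(covar) {
    t(apply(fc, 1, function(g) {
      if (stats::var(g) == 0 || stats::var(covar) == 0)
        return(c(NA_real_, NA_real_))
      ct <- stats::cor.test(g, covar, method = "pearson")
      c(ct$estimate, ct$p.value)
    }))
  }
  ca <- cors(alpha); cn <- cors(nlr); cd <- cors(dsd)
  out <- data.frame(gene = rownames(fc),
                    r_alpha = ca[, 1], p_alpha = ca[, 2],
                    r_nlr = cn[, 1], p_nlr = cn[, 2],
                    r_dsd = cd[, 1], p_dsd = cd[, 2],
                    stringsAsFactors = FALSE)
  if (!is.null(progression)) {
    cp <- cors(as.numeric(progression))
    out$r_prog <- cp[, 1]; out$p_prog <- cp[, 2]
  }
  zerovar <- apply(fc, 1, stats::var) == 0
  sig_a <- !is.na(out$p_alpha) & out$p_alpha < p_threshold
  sig_d <- !is.na(out$p_dsd) & out$p_dsd < p_threshold
  sig_n <- !is.na(out$p_nlr) & out$p_nlr < p_threshold
  out$selected <- !zerovar & (sig_a | sig_d | (sig_n & sig_d))
  tag <- character(nrow(out))
  tag[sig_a] <- "alpha"
  tag[sig_d] <- ifelse(tag[sig_d] == "", "dsd", paste0(tag[sig_d], "+dsd"))
  tag[sig_n & sig_d] <- paste0(tag[sig_n & sig_d], "+nlr")
  tag[zerovar] <- "zero_variance"
  out$tag <- tag
  rownames(out) <- NULL
  out
}

#' Exhaustive best-subset linear models of outcome on gene fold changes
#'
#' For each subset size `k = 1..max_k`, fits the linear (probability)
#' model of the 0/1 outcome on the log2 fold changes of every k-gene
#' subset and records the subset with the highest adjusted R-squared. The
#' returned optimum maximizes adjusted R-squared divided by subset size, a
#' parsimony criterion that rewards genes carrying jointly (rather than
#' redundantly) predictive signal.
#'
#' @param fc genes x patients log2 fold-change matrix.
#' @param candidates gene identifiers to search over (rows of `fc`).
#' @param outcome per-patient 0/1 outcome.
#' @param max_k largest subset size, default 15 (capped at the number of
#'   candidates and at `n - 2`).
#' @param budget maximum number of models to enumerate; exceeding it is an
#'   error instructing a lower `max_k`.
#' @return An object of class `subset_search`: list with `selected_genes`,
#'   `adj_r2`, `score` (= adj R2 / k), `k` and `trace` (per-size best
#'   subset, adjusted and raw R-squared).
#' @export
best_subset <- function(fc, candidates, outcome, max_k = 15, budget = 2e5) {
  stopifnot(length(candidates) >= 1L, all(candidates %in% rownames(fc)))
  n <- ncol(fc)
  outcome <- as.numeric(outcome)
  stopifnot(length(outcome) == n, n > 2L)
  max_k <- min(max_k, length(candidates), n - 2L)
  n_models <- sum(choose(length(candidates), seq_len(max_k)))
  if (n_models > budget)
    stop("exhaustive search would fit ", format(n_models, big.mark = ","),
         " models (budget ", format(budget, big.mark = ","),
         "); lower max_k or prune candidates")
  X <- t(fc[candidates, , drop = FALSE])
  sst <- sum((outcome - mean(outcome))^2)
  if (sst == 0) stop("outcome has zero variance")
  trace <- vector("list", max_k)
  for (k in seq_len(max_k)) {
    combs <- utils::combn(length(candidates), k)
    best_r2 <- -Inf; best_cols <- NULL
    for (j in seq_len(ncol(combs))) {
      cols <- combs[, j]
      f <- stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), outcome)
      r2 <- 1 - sum(f$residuals^2) / sst
      if (r2 > best_r2) { best_r2 <- r2; best_cols <- cols }
    }
    adj <- 1 - (1 - best_r2) * (n - 1) / (n - k - 1)
    trace[[k]] <- data.frame(k = k,
                             genes = paste(candidates[best_cols], collapse = "+"),
                             r2 = best_r2, adj_r2 = adj, score = adj / k,
                             stringsAsFactors = FALSE)
  }
  trace <- do.call(rbind, trace)
  best <- which.max(trace$score)
  structure(list(selected_genes = strsplit(trace$genes[best], "+", fixed = TRUE)[[1]],
                 adj_r2 = trace$adj_r2[best], score = trace$score[best],
                 k = trace$k[best], trace = trace),
            class = "subset_search")
}

#' @export
print.subset_search <- function(x, ...) {
  cat("Best gene subset (adjusted R^2 / k criterion):\n")
  cat("  genes:", paste(x$selected_genes, collapse = " + "), "\n")
  cat(sprintf("  k = %d, adj R^2 = %.4f, score = %.4f\n", x$k, x$adj_r2, x$score))
  invisible(x)
}

#' Composite score from sums and differences of gene fold changes
#'
#' `score = sum(fc[plus_genes]) - sum(fc[minus_genes])` per patient.
#'
#' @param fc genes x patients log2 fold-change matrix.
#' @param plus_genes,minus_genes disjoint gene identifier sets.
#' @return Named numeric vector, one score per patient.
#' @export
composite_score <- function(fc, plus_genes = character(0),
                            minus_genes = character(0)) {
  stopifnot(length(intersect(plus_genes, minus_genes)) == 0L)
  missing <- setdiff(c(plus_genes, minus_genes), rownames(fc))
  if (length(missing))
    stop("gene(s) absent from the fold-change matrix: ",
         paste(missing, collapse = ", "))
  score <- rep(0, ncol(fc))
  if (length(plus_genes))
    score <- score + colSums(fc[plus_genes, , drop = FALSE])
  if (length(minus_genes))
    score <- score - colSums(fc[minus_genes, , drop = FALSE])
  names(score) <- colnames(fc)
  score
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test; the exact null distribution is enumerated for
#' small samples (both sizes at most 8) without ties, otherwise the normal
#' approximation with tie correction is used.
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (rank-sum W of `x`) and `p_value`.
#' @export
wilcoxon_ranksum <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- stats::wilcox.test(x, y, exact = exact, correct = !exact)
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
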