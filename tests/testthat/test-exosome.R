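toy_counts <- function(n_genes = 60, n_patients = 8, seed = 1) {
  set.seed(seed)
  ids <- paste0("P", seq_len(n_patients))
  counts <- matrix(rnbinom(n_genes * 2 * n_patients, mu = 80, size = 5),
                   n_genes, 2 * n_patients)
  rownames(counts) <- sprintf("G%03d", seq_len(n_genes))
  colnames(counts) <- c(paste0(ids, "_C"), paste0(ids, "_T"))
  samples <- data.frame(sample_id = colnames(counts),
                        patient_id = rep(ids, 2),
                        role = rep(c("control", "treatment"), each = n_patients),
                        stringsAsFactors = FALSE)
  list(counts = counts, samples = samples)
}

test_that("detection filter applies the >= 50% boundary and is idempotent", {
  counts <- matrix(0, 3, 4, dimnames = list(c("zero", "half", "full"), NULL))
  counts["half", 1:2] <- 5
  counts["full", ] <- 10
  f <- filter_detected(counts)
  expect_equal(rownames(f$counts), c("half", "full"))
  expect_equal(f$removed, "zero")
  f2 <- filter_detected(f$counts)
  expect_equal(f2$counts, f$counts)
  expect_equal(length(f2$removed), 0L)
})

test_that("TMM factors normalize composition, not depth", {
  # identical columns: all factors 1
  counts <- matrix(rep(c(10, 20, 30, 40, 55), 3), ncol = 3)
  expect_equal(unname(tmm_factors(counts)), rep(1, 3), tolerance = 1e-12)

  # pure depth difference: factors stay 1
  c1 <- c(12, 25, 31, 44, 58)
  counts <- cbind(c1, 2 * c1)
  expect_equal(unname(tmm_factors(counts)), c(1, 1), tolerance = 1e-12)

  # toy with one inflated gene: matches the hand-rolled published recipe
  set.seed(5)
  counts <- matrix(rnbinom(6 * 4, mu = 120, size = 8), 6, 4)
  counts[1, 2] <- 4000
  f <- tmm_factors(counts)
  expect_equal(unname(f), unname(tmm_hand(counts)), tolerance = 1e-8)
  expect_equal(prod(f), 1, tolerance = 1e-12)

  # factors invariant to a global rescaling of all counts
  f2 <- tmm_factors(counts * 3)
  expect_equal(unname(f2), unname(f), tolerance = 1e-10)
})

test_that("paired log2 fold changes behave as ratios of normalized counts", {
  tc <- toy_counts()
  fc <- paired_log2fc(tc$counts, tc$samples)
  expect_equal(dim(fc), c(60L, 8L))

  # treatment column exactly equal to control: fold change 0
  counts <- tc$counts
  counts[, "P1_T"] <- counts[, "P1_C"]
  factors <- rep(1, ncol(counts)); names(factors) <- colnames(counts)
  # equal library sizes too, so normalized values coincide
  fc0 <- paired_log2fc(counts, tc$samples, factors = factors)
  expect_equal(unname(fc0[, "P1"]), rep(0, nrow(counts)))

  # treatment normalized to exactly twice control (effective library sizes
  # equalized through the factors): fold change ~1 when counts >> pseudocount
  big <- counts + 500
  big[, "P2_T"] <- 2 * big[, "P2_C"]
  f2 <- factors
  f2["P2_T"] <- sum(big[, "P2_C"]) / sum(big[, "P2_T"])
  fc2 <- paired_log2fc(big, tc$samples, factors = f2)
  expect_equal(unname(fc2[, "P2"]), rep(1, nrow(big)), tolerance = 0.01)

  # both counts zero -> pseudocount ratio, fold change exactly 0
  counts[5, c("P3_C", "P3_T")] <- 0
  fc3 <- paired_log2fc(counts, tc$samples, factors = factors)
  expect_equal(unname(fc3[5, "P3"]), 0)

  # antisymmetry: swapping control/treatment flips every sign
  sw <- tc$samples
  sw$role <- ifelse(sw$role == "control", "treatment", "control")
  fc_f <- paired_log2fc(tc$counts, tc$samples)
  fc_r <- paired_log2fc(tc$counts, sw)
  expect_equal(fc_r, -fc_f, tolerance = 1e-10)

  # unpaired patient rejected
  bad <- tc$samples[-1, ]
  expect_error(paired_log2fc(tc$counts[, -1], bad), "exactly one control")
})

test_that("correlation screen selects planted signal and excludes constants", {
  set.seed(17)
  n <- 30
  alpha <- rlnorm(n, log(0.08), 0.5)
  nlr <- rlnorm(n, log(2.4), 0.6)
  dsd <- rbinom(n, 1, 0.3)
  fc <- matrix(rnorm(50 * n, 0, 0.5), 50, n,
               dimnames = list(sprintf("G%02d", 1:50), paste0("P", 1:n)))
  # plant a gene correlated ~0.9 with the decay rate
  z <- scale(log(alpha))[, 1]
  fc["G01", ] <- 0.9 * z + rnorm(n, 0, sqrt(1 - 0.81))
  fc["G50", ] <- 0   # constant gene
  out <- correlation_screen(fc, alpha, nlr, dsd)
  expect_true(out$selected[out$gene == "G01"])
  expect_match(out$tag[out$gene == "G01"], "alpha")
  expect_false(out$selected[out$gene == "G50"])
  expect_equal(out$tag[out$gene == "G50"], "zero_variance")
})

test_that("subset search matches exhaustive enumeration with lm", {
  set.seed(23)
  n <- 39
  genes <- sprintf("G%02d", 1:8)
  fc <- matrix(rnorm(8 * n, 0, 0.6), 8, n,
               dimnames = list(genes, paste0("P", 1:n)))
  u <- rnorm(n); v <- rnorm(n)
  y <- as.integer(v + rnorm(n, 0, 0.6) > 0.5)
  fc["G01", ] <- u + 0.5 * v + rnorm(n, 0, 0.3)
  fc["G02", ] <- u - 0.5 * v + rnorm(n, 0, 0.3)
  res <- best_subset(fc, genes, y, max_k = 8)
  oracle <- subset_enum(fc, genes, y, max_k = 8)
  expect_setequal(res$selected_genes, oracle$selected_genes)
  expect_equal(res$score, oracle$score, tolerance = 1e-10)
  expect_equal(res$trace$adj_r2, oracle$trace$adj_r2, tolerance = 1e-10)
  # raw R^2 of the per-size best subsets is non-decreasing in k
  expect_true(all(diff(res$trace$r2) >= -1e-12))
  # the best single gene's adjusted R^2 appears in the trace
  expect_equal(res$trace$adj_r2[1], oracle$trace$adj_r2[1])

  # single candidate: that gene at k = 1
  res1 <- best_subset(fc, "G01", y)
  expect_equal(res1$selected_genes, "G01")
  expect_equal(res1$k, 1L)

  # enumeration budget guards runaway searches
  expect_error(best_subset(fc, genes, y, max_k = 8, budget = 10), "lower max_k")
})

test_that("composite scores are signed sums, linear in the fold changes", {
  fc <- matrix(c(0.7, 0.3, -0.2, 0.1, 0.5, -0.4), 3, 2,
               dimnames = list(c("A", "B", "C"), c("P1", "P2")))
  expect_equal(unname(composite_score(fc)), c(0, 0))
  s <- composite_score(fc, plus_genes = "A", minus_genes = "B")
  expect_equal(unname(s), c(0.7 - 0.3, 0.1 - 0.5))
  # linearity
  s2 <- composite_score(2 * fc, plus_genes = "A", minus_genes = "B")
  expect_equal(s2, 2 * s)
  s3 <- composite_score(fc, plus_genes = c("A", "C"), minus_genes = "B")
  expect_equal(unname(s3), unname(s + fc["C", ]))
  expect_error(composite_score(fc, plus_genes = "Z"), "absent")
  expect_error(composite_score(fc, plus_genes = "A", minus_genes = "A"))
})

test_that("rank-sum test is exact for small samples and matches enumeration", {
  # same multiset in both groups: p ~ 1 (tie-corrected normal approximation)
  x <- c(1.2, 3.4, 5.6, 7.8)
  r <- wilcoxon_ranksum(x, x)
  expect_gte(r$p_value, 0.99)

  # {1,2,3} vs {4,5,6}: exact two-sided p = 0.1
  r <- wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)

  # n = m = 5 fixtures vs full 252-assignment enumeration
  set.seed(12)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(5, 0.8)
    r <- wilcoxon_ranksum(x, y)
    o <- wilcox_enum(x, y)
    expect_equal(r$statistic, o$statistic)
    expect_equal(r$p_value, o$p_value, tolerance = 1e-12)
  }
})
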