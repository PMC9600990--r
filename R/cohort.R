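#' @keywords internal
#' @importFrom stats predict coef fitted residuals simulate median quantile var
"_PACKAGE"

# Clinical CSV schema shared by the reader, writer and the generator.
.clinical_cols <- c("patient_id", "age", "pathology", "figo_stage", "rt_field",
                    "ot_days", "td_eqd2", "pre_alc", "nlr", "followup_months",
                    "dsd", "time_to_dsd_months", "progression",
                    "time_to_progression_months")
.alc_cols <- c("patient_id", "day", "alc")

.pathology_levels  <- c("squamous", "adenocarcinoma", "adenosquamous", "carcinoma")
.figo_levels       <- c("IB-IIB", "IIIA-IIIC1", "IIIC2-IVB")
.rt_field_levels   <- c("pelvis", "pelvis+PALN")
.progression_levels <- c("none", "LP", "DM", "LP+DM")

#' Read a clinical table and serial ALC measurements into a validated cohort
#'
#' Patients whose records violate the domain invariants (fewer than 3 ALC
#' measurements, non-positive counts, negative days, event times exceeding
#' follow-up, unknown category labels) are dropped and reported in the
#' exclusion log rather than aborting the run, mirroring how retrospective
#' cohorts lose patients to incomplete ALC follow-up.
#'
#' @param clinical_path CSV with columns `patient_id, age, pathology,
#'   figo_stage, rt_field, ot_days, td_eqd2, pre_alc, nlr, followup_months,
#'   dsd, time_to_dsd_months, progression, time_to_progression_months`.
#'   Empty cells are missing values.
#' @param alc_path CSV with columns `patient_id, day, alc`; one row per
#'   measurement, `day` counted from the first radiotherapy fraction.
#' @return An object of class `alc_cohort`: a list with `clinical` (one row
#'   per retained patient), `alc` (long table of measurements, sorted by
#'   patient and day) and `exclusions` (data frame `patient_id`, `reason`).
#' @export
read_cohort <- function(clinical_path, alc_path) {
  if (!file.exists(clinical_path))
    stop("clinical file not found: ", clinical_path)
  if (!file.exists(alc_path))
    stop("ALC file not found: ", alc_path)
  clin <- utils::read.csv(clinical_path, stringsAsFactors = FALSE)
  alc <- utils::read.csv(alc_path, stringsAsFactors = FALSE)
  missing_clin <- setdiff(.clinical_cols, names(clin))
  if (length(missing_clin))
    stop("clinical table is missing required column(s): ",
         paste(missing_clin, collapse = ", "))
  missing_alc <- setdiff(.alc_cols, names(alc))
  if (length(missing_alc))
    stop("ALC table is missing required column(s): ",
         paste(missing_alc, collapse = ", "))
  if (nrow(clin) == 0L) stop("clinical table has no rows")
  if (anyDuplicated(clin$patient_id))
    stop("duplicated patient_id in clinical table")
  as_cohort(clin, alc)
}

#' Assemble a cohort object from in-memory tables
#'
#' Applies the same validation and exclusion rules as [read_cohort()].
#'
#' @param clinical data frame following the clinical CSV schema.
#' @param alc data frame following the ALC CSV schema.
#' @return An `alc_cohort` object.
#' @export
as_cohort <- function(clinical, alc) {
  excl <- data.frame(patient_id = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  drop <- function(ids, reason) {
    if (length(ids))
      rbind(excl, data.frame(patient_id = as.character(ids), reason = reason,
                             stringsAsFactors = FALSE))
    else excl
  }
  keep <- rep(TRUE, nrow(clinical))

  bad <- !(clinical$pathology %in% .pathology_levels) |
    !(clinical$figo_stage %in% .figo_levels) |
    !(clinical$rt_field %in% .rt_field_levels) |
    !(clinical$progression %in% .progression_levels)
  excl <- drop(clinical$patient_id[bad & keep], "unknown category label")
  keep <- keep & !bad

  bad <- !is.finite(clinical$td_eqd2) | clinical$td_eqd2 <= 0 |
    !is.finite(clinical$ot_days) | clinical$ot_days <= 0
  excl <- drop(clinical$patient_id[bad & keep], "non-positive dose or treatment time")
  keep <- keep & !bad

  dsd <- clinical$dsd == 1
  bad <- (dsd & (!is.finite(clinical$time_to_dsd_months) |
                   clinical$time_to_dsd_months > clinical$followup_months)) |
    (clinical$progression != "none" &
       (!is.finite(clinical$time_to_progression_months) |
          clinical$time_to_progression_months > clinical$followup_months))
  bad[is.na(bad)] <- TRUE
  excl <- drop(clinical$patient_id[bad & keep], "event time inconsistent with follow-up")
  keep <- keep & !bad

  # ALC series: positive values, non-negative days, >= 3 measurements
  alc_ok <- is.finite(alc$day) & alc$day >= 0 & is.finite(alc$alc) & alc$alc > 0
  bad_ids <- unique(alc$patient_id[!alc_ok])
  alc <- alc[alc_ok & !(alc$patient_id %in% bad_ids), , drop = FALSE]
  bad <- clinical$patient_id %in% bad_ids
  excl <- drop(clinical$patient_id[bad & keep], "invalid ALC measurement")
  keep <- keep & !bad

  n_meas <- table(factor(alc$patient_id, levels = unique(clinical$patient_id)))
  few <- names(n_meas)[n_meas < 3L]
  bad <- clinical$patient_id %in% few
  excl <- drop(clinical$patient_id[bad & keep], "fewer than 3 ALC measurements")
  keep <- keep & !bad

  clinical <- clinical[keep, , drop = FALSE]
  alc <- alc[alc$patient_id %in% clinical$patient_id, , drop = FALSE]
  alc <- alc[order(match(alc$patient_id, clinical$patient_id), alc$day), ,
             drop = FALSE]
  rownames(clinical) <- rownames(alc) <- NULL
  structure(list(clinical = clinical, alc = alc, exclusions = excl),
            class = "alc_cohort")
}

#' @export
print.alc_cohort <- function(x, ...) {
  cat("ALC cohort:", nrow(x$clinical), "patients,",
      nrow(x$alc), "lymphocyte measurements\n")
  if (nrow(x$exclusions))
    cat("Excluded:", nrow(x$exclusions), "patients (see $exclusions)\n")
  invisible(x)
}

#' Write a cohort back to its CSV representation
#'
#' Inverse of [read_cohort()] on valid tables (round-trips exactly).
#'
#' @param cohort an `alc_cohort` object.
#' @param clinical_path,alc_path output CSV paths.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, clinical_path, alc_path) {
  stopifnot(inherits(cohort, "alc_cohort"))
  utils::write.csv(cohort$clinical, clinical_path, row.names = FALSE, na = "")
  utils::write.csv(cohort$alc, alc_path, row.names = FALSE, na = "")
  invisible(cohort)
}

#' Median imputation of missing laboratory covariates
#'
#' Replaces missing values of the pre-treatment ALC and/or the
#' neutrophil-to-lymphocyte ratio with the median of the observed values,
#' the convention used for the handful of missing laboratory values in
#' retrospective chemoradiotherapy cohorts. Only `pre_alc` and `nlr` may be
#' imputed; missingness anywhere else is a validation error upstream.
#'
#' @param cohort an `alc_cohort` object.
#' @param fields character subset of `c("pre_alc", "nlr")`.
#' @return A list with `cohort` (imputed) and `n_imputed` (named integer
#'   vector of replacement counts).
#' @export
impute_median <- function(cohort, fields = c("pre_alc", "nlr")) {
  stopifnot(inherits(cohort, "alc_cohort"))
  if (!all(fields %in% c("pre_alc", "nlr")))
    stop("only 'pre_alc' and 'nlr' may be median-imputed")
  n_imputed <- integer(0)
  for (f in fields) {
    v <- cohort$clinical[[f]]
    miss <- is.na(v)
    if (all(miss)) stop("all values of '", f, "' are missing; cannot impute")
    med <- stats::median(v[!miss])
    v[miss] <- med
    cohort$clinical[[f]] <- v
    n_imputed[f] <- sum(miss)
  }
  list(cohort = cohort, n_imputed = n_imputed)
}

#' Minimum ALC within an early window of radiotherapy
#'
#' The minimum lymphocyte count among measurements taken within
#' `window_days` of the start of radiotherapy (window closed at the
#' boundary day). Returns `NA` with a warning when no measurement falls in
#' the window.
#'
#' @param series data frame with columns `day` and `alc` (one patient), or
#'   an `alc_cohort` ALC table subset.
#' @param window_days window length in days; default 40 covers five weeks
#'   of pelvic irradiation plus scheduling slack.
#' @return Minimum count (cells/uL) or `NA`.
#' @export
derive_min_alc <- function(series, window_days = 40) {
  stopifnot(nrow(series) >= 1L)
  inside <- series$day <= window_days
  if (!any(inside)) {
    warning("no ALC measurement within ", window_days, " days; returning NA")
    return(NA_real_)
  }
  min(series$alc[inside])
}

#' Split continuous values into high/low groups
#'
#' Values greater than or equal to the threshold are labelled `high`; the
#' default threshold is the sample median, so ties at the median fall in
#' the high group (matching the usual ">= median" / "< median" group
#' labels of clinical tables).
#'
#' @param values numeric vector (no missing values).
#' @param threshold numeric cut point, or `"median"`.
#' @return list with `labels` (factor, levels `low` < `high`) and
#'   `threshold` (the numeric cut actually used).
#' @export
dichotomize <- function(values, threshold = "median") {
  stopifnot(length(values) >= 1L, !anyNA(values))
  thr <- if (identical(threshold, "median")) stats::median(values) else threshold
  stopifnot(is.numeric(thr), length(thr) == 1L)
  labels <- factor(ifelse(values >= thr, "high", "low"),
                   levels = c("low", "high"))
  list(labels = labels, threshold = thr)
}
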