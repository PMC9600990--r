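#' Classify disease-specific deaths into aggressive and non-aggressive
#'
#' Deaths occurring strictly before the split threshold form the
#' aggressive group; deaths at or after it form the non-aggressive group.
#' With `split_months = "auto"` the threshold is the mean time-to-death
#' among the disease-specific deaths, the empirical divider between the
#' two modes of the time-to-death distribution.
#'
#' @param clinical clinical data frame of an `alc_cohort` (needs `dsd` and
#'   `time_to_dsd_months`).
#' @param split_months months, or `"auto"`.
#' @return list with `labels` (factor per patient: `none`, `aggressive`,
#'   `non_aggressive`) and `threshold` (months).
#' @export
split_dsd <- function(clinical, split_months = 30) {
  dsd <- clinical$dsd == 1
  if (identical(split_months, "auto")) {
    if (!any(dsd))
      stop("split_months = 'auto' requires at least one disease-specific death")
    thr <- mean(clinical$time_to_dsd_months[dsd])
  } else {
    thr <- split_months
    stopifnot(is.numeric(thr), thr > 0)
  }
  labels <- rep("none", nrow(clinical))
  labels[dsd & clinical$time_to_dsd_months < thr] <- "aggressive"
  labels[dsd & clinical$time_to_dsd_months >= thr] <- "non_aggressive"
  list(labels = factor(labels, levels = c("none", "aggressive", "non_aggressive")),
       threshold = thr)
}

#' Progression class from event presence
#'
#' @param lp_time,dm_time months to local progression / distant
#'   metastasis, or `NA` when the event did not occur.
#' @return `"none"`, `"LP"`, `"DM"` or `"LP+DM"`.
#' @export
classify_progression <- function(lp_time, dm_time) {
  lp <- !is.na(lp_time)
  dm <- !is.na(dm_time)
  ifelse(lp & dm, "LP+DM", ifelse(lp, "LP", ifelse(dm, "DM", "none")))
}

#' Build a survival endpoint for every patient
#'
#' Four endpoint definitions are supported. `dss`: any disease-specific
#' death is an event. `dss_a` / `dss_na`: only deaths of the corresponding
#' class (aggressive = before the split threshold) are events; deaths of
#' the other class are treated as cause-specific competing events and, by
#' default, censored at their death time (`censor_other = "death"`;
#' `"threshold"` instead censors late deaths at the split threshold for
#' the aggressive endpoint and vice versa). `pfs`: first of progression or
#' disease-specific death. All times run from the end of treatment.
#'
#' @param clinical clinical data frame of an `alc_cohort`.
#' @param labels aggressive/non-aggressive labels from [split_dsd()].
#' @param kind one of `"dss"`, `"dss_a"`, `"dss_na"`, `"pfs"`.
#' @param threshold the split threshold (months), used only by the
#'   `"threshold"` censoring convention.
#' @param censor_other `"death"` or `"threshold"`.
#' @return data frame `patient_id`, `endpoint`, `time`, `event`.
#' @export
build_endpoints <- function(clinical, labels = NULL,
                            kind = c("dss", "dss_a", "dss_na", "pfs"),
                            threshold = 30, censor_other = c("death", "threshold")) {
  kind <- match.arg(kind)
  censor_other <- match.arg(censor_other)
  if (is.null(labels)) labels <- split_dsd(clinical, threshold)$labels
  stopifnot(length(labels) == nrow(clinical))
  if (any((labels != "none") & clinical$dsd != 1))
    stop("aggressive/non-aggressive label on a patient without disease-specific death")
  dsd <- clinical$dsd == 1
  t_dsd <- clinical$time_to_dsd_months
  fup <- clinical$followup_months

  if (kind == "dss") {
    event <- dsd
    time <- ifelse(dsd, t_dsd, fup)
  } else if (kind %in% c("dss_a", "dss_na")) {
    target <- if (kind == "dss_a") "aggressive" else "non_aggressive"
    other <- setdiff(c("aggressive", "non_aggressive"), target)
    event <- labels == target
    time <- ifelse(event, t_dsd, fup)
    is_other <- labels == other
    time[is_other] <- if (censor_other == "death") t_dsd[is_other] else
      pmin(t_dsd[is_other], threshold)
  } else { # pfs
    prog <- clinical$progression != "none"
    t_prog <- clinical$time_to_progression_months
    event <- prog | dsd
    time <- fup
    time[event] <- pmin(t_prog[event], t_dsd[event], na.rm = TRUE)
  }
  data.frame(patient_id = clinical$patient_id, endpoint = kind,
             time = time, event = as.logical(event),
             stringsAsFactors = FALSE)
}
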