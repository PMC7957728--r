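#' Kaplan-Meier estimate of a survival curve
#'
#' Product-limit estimator of progression-free survival. Ties are handled
#' by simultaneous events at a time point, and subjects censored at an
#' event time are counted at risk for that time's events (the standard
#' convention). The median is the smallest time at which the curve drops
#' to 0.5 or below; if the curve never reaches 0.5 the median is
#' undefined (`NA`).
#'
#' @param times Non-negative follow-up times (months).
#' @param events Logical (or 0/1) event indicators; `TRUE` = progression
#'   or death, `FALSE` = censored.
#' @return A list of class `km_fit`: `curve` (data frame `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`), `median` (months or `NA`), `n`,
#'   `n_events`.
#' @examples
#' km_estimate(c(2, 4, 6, 8), c(TRUE, TRUE, FALSE, TRUE))$median
#' @export
km_estimate <- function(times, events) {
  times <- as.numeric(times)
  events <- as.logical(events)
  if (length(times) == 0L) stop("empty survival input")
  if (length(times) != length(events)) stop("times/events length mismatch")
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and non-negative")
  if (any(is.na(events))) stop("events must not be missing")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv)
  med <- km_median(curve)
  structure(list(curve = curve, median = med, n = length(times),
                 n_events = sum(events)),
            class = "km_fit")
}

km_median <- function(curve) {
  drop <- curve$time[curve$n_event > 0 & curve$surv <= 0.5 + 1e-12]
  if (length(drop) == 0L) NA_real_ else min(drop)
}

#' Median follow-up by inverse Kaplan-Meier estimation
#'
#' Runs the product-limit estimator with the event indicator complemented
#' (censorings become the "events"), so that the median of the resulting
#' curve estimates the median follow-up of the cohort. Complementing twice
#' recovers the ordinary Kaplan-Meier estimate.
#'
#' @inheritParams km_estimate
#' @return A `km_fit` for the complemented indicator; its `median` is the
#'   median follow-up.
#' @export
inverse_km_followup <- function(times, events) {
  km_estimate(times, !as.logical(events))
}

#' Median dichotomization of a parameter
#'
#' Splits per-patient values at the cohort median: `low` = values less
#' than or equal to the median, `high` = values above it. Requires at
#' least 4 non-missing values; a split in which every value equals the
#' median (so one group would be empty) is a degenerate-split error.
#'
#' @param values Per-patient parameter values (NAs allowed, excluded from
#'   the cut and labelled `NA`).
#' @return A list of class `median_split`: `labels` (factor
#'   `low`/`high`), `cut` (the median), `n_low`, `n_high`.
#' @export
dichotomize_at_median <- function(values) {
  values <- as.numeric(values)
  ok <- !is.na(values)
  if (sum(ok) < 4L) stop("at least 4 non-missing values are required")
  cut <- stats::median(values[ok])
  labels <- factor(ifelse(values <= cut, "low", "high"),
                   levels = c("low", "high"))
  n_low <- sum(labels == "low", na.rm = TRUE)
  n_high <- sum(labels == "high", na.rm = TRUE)
  if (n_low == 0L || n_high == 0L)
    stop("degenerate split: all values fall on one side of the median")
  structure(list(labels = labels, cut = cut, n_low = n_low,
                 n_high = n_high),
            class = "median_split")
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank comparison of two survival groups: at
#' each distinct event time the observed number of events in group A is
#' compared with its hypergeometric expectation given the risk sets, and
#' the variance-standardized sum is referred to a chi-square distribution
#' with 1 degree of freedom (two-sided).
#'
#' @param time Follow-up times of all subjects (months).
#' @param event Event indicators (logical or 0/1).
#' @param group Two-level factor (or vector coercible to one) assigning
#'   each subject to a group.
#' @return A list of class `logrank_test`: `statistic` (chi-square, 1 df),
#'   `p_value`, `observed` and `expected` event counts per group, `n` per
#'   group.
#' @export
logrank_test <- function(time, event, group) {
  time <- as.numeric(time)
  event <- as.logical(event)
  group <- factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups are required")
  if (any(table(group) == 0L)) stop("both groups must be non-empty")
  if (sum(event) == 0L) stop("log-rank test undefined with zero events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  stat <- sd$chisq
  structure(list(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 observed = sd$obs, expected = sd$exp,
                 n = as.vector(table(group))),
            class = "logrank_test")
}

#' Median-split survival screen over PET parameters
#'
#' For each requested parameter at the requested timepoint, dichotomizes
#' the per-patient values at the cohort median and compares
#' progression-free survival between the two groups with a log-rank test.
#' The screen is exploratory and deliberately **not** adjusted for
#' multiplicity of testing; interpret individual p-values accordingly.
#'
#' @param patients Data frame with one row per patient: `pfs_months`,
#'   `progressed`, and a column `<parameter>_<timepoint>` for each
#'   parameter (e.g. `suv_mean_interim`).
#' @param parameters Character vector of parameter names to screen.
#' @param timepoint `"interim"` or `"baseline"`.
#' @return Data frame with one row per parameter: `parameter`,
#'   `timepoint`, `cut_value`, `n_low`, `n_high`, `statistic`, `p_value`,
#'   `median_pfs_low`, `median_pfs_high`, `skipped`, `reason`. A parameter
#'   missing for more than half the cohort, or degenerate at the median,
#'   is skipped with a warning rather than failing the screen.
#' @export
survival_screen <- function(patients,
                            parameters = c("suv_mean", "suv_max", "K1",
                                           "k3", "Ki", "FD"),
                            timepoint = c("interim", "baseline")) {
  timepoint <- match.arg(timepoint)
  stopifnot(all(c("pfs_months", "progressed") %in% names(patients)))
  rows <- lapply(parameters, function(p) {
    col <- paste(p, timepoint, sep = "_")
    out <- data.frame(parameter = p, timepoint = timepoint,
                      cut_value = NA_real_, n_low = NA_integer_,
                      n_high = NA_integer_, statistic = NA_real_,
                      p_value = NA_real_, median_pfs_low = NA_real_,
                      median_pfs_high = NA_real_, skipped = TRUE,
                      reason = NA_character_)
    if (!col %in% names(patients)) {
      out$reason <- "column absent"
      warning("parameter ", p, " (", timepoint, "): column absent; skipped")
      return(out)
    }
    v <- patients[[col]]
    if (sum(is.na(v)) > nrow(patients) / 2) {
      out$reason <- "missing for more than half the cohort"
      warning("parameter ", p, " (", timepoint, "): ", out$reason,
              "; skipped")
      return(out)
    }
    split <- tryCatch(dichotomize_at_median(v), error = function(e) e)
    if (inherits(split, "error")) {
      out$reason <- conditionMessage(split)
      warning("parameter ", p, " (", timepoint, "): ", out$reason,
              "; skipped")
      return(out)
    }
    keep <- !is.na(split$labels)
    lr <- logrank_test(patients$pfs_months[keep],
                       patients$progressed[keep], split$labels[keep])
    km_lo <- km_estimate(patients$pfs_months[keep][split$labels[keep] == "low"],
                         patients$progressed[keep][split$labels[keep] == "low"])
    km_hi <- km_estimate(patients$pfs_months[keep][split$labels[keep] == "high"],
                         patients$progressed[keep][split$labels[keep] == "high"])
    out$cut_value <- split$cut
    out$n_low <- split$n_low
    out$n_high <- split$n_high
    out$statistic <- lr$statistic
    out$p_value <- lr$p_value
    out$median_pfs_low <- km_lo$median
    out$median_pfs_high <- km_hi$median
    out$skipped <- FALSE
    out
  })
  do.call(rbind, rows)
}
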