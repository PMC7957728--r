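#' Standardized uptake value
#'
#' `SUV = tissue concentration (Bq/g) / (injected dose (Bq) / body weight
#' (g))`. With the conventional tissue density of 1 g/mL, Bq/g and Bq/mL
#' are interchangeable. Vectorized over `concentration`.
#'
#' @param concentration Tissue activity concentration, Bq/g (>= 0).
#' @param injected_dose Injected activity, Bq (> 0).
#' @param body_weight Body weight, g (> 0).
#' @return Unitless SUV.
#' @examples
#' compute_suv(10000, 2.5e8, 7.0e4)  # 2.8
#' @export
compute_suv <- function(concentration, injected_dose, body_weight) {
  if (any(injected_dose <= 0)) stop("injected_dose must be positive")
  if (any(body_weight <= 0)) stop("body_weight must be positive")
  if (any(concentration < 0)) stop("concentration must be non-negative")
  concentration / (injected_dose / body_weight)
}

#' Interval change between baseline and interim values
#'
#' `change (%) = (interim - baseline) / baseline * 100`. The raw
#' percentage is returned; the reporting layer rounds it with
#' [round_percent()] (nearest integer, halves away from zero).
#'
#' @param baseline Baseline value (> 0); vectorized.
#' @param interim Interim value; vectorized.
#' @return Percent change (unrounded).
#' @examples
#' interval_change(6.9, 5.7)   # -17.39...
#' round_percent(interval_change(11.0, 7.7))  # -30
#' @export
interval_change <- function(baseline, interim) {
  if (any(baseline <= 0)) stop("interval change undefined for baseline <= 0")
  (interim - baseline) / baseline * 100
}

#' Round a percentage to the nearest integer, halves away from zero
#'
#' @param x Percent value(s).
#' @return Integer-valued numeric (e.g. -37.5 becomes -38, +12.5 becomes
#'   +13).
#' @export
round_percent <- function(x) {
  # the epsilon keeps exact halves (e.g. -12.5 reached through division)
  # on the away-from-zero side despite binary floating point
  sign(x) * floor(abs(x) + 0.5 + 1e-9)
}

#' Select the hottest lesions of a patient
#'
#' Orders one patient's baseline lesions by descending baseline `suv_max`
#' and keeps the first `n_max` (default 5, the mean-of-hottest approach;
#' `n_max = 1` gives the single-hottest-lesion approach). Ties are broken
#' deterministically by ascending lesion id, so the selection is a
#' permutation-invariant function of the input set.
#'
#' @param lesions Data frame of one patient's baseline lesion records with
#'   columns `lesion_id` and `suv_max`.
#' @param n_max Maximum number of lesions to keep.
#' @return Vector of `lesion_id`, hottest first.
#' @export
select_hottest <- function(lesions, n_max = 5) {
  if (is.null(lesions) || nrow(lesions) == 0L)
    stop("no lesions to select from")
  stopifnot(all(c("lesion_id", "suv_max") %in% names(lesions)))
  ord <- order(-lesions$suv_max, lesions$lesion_id)
  utils::head(lesions$lesion_id[ord], n_max)
}

#' Aggregate selected lesions to per-patient parameter values
#'
#' Mode `"mean_of_hottest"` takes the arithmetic mean of each parameter
#' over the selected lesions; `"single_hottest"` returns the one lesion's
#' values. Missing kinetic/FD entries (lesions outside the dynamic field
#' of view) are excluded pairwise; if a parameter is missing for every
#' selected lesion its aggregate is `NA` (a missing-output flag, not an
#' error).
#'
#' @param lesions Data frame of the selected lesion records of one patient
#'   at one timepoint.
#' @param parameters Character vector of parameter columns to aggregate.
#' @param mode `"mean_of_hottest"` or `"single_hottest"`.
#' @return Named numeric vector of per-parameter values.
#' @export
aggregate_patient <- function(lesions,
                              parameters = c("suv_mean", "suv_max", "K1",
                                             "k3", "Ki", "FD"),
                              mode = c("mean_of_hottest", "single_hottest")) {
  mode <- match.arg(mode)
  if (is.null(lesions) || nrow(lesions) == 0L) stop("empty lesion selection")
  if (mode == "single_hottest" && nrow(lesions) != 1L)
    stop("single_hottest mode expects exactly one lesion record")
  vapply(parameters, function(p) {
    v <- lesions[[p]]
    if (is.null(v) || all(is.na(v))) return(NA_real_)
    mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Aggregate a lesion table to per-patient parameter values
#'
#' Applies hottest-lesion selection ([select_hottest()], on baseline
#' `suv_max`) and per-patient aggregation ([aggregate_patient()]) to every
#' patient of a lesion table, at both timepoints. `n_max = 5` is the
#' mean-of-hottest approach, `n_max = 1` the single-hottest-lesion
#' approach.
#'
#' @param lesions Data frame with one row per (patient, lesion, timepoint):
#'   columns `patient_id`, `lesion_id`, `timepoint` and the parameter
#'   columns.
#' @param n_max Maximum number of hottest lesions per patient.
#' @param parameters Parameter columns to aggregate.
#' @return Data frame with one row per patient: `patient_id` plus columns
#'   `<parameter>_<timepoint>`.
#' @export
aggregate_cohort <- function(lesions, n_max = 5,
                             parameters = c("suv_mean", "suv_max", "K1",
                                            "k3", "Ki", "FD")) {
  stopifnot(all(c("patient_id", "lesion_id", "timepoint") %in%
                  names(lesions)))
  mode <- if (n_max == 1L) "single_hottest" else "mean_of_hottest"
  rows <- lapply(unique(lesions$patient_id), function(pid) {
    base <- lesions[lesions$patient_id == pid &
                      lesions$timepoint == "baseline", , drop = FALSE]
    sel <- select_hottest(base, n_max = n_max)
    out <- data.frame(patient_id = pid)
    for (tp in c("baseline", "interim")) {
      recs <- lesions[lesions$patient_id == pid &
                        lesions$timepoint == tp &
                        lesions$lesion_id %in% sel, , drop = FALSE]
      vals <- aggregate_patient(recs, parameters, mode = mode)
      names(vals) <- paste(parameters, tp, sep = "_")
      out <- cbind(out, as.data.frame(as.list(vals)))
    }
    out
  })
  do.call(rbind, rows)
}

#' Reshape a per-patient aggregate table to timepoint rows
#'
#' Turns the wide `<parameter>_<timepoint>` columns of
#' [aggregate_cohort()] into one row per (patient, timepoint) with plain
#' parameter columns, the layout [cohort_summary()] consumes.
#'
#' @param agg Output of [aggregate_cohort()].
#' @param parameters Parameter names present in `agg`.
#' @return Data frame with `patient_id`, `timepoint` and parameter
#'   columns.
#' @export
aggregate_to_timepoints <- function(agg,
                                    parameters = c("suv_mean", "suv_max",
                                                   "K1", "k3", "Ki",
                                                   "FD")) {
  do.call(rbind, lapply(c("baseline", "interim"), function(tp) {
    d <- data.frame(patient_id = agg$patient_id, timepoint = tp)
    for (p in parameters) d[[p]] <- agg[[paste(p, tp, sep = "_")]]
    d
  }))
}

#' Cohort median summary table
#'
#' Builds the per-parameter summary reported for a cohort: the median
#' across patients at baseline and at interim, and the interval change of
#' the two medians (the change column is computed between the medians, not
#' as the median of per-patient changes; both statistics are available —
#' see `change_of_medians_pct` versus [interval_change()] applied per
#' patient).
#'
#' @param records Data frame with one row per (patient, timepoint) holding
#'   a `timepoint` column (`"baseline"`/`"interim"`) and the parameter
#'   columns.
#' @param parameters Character vector of parameter columns to summarize.
#' @return Data frame with columns `parameter`, `baseline_median`,
#'   `interim_median`, `change_pct` (raw) and `change_pct_rounded`.
#' @export
cohort_summary <- function(records,
                           parameters = c("suv_mean", "suv_max", "K1",
                                          "k3", "Ki", "FD")) {
  stopifnot("timepoint" %in% names(records))
  base <- records[records$timepoint == "baseline", , drop = FALSE]
  intr <- records[records$timepoint == "interim", , drop = FALSE]
  if (nrow(base) == 0L || nrow(intr) == 0L)
    stop("records must span both the baseline and the interim timepoint")
  rows <- lapply(parameters, function(p) {
    bm <- stats::median(base[[p]], na.rm = TRUE)
    im <- stats::median(intr[[p]], na.rm = TRUE)
    ch <- if (is.finite(bm) && bm > 0) interval_change(bm, im) else NA_real_
    data.frame(parameter = p, baseline_median = bm, interim_median = im,
               change_pct = ch, change_pct_rounded = round_percent(ch))
  })
  do.call(rbind, rows)
}
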