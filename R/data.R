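#' Published reference medians
#'
#' Median PET parameter values (baseline and interim, with the published
#' rounded interval-change column) reported for a 25-patient metastatic
#' melanoma cohort under PD-1 blockade: melanoma lesions under the
#' mean-of-five-hottest and single-hottest-lesion approaches, and the
#' thyroid, bone-marrow and spleen reference organs. Two rows are printed
#' in the source with a change percentage that is not reproducible from
#' the change formula applied to the two medians (`formula_consistent =
#' FALSE`); they are kept for completeness but flagged, and no alternative
#' formula is inferred for them.
#'
#' @return Data frame with columns `tissue`, `parameter`,
#'   `baseline_median`, `interim_median`, `printed_change_pct`,
#'   `formula_consistent`.
#' @export
reference_medians <- function() {
  utils::read.delim(system.file("extdata", "reference_medians.tsv",
                                package = "dynpet"))
}

#' Example per-patient survival outcomes
#'
#' Progression-free survival (months from the interim scan) and
#' progression indicators of the published 25-patient melanoma cohort,
#' with treatment arms. All 18 progression events precede the earliest
#' censoring time, so the Kaplan-Meier curve of this cohort is the
#' closed-form product-limit staircase and its median (9.6 months) can be
#' verified by hand.
#'
#' @return Data frame with columns `patient_id`, `treatment`,
#'   `pfs_months`, `progressed` (logical).
#' @export
example_pfs_cohort <- function() {
  d <- utils::read.csv(system.file("extdata", "pfs_outcomes.csv",
                                   package = "dynpet"))
  d$progressed <- as.logical(d$progressed)
  d
}

#' Published lesion counts per site group
#'
#' Number of evaluated melanoma lesions per localization group, for the
#' whole-body (semiquantitative) analysis and for the subset inside the
#' dynamic field of view (kinetic and fractal analysis).
#'
#' @return Data frame with columns `site_group`, `n_whole_body`,
#'   `n_dynamic_fov`.
#' @export
lesion_site_counts <- function() {
  utils::read.csv(system.file("extdata", "lesion_site_counts.csv",
                              package = "dynpet"))
}
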