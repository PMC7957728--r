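#' Write a TAC (with its plasma curve) to CSV
#'
#' One row per frame with columns `frame_start_s`, `frame_duration_s`,
#' `tissue_kBq_per_mL` and `plasma_kBq_per_mL` (the frame-averaged plasma
#' input).
#'
#' @param tac A [tissue_tac()].
#' @param cp The plasma input function the TAC belongs to.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tac_csv <- function(tac, cp, path) {
  stopifnot(inherits(tac, "tissue_tac"))
  plasma <- frame_average(as_input_function(cp)$fun, tac$protocol)$values
  utils::write.csv(
    data.frame(frame_start_s = tac$protocol$frame_starts,
               frame_duration_s = tac$protocol$frame_durations,
               tissue_kBq_per_mL = tac$values,
               plasma_kBq_per_mL = plasma),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a TAC CSV
#'
#' Inverse of [write_tac_csv()]. The plasma column is returned both as a
#' per-frame vector and as a linear-interpolation `input_function` over
#' the frame mid-times (zero at time 0).
#'
#' @param path CSV file with columns `frame_start_s`, `frame_duration_s`,
#'   `tissue_kBq_per_mL`, `plasma_kBq_per_mL`.
#' @return A list: `tac` ([tissue_tac()]), `plasma` (per-frame vector),
#'   `cp` (interpolated `input_function`), `protocol`.
#' @export
read_tac_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("frame_start_s", "frame_duration_s", "tissue_kBq_per_mL",
            "plasma_kBq_per_mL")
  if (!all(need %in% names(d)))
    stop("TAC CSV must have columns ", paste(need, collapse = ", "))
  protocol <- acquisition_protocol(d$frame_start_s, d$frame_duration_s)
  mid <- frame_mid_times(protocol)
  knots_t <- c(0, mid)
  knots_v <- c(0, d$plasma_kBq_per_mL)
  cp <- structure(list(
    fun = function(t) stats::approx(knots_t, knots_v, xout = pmax(t, 0),
                                    rule = 2)$y,
    params = NULL), class = "input_function")
  list(tac = tissue_tac(protocol, d$tissue_kBq_per_mL),
       plasma = d$plasma_kBq_per_mL, cp = cp, protocol = protocol)
}

#' Write / read the cohort lesion and patient tables
#'
#' The lesion CSV has one row per (patient, lesion, timepoint) with the
#' lesion-record fields; the patient CSV has one row per patient with
#' `pfs_months`, `progressed` and any aggregated parameter columns.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return `path` (writers, invisibly) or the validated data frame
#'   (readers).
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_lesions_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_lesions_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("patient_id", "lesion_id", "timepoint", "suv_mean", "suv_max")
  if (!all(need %in% names(d)))
    stop("lesion CSV must have columns ", paste(need, collapse = ", "))
  if (nrow(d) == 0L) stop("lesion CSV is empty")
  d
}

#' @rdname cohort_io
#' @export
write_patients_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_patients_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("patient_id", "pfs_months", "progressed")
  if (!all(need %in% names(d)))
    stop("patient CSV must have columns ", paste(need, collapse = ", "))
  if (nrow(d) == 0L) stop("patient CSV is empty")
  d$progressed <- as.logical(d$progressed)
  d
}

#' Write a Kaplan-Meier step function to CSV
#'
#' Columns `time`, `surv`, `n_risk` (plus `group` when given), suitable
#' for plotting stepwise survival curves.
#'
#' @param km A `km_fit` (or a data frame already in curve layout).
#' @param path File path.
#' @param group Optional group label column value.
#' @return `path`, invisibly.
#' @export
write_km_csv <- function(km, path, group = NULL) {
  curve <- if (inherits(km, "km_fit")) km$curve else km
  out <- curve[, intersect(c("time", "surv", "n_risk", "group"),
                           names(curve)), drop = FALSE]
  if (!is.null(group)) out$group <- group
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
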