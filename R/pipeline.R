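#' Pipeline settings
#'
#' @param refit_tacs Refit the two-tissue model to every available lesion
#'   TAC and replace the kinetic columns with the fitted values (slower;
#'   when `FALSE`, the kinetic columns already present in the lesion table
#'   are used as-is).
#' @param recompute_fd Recompute FD by box counting from the voxel VOIs
#'   when they are available.
#' @param parameters Parameter columns carried through summaries and the
#'   survival screen.
#' @param fit Settings for the kinetic fitter ([fit_config()]).
#' @param fd_levels Dyadic levels for [fd_boxcount()].
#' @return A list of class `pipeline_settings`.
#' @export
pipeline_settings <- function(refit_tacs = FALSE, recompute_fd = TRUE,
                              parameters = c("suv_mean", "suv_max", "K1",
                                             "k3", "Ki", "FD"),
                              fit = fit_config(), fd_levels = 1:4) {
  structure(list(refit_tacs = refit_tacs, recompute_fd = recompute_fd,
                 parameters = parameters, fit = fit,
                 fd_levels = fd_levels),
            class = "pipeline_settings")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
}

#' Run the full cohort analysis pipeline
#'
#' End-to-end orchestration: (optional) cohort synthesis, kinetic
#' refitting of lesion TACs, box-counting FD from voxel VOIs, SUV
#' aggregation under both hottest-lesion approaches (mean of up to five
#' hottest lesions; single hottest lesion), cohort median summary tables
#' for lesions and each reference organ, and the median-split log-rank
#' survival screen of baseline and interim parameters. Each stage fails
#' fast with a stage-labelled error.
#'
#' @param input One of: a [cohort_config()] (the cohort is generated), a
#'   `synthetic_cohort`, or a named list of CSV paths
#'   `list(lesions = ..., patients = ..., organs = ...)` (organs
#'   optional).
#' @param settings A [pipeline_settings()].
#' @return A list of class `analysis_report`: `lesion_summary_mean5`,
#'   `lesion_summary_single`, `organ_summaries` (named list),
#'   `survival_screen` (all approaches and timepoints, with columns
#'   `approach` and the screen fields), `km_curves` (named list of
#'   two-group step functions per screened parameter), `patients`,
#'   `patients_single`, `lesions`, `organs`, `provenance`.
#' @export
run_pipeline <- function(input, settings = pipeline_settings()) {
  stopifnot(inherits(settings, "pipeline_settings"))
  params <- settings$parameters

  cohort <- run_stage("input", {
    if (inherits(input, "cohort_config")) {
      generate_cohort(input)
    } else if (inherits(input, "synthetic_cohort")) {
      input
    } else if (is.list(input) && !is.null(input$lesions)) {
      lst <- list(lesions = read_lesions_csv(input$lesions),
                  patients = if (!is.null(input$patients))
                    read_patients_csv(input$patients) else NULL,
                  organs = if (!is.null(input$organs))
                    utils::read.csv(input$organs) else NULL,
                  tacs = list(), vois = list(), config = NULL)
      structure(c(lst, list(patients_single = NULL)), class = "file_cohort")
    } else stop("unrecognized pipeline input")
  })
  lesions <- cohort$lesions
  organs <- cohort$organs

  lesions <- run_stage("kinetic_fit", {
    if (settings$refit_tacs && length(cohort$tacs) > 0L) {
      cp <- feng_input_function()
      for (key in names(cohort$tacs)) {
        parts <- strsplit(key, "_")[[1]]
        if (length(parts) != 3L || !startsWith(parts[2], "L")) next
        fit <- fit_2tc(cohort$tacs[[key]], cp, settings$fit)
        sel <- lesions$patient_id == parts[1] &
          lesions$lesion_id == as.integer(sub("^L", "", parts[2])) &
          lesions$timepoint == parts[3]
        lesions[sel, c("K1", "k2", "k3", "k4", "VB", "Ki")] <-
          as.data.frame(fit$params[c("K1", "k2", "k3", "k4", "VB", "Ki")])
      }
    }
    lesions
  })

  run_stage("fractal", {
    if (settings$recompute_fd && length(cohort$vois) > 0L) {
      for (key in names(cohort$vois)) {
        fd <- voi_fd(cohort$vois[[key]], levels = settings$fd_levels)$voi_fd
        parts <- strsplit(key, "_")[[1]]
        tp <- parts[length(parts)]
        unit <- paste(parts[-c(1, length(parts))], collapse = "_")
        if (startsWith(unit, "L")) {
          sel <- lesions$patient_id == parts[1] &
            lesions$lesion_id == as.integer(sub("^L", "", unit)) &
            lesions$timepoint == tp
          lesions$FD[sel] <- fd
        } else if (!is.null(organs)) {
          sel <- organs$patient_id == parts[1] & organs$organ == unit &
            organs$timepoint == tp
          organs$FD[sel] <- fd
        }
      }
    }
    NULL
  })

  agg <- run_stage("aggregation", {
    list(mean5 = aggregate_cohort(lesions, 5L, params),
         single = aggregate_cohort(lesions, 1L, params))
  })

  summaries <- run_stage("summary", {
    org <- list()
    if (!is.null(organs))
      for (o in unique(organs$organ))
        org[[o]] <- cohort_summary(organs[organs$organ == o, , drop = FALSE],
                                   params)
    list(mean5 = cohort_summary(aggregate_to_timepoints(agg$mean5, params),
                                params),
         single = cohort_summary(aggregate_to_timepoints(agg$single, params),
                                 params),
         organs = org)
  })

  outcome_cols <- c("patient_id", "pfs_months", "progressed")
  outcomes <- if (!is.null(cohort$patients) &&
                  all(outcome_cols %in% names(cohort$patients)))
    cohort$patients[, outcome_cols] else NULL

  screen <- NULL
  km_curves <- list()
  if (!is.null(outcomes)) {
    screen <- run_stage("survival", {
      tabs <- list()
      for (approach in c("mean5", "single")) {
        pat <- merge(outcomes, agg[[approach]], by = "patient_id")
        for (tp in c("interim", "baseline")) {
          s <- suppressWarnings(survival_screen(pat, params, tp))
          s$approach <- approach
          tabs[[paste(approach, tp)]] <- s
          for (i in which(!s$skipped)) {
            p <- s$parameter[i]
            split <- dichotomize_at_median(pat[[paste(p, tp, sep = "_")]])
            cv <- lapply(c("low", "high"), function(g) {
              keep <- !is.na(split$labels) & split$labels == g
              km <- km_estimate(pat$pfs_months[keep], pat$progressed[keep])
              cbind(km$curve[, c("time", "surv", "n_risk")], group = g)
            })
            km_curves[[paste(approach, tp, p, sep = "_")]] <-
              do.call(rbind, cv)
          }
        }
      }
      do.call(rbind, tabs)
    })
  }

  provenance <- list(
    package = "dynpet",
    version = as.character(utils::packageVersion("dynpet")),
    settings = unclass(settings[c("refit_tacs", "recompute_fd",
                                  "parameters", "fd_levels")]),
    config = if (!is.null(cohort$config)) unclass_config(cohort$config),
    seed = if (!is.null(cohort$config)) cohort$config$seed,
    multiplicity_note = paste("Survival screen p-values are not adjusted",
                              "for multiplicity of testing."))

  structure(list(
    lesion_summary_mean5 = summaries$mean5,
    lesion_summary_single = summaries$single,
    organ_summaries = summaries$organs,
    survival_screen = screen,
    km_curves = km_curves,
    patients = if (!is.null(outcomes)) merge(outcomes, agg$mean5,
                                             by = "patient_id"),
    patients_single = if (!is.null(outcomes)) merge(outcomes, agg$single,
                                                    by = "patient_id"),
    lesions = lesions, organs = organs,
    provenance = provenance), class = "analysis_report")
}

unclass_config <- function(cfg) {
  lapply(unclass(cfg), function(x) if (is.list(x)) lapply(x, as.vector)
         else as.vector(x))
}

#' Write an analysis report to disk
#'
#' One CSV per summary table, the survival-screen table, one step-function
#' CSV per exported Kaplan-Meier comparison, and a `manifest.json` listing
#' every emitted file with its MD5 checksum alongside the full provenance
#' block (settings, generator config, seed, package version). Column order
#' is stable, so an identical report writes byte-identical files.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
  }
  emit(report$lesion_summary_mean5, "lesion_summary_mean5.csv")
  emit(report$lesion_summary_single, "lesion_summary_single.csv")
  for (o in names(report$organ_summaries))
    emit(report$organ_summaries[[o]], paste0("organ_summary_", o, ".csv"))
  if (!is.null(report$survival_screen))
    emit(report$survival_screen, "survival_screen.csv")
  for (nm in names(report$km_curves))
    emit(report$km_curves[[nm]], paste0("km_", nm, ".csv"))
  if (!is.null(report$patients)) emit(report$patients, "patients.csv")
  emit(report$lesions, "lesions.csv")
  if (!is.null(report$organs)) emit(report$organs, "organs.csv")

  checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(checksums) <- files
  manifest <- list(files = checksums, provenance = report$provenance)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
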