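#' Simulate a noisy lesion time-activity curve
#'
#' Frame-averages the noiseless two-tissue-compartment forward model on
#' the protocol and adds proportional Gaussian noise (standard deviation
#' `cv x value`), clipped at zero. With `cv = 0` this is exactly the
#' frame-averaged forward model.
#'
#' @param truth Ground-truth [kinetic_params()].
#' @param cp Plasma input function.
#' @param protocol An [acquisition_protocol()].
#' @param cv Proportional noise coefficient of variation (>= 0).
#' @param seed Optional integer seed; when given, the draw is made under a
#'   local RNG state and the caller's state is untouched.
#' @return A [tissue_tac()].
#' @export
generate_lesion_tac <- function(truth, cp, protocol, cv = 0.05,
                                seed = NULL) {
  if (cv < 0) stop("cv must be non-negative")
  clean <- forward_2tc_frames(truth, cp, protocol)
  draw <- function() {
    noisy <- clean$values +
      stats::rnorm(length(clean$values)) * cv * clean$values
    tissue_tac(protocol, pmax(noisy, 0))
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Simulate a heterogeneous voxel-level VOI
#'
#' Each voxel draws its own kinetic parameters as
#' `truth x exp(h * Z)` (independent standard-normal `Z` per rate
#' constant), then a voxel TAC via [generate_lesion_tac()]. `h = 0` gives
#' identical voxel kinetics; larger `h` produces more heterogeneous voxel
#' curves and hence larger VOI fractal dimension.
#'
#' @param truth Central [kinetic_params()].
#' @param h Heterogeneity knob (>= 0), log-scale dispersion of the
#'   voxel-level kinetic parameters.
#' @param n_voxels Number of voxels (>= 1).
#' @param cp Plasma input function.
#' @param protocol An [acquisition_protocol()].
#' @param cv Per-frame proportional noise passed to the voxel TACs.
#' @param seed Optional integer seed (local RNG state).
#' @return A [voxel_dynamic_voi()].
#' @export
generate_voxel_voi <- function(truth, h, n_voxels, cp, protocol, cv = 0,
                               seed = NULL) {
  if (h < 0) stop("h must be non-negative")
  n_voxels <- as.integer(n_voxels)
  if (n_voxels < 1L) stop("n_voxels must be >= 1")
  draw <- function() {
    vals <- matrix(0, n_voxels, protocol$n_frames)
    for (v in seq_len(n_voxels)) {
      z <- stats::rnorm(5)
      p <- kinetic_params(truth$K1 * exp(h * z[1]),
                          truth$k2 * exp(h * z[2]),
                          truth$k3 * exp(h * z[3]),
                          truth$k4 * exp(h * z[4]),
                          min(truth$VB * exp(h * z[5]), 1))
      vals[v, ] <- generate_lesion_tac(p, cp, protocol, cv)$values
    }
    voxel_dynamic_voi(protocol, vals)
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Configuration of the synthetic dynamic-PET cohort
#'
#' Defines the study conditions the generator emulates: a 25-patient
#' melanoma cohort under PD-1 blockade (8 pembrolizumab, 4 nivolumab, 13
#' ipilimumab+nivolumab) imaged dynamically at baseline and after two
#' therapy cycles on the default 24-frame / 60-min protocol. Lesion and
#' reference-organ kinetic centers, SUV levels, and interim response
#' multipliers are anchored to the published cohort medians; dispersions
#' are log-normal. Progression-free survival is exponential with a
#' log-linear effect of selected standardized interim parameters and
#' administrative censoring.
#'
#' @param n_patients Number of patients.
#' @param treatment_probs Named probabilities over the three regimens.
#' @param lesion_count_lambda Lesions per patient are
#'   `1 + Poisson(lambda)` (default mean ~3.9, i.e. ~98 lesions in 25
#'   patients).
#' @param site_probs Named probabilities over the five lesion site groups.
#' @param fov_probs Named per-site probability that a lesion lies in the
#'   dynamic field of view (thorax / upper abdomen).
#' @param lesion_kinetics,organ_kinetics Named centers of `(K1, k2, k3,
#'   k4, VB)` (1/min; VB unitless) for melanoma lesions and for the
#'   thyroid / bone-marrow / spleen reference organs.
#' @param lesion_suv_mean,suv_max_ratio Baseline lesion SUV_mean center
#'   and SUV_max / SUV_mean ratio.
#' @param organ_suv_mean,organ_suv_max_ratio Per-organ SUV centers.
#' @param fd_centers Per-tissue baseline fractal-dimension centers used by
#'   the fast (`include_vois = FALSE`) path.
#' @param interim_multipliers Per-tissue named median response multipliers
#'   applied to baseline values (e.g. lesion SUV multiplier 5.7/6.9).
#' @param sigma Log-normal dispersion of baseline parameters.
#' @param response_sigma Log-normal dispersion of the response
#'   multipliers.
#' @param tac_cv Proportional TAC noise CV.
#' @param n_voxels,heterogeneity Voxel count and heterogeneity knob `h` of
#'   the simulated VOIs.
#' @param hazard_median_months Baseline median PFS (months); baseline
#'   hazard is `log(2) / hazard_median_months`.
#' @param hazard_coefs Named log-hazard coefficients on standardized
#'   per-patient covariates (names refer to columns of the aggregated
#'   patient table, e.g. `"suv_mean_interim"`). All-zero coefficients give
#'   a null cohort.
#' @param censor_window_months Administrative censoring window; censoring
#'   times are uniform on it.
#' @param include_tacs Generate per-lesion TACs (needed to exercise the
#'   kinetic fitter).
#' @param include_vois Generate voxel VOIs and compute FD by box counting;
#'   when `FALSE`, FD is drawn directly around `fd_centers` (fast path for
#'   simulation studies that do not touch the image layer).
#' @param seed Master seed; `(config, seed)` determines the cohort
#'   bit-for-bit.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_patients = 25,
    treatment_probs = c(pembrolizumab = 8, nivolumab = 4,
                        ipilimumab_nivolumab = 13) / 25,
    lesion_count_lambda = 2.9,
    site_probs = c(lymph_node = 31, osseous = 10, pulmonary = 16,
                   mesenterial_abdominal = 12, soft_tissue = 29) / 98,
    fov_probs = c(lymph_node = 15 / 31, osseous = 5 / 10,
                  pulmonary = 13 / 16, mesenterial_abdominal = 7 / 12,
                  soft_tissue = 15 / 29),
    lesion_kinetics = c(K1 = 0.19, k2 = 0.532, k3 = 0.19, k4 = 0.01,
                        VB = 0.05),
    organ_kinetics = list(
      thyroid = c(K1 = 0.32, k2 = 1.20, k3 = 0.08, k4 = 0.01, VB = 0.05),
      bone_marrow = c(K1 = 0.18, k2 = 0.45, k3 = 0.09, k4 = 0.01,
                      VB = 0.05),
      spleen = c(K1 = 0.40, k2 = 0.8633, k3 = 0.07, k4 = 0.01,
                 VB = 0.05)),
    lesion_suv_mean = 6.9, suv_max_ratio = 9.8 / 6.9,
    organ_suv_mean = c(thyroid = 2.1, bone_marrow = 2.3, spleen = 2.3),
    organ_suv_max_ratio = c(thyroid = 2.6 / 2.1, bone_marrow = 3.1 / 2.3,
                            spleen = 3.2 / 2.3),
    fd_centers = c(lesion = 1.19, thyroid = 1.06, bone_marrow = 1.06,
                   spleen = 1.10),
    interim_multipliers = list(
      lesion = c(suv = 5.7 / 6.9, K1 = 0.15 / 0.19, k3 = 0.18 / 0.19,
                 FD = 1.21 / 1.19),
      thyroid = c(suv = 2.3 / 2.1, K1 = 0.28 / 0.32, k3 = 0.22 / 0.08,
                  FD = 1.09 / 1.06),
      bone_marrow = c(suv = 2.4 / 2.3, K1 = 0.13 / 0.18, k3 = 0.12 / 0.09,
                      FD = 1.07 / 1.06),
      spleen = c(suv = 2.2 / 2.3, K1 = 0.25 / 0.40, k3 = 0.05 / 0.07,
                 FD = 1.09 / 1.10)),
    sigma = 0.25, response_sigma = 0.2, tac_cv = 0.05,
    n_voxels = 16, heterogeneity = 0.3,
    hazard_median_months = 9.6,
    hazard_coefs = c(suv_mean_interim = 0.7),
    censor_window_months = c(18, 42),
    include_tacs = TRUE, include_vois = TRUE,
    seed = 1) {
  cfg <- as.list(environment())
  bad <- character(0)
  if (abs(sum(treatment_probs) - 1) > 1e-9) bad <- c(bad, "treatment_probs")
  if (abs(sum(site_probs) - 1) > 1e-9) bad <- c(bad, "site_probs")
  if (any(fov_probs < 0 | fov_probs > 1)) bad <- c(bad, "fov_probs")
  if (n_patients < 1) bad <- c(bad, "n_patients")
  if (sigma < 0 || response_sigma < 0) bad <- c(bad, "sigma")
  if (tac_cv < 0) bad <- c(bad, "tac_cv")
  if (heterogeneity < 0) bad <- c(bad, "heterogeneity")
  if (hazard_median_months <= 0) bad <- c(bad, "hazard_median_months")
  if (length(censor_window_months) != 2L ||
      any(censor_window_months <= 0) ||
      diff(censor_window_months) < 0) bad <- c(bad, "censor_window_months")
  if (length(bad) > 0L)
    stop("invalid cohort config field(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "cohort_config")
}

rlnormc <- function(n, center, sigma) center * exp(sigma * stats::rnorm(n))

#' Generate a synthetic dynamic-PET cohort
#'
#' Draws a complete cohort under a [cohort_config()]: patients with
#' treatment arms; lesions in five site groups with baseline SUV and (for
#' lesions inside the dynamic field of view) ground-truth two-tissue
#' kinetics; thyroid, bone-marrow and spleen reference-organ records;
#' interim values as baseline times a log-normal response multiplier;
#' per-lesion TACs and voxel-level VOIs with box-counting FD (when
#' enabled); and progression-free survival drawn from an exponential
#' distribution whose log-hazard is linear in the chosen standardized
#' interim covariates, with administrative censoring. The whole cohort is
#' a deterministic function of `(config, seed)`.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort`: `patients` (per-patient
#'   table with PFS outcome and mean-of-hottest aggregated parameter
#'   columns `<parameter>_<timepoint>`), `patients_single` (same with
#'   single-hottest aggregation), `lesions`, `organs`, `tacs` (named list
#'   of [tissue_tac()]), `vois` (named list of [voxel_dynamic_voi()]),
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_local_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  protocol <- default_protocol()
  cp <- feng_input_function()
  params6 <- c("suv_mean", "suv_max", "K1", "k3", "Ki", "FD")

  n <- cfg$n_patients
  patients <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    treatment = sample(names(cfg$treatment_probs), n, replace = TRUE,
                       prob = cfg$treatment_probs))

  draw_kinetics <- function(centers) {
    kinetic_params(
      K1 = rlnormc(1, centers[["K1"]], cfg$sigma),
      k2 = rlnormc(1, centers[["k2"]], cfg$sigma),
      k3 = rlnormc(1, centers[["k3"]], cfg$sigma),
      k4 = min(rlnormc(1, centers[["k4"]], cfg$sigma), 0.05),
      VB = min(rlnormc(1, centers[["VB"]], cfg$sigma), 0.3))
  }
  respond <- function(mult) mult * exp(cfg$response_sigma * stats::rnorm(1))

  tacs <- list()
  vois <- list()
  lesion_rows <- list()
  organ_rows <- list()

  emit_dynamic <- function(key, kp) {
    # TAC, voxel VOI and FD for one tissue at one timepoint
    fd <- NA_real_
    if (cfg$include_tacs)
      tacs[[key]] <<- generate_lesion_tac(kp, cp, protocol, cfg$tac_cv)
    if (cfg$include_vois) {
      voi <- generate_voxel_voi(kp, cfg$heterogeneity, cfg$n_voxels, cp,
                                protocol, cfg$tac_cv)
      vois[[key]] <<- voi
      fd <- voi_fd(voi)$voi_fd
    }
    fd
  }
  draw_fd <- function(center) min(max(stats::rnorm(1, center, 0.05), 0), 2)

  for (i in seq_len(n)) {
    pid <- patients$patient_id[i]
    n_les <- 1L + stats::rpois(1, cfg$lesion_count_lambda)
    sites <- sample(names(cfg$site_probs), n_les, replace = TRUE,
                    prob = cfg$site_probs)
    for (l in seq_len(n_les)) {
      site <- sites[l]
      in_fov <- stats::runif(1) < cfg$fov_probs[[site]]
      suv_mean_b <- rlnormc(1, cfg$lesion_suv_mean, cfg$sigma)
      suv_max_b <- suv_mean_b * cfg$suv_max_ratio * exp(0.1 * stats::rnorm(1))
      suv_max_b <- max(suv_max_b, suv_mean_b)
      suv_resp <- respond(cfg$interim_multipliers$lesion[["suv"]])
      mk_row <- function(tp, suv_mean, suv_max, kp, fd) {
        data.frame(patient_id = pid, lesion_id = l, site_group = site,
                   timepoint = tp, suv_mean = suv_mean, suv_max = suv_max,
                   K1 = if (is.null(kp)) NA_real_ else kp$K1,
                   k2 = if (is.null(kp)) NA_real_ else kp$k2,
                   k3 = if (is.null(kp)) NA_real_ else kp$k3,
                   k4 = if (is.null(kp)) NA_real_ else kp$k4,
                   VB = if (is.null(kp)) NA_real_ else kp$VB,
                   Ki = if (is.null(kp)) NA_real_ else kp$Ki,
                   FD = fd, in_dynamic_fov = in_fov)
      }
      if (in_fov) {
        kp_b <- draw_kinetics(cfg$lesion_kinetics)
        kp_i <- kinetic_params(
          kp_b$K1 * respond(cfg$interim_multipliers$lesion[["K1"]]),
          kp_b$k2,
          kp_b$k3 * respond(cfg$interim_multipliers$lesion[["k3"]]),
          kp_b$k4, kp_b$VB)
        key_b <- sprintf("%s_L%d_baseline", pid, l)
        key_i <- sprintf("%s_L%d_interim", pid, l)
        fd_b <- emit_dynamic(key_b, kp_b)
        fd_i <- emit_dynamic(key_i, kp_i)
        if (!cfg$include_vois) {
          fd_b <- draw_fd(cfg$fd_centers[["lesion"]])
          fd_i <- draw_fd(cfg$fd_centers[["lesion"]] *
                            cfg$interim_multipliers$lesion[["FD"]])
        }
        lesion_rows[[length(lesion_rows) + 1L]] <-
          rbind(mk_row("baseline", suv_mean_b, suv_max_b, kp_b, fd_b),
                mk_row("interim", suv_mean_b * suv_resp,
                       suv_max_b * suv_resp, kp_i, fd_i))
      } else {
        lesion_rows[[length(lesion_rows) + 1L]] <-
          rbind(mk_row("baseline", suv_mean_b, suv_max_b, NULL, NA_real_),
                mk_row("interim", suv_mean_b * suv_resp,
                       suv_max_b * suv_resp, NULL, NA_real_))
      }
    }

    for (organ in names(cfg$organ_kinetics)) {
      kp_b <- draw_kinetics(cfg$organ_kinetics[[organ]])
      mult <- cfg$interim_multipliers[[organ]]
      kp_i <- kinetic_params(kp_b$K1 * respond(mult[["K1"]]), kp_b$k2,
                             kp_b$k3 * respond(mult[["k3"]]), kp_b$k4,
                             kp_b$VB)
      suv_mean_b <- rlnormc(1, cfg$organ_suv_mean[[organ]], cfg$sigma)
      suv_max_b <- suv_mean_b * cfg$organ_suv_max_ratio[[organ]]
      suv_resp <- respond(mult[["suv"]])
      key_b <- sprintf("%s_%s_baseline", pid, organ)
      key_i <- sprintf("%s_%s_interim", pid, organ)
      fd_b <- emit_dynamic(key_b, kp_b)
      fd_i <- emit_dynamic(key_i, kp_i)
      if (!cfg$include_vois) {
        fd_b <- draw_fd(cfg$fd_centers[[organ]])
        fd_i <- draw_fd(cfg$fd_centers[[organ]] * mult[["FD"]])
      }
      mk_org <- function(tp, suv_mean, suv_max, kp, fd) {
        data.frame(patient_id = pid, organ = organ, timepoint = tp,
                   suv_mean = suv_mean, suv_max = suv_max, K1 = kp$K1,
                   k2 = kp$k2, k3 = kp$k3, k4 = kp$k4, VB = kp$VB,
                   Ki = kp$Ki, FD = fd)
      }
      organ_rows[[length(organ_rows) + 1L]] <-
        rbind(mk_org("baseline", suv_mean_b, suv_max_b, kp_b, fd_b),
              mk_org("interim", suv_mean_b * suv_resp,
                     suv_max_b * suv_resp, kp_i, fd_i))
    }
  }

  lesions <- do.call(rbind, lesion_rows)
  organs <- do.call(rbind, organ_rows)

  agg5 <- aggregate_cohort(lesions, n_max = 5L, parameters = params6)
  agg1 <- aggregate_cohort(lesions, n_max = 1L, parameters = params6)

  # exponential PFS with log-linear covariate effects + admin censoring
  eta <- numeric(n)
  for (nm in names(cfg$hazard_coefs)) {
    x <- agg5[[nm]]
    if (is.null(x)) stop("hazard_coefs names a missing covariate: ", nm)
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    s <- stats::sd(x)
    z <- if (is.finite(s) && s > 0) (x - mean(x)) / s else rep(0, n)
    eta <- eta + cfg$hazard_coefs[[nm]] * z
  }
  rate <- log(2) / cfg$hazard_median_months * exp(eta)
  t_event <- stats::rexp(n, rate)
  t_censor <- stats::runif(n, cfg$censor_window_months[1],
                           cfg$censor_window_months[2])
  patients$pfs_months <- pmin(t_event, t_censor)
  patients$progressed <- t_event <= t_censor

  structure(list(
    patients = cbind(patients, agg5[, -1, drop = FALSE]),
    patients_single = cbind(patients, agg1[, -1, drop = FALSE]),
    lesions = lesions, organs = organs, tacs = tacs, vois = vois,
    config = cfg), class = "synthetic_cohort")
}
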