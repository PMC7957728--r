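light_config <- function(seed, coef = c(suv_mean_interim = 0.7),
                         n_patients = 25) {
  cohort_config(n_patients = n_patients, hazard_coefs = coef,
                include_tacs = FALSE, include_vois = FALSE, seed = seed)
}

test_that("lesion TAC simulation is exact at cv = 0 and seeded at cv > 0", {
  truth <- kinetic_params(0.19, 0.53, 0.19, 0.01, 0.05)
  clean <- generate_lesion_tac(truth, feng_cp, proto24, cv = 0, seed = 1)
  expect_equal(clean$values,
               forward_2tc_frames(truth, feng_cp, proto24)$values)
  a <- generate_lesion_tac(truth, feng_cp, proto24, cv = 0.05, seed = 7)
  b <- generate_lesion_tac(truth, feng_cp, proto24, cv = 0.05, seed = 7)
  c <- generate_lesion_tac(truth, feng_cp, proto24, cv = 0.05, seed = 8)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
  expect_true(all(a$values >= 0))
  expect_error(generate_lesion_tac(truth, feng_cp, proto24, cv = -0.1),
               "non-negative")
})

test_that("noisy TACs average back to the noiseless curve", {
  truth <- kinetic_params(0.19, 0.53, 0.19, 0.01, 0.05)
  clean <- forward_2tc_frames(truth, feng_cp, proto24)$values
  acc <- matrix(0, 500, 24)
  for (s in seq_len(500))
    acc[s, ] <- generate_lesion_tac(truth, feng_cp, proto24, cv = 0.05,
                                    seed = s)$values
  expect_lt(max(abs(colMeans(acc) - clean) / clean), 0.01)
})

test_that("voxel VOI generation honours its contracts", {
  truth <- kinetic_params(0.19, 0.53, 0.19, 0.01, 0.05)
  voi <- generate_voxel_voi(truth, 0.3, 9, feng_cp, proto24, seed = 2)
  expect_s3_class(voi, "voxel_dynamic_voi")
  expect_equal(nrow(voi$voxel_values), 9L)
  expect_equal(ncol(voi$voxel_values), 24L)
  # h = 0 and cv = 0: every voxel is the identical noiseless curve
  flat <- generate_voxel_voi(truth, 0, 4, feng_cp, proto24, cv = 0,
                             seed = 3)
  expect_equal(unname(apply(flat$voxel_values, 2, stats::var)), rep(0, 24))
  expect_error(generate_voxel_voi(truth, -1, 4, feng_cp, proto24),
               "non-negative")
})

test_that("cohort generation is bit-reproducible and shaped by its config", {
  cfg <- light_config(seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$lesions, b$lesions)
  expect_identical(a$organs, b$organs)
  d <- generate_cohort(light_config(seed = 6))
  expect_false(identical(a$patients$pfs_months, d$patients$pfs_months))

  expect_equal(nrow(a$patients), 25L)
  expect_true(all(table(a$lesions$timepoint) ==
                    nrow(a$lesions) / 2))            # both timepoints
  expect_equal(nrow(a$organs), 25L * 3L * 2L)
  expect_true(all(a$lesions$site_group %in%
                    c("lymph_node", "osseous", "pulmonary",
                      "mesenterial_abdominal", "soft_tissue")))
  # kinetic fields only inside the dynamic FOV
  expect_true(all(is.na(a$lesions$K1[!a$lesions$in_dynamic_fov])))
  expect_true(all(!is.na(a$lesions$K1[a$lesions$in_dynamic_fov])))
  expect_true(all(a$patients$pfs_months >= 0))
  expect_error(cohort_config(censor_window_months = c(-1, 5)), "invalid")
})

test_that("full cohorts carry TACs and box-counting FD for dynamic units", {
  cfg <- cohort_config(n_patients = 3, n_voxels = 6, seed = 9)
  co <- generate_cohort(cfg)
  fov_keys <- with(co$lesions[co$lesions$in_dynamic_fov &
                                co$lesions$timepoint == "baseline", ],
                   sprintf("%s_L%d_baseline", patient_id, lesion_id))
  expect_true(all(fov_keys %in% names(co$tacs)))
  expect_true(all(fov_keys %in% names(co$vois)))
  fd <- co$lesions$FD[co$lesions$in_dynamic_fov]
  expect_true(all(fd >= 0 & fd <= 2))
  expect_true(all(!is.na(co$organs$FD)))
})

test_that("generated lesion kinetics recover under the fitter at cv = 5%", {
  # reduced-rep closure of the simulate -> fit loop (the full 50-TAC
  # ensemble runs in the acceptance suite)
  truth <- kinetic_params(0.19, 0.532, 0.19, 0.01, 0.05)
  rel_err <- vapply(1:6, function(s) {
    tac <- generate_lesion_tac(truth, feng_cp, proto24, cv = 0.05,
                               seed = 500 + s)
    fit <- fit_2tc(tac, feng_cp)
    abs(fit$params$Ki - truth$Ki) / truth$Ki
  }, numeric(1))
  expect_lt(stats::median(rel_err), 0.15)
})

test_that("cohort medians sit near their configured centers", {
  meds <- sapply(1:5, function(s) {
    co <- generate_cohort(light_config(seed = 100 + s))
    base <- co$patients[, c("K1_baseline", "k3_baseline", "Ki_baseline")]
    apply(base, 2, stats::median, na.rm = TRUE)
  })
  avg <- rowMeans(meds)
  expect_lt(abs(avg[["K1_baseline"]] - 0.19) / 0.19, 0.10)
  expect_lt(abs(avg[["k3_baseline"]] - 0.19) / 0.19, 0.10)
  expect_lt(abs(avg[["Ki_baseline"]] - 0.05) / 0.05, 0.10)
})

test_that("an adverse interim-SUV hazard yields the expected detection rate", {
  # package generator: median-split log-rank on interim SUV_mean
  n_seeds <- 120
  hits <- 0L
  for (s in seq_len(n_seeds)) {
    co <- generate_cohort(light_config(seed = 2000 + s))
    p <- survival_screen(co$patients, "suv_mean", "interim")$p_value
    if (!is.na(p) && p < 0.05) hits <- hits + 1L
  }
  rate <- hits / n_seeds

  # independent oracle: plain R simulation of the same design (log-normal
  # covariate, exponential PFS with the same log-hazard, same censoring),
  # split at the median and tested with the hand log-rank
  set.seed(77)
  o_hits <- 0L
  for (s in seq_len(n_seeds)) {
    n <- 25
    x <- rlnorm(n, log(6.9 * 5.7 / 6.9), 0.25 + 0.2)  # baseline*response
    z <- (x - mean(x)) / sd(x)
    t_ev <- rexp(n, log(2) / 9.6 * exp(0.7 * z))
    t_cn <- runif(n, 18, 42)
    time <- pmin(t_ev, t_cn); ev <- t_ev <= t_cn
    g <- ifelse(x <= median(x), "low", "high")
    if (length(unique(g)) == 2 && sum(ev) > 0) {
      p <- hand_logrank(time, ev, g)$p_value
      if (p < 0.05) o_hits <- o_hits + 1L
    }
  }
  expect_lt(abs(rate - o_hits / n_seeds), 0.10)
})
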