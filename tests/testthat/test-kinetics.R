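test_that("influx rate follows Ki = K1*k3/(k2+k3) with its limits", {
  expect_equal(compute_influx(0.19, 0.532, 0.19), 0.19 * 0.19 / 0.722)
  expect_equal(round(compute_influx(0.19, 0.532, 0.19), 3), 0.050)
  expect_equal(compute_influx(0.3, 0.5, 0), 0)     # no phosphorylation
  expect_equal(compute_influx(0.3, 0, 0.2), 0.3)   # no washout: Ki = K1
  expect_equal(compute_influx(0.3, 0, 0), 0)       # defined limit
  expect_error(compute_influx(-0.1, 0.5, 0.2), "non-negative")
})

test_that("Ki never exceeds K1 over random valid parameter sets", {
  set.seed(11)
  for (i in 1:200) {
    p <- kinetic_params(runif(1, 0, 2), runif(1, 0, 2), runif(1, 0, 2),
                        runif(1, 0, 0.05), runif(1, 0, 0.3))
    expect_lte(p$Ki, p$K1 + 1e-12)
  }
})

test_that("forward model degenerate limits are exact", {
  p24 <- default_protocol()
  tt <- frame_mid_times(p24)
  # no tracer enters tissue
  none <- forward_2tc(kinetic_params(0, 0.5, 0.1, 0, 0), feng_cp, tt)
  expect_equal(none, rep(0, 24))
  # irreversible trapping with constant input: linear accumulation K1*C0*t
  lin <- forward_2tc(kinetic_params(0.2, 0, 0, 0, 0),
                     constant_input_function(10), tt)
  expect_equal(lin, 0.2 * 10 * tt, tolerance = 1e-7)
})

test_that("forward model matches adaptive ODE integration of the system", {
  skip_if_not_installed("deSolve")
  p <- kinetic_params(0.19, 0.53, 0.19, 0.01, 0.05)
  tt <- frame_mid_times(default_protocol())
  ana <- forward_2tc(p, feng_cp, tt)
  ode <- ode_2tc_oracle(p, feng_cp$fun, tt)
  expect_lt(max(abs(ana - ode) / ode), 1e-3)
})

test_that("with k3 = k4 = 0 the model reduces to the one-tissue closed form", {
  # closed-form convolution of K1 e^{-k2 t} with the analytic bolus:
  # each bolus term has an exact antiderivative, so the reference is exact
  K1 <- 0.2; k2 <- 0.4
  A <- feng_cp$params$A; lam <- feng_cp$params$lambda
  conv_exp_term <- function(a, mu, t)        # a e^{mu s} (*) e^{-k2 t}
    a * (exp(mu * t) - exp(-k2 * t)) / (mu + k2)
  conv_ramp_term <- function(a, mu, t) {     # a s e^{mu s} (*) e^{-k2 t}
    a / (mu + k2) * (t * exp(mu * t) -
                       (exp(mu * t) - exp(-k2 * t)) / (mu + k2))
  }
  closed_form <- function(t) {
    K1 * (conv_ramp_term(A[1], lam[1], t) +
            conv_exp_term(-A[2] - A[3], lam[1], t) +
            conv_exp_term(A[2], lam[2], t) +
            conv_exp_term(A[3], lam[3], t))
  }
  tt <- seq(1, 60, by = 1)
  # fine quadrature grid so that agreement is limited by round-off, not dt
  got <- forward_2tc(kinetic_params(K1, k2, 0, 0, 0), feng_cp, tt,
                     dt = 0.02)
  expect_lt(max(abs(got - closed_form(tt)) / closed_form(tt)), 1e-6)
})

test_that("forward model output is non-negative for valid inputs", {
  set.seed(21)
  tt <- frame_mid_times(default_protocol())
  for (i in 1:20) {
    p <- kinetic_params(runif(1, 0, 1), runif(1, 0, 1), runif(1, 0, 1),
                        runif(1, 0, 0.05), runif(1, 0, 0.3))
    expect_true(all(forward_2tc(p, feng_cp, tt) >= 0))
  }
})

test_that("forward model rejects invalid parameters and times", {
  expect_error(kinetic_params(-0.1, 0.5, 0.1), "non-negative")
  expect_error(kinetic_params(0.1, 0.5, 0.1, VB = 1.5), "VB")
  p <- kinetic_params(0.1, 0.5, 0.1)
  expect_error(forward_2tc(p, feng_cp, c(5, 3, 8)), "increasing")
  expect_error(forward_2tc(p, feng_cp, c(-1, 3)), "non-negative")
})

test_that("noiseless self-generated data is recovered to < 1%", {
  truth <- kinetic_params(0.25, 0.40, 0.15, 0.01, 0.05)
  tac <- forward_2tc_frames(truth, feng_cp, proto24)
  fit <- fit_2tc(tac, feng_cp)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$K1 - truth$K1) / truth$K1, 0.01)
  expect_lt(abs(fit$params$Ki - truth$Ki) / truth$Ki, 0.01)
  expect_lte(fit$params$Ki, fit$params$K1)
})

test_that("a pure blood-signal TAC fits with K1 near zero", {
  vb_tac <- frame_average(function(t) 0.08 * feng_cp$fun(t), proto24)
  fit <- fit_2tc(vb_tac, feng_cp)
  expect_lt(fit$params$K1 * fit$params$k3 /
              max(fit$params$k2 + fit$params$k3, 1e-9), 1e-3)
  expect_lt(fit$params$Ki, 1e-3)
})

test_that("an all-zero TAC returns the zero_tac warning flag", {
  tac <- tissue_tac(proto24, rep(0, 24))
  fit <- fit_2tc(tac, feng_cp)
  expect_identical(fit$warning, "zero_tac")
  expect_lt(fit$params$K1, 1e-3)
})

test_that("the fit is invariant under joint rescaling of TAC and Cp", {
  truth <- kinetic_params(0.25, 0.40, 0.15, 0.01, 0.05)
  tac <- forward_2tc_frames(truth, feng_cp, proto24)
  fit1 <- fit_2tc(tac, feng_cp)
  s <- 37  # common positive factor on both curves
  cp_s <- structure(list(fun = function(t) s * feng_cp$fun(t),
                         params = NULL), class = "input_function")
  tac_s <- tissue_tac(proto24, s * tac$values)
  fit2 <- fit_2tc(tac_s, cp_s)
  for (nm in c("K1", "k2", "k3", "Ki"))
    expect_lt(abs(fit2$params[[nm]] - fit1$params[[nm]]) /
                max(fit1$params[[nm]], 1e-9), 1e-3)
})

test_that("fitting refuses short TACs", {
  p5 <- acquisition_protocol(seq(0, 48, by = 12), rep(12, 5))
  expect_error(fit_2tc(tissue_tac(p5, rep(1, 5)), feng_cp), "6 frames")
})
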