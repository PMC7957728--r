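#' Two-tissue compartment kinetic parameters
#'
#' Container for the rate constants of the irreversible-FDG two-tissue
#' compartment model. `K1` (mL plasma per mL tissue per min, conventionally
#' written 1/min) is carrier-mediated transport from plasma into tissue,
#' `k2` transport back to plasma, `k3` the phosphorylation rate, `k4` the
#' dephosphorylation rate, and `VB` the fractional blood volume
#' contributing plasma signal directly to the measured tissue curve. The
#' influx rate `Ki = K1*k3/(k2+k3)` is derived, never stored independently.
#'
#' @param K1,k2,k3,k4 Non-negative rate constants in 1/min.
#' @param VB Fractional blood volume in `[0, 1]`.
#' @return An object of class `kinetic_params` with fields `K1`, `k2`,
#'   `k3`, `k4`, `VB` and the derived `Ki`.
#' @examples
#' kinetic_params(K1 = 0.19, k2 = 0.532, k3 = 0.19, k4 = 0.01, VB = 0.05)$Ki
#' @export
kinetic_params <- function(K1, k2, k3, k4 = 0, VB = 0) {
  vals <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4, VB = VB)
  if (any(!is.finite(vals))) stop("kinetic parameters must be finite")
  if (any(vals[1:4] < 0)) stop("rate constants must be non-negative")
  if (VB < 0 || VB > 1) stop("VB must lie in [0, 1]")
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, VB = VB,
                 Ki = compute_influx(K1, k2, k3)),
            class = "kinetic_params")
}

#' FDG influx rate
#'
#' `Ki = (K1 * k3) / (k2 + k3)`, the composite irreversible uptake rate of
#' the two-tissue compartment model; defined as 0 when `k2 + k3 = 0`.
#' Always `Ki <= K1`.
#'
#' @param K1,k2,k3 Non-negative rate constants in 1/min (vectorized).
#' @return Influx rate(s) in 1/min.
#' @examples
#' compute_influx(0.19, 0.532, 0.19)  # 0.05
#' @export
compute_influx <- function(K1, k2, k3) {
  if (any(c(K1, k2, k3) < 0, na.rm = TRUE))
    stop("rate constants must be non-negative")
  denom <- k2 + k3
  ifelse(denom > 0, K1 * k3 / denom, 0)
}

# Trapezoidal convolution of Cp with exp(-alpha * t) on a uniform grid,
# using the exact one-step exponential recursion
#   y_i = e^{-alpha dt} y_{i-1} + dt/2 (cp_i + e^{-alpha dt} cp_{i-1}),
# evaluated in C via stats::filter(method = "recursive").
conv_exp <- function(cp_vals, alpha, dt) {
  n <- length(cp_vals)
  a <- exp(-alpha * dt)
  b <- c(0, dt / 2 * (cp_vals[-1] + a * cp_vals[-n]))
  as.numeric(stats::filter(b, a, method = "recursive"))
}

# Dense-grid tissue curve of the 2TC model (internal workhorse).
# Returns Ct on the uniform grid t = (0:n)*dt minutes.
forward_2tc_dense <- function(params, cp_dense, dt) {
  K1 <- params$K1; k2 <- params$k2; k3 <- params$k3
  k4 <- params$k4; VB <- params$VB
  if (K1 == 0) {
    ct_tissue <- numeric(length(cp_dense))
  } else {
    s <- k2 + k3 + k4
    disc <- s^2 - 4 * k2 * k4
    disc <- max(disc, 0)
    a1 <- (s - sqrt(disc)) / 2
    a2 <- (s + sqrt(disc)) / 2
    if (a2 - a1 < 1e-9) a2 <- a1 + 1e-9  # repeated-root guard
    B1 <- (k3 + k4 - a1) / (a2 - a1)
    B2 <- (a2 - k3 - k4) / (a2 - a1)
    ct_tissue <- K1 * (B1 * conv_exp(cp_dense, a1, dt) +
                         B2 * conv_exp(cp_dense, a2, dt))
  }
  (1 - VB) * ct_tissue + VB * cp_dense
}

#' Forward simulation of the two-tissue compartment model
#'
#' Computes the model tissue curve
#' \deqn{C_t(t) = (1 - V_B)\,[h \otimes C_p](t) + V_B C_p(t)}
#' where the impulse response `h` is the closed-form bi-exponential
#' \eqn{h(t) = K_1 (B_1 e^{-\alpha_1 t} + B_2 e^{-\alpha_2 t})} with
#' \eqn{\alpha_{1,2} = ((k_2+k_3+k_4) \mp
#'   \sqrt{(k_2+k_3+k_4)^2 - 4 k_2 k_4})/2}.
#' The convolution is evaluated on a dense uniform internal grid
#' (trapezoidal quadrature at `dt` second resolution) and interpolated at
#' the requested times. All activities are assumed decay-corrected to
#' injection time.
#'
#' @param params A [kinetic_params()].
#' @param cp An [input_function()][feng_input_function] (or a function of
#'   time in minutes).
#' @param times Non-negative, increasing times in minutes.
#' @param dt Internal grid resolution in seconds (default 1).
#' @return Numeric vector of tissue activity concentrations (kBq/mL) at
#'   `times`.
#' @export
forward_2tc <- function(params, cp, times, dt = 1) {
  stopifnot(inherits(params, "kinetic_params"))
  cp <- as_input_function(cp)
  times <- as.numeric(times)
  if (any(times < 0)) stop("times must be non-negative")
  if (is.unsorted(times, strictly = FALSE)) stop("times must be increasing")
  dt_min <- dt / 60
  n <- ceiling(max(times, dt_min) / dt_min)
  grid <- (0:n) * dt_min
  ct <- forward_2tc_dense(params, cp$fun(grid), dt_min)
  stats::approx(grid, ct, xout = times, rule = 2)$y
}

# Frame-averaged model curve: trapezoidal mean of the dense curve over each
# frame. Frame boundaries must align with the dense grid (true for the
# default protocols at dt = 1 s).
frame_average_dense <- function(ct_dense, protocol, dt) {
  starts <- protocol$frame_starts / dt
  ends <- (protocol$frame_starts + protocol$frame_durations) / dt
  i0 <- round(starts); i1 <- round(ends)
  if (max(abs(starts - i0)) > 1e-6 || max(abs(ends - i1)) > 1e-6)
    stop("frame boundaries must be multiples of the grid resolution")
  vapply(seq_along(i0), function(f) {
    idx <- (i0[f]:i1[f]) + 1L
    v <- ct_dense[idx]
    (sum(v) - (v[1] + v[length(v)]) / 2) / (i1[f] - i0[f])
  }, numeric(1))
}

#' Frame-averaged forward model on a protocol
#'
#' Convenience wrapper used by the fitter and the synthetic generator:
#' [forward_2tc()] on the dense grid followed by exact trapezoidal
#' averaging over each frame of `protocol`.
#'
#' @inheritParams forward_2tc
#' @param protocol An [acquisition_protocol()].
#' @return A [tissue_tac()] with duration weights.
#' @export
forward_2tc_frames <- function(params, cp, protocol, dt = 1) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  cp <- as_input_function(cp)
  dt_min <- dt / 60
  end_min <- (protocol$frame_starts[protocol$n_frames] +
                protocol$frame_durations[protocol$n_frames]) / 60
  n <- round(end_min / dt_min)
  grid <- (0:n) * dt_min
  ct <- forward_2tc_dense(params, cp$fun(grid), dt_min)
  tissue_tac(protocol, frame_average_dense(ct, protocol, dt_min * 60))
}

#' Fit settings for the compartment-model fitter
#'
#' @param lower,upper Named bounds on `(K1, k2, k3, k4, VB)`. Defaults:
#'   rate constants in `[1e-6, 5]` 1/min, `k4` in `[0, 0.05]` 1/min (FDG is
#'   nearly irreversible over a one-hour acquisition), `VB` in `[0, 0.3]`.
#' @param n_starts Number of seeded uniform random initializations drawn
#'   within the bounds (a fixed physiological start is always added).
#' @param n_polish Number of best-scoring starts carried into full bounded
#'   optimization.
#' @param seed Integer seed for the start draws.
#' @param dt Internal convolution grid resolution in seconds.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(lower = c(K1 = 1e-6, k2 = 1e-6, k3 = 1e-6, k4 = 0, VB = 0),
                       upper = c(K1 = 5, k2 = 5, k3 = 5, k4 = 0.05, VB = 0.3),
                       n_starts = 10, n_polish = 3, seed = 42, dt = 1) {
  nm <- c("K1", "k2", "k3", "k4", "VB")
  lower <- lower[nm]; upper <- upper[nm]
  if (any(is.na(lower)) || any(is.na(upper)) || any(lower > upper))
    stop("bounds must be named for K1, k2, k3, k4, VB with lower <= upper")
  structure(list(lower = lower, upper = upper, n_starts = n_starts,
                 n_polish = n_polish, seed = seed, dt = dt),
            class = "fit_config")
}

#' Weighted nonlinear fit of the two-tissue compartment model
#'
#' Estimates `(K1, k2, k3, k4, VB)` from a measured frame-averaged tissue
#' curve by weighted least squares,
#' \eqn{\min_\theta \sum_f w_f (C_t^{model}(f) - C_t^{obs}(f))^2},
#' using bounded multi-start optimization (`nlminb`, PORT): `n_starts`
#' seeded uniform draws within the bounds plus one fixed physiological
#' start are scored, and the `n_polish` best are polished to convergence.
#' The influx rate `Ki` is derived from the best fit.
#'
#' @param tac A [tissue_tac()] (weights are used as fit weights).
#' @param cp The plasma input function.
#' @param config A [fit_config()].
#' @return A list of class `fit_2tc` with elements `params`
#'   ([kinetic_params()], including `Ki`), `rss` (weighted residual sum of
#'   squares), `converged` (logical), `warning` (`NA` or a short label such
#'   as `"zero_tac"`), and `starts` (score table of the multi-start phase).
#' @export
fit_2tc <- function(tac, cp, config = fit_config()) {
  stopifnot(inherits(tac, "tissue_tac"), inherits(config, "fit_config"))
  cp <- as_input_function(cp)
  protocol <- tac$protocol
  if (protocol$n_frames < 6L) stop("at least 6 frames are required to fit")
  obs <- tac$values
  w <- tac$weights

  dt_min <- config$dt / 60
  end_min <- (protocol$frame_starts[protocol$n_frames] +
                protocol$frame_durations[protocol$n_frames]) / 60
  grid <- (0:round(end_min / dt_min)) * dt_min
  cp_dense <- cp$fun(grid)

  # normalized objective: keeps the surface O(1) so finite-difference
  # gradients are not drowned by round-off (raw weighted RSS can reach
  # 1e6 at clinical activity scales, stalling the optimizer short of the
  # narrow k2/k3/k4 valley)
  norm <- sum(w * obs^2)
  if (norm <= 0) norm <- 1
  objective <- function(theta) {
    p <- list(K1 = theta[1], k2 = theta[2], k3 = theta[3],
              k4 = theta[4], VB = theta[5])
    model <- frame_average_dense(forward_2tc_dense(p, cp_dense, dt_min),
                                 protocol, config$dt)
    sum(w * (model - obs)^2) / norm
  }

  lo <- config$lower; up <- config$upper
  starts <- with_local_seed(config$seed, {
    m <- matrix(stats::runif(config$n_starts * 5), ncol = 5)
    sweep(sweep(m, 2, up - lo, "*"), 2, lo, "+")
  })
  starts <- rbind(pmin(pmax(c(0.1, 0.5, 0.1, 0.01, 0.05), lo), up), starts)
  scores <- apply(starts, 1, objective)
  polish_idx <- order(scores)[seq_len(min(config$n_polish, nrow(starts)))]

  best <- NULL
  converged <- FALSE
  for (i in polish_idx) {
    th0 <- starts[i, ]
    res <- NULL
    for (round in 1:3) {  # restart to shake off false convergence
      r <- tryCatch(
        stats::nlminb(th0, objective, lower = lo, upper = up,
                      control = list(iter.max = 500, eval.max = 1000)),
        error = function(e) NULL)
      if (is.null(r)) break
      if (!is.null(res) && res$objective - r$objective < 1e-14) {
        res <- r
        break
      }
      res <- r
      th0 <- r$par
    }
    if (is.null(res)) next
    if (is.null(best) || res$objective < best$objective) best <- res
    if (res$convergence == 0) converged <- TRUE
  }
  if (is.null(best))
    stop("fit failure: no start converged (", length(polish_idx),
         " polished starts)")

  th <- best$par
  params <- kinetic_params(th[1], th[2], th[3], th[4], th[5])
  warn <- NA_character_
  if (all(obs == 0) && any(cp_dense > 0)) warn <- "zero_tac"
  structure(list(params = params, rss = best$objective * norm,
                 converged = converged, warning = warn,
                 starts = data.frame(start = seq_along(scores),
                                     score = scores)),
            class = "fit_2tc")
}

# Evaluate expr with a temporarily seeded RNG, restoring the caller's state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
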