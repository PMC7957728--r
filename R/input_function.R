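#' Feng bolus arterial input function
#'
#' Analytic plasma input model for an FDG bolus:
#' \deqn{C_p(t) = (A_1 t - A_2 - A_3) e^{\lambda_1 t} + A_2 e^{\lambda_2 t}
#'   + A_3 e^{\lambda_3 t}}
#' with time in minutes. By construction \eqn{C_p(0) = 0}; with the default
#' published constants the curve is non-negative over the first hour, rises
#' to a sharp bolus peak within the first minute and decays to a slowly
#' clearing tail, which is the shape the tissue model is driven by.
#'
#' @param A Amplitudes `c(A1, A2, A3)`; `A1` in kBq/mL/min, `A2`, `A3` in
#'   kBq/mL.
#' @param lambda Decay rates `c(lambda1, lambda2, lambda3)` in 1/min,
#'   all negative.
#'
#' @return An object of class `input_function`: a list with `fun`, a
#'   vectorized evaluator of time in minutes, and `params`.
#'
#' @examples
#' cp <- feng_input_function()
#' cp$fun(0)           # 0 by construction
#' cp$fun(c(1, 30))    # peak region and tail
#' @export
feng_input_function <- function(A = c(851.1225, 21.8798, 20.8113),
                                lambda = c(-4.133859, -0.0104344944, -0.1190996)) {
  A <- as.numeric(A); lambda <- as.numeric(lambda)
  if (length(A) != 3L || length(lambda) != 3L)
    stop("A and lambda must each have length 3")
  if (any(!is.finite(A)) || any(!is.finite(lambda)))
    stop("input-function parameters must be finite")
  if (A[1] <= 0 || any(A[2:3] < 0)) stop("amplitudes must be positive")
  if (any(lambda >= 0)) stop("decay rates must be negative")
  f <- function(t) {
    t <- as.numeric(t)
    out <- (A[1] * t - A[2] - A[3]) * exp(lambda[1] * t) +
      A[2] * exp(lambda[2] * t) + A[3] * exp(lambda[3] * t)
    out[t < 0] <- 0
    out
  }
  # validity: Cp must be non-negative over the first hour
  grid <- seq(0, 60, by = 1 / 60)
  if (any(f(grid) < -1e-9))
    stop("input-function parameters yield negative Cp on [0, 60] min")
  structure(list(fun = f, params = list(A = A, lambda = lambda)),
            class = "input_function")
}

#' Constant input function (mainly for closed-form checks)
#'
#' Unlike a physiological bolus, this input is right-continuous at zero
#' (`Cp(0) = value`), so quadrature against it is exact and closed-form
#' limits like linear irreversible accumulation hold to machine precision.
#'
#' @param value Constant plasma concentration for t >= 0 (kBq/mL).
#' @return An `input_function` with `Cp(t) = value` for `t >= 0`.
#' @export
constant_input_function <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, value >= 0)
  f <- function(t) ifelse(t >= 0, value, 0)
  structure(list(fun = f, params = list(value = value)),
            class = "input_function")
}

as_input_function <- function(cp) {
  if (inherits(cp, "input_function")) return(cp)
  if (is.function(cp))
    return(structure(list(fun = cp, params = NULL), class = "input_function"))
  stop("cp must be an input_function or a function of time in minutes")
}
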