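#' Chemotactic response parameters
#'
#' Constructs the five-parameter genotype of a run-and-tumble responder.
#' The tumbling (tumble-start) rate is
#' \deqn{\alpha(t) = \max\left(0,\; \alpha_0 + \int_0^\infty R(s)\,
#'   c(x_B(t-s), t-s)\, ds\right)}
#' with the bilobed linear-response kernel
#' \eqn{R(s) = (A/\tau + B s/\tau^2) e^{-s/\tau}}. The strategy tag encodes
#' the sign constraints on the kernel amplitudes:
#'
#' * `adaptive`: \eqn{A = -B}, \eqn{B > 0} — equal positive and negative lobe
#'   areas, hence perfect adaptation (steady-state rate returns to
#'   \eqn{\alpha_0} under any constant concentration).
#' * `inverted`: \eqn{A > 0}, \eqn{B = 0} — single-lobe kernel; tumbling
#'   tracks the absolute concentration.
#' * `speculator`: \eqn{A > 0 > B} — bilobed kernel with unequal lobes; the
#'   cell compares recent concentration to a long-term average and tumbles
#'   persistently when conditions beat the average.
#' * `null`: \eqn{A = B = 0} — the non-chemotaxing baseline.
#'
#' @param strategy One of `"adaptive"`, `"inverted"`, `"speculator"`, `"null"`.
#' @param alpha0 Basal tumble-start rate (1/time), \eqn{\ge 0}.
#' @param beta Tumble-stop rate (1/time), \eqn{> 0}; `1/beta` is the mean
#'   tumble duration.
#' @param A Kernel amplitude (1/(concentration time)). For `adaptive` it is
#'   derived as `-B` and need not be given.
#' @param B Kernel slope amplitude (1/(concentration time)). Zero for
#'   `inverted`; omitted (zero) for `null`.
#' @param tau Memory length (time), \eqn{> 0}.
#' @return An object of class `response_params`.
#' @examples
#' response_params("adaptive", alpha0 = 10, beta = 1, B = 20, tau = 5)
#' response_params("speculator", alpha0 = 10, beta = 1, A = 20, B = -18, tau = 5)
#' @export
response_params <- function(strategy = c("adaptive", "inverted", "speculator", "null"),
                            alpha0, beta, A = NULL, B = NULL, tau) {
  strategy <- match.arg(strategy)
  if (strategy == "adaptive") {
    if (is.null(B) && !is.null(A)) B <- -A
    stopifnot(!is.null(B), B > 0)
    A <- -B
  } else if (strategy == "inverted") {
    stopifnot(!is.null(A), A > 0)
    B <- 0
  } else if (strategy == "speculator") {
    stopifnot(!is.null(A), !is.null(B), A > 0, B < 0)
  } else {
    A <- 0
    B <- 0
  }
  stopifnot(alpha0 >= 0, beta > 0, tau > 0)
  structure(
    list(strategy = strategy, alpha0 = alpha0, beta = beta,
         A = A, B = B, tau = tau),
    class = "response_params"
  )
}

#' @export
print.response_params <- function(x, ...) {
  cat(sprintf(
    "<response_params: %s>\n  alpha0 = %g  beta = %g  A = %g  B = %g  tau = %g\n",
    x$strategy, x$alpha0, x$beta, x$A, x$B, x$tau))
  invisible(x)
}

#' @export
as.data.frame.response_params <- function(x, ...) {
  data.frame(strategy = x$strategy, alpha0 = x$alpha0, beta = x$beta,
             A = x$A, B = x$B, tau = x$tau)
}

#' The non-chemotaxing baseline responder
#'
#' An always-running cell: zero kernel (`A = B = 0`) and zero basal tumbling
#' rate. Its experienced-concentration statistics equal the field's spatial
#' statistics, so its fitness is independent of the field's correlation time
#' and length. `tau` is set large enough that the memory-resolution term of
#' the step-size rule is never binding.
#'
#' @param T_corr,L Field correlation time and length the baseline will be run
#'   in (used only to size `tau`).
#' @param v Running speed.
#' @return A `response_params` object with strategy `"null"`.
#' @export
null_response <- function(T_corr, L, v = 1) {
  response_params("null", alpha0 = 0, beta = 1,
                  tau = 20 * min(T_corr, L / v))
}

#' Response kernel value
#'
#' Evaluates \eqn{R(t) = (A/\tau + B t/\tau^2) e^{-t/\tau}} at lags
#' \eqn{t \ge 0}. The kernel is causal: negative lags are an error.
#'
#' @param params A [response_params()] object.
#' @param t Vector of non-negative lags.
#' @return Numeric vector of kernel values (rate per unit concentration per
#'   unit time).
#' @export
kernel_value <- function(params, t) {
  if (any(t < 0)) stop("kernel is causal: t must be >= 0")
  (params$A / params$tau + params$B * t / params$tau^2) * exp(-t / params$tau)
}

#' Net kernel area
#'
#' The exact value of \eqn{\int_0^\infty R(s)\,ds = A + B}. Zero net area
#' (adaptive constraint \eqn{B = -A}) is equivalent to perfect adaptation.
#'
#' @inheritParams kernel_value
#' @return A single number (rate per unit concentration).
#' @export
kernel_integral <- function(params) {
  params$A + params$B
}

#' Exponential-memory state of the response convolution
#'
#' The convolution \eqn{\int_0^\infty R(s) c(t-s) ds} is carried recursively
#' through two exponentially weighted integrals of the concentration history,
#' \deqn{M_1(t) = \int_0^\infty e^{-s/\tau} c(t-s)\,ds, \qquad
#'       M_2(t) = \int_0^\infty s\, e^{-s/\tau} c(t-s)\,ds,}
#' so that the response integral is \eqn{(A/\tau) M_1 + (B/\tau^2) M_2}.
#' `init_memory` returns the steady state reached after sitting at a constant
#' concentration forever: \eqn{M_1 = c\tau}, \eqn{M_2 = c\tau^2}.
#'
#' @inheritParams kernel_value
#' @param c_const Constant past concentration (\eqn{\ge 0}).
#' @return A `kernel_state` list with elements `M1` and `M2`.
#' @export
init_memory <- function(params, c_const) {
  stopifnot(c_const >= 0)
  structure(list(M1 = c_const * params$tau, M2 = c_const * params$tau^2),
            class = "kernel_state")
}

#' Advance the memory state over one piecewise-constant step
#'
#' Exact update of the two exponential filters when the concentration is held
#' at `c` over a step of length `dt` (obtained by splitting the defining
#' integrals at age `dt`):
#' \deqn{M_1 \leftarrow e^{-dt/\tau} M_1 + c\,\tau(1 - e^{-dt/\tau})}
#' \deqn{M_2 \leftarrow e^{-dt/\tau} (M_2 + dt\, M_1^{old}) +
#'   c\,[\tau^2 - e^{-dt/\tau}(\tau^2 + \tau\, dt)]}
#' The update is exact for piecewise-constant concentration histories, which
#' is what the discrete-time simulation produces, so there is no within-step
#' discretization error.
#'
#' @param state A `kernel_state` (see [init_memory()]).
#' @param c Concentration held over the step.
#' @param dt Step length (> 0).
#' @param tau Memory length of the kernel.
#' @return The updated `kernel_state`.
#' @export
update_memory <- function(state, c, dt, tau) {
  stopifnot(dt > 0)
  e <- exp(-dt / tau)
  M1_old <- state$M1
  state$M1 <- e * state$M1 + c * tau * (1 - e)
  state$M2 <- e * (state$M2 + dt * M1_old) + c * (tau^2 - e * (tau^2 + tau * dt))
  state
}

#' Instantaneous tumble-start rate
#'
#' \eqn{\alpha = \max(0, \alpha_0 + (A/\tau) M_1 + (B/\tau^2) M_2)}. At the
#' steady state under constant concentration \eqn{c} this reduces to
#' \eqn{\max(0, \alpha_0 + c (A + B))}; for adaptive parameters the kernel
#' area \eqn{A + B} vanishes and the rate is exactly \eqn{\alpha_0}.
#'
#' @inheritParams update_memory
#' @param params A [response_params()] object.
#' @return The clipped tumble-start rate (1/time).
#' @export
tumble_start_rate <- function(params, state) {
  max(0, params$alpha0 + (params$A / params$tau) * state$M1 +
        (params$B / params$tau^2) * state$M2)
}

#' Closed-form tumbling-rate response to a concentration step
#'
#' For a spatially uniform concentration step \eqn{0 \to c_0} at `t_on` and
#' back to 0 at `t_off` (with zero concentration before `t_on`), the response
#' integral has the closed form, with \eqn{\hat t} the time since step-on,
#' \deqn{\alpha(t) = \max\!\big(0,\ \alpha_0 + c_0 [A(1 - e^{-\hat t/\tau}) +
#'   B(1 - (1 + \hat t/\tau) e^{-\hat t/\tau})]\big)}
#' plus the superposed opposite step at `t_off`. Used as the independent
#' oracle for the recursive evaluation and as the forward model of the
#' kernel fit.
#'
#' @inheritParams kernel_value
#' @param c0 Step concentration.
#' @param t_on,t_off Step onset and removal times.
#' @return Numeric vector of \eqn{\alpha(t)}.
#' @export
step_response_rate <- function(params, c0, t_on, t_off, t) {
  ramp <- function(th) {
    # response integral per unit concentration, th = time since a unit step-on
    out <- numeric(length(th))
    pos <- th > 0
    e <- exp(-th[pos] / params$tau)
    out[pos] <- params$A * (1 - e) +
      params$B * (1 - (1 + th[pos] / params$tau) * e)
    out
  }
  raw <- params$alpha0 + c0 * (ramp(t - t_on) - ramp(t - t_off))
  pmax(0, raw)
}
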