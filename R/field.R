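#' Stochastic attractant field parameters
#'
#' The 1D attractant field is a truncated Fourier series
#' \deqn{c(x, t) = \max\left(0, \sum_{p=1}^{p^*} X_p(t) \cos(2\pi p x/\ell) +
#'   Y_p(t) \sin(2\pi p x/\ell)\right)}
#' whose mode weights follow independent AR(1) (discretized
#' Ornstein-Uhlenbeck) processes with correlation time `T_corr`, updated
#' every \eqn{\Delta t_c = T/100}:
#' \deqn{X_p(t + \Delta t_c) = X_p(t)(1 - \Delta t_c/T) +
#'   \eta \sqrt{2 \Delta t_c / (T p^*)}, \quad \eta \sim N(0, 1).}
#' The highest mode is \eqn{p^* = \ell/L}, giving nominal correlation length
#' `L`; the per-weight stationary variance is \eqn{\approx 1/p^*} so the
#' total unclipped field variance is \eqn{\approx 1} independent of `T_corr`
#' and `L`, which keeps the average available attractant independent of the
#' field parameters.
#'
#' @param T_corr Correlation time `T` of the mode weights (time units).
#' @param L Nominal correlation length (length units), \eqn{0 < L \le \ell}.
#' @param ell World length (default 100, periodic).
#' @return A `field_params` object with derived members `p_star` (number of
#'   modes, `round(ell/L)`, at least 1) and `dt_c = T_corr/100`.
#' @export
field_params <- function(T_corr, L, ell = 100) {
  stopifnot(T_corr > 0, L > 0, L <= ell, ell > 0)
  ratio <- ell / L
  p_star <- max(1L, as.integer(round(ratio)))
  if (abs(ratio - p_star) > 1e-8)
    warning(sprintf("ell/L = %g is not an integer; using p_star = %d", ratio, p_star))
  structure(list(T_corr = T_corr, L = L, ell = ell,
                 p_star = p_star, dt_c = T_corr / 100),
            class = "field_params")
}

#' @export
print.field_params <- function(x, ...) {
  cat(sprintf("<field_params: T = %g, L = %g, ell = %g, p* = %d, dt_c = %g>\n",
              x$T_corr, x$L, x$ell, x$p_star, x$dt_c))
  invisible(x)
}

n_equilibration_updates <- function(params, t_eq = 2 * params$T_corr) {
  # equilibrate for t_eq (default 2T, comfortably past the "at least T" mark)
  as.integer(ceiling(t_eq / params$dt_c))
}

#' Initialize an equilibrated stochastic field
#'
#' All weights start at zero and the field is advanced for an equilibration
#' period `t_eq` (default `2 * T_corr`) so the returned state at `t = 0` is
#' approximately stationary. Each field instance owns a deterministic noise
#' stream keyed by `seed`, so a realization is reproducible bit-for-bit from
#' its seed (this underpins the paired wild-type/mutant fitness scheme).
#'
#' @param params A [field_params()] object.
#' @param seed Integer seed of the field's private noise stream.
#' @param t_eq Equilibration time (default `2 * T_corr`; use 0 to obtain the
#'   all-zero initial state).
#' @return A `field_state` with weight vectors `X`, `Y` (length `p_star`),
#'   field time `t = 0`, and the stream bookkeeping needed by
#'   [update_field()].
#' @export
init_field <- function(params, seed, t_eq = 2 * params$T_corr) {
  n_eq <- as.integer(ceiling(t_eq / params$dt_c))
  if (n_eq > 0) {
    snap <- cpp_field_snapshot(params$T_corr, params$dt_c, params$p_star,
                               seed, n_eq)
    X <- snap$X; Y <- snap$Y
  } else {
    X <- Y <- numeric(params$p_star)
  }
  structure(list(X = X, Y = Y, t = 0, seed = seed, n_done = n_eq),
            class = "field_state")
}

#' Advance the stochastic field
#'
#' Applies `n` AR(1) weight updates, each advancing field time by `dt_c`.
#' Noise is taken from the field's private stream (continuing exactly where
#' [init_field()] left off), or from `noise` if supplied: a matrix with `n`
#' rows and `2 * p_star` columns (standard-normal draws, columns
#' `X_1..X_p*, Y_1..Y_p*`), which makes the update fully deterministic for
#' testing.
#'
#' @param state A `field_state`.
#' @param params The matching [field_params()].
#' @param n Number of updates to apply.
#' @param noise Optional matrix of standard-normal draws.
#' @param keep If `TRUE`, attach the full weight trajectory (an
#'   `n x 2 p_star` matrix, attribute `"trajectory"`) to the result.
#' @return The advanced `field_state`.
#' @export
update_field <- function(state, params, n = 1, noise = NULL, keep = FALSE) {
  a <- 1 - params$dt_c / params$T_corr
  sdv <- sqrt(2 * params$dt_c / (params$T_corr * params$p_star))
  if (!is.null(noise)) {
    noise <- matrix(noise, nrow = n)
    stopifnot(ncol(noise) == 2 * params$p_star)
    X <- state$X; Y <- state$Y
    traj <- if (keep) matrix(NA_real_, n, 2 * params$p_star)
    for (i in seq_len(n)) {
      X <- a * X + sdv * noise[i, seq_len(params$p_star)]
      Y <- a * Y + sdv * noise[i, params$p_star + seq_len(params$p_star)]
      if (keep) traj[i, ] <- c(X, Y)
    }
    state$X <- X; state$Y <- Y
  } else {
    run <- cpp_field_series(params$T_corr, params$dt_c, params$p_star,
                            state$seed, state$n_done, n)
    state$X <- run$X; state$Y <- run$Y
    state$n_done <- state$n_done + n
    traj <- if (keep) run$weights
  }
  state$t <- state$t + n * params$dt_c
  if (keep) attr(state, "trajectory") <- traj
  state
}

#' Evaluate the attractant concentration
#'
#' Sums the cosine and sine modes at (wrapped) positions `x` and clips the
#' result at zero: negative excursions of the Fourier sum carry no
#' attractant.
#'
#' @inheritParams update_field
#' @param x Positions (wrapped modulo `ell` before evaluation).
#' @param clip Clip negative values at 0 (the physical field). Set `FALSE`
#'   to obtain the raw Fourier sum, e.g. for covariance diagnostics.
#' @return Concentrations, same length as `x`.
#' @export
concentration <- function(state, params, x, clip = TRUE) {
  cpp_conc1d(state$X, state$Y, params$ell, x %% params$ell, clip)
}

#' Closed-form spatial autocovariance of the unclipped field
#'
#' At stationarity the unclipped Fourier sum has spatial covariance
#' \eqn{C(d) = (1/p^*) \sum_{p=1}^{p^*} \cos(2\pi p d/\ell)} (each mode pair
#' contributes its weight variance \eqn{1/p^*}). Used as the oracle for
#' field diagnostics; also the normalized spatial autocorrelation since
#' \eqn{C(0) = 1}.
#'
#' @param d Separations.
#' @param p_star Number of modes.
#' @param ell World length.
#' @export
field_spatial_covariance <- function(d, p_star, ell = 100) {
  vapply(d, function(dd) sum(cos(2 * pi * seq_len(p_star) * dd / ell)) / p_star,
         numeric(1))
}

#' Static 3D stochastic field
#'
#' An isotropic 3D analogue of the 1D field for traversal experiments:
#' \deqn{c(x,y,z) = \sum_{p,q,r=1}^{p^*} X_{pqr}
#'   \cos(\xi_p(x) + \xi_q(y) + \xi_r(z)) + Y_{pqr}
#'   \sin(\xi_p(x) + \xi_q(y) + \xi_r(z))}
#' with \eqn{\xi_p(x) = 2\pi p x/\ell} and i.i.d. Gaussian weights of
#' variance \eqn{p^{*-3}} (total field variance 1). The field is static in
#' time and, by symmetry of the mode set, has the same correlation length
#' `L = ell/p_star` along each axis. Values are not clipped at zero by
#' default: the traversal experiment compares correlation structure, for
#' which clipping is irrelevant; a clipped variant is available via the
#' `clip` flag of [field3d_concentration()].
#'
#' @inheritParams init_field
#' @return A `field3d` object with weight vectors `X3`, `Y3` (length
#'   `p_star^3`, mode order `(p,q,r)` with `r` fastest).
#' @export
make_field_3d <- function(params, seed) {
  n_modes <- params$p_star^3
  draws <- cpp_pcg_normals(seed, 2 * n_modes) * params$p_star^(-3 / 2)
  structure(list(X3 = draws[seq_len(n_modes)],
                 Y3 = draws[n_modes + seq_len(n_modes)],
                 p_star = params$p_star, ell = params$ell, seed = seed),
            class = "field3d")
}

#' @rdname make_field_3d
#' @param field A `field3d` object.
#' @param x,y,z Coordinates (wrapped modulo `ell`).
#' @param clip Clip negative values at zero.
#' @export
field3d_concentration <- function(field, x, y, z, clip = FALSE) {
  cpp_conc3d(field$X3, field$Y3, field$p_star, field$ell,
             x %% field$ell, y %% field$ell, z %% field$ell, clip)
}

# ---------------------------------------------------------------------------
# Deterministic test environments and the common environment contract.
# An environment is a tagged object the agent simulator can evaluate as
# concentration(position, time) >= 0.
# ---------------------------------------------------------------------------

new_environment <- function(tag, par, ell, fun) {
  structure(list(tag = tag, par = par, ell = ell, fun = fun),
            class = "chemo_env")
}

#' @export
print.chemo_env <- function(x, ...) {
  cat(sprintf("<environment: %s>\n", x$tag))
  invisible(x)
}

#' Evaluate an environment
#'
#' @param env A `chemo_env` object.
#' @param x Position(s).
#' @param t Time.
#' @return Concentration(s), always \eqn{\ge 0}.
#' @export
env_concentration <- function(env, x, t) env$fun(x %% env$ell, t)

#' Spatially uniform attractant step
#'
#' Concentration `c0` for `t_on <= t < t_off`, zero otherwise.
#'
#' @param c0 Step concentration.
#' @param t_on,t_off Onset and removal times (`t_on < t_off`).
#' @param ell World length.
#' @export
step_environment <- function(c0, t_on, t_off, ell = 100) {
  stopifnot(t_on < t_off)
  new_environment("step", c(c0 = c0, t_on = t_on, t_off = t_off), ell,
                  function(x, t) rep(if (t >= t_on && t < t_off) c0 else 0,
                                     length(x)))
}

#' Constant uniform environment
#'
#' @param c0 Concentration everywhere, at all times.
#' @param ell World length.
#' @export
constant_environment <- function(c0, ell = 100) {
  stopifnot(c0 >= 0)
  new_environment("constant", c(c0 = c0), ell,
                  function(x, t) rep(c0, length(x)))
}

#' Dynamic stochastic field environment
#'
#' Wraps [field_params()] plus a seed as an agent environment. The simulator
#' regenerates the field internally from the seed (equilibrating for
#' `2 * T_corr` before the agent is released) and holds the field constant
#' between its `dt_c` updates.
#'
#' @param params A [field_params()] object.
#' @param seed Field noise-stream seed.
#' @export
stochastic_environment <- function(params, seed) {
  env <- new_environment("stochastic",
                         c(T_corr = params$T_corr, dt_c = params$dt_c,
                           p_star = params$p_star, seed = seed,
                           n_eq = n_equilibration_updates(params)),
                         params$ell, NULL)
  env$field_params <- params
  env$fun <- function(x, t) {
    stop("stochastic environments are evaluated inside the simulator; ",
         "use init_field()/concentration() for direct evaluation")
  }
  env
}

#' Two oscillating Gaussian attractant peaks
#'
#' Two Gaussian bumps (standard deviation `sigma_g`, peak amplitude at most
#' 1) whose amplitudes oscillate in antiphase with period `period`:
#' \deqn{c(x, t) = A_1(t)\, g(x; 25, \sigma) + (1 - A_1(t))\, g(x; 75, \sigma),
#'   \qquad A_1(t) = (1 + \cos(2\pi t/\mathrm{period}))/2.}
#' When one Gaussian is at full amplitude the other has amplitude zero; at
#' quarter period both are at 0.5. Bumps are evaluated with periodic
#' wrapping. The waveform is the package's choice of a smooth antiphase
#' oscillation between 0 and 1.
#'
#' @param period Oscillation period (default 5000 time units).
#' @param centers Positions of the two peaks.
#' @param sigma_g Standard deviation of each Gaussian bump.
#' @param ell World length.
#' @export
two_gaussian_environment <- function(period = 5000, centers = c(25, 75),
                                     sigma_g = 3, ell = 100) {
  stopifnot(length(centers) == 2, all(centers >= 0), all(centers < ell))
  par <- c(period = period, mu1 = centers[1], mu2 = centers[2],
           sigma = sigma_g, ell = ell)
  gauss <- function(x, mu) {
    d <- (x - mu + ell / 2) %% ell - ell / 2
    exp(-0.5 * d^2 / sigma_g^2)
  }
  new_environment("two_gaussian", par, ell, function(x, t) {
    A1 <- 0.5 * (1 + cos(2 * pi * t / period))
    A1 * gauss(x, centers[1]) + (1 - A1) * gauss(x, centers[2])
  })
}
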