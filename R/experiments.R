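#' Deterministic tumbling-rate time course under an attractant step
#'
#' Integrates the response convolution on a spatially uniform step
#' environment (no agent motion is involved) with the exact recursive memory
#' update, returning \eqn{\alpha(t)} sampled every `dt`. Agrees with the
#' closed-form step solution [step_response_rate()] to machine precision
#' when `t_on` and `t_off` fall on the step grid.
#'
#' @param params A [response_params()] object.
#' @param c0 Step concentration.
#' @param t_on,t_off Step onset and removal times.
#' @param t_end End of the time course.
#' @param dt Integration step (must resolve the memory, `dt <= tau/20`).
#' @return A tibble with columns `t`, `c`, `alpha`.
#' @export
step_response_timecourse <- function(params, c0 = 1, t_on = 50, t_off = 350,
                                     t_end = 700, dt = params$tau / 20) {
  stopifnot(dt <= params$tau / 20 + 1e-12)
  n <- ceiling(t_end / dt)
  tau <- params$tau
  e <- exp(-dt / tau)
  k1 <- tau * (1 - e)
  k2 <- tau^2 - e * (tau^2 + tau * dt)
  Ao <- params$A / tau
  Bo <- params$B / tau^2
  t_grid <- numeric(n); c_grid <- numeric(n); a_grid <- numeric(n)
  M1 <- 0; M2 <- 0; t <- 0
  for (i in seq_len(n)) {
    c_here <- if (t >= t_on && t < t_off) c0 else 0
    M1_old <- M1
    M1 <- e * M1 + c_here * k1
    M2 <- e * (M2 + dt * M1_old) + c_here * k2
    t <- t + dt
    t_grid[i] <- t
    c_grid[i] <- c_here
    a_grid[i] <- max(0, params$alpha0 + Ao * M1 + Bo * M2)
  }
  tibble::tibble(t = t_grid, c = c_grid, alpha = a_grid)
}

#' Two-state tumbling probability driven by a rate series
#'
#' Integrates the first-order two-state master equation
#' \eqn{dP/dt = \alpha(t)(1 - P) - \beta P} with \eqn{\alpha} piecewise
#' constant between samples (exact exponential update per interval).
#' `P0` defaults to the steady state of the first sample.
#'
#' @param t Sample times (strictly increasing).
#' @param alpha Tumble-start rate at each sample.
#' @param beta Tumble-stop rate.
#' @param P0 Initial tumbling probability.
#' @return Vector of tumbling probabilities at `t`.
#' @export
two_state_probability <- function(t, alpha, beta, P0 = NULL) {
  n <- length(t)
  stopifnot(length(alpha) == n, n >= 2)
  P <- numeric(n)
  P[1] <- P0 %||% (alpha[1] / (alpha[1] + beta))
  for (i in 2:n) {
    rate <- alpha[i - 1] + beta
    Pinf <- if (rate > 0) alpha[i - 1] / rate else 0
    P[i] <- Pinf + (P[i - 1] - Pinf) * exp(-rate * (t[i] - t[i - 1]))
  }
  P
}

# forward model of the kernel fit: observable at the data times
step_series_model <- function(params, c0, t_on, t_off, t,
                              observable = c("probability", "rate"),
                              n_sub = 5) {
  observable <- match.arg(observable)
  alpha <- step_response_rate(params, c0, t_on, t_off, t)
  if (observable == "rate") return(alpha)
  # refine the grid for the master-equation integration, then read off
  t_fine <- sort(unique(c(t, seq(min(t), max(t),
                                 length.out = n_sub * length(t)))))
  a_fine <- step_response_rate(params, c0, t_on, t_off, t_fine)
  P <- two_state_probability(t_fine, a_fine, params$beta)
  P[match(t, t_fine)]
}

#' Generate a synthetic step-response series
#'
#' Forward-simulates the tumbling observable of a responder subjected to an
#' attractant step and adds optional i.i.d. Gaussian noise. This is the
#' package's synthetic stand-in for digitized experimental tumbling time
#' courses; the default generating parameters are a speculator response in
#' seconds/mM units.
#'
#' The default step concentration is deliberately weak (`c0 = 0.001`): it
#' keeps the tumbling rate of the default responder within a few multiples
#' of the tumble-stop rate, so the probability observable spans its dynamic
#' range and all five parameters are identifiable. At a saturating step
#' (e.g. `c0 = 1` for these parameters) the probability pins to 1 during
#' stimulation and the amplitude scale of the kernel is carried only by
#' sub-second transients — recovery from noisy data is then
#' information-limited no matter the fitting algorithm.
#'
#' @inheritParams step_response_timecourse
#' @param t Sample times.
#' @param noise_sd Gaussian noise standard deviation on the observable.
#' @param observable `"probability"` (two-state tumbling probability) or
#'   `"rate"` (raw \eqn{\alpha}).
#' @return A tibble with columns `t` and `y`.
#' @export
synthetic_step_series <- function(params = response_params(
                                    "speculator", alpha0 = 0.074,
                                    beta = 0.034, A = 1300, B = -1000,
                                    tau = 71),
                                  c0 = 0.001, t_on = 50, t_off = 350,
                                  t = seq(0, 700, by = 1), noise_sd = 0,
                                  observable = "probability") {
  y <- step_series_model(params, c0, t_on, t_off, t, observable)
  if (noise_sd > 0) y <- y + rnorm(length(t), 0, noise_sd)
  tibble::tibble(t = t, y = y)
}

#' Fit response parameters to a tumbling time course
#'
#' Nonlinear least squares of the step-response forward model against an
#' observed series (two columns: time and tumbling probability or rate).
#' The observable is by default the tumbling probability of the two-state
#' system driven by \eqn{\alpha(t)} (the master equation of
#' [two_state_probability()], which is what makes `beta` and the overall
#' rate scale identifiable); raw-rate fitting is available via
#' `observable = "rate"`. Parameters are optimized on a log scale with the
#' speculator sign convention (`A > 0 > B`) and the fit is restarted from
#' multiple perturbed initializations, keeping the best converged solution.
#'
#' @param data A data frame whose first two columns are time and the
#'   observable (columns `t`, `y`).
#' @param c0 Step concentration of the protocol.
#' @param t_on,t_off Step onset and removal times.
#' @param init Optional initial [response_params()] guess (default: a
#'   data-driven heuristic).
#' @param observable `"probability"` or `"rate"`.
#' @param n_starts Number of initializations.
#' @return A `kernel_fit` object: `params` (fitted [response_params()]),
#'   `B_over_A`, `ssr`, `fitted`, `data`, `degenerate`, `converged`.
#' @export
fit_step_response <- function(data, c0 = 0.001, t_on = 50, t_off = 350,
                              init = NULL, observable = c("probability", "rate"),
                              n_starts = 12) {
  observable <- match.arg(observable)
  t <- data[[1]]
  y <- data[[2]]
  stopifnot(length(t) > 10, all(diff(t) > 0))

  theta0 <- log(fit_init_heuristic(t, y, c0, t_on, t_off, init, observable))

  model_theta <- function(theta) {
    p <- theta_to_params(theta)
    step_series_model(p, c0, t_on, t_off, t, observable)
  }
  resid_fun <- function(theta) model_theta(theta) - y

  # deterministic multi-start: systematic log-scale ladders over the
  # amplitude scale (A, B jointly) and the memory length (the two directions
  # along which clipped step responses develop local minima), plus fixed
  # pseudo-random perturbations
  ladder <- expand.grid(s_amp = log(c(1 / 5, 1, 5, 25)),
                        s_tau = log(c(1 / 4, 1, 4)))
  starts <- cbind(0, 0, ladder$s_amp, ladder$s_amp, ladder$s_tau)
  if (n_starts > nrow(starts)) {
    perturb <- matrix(cpp_pcg_normals(987654321,
                                      5 * (n_starts - nrow(starts))),
                      ncol = 5) * 0.7
    starts <- rbind(starts, perturb)
  } else {
    keep <- unique(c(which(ladder$s_amp == 0 & ladder$s_tau == 0),
                     seq_len(nrow(starts))))[seq_len(max(n_starts, 1))]
    starts <- starts[keep, , drop = FALSE]
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = theta0 + starts[i, ], fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) stop("kernel fit failed from every initialization")

  theta_hat <- best$fit$par
  params <- theta_to_params(theta_hat)
  fitted <- model_theta(theta_hat)
  degenerate <- sd(y) < 1e-10 ||
    (abs(params$A) + abs(params$B)) * c0 < 1e-3 * params$alpha0
  structure(list(params = params, B_over_A = params$B / params$A,
                 ssr = best$ssr,
                 fitted = tibble::tibble(t = t, y = y, fitted = fitted),
                 observable = observable, degenerate = degenerate,
                 converged = best$fit$info %in% 1:4),
            class = "kernel_fit")
}

theta_to_params <- function(theta) {
  response_params("speculator", alpha0 = exp(theta[1]), beta = exp(theta[2]),
                  A = exp(theta[3]), B = -exp(theta[4]), tau = exp(theta[5]))
}

fit_init_heuristic <- function(t, y, c0, t_on, t_off, init, observable) {
  if (!is.null(init)) {
    if (inherits(init, "response_params"))
      return(c(init$alpha0, init$beta, abs(init$A), abs(init$B), init$tau))
    return(abs(init[c("alpha0", "beta", "A", "B", "tau")]))
  }
  eps <- 1e-4
  base <- y[t < t_on]
  p0 <- min(max(mean(if (length(base)) base else y[1]), eps), 1 - eps)
  on2 <- y[t > (t_on + t_off) / 2 & t < t_off]
  p1 <- min(max(mean(if (length(on2)) on2 else max(y)), eps), 1 - eps)
  tau0 <- (t_off - t_on) / 4
  if (observable == "probability") {
    beta0 <- 2 / tau0              # tumble relaxation faster than memory
    alpha00 <- beta0 * p0 / (1 - p0)
    a_ss <- beta0 * p1 / (1 - p1)  # steady rate on the plateau
  } else {
    beta0 <- 0.1
    alpha00 <- max(p0, eps)
    a_ss <- max(p1, 2 * eps)
  }
  net <- max((a_ss - alpha00) / c0, eps) # = A + B at steady state
  A0 <- 5 * net                          # assume B/A near -0.8
  B0 <- 4 * net
  c(alpha00, beta0, A0, B0, tau0)
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat(sprintf("<kernel_fit (%s): ssr = %.4g, B/A = %.3f%s>\n", x$observable,
              x$ssr, x$B_over_A,
              if (x$degenerate) ", DEGENERATE" else ""))
  print(x$params)
  invisible(x)
}

#' @rdname fit_step_response
#' @param x A `kernel_fit`.
#' @param ... Unused.
#' @export
tidy.kernel_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(term = c("alpha0", "beta", "A", "B", "tau"),
                 estimate = c(p$alpha0, p$beta, p$A, p$B, p$tau))
}

#' @rdname fit_step_response
#' @export
glance.kernel_fit <- function(x, ...) {
  tibble::tibble(ssr = x$ssr, B_over_A = x$B_over_A,
                 degenerate = x$degenerate, converged = x$converged,
                 n = nrow(x$fitted))
}

#' @rdname fit_step_response
#' @param object A `kernel_fit`.
#' @export
autoplot.kernel_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted, ggplot2::aes(.data$t, .data$y)) +
    ggplot2::geom_point(size = 0.8, colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "forestgreen") +
    ggplot2::labs(x = "time", y = object$observable)
}

# ---------------------------------------------------------------------------
# Oscillating two-Gaussian world
# ---------------------------------------------------------------------------

circular_mean_pos <- function(x, ell) {
  ang <- 2 * pi * x / ell
  (atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi) * ell) %% ell
}

circular_sd_pos <- function(x, ell) {
  ang <- 2 * pi * x / ell
  Rbar <- sqrt(mean(sin(ang))^2 + mean(cos(ang))^2)
  sqrt(pmax(0, -2 * log(Rbar))) * ell / (2 * pi)
}

#' Track a responder in the oscillating two-Gaussian world
#'
#' Simulates `n_agents` independent cells in the [two_gaussian_environment()]
#' for one burn-in period plus `n_periods` recorded periods, folds the
#' sampled positions by oscillation phase \eqn{\theta = t \bmod} period, and
#' returns wrap-aware (circular) mean and standard deviation of position per
#' phase bin. The agent time step is
#' `min(T_ref, L_ref/v, tau/20)` with `T_ref`, `L_ref` the stochastic-field
#' condition the world emulates.
#'
#' @param params A [response_params()] object.
#' @param n_agents Number of independent cells.
#' @param n_periods Recorded periods after burn-in.
#' @param burn_in_periods Burn-in before phase folding.
#' @param env A [two_gaussian_environment()].
#' @param theta_bin Phase bin width (time units).
#' @param T_ref,L_ref Reference field condition for the step-size rule.
#' @param v Running speed.
#' @return A `gaussian_world_result`: tibble `summary` (`theta`, `mean_pos`,
#'   `sd_pos`, `n`), raw `samples`, and metadata.
#' @export
oscillating_world_experiment <- function(params, n_agents = 50, n_periods = 2,
                                         burn_in_periods = 1,
                                         env = two_gaussian_environment(),
                                         theta_bin = 25, T_ref = 1e4,
                                         L_ref = 20, v = 1) {
  period <- env$par[["period"]]
  cfg <- make_sim_config(T_ref, L_ref, params$tau, v = v,
                         stop_attractant = Inf,
                         t_max = (burn_in_periods + n_periods) * period,
                         ell = env$ell)
  samples <- lapply(seq_len(n_agents), function(i) {
    sim <- simulate_agent(params, env, cfg, record = TRUE,
                          record_every = min(theta_bin, period / 200))
    tr <- sim$trajectory[sim$trajectory$t >= burn_in_periods * period, ]
    tibble::tibble(agent = i, t = tr$t, theta = tr$t %% period, x = tr$x)
  })
  samples <- dplyr::bind_rows(samples)
  samples$theta_bin <- floor(samples$theta / theta_bin) * theta_bin
  summary <- dplyr::summarise(
    dplyr::group_by(samples, theta = .data$theta_bin),
    mean_pos = circular_mean_pos(.data$x, env$ell),
    sd_pos = circular_sd_pos(.data$x, env$ell),
    n = dplyr::n(), .groups = "drop")
  structure(list(summary = summary, samples = samples, env = env,
                 params = params),
            class = "gaussian_world_result")
}

#' Compare adaptive and speculator tracking in the two-Gaussian world
#'
#' Runs [oscillating_world_experiment()] for an adaptive and a speculator
#' responder and binds the phase-folded position summaries.
#'
#' @param params_adaptive,params_speculator [response_params()] for the two
#'   strategies.
#' @inheritParams oscillating_world_experiment
#' @return A tibble with a `strategy` column plus the per-phase summary; the
#'   two full `gaussian_world_result`s are attached as attribute `"results"`.
#' @export
two_gaussian_experiment <- function(params_adaptive, params_speculator,
                                    n_agents = 50, n_periods = 2, ...) {
  res_a <- oscillating_world_experiment(params_adaptive, n_agents, n_periods, ...)
  res_s <- oscillating_world_experiment(params_speculator, n_agents, n_periods, ...)
  out <- dplyr::bind_rows(
    dplyr::mutate(res_a$summary, strategy = "adaptive"),
    dplyr::mutate(res_s$summary, strategy = "speculator"))
  attr(out, "results") <- list(adaptive = res_a, speculator = res_s)
  out
}

#' Phase at which the tracked population crosses to the other peak
#'
#' The first phase \eqn{\theta > 0} at which the circular mean position is
#' closer (in wrap-aware distance) to the destination peak than to the
#' origin peak.
#'
#' @param result A `gaussian_world_result`.
#' @param from,to Positions of the origin and destination peaks.
#' @return The crossing phase (time units within one period), or `NA` if the
#'   population never crosses.
#' @export
crossing_phase <- function(result, from = 25, to = 75) {
  s <- result$summary
  ell <- result$env$ell
  dist_c <- function(a, b) pmin(abs(a - b) %% ell, ell - abs(a - b) %% ell)
  crossed <- dist_c(s$mean_pos, to) < dist_c(s$mean_pos, from)
  if (!any(crossed)) return(NA_real_)
  min(s$theta[crossed])
}

#' @export
print.gaussian_world_result <- function(x, ...) {
  cat(sprintf("<gaussian_world_result: %d agents, %d phase bins>\n",
              length(unique(x$samples$agent)), nrow(x$summary)))
  invisible(x)
}

#' @rdname oscillating_world_experiment
#' @param object A `gaussian_world_result`.
#' @param ... Unused.
#' @export
autoplot.gaussian_world_result <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(.data$theta, .data$mean_pos)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_pos - .data$sd_pos,
      ymax = .data$mean_pos + .data$sd_pos), fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(25, 75), linetype = "dashed",
                        colour = c("goldenrod", "turquoise4")) +
    ggplot2::labs(x = expression(theta), y = "position")
}

# ---------------------------------------------------------------------------
# 3D traversal
# ---------------------------------------------------------------------------

#' Concentration experienced along a 3D ballistic traversal
#'
#' Moves at speed `v` along a uniformly random 3D direction, redrawing the
#' direction after every traversed distance `2 * ell` (positions wrap
#' periodically per axis), sampling the static 3D field every
#' `dx = v * dt`. Direction draws use R's RNG.
#'
#' @param field A [make_field_3d()] object.
#' @param v Speed.
#' @param n_segments Number of straight segments (each of length `2 * ell`).
#' @param dx Spatial sampling interval along the path.
#' @param start Optional starting coordinates (default uniform).
#' @param direction Optional fixed unit direction (recycled for all
#'   segments); default: random per segment.
#' @return A tibble with columns `t`, `segment`, `x`, `y`, `z`, `c`.
#' @export
traverse_3d <- function(field, v = 1, n_segments = 20, dx = 0.5,
                        start = NULL, direction = NULL) {
  ell <- field$ell
  pos <- start %||% runif(3, 0, ell)
  n_per <- floor(2 * ell / dx)
  out <- vector("list", n_segments)
  t0 <- 0
  for (s in seq_len(n_segments)) {
    u <- if (is.null(direction)) {
      raw <- rnorm(3)
      raw / sqrt(sum(raw^2))
    } else direction / sqrt(sum(direction^2))
    steps <- seq_len(n_per) * dx
    xs <- (pos[1] + u[1] * steps) %% ell
    ys <- (pos[2] + u[2] * steps) %% ell
    zs <- (pos[3] + u[3] * steps) %% ell
    cc <- field3d_concentration(field, xs, ys, zs)
    out[[s]] <- tibble::tibble(t = t0 + steps / v, segment = s,
                               x = xs, y = ys, z = zs, c = cc)
    pos <- c(xs[n_per], ys[n_per], zs[n_per])
    t0 <- t0 + n_per * dx / v
  }
  dplyr::bind_rows(out)
}

#' Normalized autocorrelation of a stationary series
#'
#' Mean-removed autocovariance with the biased (1/n) normalization,
#' normalized to `r(0) = 1` (computed via [stats::acf()]).
#'
#' @param y Numeric series, or a data frame whose last column is the series.
#' @param max_lag Largest lag (in samples).
#' @return A tibble with columns `lag` and `r`.
#' @export
acf_series <- function(y, max_lag) {
  if (is.data.frame(y)) y <- y[[ncol(y)]]
  a <- stats::acf(y, lag.max = max_lag, plot = FALSE, demean = TRUE)
  tibble::tibble(lag = as.vector(a$lag), r = as.vector(a$acf))
}
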