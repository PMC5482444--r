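#' Simulation configuration for a single agent
#'
#' The agent state is updated every
#' \eqn{\Delta t_B = \min(T, L/v, \tau/20)}: the step must resolve the
#' field's correlation time, the distance between attractant peaks at
#' running speed, and the response memory. A fitness run ends when the agent
#' has experienced `stop_attractant` units of attractant (default `50 * T`,
#' integrated concentration x time); `t_max` is a safety cap for
#' pathological parameter sets (truncations are flagged and counted).
#'
#' @param T_corr Field correlation time.
#' @param L Field correlation length.
#' @param tau Response memory length of the simulated cell.
#' @param v Running speed (default 1).
#' @param stop_attractant Accumulated-attractant stopping threshold.
#' @param t_max Hard time cap.
#' @param ell World length.
#' @return A `sim_config` object.
#' @export
make_sim_config <- function(T_corr, L, tau, v = 1,
                            stop_attractant = 50 * T_corr,
                            t_max = 1e4 * T_corr, ell = 100) {
  stopifnot(T_corr > 0, L > 0, tau > 0, v > 0)
  structure(list(v = v, dt_B = min(T_corr, L / v, tau / 20),
                 stop_attractant = stop_attractant, t_max = t_max, ell = ell),
            class = "sim_config")
}

#' Initialize an agent
#'
#' Position uniform on `[0, ell)`, running in a random direction, memory
#' initialized at the local equilibrated concentration (as if the cell had
#' sat there forever).
#'
#' @param env A `chemo_env` the agent will live in (deterministic tags only;
#'   stochastic-field runs initialize inside the simulator).
#' @param params A [response_params()] object.
#' @param cfg A [make_sim_config()] object.
#' @return An `agent_state` list: `x`, `mode` (`"run_right"`, `"run_left"` or
#'   `"tumble"`), `memory`, `accumulated`, `t`.
#' @export
init_agent <- function(env, params, cfg) {
  x <- runif(1, 0, cfg$ell)
  structure(list(
    x = x,
    mode = if (runif(1) < 0.5) "run_right" else "run_left",
    memory = init_memory(params, env_concentration(env, x, 0)),
    accumulated = 0,
    t = 0
  ), class = "agent_state")
}

#' Advance an agent by one time step (reference implementation)
#'
#' One step of the two-state Monte Carlo scheme, in order: read the local
#' concentration; update the response memory; compute the tumble-start rate
#' \eqn{\alpha}; attempt one mode switch (run \eqn{\to} tumble with
#' probability \eqn{1 - e^{-\alpha \Delta t_B}}, tumble \eqn{\to} run with
#' probability \eqn{1 - e^{-\beta \Delta t_B}}, resuming left or right with
#' equal probability); move if running (tumbling agents hold position);
#' accumulate experienced attractant; advance time. The exponential
#' switching probability is the exact first-order two-state form, safe for
#' large \eqn{\alpha \Delta t_B}.
#'
#' This R implementation defines the step semantics and backs the unit
#' tests; production runs go through the compiled loop in
#' [simulate_agent()].
#'
#' @param agent An `agent_state`.
#' @inheritParams init_agent
#' @return The advanced `agent_state`, with the step's concentration and
#'   rate attached as attributes `"c"` and `"alpha"`.
#' @export
step_agent <- function(agent, env, params, cfg) {
  c_here <- env_concentration(env, agent$x, agent$t)
  agent$memory <- update_memory(agent$memory, c_here, cfg$dt_B, params$tau)
  alpha <- tumble_start_rate(params, agent$memory)
  if (agent$mode == "tumble") {
    if (runif(1) < -expm1(-params$beta * cfg$dt_B))
      agent$mode <- if (runif(1) < 0.5) "run_right" else "run_left"
  } else if (alpha > 0 && runif(1) < -expm1(-alpha * cfg$dt_B)) {
    agent$mode <- "tumble"
  }
  if (agent$mode != "tumble") {
    dx <- if (agent$mode == "run_right") cfg$v * cfg$dt_B else -cfg$v * cfg$dt_B
    agent$x <- (agent$x + dx) %% cfg$ell
  }
  agent$accumulated <- agent$accumulated + c_here * cfg$dt_B
  agent$t <- agent$t + cfg$dt_B
  attr(agent, "c") <- c_here
  attr(agent, "alpha") <- alpha
  agent
}

env_code <- function(env) {
  switch(env$tag, stochastic = 0L, constant = 1L, step = 2L,
         two_gaussian = 3L,
         stop("unknown environment tag: ", env$tag))
}

env_par_vector <- function(env) {
  switch(env$tag,
         stochastic = c(0, 0, 0, 0, 0), # field spec passed separately
         constant = c(env$par[["c0"]], 0, 0, 0, 0),
         step = c(env$par[["c0"]], env$par[["t_on"]], env$par[["t_off"]], 0, 0),
         two_gaussian = unname(env$par))
}

field_par_vector <- function(env) {
  if (env$tag == "stochastic")
    c(env$par[["T_corr"]], env$par[["dt_c"]], env$par[["p_star"]],
      env$par[["seed"]], env$par[["n_eq"]])
  else numeric(5)
}

#' Simulate a run-and-tumble trajectory
#'
#' Runs the compiled simulation loop until the agent has accumulated
#' `cfg$stop_attractant` experienced-attractant units (or `cfg$t_max` is
#' reached, in which case the result is flagged truncated). For stochastic
#' environments the field is regenerated deterministically from the
#' environment's seed, equilibrated for `2 T`, and updated on its own
#' `dt_c` clock while the agent steps every `dt_B` (the agent reads the most
#' recent field state). Agent-level randomness (initial position and
#' direction, mode switching) is drawn from R's global RNG, so trajectories
#' are reproducible under `set.seed()`.
#'
#' @inheritParams init_agent
#' @param record If `TRUE`, return the trajectory sampled every
#'   `record_every` time units.
#' @param record_every Sampling interval of the recorded trajectory
#'   (defaults to `10 * dt_B`).
#' @return A `chemo_sim` list: `D` (time to threshold), `truncated`,
#'   `accumulated`, and (if recording) `trajectory`, a tibble with columns
#'   `t`, `x`, `mode`, `c`, `alpha`, `accumulated`.
#' @export
simulate_agent <- function(params, env, cfg, record = FALSE,
                           record_every = 10 * cfg$dt_B) {
  res <- cpp_simulate(
    c(params$alpha0, params$beta, params$A, params$B, params$tau),
    env_code(env), env_par_vector(env),
    c(cfg$v, cfg$dt_B, cfg$stop_attractant, cfg$t_max, cfg$ell),
    field_par_vector(env),
    if (record) record_every else 0
  )
  out <- list(D = res$D, truncated = res$truncated,
              accumulated = res$accumulated)
  if (record) {
    m <- res$trajectory
    out$trajectory <- tibble::tibble(
      t = m[, 1], x = m[, 2],
      mode = c("run_right", "run_left", "tumble")[m[, 3] + 1],
      c = m[, 4], alpha = m[, 5], accumulated = m[, 6])
  }
  structure(out, class = "chemo_sim")
}

#' @export
print.chemo_sim <- function(x, ...) {
  cat(sprintf("<chemo_sim: D = %g%s, accumulated = %g>\n", x$D,
              if (x$truncated) " (truncated)" else "", x$accumulated))
  invisible(x)
}

#' @rdname simulate_agent
#' @param object A `chemo_sim` with a recorded trajectory.
#' @param ... Unused.
#' @export
autoplot.chemo_sim <- function(object, ...) {
  if (is.null(object$trajectory))
    stop("simulate with record = TRUE to plot a trajectory")
  ggplot2::ggplot(object$trajectory, ggplot2::aes(.data$t, .data$x)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$c), size = 0.4) +
    ggplot2::scale_colour_viridis_c(name = "attractant") +
    ggplot2::labs(x = "time", y = "position")
}
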