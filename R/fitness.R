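#' Fitness from times-to-threshold
#'
#' Fitness approximates the average cell-division rate as
#' \eqn{F = T \langle 1/D_i \rangle_i}: the mean inverse time for replicate
#' cells to experience a fixed amount of attractant, scaled by the field
#' correlation time so the non-chemotaxing baseline is comparable across
#' conditions.
#'
#' @param D Vector of per-replicate times to the attractant threshold.
#' @param T_corr Field correlation time used for scaling.
#' @return The fitness (dimensionless under simulation units).
#' @export
fitness_from_times <- function(D, T_corr) {
  stopifnot(length(D) >= 1, all(D > 0))
  T_corr * mean(1 / D)
}

#' Evaluate the fitness of a response in stochastic environments
#'
#' Runs one [simulate_agent()] per field seed, each in a freshly initialized
#' (equilibrated) field realization, until the agent experiences
#' `stop_attractant` units of attractant. Truncated runs (time cap reached)
#' contribute the conservative lower bound `1/t_max` to the mean and are
#' counted; if every replicate truncates the parameter set is degenerate and
#' an error is raised.
#'
#' @param params A [response_params()] object.
#' @param T_corr,L Field correlation time and length.
#' @param field_seeds Integer seeds, one replicate field per seed.
#' @param stop_attractant Attractant threshold (default `50 * T_corr`; the
#'   desk-scale evolution preset uses `5 * T_corr`).
#' @param t_max Time cap per replicate.
#' @param v,ell Running speed and world length.
#' @param agent_seeds Optional integer seeds for the agent-level randomness
#'   of each replicate (default: fresh draws from the current RNG stream).
#'   Supplying them makes the evaluation fully deterministic, which is how
#'   [relative_fitness()] shares agent randomness between the candidate and
#'   the baseline.
#' @return A `fitness_result` list: `F`, `D` (per-replicate times),
#'   `n_truncated`, `seeds`, `T_corr`, `L`.
#' @export
evaluate_fitness <- function(params, T_corr, L, field_seeds,
                             stop_attractant = 50 * T_corr,
                             t_max = 1e4 * T_corr, v = 1, ell = 100,
                             agent_seeds = NULL) {
  stopifnot(length(field_seeds) >= 1)
  if (!is.null(agent_seeds))
    stopifnot(length(agent_seeds) == length(field_seeds))
  fp <- field_params(T_corr, L, ell)
  cfg <- make_sim_config(T_corr, L, params$tau, v = v,
                         stop_attractant = stop_attractant,
                         t_max = t_max, ell = ell)
  runs <- lapply(seq_along(field_seeds), function(i) {
    if (!is.null(agent_seeds)) set.seed(agent_seeds[i])
    simulate_agent(params, stochastic_environment(fp, field_seeds[i]), cfg)
  })
  D <- vapply(runs, `[[`, numeric(1), "D")
  truncated <- vapply(runs, `[[`, logical(1), "truncated")
  if (all(truncated))
    stop("degenerate parameters: all replicates hit t_max before the ",
         "attractant threshold")
  if (mean(truncated) > 0.2)
    warning(sprintf("%d of %d replicates truncated at t_max; ",
                    sum(truncated), length(truncated)),
            "fitness estimate unreliable")
  structure(list(F = fitness_from_times(D, T_corr), D = D,
                 n_truncated = sum(truncated),
                 seeds = field_seeds, T_corr = T_corr, L = L),
            class = "fitness_result")
}

#' @export
print.fitness_result <- function(x, ...) {
  cat(sprintf("<fitness_result: F = %g over %d replicates (%d truncated)>\n",
              x$F, length(x$D), x$n_truncated))
  invisible(x)
}

#' @rdname evaluate_fitness
#' @param x A `fitness_result`.
#' @param ... Unused.
#' @export
tidy.fitness_result <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$D), seed = x$seeds, D = x$D,
                 inv_D = 1 / x$D)
}

#' Paired wild-type / mutant fitness evaluation
#'
#' Both responses are evaluated on the same list of field seeds, so
#' replicate `i` of the mutant explores a bit-identical field realization to
#' replicate `i` of the wild type (common random numbers: lucky attractant
#' draws cannot fix a mutant). Agent-level randomness is fresh for every
#' run.
#'
#' @param wt,mut [response_params()] for the wild type and the mutant.
#' @inheritParams evaluate_fitness
#' @return A list with elements `wt` and `mut`, each a `fitness_result`.
#' @export
paired_evaluate <- function(wt, mut, T_corr, L, field_seeds, ...) {
  list(wt = evaluate_fitness(wt, T_corr, L, field_seeds, ...),
       mut = evaluate_fitness(mut, T_corr, L, field_seeds, ...))
}

#' Fitness relative to the non-chemotaxing baseline
#'
#' Scales the fitness of `params` by the fitness of the always-running
#' [null_response()] evaluated on the same field seeds and the same
#' agent-level seeds (common random numbers throughout, so an agent
#' identical to the baseline scores exactly 1). The baseline's
#' experienced-concentration statistics equal the field's spatial
#' statistics, making its fitness independent of `T_corr` and `L`.
#'
#' @inheritParams evaluate_fitness
#' @param ... Passed to [evaluate_fitness()] (e.g. `stop_attractant`).
#' @return The dimensionless fitness ratio.
#' @export
relative_fitness <- function(params, T_corr, L, field_seeds,
                             agent_seeds = NULL, ...) {
  agent_seeds <- agent_seeds %||%
    (as.integer(field_seeds) %% 2000000000L + 7L)
  f <- evaluate_fitness(params, T_corr, L, field_seeds,
                        agent_seeds = agent_seeds, ...)
  f0 <- evaluate_fitness(null_response(T_corr, L), T_corr, L, field_seeds,
                         agent_seeds = agent_seeds, ...)
  f$F / f0$F
}
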