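#' Evolutionary optimization configuration
#'
#' Settings of the Metropolis-Hastings optimization of response parameters.
#' One generation is mutate, evaluate (paired wild type and mutant on shared
#' field realizations), accept. The `"full"` scale uses the full study
#' conditions (10 replicate cells per fitness, threshold `50 T`); the
#' `"desk"` scale is a first-class reduced preset (5 replicates, threshold
#' `5 T`, at most 3000 generations) for benchmarking on a single workstation.
#'
#' @param T_corr,L Field correlation time and length.
#' @param scale `"full"` or `"desk"` preset.
#' @param U Metropolis temperature (default 0.005).
#' @param r_range Half-width of the uniform log-scale mutation step
#'   (default 0.2).
#' @param n_replicates Replicate cells per fitness evaluation.
#' @param window Convergence / summary window in generations (default 600).
#' @param max_generations Generation cap.
#' @param stop_attractant Attractant threshold per replicate.
#' @param t_max Time cap per replicate.
#' @param eps_rel Relative tolerance of the fitness-plateau convergence test.
#' @param seed Optional seed for the whole run (field seeds, mutations and
#'   agent randomness all flow from R's RNG once set).
#' @return An `evolution_config` list.
#' @export
evolution_config <- function(T_corr, L, scale = c("full", "desk"),
                             U = 0.005, r_range = 0.2,
                             n_replicates = NULL, window = 600,
                             max_generations = NULL,
                             stop_attractant = NULL, t_max = 1e4 * T_corr,
                             eps_rel = 0.01, seed = NULL) {
  scale <- match.arg(scale)
  defaults <- switch(scale,
    full = list(n_replicates = 10, stop_attractant = 50 * T_corr,
                 max_generations = 100000),
    desk = list(n_replicates = 5, stop_attractant = 5 * T_corr,
                max_generations = 3000))
  structure(list(
    T_corr = T_corr, L = L, scale = scale, U = U, r_range = r_range,
    n_replicates = n_replicates %||% defaults$n_replicates,
    window = window,
    max_generations = max_generations %||% defaults$max_generations,
    stop_attractant = stop_attractant %||% defaults$stop_attractant,
    t_max = t_max, eps_rel = eps_rel, seed = seed
  ), class = "evolution_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# magnitude floors imposed for computational tractability; a parameter with
# no stated floor gets 0 (beta gets a small numerical-safety floor)
param_floors <- function(strategy) {
  switch(strategy,
         adaptive = c(alpha0 = 1e-3, beta = 1e-6, B = 0, tau = 0.01),
         inverted = c(alpha0 = 1e-3, beta = 1e-6, A = 0, tau = 0),
         speculator = c(alpha0 = 0, beta = 1e-6, A = exp(-1), B = exp(-1),
                        tau = 0))
}

mutable_params <- function(strategy) {
  switch(strategy,
         adaptive = c("alpha0", "beta", "B", "tau"), # A slaved to -B
         inverted = c("alpha0", "beta", "A", "tau"),
         speculator = c("alpha0", "beta", "A", "B", "tau"))
}

runif_above <- function(lo, hi, floor) {
  # uniform on (lo, hi) conditioned above the magnitude floor
  repeat {
    x <- runif(1, lo, hi)
    if (abs(x) > floor) return(x)
  }
}

#' Random initial response parameters
#'
#' All parameters start uniform on (0, 1), subject to the strategy's
#' constraints: adaptive draws only `B` (`A = -B`; at `T_corr >= 1e4`, `B`
#' starts between 1 and 10), inverted fixes `B = 0`, speculator draws `B`
#' between -1 and 0. Draws are rejection-sampled inside the tractability
#' floors (see [mutate_params()]), since a parameter initialized below its
#' floor could never satisfy it under bounded multiplicative mutation.
#'
#' @param strategy `"adaptive"`, `"inverted"` or `"speculator"`.
#' @param T_corr Field correlation time of the target condition.
#' @return A [response_params()] object.
#' @export
init_params <- function(strategy = c("adaptive", "inverted", "speculator"),
                        T_corr) {
  strategy <- match.arg(strategy)
  fl <- param_floors(strategy)
  alpha0 <- runif_above(0, 1, fl[["alpha0"]])
  beta <- runif_above(0, 1, fl[["beta"]])
  tau <- runif_above(0, 1, fl[["tau"]])
  if (strategy == "adaptive") {
    B <- if (T_corr >= 1e4) runif(1, 1, 10) else runif_above(0, 1, fl[["B"]])
    response_params("adaptive", alpha0 = alpha0, beta = beta, B = B, tau = tau)
  } else if (strategy == "inverted") {
    A <- runif_above(0, 1, fl[["A"]])
    response_params("inverted", alpha0 = alpha0, beta = beta, A = A, tau = tau)
  } else {
    A <- runif_above(0, 1, fl[["A"]])
    B <- -runif_above(0, 1, fl[["B"]])
    response_params("speculator", alpha0 = alpha0, beta = beta, A = A, B = B,
                    tau = tau)
  }
}

#' Mutate one response parameter on a log scale
#'
#' Chooses one mutable parameter uniformly at random (for the adaptive
#' strategy `A` is slaved to `-B` and is not in the set) and multiplies its
#' magnitude by \eqn{e^r}, \eqn{r \sim U(-0.2, 0.2)}, preserving the sign.
#' Magnitude floors (`alpha0 > 1e-3` for adaptive and inverted,
#' `A, |B| > e^{-1}` for speculator, `tau > 0.01` for adaptive, and a
#' numerical-safety floor `beta > 1e-6`) are enforced by redrawing `r`; if
#' 100 redraws fail the parent value is kept with a warning.
#'
#' @param params Parent [response_params()].
#' @param r_range Half-width of the uniform distribution of `r`.
#' @return The mutated [response_params()], with the chosen parameter name
#'   in attribute `"mutated"`.
#' @export
mutate_params <- function(params, r_range = 0.2) {
  strategy <- params$strategy
  fl <- param_floors(strategy)
  which_par <- sample(mutable_params(strategy), 1)
  old <- params[[which_par]]
  sign_old <- if (old < 0) -1 else 1
  mag <- abs(old)
  ok <- FALSE
  for (i in seq_len(100)) {
    r <- runif(1, -r_range, r_range)
    new_mag <- exp(log(mag) + r)
    if (new_mag > fl[[which_par]]) { ok <- TRUE; break }
  }
  if (!ok) {
    warning("mutation redraw budget exhausted for ", which_par,
            "; keeping parent value")
    new_mag <- mag
  }
  params[[which_par]] <- sign_old * new_mag
  if (strategy == "adaptive") params$A <- -params$B
  attr(params, "mutated") <- which_par
  params
}

#' Metropolis-Hastings acceptance probability
#'
#' \eqn{p = 1} if the mutant fitness is at least the wild type's, else
#' \eqn{p = \exp((F_m - F_w)/(U F_w))} with temperature `U`.
#'
#' @param F_m,F_w Mutant and wild-type fitness (`F_w > 0`).
#' @param U Metropolis temperature.
#' @return The acceptance probability.
#' @export
accept_probability <- function(F_m, F_w, U = 0.005) {
  stopifnot(F_w > 0)
  ifelse(F_m >= F_w, 1, exp((F_m - F_w) / (U * F_w)))
}

#' Run the Metropolis-Hastings evolutionary optimization
#'
#' Iterates mutate, paired fitness evaluation (fresh field seeds every
#' generation, shared between wild type and mutant), and Metropolis
#' acceptance, until the chain fitness has plateaued for `window`
#' generations (see [has_converged()]) or the generation cap is reached.
#' A mutant whose fitness evaluation degenerates (all replicates truncated)
#' is rejected outright.
#'
#' Set `environment = "constant"` to run the chain on a flat fitness
#' landscape (spatially uniform attractant): every mutation is then
#' accepted and the log-parameter marginals perform a pure random walk, a
#' useful detailed-balance diagnostic.
#'
#' @param strategy `"adaptive"`, `"inverted"` or `"speculator"`.
#' @param config An [evolution_config()].
#' @param init Optional starting [response_params()] (default
#'   [init_params()]).
#' @param environment `"stochastic"` (the study condition) or `"constant"`.
#' @param check_every Convergence is tested every this many generations.
#' @param verbose Print progress every 100 generations.
#' @return An `evolution_trace`: the per-generation tibble (`generation`,
#'   `mutated_param`, `F_w`, `F_m`, `accepted`, post-selection parameter
#'   columns, `B_over_A`, `fitness` = chain fitness) plus metadata.
#' @export
run_evolution <- function(strategy, config, init = NULL,
                          environment = c("stochastic", "constant"),
                          check_every = 25, verbose = FALSE) {
  environment <- match.arg(environment)
  if (!is.null(config$seed)) set.seed(config$seed)
  wt <- init %||% init_params(strategy, config$T_corr)
  n_gen <- config$max_generations
  rows <- vector("list", 0)
  fitness_chain <- numeric(0)
  converged <- FALSE

  eval_one <- function(p, seeds) {
    if (environment == "constant") {
      cfg <- make_sim_config(config$T_corr, config$L, p$tau,
                             stop_attractant = config$stop_attractant,
                             t_max = config$t_max)
      sims <- vapply(seeds, function(s)
        simulate_agent(p, constant_environment(1), cfg)$D, numeric(1))
      fitness_from_times(sims, config$T_corr)
    } else {
      evaluate_fitness(p, config$T_corr, config$L, seeds,
                       stop_attractant = config$stop_attractant,
                       t_max = config$t_max)$F
    }
  }

  for (gen in seq_len(n_gen)) {
    seeds <- sample.int(2147483646, config$n_replicates)
    mut <- mutate_params(wt, config$r_range)
    F_w <- eval_one(wt, seeds)
    F_m <- tryCatch(eval_one(mut, seeds), error = function(e) NA_real_)
    accepted <- !is.na(F_m) &&
      runif(1) < accept_probability(F_m, F_w, config$U)
    if (accepted) wt <- mut
    chain_F <- if (accepted) F_m else F_w
    fitness_chain[gen] <- chain_F
    rows[[gen]] <- data.frame(
      generation = gen, mutated_param = attr(mut, "mutated"),
      F_w = F_w, F_m = F_m, accepted = accepted,
      alpha0 = wt$alpha0, beta = wt$beta, A = wt$A, B = wt$B, tau = wt$tau,
      B_over_A = if (wt$A != 0) wt$B / wt$A else NA_real_,
      fitness = chain_F)
    if (verbose && gen %% 100 == 0)
      message(sprintf("gen %d: F = %.4g (accepted %.1f%%)", gen, chain_F,
                      100 * mean(vapply(rows[seq_len(gen)], `[[`, logical(1),
                                        "accepted"))))
    if (gen >= config$window && gen %% check_every == 0 &&
        has_converged(fitness_chain, config$window, config$eps_rel)) {
      converged <- TRUE
      break
    }
  }

  structure(list(
    trace = tibble::as_tibble(dplyr::bind_rows(rows)),
    strategy = strategy, config = config, converged = converged,
    final = wt
  ), class = "evolution_trace")
}

#' Fitness-plateau convergence test
#'
#' The chain is converged when no fitness in the last `window` generations
#' exceeds the fitness at the window's start by more than `eps_rel`
#' relative — an operational version of "the fitness stops increasing and
#' stays constant" that tolerates the stochastic fitness noise.
#'
#' @param trace An `evolution_trace` or a numeric chain-fitness vector of
#'   length at least `window`.
#' @param window Plateau length in generations.
#' @param eps_rel Relative tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
has_converged <- function(trace, window = 600, eps_rel = 0.01) {
  f <- if (inherits(trace, "evolution_trace")) trace$trace$fitness else trace
  n <- length(f)
  if (n < window) return(FALSE)
  win <- f[(n - window + 1):n]
  all(win <= win[1] * (1 + eps_rel))
}

#' Final-window parameter summary of an evolutionary run
#'
#' Arithmetic means of each response parameter (and of the adaptation ratio
#' `B/A`) over the chain states of the final `window` generations — the
#' standard end-of-run summary of a converged chain.
#'
#' @param trace An `evolution_trace`.
#' @param window Summary window (default 600 generations).
#' @return A one-row tibble: `strategy`, `generations`, `converged`, means
#'   of `alpha0`, `beta`, `A`, `B`, `tau`, `B_over_A`, and `fitness`.
#' @export
summarize_trace <- function(trace, window = 600) {
  tr <- trace$trace
  n <- nrow(tr)
  win <- tr[max(1, n - window + 1):n, ]
  tibble::tibble(
    strategy = trace$strategy, generations = n, converged = trace$converged,
    alpha0 = mean(win$alpha0), beta = mean(win$beta),
    A = mean(win$A), B = mean(win$B), tau = mean(win$tau),
    B_over_A = mean(win$B_over_A), fitness = mean(win$fitness))
}

#' Replicate ranges of final-window parameter means
#'
#' Summarizes several replicate runs of the same strategy and condition as
#' the (min, max) range of the replicate means of each parameter.
#'
#' @param traces A list of `evolution_trace` objects.
#' @param window Summary window per replicate.
#' @return A tibble with one row per parameter: `parameter`, `min`, `max`.
#' @export
summarize_replicates <- function(traces, window = 600) {
  means <- dplyr::bind_rows(lapply(traces, summarize_trace, window = window))
  long <- tidyr::pivot_longer(
    means[, c("alpha0", "beta", "A", "B", "tau", "B_over_A")],
    cols = dplyr::everything(), names_to = "parameter")
  dplyr::summarise(dplyr::group_by(long, .data$parameter),
                   min = min(.data$value), max = max(.data$value),
                   .groups = "drop")
}

#' @rdname run_evolution
#' @param x An `evolution_trace`.
#' @param ... Unused.
#' @export
tidy.evolution_trace <- function(x, ...) x$trace

#' @rdname run_evolution
#' @export
glance.evolution_trace <- function(x, ...) summarize_trace(x, x$config$window)

#' @rdname run_evolution
#' @param object An `evolution_trace`.
#' @export
autoplot.evolution_trace <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$generation, .data$fitness)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = dplyr::filter(object$trace, .data$accepted),
                        colour = "firebrick", size = 0.5) +
    ggplot2::labs(x = "generation", y = "chain fitness",
                  title = sprintf("%s response", object$strategy))
}

#' @export
print.evolution_trace <- function(x, ...) {
  cat(sprintf("<evolution_trace: %s, %d generations%s>\n", x$strategy,
              nrow(x$trace), if (x$converged) ", converged" else ""))
  print(x$final)
  invisible(x)
}
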