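run_config_defaults <- function() {
  list(T_corr = NULL, L = NULL, ell = 100, v = 1, strategy = NULL,
       alpha0 = NULL, beta = NULL, A = NULL, B = NULL, tau = NULL,
       U = 0.005, r_range = 0.2, window = 600, n_replicates = NULL,
       max_generations = NULL, stop_attractant = NULL, t_max = NULL,
       scale = "desk", seed = 1, out = NULL)
}

#' Load a run configuration
#'
#' Reads a YAML or JSON configuration (by file extension), validates the
#' keys against the known schema, fills defaults (`ell = 100`, `v = 1`,
#' `U = 0.005`, `window = 600`, ...) and derives the clock settings
#' (`dt_c = T/100`; `dt_B = min(T, L/v, tau/20)` when `tau` is known).
#' Unknown keys are rejected by name. The key `T` is accepted as an alias
#' for `T_corr`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config` list, fully serializable; a run is reproducible
#'   from its config plus seed.
#' @export
load_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json")
  if (!is.null(raw$T)) {
    raw$T_corr <- raw$T
    raw$T <- NULL
  }
  raw$dt_c <- NULL  # derived keys are recomputed, not trusted
  raw$dt_B <- NULL
  defaults <- run_config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw, keep.null = TRUE)
  if (is.null(cfg$T_corr) || is.null(cfg$L))
    stop("config must provide T (correlation time) and L (correlation length)")
  cfg$dt_c <- cfg$T_corr / 100
  if (!is.null(cfg$tau))
    cfg$dt_B <- min(cfg$T_corr, cfg$L / cfg$v, cfg$tau / 20)
  structure(cfg, class = "run_config")
}

#' @rdname load_run_config
#' @param config A `run_config`.
#' @export
save_run_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a time-series CSV with a units comment line
#'
#' @param data A data frame.
#' @param path Output path.
#' @param units A comment line describing columns and units.
#' @export
write_series_csv <- function(data, path, units = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(units)) writeLines(paste0("# ", units), con)
  utils::write.table(data, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' Generate deterministic test fixtures
#'
#' Writes small CSV fixtures for testing and demonstration. Kinds:
#'
#' * `"step-series"`: a noisy synthetic speculator step-response series
#'   (time, tumbling probability) from stated generating parameters — a
#'   synthetic stand-in for digitized experimental tumbling data.
#' * `"field-snapshot"`: an equilibrated stochastic-field snapshot `(x, c)`
#'   on a 1000-point grid.
#' * `"trace"`: a 700-generation synthetic fitness plateau (passes
#'   [has_converged()]).
#'
#' Fixtures are byte-identical on re-run for the same arguments and seed.
#'
#' @param kind One of `"step-series"`, `"field-snapshot"`, `"trace"`.
#' @param path Output CSV path.
#' @param seed Integer seed.
#' @param params Optional generating [response_params()] (step-series) or
#'   [field_params()] (field-snapshot).
#' @param noise_sd Noise level of the step series.
#' @return The path, invisibly.
#' @export
generate_fixture <- function(kind = c("step-series", "field-snapshot", "trace"),
                             path, seed = 1, params = NULL, noise_sd = 0.02) {
  kind <- match.arg(kind)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  if (kind == "step-series") {
    if (is.null(params))
      params <- response_params("speculator", alpha0 = 0.074, beta = 0.034,
                                A = 1300, B = -1000, tau = 71)
    series <- synthetic_step_series(params, noise_sd = noise_sd)
    write_series_csv(series, path,
                     paste("t (s), y = tumbling probability (dimensionless);",
                           "synthetic; step c0 = 0.001 mM on t in [50, 350)"))
  } else if (kind == "field-snapshot") {
    if (is.null(params)) params <- field_params(1000, 20)
    state <- init_field(params, seed)
    x <- seq(0, params$ell, length.out = 1001)[1:1000]
    write_series_csv(tibble::tibble(x = x,
                                    c = concentration(state, params, x)),
                     path, "x (length units), c (concentration units)")
  } else {
    gens <- 1:700
    fitness <- 5 + 0.002 * pmin(gens, 80) + 0.002 * sin(gens / 7)
    write_series_csv(tibble::tibble(generation = gens, fitness = fitness),
                     path, "generation, fitness (plateau fixture)")
  }
  invisible(path)
}
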