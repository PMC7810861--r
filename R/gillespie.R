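#' Noise-granularity configuration for stochastic simulation
#'
#' The Gillespie jump size per reaction event.  Each production/decay event
#' moves a node by `eta` concentration units while propensities are divided
#' by `eta`, preserving the deterministic drift and scaling the variance
#' with `eta`.  PTB and RESTc operate near relative concentration 1 (the
#' other factors nearer 5) and fit with much faster turnover, so their
#' granularity is reduced by two factors of 1/5: with the default base of
#' 0.1 their effective granularity is 0.004 while nPTB, miRs and Ascl1 stay
#' at 0.1.
#'
#' @param eta base granularity (> 0), default 0.1.
#' @param multipliers named per-node multipliers; unnamed nodes get 1.
#' @return object of class `grn_noise`.
#' @export
noise_config <- function(eta = 0.1,
                         multipliers = c(PTB = 1 / 25, RESTc = 1 / 25)) {
  if (!is.numeric(eta) || length(eta) != 1 || eta <= 0)
    stop("base granularity eta must be a single positive number")
  if (length(multipliers) && (is.null(names(multipliers)) ||
                              any(multipliers <= 0)))
    stop("multipliers must be named and positive")
  structure(list(eta = eta, multipliers = multipliers), class = "grn_noise")
}

#' Effective granularity for one node
#'
#' Base `eta` times the node's multiplier (default 1).
#'
#' @param noise a `grn_noise` configuration.
#' @param node node name.
#' @param nodes declared node set used for validation (optional).
#' @return numeric granularity.
#' @export
effective_eta <- function(noise, node, nodes = NULL) {
  stopifnot(inherits(noise, "grn_noise"))
  if (!is.null(nodes) && !node %in% nodes) stop("unknown node: ", node)
  m <- if (node %in% names(noise$multipliers))
    noise$multipliers[[node]] else 1
  noise$eta * m
}

#' One stochastic (Gillespie) simulation of a network model
#'
#' Direct-method stochastic simulation of the rescaled reaction system: per
#' node a production channel (`+eta`, propensity `alpha * SA / eta`) and a
#' decay channel (`-eta`, propensity `delta * [X] / eta`), with the
#' Shea-Ackers activity recomputed after every event.  The initial state is
#' snapped to non-negative multiples of each node's granularity.  The
#' trajectory is recorded on a uniform output grid by last-value
#' carry-forward.  Uses R's Mersenne-Twister stream, so the same `seed`
#' reproduces the run exactly.
#'
#' @param model a `grn_model`.
#' @param initial_state named non-negative concentrations.
#' @param duration hours.
#' @param noise a `grn_noise` configuration.
#' @param seed integer seed (required for reproducibility).
#' @param active_inputs external inputs switched on.
#' @param out_step output grid step in hours (default 0.5).
#' @return a `grn_trajectory` with the seed recorded.
#' @export
gillespie_run <- function(model, initial_state, duration,
                          noise = noise_config(), seed,
                          active_inputs = character(), out_step = 0.5) {
  stopifnot(inherits(model, "grn_model"))
  nodes <- model$topology$nodes
  y0 <- initial_state[nodes]
  if (any(is.na(y0)) || any(y0 < 0))
    stop("initial state must cover all nodes and be non-negative")
  eta <- vapply(nodes, function(n) effective_eta(noise, n), numeric(1))
  cm <- compile_model(model$topology, model$params, active_inputs)
  if (!missing(seed) && !is.null(seed)) set.seed(seed)
  res <- .gillespie_cpp(cm, as.numeric(y0), duration, as.numeric(eta),
                        out_step)
  tr <- new_trajectory(res$times, res$path, nodes, stage = "stochastic",
                       seed = if (missing(seed)) NA_integer_ else seed)
  tr$nevents <- res$nevents
  tr
}

#' Ensemble of independent stochastic runs
#'
#' Defaults mirror the perturbation-scenario setting: 50 independent
#' 14-day (336 h) single-cell simulations.
#'
#' @param model a `grn_model`.
#' @param initial_state named initial concentrations (default: fibroblast
#'   baseline, Ascl1 at 0).
#' @param n_runs number of runs (>= 1).
#' @param duration hours (default 336).
#' @param noise a `grn_noise` configuration.
#' @param seeds integer vector of distinct per-run seeds; by default
#'   derived from `seed` as `seed + 0:(n_runs-1)`.
#' @param seed base seed used when `seeds` is not given.
#' @param active_inputs external inputs switched on.
#' @param out_step output grid step in hours.
#' @return list of `grn_trajectory`, classed `grn_ensemble`.
#' @export
run_ensemble <- function(model, initial_state = NULL, n_runs = 50,
                         duration = 336, noise = noise_config(),
                         seeds = NULL, seed = 1,
                         active_inputs = character(), out_step = 0.5) {
  stopifnot(n_runs >= 1)
  nodes <- model$topology$nodes
  if (is.null(initial_state)) {
    initial_state <- setNames(rep(1, length(nodes)), nodes)
    if ("Ascl1" %in% nodes) initial_state[["Ascl1"]] <- 0
  }
  if (is.null(seeds)) seeds <- seed + seq_len(n_runs) - 1L
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  if (length(seeds) != n_runs) stop("need one seed per run")
  runs <- lapply(seeds, function(s)
    gillespie_run(model, initial_state, duration, noise, seed = s,
                  active_inputs = active_inputs, out_step = out_step))
  structure(runs, class = "grn_ensemble", seeds = seeds)
}

#' @export
print.grn_ensemble <- function(x, ...) {
  cat("GRN stochastic ensemble:", length(x), "runs,",
      max(x[[1]]$times), "h each\n")
  invisible(x)
}

#' @export
as.data.frame.grn_ensemble <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x), function(i) {
    df <- as.data.frame(x[[i]])
    df$run <- i
    df$seed <- x[[i]]$seed
    df
  }))
}

#' Stochastic simulation method for fitted models
#'
#' `simulate()` on a `grn_model` (or `grn_fit`) draws a stochastic ensemble
#' under an optional perturbation scenario.
#'
#' @param object a `grn_model`.
#' @param nsim number of runs.
#' @param seed base seed.
#' @param scenario optional `grn_scenario` applied before simulating.
#' @param duration hours.
#' @param noise a `grn_noise`.
#' @param ... passed to [run_ensemble()].
#' @return a `grn_ensemble`.
#' @export
simulate.grn_model <- function(object, nsim = 50, seed = 1, scenario = NULL,
                               duration = 336, noise = noise_config(), ...) {
  model <- object
  active <- character()
  if (!is.null(scenario)) {
    p <- apply_scenario(object$params, scenario, object$topology)
    attr(p, "scenario") <- NULL
    model <- grn_model(object$topology, p)
    active <- scenario_active_inputs(scenario)
  }
  run_ensemble(model, n_runs = nsim, duration = duration, noise = noise,
               seed = seed, active_inputs = active, ...)
}
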