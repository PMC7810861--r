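#' Genetic-algorithm configuration
#'
#' Defaults follow the fitting procedure used for these models: population
#' 100, uniform crossover (per-gene 0.5 exchange between randomly paired
#' tournament-selected parents), the three-component multiplicative
#' log-normal mutation `m(2/n, 1.01) * m(2/(3n), 1.05) * m(1/(5n), 1.5)`,
#' penalty weights `lambda = mu = 1/20`, single-elite carryover and genes
#' initialised uniformly on (0, 1) unless seed genomes are supplied.
#'
#' @param pop_size population size (>= 2).
#' @param generations number of generations.
#' @param lambda,mu smoothness / stability penalty weights.
#' @param tournament tournament size for parent selection.
#' @param elite number of best individuals carried over unchanged.
#' @param seed RNG seed for the run.
#' @param seed_genomes optional list of raw genomes injected into the
#'   initial population (e.g. parameters from a simpler model).
#' @param step RK4 step in hours used during fitting.
#' @param conversion_init initial-state policy for the conversion stage
#'   (`"observed"` uses the day-3 post-knockdown medians).
#' @param worst_fitness sentinel fitness for diverging genomes.
#' @return list of class `grn_fit_config`.
#' @export
fit_config <- function(pop_size = 100, generations = 150,
                       lambda = 1 / 20, mu = 1 / 20,
                       tournament = 2, elite = 1, seed = 1,
                       seed_genomes = NULL, step = 0.05,
                       conversion_init = "observed",
                       worst_fitness = -1e18) {
  stopifnot(pop_size >= 2, generations >= 0, lambda >= 0, mu >= 0,
            tournament >= 1, elite >= 0)
  structure(list(pop_size = pop_size, generations = generations,
                 lambda = lambda, mu = mu, tournament = tournament,
                 elite = elite, seed = seed, seed_genomes = seed_genomes,
                 step = step, conversion_init = conversion_init,
                 worst_fitness = worst_fitness),
            class = "grn_fit_config")
}

# one m(p, sigma) mixture component applied to a whole genome; sigma is
# the geometric standard deviation of the log-normal factor
mutation_component <- function(n, p, sigma) {
  hit <- runif(n) < p
  f <- rep(1, n)
  f[hit] <- exp(rnorm(sum(hit), 0, log(sigma)))
  f
}

#' Composite multiplicative mutation operator
#'
#' Each gene is multiplied by the product of three independent draws from
#' `m(p, sigma)` mixtures -- with probability `1 - p` the factor is 1,
#' otherwise log-normal with geometric standard deviation `sigma` -- at
#' `(2/n, 1.01)`, `(2/(3n), 1.05)` and `(1/(5n), 1.5)`, `n` being the
#' genome length.  The cascade mixes frequent ~1% tweaks, occasional ~5%
#' moves and rare ~50% jumps; most offspring differ from their parent in
#' only a couple of genes.
#'
#' @param genome positive gene vector.
#' @return mutated genome (always positive).
#' @export
mutate_genome <- function(genome) {
  n <- length(genome)
  genome *
    mutation_component(n, 2 / n, 1.01) *
    mutation_component(n, 2 / (3 * n), 1.05) *
    mutation_component(n, 1 / (5 * n), 1.5)
}

#' Uniform crossover
#'
#' Each gene is exchanged between the two parents independently with
#' probability 1/2.
#' @param a,b parent genomes of equal length.
#' @return list of two offspring.
#' @export
uniform_crossover <- function(a, b) {
  swap <- runif(length(a)) < 0.5
  c1 <- a; c2 <- b
  c1[swap] <- b[swap]
  c2[swap] <- a[swap]
  list(c1, c2)
}

#' Run the genetic algorithm on an arbitrary fitness function
#'
#' Generational GA: tournament selection, uniform crossover, composite
#' multiplicative mutation, elitist carryover of the best individual(s).
#' The best-ever fitness is non-decreasing by construction.
#'
#' @param fitness_fn function(genome) -> scalar fitness (higher better).
#' @param n_genes genome length.
#' @param config a [fit_config()].
#' @return list with `best_genome`, `best_fitness` and `trace` (best-ever
#'   fitness per generation, element 1 = initial population).
#' @export
ga_optimize <- function(fitness_fn, n_genes, config = fit_config()) {
  set.seed(config$seed)
  np <- config$pop_size
  pop <- lapply(seq_len(np), function(i) runif(n_genes))
  if (!is.null(config$seed_genomes)) {
    sg <- config$seed_genomes
    if (!is.list(sg)) sg <- list(sg)
    for (i in seq_along(sg)) pop[[i]] <- as.numeric(sg[[i]])
  }
  fit <- vapply(pop, fitness_fn, numeric(1))
  best_i <- which.max(fit)
  best_genome <- pop[[best_i]]
  best_fitness <- fit[best_i]
  trace <- numeric(config$generations + 1)
  trace[1] <- best_fitness

  tournament_pick <- function() {
    cand <- sample.int(np, config$tournament, replace = TRUE)
    cand[which.max(fit[cand])]
  }

  for (g in seq_len(config$generations)) {
    ord <- order(fit, decreasing = TRUE)
    newpop <- pop[ord[seq_len(config$elite)]]
    while (length(newpop) < np) {
      pa <- pop[[tournament_pick()]]
      pb <- pop[[tournament_pick()]]
      kids <- uniform_crossover(pa, pb)
      newpop <- c(newpop, lapply(kids, mutate_genome))
    }
    pop <- newpop[seq_len(np)]
    fit <- vapply(pop, fitness_fn, numeric(1))
    gi <- which.max(fit)
    if (fit[gi] > best_fitness) {
      best_fitness <- fit[gi]
      best_genome <- pop[[gi]]
    }
    trace[g + 1] <- best_fitness
  }
  list(best_genome = best_genome, best_fitness = best_fitness,
       trace = trace)
}

#' Fit a network topology to time-series data by genetic algorithm
#'
#' Wraps [ga_optimize()] around the three-term objective (SSE at the six
#' data anchors, smoothness of the first five conversion days, fibroblast
#' stability).
#'
#' @param topology a `grn_topology`.
#' @param dataset a `grn_dataset`.
#' @param protocol fitting protocol; conversion stage >= 120 h.
#' @param config a [fit_config()].
#' @return list with `best_genome`, `best_params`, `best_fitness`, `trace`.
#' @export
run_ga <- function(topology, dataset,
                   protocol = canonical_protocol(conversion_hours = 120),
                   config = fit_config()) {
  obs <- precompute_objective(topology, dataset, protocol, config)
  res <- ga_optimize(obs$fitness_fn, length(param_names(topology)), config)
  res$best_params <- decode_genome(res$best_genome, topology)
  res
}

# Close over everything that does not change between genomes so the GA
# inner loop avoids repeated data-frame work.
precompute_objective <- function(topology, dataset, protocol, config) {
  nodes <- topology$nodes
  init <- initial_policy(nodes, conversion = config$conversion_init)
  y_fib <- init$fibroblast[nodes]
  y_conv <- if (identical(config$conversion_init, "observed") &&
                !is.null(dataset))
    observed_state(dataset, "rest_kd", nodes) else NULL
  med <- dataset_medians(dataset)
  binding <- dataset_binding(dataset)
  obs_kd <- vapply(nodes, function(nd)
    anchor_median(med, binding[[nd]], "rest_kd", NULL), numeric(1))
  obs_conv <- sapply(nodes, function(nd)
    vapply(SSE_CONV_ANCHORS, function(t)
      anchor_median(med, binding[[nd]], "conversion", t), numeric(1)))
  durs <- setNames(protocol$duration, protocol$name)
  step <- config$step
  # thinned recording: conversion rows every 8 h so the SSE anchors stay
  # on recorded rows; the penalty quadratures are accumulated inside the
  # kernel on the full-resolution grid
  conv_rec <- as.integer(round(8 / step))
  conv_idx <- as.integer(round(SSE_CONV_ANCHORS / 8)) + 1L
  ends_only <- as.integer(round(max(durs) / step))

  fitness_fn <- function(genome) {
    params <- tryCatch(decode_genome(genome, topology),
                       error = function(e) NULL)
    if (is.null(params)) return(config$worst_fitness)
    out <- tryCatch({
      fib <- .rk4_cpp(compile_model(topology, params, character()),
                      as.numeric(y_fib), durs[["fibroblast"]], step,
                      ends_only)
      kd <- .rk4_cpp(compile_model(topology, params, "RESTi"),
                     as.numeric(y_fib), durs[["rest_kd"]], step,
                     ends_only)
      y0c <- if (is.null(y_conv)) kd$path[nrow(kd$path), ] else
        as.numeric(y_conv)
      cm_conv <- compile_model(topology, params, c("RESTi", "vAscl1"))
      if (abs(durs[["conversion"]] - 120) < 1e-9) {
        cv <- .rk4_cpp(cm_conv, y0c, 120, step, conv_rec)
        r1 <- config$lambda * sum(cv$d2int)
        cpath <- cv$path[conv_idx, , drop = FALSE]
      } else {
        # conversion stage longer than the fitted 5-day window: record
        # densely and apply the smoothness term to the window only
        cv <- .rk4_cpp(cm_conv, y0c, durs[["conversion"]], step, 1L)
        r1 <- smoothness_penalty(
          new_trajectory(cv$times, cv$path, nodes, "conversion"),
          config$lambda)
        cpath <- cv$path[round(SSE_CONV_ANCHORS / step) + 1L, ,
                         drop = FALSE]
      }
      sse <- sum((kd$path[nrow(kd$path), ] - obs_kd)^2) +
        sum((cpath - obs_conv)^2)
      -(sse + r1 + config$mu * sum(fib$absint))
    }, error = function(e) NA_real_)
    if (!is.finite(out)) config$worst_fitness else out
  }
  list(fitness_fn = fitness_fn)
}
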