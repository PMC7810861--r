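#' Fit a Shea-Ackers network model to conversion time-series data
#'
#' The central fitting function: estimates all rate, interaction and
#' background constants of a network topology from replicated expression
#' time series by maximising `-(SSE + R1 + R2)` with a real-valued genetic
#' algorithm, where SSE compares simulated curves with the observed
#' per-factor medians at the six data anchors, `R1` penalises curvature of
#' the first five conversion days and `R2` penalises any fibroblast-stage
#' drift.
#'
#' @param dataset a `grn_dataset` (see [generate_dataset()] /
#'   [load_dataset()]).
#' @param topology a `grn_topology` (default: the literature network).
#' @param protocol fitting protocol; the conversion stage must cover the
#'   five fitted days (120 h).
#' @param config a [fit_config()].
#' @return an object of class `c("grn_fit", "grn_model")` with components
#'   `topology`, `params`, `dataset`, `protocol`, `config`, `trace`,
#'   `fitness`.
#' @seealso [predict.grn_fit()], [residuals.grn_fit()],
#'   [simulate.grn_model()], [scenario_table()]
#' @export
grn_fit <- function(dataset, topology = literature_topology(),
                    protocol = canonical_protocol(conversion_hours = 120),
                    config = fit_config()) {
  stopifnot(inherits(dataset, "grn_dataset"))
  res <- run_ga(topology, dataset, protocol, config)
  structure(list(topology = topology, params = res$best_params,
                 dataset = dataset, protocol = protocol, config = config,
                 trace = res$trace, fitness = res$best_fitness,
                 genome = res$best_genome),
            class = c("grn_fit", "grn_model"))
}

#' @export
print.grn_fit <- function(x, ...) {
  cat("GRN model fit (genetic algorithm)\n")
  cat("  topology:", length(x$topology$nodes), "nodes,",
      nrow(x$topology$edges), "edges\n")
  cat("  free parameters:", length(x$params), "\n")
  cat("  generations:", length(x$trace) - 1,
      " population:", x$config$pop_size, "\n")
  cat("  best fitness:", format(x$fitness, digits = 6), "\n")
  invisible(x)
}

#' @export
summary.grn_fit <- function(object, ...) {
  run <- predict(object)
  model <- grn_model(object$topology, object$params)
  terms <- c(
    sse = sse_term(run, object$dataset),
    smoothness = smoothness_penalty(run$conversion, object$config$lambda),
    stability = stability_penalty(run$fibroblast, model, object$config$mu))
  out <- list(fit = object, terms = terms,
              fitness = -sum(terms),
              residuals = residuals(object))
  class(out) <- "summary.grn_fit"
  out
}

#' @export
print.summary.grn_fit <- function(x, ...) {
  print(x$fit)
  cat("  objective decomposition (lower is better):\n")
  for (nm in names(x$terms))
    cat(sprintf("    %-10s %.6g\n", nm, x$terms[[nm]]))
  cat("  anchor residuals (simulated - observed median):\n")
  print(x$residuals, digits = 3)
  invisible(x)
}

#' Simulated trajectories of a fitted model
#'
#' Re-runs the fitted protocol (or any other) and returns the per-stage
#' trajectories.
#' @param object a `grn_fit`.
#' @param protocol protocol to simulate (default: the fitting protocol).
#' @param step RK4 step in hours.
#' @param ... unused.
#' @return a `grn_protocol_run`.
#' @export
predict.grn_fit <- function(object, protocol = object$protocol,
                            step = object$config$step, ...) {
  model <- grn_model(object$topology, object$params)
  run_protocol(model, protocol,
               init = initial_policy(object$topology$nodes,
                                     object$config$conversion_init),
               dataset = object$dataset, step = step)
}

#' @export
predict.grn_model <- function(object, protocol = canonical_protocol(),
                              dataset = NULL, step = 0.05, ...) {
  run_protocol(object, protocol, dataset = dataset, step = step)
}

#' Residuals at the fitted data anchors
#'
#' Simulated minus observed median at the REST-knockdown endpoint and the
#' five conversion anchors, per node.
#' @param object a `grn_fit`.
#' @param ... unused.
#' @return matrix (anchors x nodes).
#' @export
residuals.grn_fit <- function(object, ...) {
  run <- predict(object)
  med <- dataset_medians(object$dataset)
  binding <- dataset_binding(object$dataset)
  nodes <- names(binding)
  anchors <- c("rest_kd 72 h", paste0("conversion ", SSE_CONV_ANCHORS, " h"))
  out <- matrix(NA_real_, length(anchors), length(nodes),
                dimnames = list(anchors, nodes))
  kd_end <- trajectory_at(run$rest_kd, max(run$rest_kd$times))
  for (node in nodes) {
    fac <- binding[[node]]
    out[1, node] <- kd_end[[node]] - anchor_median(med, fac, "rest_kd", NULL)
    for (j in seq_along(SSE_CONV_ANCHORS)) {
      t <- SSE_CONV_ANCHORS[j]
      out[j + 1, node] <- trajectory_at(run$conversion, t)[[node]] -
        anchor_median(med, fac, "conversion", t)
    }
  }
  out
}

#' @export
fitted.grn_fit <- function(object, ...) {
  r <- residuals(object)
  med <- dataset_medians(object$dataset)
  binding <- dataset_binding(object$dataset)
  obs <- r
  for (node in colnames(r)) {
    fac <- binding[[node]]
    obs[1, node] <- anchor_median(med, fac, "rest_kd", NULL)
    for (j in seq_along(SSE_CONV_ANCHORS))
      obs[j + 1, node] <- anchor_median(med, fac, "conversion",
                                        SSE_CONV_ANCHORS[j])
  }
  r + obs
}

#' Plot a fitted model against its data
#'
#' Three-phase trajectory panels with the observed per-factor medians
#' overplotted as points on the knockdown and conversion stages.
#'
#' @param x a `grn_fit`.
#' @param ... passed through to [plot.grn_protocol_run()].
#' @export
plot.grn_fit <- function(x, ...) {
  run <- predict(x)
  runs <- unclass(run)
  nodes <- x$topology$nodes
  med <- dataset_medians(x$dataset)
  binding <- dataset_binding(x$dataset)
  ymax <- max(vapply(runs, function(tr) max(tr$states), numeric(1)),
              med$median[med$factor %in% unlist(binding)])
  old <- graphics::par(mfrow = c(1, length(runs)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (stage in names(runs)) {
    tr <- runs[[stage]]
    graphics::matplot(tr$times, tr$states, type = "l", lty = 1,
                      ylim = c(0, ymax), xlab = "time (h)",
                      ylab = "relative mRNA", main = stage, ...)
    for (ni in seq_along(nodes)) {
      fac <- binding[[nodes[ni]]]
      if (is.null(fac)) next
      pts <- med[med$factor == fac & med$stage == stage, ]
      if (nrow(pts))
        graphics::points(pts$time_h, pts$median, col = ni, pch = 19)
    }
  }
  graphics::legend("topright", legend = nodes, lty = 1,
                   col = seq_along(nodes), cex = 0.8)
  invisible(x)
}
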