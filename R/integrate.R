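new_trajectory <- function(times, path, nodes, stage = NA_character_,
                           clamped = 0L, seed = NA_integer_) {
  colnames(path) <- nodes
  structure(list(times = times, states = path, stage = stage,
                 clamped = clamped, seed = seed),
            class = "grn_trajectory")
}

#' @export
print.grn_trajectory <- function(x, ...) {
  cat("GRN trajectory: stage", x$stage, "-", length(x$times), "points over",
      max(x$times), "h,", ncol(x$states), "nodes\n")
  invisible(x)
}

#' Tidy view of a trajectory
#'
#' @param x a `grn_trajectory`.
#' @param ... unused.
#' @return data.frame with columns `time_h`, `stage`, `node`, `value`.
#' @export
as.data.frame.grn_trajectory <- function(x, ...) {
  nodes <- colnames(x$states)
  data.frame(time_h = rep(x$times, times = length(nodes)),
             stage = x$stage,
             node = rep(nodes, each = length(x$times)),
             value = as.vector(x$states),
             stringsAsFactors = FALSE)
}

trajectory_at <- function(traj, time_h) {
  i <- match(TRUE, abs(traj$times - time_h) < 1e-9)
  if (is.na(i)) stop("time ", time_h, " h is not on the trajectory grid")
  traj$states[i, ]
}

#' Fixed-step fourth-order Runge-Kutta for an arbitrary RHS
#'
#' Reference R implementation used for arbitrary right-hand sides (the
#' production path for network models is the compiled kernel behind
#' [integrate_stage()]).  A final partial step is taken when `duration` is
#' not a multiple of `step`; the returned grid includes `t = 0` and
#' `t = duration`.
#'
#' @param rhs function(state) -> derivative vector.
#' @param y0 initial state (named or not).
#' @param duration hours, `>= 0`.
#' @param step step size in hours (default 0.05).
#' @return list with `times` and `states` (matrix, one row per grid point).
#' @export
rk4_integrate <- function(rhs, y0, duration, step = 0.05) {
  stopifnot(duration >= 0, step > 0)
  nfull <- floor(duration / step + 1e-9)
  rem <- duration - nfull * step
  if (rem < 1e-9) rem <- 0
  steps <- c(rep(step, nfull), if (rem > 0) rem)
  states <- matrix(0, nrow = length(steps) + 1, ncol = length(y0))
  states[1, ] <- y0
  y <- y0
  for (s in seq_along(steps)) {
    h <- steps[s]
    k1 <- rhs(y)
    k2 <- rhs(y + h / 2 * k1)
    k3 <- rhs(y + h / 2 * k2)
    k4 <- rhs(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(y)))
      stop("integration blew up at t = ", sum(steps[1:s]), " h")
    states[s + 1, ] <- y
  }
  list(times = cumsum(c(0, steps)), states = states)
}

#' Integrate one protocol stage of a network model
#'
#' Classic RK4 at a fixed step (default 0.05 h, chosen so every data-anchor
#' time lands exactly on a grid point).  Concentrations are clamped at zero
#' and the number of clamped values is recorded on the trajectory.
#'
#' @param model a `grn_model`.
#' @param initial_state named non-negative concentrations.
#' @param duration hours.
#' @param step grid step in hours.
#' @param active_inputs external inputs switched on during the stage.
#' @param stage stage label recorded on the trajectory.
#' @return a `grn_trajectory`.
#' @export
integrate_stage <- function(model, initial_state, duration, step = 0.05,
                            active_inputs = character(),
                            stage = NA_character_) {
  stopifnot(inherits(model, "grn_model"))
  nodes <- model$topology$nodes
  y0 <- initial_state[nodes]
  if (any(is.na(y0)) || any(y0 < 0))
    stop("initial state must cover all nodes and be non-negative")
  cm <- compile_model(model$topology, model$params, active_inputs)
  res <- .rk4_cpp(cm, as.numeric(y0), duration, step)
  new_trajectory(res$times, res$path, nodes, stage = stage,
                 clamped = res$clamped)
}

#' Simulate a full multi-stage protocol
#'
#' Integrates the model once per protocol stage with stage-appropriate
#' external inputs, yielding the fibroblast, REST-knockdown and conversion
#' curves.  Initial states follow the supplied policy: an explicit named
#' vector, `"carry"` (final state of the previous stage) or `"observed"`
#' (stage-anchor medians of `dataset`, mapped through its node binding).
#'
#' @param model a `grn_model`.
#' @param protocol a `grn_protocol`.
#' @param init per-stage initial-state policy, see [initial_policy()].
#' @param dataset optional `grn_dataset` backing `"observed"` policies.
#' @param step RK4 step in hours.
#' @return named list of `grn_trajectory` objects, classed
#'   `grn_protocol_run`.
#' @export
run_protocol <- function(model, protocol = canonical_protocol(),
                         init = initial_policy(model$topology$nodes),
                         dataset = NULL, step = 0.05) {
  stopifnot(inherits(model, "grn_model"), inherits(protocol, "grn_protocol"))
  nodes <- model$topology$nodes
  out <- list()
  prev <- NULL
  for (i in seq_len(nrow(protocol))) {
    stage <- protocol$name[i]
    pol <- if (!is.null(init[[stage]])) init[[stage]] else "carry"
    y0 <- resolve_initial_state(pol, stage, prev, dataset, nodes)
    tr <- tryCatch(
      integrate_stage(model, y0, protocol$duration[i], step = step,
                      active_inputs = protocol$inputs[[i]], stage = stage),
      error = function(e) stop("stage '", stage, "': ", conditionMessage(e),
                               call. = FALSE))
    out[[stage]] <- tr
    prev <- tr
  }
  structure(out, class = "grn_protocol_run")
}

resolve_initial_state <- function(policy, stage, prev, dataset, nodes) {
  if (is.numeric(policy)) {
    y0 <- policy[nodes]
    if (any(is.na(y0))) stop("explicit initial state must name all nodes")
    return(y0)
  }
  if (identical(policy, "carry")) {
    if (is.null(prev)) {
      y0 <- setNames(rep(1, length(nodes)), nodes)
      if ("Ascl1" %in% nodes) y0[["Ascl1"]] <- 0
      return(y0)
    }
    return(prev$states[nrow(prev$states), ])
  }
  if (identical(policy, "observed")) {
    if (is.null(dataset)) {
      # without data, fall back to carrying the previous stage forward
      return(resolve_initial_state("carry", stage, prev, dataset, nodes))
    }
    anchor_stage <- if (stage == "conversion") "rest_kd" else "fibroblast"
    return(observed_state(dataset, anchor_stage, nodes))
  }
  stop("unknown initial-state policy for stage '", stage, "'")
}

#' @export
as.data.frame.grn_protocol_run <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), as.data.frame))
}

#' @export
print.grn_protocol_run <- function(x, ...) {
  cat("GRN protocol run:",
      paste(sprintf("%s (%g h)", names(x),
                    vapply(x, function(t) max(t$times), numeric(1))),
            collapse = " -> "), "\n")
  invisible(x)
}

#' Plot protocol trajectories in the three-phase layout
#'
#' One panel per stage, one curve per node, on a shared concentration
#' scale (relative to fibroblast baseline = 1).
#'
#' @param x a `grn_protocol_run`.
#' @param nodes nodes to draw (default all).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.grn_protocol_run <- function(x, nodes = NULL, ...) {
  runs <- unclass(x)
  if (is.null(nodes)) nodes <- colnames(runs[[1]]$states)
  ymax <- max(vapply(runs, function(tr) max(tr$states[, nodes]), numeric(1)))
  old <- graphics::par(mfrow = c(1, length(runs)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (stage in names(runs)) {
    tr <- runs[[stage]]
    graphics::matplot(tr$times, tr$states[, nodes, drop = FALSE],
                      type = "l", lty = 1, ylim = c(0, ymax),
                      xlab = "time (h)", ylab = "relative mRNA",
                      main = stage, ...)
  }
  graphics::legend("topright", legend = nodes, lty = 1,
                   col = seq_along(nodes), cex = 0.8)
  invisible(x)
}

#' Export trajectories as tidy CSV
#'
#' Columns: `time_h`, `stage`, `node`, `value`.
#' @param x a `grn_trajectory` or `grn_protocol_run`.
#' @param path output file.
#' @export
write_trajectory_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
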