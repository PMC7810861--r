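#' Genome-to-Hill-exponent transform
#'
#' Raw (unbounded positive) genes are mapped to Hill cooperativity
#' exponents via `h = 4 h' / (1 + h')`: strictly increasing, `h(1) = 2`,
#' bounded above by 4.
#'
#' @param raw positive raw gene value(s).
#' @return Hill exponent(s) in (0, 4).
#' @export
decode_hill <- function(raw) {
  if (any(!is.finite(raw)) || any(raw <= 0))
    stop("raw Hill gene values must be strictly positive")
  4 * raw / (1 + raw)
}

#' Inverse of the Hill transform
#' @param h Hill exponent in (0, 4).
#' @return raw gene value.
#' @export
encode_hill <- function(h) {
  if (any(h <= 0) || any(h >= 4)) stop("h must lie strictly in (0, 4)")
  h / (4 - h)
}

#' Decode a genome into a parameter set
#'
#' A genome is a vector of positive reals in the canonical
#' [param_names()] order.  Hill genes (`h_*`) are stored raw and decoded
#' through [decode_hill()]; all other genes are used directly.
#'
#' @param genome numeric vector of positive reals.
#' @param topology a `grn_topology`.
#' @return a `grn_params` vector.
#' @export
decode_genome <- function(genome, topology) {
  nm <- param_names(topology)
  if (length(genome) != length(nm))
    stop("genome length ", length(genome), " != ", length(nm),
         " free parameters")
  p <- setNames(as.numeric(genome), nm)
  hmask <- startsWith(nm, "h_")
  p[hmask] <- decode_hill(p[hmask])
  grn_params(p, topology)
}

#' Encode a parameter set as a genome
#' @param params a parameter vector matching `topology`.
#' @param topology a `grn_topology`.
#' @return raw genome vector.
#' @export
encode_genome <- function(params, topology) {
  nm <- param_names(topology)
  g <- as.numeric(grn_params(params, topology))
  hmask <- startsWith(nm, "h_")
  g[hmask] <- encode_hill(g[hmask])
  setNames(g, nm)
}

# -- objective terms ---------------------------------------------------------

# anchor times (hours into the conversion stage) entering the error term
SSE_CONV_ANCHORS <- c(8, 24, 48, 72, 120)

#' Sum-of-squared-errors term of the fitting objective
#'
#' Compares simulated curves to the per-factor medians of the replicate
#' observations at six time points: the REST-knockdown endpoint (72 h) and
#' the conversion anchors 8 h, 1, 2, 3 and 5 days.  The fibroblast stage
#' contributes nothing here (it is covered by the stability penalty).
#'
#' @param run a `grn_protocol_run` with `rest_kd` and `conversion` stages.
#' @param dataset a `grn_dataset`.
#' @param binding named map node -> dataset factor (default from dataset).
#' @return non-negative sum of squared deviations.
#' @export
sse_term <- function(run, dataset, binding = NULL) {
  if (is.null(binding)) binding <- dataset_binding(dataset)
  med <- dataset_medians(dataset)
  nodes <- names(binding)
  sse <- 0
  kd_end <- trajectory_at(run$rest_kd, max(run$rest_kd$times))
  for (node in nodes) {
    fac <- binding[[node]]
    obs_kd <- anchor_median(med, fac, "rest_kd", NULL)
    sse <- sse + (kd_end[[node]] - obs_kd)^2
    for (t in SSE_CONV_ANCHORS) {
      obs <- anchor_median(med, fac, "conversion", t)
      sim <- trajectory_at(run$conversion, t)[[node]]
      sse <- sse + (sim - obs)^2
    }
  }
  sse
}

anchor_median <- function(med, fac, stage, time_h) {
  row <- med$factor == fac & med$stage == stage
  if (!is.null(time_h)) row <- row & abs(med$time_h - time_h) < 1e-9
  v <- med$median[row]
  if (length(v) != 1)
    stop("missing data anchor: factor ", fac, ", stage ", stage,
         if (!is.null(time_h)) paste0(", t = ", time_h, " h"))
  v
}

#' Smoothness regularisation of the conversion curve
#'
#' \eqn{R_1 = \lambda \sum_X \int_0^{5d} |d^2 f_X / dt^2| \, dt}, with the
#' second derivative taken by central finite differences on the integration
#' grid (one-sided at the ends) and the integral by the composite trapezoid
#' rule.  Penalises the erratic oscillation a pure SSE fit tends to adopt.
#'
#' @param conv_traj conversion-stage `grn_trajectory` covering >= 120 h.
#' @param lambda penalty weight (default 1/20).
#' @param horizon integration window in hours (default 120 = 5 days).
#' @return non-negative penalty.
#' @export
smoothness_penalty <- function(conv_traj, lambda = 1 / 20, horizon = 120) {
  if (lambda == 0) return(0)
  keep <- conv_traj$times <= horizon + 1e-9
  if (max(conv_traj$times) < horizon - 1e-9)
    stop("conversion trajectory shorter than the ", horizon, " h window")
  x <- conv_traj$states[keep, , drop = FALSE]
  tt <- conv_traj$times[keep]
  dt <- tt[2] - tt[1]
  total <- 0
  for (j in seq_len(ncol(x))) {
    d2 <- diff(x[, j], differences = 2) / dt^2
    d2 <- abs(c(d2[1], d2, d2[length(d2)]))   # replicate at the endpoints
    total <- total + sum((d2[-1] + d2[-length(d2)]) / 2) * dt
  }
  lambda * total
}

#' Fibroblast stability penalty
#'
#' \eqn{R_2 = \mu \sum_X \int_0^{3d} |d f_X / dt| \, dt} over the
#' fibroblast stage with both external inputs off: fibroblasts must not
#' spontaneously convert, so any drift from the initial state is punished.
#' The derivative is the model right-hand side evaluated along the
#' trajectory; quadrature is trapezoidal.
#'
#' @param fibro_traj fibroblast-stage `grn_trajectory`.
#' @param model the `grn_model` that produced it.
#' @param mu penalty weight (default 1/20).
#' @return non-negative penalty.
#' @export
stability_penalty <- function(fibro_traj, model, mu = 1 / 20) {
  if (mu == 0) return(0)
  if (!identical(fibro_traj$stage, "fibroblast"))
    stop("stability penalty is defined on the fibroblast stage ",
         "(external inputs off); got stage '", fibro_traj$stage, "'")
  dmat <- rhs_along_path(model, fibro_traj$states, character())
  dt <- fibro_traj$times[2] - fibro_traj$times[1]
  a <- abs(dmat)
  mu * sum((a[-1, , drop = FALSE] + a[-nrow(a), , drop = FALSE]) / 2 * dt)
}

# vectorised RHS over the rows of a state matrix
rhs_along_path <- function(model, states, active_inputs = character()) {
  topo <- model$topology
  params <- model$params
  nodes <- topo$nodes
  nt <- nrow(states)
  sact <- matrix(0, nt, length(nodes), dimnames = list(NULL, nodes))
  sinh <- sact
  e <- topo$edges
  for (i in seq_len(nrow(e))) {
    key <- edge_key(e$source[i], e$target[i])
    term <- (states[, e$source[i]] / params[[paste0("k_", key)]]) ^
      params[[paste0("h_", key)]]
    term[states[, e$source[i]] <= 0] <- 0
    if (e$sign[i] == ACTIVATION) sact[, e$target[i]] <- sact[, e$target[i]] + term
    else sinh[, e$target[i]] <- sinh[, e$target[i]] + term
  }
  out <- matrix(0, nt, length(nodes), dimnames = list(NULL, nodes))
  for (node in nodes) {
    num0 <- if (node %in% topo$beta_nodes)
      params[[paste0("beta_", node)]] else 0
    den0 <- 0
    inp <- topo$inputs
    inp <- inp[inp$target == node & inp$input %in% active_inputs, ,
               drop = FALSE]
    for (i in seq_len(nrow(inp))) {
      b <- params[[paste0("beta_", inp$input[i])]]
      if (inp$sign[i] == ACTIVATION) num0 <- num0 + b else den0 <- den0 + b
    }
    eq4 <- !(node %in% topo$beta_nodes) &&
      !any(e$target == node & e$sign == ACTIVATION) &&
      !any(topo$inputs$target == node & topo$inputs$sign == ACTIVATION)
    sa <- if (eq4) 1 / (1 + sinh[, node] + den0)
          else (num0 + sact[, node]) /
               (1 + num0 + sact[, node] + sinh[, node] + den0)
    out[, node] <- params[[paste0("alpha_", node)]] * sa -
      params[[paste0("delta_", node)]] * states[, node]
  }
  out
}

#' Fitness of a genome (higher is better)
#'
#' Decodes the genome, simulates the three-stage protocol and returns
#' `-(SSE + R1 + R2)`.  A genome whose simulation diverges receives a
#' large negative sentinel so the genetic algorithm can keep running.
#'
#' @param genome raw positive gene vector.
#' @param topology a `grn_topology`.
#' @param dataset a `grn_dataset`.
#' @param protocol fitting protocol (conversion stage >= 120 h).
#' @param config a [fit_config()].
#' @return scalar fitness.
#' @export
ga_fitness <- function(genome, topology, dataset,
                       protocol = canonical_protocol(conversion_hours = 120),
                       config = fit_config()) {
  params <- tryCatch(decode_genome(genome, topology),
                     error = function(e) NULL)
  if (is.null(params)) return(config$worst_fitness)
  model <- grn_model(topology, params)
  run <- tryCatch(
    run_protocol(model, protocol,
                 init = initial_policy(topology$nodes,
                                       conversion = config$conversion_init),
                 dataset = dataset, step = config$step),
    error = function(e) NULL)
  if (is.null(run)) return(config$worst_fitness)
  val <- tryCatch(
    -(sse_term(run, dataset) +
        smoothness_penalty(run$conversion, config$lambda) +
        stability_penalty(run$fibroblast, model, config$mu)),
    error = function(e) NA_real_)
  if (!is.finite(val)) config$worst_fitness else val
}
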