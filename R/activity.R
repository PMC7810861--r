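#' Shea-Ackers regulatory activity of one node
#'
#' Thermodynamic promoter-occupancy activity in `[0, 1)`: the ratio of
#' activator binding terms to all binding-state terms,
#' \deqn{SA(X) = \frac{\beta_X + \sum_{T \in act'} ([T]/k_{T,X})^{h_{T,X}}}
#'   {1 + \beta_X + \sum_{act'} ([T]/k)^h + \sum_{inh'} ([T]/k)^h},}
#' where constitutive regulation is folded into the background \eqn{\beta_X}
#' and active external inputs contribute their strength (`beta_vAscl1` to
#' the numerator of an activated node, `beta_RESTi` to the denominator of
#' an inhibited node).  Nodes with no non-constitutive activator and no
#' background use the reduced form \eqn{1 / (1 + \sum_{inh'} ([T]/k)^h)}.
#'
#' @param node node name.
#' @param state named non-negative concentrations for all nodes.
#' @param topology a `grn_topology`.
#' @param params parameter vector for the topology.
#' @param active_inputs character subset of the topology's external inputs
#'   that are currently switched on.
#' @return activity value.
#' @export
shea_ackers_activity <- function(node, state, topology, params,
                                 active_inputs = character()) {
  if (!node %in% topology$nodes) stop("unknown node: ", node)
  state <- state[topology$nodes]
  if (any(is.na(state)) || any(state < 0))
    stop("concentrations must be named, complete and non-negative")
  parts <- activity_terms(node, state, topology, params, active_inputs)
  if (parts$eq4) {
    1 / (1 + parts$sum_inh)
  } else {
    num <- parts$sum_act
    num / (1 + num + parts$sum_inh)
  }
}

# Numerator/denominator building blocks of SA(X), shared with the
# dissection analysis.  sum_act includes beta_X and active activating
# inputs; sum_inh includes active inhibiting inputs.
activity_terms <- function(node, state, topology, params,
                           active_inputs = character()) {
  acts <- topology_edges(topology, target = node, sign = ACTIVATION)
  inhs <- topology_edges(topology, target = node, sign = INHIBITION)
  term <- function(e) {
    key <- edge_key(e$source, e$target)
    conc <- unname(state[e$source])
    k <- params[[paste0("k_", key)]]
    h <- params[[paste0("h_", key)]]
    ifelse(conc <= 0, 0, (conc / k)^h)
  }
  act_split <- if (nrow(acts)) setNames(vapply(seq_len(nrow(acts)),
    function(i) term(acts[i, ]), numeric(1)), acts$source) else numeric()
  inh_split <- if (nrow(inhs)) setNames(vapply(seq_len(nrow(inhs)),
    function(i) term(inhs[i, ]), numeric(1)), inhs$source) else numeric()

  has_beta <- node %in% topology$beta_nodes
  if (has_beta)
    act_split <- c(constitutive = params[[paste0("beta_", node)]], act_split)

  inp <- topology$inputs
  inp <- inp[inp$target == node & inp$input %in% active_inputs, , drop = FALSE]
  if (nrow(inp)) {
    for (i in seq_len(nrow(inp))) {
      b <- params[[paste0("beta_", inp$input[i])]]
      if (inp$sign[i] == ACTIVATION)
        act_split <- c(act_split, setNames(b, inp$input[i]))
      else
        inh_split <- c(inh_split, setNames(b, inp$input[i]))
    }
  }
  # a node is in the reduced (no-background) form when it has no
  # non-constitutive activator and carries no beta flag
  eq4 <- !has_beta && nrow(acts) == 0 &&
    !any(topology$inputs$target == node &
           topology$inputs$sign == ACTIVATION)
  list(sum_act = sum(act_split), sum_inh = sum(inh_split),
       act_split = act_split, inh_split = inh_split, eq4 = eq4)
}

#' ODE right-hand side of a Shea-Ackers network model
#'
#' Each node follows \eqn{d[X]/dt = \alpha_X SA(X) - \delta_X [X]}: promoter
#' activity scaled by a transcription coefficient, minus first-order decay
#' (half-life \eqn{\ln 2 / \delta_X}).
#'
#' @inheritParams shea_ackers_activity
#' @return a function mapping a named state vector to named derivatives.
#' @export
ode_rhs <- function(topology, params, active_inputs = character()) {
  nodes <- topology$nodes
  alpha <- vapply(nodes, function(n) params[[paste0("alpha_", n)]], numeric(1))
  delta <- vapply(nodes, function(n) params[[paste0("delta_", n)]], numeric(1))
  function(state) {
    sa <- vapply(nodes, function(n)
      shea_ackers_activity(n, state, topology, params, active_inputs),
      numeric(1))
    setNames(alpha * sa - delta * state[nodes], nodes)
  }
}

#' Stage-effective parameters
#'
#' External-input strengths are toggled per protocol stage: in the
#' fibroblast stage both `beta_RESTi` and `beta_vAscl1` are zero, during
#' REST knockdown only `beta_RESTi` acts, and during conversion both act.
#' For use with machinery that keeps all inputs formally "active", this
#' returns a copy of the parameters with the inactive input strengths set
#' to zero (numerically equivalent to deactivating the inputs).
#'
#' @param params parameter vector.
#' @param stage one of `"fibroblast"`, `"rest_kd"`, `"conversion"`.
#' @return modified parameter vector (same class as input).
#' @export
stage_effective_params <- function(params, stage) {
  off <- switch(stage,
    fibroblast = c("beta_RESTi", "beta_vAscl1"),
    rest_kd    = "beta_vAscl1",
    conversion = character(),
    stop("unknown stage: ", stage))
  out <- unclass(params)
  out[intersect(off, names(out))] <- 0
  class(out) <- class(params)
  out
}

stage_active_inputs <- function(stage) {
  switch(stage,
    fibroblast = character(),
    rest_kd    = "RESTi",
    conversion = c("RESTi", "vAscl1"),
    stop("unknown stage: ", stage))
}
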