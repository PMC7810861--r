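#' Bundle a topology and a parameter set into a model object
#'
#' @param topology a `grn_topology`.
#' @param params named parameter vector (validated via [grn_params()]).
#' @return object of class `grn_model` with elements `topology`, `params`.
#' @export
grn_model <- function(topology, params) {
  params <- grn_params(params, topology)
  structure(list(topology = topology, params = params),
            class = "grn_model")
}

#' @export
print.grn_model <- function(x, ...) {
  cat("Shea-Ackers GRN model\n")
  print(x$topology)
  cat("  parameters:", length(x$params), "\n")
  invisible(x)
}

#' @export
coef.grn_model <- function(object, ...) object$params

# Flatten (topology, params, active inputs) into the numeric arrays the
# C++ kernels consume.  External-input strengths are folded into per-node
# constants: active activating inputs into num0, inhibiting into den0.
compile_model <- function(topology, params, active_inputs = character()) {
  nodes <- topology$nodes
  n <- length(nodes)
  idx <- setNames(seq_len(n) - 1L, nodes)
  alpha <- as.numeric(params[paste0("alpha_", nodes)])
  delta <- as.numeric(params[paste0("delta_", nodes)])
  num0 <- den0 <- numeric(n)
  eq4 <- integer(n)
  for (i in seq_len(n)) {
    node <- nodes[i]
    if (node %in% topology$beta_nodes)
      num0[i] <- params[[paste0("beta_", node)]]
    inp <- topology$inputs
    inp <- inp[inp$target == node & inp$input %in% active_inputs, ,
               drop = FALSE]
    if (nrow(inp)) {
      b <- vapply(inp$input, function(nmi) params[[paste0("beta_", nmi)]],
                  numeric(1))
      num0[i] <- num0[i] + sum(b[inp$sign == ACTIVATION])
      den0[i] <- den0[i] + sum(b[inp$sign == INHIBITION])
    }
    has_act_edge <- any(topology$edges$target == node &
                          topology$edges$sign == ACTIVATION)
    has_act_input <- any(topology$inputs$target == node &
                           topology$inputs$sign == ACTIVATION)
    eq4[i] <- as.integer(!(node %in% topology$beta_nodes) &&
                           !has_act_edge && !has_act_input)
  }
  e <- topology$edges
  ek <- eh <- numeric(nrow(e))
  if (nrow(e)) {
    keys <- edge_key(e$source, e$target)
    ek <- as.numeric(params[paste0("k_", keys)])
    eh <- as.numeric(params[paste0("h_", keys)])
  }
  list(n = n, alpha = alpha, delta = delta, num0 = num0, den0 = den0,
       eq4 = eq4,
       esrc = unname(idx[e$source]), etgt = unname(idx[e$target]),
       esign = as.integer(ifelse(e$sign == ACTIVATION, 1L, -1L)),
       ek = ek, eh = eh, nodes = nodes)
}
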