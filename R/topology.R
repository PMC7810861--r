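#' Construct a signed gene-regulatory-network topology
#'
#' A topology is a set of named nodes, signed directed regulatory edges, and
#' attachment points for the two external experimental inputs: `RESTi`
#' (shRNA knockdown of REST, a constant inhibitor) and `vAscl1` (viral
#' Ascl1, a constant activator).  Self-edges and double interactions (one
#' ordered pair carrying both an activation and an inhibition) are rejected;
#' experimentally motivated self-inhibitions can be introduced through
#' [variant_family()].
#'
#' Nodes that have at least one non-constitutive activator -- a network
#' activation edge or an activating external input -- carry a constitutive
#' background parameter `beta_<node>`; all other nodes use the reduced
#' activity form `1 / (1 + sum of inhibitor terms)`.  The default flag
#' assignment follows that rule and can be overridden via `beta_nodes`.
#'
#' @param nodes character vector of node names.
#' @param edges data.frame with columns `source`, `target`, `sign`
#'   (`"activation"` or `"inhibition"`), or NULL for no edges.
#' @param inputs data.frame with columns `input`, `target`, `sign`
#'   describing external-input attachments, or NULL.
#' @param beta_nodes nodes carrying a constitutive background term; by
#'   default derived from the activator rule above.
#' @param allow_self permit self-edges (used internally by variant
#'   families for the experimentally observed self-inhibitions).
#' @return an object of class `grn_topology`.
#' @seealso [literature_topology()], [add_edge()]
#' @export
grn_topology <- function(nodes, edges = NULL, inputs = NULL,
                         beta_nodes = NULL, allow_self = FALSE) {
  stopifnot(is.character(nodes), length(nodes) >= 1, !anyDuplicated(nodes))
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target", "sign") %in% names(edges)))
  if (is.null(inputs)) {
    inputs <- data.frame(input = character(), target = character(),
                         sign = character(), stringsAsFactors = FALSE)
  }
  inputs <- as.data.frame(inputs, stringsAsFactors = FALSE)

  bad <- setdiff(c(edges$source, edges$target, inputs$target), nodes)
  if (length(bad))
    stop("edge/input endpoints not declared as nodes: ",
         paste(unique(bad), collapse = ", "))
  if (!all(edges$sign %in% c(ACTIVATION, INHIBITION)))
    stop("edge sign must be 'activation' or 'inhibition'")
  if (!all(inputs$sign %in% c(ACTIVATION, INHIBITION)))
    stop("input sign must be 'activation' or 'inhibition'")
  if (!allow_self && any(edges$source == edges$target))
    stop("self-edges are not allowed")
  pair <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(pair))
    stop("double interaction: an ordered pair may carry only one sign")

  if (is.null(beta_nodes)) {
    act_tgt <- edges$target[edges$sign == ACTIVATION]
    act_inp <- inputs$target[inputs$sign == ACTIVATION]
    beta_nodes <- intersect(nodes, unique(c(act_tgt, act_inp)))
  } else {
    stopifnot(all(beta_nodes %in% nodes))
  }

  structure(list(nodes = nodes, edges = edges, inputs = inputs,
                 beta_nodes = beta_nodes),
            class = "grn_topology")
}

#' The literature-based neural conversion network
#'
#' Five nodes (PTB, nPTB, miRs, RESTc, Ascl1) with the interactions
#' established in the reprogramming literature: miRs represses PTB, nPTB
#' and RESTc; PTB represses nPTB and activates RESTc (via competition for
#' SCP1 repression); RESTc represses miRs and Ascl1.  External inputs:
#' shREST (`RESTi`) inhibits RESTc, viral Ascl1 (`vAscl1`) activates miRs.
#'
#' @return a `grn_topology`.
#' @export
literature_topology <- function() {
  edges <- data.frame(
    source = c("miRs", "miRs", "PTB",  "miRs",  "PTB",   "RESTc", "RESTc"),
    target = c("PTB",  "nPTB", "nPTB", "RESTc", "RESTc", "miRs",  "Ascl1"),
    sign   = c(INHIBITION, INHIBITION, INHIBITION, INHIBITION,
               ACTIVATION, INHIBITION, INHIBITION),
    stringsAsFactors = FALSE)
  inputs <- data.frame(
    input  = c("RESTi", "vAscl1"),
    target = c("RESTc", "miRs"),
    sign   = c(INHIBITION, ACTIVATION),
    stringsAsFactors = FALSE)
  grn_topology(GRN_NODES, edges, inputs)
}

#' The nPTB -> PTB network variant
#'
#' The literature network plus an activation of PTB by nPTB, the single
#' added interaction that introduces direct negative feedback between nPTB
#' and PTB.
#' @return a `grn_topology`.
#' @export
nptb_ptb_topology <- function() {
  add_edge(literature_topology(), "nPTB", "PTB", ACTIVATION)
}

#' Add a single regulatory edge to a topology
#'
#' Returns a modified copy; the original is untouched.  Self-edges and
#' double interactions are rejected.  Background-term flags are re-derived,
#' so a node that gains its first activator also gains a `beta` parameter.
#'
#' @param topology a `grn_topology`.
#' @param source,target node names.
#' @param sign `"activation"` or `"inhibition"`.
#' @param allow_self internal escape hatch for variant families.
#' @return a new `grn_topology`.
#' @export
add_edge <- function(topology, source, target, sign, allow_self = FALSE) {
  stopifnot(inherits(topology, "grn_topology"))
  if (!source %in% topology$nodes || !target %in% topology$nodes)
    stop("unknown node: ", paste(setdiff(c(source, target), topology$nodes),
                                 collapse = ", "))
  if (!allow_self && source == target)
    stop("self-edge not allowed: ", source)
  e <- topology$edges
  if (any(e$source == source & e$target == target))
    stop("double interaction: ", source, " already regulates ", target)
  e <- rbind(e, data.frame(source = source, target = target, sign = sign,
                           stringsAsFactors = FALSE))
  grn_topology(topology$nodes, e, topology$inputs, allow_self = TRUE)
}

edge_key <- function(source, target) paste0(source, "_", target)

topology_edges <- function(topology, target = NULL, sign = NULL) {
  e <- topology$edges
  if (!is.null(target)) e <- e[e$target == target, , drop = FALSE]
  if (!is.null(sign)) e <- e[e$sign == sign, , drop = FALSE]
  e
}

#' @export
print.grn_topology <- function(x, ...) {
  cat("GRN topology:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  if (nrow(x$edges)) {
    arr <- ifelse(x$edges$sign == ACTIVATION, "→", "⊣")
    cat("  edges:", paste(x$edges$source, arr, x$edges$target,
                          collapse = ";  "), "\n")
  }
  if (nrow(x$inputs)) {
    arr <- ifelse(x$inputs$sign == ACTIVATION, "→", "⊣")
    cat("  inputs:", paste(x$inputs$input, arr, x$inputs$target,
                           collapse = ";  "), "\n")
  }
  if (length(x$beta_nodes))
    cat("  constitutive background (beta):",
        paste(x$beta_nodes, collapse = ", "), "\n")
  invisible(x)
}
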