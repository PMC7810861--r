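#' Parameter names required by a topology
#'
#' Canonical ordering: per node `alpha_X`, `delta_X`; per beta-flagged node
#' `beta_X`; per edge `k_<source>_<target>`, `h_<source>_<target>`; then one
#' strength per external input (`beta_RESTi`, `beta_vAscl1`).  This is also
#' the gene order of a genetic-algorithm genome for the topology.
#'
#' @param topology a `grn_topology`.
#' @return character vector of parameter names.
#' @export
param_names <- function(topology) {
  stopifnot(inherits(topology, "grn_topology"))
  nm <- c(paste0("alpha_", topology$nodes), paste0("delta_", topology$nodes))
  if (length(topology$beta_nodes))
    nm <- c(nm, paste0("beta_", topology$beta_nodes))
  if (nrow(topology$edges)) {
    ek <- edge_key(topology$edges$source, topology$edges$target)
    nm <- c(nm, paste0("k_", ek), paste0("h_", ek))
  }
  if (nrow(topology$inputs))
    nm <- c(nm, paste0("beta_", topology$inputs$input))
  nm
}

#' Validate a parameter set against a topology
#'
#' All rate, interaction and background constants of the Shea-Ackers model:
#' transcription coefficients `alpha` (concentration/hour), decay
#' coefficients `delta` (1/hour), constitutive backgrounds `beta`
#' (dimensionless), per-edge dissociation constants `k` (concentration) and
#' Hill exponents `h` (dimensionless, capped at 4), and external-input
#' strengths.  All values must be strictly positive.
#'
#' @param params named numeric vector.
#' @param topology a `grn_topology`.
#' @return the parameter vector, invisibly classed `grn_params`.
#' @export
grn_params <- function(params, topology) {
  nm <- param_names(topology)
  missing <- setdiff(nm, names(params))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(params), nm)
  if (length(extra))
    stop("parameters not in topology: ", paste(extra, collapse = ", "))
  params <- params[nm]
  if (any(!is.finite(params)) || any(params <= 0))
    stop("all parameters must be finite and strictly positive")
  hmask <- startsWith(nm, "h_")
  if (any(params[hmask] > 4))
    stop("Hill exponents are capped at 4")
  structure(params, class = "grn_params")
}

#' @export
print.grn_params <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}

#' @export
as.data.frame.grn_params <- function(x, ...) {
  data.frame(parameter = names(x), value = as.numeric(x),
             stringsAsFactors = FALSE)
}

param_or_zero <- function(params, name) {
  if (name %in% names(params)) unname(params[[name]]) else 0
}
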