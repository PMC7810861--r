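# YAML interchange for topologies, protocols and run configuration.

#' Write / read a topology as YAML
#'
#' The YAML carries the node list, signed edge triples, external-input
#' attachments and the background-term flags.
#'
#' @param topology a `grn_topology`.
#' @param path YAML file.
#' @return `read_topology_yaml()` returns a `grn_topology`.
#' @export
write_topology_yaml <- function(topology, path) {
  yaml::write_yaml(list(
    nodes = as.list(topology$nodes),
    edges = unname(apply(topology$edges, 1, as.list)),
    inputs = unname(apply(topology$inputs, 1, as.list)),
    beta_nodes = as.list(topology$beta_nodes)), path)
  invisible(path)
}

#' @rdname write_topology_yaml
#' @export
read_topology_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  to_df <- function(x) if (length(x))
    do.call(rbind, lapply(x, as.data.frame, stringsAsFactors = FALSE))
    else NULL
  grn_topology(unlist(y$nodes), to_df(y$edges), to_df(y$inputs),
               beta_nodes = unlist(y$beta_nodes), allow_self = TRUE)
}

#' Write / read a stage protocol as YAML
#' @param protocol a `grn_protocol`.
#' @param path YAML file.
#' @export
write_protocol_yaml <- function(protocol, path) {
  yaml::write_yaml(list(stages = lapply(seq_len(nrow(protocol)),
    function(i) list(name = protocol$name[i],
                     duration = protocol$duration[i],
                     inputs = as.list(protocol$inputs[[i]])))), path)
  invisible(path)
}

#' @rdname write_protocol_yaml
#' @export
read_protocol_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  grn_protocol(data.frame(
    name = vapply(y$stages, `[[`, character(1), "name"),
    duration = vapply(y$stages, `[[`, numeric(1), "duration"),
    inputs = I(lapply(y$stages, function(s)
      as.character(unlist(s$inputs)))),
    stringsAsFactors = FALSE))
}

#' Write / read a scenario grid as YAML
#' @param scenarios named list of `grn_scenario`.
#' @param path YAML file.
#' @export
write_scenarios_yaml <- function(scenarios, path) {
  yaml::write_yaml(lapply(scenarios, function(s)
    list(name = s$name, alpha_mult = as.list(s$alpha_mult),
         resti = s$resti, vascl1 = s$vascl1,
         beta_mult = as.list(s$beta_mult))), path)
  invisible(path)
}

#' @rdname write_scenarios_yaml
#' @export
read_scenarios_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  out <- lapply(y, function(s)
    scenario_spec(s$name, alpha_mult = unlist(s$alpha_mult),
                  resti = s$resti %||% 0, vascl1 = s$vascl1 %||% 0,
                  beta_mult = unlist(s$beta_mult)))
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fitness trace CSV
#' @param fit a `grn_fit` or `run_ga()` result.
#' @param path output CSV.
#' @export
write_trace_csv <- function(fit, path) {
  trace <- if (inherits(fit, "grn_fit")) fit$trace else fit$trace
  write.csv(data.frame(generation = seq_along(trace) - 1,
                       best_fitness = trace), path, row.names = FALSE)
  invisible(path)
}
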