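#' Decompose a node's transcription rate into regulator "arrows"
#'
#' At a given state, the total activation arrow length is
#' \eqn{L_{act} = \Sigma_{act} / (1 + \Sigma_{act})} -- the fraction of the
#' maximum transcription rate that would be realised with no inhibitors --
#' and the total inhibition length
#' \eqn{L_{inh} = \Sigma_{act}\Sigma_{inh} /
#' ((1+\Sigma_{act})(1+\Sigma_{act}+\Sigma_{inh}))}, defined so that
#' \eqn{L_{act} - L_{inh} = SA(X)} exactly.  \eqn{\Sigma_{act}} and
#' \eqn{\Sigma_{inh}} include the constitutive background and any active
#' external inputs as named pseudo-regulators (`"constitutive"`,
#' `"RESTi"`, `"vAscl1"`).  Individual regulators receive sublengths
#' proportional to their term \eqn{([T]/k)^h}.  A decay arrow of length
#' \eqn{(\delta_X/\alpha_X)[X]} expresses decay in the same units, so the
#' net arrow sum equals the rate of change divided by \eqn{\alpha_X}.
#'
#' For reduced-form nodes (no activators, no background) the constitutive
#' activation is saturated: \eqn{L_{act} = 1} with a single
#' `"constitutive"` arrow, and \eqn{L_{inh} = \Sigma_{inh}/(1+\Sigma_{inh})},
#' which is the \eqn{\Sigma_{act}\to\infty} limit of the general formulas
#' and preserves the identity \eqn{L_{act} - L_{inh} = SA}.
#'
#' @inheritParams shea_ackers_activity
#' @return list with `L_act`, `L_inh`, `act_split`, `inh_split`
#'   (named sublengths), `decay`, `sa`.
#' @export
arrow_lengths <- function(node, state, topology, params,
                          active_inputs = character()) {
  if (!node %in% topology$nodes) stop("unknown node: ", node)
  alpha <- params[[paste0("alpha_", node)]]
  if (!is.finite(alpha) || alpha <= 0)
    stop("arrow decomposition requires alpha_", node, " > 0")
  parts <- activity_terms(node, state, topology, params, active_inputs)
  s_inh <- parts$sum_inh
  if (parts$eq4) {
    L_act <- 1
    L_inh <- s_inh / (1 + s_inh)
    act_split <- c(constitutive = 1)
    sa <- 1 / (1 + s_inh)
  } else {
    s_act <- parts$sum_act
    L_act <- s_act / (1 + s_act)
    L_inh <- s_act * s_inh / ((1 + s_act) * (1 + s_act + s_inh))
    act_split <- if (s_act > 0) parts$act_split / s_act * L_act else
      parts$act_split * 0
    sa <- s_act / (1 + s_act + s_inh)
  }
  inh_split <- if (s_inh > 0) parts$inh_split / s_inh * L_inh else
    parts$inh_split * 0
  delta <- params[[paste0("delta_", node)]]
  list(L_act = L_act, L_inh = L_inh,
       act_split = act_split, inh_split = inh_split,
       decay = delta / alpha * unname(state[[node]]), sa = sa)
}

#' Arrow decomposition along a trajectory
#'
#' Evaluates [arrow_lengths()] for every node at (a thinning of) the
#' trajectory grid, yielding the data behind stacked-arrow influence
#' plots.
#'
#' @param traj a `grn_trajectory`.
#' @param topology,params the model that produced it.
#' @param active_inputs external inputs active during the stage (defaults
#'   to the stage annotation's canonical input set when recognisable).
#' @param every keep every `every`-th grid point (default 1 = all).
#' @return long data.frame with columns `time_h`, `node`, `regulator`,
#'   `class` (`"act"`, `"inh"`, `"decay"`), `length`, plus per-row `sa`;
#'   classed `grn_dissection`.
#' @export
dissect_trajectory <- function(traj, topology, params,
                               active_inputs = NULL, every = 1L) {
  stopifnot(inherits(traj, "grn_trajectory"))
  if (is.null(active_inputs)) {
    active_inputs <- if (traj$stage %in% c("fibroblast", "rest_kd",
                                           "conversion"))
      stage_active_inputs(traj$stage) else character()
  }
  idx <- seq(1, length(traj$times), by = every)
  rows <- vector("list", length(idx) * length(topology$nodes))
  r <- 0
  for (i in idx) {
    state <- traj$states[i, ]
    for (node in topology$nodes) {
      ar <- arrow_lengths(node, state, topology, params, active_inputs)
      reg <- c(names(ar$act_split), names(ar$inh_split), "decay")
      cls <- c(rep("act", length(ar$act_split)),
               rep("inh", length(ar$inh_split)), "decay")
      len <- c(unname(ar$act_split), unname(ar$inh_split), ar$decay)
      r <- r + 1
      rows[[r]] <- data.frame(time_h = traj$times[i], node = node,
                              regulator = reg, class = cls, length = len,
                              sa = ar$sa, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(r)])
  class(out) <- c("grn_dissection", "data.frame")
  out
}

#' Stacked-arrow influence plot
#'
#' One panel per node: activator sublengths stacked upward from zero,
#' inhibitor sublengths plus the decay arrow stacked downward.
#'
#' @param x a `grn_dissection`.
#' @param nodes nodes to draw.
#' @param ... unused.
#' @export
plot.grn_dissection <- function(x, nodes = unique(x$node), ...) {
  old <- graphics::par(mfrow = c(1, length(nodes)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (node in nodes) {
    d <- x[x$node == node, ]
    tt <- sort(unique(d$time_h))
    up <- d[d$class == "act", ]
    dn <- d[d$class != "act", ]
    ylim <- c(-max(tapply(dn$length, dn$time_h, sum), 0.1),
              max(tapply(up$length, up$time_h, sum), 0.1))
    graphics::plot(NA, xlim = range(tt), ylim = ylim, xlab = "time (h)",
                   ylab = "arrow length", main = node)
    graphics::abline(h = 0, col = "grey")
    base <- setNames(rep(0, length(tt)), tt)
    for (reg in unique(up$regulator)) {
      s <- up[up$regulator == reg, ]
      y1 <- base[as.character(s$time_h)] + s$length
      graphics::lines(s$time_h, y1, col = which(unique(up$regulator) == reg))
      base[as.character(s$time_h)] <- y1
    }
    base <- setNames(rep(0, length(tt)), tt)
    for (reg in unique(dn$regulator)) {
      s <- dn[dn$regulator == reg, ]
      y1 <- base[as.character(s$time_h)] - s$length
      graphics::lines(s$time_h, y1, lty = 2,
                      col = which(unique(dn$regulator) == reg))
      base[as.character(s$time_h)] <- y1
    }
  }
  invisible(x)
}
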