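#' Overexpression / knockdown scenario specification
#'
#' A scenario perturbs a fitted model: transcription-rate coefficients
#' are multiplied by 5 (overexpression) or 1/5 (knockdown); viral Ascl1
#' overexpression and shRNA REST knockdown are instead toggled through the
#' dedicated external inputs (`vascl1`, `resti` in `{0, 1}`); and
#' constitutive background terms can be rescaled for the
#' constitutive-activation experiments.
#'
#' @param name scenario label.
#' @param alpha_mult named positive multipliers on `alpha_<node>`.
#' @param resti,vascl1 0/1 toggles for the external inputs.
#' @param beta_mult named positive multipliers on `beta_<node>`.
#' @return object of class `grn_scenario`.
#' @export
scenario_spec <- function(name, alpha_mult = numeric(), resti = 0,
                          vascl1 = 0, beta_mult = numeric()) {
  stopifnot(resti %in% c(0, 1), vascl1 %in% c(0, 1))
  if (length(alpha_mult) && (is.null(names(alpha_mult)) ||
                             any(alpha_mult <= 0)))
    stop("alpha_mult must be named and positive")
  if (length(beta_mult) && (is.null(names(beta_mult)) ||
                            any(beta_mult <= 0)))
    stop("beta_mult must be named and positive")
  if ("Ascl1" %in% names(alpha_mult) && vascl1 == 1)
    stop("ambiguous Ascl1 perturbation: use either the alpha multiplier ",
         "or the viral vAscl1 toggle, not both")
  structure(list(name = name, alpha_mult = alpha_mult, resti = resti,
                 vascl1 = vascl1, beta_mult = beta_mult),
            class = "grn_scenario")
}

#' The canonical eight-scenario perturbation grid
#'
#' Fibroblast (no perturbation), OX Ascl1, OX miRs, KD REST,
#' OX Ascl1 + KD REST, OX Ascl1 + OX REST, OX Ascl1 + OX PTB, KD PTB.
#' Viral Ascl1 and REST knockdown act through the external-input toggles;
#' all other perturbations scale the node's transcription coefficient by
#' 5 or 1/5.
#'
#' @return named list of `grn_scenario` objects.
#' @export
canonical_scenarios <- function() {
  list(
    "Fibroblast"        = scenario_spec("Fibroblast"),
    "OX Ascl1"          = scenario_spec("OX Ascl1", vascl1 = 1),
    "OX miRs"           = scenario_spec("OX miRs",
                                        alpha_mult = c(miRs = 5)),
    "KD REST"           = scenario_spec("KD REST", resti = 1),
    "OX Ascl1 + KD REST" = scenario_spec("OX Ascl1 + KD REST",
                                         resti = 1, vascl1 = 1),
    "OX Ascl1 + OX REST" = scenario_spec("OX Ascl1 + OX REST",
                                         alpha_mult = c(RESTc = 5),
                                         vascl1 = 1),
    "OX Ascl1 + OX PTB" = scenario_spec("OX Ascl1 + OX PTB",
                                        alpha_mult = c(PTB = 5),
                                        vascl1 = 1),
    "KD PTB"            = scenario_spec("KD PTB",
                                        alpha_mult = c(PTB = 1 / 5)))
}

#' Apply a scenario to a parameter set
#'
#' Multiplies the targeted `alpha` coefficients, then any `beta`
#' background multipliers.  The returned vector carries the scenario name
#' as attribute `"scenario"`; applying a second scenario on top raises an
#' error (multipliers compose, which is never what the canonical grid
#' means).  The external-input toggles do not change the parameters --
#' they determine the active-input set, see [scenario_active_inputs()].
#'
#' @param params a `grn_params` vector.
#' @param spec a `grn_scenario`.
#' @param topology the matching `grn_topology`.
#' @return perturbed parameter vector.
#' @export
apply_scenario <- function(params, spec, topology) {
  stopifnot(inherits(spec, "grn_scenario"))
  if (!is.null(attr(params, "scenario")))
    stop("scenario '", attr(params, "scenario"),
         "' already applied; refusing to compose perturbations")
  out <- unclass(params)
  for (node in names(spec$alpha_mult)) {
    key <- paste0("alpha_", node)
    if (!key %in% names(out)) stop("unknown node in alpha_mult: ", node)
    out[[key]] <- out[[key]] * spec$alpha_mult[[node]]
  }
  for (node in names(spec$beta_mult)) {
    key <- paste0("beta_", node)
    if (!key %in% names(out))
      stop("no constitutive background on node: ", node)
    out[[key]] <- out[[key]] * spec$beta_mult[[node]]
  }
  class(out) <- class(params)
  attr(out, "scenario") <- spec$name
  out
}

#' Active external inputs implied by a scenario
#' @param spec a `grn_scenario`.
#' @return character vector, subset of `c("RESTi", "vAscl1")`.
#' @export
scenario_active_inputs <- function(spec) {
  c(character(), if (spec$resti == 1) "RESTi",
    if (spec$vascl1 == 1) "vAscl1")
}

#' Classify conversion outcome of a stochastic ensemble
#'
#' A run converts when its endogenous Ascl1 reaches the
#' detection-limit-normalised threshold (default 1, compared with `>=`;
#' `strict = TRUE` uses `>`) at any recorded time.  A scenario converts
#' when at least `min_hits` of the runs do.
#'
#' @param ensemble a `grn_ensemble` (or list of trajectories).
#' @param threshold conversion threshold on endogenous Ascl1.
#' @param min_hits minimum number of converting runs.
#' @param strict use strict inequality.
#' @param node name of the endogenous Ascl1 node.
#' @return list with `converted` (logical), `efficiency`, `n_converted`,
#'   `n_runs`.
#' @export
classify_conversion <- function(ensemble, threshold = 1, min_hits = 1,
                                strict = FALSE, node = "Ascl1") {
  if (!length(ensemble)) stop("empty ensemble")
  peaks <- vapply(ensemble, function(tr) {
    if (!node %in% colnames(tr$states)) stop("no ", node, " series")
    max(tr$states[, node])
  }, numeric(1))
  hits <- if (strict) peaks > threshold else peaks >= threshold
  list(converted = sum(hits) >= min_hits,
       efficiency = mean(hits),
       n_converted = sum(hits),
       n_runs = length(ensemble))
}

#' Run the perturbation-scenario grid on a fitted model
#'
#' For each scenario: a deterministic 14-day trajectory and a stochastic
#' ensemble (default 50 Gillespie runs of 336 h) from the fibroblast
#' baseline, with the scenario's external inputs applied from t = 0.  The
#' combined OX Ascl1 + KD REST row additionally reports whether its
#' conversion efficiency strictly exceeds OX Ascl1 alone (the `plus_flag`).
#'
#' @param model a `grn_model` or `grn_fit`.
#' @param scenarios named list of `grn_scenario` (default: canonical grid).
#' @param noise a `grn_noise`.
#' @param n_runs stochastic runs per scenario.
#' @param duration hours (default 336 = 14 days).
#' @param seed base seed; per-scenario seeds are offset deterministically.
#' @param threshold,min_hits,strict conversion-call settings.
#' @return data.frame with one row per scenario: `scenario`,
#'   `deterministic_peak_ascl1`, `n_converted`, `n_runs`, `efficiency`,
#'   `call`, `plus_flag`.
#' @export
scenario_table <- function(model, scenarios = canonical_scenarios(),
                           noise = noise_config(), n_runs = 50,
                           duration = 336, seed = 1, threshold = 1,
                           min_hits = 1, strict = FALSE) {
  stopifnot(inherits(model, "grn_model"))
  nodes <- model$topology$nodes
  init <- setNames(rep(1, length(nodes)), nodes)
  if ("Ascl1" %in% nodes) init[["Ascl1"]] <- 0
  rows <- list()
  eff <- setNames(numeric(length(scenarios)), names(scenarios))
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    p <- apply_scenario(model$params, sc, model$topology)
    attr(p, "scenario") <- NULL
    m <- grn_model(model$topology, p)
    active <- scenario_active_inputs(sc)
    det <- integrate_stage(m, init, duration, active_inputs = active,
                           stage = sc$name)
    ens <- run_ensemble(m, init, n_runs = n_runs, duration = duration,
                        noise = noise, seed = seed + 1000L * (i - 1L),
                        active_inputs = active)
    cl <- classify_conversion(ens, threshold, min_hits, strict)
    eff[i] <- cl$efficiency
    rows[[i]] <- data.frame(
      scenario = sc$name,
      deterministic_peak_ascl1 = max(det$states[, "Ascl1"]),
      n_converted = cl$n_converted, n_runs = cl$n_runs,
      efficiency = cl$efficiency,
      call = ifelse(cl$converted, "Yes", "No"),
      plus_flag = NA, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  both <- c("OX Ascl1 + KD REST", "OX Ascl1")
  if (all(both %in% out$scenario)) {
    i <- match(both[1], out$scenario)
    out$plus_flag[i] <- eff[[both[1]]] > eff[[both[2]]]
    if (isTRUE(out$plus_flag[i]) && out$call[i] == "Yes")
      out$call[i] <- "Yes+"
  }
  out
}

#' Deep PTB-knockdown probe with reduced constitutive REST activation
#'
#' Runs the PTB knockdown at a much deeper multiplier (default 1/5000),
#' once with the fitted constitutive RESTc background and once with that
#' background reduced (default x 1/5).  In models where constitutive REST
#' activation keeps RESTc at nominal levels, the first arm does not
#' convert while the second can.
#'
#' @param model a `grn_model` with a `beta_RESTc` parameter.
#' @param alpha_mult deep knockdown multiplier on `alpha_PTB`.
#' @param beta_mult vector of `beta_RESTc` multipliers to probe.
#' @param ... passed to [scenario_table()] machinery
#'   (`noise`, `n_runs`, `duration`, `seed`, ...).
#' @return data.frame with one row per `beta_mult` arm.
#' @export
deep_ptb_kd_probe <- function(model, alpha_mult = 1 / 5000,
                              beta_mult = c(1, 1 / 5), ...) {
  if (!"beta_RESTc" %in% names(model$params))
    stop("model has no constitutive RESTc activation (beta_RESTc); ",
         "the probe is not applicable")
  scen <- lapply(beta_mult, function(bm) {
    nm <- sprintf("KD PTB x %g, beta_RESTc x %g", alpha_mult, bm)
    if (bm == 1)
      scenario_spec(nm, alpha_mult = c(PTB = alpha_mult))
    else
      scenario_spec(nm, alpha_mult = c(PTB = alpha_mult),
                    beta_mult = c(RESTc = bm))
  })
  names(scen) <- vapply(scen, `[[`, character(1), "name")
  scenario_table(model, scen, ...)
}
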