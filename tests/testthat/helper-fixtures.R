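# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture_truth <- function(variant = "nptb_ptb", seed = 42) {
  key <- paste0("truth_", variant, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_paper_like_truth(variant, seed = seed)
  .fixture_env[[key]]
}

fixture_dataset <- function(sigma = 0, seed = 1) {
  key <- paste0("ds_", sigma, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    tr <- fixture_truth()
    .fixture_env[[key]] <- generate_dataset(tr$topology, tr$params,
                                            sigma = sigma,
                                            shadow_sigma = sigma / 2,
                                            seed = seed)
  }
  .fixture_env[[key]]
}

fixture_model <- function() {
  tr <- fixture_truth()
  grn_model(tr$topology, tr$params)
}

# a positive random parameter vector for an arbitrary topology (no
# dynamical screening; for algebraic oracles only)
random_params <- function(topology) {
  nm <- param_names(topology)
  p <- setNames(numeric(length(nm)), nm)
  for (i in seq_along(nm)) {
    p[i] <- if (startsWith(nm[i], "h_")) runif(1, 0.5, 3.9)
    else if (startsWith(nm[i], "delta_")) runif(1, 0.1, 1.5)
    else if (startsWith(nm[i], "alpha_")) runif(1, 0.2, 3)
    else runif(1, 0.2, 3)
  }
  grn_params(p, topology)
}

random_state <- function(nodes, max = 3) {
  setNames(runif(length(nodes), 0, max), nodes)
}

# single-node birth-death model through the public API: one node, no
# regulators, reduced activity form => SA = 1 identically
birth_death_model <- function(alpha, delta) {
  topo <- grn_topology("X")
  grn_model(topo, c(alpha_X = alpha, delta_X = delta))
}

# an independent, line-by-line transcription of the literature-network
# ODE system (PTB, nPTB, miRs, RESTc, Ascl1), used as the oracle the
# generic model compiler is checked against
literature_rhs_oracle <- function(state, p, resti = FALSE, vascl1 = FALSE) {
  P <- state[["PTB"]]; N <- state[["nPTB"]]; M <- state[["miRs"]]
  R <- state[["RESTc"]]; A <- state[["Ascl1"]]
  bR  <- if (resti) p[["beta_RESTi"]] else 0
  bvA <- if (vascl1) p[["beta_vAscl1"]] else 0
  dP <- p[["alpha_PTB"]] /
    (1 + (M / p[["k_miRs_PTB"]])^p[["h_miRs_PTB"]]) -
    p[["delta_PTB"]] * P
  dN <- p[["alpha_nPTB"]] /
    (1 + (M / p[["k_miRs_nPTB"]])^p[["h_miRs_nPTB"]] +
       (P / p[["k_PTB_nPTB"]])^p[["h_PTB_nPTB"]]) -
    p[["delta_nPTB"]] * N
  dM <- p[["alpha_miRs"]] * (p[["beta_miRs"]] + bvA) /
    (1 + p[["beta_miRs"]] + bvA +
       (R / p[["k_RESTc_miRs"]])^p[["h_RESTc_miRs"]]) -
    p[["delta_miRs"]] * M
  dR <- p[["alpha_RESTc"]] *
    (p[["beta_RESTc"]] + (P / p[["k_PTB_RESTc"]])^p[["h_PTB_RESTc"]]) /
    (1 + p[["beta_RESTc"]] + (P / p[["k_PTB_RESTc"]])^p[["h_PTB_RESTc"]] +
       (M / p[["k_miRs_RESTc"]])^p[["h_miRs_RESTc"]] + bR) -
    p[["delta_RESTc"]] * R
  dA <- p[["alpha_Ascl1"]] /
    (1 + (R / p[["k_RESTc_Ascl1"]])^p[["h_RESTc_Ascl1"]]) -
    p[["delta_Ascl1"]] * A
  c(PTB = dP, nPTB = dN, miRs = dM, RESTc = dR, Ascl1 = dA)
}
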