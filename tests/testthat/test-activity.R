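base_state <- function(PTB = 0, nPTB = 0, miRs = 0, RESTc = 0, Ascl1 = 0) {
  c(PTB = PTB, nPTB = nPTB, miRs = miRs, RESTc = RESTc, Ascl1 = Ascl1)
}

test_that("activity reduces to hand-computable values in simple states", {
  topo <- literature_topology()
  p <- random_params(topo)

  # RESTc with only its constitutive term: beta_R = 1 -> 1/(1+1)
  p1 <- unclass(p); p1[["beta_RESTc"]] <- 1
  expect_equal(shea_ackers_activity("RESTc", base_state(), topo, p1), 0.5)

  # Ascl1 (reduced form) with no repressor present -> activity 1
  expect_equal(shea_ackers_activity("Ascl1", base_state(), topo, p), 1)

  # miRs with beta_M = 1, vAscl1 off, [RESTc] = k -> 1/3 for any h
  p2 <- unclass(p); p2[["beta_miRs"]] <- 1
  st <- base_state(RESTc = p2[["k_RESTc_miRs"]])
  expect_equal(shea_ackers_activity("miRs", st, topo, p2), 1 / 3)

  # with vAscl1 active the input strength joins numerator and denominator
  p3 <- unclass(p); p3[["beta_miRs"]] <- 1; p3[["beta_vAscl1"]] <- 2
  expect_equal(shea_ackers_activity("miRs", base_state(), topo, p3,
                                    active_inputs = "vAscl1"),
               3 / 4)
})

test_that("activity errors on unknown nodes and negative concentrations", {
  topo <- literature_topology()
  p <- random_params(topo)
  expect_error(shea_ackers_activity("Brn2", base_state(), topo, p),
               "unknown node")
  st <- base_state(); st[["PTB"]] <- -0.1
  expect_error(shea_ackers_activity("nPTB", st, topo, p), "non-negative")
})

test_that("activity stays in [0, 1) when any denominator-only term is positive", {
  topo <- nptb_ptb_topology()
  set.seed(1)
  for (i in 1:50) {
    p <- random_params(topo)
    st <- random_state(topo$nodes)
    for (node in topo$nodes) {
      sa <- shea_ackers_activity(node, st, topo, p,
                                 active_inputs = c("RESTi", "vAscl1"))
      expect_gte(sa, 0)
      expect_lt(sa, 1)
    }
  }
})

test_that("activity is monotone in activators and inhibitors", {
  topo <- nptb_ptb_topology()
  set.seed(2)
  p <- random_params(topo)
  grid <- seq(0, 3, by = 0.25)
  # nPTB activates PTB; miRs inhibits PTB
  act <- vapply(grid, function(v)
    shea_ackers_activity("PTB", base_state(nPTB = v, miRs = 1), topo, p),
    numeric(1))
  inh <- vapply(grid, function(v)
    shea_ackers_activity("PTB", base_state(nPTB = 1, miRs = v), topo, p),
    numeric(1))
  expect_true(all(diff(act) >= 0))
  expect_true(all(diff(inh) <= 0))
})

test_that("the compiled model and ode_rhs reproduce a hand-coded literature system", {
  topo <- literature_topology()
  set.seed(3)
  for (i in 1:100) {
    p <- random_params(topo)
    st <- random_state(topo$nodes)
    for (io in list(c(FALSE, FALSE), c(TRUE, FALSE), c(TRUE, TRUE))) {
      active <- c(if (io[1]) "RESTi", if (io[2]) "vAscl1")
      want <- literature_rhs_oracle(st, p, io[1], io[2])
      got_r <- ode_rhs(topo, p, active)(st)
      cm <- grnconv:::compile_model(topo, p, active)
      got_c <- setNames(grnconv:::.rhs_cpp(cm, as.numeric(st[topo$nodes])),
                        topo$nodes)
      expect_equal(got_r, want, tolerance = 1e-12)
      expect_equal(got_c, want, tolerance = 1e-12)
    }
  }
})

test_that("folding a constant regulator into the background leaves the rate identical", {
  # explicit model: constant activator C feeding X, inhibitor I constant
  topo_full <- grn_topology(
    c("X", "C", "I"),
    data.frame(source = c("C", "I"), target = c("X", "X"),
               sign = c("activation", "inhibition")),
    beta_nodes = character())
  p_full <- c(alpha_X = 2, delta_X = 0.3, alpha_C = 1, delta_C = 1,
              alpha_I = 1, delta_I = 1,
              k_C_X = 0.7, h_C_X = 2.5, k_I_X = 1.3, h_I_X = 1.5)
  cC <- 0.9; cI <- 1.8                      # frozen regulator levels
  b_act <- (cC / 0.7)^2.5
  b_inh <- (cI / 1.3)^1.5
  # reduced model: X alone with beta = b_act/(1+b_inh) and alpha rescaled
  topo_red <- grn_topology("X", beta_nodes = "X")
  p_red <- c(alpha_X = 2, delta_X = 0.3, beta_X = b_act / (1 + b_inh))
  set.seed(4)
  for (x in runif(20, 0, 3)) {
    full <- p_full[["alpha_X"]] *
      shea_ackers_activity("X", c(X = x, C = cC, I = cI), topo_full,
                           p_full)
    # dividing numerator and denominator by (1 + b_inh) is exact, so the
    # reduced rate needs no alpha rescaling
    red <- p_red[["alpha_X"]] *
      shea_ackers_activity("X", c(X = x), topo_red, p_red)
    expect_equal(red, full, tolerance = 1e-12)
  }
})

test_that("stage-effective parameters zero exactly the inactive inputs", {
  topo <- literature_topology()
  p <- unclass(random_params(topo))
  p[["beta_RESTi"]] <- 3.7; p[["beta_vAscl1"]] <- 2.2
  fib <- stage_effective_params(p, "fibroblast")
  expect_equal(unname(fib[["beta_RESTi"]]), 0)
  expect_equal(unname(fib[["beta_vAscl1"]]), 0)
  kd <- stage_effective_params(p, "rest_kd")
  expect_equal(unname(kd[["beta_RESTi"]]), 3.7)
  expect_equal(unname(kd[["beta_vAscl1"]]), 0)
  conv <- stage_effective_params(p, "conversion")
  expect_equal(unname(conv[["beta_RESTi"]]), 3.7)
  expect_equal(unname(conv[["beta_vAscl1"]]), 2.2)
  expect_error(stage_effective_params(p, "maturation"), "unknown stage")
  # zeroing the strengths while keeping an input active matches
  # deactivating the input
  st <- random_state(topo$nodes)
  expect_equal(
    shea_ackers_activity("RESTc", st, topo, kd, active_inputs = "RESTi"),
    shea_ackers_activity("RESTc", st, topo, p, active_inputs = "RESTi"))
  expect_equal(
    shea_ackers_activity("RESTc", st, topo, fib,
                         active_inputs = c("RESTi", "vAscl1")),
    shea_ackers_activity("RESTc", st, topo, p))
})
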