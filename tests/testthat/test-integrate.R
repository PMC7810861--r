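test_that("RK4 matches linear-ODE closed forms at step 0.05 h", {
  # pure exponential decay, half-life one day
  d <- log(2) / 24
  r <- rk4_integrate(function(y) -d * y, 1, 24, 0.05)
  expect_equal(tail(r$states[, 1], 1), 0.5, tolerance = 1e-6)
  # constant production with decay: y(T) = (a/d)(1 - exp(-dT))
  a <- 0.7; d2 <- 0.2
  r2 <- rk4_integrate(function(y) a - d2 * y, 0, 30, 0.05)
  expect_equal(tail(r2$states[, 1], 1), a / d2 * (1 - exp(-d2 * 30)),
               tolerance = 1e-6)
})

test_that("zero duration yields a single-point trajectory; partial final steps are taken", {
  r <- rk4_integrate(function(y) -y, 2, 0, 0.05)
  expect_equal(r$times, 0)
  expect_equal(r$states[1, 1], 2)
  r2 <- rk4_integrate(function(y) -0.1 * y, 1, 0.12, 0.05)
  expect_equal(r2$times, c(0, 0.05, 0.1, 0.12))
  expect_equal(tail(r2$states[, 1], 1), exp(-0.1 * 0.12),
               tolerance = 1e-9)
  # compiled path: same contract
  m <- birth_death_model(1e-12, 0.1)
  tr <- integrate_stage(m, c(X = 1), 0.12, step = 0.05)
  expect_equal(tr$times, c(0, 0.05, 0.1, 0.12))
})

test_that("the compiled integrator agrees with the plain-R RK4 exactly", {
  tr <- fixture_truth()
  m <- grn_model(tr$topology, tr$params)
  y0 <- c(PTB = 1, nPTB = 1, miRs = 1, RESTc = 1, Ascl1 = 0)
  fast <- integrate_stage(m, y0, 12, step = 0.05,
                          active_inputs = c("RESTi", "vAscl1"))
  slow <- rk4_integrate(ode_rhs(tr$topology, tr$params,
                                c("RESTi", "vAscl1")),
                        y0, 12, 0.05)
  expect_equal(unname(fast$states), unname(slow$states),
               tolerance = 1e-12)
})

test_that("halving the step changes recorded values by less than 1e-6 relative", {
  tr <- fixture_truth()
  m <- grn_model(tr$topology, tr$params)
  y0 <- c(PTB = 1, nPTB = 1, miRs = 1, RESTc = 1, Ascl1 = 0)
  a <- integrate_stage(m, y0, 48, step = 0.05,
                       active_inputs = c("RESTi", "vAscl1"))
  b <- integrate_stage(m, y0, 48, step = 0.025,
                       active_inputs = c("RESTi", "vAscl1"))
  ia <- seq(1, length(a$times))
  ib <- seq(1, length(b$times), by = 2)
  rel <- abs(a$states[ia, ] - b$states[ib, ]) /
    pmax(abs(b$states[ib, ]), 1e-8)
  expect_lt(max(rel), 1e-6)
})

test_that("RK4 agrees with an independent adaptive-step reference integrator", {
  skip_if_not_installed("deSolve")
  topo <- nptb_ptb_topology()
  set.seed(7)
  for (i in 1:10) {
    p <- random_params(topo)
    rhs <- ode_rhs(topo, p, "RESTi")
    y0 <- random_state(topo$nodes, max = 2)
    ours <- integrate_stage(grn_model(topo, p), y0, 24, step = 0.05,
                            active_inputs = "RESTi")
    ref <- deSolve::lsoda(
      y = y0[topo$nodes],
      times = seq(0, 24, by = 4),
      func = function(t, y, parms) list(unname(rhs(y))),
      rtol = 1e-10, atol = 1e-12)
    for (ti in seq(0, 24, by = 4)) {
      ours_v <- ours$states[abs(ours$times - ti) < 1e-9, ]
      ref_v <- ref[abs(ref[, "time"] - ti) < 1e-9, topo$nodes]
      expect_equal(unname(ours_v), unname(unlist(ref_v)),
                   tolerance = 1e-5)
    }
  }
})

test_that("run_protocol returns the three canonical stages with their durations", {
  m <- fixture_model()
  run <- run_protocol(m, canonical_protocol())
  expect_named(run, c("fibroblast", "rest_kd", "conversion"))
  expect_equal(vapply(run, function(t) max(t$times), numeric(1)),
               c(fibroblast = 72, rest_kd = 72, conversion = 504))
  expect_true(all(vapply(run, function(t) all(t$states >= 0), logical(1))))
  # stage annotations are carried on each trajectory
  expect_equal(vapply(run, `[[`, character(1), "stage"),
               c(fibroblast = "fibroblast", rest_kd = "rest_kd",
                 conversion = "conversion"))
})

test_that("a fibroblast steady state stays constant and REST inhibition lowers RESTc activity", {
  tr <- fixture_truth()
  m <- grn_model(tr$topology, tr$params)
  run <- run_protocol(m, canonical_protocol())
  fib <- run$fibroblast$states
  expect_lt(max(abs(sweep(fib, 2, fib[1, ]))), 0.015)
  # switching RESTi on strictly lowers RESTc activity at equal state
  st <- fib[1, ]
  sa_off <- shea_ackers_activity("RESTc", st, tr$topology, tr$params)
  sa_on <- shea_ackers_activity("RESTc", st, tr$topology, tr$params,
                                active_inputs = "RESTi")
  expect_lt(sa_on, sa_off)
})

test_that("trajectories convert to tidy data frames and CSV round-trips", {
  m <- fixture_model()
  tr <- integrate_stage(m, c(PTB = 1, nPTB = 1, miRs = 1, RESTc = 1,
                             Ascl1 = 0), 1, stage = "fibroblast")
  df <- as.data.frame(tr)
  expect_named(df, c("time_h", "stage", "node", "value"))
  expect_equal(nrow(df), length(tr$times) * 5)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(df))
  expect_equal(back$value, df$value, tolerance = 1e-12)
})
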