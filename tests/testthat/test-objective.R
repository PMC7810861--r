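test_that("the Hill-gene transform is bounded by 4 and hits known points", {
  expect_equal(decode_hill(1), 2)
  expect_equal(decode_hill(1 / 3), 1)
  expect_lt(decode_hill(1e12), 4)
  expect_equal(decode_hill(1e12), 4, tolerance = 1e-10)
  x <- seq(0.01, 50, length.out = 200)
  expect_true(all(diff(decode_hill(x)) > 0))
  expect_true(all(decode_hill(x) < 4))
  expect_error(decode_hill(0), "positive")
  expect_error(decode_hill(-2), "positive")
  # encode/decode round-trip
  h <- c(0.5, 1, 2, 3.9)
  expect_equal(decode_hill(encode_hill(h)), h, tolerance = 1e-12)
})

test_that("genomes decode positionally with Hill genes transformed", {
  topo <- nptb_ptb_topology()
  nm <- param_names(topo)
  g <- runif(length(nm), 0.1, 2)
  p <- decode_genome(g, topo)
  hmask <- startsWith(nm, "h_")
  expect_equal(unname(unclass(p)[!hmask]), g[!hmask])
  expect_equal(unname(unclass(p)[hmask]), 4 * g[hmask] / (1 + g[hmask]))
  expect_error(decode_genome(g[-1], topo), "genome length")
  # round-trip through encode_genome
  expect_equal(unname(encode_genome(p, topo)), g, tolerance = 1e-12)
})

# build a protocol run whose conversion curve is an arbitrary function of
# time, bypassing integration (for objective-term oracles)
synthetic_run <- function(f, nodes = GRN_NODES, duration = 120,
                          step = 0.05, stage = "conversion") {
  tt <- seq(0, duration, by = step)
  states <- vapply(nodes, function(n) f(tt, n), numeric(length(tt)))
  grnconv:::new_trajectory(tt, states, nodes, stage)
}

test_that("the SSE term counts one knockdown anchor and five conversion anchors per factor", {
  ds <- fixture_dataset(sigma = 0)
  tr <- fixture_truth()
  m <- grn_model(tr$topology, tr$params)
  run <- run_protocol(m, canonical_protocol(conversion_hours = 120),
                      init = initial_policy(conversion = "observed"),
                      dataset = ds)
  # noiseless data generated from the same model: SSE is (numerically) 0
  expect_lt(sse_term(run, ds), 1e-12)

  # shift a single factor by +0.1 everywhere: 6 comparisons x 0.01
  run_off <- run
  run_off$rest_kd$states[, "PTB"] <- run$rest_kd$states[, "PTB"] + 0.1
  run_off$conversion$states[, "PTB"] <-
    run$conversion$states[, "PTB"] + 0.1
  expect_equal(sse_term(run_off, ds), 6 * 0.01, tolerance = 1e-9)

  # +1 on conversion anchors only: five anchors in the inner sum
  run_off2 <- run
  run_off2$conversion$states[, "miRs"] <-
    run$conversion$states[, "miRs"] + 1
  expect_equal(sse_term(run_off2, ds), 5, tolerance = 1e-9)
})

test_that("missing anchors are reported with factor and time", {
  ds <- fixture_dataset(sigma = 0)
  ds2 <- ds
  v <- ds2$values
  ds2$values <- v[!(v$factor == "REST" & v$stage == "rest_kd"), ]
  tr <- fixture_truth()
  run <- run_protocol(grn_model(tr$topology, tr$params),
                      canonical_protocol(conversion_hours = 120),
                      dataset = ds)
  expect_error(sse_term(run, ds2), "REST")
})

test_that("smoothness penalty matches curvature oracles", {
  lin <- synthetic_run(function(t, n) 0.3 * t + 2)
  expect_equal(smoothness_penalty(lin, lambda = 1), 0, tolerance = 1e-8)
  quad <- synthetic_run(function(t, n) if (n == "PTB") t^2 else 0 * t)
  # integral of |2| over 120 h
  expect_equal(smoothness_penalty(quad, lambda = 1), 240,
               tolerance = 1e-6)
  expect_equal(smoothness_penalty(quad, lambda = 1 / 20), 12,
               tolerance = 1e-6)
  expect_equal(smoothness_penalty(quad, lambda = 0), 0)
  short <- synthetic_run(function(t, n) t, duration = 48)
  expect_error(smoothness_penalty(short, 1), "shorter")
})

test_that("stability penalty is total variation along the model flow", {
  # single-node relaxation x' = a - d x from x0: integral |x'| dt is the
  # net monotone displacement |x(T) - x0|
  a <- 0.05; d <- 0.1; x0 <- 1
  m <- birth_death_model(a, d)
  tr <- integrate_stage(m, c(X = x0), 72, stage = "fibroblast")
  want <- abs(tail(tr$states[, 1], 1) - x0)
  expect_equal(stability_penalty(tr, m, mu = 1), want, tolerance = 1e-5)
  expect_equal(stability_penalty(tr, m, mu = 0), 0)
  # an exact steady state contributes nothing
  m2 <- birth_death_model(0.5, 0.5)
  tr2 <- integrate_stage(m2, c(X = 1), 72, stage = "fibroblast")
  expect_lt(stability_penalty(tr2, m2, mu = 1), 1e-12)
  # wrong stage is refused
  tr3 <- tr; tr3$stage <- "conversion"
  expect_error(stability_penalty(tr3, m, mu = 1), "fibroblast")
})

test_that("fitness is exactly the negated sum of its three terms", {
  tr <- fixture_truth()
  ds <- fixture_dataset(sigma = 0)
  cfg <- fit_config()
  proto <- canonical_protocol(conversion_hours = 120)
  set.seed(10)
  for (i in 1:5) {
    g <- runif(length(param_names(tr$topology)), 0.2, 1.5)
    f <- ga_fitness(g, tr$topology, ds, proto, cfg)
    p <- decode_genome(g, tr$topology)
    m <- grn_model(tr$topology, p)
    run <- run_protocol(m, proto,
                        init = initial_policy(conversion = "observed"),
                        dataset = ds)
    manual <- -(sse_term(run, ds) +
                  smoothness_penalty(run$conversion, cfg$lambda) +
                  stability_penalty(run$fibroblast, m, cfg$mu))
    expect_equal(f, manual, tolerance = 1e-9)
    # the fast objective used inside the GA agrees too
    obj <- grnconv:::precompute_objective(tr$topology, ds, proto, cfg)
    expect_equal(obj$fitness_fn(g), manual, tolerance = 1e-9)
  }
})

test_that("a diverging genome receives the worst-fitness sentinel", {
  tr <- fixture_truth()
  ds <- fixture_dataset(sigma = 0)
  g <- rep(1e8, length(param_names(tr$topology)))
  f <- ga_fitness(g, tr$topology, ds, config = fit_config())
  expect_true(is.finite(f))
  expect_equal(f, fit_config()$worst_fitness)
})

test_that("adding curvature to a perfect fit strictly lowers fitness", {
  ds <- fixture_dataset(sigma = 0)
  tr <- fixture_truth()
  run <- run_protocol(grn_model(tr$topology, tr$params),
                      canonical_protocol(conversion_hours = 120),
                      init = initial_policy(conversion = "observed"),
                      dataset = ds)
  base <- -(sse_term(run, ds) + smoothness_penalty(run$conversion, 1 / 20))
  wob <- run
  wob$conversion$states[, "PTB"] <- wob$conversion$states[, "PTB"] +
    0.001 * sin(wob$conversion$times)
  wobbled <- -(sse_term(wob, ds) +
                 smoothness_penalty(wob$conversion, 1 / 20))
  expect_lt(wobbled, base)
})
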