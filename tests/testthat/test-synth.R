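test_that("the generating truth passes its qualitative screens", {
  tr <- fixture_truth()
  m <- grn_model(tr$topology, tr$params)
  run <- run_protocol(m, canonical_protocol(),
                      init = initial_policy(conversion = "carry"))
  # near-steady fibroblast stage: < 1% drift per node over 72 h
  fib <- run$fibroblast$states
  expect_lt(max(apply(abs(sweep(fib, 2, fib[1, ])), 2, max)), 0.01)
  # damped fluctuations: a derivative sign change within two days for
  # PTB, RESTc and miRs (the negative-feedback signature)
  conv <- run$conversion$states
  tt <- run$conversion$times
  for (node in c("PTB", "RESTc", "miRs")) {
    d <- diff(conv[tt <= 48, node])
    d <- d[abs(d) > 1e-10]
    expect_gt(sum(diff(sign(d)) != 0), 0)
  }
  # the truth converts: endogenous Ascl1 reaches the detection threshold
  expect_gte(max(conv[, "Ascl1"]), 1)
})

test_that("truth generation is deterministic in its seed and supports the literature control", {
  t1 <- make_paper_like_truth("nptb_ptb", seed = 7)
  t2 <- make_paper_like_truth("nptb_ptb", seed = 7)
  expect_identical(unclass(t1$params), unclass(t2$params))
  lit <- make_paper_like_truth("literature", seed = 7)
  expect_equal(nrow(lit$topology$edges), 7)
  expect_false("beta_PTB" %in% names(lit$params))
})

test_that("noiseless datasets reproduce the trajectory exactly, in triplicate at 10 anchors", {
  tr <- fixture_truth()
  ds <- generate_dataset(tr$topology, tr$params, sigma = 0,
                         shadow_sigma = 0, seed = 1)
  v <- ds$values
  core <- unique(unlist(dataset_binding(ds)))
  expect_setequal(unique(v$factor),
                  c(core, "miR-9", "SCP1"))
  for (fac in unique(v$factor)) {
    cnt <- table(paste(v$stage, v$time_h)[v$factor == fac])
    expect_length(cnt, 10)
    expect_true(all(cnt == 3))
  }
  # replicates are identical at sigma 0 and equal the trajectory sample
  run <- run_protocol(grn_model(tr$topology, tr$params),
                      canonical_protocol(),
                      init = initial_policy(conversion = "carry"))
  med <- dataset_medians(ds)
  for (i in seq_len(nrow(med))) {
    node <- names(which(dataset_binding(ds) == med$factor[i]))
    if (!length(node)) next
    want <- grnconv:::trajectory_at(run[[med$stage[i]]],
                                    med$time_h[i])[[node]]
    expect_equal(med$median[i], unname(want), tolerance = 1e-12)
  }
})

test_that("datasets are reproducible by seed and noise behaves multiplicatively", {
  tr <- fixture_truth()
  d1 <- generate_dataset(tr$topology, tr$params, sigma = 0.1, seed = 5)
  d2 <- generate_dataset(tr$topology, tr$params, sigma = 0.1, seed = 5)
  expect_identical(d1$values, d2$values)
  d3 <- generate_dataset(tr$topology, tr$params, sigma = 0.1, seed = 6)
  expect_false(identical(d1$values, d3$values))
  # Ascl1 is exactly zero at the fibroblast baseline, noise or not
  v <- d1$values
  expect_true(all(v$value[v$factor == "Ascl1" &
                            v$stage == "fibroblast"] == 0))
  expect_true(all(v$value >= 0))
})

test_that("aggregate shadows track their primaries closely", {
  tr <- fixture_truth()
  ds <- generate_dataset(tr$topology, tr$params, sigma = 0.1,
                         shadow_sigma = 0.05, seed = 2)
  med <- dataset_medians(ds)
  key <- function(fac) {
    r <- med[med$factor == fac, ]
    r$median[order(r$stage, r$time_h)]
  }
  expect_gt(cor(key("miR-124"), key("miR-9")), 0.9)
  expect_gt(cor(key("REST"), key("SCP1")), 0.9)
})

test_that("an unstable truth is rejected as a generator input", {
  # far-from-steady parameters: strong production, weak decay
  topo <- grn_topology("X")
  expect_error(generate_dataset(topo, c(alpha_X = 5, delta_X = 0.05)),
               "near-steady")
})

test_that("datasets round-trip losslessly through CSV + YAML and are schema-checked", {
  tr <- fixture_truth()
  ds <- generate_dataset(tr$topology, tr$params, sigma = 0.1, seed = 3)
  path <- tempfile(fileext = ".csv")
  save_dataset(ds, path)
  back <- load_dataset(path)
  expect_equal(back$values$value, ds$values$value, tolerance = 1e-12)
  expect_equal(back$binding, ds$binding)
  expect_equal(back$anchors$time_h, ds$anchors$time_h)
  # dropping an anchor row breaks the schema with a named error
  v <- ds$values
  broken <- v[!(v$factor == "PTB" & v$stage == "rest_kd"), ]
  write.csv(broken, path, row.names = FALSE)
  expect_error(load_dataset(path), "missing anchor")
  # a fourth replicate is refused too
  extra <- rbind(v, v[v$factor == "PTB" & v$stage == "rest_kd", ][1, ])
  write.csv(extra, path, row.names = FALSE)
  expect_error(load_dataset(path), "3 replicates")
})

test_that("the optional viral series is a saturating plateau during conversion only", {
  tr <- fixture_truth()
  ds <- generate_dataset(tr$topology, tr$params, sigma = 0, seed = 1,
                         viral = TRUE)
  v <- ds$values[ds$values$factor == "viral Ascl1", ]
  expect_true(all(v$value[v$stage == "conversion"] >= 1e5))
  expect_true(all(v$value[v$stage != "conversion"] == 0))
})

test_that("the shipped example dataset and model load cleanly", {
  csv <- system.file("extdata", "synthetic_timeseries.csv",
                     package = "grnconv")
  ds <- load_dataset(csv)
  expect_s3_class(ds, "grn_dataset")
  expect_true("viral Ascl1" %in% unique(ds$values$factor))
  sb <- read_sbml(system.file("extdata", "synthetic_nptb_ptb_model.xml",
                              package = "grnconv"))
  expect_s3_class(sb$model, "grn_model")
  expect_equal(nrow(sb$model$topology$edges), 8)
  topo <- read_topology_yaml(system.file("extdata",
                                         "nptb_ptb_topology.yml",
                                         package = "grnconv"))
  expect_setequal(topo$nodes, GRN_NODES)
})
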