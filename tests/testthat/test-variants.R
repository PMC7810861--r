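test_that("exactly 12 single additions exist for the literature base", {
  vars <- enumerate_single_additions(literature_topology())
  expect_length(vars, 12)
  # closed form: 2 * ordered pairs - 2 * occupied pairs
  expect_length(vars, 2 * 4 * 3 - 2 * 6)
  expect_true("nPTB → PTB" %in% names(vars))
  # PTB -| RESTc is excluded because PTB -> RESTc already exists
  expect_false(any(grepl("^PTB . REST$", names(vars))))
  expect_false("PTB ⊣ REST" %in% names(vars))
  # Ascl1 is not an eligible endpoint
  expect_false(any(grepl("Ascl1", names(vars))))
  # deterministic and order-stable
  expect_identical(names(vars),
                   names(enumerate_single_additions(literature_topology())))
})

test_that("each single-addition variant extends the base by its named edge", {
  vars <- enumerate_single_additions(literature_topology())
  for (lab in names(vars)) {
    e <- parse_variant_label(lab)
    topo <- vars[[lab]]
    expect_equal(nrow(topo$edges), 8)
    expect_true(any(topo$edges$source == e$source &
                      topo$edges$target == e$target &
                      topo$edges$sign == e$sign))
  }
})

test_that("variant labels round-trip through the parser", {
  labels <- c("nPTB → PTB",
              "nPTB → REST + PTB",
              "nPTB → REST → PTB",
              "REST ⊣ nPTB → PTB")
  for (lab in labels) {
    edges <- parse_variant_label(lab)
    expect_equal(variant_label(edges), lab)
  }
  # parsed edges name RESTc internally
  e <- parse_variant_label("REST ⊣ nPTB → PTB")
  expect_equal(e$source, c("RESTc", "nPTB"))
  expect_equal(e$target, c("nPTB", "PTB"))
  expect_equal(e$sign, c("inhibition", "activation"))
})

test_that("the named two-interaction variants build and validate", {
  vars <- table2_variants()
  expect_named(vars, c("nPTB → REST + PTB",
                       "nPTB → REST → PTB",
                       "REST ⊣ nPTB → PTB"))
  for (v in vars) expect_equal(nrow(v$edges), 9)
  # a duplicated edge within a pair is rejected
  expect_error(paired_addition_variants(
    literature_topology(),
    list(data.frame(source = c("nPTB", "nPTB"),
                    target = c("PTB", "PTB"),
                    sign = c("activation", "activation")))),
    "duplicate")
})

test_that("family flags expand to the blue and yellow edge blocks", {
  blue <- variant_family(literature_topology(), with_mirs_to_ascl1 = TRUE)
  expect_true(any(blue$edges$source == "miRs" &
                    blue$edges$target == "Ascl1" &
                    blue$edges$sign == "activation"))
  # miRs -> Ascl1 gives Ascl1 an activator, hence a background term
  expect_true("Ascl1" %in% blue$beta_nodes)
  yellow <- variant_family(literature_topology(),
                           with_ptb_nptb_inhibitions = TRUE)
  expect_true(any(yellow$edges$source == "PTB" &
                    yellow$edges$target == "PTB"))
  expect_true(any(yellow$edges$source == "nPTB" &
                    yellow$edges$target == "nPTB"))
  expect_true(any(yellow$edges$source == "nPTB" &
                    yellow$edges$target == "PTB" &
                    yellow$edges$sign == "inhibition"))
  # self-edges stay forbidden outside the flag
  expect_error(variant_family(
    literature_topology(),
    added_edges = data.frame(source = "PTB", target = "PTB",
                             sign = "inhibition")), "self-edge")
  # combining the yellow block with an nPTB -> PTB activation would be a
  # double interaction and is refused
  expect_error(variant_family(nptb_ptb_topology(),
                              with_ptb_nptb_inhibitions = TRUE),
               "double interaction")
})

test_that("comparative fitting ranks variants and is seed-reproducible", {
  tr <- fixture_truth()
  ds <- fixture_dataset(sigma = 0)
  vars <- list(literature = literature_topology(),
               nptb_ptb = tr$topology)
  cfg <- fit_config(pop_size = 16, generations = 4, seed = 77)
  cmp <- compare_models(vars, ds, config = cfg, n_restarts = 2)
  expect_equal(nrow(cmp$results), 4)
  expect_setequal(names(cmp$best), names(vars))
  expect_true(all(diff(cmp$best) <= 0))   # ranked decreasing
  cmp2 <- compare_models(vars, ds, config = cfg, n_restarts = 2)
  expect_equal(cmp$results$fitness, cmp2$results$fitness)
})

test_that("embedding a simpler fit into a larger topology preserves its rate laws", {
  lit <- literature_topology()
  big <- nptb_ptb_topology()
  set.seed(15)
  p <- random_params(lit)
  emb <- embed_params(p, lit, big)
  expect_named(emb, param_names(big), ignore.order = TRUE)
  for (i in 1:20) {
    st <- random_state(lit$nodes)
    a <- ode_rhs(lit, p, c("RESTi", "vAscl1"))(st)
    b <- ode_rhs(big, emb, c("RESTi", "vAscl1"))(st)
    expect_lt(max(abs(a - b)), 1e-3)
  }
  expect_error(embed_params(p, big, lit), "every edge")
})
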