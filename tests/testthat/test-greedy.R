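test_that("leaf-removal rules alone solve the hand-traceable cases", {
  # chain: rules finish without heuristic, certified optimal
  cfg <- approx_min_inputs(chain_net(3), 1, seed = 1)
  expect_true(cfg$certified_optimal)
  expect_equal(cfg$inputs, c(1L, 2L))
  expect_true(verify_input_set(chain_net(3), cfg$inputs, 1))

  # edgeless graph: every node becomes dominating by the source rule
  e <- approx_min_inputs(dnet(integer(), integer(), n = 4), 2, seed = 1)
  expect_equal(e$inputs, 1:4)
  expect_true(e$certified_optimal)
  expect_equal(e$matching$size, 0L)

  # 2-cycle: both cores nonempty, one heuristic step, still one input
  cy <- approx_min_inputs(cycle_net(2), 1, seed = 1)
  expect_equal(length(cy$inputs), 1L)
  expect_false(cy$certified_optimal)
  expect_gte(cy$core$heuristic_steps_used, 1L)

  # complete digraph: heuristic resolves to a single input
  k5 <- approx_min_inputs(complete_net(5), 1, seed = 2)
  expect_equal(length(k5$inputs), 1L)
})

test_that("greedy output always verifies and never beats the optimum", {
  for (s in 1:15) {
    n <- sample(4:8, 1)
    g <- rand_net(n, runif(1, 0.5, 2.2), seed = 400 + s)
    l <- sample(c(1, 2, 3, Inf), 1)
    cfg <- approx_min_inputs(g, l, seed = s)
    expect_true(verify_input_set(g, cfg$inputs, l))
    expect_identical(sort(cfg$inputs), sort(cfg$matching$unmatched_minus))
    bf <- brute_force_min_inputs(g, l)
    expect_gte(length(cfg$inputs), length(bf$inputs))
    if (cfg$certified_optimal)
      expect_equal(length(cfg$inputs), length(bf$inputs))
  }
})

test_that("an empty combined core certifies optimality", {
  for (s in 1:6) {
    g <- rand_net(30, 0.8, seed = 500 + s) # sparse, tree-like
    cfg <- approx_min_inputs(g, 3, seed = s)
    if (cfg$core$combined_core_fraction == 0)
      expect_true(cfg$certified_optimal)
    if (cfg$certified_optimal)
      expect_equal(cfg$core$heuristic_steps_used, 0L)
  }
})

test_that("stalled core size is seed-independent for the coupled scheme", {
  g <- sf_static(300, 4, 3, seed = 42)
  cores <- vapply(1:5, function(s) {
    set.seed(s)
    core_sizes(g, 2, mode = "coupled")$combined_core_fraction
  }, numeric(1))
  expect_equal(length(unique(cores)), 1L)
})

test_that("uncoupled engines reproduce their own guarantees", {
  # Karp-Sipser on a tree-like graph: empty core, maximum matching
  g <- rand_net(40, 0.7, seed = 6)
  mm <- mlr_matching(g, seed = 1)
  expect_equal(attr(mm, "core_edges"), 0)
  expect_equal(mm$size, max_matching(g)$size)

  # matching fallback still reaches a maximal matching on a dense graph
  k <- complete_net(5)
  mk <- mlr_matching(k, seed = 1)
  expect_gte(attr(mk, "core_edges"), 1)
  expect_equal(mk$size, max_matching(k)$size)

  # dominating-set leaf removal yields a dominating set
  for (s in 1:5) {
    gr <- rand_net(25, 1.5, seed = 600 + s)
    for (l in c(1, 2)) {
      ds <- dslr_dominating(gr, l, seed = s)
      expect_true(is_dominating(accessibility_graph(gr, l), ds$set))
    }
  }
  # exact on an empty-core instance: chain G_1 is a tree
  ds <- dslr_dominating(chain_net(9), 1, seed = 1)
  expect_equal(length(ds$set),
               enum_min_dominating(accessibility_graph(chain_net(9), 1)))
})

test_that("core modes expose the matching and domination cores separately", {
  g <- sf_static(200, 5, 3, seed = 8)
  cm <- core_sizes(g, 1, mode = "mlr")
  cc <- core_sizes(g, 1, mode = "coupled")
  cd <- core_sizes(g, 1, mode = "dslr")
  expect_gte(cm$m_core_fraction, 0)
  expect_equal(cc$combined_core_fraction,
               (cc$m_core_fraction + cc$ds_core_fraction) / 2)
  expect_equal(cd$m_core_fraction, 0)
  # percolation contrast at ell = 3: below threshold only an O(1%) residual
  # of rule-immune configurations survives, above it the core is extensive
  g0 <- er_directed(2000, 0.5, seed = 9)
  expect_lt(core_sizes(g0, 3, mode = "coupled")$combined_core_fraction, 0.02)
  g5 <- er_directed(2000, 5, seed = 9)
  expect_gt(core_sizes(g5, 3, mode = "coupled")$combined_core_fraction, 0.1)
})

test_that("the naive union baseline is valid but not better than coupled", {
  for (s in 1:5) {
    g <- rand_net(30, 1.5, seed = 700 + s)
    nv <- naive_input_set(g, 2, seed = s)
    expect_true(verify_input_set(g, nv, 2))
    cfg <- approx_min_inputs(g, 2, seed = s)
    expect_lte(length(cfg$inputs), length(nv))
  }
})
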