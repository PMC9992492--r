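test_that("ER generator places exactly round(n*c) clean links", {
  g <- er_directed(1000, 2, seed = 1)
  expect_equal(n_links(g), 2000L)
  expect_false(has_self_loops(g))
  expect_equal(anyDuplicated(paste(g$from, g$to)), 0L)
  # same seed, same graph; different seed, different graph
  g2 <- er_directed(1000, 2, seed = 1)
  expect_identical(g[c("from", "to")], g2[c("from", "to")])
  g3 <- er_directed(1000, 2, seed = 2)
  expect_false(identical(g[c("from", "to")], g3[c("from", "to")]))
  # c is the mean per-direction degree
  expect_equal(mean(tabulate(g$from, g$n)), 2, tolerance = 1e-9)
  expect_error(er_directed(10, 20), "more links")
})

test_that("ER in-degrees look Poisson(c)", {
  g <- er_directed(20000, 2, seed = 3)
  deg <- tabulate(g$to, g$n)
  expect_equal(mean(deg), 2, tolerance = 0.01)
  expect_equal(var(deg), 2, tolerance = 0.1) # Poisson: variance == mean
  pk <- tabulate(deg + 1, 8) / g$n
  expect_equal(pk, dpois(0:7, 2), tolerance = 0.02)
})

test_that("static scale-free model hits its link count and heavy tail", {
  g <- sf_static(20000, 2, 2.5, seed = 4)
  expect_equal(n_links(g), 40000L)
  expect_false(has_self_loops(g))
  deg <- tabulate(g$from, g$n) + tabulate(g$to, g$n)
  # Hill estimator over the top degrees: tail exponent near gamma
  tail_deg <- sort(deg, decreasing = TRUE)[1:200]
  gamma_hat <- 1 + 1 / mean(log(tail_deg / tail_deg[200]))
  expect_lt(abs(gamma_hat - 2.5), 0.4)
  # the large-gamma limit flattens toward ER: hub sizes become comparable
  gflat <- sf_static(5000, 2, 60, seed = 5)
  ger <- er_directed(5000, 2, seed = 5)
  expect_lt(max(tabulate(gflat$from, 5000)),
            3 * max(tabulate(ger$from, 5000)))
})

test_that("rewiring preserves degree sequences and the trial formula", {
  g <- er_directed(1000, 2, seed = 6)
  r <- rewire_degree_preserving(g, epsilon = 1e-6, seed = 7)
  expect_equal(attr(r, "trials"), ceiling(2000 / 2 * log(1e6))) # 13816
  expect_equal(tabulate(r$from, 1000), tabulate(g$from, 1000))
  expect_equal(tabulate(r$to, 1000), tabulate(g$to, 1000))
  expect_false(identical(paste(g$from, g$to), paste(r$from, r$to)))
  expect_gt(attr(r, "accepted_swaps"), 0)

  # a chain admits no valid swap: frozen
  ch <- chain_net(3)
  rc <- rewire_degree_preserving(ch, seed = 8)
  expect_identical(rc[c("from", "to")], ch[c("from", "to")])
})
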