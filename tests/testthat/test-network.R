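test_that("dnet validates, collapses duplicates and flags self-loops", {
  g <- dnet(c(1, 2), c(2, 3))
  expect_equal(g$n, 3L)
  expect_equal(n_links(g), 2L)
  expect_false(has_self_loops(g))
  expect_warning(gd <- dnet(c(1, 1, 2), c(2, 2, 2)), "duplicate")
  expect_equal(n_links(gd), 2L)
  gs <- dnet(c(1, 2), c(1, 3))
  expect_true(has_self_loops(gs))
  expect_error(dnet(1, 4, n = 3), "exceeds")
  expect_error(dnet(0, 1), "positive")
})

test_that("fixture networks have the expected shapes", {
  expect_equal(n_links(chain_net(15)), 14L)
  expect_equal(n_links(star_net(3)), 3L)
  expect_equal(n_links(complete_net(4)), 12L)
  expect_equal(n_links(cycle_net(2)), 2L)
  expect_equal(toy7_net()$n, 7L)
  expect_equal(source_nodes(chain_net(5)), 1L)
  expect_equal(source_nodes(star_net(3)), 1L)
  expect_equal(length(source_nodes(cycle_net(4))), 0L)
})

test_that("edge list i/o round-trips, keeps labels, reports bad lines", {
  tf <- withr::local_tempfile(fileext = ".edges")
  writeLines(c("# comment", "0 1", "1 2", "", "0 1"), tf)
  expect_warning(g <- read_edgelist(tf), "duplicate")
  expect_equal(g$n, 3L)
  expect_equal(g$labels, c(0L, 1L, 2L)) # 0-based labels remapped to 1..n
  expect_equal(sort(g$from), c(1L, 2L))

  # round trip on a random graph, including isolated trailing nodes
  g2 <- er_directed(30, 1.2, seed = 4)
  tf2 <- withr::local_tempfile(fileext = ".edges")
  write_edgelist(g2, tf2)
  g3 <- read_edgelist(tf2)
  expect_equal(g3$n, g2$n)
  expect_setequal(paste(g3$from, g3$to), paste(g2$from, g2$to))

  tf3 <- withr::local_tempfile(fileext = ".edges")
  writeLines(c("1 2", "3 four"), tf3)
  expect_error(read_edgelist(tf3), "line 2")
})

test_that("bipartite representation mirrors the links", {
  b <- build_bipartite(dnet(c(1, 2), c(2, 3)))
  expect_equal(b$n, 3L)
  expect_setequal(paste(b$plus, b$minus), c("1 2", "2 3"))
  b0 <- build_bipartite(dnet(integer(), integer(), n = 3))
  expect_equal(length(b0$plus), 0L)
  expect_equal(b0$n, 3L)
  # self-loop becomes the (v+, v-) edge
  bs <- build_bipartite(dnet(1, 1))
  expect_equal(paste(bs$plus, bs$minus), "1 1")
})
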