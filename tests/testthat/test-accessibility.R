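test_that("accessibility graph matches the matrix-power oracle", {
  g <- chain_net(3)
  a1 <- accessibility_graph(g, 1)
  expect_setequal(paste(a1$from, a1$to), c("1 2", "2 3"))
  a2 <- accessibility_graph(g, 2)
  expect_setequal(paste(a2$from, a2$to), c("1 2", "1 3", "2 3"))
  expect_error(accessibility_graph(g, 0), "positive")

  for (s in 1:8) {
    gr <- rand_net(8, 1.5, seed = s)
    for (l in c(1, 2, 3, 8)) {
      acc <- accessibility_graph(gr, l)
      R <- reach_oracle(gr, l)
      got <- matrix(FALSE, 8, 8)
      got[cbind(acc$from, acc$to)] <- TRUE
      expect_identical(got, R)
    }
  }
})

test_that("accessibility is monotone in ell and stabilizes at the closure", {
  g <- rand_net(12, 1.4, seed = 2)
  prev <- character(0)
  for (l in 1:12) {
    acc <- accessibility_graph(g, l)
    cur <- paste(acc$from, acc$to)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  accI <- accessibility_graph(g, Inf)
  expect_setequal(paste(accI$from, accI$to), prev)
})

test_that("longest control chain follows the distance definition", {
  # directed path on labels 1, 3, 4, 6, 7 read from an edge list
  tf <- withr::local_tempfile(fileext = ".edges")
  writeLines(c("1 3", "3 4", "4 6", "6 7"), tf)
  g <- read_edgelist(tf)
  expect_equal(longest_control_chain(g, which(g$labels == 1)), 4)
  expect_equal(longest_control_chain(g, seq_len(g$n)), 0)
  iso <- dnet(integer(), integer(), n = 2)
  expect_equal(longest_control_chain(iso, 1), Inf)
  expect_error(longest_control_chain(g, integer()), "empty")
})

test_that("domination on G_ell is equivalent to LCC <= ell (exhaustive)", {
  g <- chain_net(3)
  expect_true(is_dominating(accessibility_graph(g, 2), 1))
  expect_false(is_dominating(accessibility_graph(g, 1), 1))

  for (s in 1:5) {
    gr <- rand_net(6, 1.3, seed = 100 + s)
    for (l in c(1, 2, 6)) {
      acc <- accessibility_graph(gr, l)
      for (mask in 1:(2^6 - 1)) {
        ss <- which(bitwAnd(mask, 2^(0:5)) > 0)
        expect_equal(is_dominating(acc, ss),
                     longest_control_chain(gr, ss) <= l)
      }
    }
  }
})

test_that("closed in-neighborhoods include the node itself", {
  nb <- in_neighborhoods(accessibility_graph(chain_net(3), 1))
  expect_equal(nb[[1]], 1L)
  expect_setequal(nb[[2]], c(2L, 1L))
  expect_setequal(nb[[3]], c(3L, 2L))
})
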