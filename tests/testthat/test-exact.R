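test_that("exhaustive search solves the named cases", {
  expect_equal(length(brute_force_min_inputs(chain_net(8), 2)$inputs), 3L)
  expect_equal(length(brute_force_min_inputs(complete_net(4), 1)$inputs), 1L)
  e <- brute_force_min_inputs(dnet(integer(), integer(), n = 5), 1)
  expect_equal(e$inputs, 1:5)
  expect_error(brute_force_min_inputs(chain_net(13), 1), "n <= 12")
  # every answer is a verified input configuration
  b <- brute_force_min_inputs(toy7_net(), 2)
  expect_true(verify_input_set(toy7_net(), b$inputs, 2))
  expect_true(b$certified_optimal)
})

test_that("exhaustive minimum matches the frozen toy-network table", {
  toy <- toy7_net()
  for (i in seq_len(nrow(toy7_ni_table)))
    expect_equal(length(brute_force_min_inputs(toy, toy7_ni_table$ell[i])$inputs),
                 toy7_ni_table$ni[i])
})

test_that("ILP reproduces chains, stars and degenerate graphs exactly", {
  cfg <- solve_ilp(chain_net(15), 2)
  expect_equal(length(cfg$inputs), 5L) # ceil(15 / 3)
  expect_true(cfg$certified_optimal)
  expect_true(verify_input_set(chain_net(15), cfg$inputs, 2))
  expect_lte(cfg$achieved_lcc, 2)

  expect_equal(length(solve_ilp(dnet(integer(), integer(), n = 1), 3)$inputs), 1L)
  expect_equal(length(solve_ilp(star_net(3), 1)$inputs), 3L)
  expect_equal(length(solve_ilp(complete_net(4), 1)$inputs), 1L)
})

test_that("ILP equals exhaustive search on random digraphs", {
  for (s in 1:10) {
    n <- sample(4:8, 1)
    g <- rand_net(n, runif(1, 0.6, 2), seed = 300 + s)
    l <- sample(1:3, 1)
    bf <- brute_force_min_inputs(g, l)
    ilp <- solve_ilp(g, l)
    expect_equal(length(ilp$inputs), length(bf$inputs))
    expect_true(ilp$certified_optimal)
    expect_true(verify_input_set(g, ilp$inputs, l))
  }
})

test_that("the optimum is nonincreasing in ell and flat beyond n", {
  g <- rand_net(8, 1.3, seed = 77)
  sizes <- vapply(1:8, function(l)
    length(brute_force_min_inputs(g, l)$inputs), integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[8], length(brute_force_min_inputs(g, Inf)$inputs))
  expect_equal(length(solve_ilp(toy7_net(), 7)$inputs),
               length(solve_ilp(toy7_net(), 3)$inputs))
})
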