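test_that("ensemble scan emits a tidy, self-consistent table", {
  tab <- scan_ni("er", n = 80, c_values = c(1, 3), ell_values = c(1, 3),
                 reps = 2, seed = 21)
  expect_equal(nrow(tab), 8L)
  expect_true(all(c("model", "c", "ell", "rep", "n_i", "lower", "upper",
                    "core_fraction", "certified") %in% names(tab)))
  expect_true(all(tab$n_i <= tab$upper + 1e-12))
  expect_true(all(tab$n_i >= 0 & tab$n_i <= 1))
  # denser ensembles need fewer inputs; larger ell never needs more
  m <- tapply(tab$n_i, list(tab$c, tab$ell), mean)
  expect_lt(m["3", "1"], m["1", "1"])
  expect_lte(m["1", "3"], m["1", "1"])
  expect_equal(attr(tab, "provenance")$seed, 21)
})

test_that("LCC cost vanishes on the complete digraph and is positive on chains", {
  k <- cost_of_lcc_fixture <- complete_net(12)
  ni1 <- length(approx_min_inputs(k, 1, seed = 1)$inputs)
  niI <- length(approx_min_inputs(k, Inf, seed = 1)$inputs)
  expect_equal(ni1 - niI, 0L)
  tab <- cost_of_lcc("er", n = 120, c = 2, ell = 1, reps = 3, seed = 22)
  expect_true(all(tab$cost >= -1e-12))
  expect_true(all(is.finite(attr(tab, "summary"))))
})

test_that("rewiring-frozen networks have identical randomized input counts", {
  # the 2-link chain admits no legal swap, so randomization is the identity
  rc <- randomization_comparison(chain_net(3), ell = 1, reps = 3, seed = 23)
  expect_equal(rc$n_i_rand, rc$n_i)
  expect_equal(rc$se, 0)
})

test_that("ER networks are statistically their own randomization", {
  g <- er_directed(300, 1.5, seed = 24)
  rc <- randomization_comparison(g, ell = 2, reps = 5, seed = 25)
  expect_lt(abs(rc$n_i_rand - rc$n_i), 0.04)
})

test_that("core scan reports onsets per mode", {
  sc <- core_percolation_scan("er", n = 3000, c_grid = c(1, 2, 4),
                              reps = 2, seed = 26, mode = "mlr")
  on <- attr(sc, "onset")
  expect_true(is.na(on[["mlr"]]) || on[["mlr"]] >= 2) # no core below c = e
  sc1 <- core_percolation_scan("er", n = 3000, ell_values = 1,
                               c_grid = c(1, 2), reps = 2, seed = 27,
                               mode = "coupled")
  expect_true(all(sc1$core_fraction > 0)) # l = 1 core at any tested c
})

test_that("validation table obeys the solver ordering", {
  v <- validation_delta(model = "er", n = 50, c_values = c(1, 2),
                        gamma_values = NA, ell_values = 1, reps = 2,
                        seed = 28)
  expect_true(all(v$delta >= -1e-12))
  expect_true(all(v$exact_certified))
  expect_true(all(v$delta[v$greedy_certified] == 0))
  expect_equal(nrow(attr(v, "summary")), 2L)
})
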