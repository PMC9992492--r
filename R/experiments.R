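# Scripted ensemble experiments producing tidy tables. Every row carries the
# generating spec; seeds are derived per replicate from the top-level seed so
# runs are reproducible and parallel-safe to subset.

gen_model <- function(model, n, c, gamma, seed) {
  switch(model,
         er = er_directed(n, c, seed = seed),
         sf = sf_static(n, c, gamma, seed = seed),
         stop("unknown model '", model, "'"))
}

rep_seed <- function(seed, i) (as.integer(seed) + 104729L * i) %% 2147483647L

with_provenance <- function(df, seed) {
  attr(df, "provenance") <- list(
    package = "lccontrol",
    version = as.character(utils::packageVersion("lccontrol")),
    seed = seed, date = format(Sys.time(), "%Y-%m-%d"))
  df
}

#' Input fraction scan over model ensembles
#'
#' Measures the minimum input fraction `n_i(l) = N_i(l)/N` (greedy solver)
#' over a grid of average degrees, degree exponents and LCC budgets,
#' together with the matching/domination bounds and the core fraction.
#'
#' @param model `"er"` or `"sf"`.
#' @param n nodes per network.
#' @param c_values average in-degrees to scan.
#' @param gamma_values degree exponents (`"sf"` only; use `NA` for `"er"`).
#' @param ell_values LCC budgets.
#' @param reps networks per grid point.
#' @param seed integer seed.
#' @param bounds also compute [compute_bounds()] per instance (approximate
#'   dominating set for speed).
#' @return A tidy data frame, one row per (grid point, replicate).
#' @export
scan_ni <- function(model, n, c_values, gamma_values = NA, ell_values,
                    reps = 10, seed = 1, bounds = TRUE) {
  grid <- expand.grid(c = c_values, gamma = gamma_values, rep = seq_len(reps),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    gsd <- rep_seed(seed, i)
    g <- gen_model(model, n, grid$c[i], grid$gamma[i], gsd)
    do.call(rbind, lapply(ell_values, function(l) {
      cfg <- approx_min_inputs(g, l, seed = gsd + 1L)
      b <- if (bounds) compute_bounds(g, l, exact_ds = FALSE) else NULL
      data.frame(model = model, n = n, c = grid$c[i], gamma = grid$gamma[i],
                 ell = l, rep = grid$rep[i],
                 n_i = length(cfg$inputs) / n,
                 lower = if (bounds) b$lower / n else NA_real_,
                 upper = if (bounds) b$upper / n else NA_real_,
                 core_fraction = cfg$core$combined_core_fraction,
                 certified = cfg$certified_optimal)
    }))
  })
  with_provenance(do.call(rbind, rows), seed)
}

#' Cost of constraining the longest control chain
#'
#' `C(l) = n_i(l) - n_i(Inf)`: the extra input fraction needed to cap the
#' LCC at `l` relative to the unconstrained minimum (computed at the
#' full-reachability sentinel `ell = n`). Greedy solver, one row per
#' replicate plus mean and standard error in the attributes.
#'
#' @inheritParams scan_ni
#' @param c,gamma model parameters.
#' @param ell LCC budget for the constrained solve.
#' @return Data frame with columns `rep`, `n_i_ell`, `n_i_inf`, `cost`;
#'   `attr(, "summary")` holds the ensemble mean and standard error.
#' @export
cost_of_lcc <- function(model, n, c, gamma = NA, ell = 1, reps = 20,
                        seed = 1) {
  rows <- lapply(seq_len(reps), function(i) {
    gsd <- rep_seed(seed, i)
    g <- gen_model(model, n, c, gamma, gsd)
    ni_l <- length(approx_min_inputs(g, ell, seed = gsd + 1L)$inputs) / n
    ni_inf <- length(approx_min_inputs(g, Inf, seed = gsd + 2L)$inputs) / n
    data.frame(rep = i, n_i_ell = ni_l, n_i_inf = ni_inf,
               cost = ni_l - ni_inf)
  })
  out <- with_provenance(do.call(rbind, rows), seed)
  attr(out, "summary") <- c(mean = mean(out$cost),
                            se = sd(out$cost) / sqrt(reps))
  out
}

#' Input counts of a network versus its degree-preserving randomization
#'
#' Measures `n_i(l)` for a network and for an ensemble of its
#' degree-preserving rewirings, isolating what the degree sequence alone
#' explains.
#'
#' @param g a [dnet] object.
#' @param ell LCC budget.
#' @param epsilon rewiring mixing parameter, see
#'   [rewire_degree_preserving()].
#' @param reps randomized copies.
#' @param seed integer seed.
#' @return List with `n_i`, `n_i_rand` (mean), `se`, and the per-replicate
#'   vector `rand_values`.
#' @export
randomization_comparison <- function(g, ell, epsilon = 1e-6, reps = 20,
                                     seed = 1) {
  n_i <- length(approx_min_inputs(g, ell, seed = seed)$inputs) / g$n
  vals <- vapply(seq_len(reps), function(i) {
    gr <- rewire_degree_preserving(g, epsilon, seed = rep_seed(seed, i))
    length(approx_min_inputs(gr, ell, seed = rep_seed(seed, i) + 1L)$inputs) / g$n
  }, numeric(1))
  list(n_i = n_i, n_i_rand = mean(vals), se = sd(vals) / sqrt(reps),
       rand_values = vals)
}

#' Core percolation scan
#'
#' Relative core size at the leaf-removal stall as a function of the average
#' degree, with an onset estimate `c*`: the smallest scanned `c` whose
#' ensemble-mean core fraction exceeds `floor`. Modes as in [core_sizes()]
#' (`"mlr"` for the matching core alone, `"coupled"` for the joint scheme).
#'
#' @inheritParams scan_ni
#' @param c_grid average-degree grid (give a 0.1-spaced grid for onset
#'   estimates at that resolution).
#' @param mode which core to measure.
#' @param floor onset detection floor for the mean core fraction.
#' @return Data frame of per-instance core fractions; `attr(, "onset")`
#'   holds the estimated `c*` per `ell`.
#' @export
core_percolation_scan <- function(model, n, ell_values = 1, c_grid,
                                  gamma_values = NA, reps = 3, seed = 1,
                                  mode = c("coupled", "mlr", "dslr"),
                                  floor = 1e-3) {
  mode <- match.arg(mode)
  grid <- expand.grid(c = c_grid, gamma = gamma_values, rep = seq_len(reps),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- gen_model(model, n, grid$c[i], grid$gamma[i], rep_seed(seed, i))
    do.call(rbind, lapply(if (mode == "mlr") ell_values[1] else ell_values,
                          function(l) {
      cr <- core_sizes(g, l, mode = mode)
      data.frame(model = model, n = n, c = grid$c[i], gamma = grid$gamma[i],
                 ell = if (mode == "mlr") NA else l, rep = grid$rep[i],
                 m_core = cr$m_core_fraction, ds_core = cr$ds_core_fraction,
                 core_fraction = cr$combined_core_fraction)
    }))
  })
  out <- with_provenance(do.call(rbind, rows), seed)
  ell_key <- ifelse(is.na(out$ell), "mlr", as.character(out$ell))
  onset <- vapply(split(out, ell_key), function(d) {
    m <- tapply(d$core_fraction, d$c, mean)
    cs <- as.numeric(names(m))
    hit <- which(m > floor)
    if (length(hit)) cs[min(hit)] else NA_real_
  }, numeric(1))
  attr(out, "onset") <- onset
  out
}

#' Greedy-versus-exact validation
#'
#' Generates model ensembles small enough for the exact solver and tabulates
#' the excess input fraction `delta = n_i_approx(l) - n_i_exact(l)` of the
#' coupled leaf-removal approximation against the certified ILP optimum.
#'
#' @inheritParams scan_ni
#' @param time_limit per-batch ILP time limit (seconds).
#' @return Data frame with per-instance `delta` and core/certification
#'   columns; `attr(, "summary")` holds mean `delta` per `(c, ell)` grid
#'   point.
#' @export
validation_delta <- function(model = "sf", n = 300, c_values = 1:8,
                             gamma_values = 3, ell_values = 1:3, reps = 10,
                             seed = 1, time_limit = 120) {
  grid <- expand.grid(c = c_values, gamma = gamma_values,
                      stringsAsFactors = FALSE)
  rows <- list()
  idx <- 0L
  for (i in seq_len(nrow(grid))) {
    graphs <- lapply(seq_len(reps), function(r) {
      idx <<- idx + 1L
      gen_model(model, n, grid$c[i], grid$gamma[i], rep_seed(seed, idx))
    })
    for (l in ell_values) {
      exact <- solve_ilp_batch(graphs, l, time_limit = time_limit)
      for (r in seq_len(reps)) {
        cfg <- approx_min_inputs(graphs[[r]], l,
                                 seed = rep_seed(seed, idx + r) + 7L)
        rows[[length(rows) + 1]] <- data.frame(
          model = model, n = n, c = grid$c[i], gamma = grid$gamma[i],
          ell = l, rep = r,
          n_exact = length(exact[[r]]$inputs) / n,
          n_approx = length(cfg$inputs) / n,
          delta = (length(cfg$inputs) - length(exact[[r]]$inputs)) / n,
          exact_certified = exact[[r]]$certified_optimal,
          greedy_certified = cfg$certified_optimal,
          core_fraction = cfg$core$combined_core_fraction)
      }
    }
  }
  out <- with_provenance(do.call(rbind, rows), seed)
  agg <- stats::aggregate(
    out$delta,
    by = list(c = out$c, gamma = ifelse(is.na(out$gamma), "-",
                                        as.character(out$gamma)),
              ell = out$ell),
    FUN = mean)
  names(agg)[names(agg) == "x"] <- "delta"
  attr(out, "summary") <- agg
  out
}
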