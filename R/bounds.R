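#' Matching and domination bounds on the minimum input count
#'
#' Lower bound: the inputs are unmatched in some matching and dominate the
#' accessibility graph, so their number is at least `min(N_M, N_DS)`, with
#' `N_M` the unmatched count of a maximum matching and `N_DS` the minimum
#' dominating set size of `G_l`. Upper bound: a maximum matching and a
#' dominating set found independently combine into a feasible input set
#' (unmatching the dominated-but-matched nodes keeps a valid matching),
#' giving `N_M + N_DS - N_s` after discounting the source nodes counted by
#' both sides.
#'
#' @param g a [dnet] object.
#' @param ell LCC budget (positive integer or `Inf`).
#' @param exact_ds solve the minimum dominating set exactly (set-cover ILP);
#'   default for graphs up to 2000 nodes. With the leaf-removal
#'   approximation instead, `N_DS` overestimates the minimum and the lower
#'   bound is only indicative.
#' @param time_limit ILP time limit (seconds) when `exact_ds` is `TRUE`.
#' @return A `bound_report`: `n_m`, `n_ds`, `ds_exact`, `n_sources`,
#'   `lower`, `upper`.
#' @examples
#' \donttest{compute_bounds(chain_net(15), ell = 2)  # lower 1, upper 5}
#' @export
compute_bounds <- function(g, ell, exact_ds = NULL, time_limit = 60) {
  stopifnot(inherits(g, "dnet"))
  if (is.null(exact_ds)) exact_ds <- g$n <= 2000
  n_m <- g$n - max_matching(g)$size
  acc <- accessibility_graph(g, ell)
  if (exact_ds) {
    ds <- min_dominating_exact(acc, time_limit = time_limit)
    n_ds <- length(ds$set)
    ds_exact <- ds$exact
  } else {
    res <- cpp_dslr(g$n, acc$from, acc$to, TRUE)
    n_ds <- length(res$dominating)
    ds_exact <- FALSE
  }
  n_s <- length(source_nodes(g))
  structure(list(n = g$n, ell = ell, n_m = n_m, n_ds = n_ds,
                 ds_exact = ds_exact, n_sources = n_s,
                 lower = min(n_m, n_ds), upper = n_m + n_ds - n_s),
            class = "bound_report")
}

#' @export
print.bound_report <- function(x, ...) {
  cat(sprintf(
    "<bound_report> l = %s: N_M = %d, N_DS = %d%s, N_s = %d -> %d <= N_i <= %d%s\n",
    format(x$ell), x$n_m, x$n_ds, if (x$ds_exact) "" else " (approx)",
    x$n_sources, x$lower, x$upper,
    if (x$ds_exact) "" else " (lower bound indicative only)"))
  invisible(x)
}
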