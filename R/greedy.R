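# Coupled leaf-removal approximation and core-percolation measurements.

new_core_report <- function(mode, ell, m_core, ds_core, m_edges, g_edges,
                            steps) {
  frac <- function(core, total) if (total > 0) core / total else 0
  m_frac <- frac(m_core, m_edges)
  ds_frac <- frac(ds_core, g_edges)
  combined <- switch(mode,
                     mlr = m_frac,
                     dslr = ds_frac,
                     (m_frac + ds_frac) / 2)
  structure(list(mode = mode, ell = ell,
                 m_core_edges = as.integer(m_core),
                 ds_core_edges = as.integer(ds_core),
                 m_core_fraction = m_frac, ds_core_fraction = ds_frac,
                 combined_core_fraction = combined,
                 heuristic_steps_used = as.integer(steps)),
            class = "core_report")
}

#' @export
print.core_report <- function(x, ...) {
  cat(sprintf(
    "<core_report> %s, l = %s: M-core %d edges (%.4g), DS-core %d edges (%.4g), combined %.4g\n",
    x$mode, format(x$ell), x$m_core_edges, x$m_core_fraction,
    x$ds_core_edges, x$ds_core_fraction, x$combined_core_fraction))
  invisible(x)
}

#' Approximate minimum input set by coupled leaf removal
#'
#' Greedy approximation of the LCC-constrained minimum input problem:
#' matching leaf removal on the bipartite representation and dominating-set
#' leaf removal on the accessibility graph are applied jointly, each rule
#' constrained so it is locally optimal for both problems, with
#' cross-updates (an isolated minus copy forces an input; a dominating node
#' frees its minus copy from the matching). If the rules exhaust both edge
#' sets the solution is provably optimal; otherwise the remaining edges form
#' the M-core and DS-core and heuristic fallback steps are taken: match the
#' minus copy of the node with the least live accessibility degree, or --
#' once the bipartite graph is empty -- commit the highest-degree node as
#' dominating.
#'
#' For the full-reachability sentinel (`ell >= n`, including `Inf`) the
#' engine runs on a domination-equivalent reduction of the transitive
#' closure (reachability edges out of source strongly connected components
#' only); feasible input sets and optima are identical, and certified
#' results remain certified.
#'
#' @param g a [dnet] object.
#' @param ell LCC budget (positive integer or `Inf`).
#' @param seed optional integer seed for tie-breaking randomness.
#' @param heuristic_degree degree key for the fallback: the node's total
#'   degree in the `"original"` accessibility graph (default; measurably
#'   closer to the exact optimum) or in the `"live"` reduced one.
#' @return An `input_config` whose `core` field is a `core_report`;
#'   `certified_optimal` is `TRUE` iff no heuristic step fired.
#' @examples
#' approx_min_inputs(chain_net(15), ell = 2)  # 5 inputs, certified
#' @export
approx_min_inputs <- function(g, ell, seed = NULL,
                              heuristic_degree = c("original", "live")) {
  stopifnot(inherits(g, "dnet"))
  heuristic_degree <- match.arg(heuristic_degree)
  if (!is.null(seed)) set.seed(seed)
  acc <- domination_graph(g, ell)
  res <- cpp_coupled(g$n, g$from, g$to, acc$from, acc$to, TRUE,
                     key_original = heuristic_degree == "original")
  core <- new_core_report("coupled", ell, res$b_core_edges, res$g_core_edges,
                          n_links(g), length(acc$from), res$heuristic_steps)
  new_input_config(g, ell, res$inputs,
                   cbind(from = res$match_from, to = res$match_to),
                   "greedy", certified = res$heuristic_steps == 0,
                   core = core)
}

#' Core sizes at the leaf-removal stall
#'
#' Runs the deterministic leaf-removal rules only (no heuristic fallback)
#' and reports the edges remaining when no rule can fire. An empty core
#' certifies that the greedy solution is optimal. Modes: `"coupled"` (the
#' joint scheme), `"mlr"` (Karp-Sipser matching rules alone, on the
#' bipartite representation; `ell` is ignored), `"dslr"` (dominating-set
#' rules alone, on the accessibility graph).
#'
#' @param g a [dnet] object.
#' @param ell LCC budget (used by modes `"coupled"` and `"dslr"`).
#' @param mode which rule set to stall.
#' @return A `core_report`.
#' @export
core_sizes <- function(g, ell = 1, mode = c("coupled", "mlr", "dslr")) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "dnet"))
  if (mode == "mlr") {
    res <- cpp_mlr(g$n, g$from, g$to, FALSE)
    return(new_core_report("mlr", NA, res$b_core_edges, 0, n_links(g), 0,
                           res$heuristic_steps))
  }
  acc <- accessibility_graph(g, ell)
  res <- if (mode == "coupled")
    cpp_coupled(g$n, g$from, g$to, acc$from, acc$to, FALSE)
  else cpp_dslr(g$n, acc$from, acc$to, FALSE)
  new_core_report(mode, ell, res$b_core_edges, res$g_core_edges,
                  n_links(g), length(acc$from), res$heuristic_steps)
}

#' Uncoupled leaf-removal baselines
#'
#' The two constituent greedy engines run on their own: Karp-Sipser matching
#' leaf removal with a random-link fallback ([mlr_matching()]), and
#' dominating-set leaf removal with a highest-degree fallback
#' ([dslr_dominating()]). Useful as core-percolation baselines and for
#' approximate bounds.
#'
#' @param g a [dnet] object.
#' @param seed optional integer seed.
#' @return [mlr_matching()]: an `lcc_matching` plus core attributes;
#'   [dslr_dominating()]: list with `set`, `core_edges`, `heuristic_steps`.
#' @export
mlr_matching <- function(g, seed = NULL) {
  stopifnot(inherits(g, "dnet"))
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_mlr(g$n, g$from, g$to, TRUE)
  out <- structure(list(
    n = g$n,
    matched_links = cbind(from = res$match_from, to = res$match_to),
    unmatched_minus = res$inputs, size = length(res$match_from)),
    class = "lcc_matching")
  attr(out, "core_edges") <- res$b_core_edges
  attr(out, "heuristic_steps") <- res$heuristic_steps
  out
}

#' @rdname mlr_matching
#' @param ell LCC budget defining the accessibility graph.
#' @export
dslr_dominating <- function(g, ell, seed = NULL) {
  stopifnot(inherits(g, "dnet"))
  if (!is.null(seed)) set.seed(seed)
  acc <- accessibility_graph(g, ell)
  res <- cpp_dslr(g$n, acc$from, acc$to, TRUE)
  list(set = res$dominating, core_edges = res$g_core_edges,
       heuristic_steps = res$heuristic_steps)
}

#' Naive two-stage baseline
#'
#' The union of the unmatched nodes of a maximum matching and a dominating
#' set of the accessibility graph found independently. Always a valid input
#' set, but typically far from minimal -- the comparator that the coupled
#' scheme is designed to beat.
#'
#' @inheritParams approx_min_inputs
#' @param exact_ds use the exact set-cover ILP for the dominating set
#'   (otherwise leaf-removal approximation).
#' @return integer vector of input node ids.
#' @export
naive_input_set <- function(g, ell, exact_ds = FALSE, seed = NULL) {
  mm <- max_matching(g)
  ds <- if (exact_ds) min_dominating_exact(accessibility_graph(g, ell))$set
        else dslr_dominating(g, ell, seed = seed)$set
  sort(union(mm$unmatched_minus, ds))
}
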