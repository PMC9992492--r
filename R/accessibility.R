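#' l-step accessibility graph
#'
#' The accessibility graph `G_l` links `v -> w` whenever a directed path of
#' at most `l` steps leads from `v` to `w` in the original network (`v != w`;
#' self-coverage is handled through closed neighborhoods, so `G_l` carries no
#' self-loops even when a node lies on a short cycle). `ell = Inf` is a
#' sentinel for full reachability and maps to `ell = n`, the longest possible
#' simple path.
#'
#' @param g a [dnet] object.
#' @param ell positive integer path-length budget, or `Inf`.
#' @return An object of class `acc_net` with fields `n`, `ell`, `ell_eff`,
#'   `from`, `to`.
#' @examples
#' accessibility_graph(chain_net(3), 2)
#' @export
accessibility_graph <- function(g, ell) {
  stopifnot(inherits(g, "dnet"))
  if (!is.numeric(ell) || length(ell) != 1 || is.na(ell) || ell < 1)
    stop("ell must be a positive integer (or Inf)")
  ell_eff <- as.integer(min(ell, g$n))
  keep <- g$from != g$to
  acc <- cpp_access_edges(g$n, g$from[keep], g$to[keep], ell_eff)
  structure(list(n = g$n, ell = ell, ell_eff = ell_eff,
                 from = acc$from, to = acc$to), class = "acc_net")
}

#' @export
print.acc_net <- function(x, ...) {
  cat(sprintf("<acc_net> l = %s: %d nodes, %d links\n",
              format(x$ell), x$n, length(x$from)))
  invisible(x)
}

# Domination-equivalent stand-in for the accessibility graph, reduced when
# ell covers full reachability: dominating the transitive closure is
# equivalent to hitting every source strongly connected component (every
# node is reachable from some source SCC, and source SCCs have no external
# in-links), so only the reachability edges out of source-SCC members are
# kept. Feasible input sets -- and hence optima -- are unchanged, while the
# edge count drops by orders of magnitude on supercritical networks.
domination_graph <- function(g, ell) {
  if (ell < g$n) return(accessibility_graph(g, ell))
  ig <- igraph::graph_from_edgelist(cbind(g$from, g$to), directed = TRUE)
  if (igraph::vcount(ig) < g$n)
    ig <- igraph::add_vertices(ig, g$n - igraph::vcount(ig))
  comp <- igraph::components(ig, mode = "strong")$membership
  has_ext_in <- tapply(comp[g$from] != comp[g$to], comp[g$to], any)
  src_comp <- setdiff(seq_len(max(comp)),
                      as.integer(names(has_ext_in))[unlist(has_ext_in)])
  src_nodes <- which(comp %in% src_comp)
  keep <- g$from != g$to
  red <- cpp_reach_edges(g$n, g$from[keep], g$to[keep], src_nodes)
  structure(list(n = g$n, ell = ell, ell_eff = as.integer(g$n),
                 from = red$from, to = red$to, reduced = TRUE),
            class = "acc_net")
}

#' Closed in-neighborhoods of an accessibility graph
#'
#' For each node `v`, the set `{v} union {u : (u -> v) in G_l}` -- the nodes
#' whose selection as inputs covers `v`. These sets define both the
#' domination test and the covering constraints of the exact solver.
#'
#' @param acc an `acc_net` object.
#' @return A list of integer vectors, one per node (the node itself first).
#' @export
in_neighborhoods <- function(acc) {
  nb <- split(acc$from, factor(acc$to, levels = seq_len(acc$n)))
  lapply(seq_len(acc$n), function(v) c(v, nb[[v]]))
}

#' Longest control chain of an input placement
#'
#' The maximum over nodes of the shortest-path distance from the nearest
#' input node; `Inf` if some node is unreachable. An empty input set has no
#' defined LCC and is an error.
#'
#' @param g a [dnet] object.
#' @param inputs nonempty set of input node ids.
#' @examples
#' longest_control_chain(chain_net(5), 1)  # 4
#' @export
longest_control_chain <- function(g, inputs) {
  inputs <- unique(as.integer(inputs))
  if (!length(inputs)) stop("LCC is undefined for an empty input set")
  stopifnot(all(inputs >= 1), all(inputs <= g$n))
  if (g$n == 0) return(0)
  d <- cpp_multisource_dist(g$n, g$from, g$to, inputs)
  if (any(d < 0)) Inf else max(d)
}

#' Domination test on an accessibility graph
#'
#' `s` dominates `G_l` iff every node is in `s` or has an in-neighbor in `s`;
#' equivalently, iff the longest control chain of `s` is at most `l`.
#'
#' @param acc an `acc_net` object.
#' @param s candidate input node set.
#' @export
is_dominating <- function(acc, s) {
  s <- unique(as.integer(s))
  covered <- logical(acc$n)
  covered[s] <- TRUE
  covered[acc$to[acc$from %in% s]] <- TRUE
  all(covered)
}
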