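#' Bipartite representation of a directed network
#'
#' Splits every node `v` into copies `v+` and `v-`; each directed link
#' `(v -> w)` becomes the undirected edge `(v+, w-)`, so directed matchings
#' of the network are exactly bipartite matchings of the representation.
#'
#' @param g a [dnet] object.
#' @return An object of class `bipartite_rep` with fields `n`, `plus`,
#'   `minus` (edge endpoints as original node ids).
#' @export
build_bipartite <- function(g) {
  stopifnot(inherits(g, "dnet"))
  structure(list(n = g$n, plus = g$from, minus = g$to),
            class = "bipartite_rep")
}

#' @export
print.bipartite_rep <- function(x, ...) {
  cat(sprintf("<bipartite_rep> %d + %d node copies, %d edges\n",
              x$n, x$n, length(x$plus)))
  invisible(x)
}

#' Maximum directed matching
#'
#' Maximum-cardinality matching of the bipartite representation, optionally
#' with some minus copies excluded (their nodes are then forced unmatched --
#' the certificate needed when a candidate input set is verified). The
#' cardinality is unique; the matched link set is whichever optimum the
#' solver returns.
#'
#' @param g a [dnet] or [build_bipartite()] object.
#' @param forbidden_minus node ids whose `v-` copy may not be matched.
#' @return An object of class `lcc_matching`: `matched_links` (two-column
#'   matrix of directed links), `unmatched_minus` (nodes with no matched
#'   incoming link), `size`.
#' @examples
#' max_matching(chain_net(3))  # two links matched, node 1 unmatched
#' @export
max_matching <- function(g, forbidden_minus = integer()) {
  if (inherits(g, "bipartite_rep"))
    g <- dnet(g$plus, g$minus, n = g$n)
  stopifnot(inherits(g, "dnet"))
  forbidden_minus <- unique(as.integer(forbidden_minus))
  n <- g$n
  if (n == 0 || !length(g$from)) {
    return(structure(list(
      n = n, matched_links = cbind(from = integer(), to = integer()),
      unmatched_minus = seq_len(n), size = 0L), class = "lcc_matching"))
  }
  bg <- as_igraph_bipartite(g, forbidden_minus)
  mm <- igraph::max_bipartite_match(
    bg, types = rep(c(FALSE, TRUE), each = n))$matching
  partner <- mm[n + seq_len(n)]  # plus partner of each v-, NA if unmatched
  matched <- which(!is.na(partner))
  structure(list(
    n = n,
    matched_links = cbind(from = as.integer(partner[matched]),
                          to = as.integer(matched)),
    unmatched_minus = which(is.na(partner)),
    size = length(matched)), class = "lcc_matching")
}

#' @export
print.lcc_matching <- function(x, ...) {
  cat(sprintf("<lcc_matching> %d matched links, %d unmatched nodes\n",
              x$size, length(x$unmatched_minus)))
  invisible(x)
}

#' Verify a candidate input set
#'
#' A node set `s` is a valid input set for LCC budget `l` iff (a) the
#' bipartite representation restricted to the minus copies outside `s` has a
#' matching saturating all of them (so some matching's unmatched set is
#' exactly `s`), and (b) `s` dominates the accessibility graph `G_l`.
#'
#' @param g a [dnet] object.
#' @param s candidate input node ids.
#' @param ell LCC budget (positive integer or `Inf`).
#' @return `TRUE`/`FALSE` with attribute `diagnostics` naming the violated
#'   condition(s) and carrying the certifying matching when valid.
#' @export
verify_input_set <- function(g, s, ell) {
  s <- unique(as.integer(s))
  stopifnot(all(s >= 1 & s <= g$n))
  mm <- max_matching(g, forbidden_minus = s)
  matching_ok <- mm$size == g$n - length(s)
  acc <- accessibility_graph(g, ell)
  domination_ok <- is_dominating(acc, s)
  out <- matching_ok && domination_ok
  attr(out, "diagnostics") <- list(
    matching_ok = matching_ok, domination_ok = domination_ok,
    matching = mm,
    failed = c(if (!matching_ok) "matching", if (!domination_ok) "domination"))
  out
}
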