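# Exhaustive-search oracle for small instances.
#
# Independent of the main solving paths on purpose: matchability is decided
# by a self-contained augmenting-path routine (not igraph), domination by
# direct coverage accumulation, so the oracle can cross-check both the ILP
# and the greedy solver.

# Kuhn's augmenting-path matching restricted to the minus copies in `keep`.
# pred[[v]] lists the candidate plus partners of v- (links u -> v).
# Returns NULL if some kept minus copy cannot be saturated, otherwise the
# plus -> minus assignment vector.
kuhn_saturate <- function(n, pred, keep) {
  match_plus <- integer(n) # plus u -> minus v, 0 = free
  visited <- logical(n)
  aug <- function(v) {
    for (u in pred[[v]]) {
      if (!visited[u]) {
        visited[u] <<- TRUE
        if (match_plus[u] == 0L || aug(match_plus[u])) {
          match_plus[u] <<- v
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (v in keep) {
    visited[] <- FALSE
    if (!aug(v)) return(NULL)
  }
  match_plus
}

# maximum matching cardinality by the same routine (greedy augmentation
# over all minus copies)
kuhn_max_size <- function(n, pred) {
  match_plus <- integer(n)
  visited <- logical(n)
  aug <- function(v) {
    for (u in pred[[v]]) {
      if (!visited[u]) {
        visited[u] <<- TRUE
        if (match_plus[u] == 0L || aug(match_plus[u])) {
          match_plus[u] <<- v
          return(TRUE)
        }
      }
    }
    FALSE
  }
  size <- 0L
  for (v in seq_len(n)) {
    visited[] <- FALSE
    if (aug(v)) size <- size + 1L
  }
  size
}

#' Exact minimum input set by exhaustive search
#'
#' Enumerates candidate input sets by increasing size and returns the first
#' one that passes both the matching and the domination condition.
#' Guaranteed optimal; guarded to `n <= 12` nodes. Source nodes (zero
#' in-degree) are forced into every candidate, and enumeration starts at the
#' number of unmatched nodes of a maximum matching, both of which are
#' necessary.
#'
#' @param g a [dnet] object with at most 12 nodes.
#' @param ell LCC budget (positive integer or `Inf`).
#' @return An `input_config` object with `method = "brute"`.
#' @export
brute_force_min_inputs <- function(g, ell) {
  stopifnot(inherits(g, "dnet"))
  if (g$n > 12) stop("exhaustive search is guarded to n <= 12 nodes")
  n <- g$n
  if (n == 0)
    return(new_input_config(g, ell, integer(),
                            cbind(from = integer(), to = integer()),
                            "brute", TRUE))
  pred <- split(g$from, factor(g$to, levels = seq_len(n)))
  acc <- accessibility_graph(g, ell)
  covers <- split(acc$to, factor(acc$from, levels = seq_len(n)))
  forced <- source_nodes(g)
  free <- setdiff(seq_len(n), forced)
  k_min <- max(length(forced), n - kuhn_max_size(n, pred), 1L)
  for (k in k_min:n) {
    extra <- k - length(forced)
    if (extra < 0 || extra > length(free)) next
    cand <- if (extra == 0) matrix(integer(), nrow = 0, ncol = 1)
            else combn(free, extra)
    for (j in seq_len(max(ncol(cand), if (extra == 0) 1 else 0))) {
      s <- c(forced, if (extra > 0) cand[, j])
      covered <- logical(n)
      covered[s] <- TRUE
      covered[unlist(covers[s], use.names = FALSE)] <- TRUE
      if (!all(covered)) next
      mp <- kuhn_saturate(n, pred, setdiff(seq_len(n), s))
      if (is.null(mp)) next
      matched_plus <- which(mp > 0L)
      matched <- cbind(from = matched_plus, to = mp[matched_plus])
      return(new_input_config(g, ell, s, matched, "brute", TRUE))
    }
  }
  new_input_config(g, ell, seq_len(n),
                   cbind(from = integer(), to = integer()), "brute", TRUE)
}
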