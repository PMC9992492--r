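#' Simple directed network
#'
#' Container for an unweighted simple digraph on nodes `1..n`. Duplicate
#' links are collapsed with a warning; self-loops are kept (they are
#' matchable under structural controllability) and flagged.
#'
#' @param from,to integer vectors of link endpoints (`from[k] -> to[k]`).
#' @param n node count; defaults to the largest endpoint.
#' @return An object of class `dnet` with fields `n`, `from`, `to`.
#' @examples
#' g <- dnet(c(1, 2), c(2, 3))
#' g
#' @export
dnet <- function(from, to, n = NULL) {
  from <- as.integer(from)
  to <- as.integer(to)
  stopifnot(length(from) == length(to))
  if (length(from) && (anyNA(from) || anyNA(to) || min(from, to) < 1L))
    stop("links must reference positive integer node ids")
  n <- if (is.null(n)) max(0L, from, to) else as.integer(n)
  if (length(from) && max(from, to) > n)
    stop("link endpoint exceeds node count n = ", n)
  key <- (as.double(from) - 1) * max(n, 1L) + as.double(to)
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate link(s)", sum(dup)))
    from <- from[!dup]
    to <- to[!dup]
  }
  structure(list(n = n, from = from, to = to), class = "dnet")
}

#' @export
print.dnet <- function(x, ...) {
  nl <- sum(x$from == x$to)
  cat(sprintf("<dnet> %d nodes, %d links%s\n", x$n, length(x$from),
              if (nl) sprintf(" (%d self-loop%s)", nl, if (nl > 1) "s" else "")
              else ""))
  invisible(x)
}

#' Number of links of a directed network
#' @param g a [dnet] object.
#' @export
n_links <- function(g) length(g$from)

#' @rdname n_links
#' @export
has_self_loops <- function(g) any(g$from == g$to)

in_degrees <- function(g) tabulate(g$to, g$n)
out_degrees <- function(g) tabulate(g$from, g$n)

#' Source nodes (zero in-degree)
#'
#' Sources are forced inputs: their minus copy in the bipartite
#' representation is isolated, so they are always unmatched, and nothing can
#' dominate them but themselves.
#' @param g a [dnet] object.
#' @export
source_nodes <- function(g) which(in_degrees(g) == 0L)

#' Read and write plain-text edge lists
#'
#' The format is one whitespace-separated `source target` pair per line;
#' lines starting with `#` are comments. Arbitrary integer labels are
#' remapped to contiguous ids `1..n` (the original labels are kept in the
#' `labels` field and restored on write). A `# n <count>` comment, written by
#' [write_edgelist()], preserves isolated trailing nodes across a round trip.
#'
#' @param path file path.
#' @return [read_edgelist()] returns a [dnet]; [write_edgelist()] returns
#'   `path` invisibly.
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path)
  n_declared <- NA_integer_
  hdr <- grep("^#\\s*n\\s+[0-9]+", lines, value = TRUE)
  if (length(hdr))
    n_declared <- as.integer(sub("^#\\s*n\\s+([0-9]+).*", "\\1", hdr[1]))
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(toks, function(t)
    length(t) != 2L || anyNA(suppressWarnings(as.integer(t))), logical(1)))
  if (length(bad))
    stop(sprintf("malformed edge list line %d: '%s'", idx[bad[1]],
                 lines[idx[bad[1]]]))
  uv <- matrix(as.integer(unlist(toks)), ncol = 2, byrow = TRUE)
  labels <- sort(unique(as.vector(uv)))
  if (!is.na(n_declared) && length(labels) &&
      min(labels) >= 1L && max(labels) <= n_declared) {
    # header-declared node count with in-range ids: keep ids verbatim
    return(dnet(uv[, 1], uv[, 2], n = n_declared))
  }
  n <- max(length(labels), n_declared, 0L, na.rm = TRUE)
  g <- dnet(match(uv[, 1], labels), match(uv[, 2], labels), n = n)
  if (length(labels) && !identical(labels, seq_len(n)))
    g$labels <- labels
  g
}

#' @rdname read_edgelist
#' @param g a [dnet] object.
#' @export
write_edgelist <- function(g, path) {
  lab <- if (is.null(g$labels)) seq_len(g$n) else g$labels
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n %d", g$n), con)
  if (length(g$from))
    writeLines(paste(lab[g$from], lab[g$to]), con)
  invisible(path)
}

#' Deterministic fixture networks
#'
#' Small named networks used throughout the examples and tests: a directed
#' chain, a star pointing from its hub to `k` leaves, the 2-cycle, the
#' complete digraph, and a 7-node toy whose minimum inputs rearrange (and
#' grow by one) when the longest control chain is capped at two.
#'
#' @param n,k node/leaf counts.
#' @export
chain_net <- function(n) {
  if (n < 1) stop("n >= 1 required")
  if (n == 1) dnet(integer(), integer(), n = 1L)
  else dnet(seq_len(n - 1), seq_len(n - 1) + 1L, n = n)
}

#' @rdname chain_net
#' @export
star_net <- function(k) dnet(rep(1L, k), seq_len(k) + 1L, n = k + 1L)

#' @rdname chain_net
#' @export
cycle_net <- function(n) dnet(seq_len(n), c(seq_len(n - 1) + 1L, 1L), n = n)

#' @rdname chain_net
#' @export
complete_net <- function(n) {
  uv <- expand.grid(from = seq_len(n), to = seq_len(n))
  uv <- uv[uv$from != uv$to, ]
  dnet(uv$from, uv$to, n = n)
}

#' @rdname chain_net
#' @export
toy7_net <- function() {
  # unconstrained minimum inputs {1, 2}; capping the LCC at 2 forces
  # {1, 3, 7}: one extra input and node 3 controlled instead of node 2
  dnet(c(1L, 1L, 2L, 3L, 4L, 6L), c(2L, 3L, 5L, 4L, 6L, 7L), n = 7L)
}

#' @rdname chain_net
#' @export
fixtures <- function() {
  list(chain15 = chain_net(15), star3 = star_net(3), cycle2 = cycle_net(2),
       k4 = complete_net(4), toy7 = toy7_net())
}

as_igraph_bipartite <- function(g, forbidden_minus = integer()) {
  n <- g$n
  keep <- !(g$to %in% forbidden_minus)
  igraph::make_bipartite_graph(
    types = rep(c(FALSE, TRUE), each = n),
    edges = as.vector(rbind(g$from[keep], g$to[keep] + n)))
}
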