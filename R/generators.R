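# Model network generators.
#
# Degree convention: the parameter `c` is the average in-degree, which
# equals the average out-degree, so a realization has exactly
# L = round(N * c) directed links and mean total degree 2c. Under this
# convention the matching core of directed ER ensembles emerges at c = e,
# the standard leaf-removal threshold.

draw_distinct_links <- function(n, L, draw_from, draw_to, max_iter = 200L) {
  if (L > n * (n - 1))
    stop("requested more links than a simple digraph on ", n, " nodes holds")
  from <- integer(0)
  to <- integer(0)
  key <- double(0)
  it <- 0L
  while (length(from) < L) {
    it <- it + 1L
    if (it > max_iter)
      stop("rejection sampling stalled (graph too dense for the model)")
    need <- L - length(from)
    size <- max(100L, ceiling(need * 1.3))
    u <- draw_from(size)
    v <- draw_to(size)
    ok <- u != v
    u <- u[ok]
    v <- v[ok]
    k <- (as.double(u) - 1) * n + v
    keep <- !duplicated(c(key, k))[length(key) + seq_along(k)]
    u <- u[keep][seq_len(min(need, sum(keep)))]
    v <- v[keep][seq_len(min(need, sum(keep)))]
    from <- c(from, u)
    to <- c(to, v)
    key <- c(key, (as.double(u) - 1) * n + v)
  }
  dnet(from, to, n = n)
}

#' Directed Erdos-Renyi network
#'
#' Exactly `round(n * c)` distinct directed links drawn uniformly among
#' ordered pairs `u != v`: no self-loops, no multi-links. `c` is the average
#' in-degree (= average out-degree; mean total degree `2c`).
#'
#' @param n node count.
#' @param c average in-degree (> 0).
#' @param seed optional integer seed.
#' @return A [dnet] object.
#' @export
er_directed <- function(n, c, seed = NULL) {
  stopifnot(n >= 2, c > 0)
  if (!is.null(seed)) set.seed(seed)
  L <- round(n * c)
  draw_distinct_links(n, L,
                      function(k) sample.int(n, k, replace = TRUE),
                      function(k) sample.int(n, k, replace = TRUE))
}

#' Static-model scale-free network
#'
#' Hidden-parameter construction: node `i` carries weight `i^(-alpha)` with
#' `alpha = 1/(gamma - 1)`; link sources and targets are drawn independently
#' in proportion to the weights (the same weight set on both ends), and
#' self-loops and duplicates are rejected until `round(n * c)` distinct
#' links are placed. Both the in- and out-degree tails then decay with
#' exponent `gamma`. As `gamma -> Inf` the weights flatten and the model
#' reduces to [er_directed()].
#'
#' @param n node count.
#' @param c average in-degree (> 0).
#' @param gamma degree exponent (> 2).
#' @param seed optional integer seed.
#' @return A [dnet] object.
#' @export
sf_static <- function(n, c, gamma, seed = NULL) {
  stopifnot(n >= 2, c > 0, gamma > 2)
  if (!is.null(seed)) set.seed(seed)
  alpha <- 1 / (gamma - 1)
  w <- seq_len(n)^(-alpha)
  L <- round(n * c)
  draw_distinct_links(n, L,
                      function(k) sample.int(n, k, replace = TRUE, prob = w),
                      function(k) sample.int(n, k, replace = TRUE, prob = w))
}

#' Degree-preserving randomization
#'
#' Double-edge swaps: `ceiling(L/2 * log(1/epsilon))` trials, each picking
#' two links `(a -> b)`, `(c -> d)` and rewiring to `(a -> d)`, `(c -> b)`
#' unless a self-loop or duplicate would arise. In- and out-degree sequences
#' are preserved exactly; higher-order structure is destroyed.
#'
#' @param g a [dnet] object.
#' @param epsilon mixing parameter controlling the trial count (default
#'   `1e-6`, i.e. about `6.9 * L` trials).
#' @param seed optional integer seed.
#' @return A randomized [dnet]; the number of accepted swaps is available as
#'   `attr(, "accepted_swaps")`.
#' @export
rewire_degree_preserving <- function(g, epsilon = 1e-6, seed = NULL) {
  stopifnot(inherits(g, "dnet"), epsilon > 0, epsilon < 1)
  if (!is.null(seed)) set.seed(seed)
  trials <- ceiling(n_links(g) / 2 * log(1 / epsilon))
  res <- cpp_rewire(g$n, g$from, g$to, trials)
  out <- dnet(res$from, res$to, n = g$n)
  attr(out, "accepted_swaps") <- res$accepted
  attr(out, "trials") <- trials
  out
}
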