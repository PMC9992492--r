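# Independent oracles used to cross-check the implementation paths.

# support of sum_{k=1..ell} A^k (boolean matrix powers), diagonal dropped:
# reachability within ell steps
reach_oracle <- function(g, ell) {
  n <- g$n
  A <- matrix(0, n, n)
  A[cbind(g$from, g$to)] <- 1
  R <- matrix(FALSE, n, n)
  P <- diag(n)
  for (k in seq_len(min(ell, n))) {
    P <- (P %*% A) > 0
    R <- R | P
    P <- P * 1
  }
  diag(R) <- FALSE
  R
}

# exhaustive maximum-matching cardinality by branching over links
enum_max_matching <- function(g) {
  m <- length(g$from)
  best <- 0L
  usedP <- logical(g$n)
  usedM <- logical(g$n)
  rec <- function(i, size) {
    if (size + (m - i + 1L) <= best) return(invisible())
    if (i > m) {
      best <<- max(best, size)
      return(invisible())
    }
    rec(i + 1L, size)
    u <- g$from[i]
    v <- g$to[i]
    if (!usedP[u] && !usedM[v]) {
      usedP[u] <<- TRUE
      usedM[v] <<- TRUE
      rec(i + 1L, size + 1L)
      usedP[u] <<- FALSE
      usedM[v] <<- FALSE
    }
  }
  rec(1L, 0L)
  best
}

# exhaustive minimum dominating set of an accessibility graph (n <= ~12)
enum_min_dominating <- function(acc) {
  n <- acc$n
  covers <- split(acc$to, factor(acc$from, levels = seq_len(n)))
  best <- n
  for (mask in 0:(2^n - 1)) {
    s <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(s) >= best) next
    covered <- logical(n)
    covered[s] <- TRUE
    covered[unlist(covers[s], use.names = FALSE)] <- TRUE
    if (all(covered)) best <- length(s)
  }
  best
}

# small random digraph helper
rand_net <- function(n, c, seed) er_directed(n, c, seed = seed)

# exact input counts of the 7-node toy network, frozen from exhaustive
# search (brute_force_min_inputs) over all LCC budgets
toy7_ni_table <- data.frame(ell = c(1, 2, 3, 4, 7, Inf),
                            ni = c(4, 3, 2, 2, 2, 2))
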