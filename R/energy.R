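# Control-energy computations for linear time-invariant dynamics
# x' = A x + B u with single-node inputs (one nonzero per column of B).

mat_exp <- function(M) as.matrix(Matrix::expm(Matrix::Matrix(M)))

#' Linear system on a directed network
#'
#' Builds the state matrix `A` (entry `A[j, i]` weights link `i -> j`) and
#' the input matrix `B` (one column per input node, a single 1 in that
#' node's row). Weight schemes: `"unit"` puts 1 on every link; `"random"`
#' draws weights uniformly from [0.5, 1.5]; `"stabilized"` is `"unit"` plus
#' `-d` on the diagonal.
#'
#' @param g a [dnet] object.
#' @param inputs input node ids (columns of `B`).
#' @param tf control time horizon (> 0).
#' @param weights weight scheme for the links.
#' @param d diagonal stabilization strength (scheme `"stabilized"`).
#' @param seed optional seed (scheme `"random"`).
#' @return An object of class `lti_system` with fields `A`, `B`, `tf`,
#'   `inputs`.
#' @export
lti_system <- function(g, inputs, tf = 1,
                       weights = c("unit", "random", "stabilized"),
                       d = 1, seed = NULL) {
  stopifnot(inherits(g, "dnet"), tf > 0, length(inputs) >= 1)
  weights <- match.arg(weights)
  if (!is.null(seed)) set.seed(seed)
  inputs <- sort(unique(as.integer(inputs)))
  n <- g$n
  A <- matrix(0, n, n)
  w <- switch(weights,
              unit = rep(1, n_links(g)),
              random = runif(n_links(g), 0.5, 1.5),
              stabilized = rep(1, n_links(g)))
  A[cbind(g$to, g$from)] <- w
  if (weights == "stabilized") diag(A) <- diag(A) - d
  B <- matrix(0, n, length(inputs))
  B[cbind(inputs, seq_along(inputs))] <- 1
  structure(list(A = A, B = B, tf = tf, inputs = inputs,
                 weights = weights), class = "lti_system")
}

#' @export
print.lti_system <- function(x, ...) {
  cat(sprintf("<lti_system> %d states, %d inputs (%s weights), tf = %g\n",
              nrow(x$A), ncol(x$B), x$weights, x$tf))
  invisible(x)
}

#' Finite-time controllability Gramian and mean control energy
#'
#' Computes `W = integral_0^tf exp(A t) B B' exp(A' t) dt` by the block
#' matrix-exponential identity (exponential of the augmented matrix
#' `[[-A, BB'], [0, A']]`), symmetrizes, and summarizes the mean control
#' energy `tr(W^-1)`. Gramians of weakly coupled placements are often
#' numerically singular; eigenvalues below `floor_rel` times the largest are
#' floored for the reported energy and flagged.
#'
#' @param sys an [lti_system()] object.
#' @param floor_rel relative eigenvalue floor for the pseudo-inverse trace.
#' @return A `gramian_result`: `W`, `eigenvalues`, `mean_energy` (floored
#'   trace of the inverse), `mean_energy_raw` (`Inf` when singular),
#'   `singular`, `condition`.
#' @examples
#' sys <- lti_system(chain_net(2), inputs = 1)
#' finite_time_gramian(sys)$W  # [[1, 1/2], [1/2, 1/3]]
#' @export
finite_time_gramian <- function(sys, floor_rel = 1e-12) {
  stopifnot(inherits(sys, "lti_system"))
  A <- sys$A
  n <- nrow(A)
  Q <- sys$B %*% t(sys$B)
  blk <- rbind(cbind(-A, Q), cbind(matrix(0, n, n), t(A)))
  E <- mat_exp(blk * sys$tf)
  F2 <- E[n + seq_len(n), n + seq_len(n), drop = FALSE]
  G1 <- E[seq_len(n), n + seq_len(n), drop = FALSE]
  W <- t(F2) %*% G1
  W <- (W + t(W)) / 2
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(ev, 0)
  singular <- lmax <= 0 || min(ev) < floor_rel * lmax
  floored <- pmax(ev, floor_rel * lmax)
  structure(list(W = W, eigenvalues = ev,
                 mean_energy = sum(1 / floored),
                 mean_energy_raw = if (singular) Inf else sum(1 / ev),
                 singular = singular,
                 condition = if (min(ev) > 0) lmax / min(ev) else Inf),
            class = "gramian_result")
}

#' @export
print.gramian_result <- function(x, ...) {
  cat(sprintf("<gramian_result> %dx%d, tr(W^-1) = %.6g%s\n", nrow(x$W),
              ncol(x$W), x$mean_energy,
              if (x$singular) " (singular; eigenvalue-floored)" else ""))
  invisible(x)
}

#' Minimum-energy control signal
#'
#' The open-loop signal steering the system from `x0` at time 0 to `xf` at
#' time `tf` with least energy:
#' `u(t) = B' exp(A'(tf - t)) W^-1 (xf - exp(A tf) x0)`. Its energy equals
#' the Gramian quadratic form `v' W^-1 v` with `v = xf - exp(A tf) x0`.
#'
#' @param sys an [lti_system()] object.
#' @param x0,xf initial and target state vectors.
#' @return A function of time returning the input vector `u(t)`.
#' @export
optimal_signal <- function(sys, x0, xf) {
  gr <- finite_time_gramian(sys)
  if (gr$singular)
    stop("Gramian is numerically singular; the target is not reachable at working precision")
  v <- xf - mat_exp(sys$A * sys$tf) %*% x0
  wv <- solve(gr$W, v)
  At <- t(sys$A)
  Bt <- t(sys$B)
  function(t) {
    vapply(t, function(ti) as.vector(Bt %*% mat_exp(At * (sys$tf - ti)) %*% wv),
           numeric(ncol(sys$B)))
  }
}

#' @rdname optimal_signal
#' @param n_grid quadrature grid size (odd; Simpson's rule).
#' @return [control_energy()]: the energy `integral |u(t)|^2 dt` of the
#'   minimum-energy signal, by quadrature.
#' @export
control_energy <- function(sys, x0, xf, n_grid = 2001) {
  if (n_grid %% 2 == 0) n_grid <- n_grid + 1
  u <- optimal_signal(sys, x0, xf)
  ts <- seq(0, sys$tf, length.out = n_grid)
  uu <- u(ts)
  if (is.null(dim(uu))) uu <- matrix(uu, nrow = 1)
  f <- colSums(uu^2)
  h <- sys$tf / (n_grid - 1)
  idx <- seq_len(n_grid)
  wts <- ifelse(idx %% 2 == 0, 4, 2)
  wts[c(1, n_grid)] <- 1
  sum(wts * f) * h / 3
}

#' @rdname optimal_signal
#' @return [gramian_energy()]: the closed-form energy `v' W^-1 v`.
#' @export
gramian_energy <- function(sys, x0, xf) {
  gr <- finite_time_gramian(sys)
  v <- xf - mat_exp(sys$A * sys$tf) %*% x0
  as.numeric(t(v) %*% solve(gr$W, v))
}

#' Control energy: LCC-aware versus random input placement
#'
#' For each input budget `M`, places inputs two ways and compares the mean
#' control energy `tr(W^-1)` at `tf`: (i) LCC placement -- solve the
#' constrained input problem at the smallest budget `l` with
#' `N_i(l) <= M` and add the remaining `M - N_i(l)` inputs at random;
#' (ii) random placement -- a matching-based minimum input set that ensures
#' controllability, topped up with random inputs. Energies are averaged over
#' `reps` draws of the random additions; numerically singular Gramians are
#' floored (and counted).
#'
#' @param g a [dnet] object.
#' @param M_values input budgets to scan (default: smallest feasible to n).
#' @param reps random draws per budget.
#' @param tf control time.
#' @param weights link weight scheme, see [lti_system()].
#' @param method solver for the placements (`"greedy"` or `"ilp"`).
#' @param seed optional integer seed.
#' @param floor_rel eigenvalue floor, see [finite_time_gramian()].
#' @return A data frame with one row per `(M, strategy)`: the budget, the
#'   LCC budget `ell` attained, mean and median energy, and the count of
#'   floored (singular) Gramians.
#' @export
lcc_vs_random_experiment <- function(g, M_values = NULL, reps = 20, tf = 1,
                                     weights = "unit",
                                     method = c("greedy", "ilp"),
                                     seed = NULL, floor_rel = 1e-12) {
  stopifnot(inherits(g, "dnet"))
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  n <- g$n
  solve1 <- function(l) min_inputs(g, l, method = method)
  # input counts per LCC budget; breakpoints where the count changes
  ells <- seq_len(n)
  cfgs <- lapply(ells, solve1)
  ni <- vapply(cfgs, function(cf) length(cf$inputs), integer(1))
  base_cfg <- cfgs[[n]] # unconstrained (matching-based) minimum
  if (is.null(M_values)) M_values <- seq(min(ni), n)
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  rows <- list()
  for (M in M_values) {
    feas <- which(ni <= M)
    strategies <- list(
      lcc = if (length(feas)) cfgs[[min(feas)]]$inputs else NULL,
      random = if (length(base_cfg$inputs) <= M) base_cfg$inputs else NULL)
    ell_star <- if (length(feas)) min(feas) else NA_integer_
    for (st in names(strategies)) {
      base <- strategies[[st]]
      if (is.null(base)) next
      extra_pool <- setdiff(seq_len(n), base)
      k <- M - length(base)
      en <- numeric(reps)
      sing <- 0L
      for (r in seq_len(reps)) {
        inp <- c(base, if (k > 0) sample(extra_pool, k))
        gr <- finite_time_gramian(lti_system(g, inp, tf = tf,
                                             weights = weights),
                                  floor_rel = floor_rel)
        en[r] <- gr$mean_energy
        if (gr$singular) sing <- sing + 1L
      }
      rows[[length(rows) + 1]] <- data.frame(
        M = M, strategy = st, ell = ell_star,
        mean_energy = mean_or_na(en), median_energy = stats::median(en),
        n_singular = sing)
    }
  }
  do.call(rbind, rows)
}
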