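# Exact solver: the minimum input problem as an integer linear program.
#
# One binary variable per directed link marks membership in the matching.
# Constraints: every plus copy and every minus copy of the bipartite
# representation touches at most one matched link, and for every node v the
# closed in-neighborhood of v in the accessibility graph must contain at
# least one unmatched (= input) node. The objective counts unmatched minus
# copies. Models are assembled here and solved by a bundled helper driving
# the HiGHS branch-and-bound (single thread, zero gap: certified optima).

lcc_python <- function() {
  py <- getOption("lccontrol.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("no python interpreter found; set options(lccontrol.python = ...)")
  py
}

# problems: list of list(kind = 0 (min-input) | 1 (dominating set), n,
# bfrom, bto, gfrom, gto); returns list of list(status, objective, x)
milp_backend <- function(problems, time_limit = 60) {
  script <- system.file("python", "milp_solve.py", package = "lccontrol")
  if (!nzchar(script)) stop("bundled solver script not found")
  infile <- tempfile("milp", fileext = ".txt")
  outfile <- tempfile("milp", fileext = ".json")
  on.exit(unlink(c(infile, outfile)))
  con <- file(infile, "w")
  writeLines(as.character(length(problems)), con)
  for (p in problems) {
    writeLines(paste(p$kind, p$n, length(p$bfrom), length(p$gfrom)), con)
    for (v in list(p$bfrom, p$bto, p$gfrom, p$gto))
      writeLines(paste(v, collapse = " "), con)
  }
  close(con)
  res <- suppressWarnings(system2(lcc_python(), c(shQuote(script),
                                                  shQuote(infile),
                                                  shQuote(outfile),
                                                  format(time_limit)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0)
    stop("ILP helper failed:\n", paste(res, collapse = "\n"))
  jsonlite::fromJSON(outfile, simplifyVector = FALSE)
}

#' Exact minimum input set via integer linear programming
#'
#' Solves the LCC-constrained minimum input problem to proven optimality
#' with branch-and-bound (HiGHS backend). One binary variable per link
#' selects the matching; matching constraints limit every node copy to one
#' matched link, and each node's closed in-neighborhood in the accessibility
#' graph must contain an unmatched node. Practical up to a few thousand
#' links.
#'
#' @param g a [dnet] object.
#' @param ell LCC budget (positive integer or `Inf`).
#' @param time_limit solver time limit in seconds; on timeout the incumbent
#'   is returned with `certified_optimal = FALSE`.
#' @return An `input_config` object.
#' @examples
#' \donttest{solve_ilp(chain_net(15), ell = 2)  # 5 inputs}
#' @export
solve_ilp <- function(g, ell, time_limit = 60) {
  stopifnot(inherits(g, "dnet"))
  cfgs <- solve_ilp_batch(list(g), ell, time_limit = time_limit)
  cfgs[[1]]
}

#' @rdname solve_ilp
#' @param graphs a list of [dnet] objects sharing one `ell` (solved in a
#'   single backend call; much faster than repeated [solve_ilp()]).
#' @export
solve_ilp_batch <- function(graphs, ell, time_limit = 60) {
  stopifnot(all(vapply(graphs, inherits, logical(1), "dnet")))
  trivial <- vapply(graphs, function(g) n_links(g) == 0L, logical(1))
  problems <- lapply(graphs[!trivial], function(g) {
    acc <- accessibility_graph(g, ell)
    list(kind = 0L, n = g$n, bfrom = g$from, bto = g$to,
         gfrom = acc$from, gto = acc$to)
  })
  sols <- if (length(problems)) milp_backend(problems, time_limit) else list()
  out <- vector("list", length(graphs))
  k <- 0L
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (trivial[i]) {
      out[[i]] <- new_input_config(
        g, ell, seq_len(g$n),
        cbind(from = integer(), to = integer()), "ilp", TRUE)
      next
    }
    k <- k + 1L
    s <- sols[[k]]
    if (is.null(s$x))
      stop("ILP returned no feasible solution (status ", s$status, ")")
    x <- unlist(s$x) > 0.5
    matched <- cbind(from = g$from[x], to = g$to[x])
    inputs <- setdiff(seq_len(g$n), matched[, "to"])
    out[[i]] <- new_input_config(g, ell, inputs, matched, "ilp",
                                 certified = s$status == 0)
  }
  out
}

# exact minimum dominating set of an accessibility graph (set-cover ILP
# over closed in-neighborhoods)
min_dominating_exact <- function(acc, time_limit = 60) {
  sol <- milp_backend(list(list(kind = 1L, n = acc$n,
                                bfrom = integer(), bto = integer(),
                                gfrom = acc$from, gto = acc$to)),
                      time_limit)[[1]]
  if (is.null(sol$x))
    stop("dominating-set ILP returned no solution (status ", sol$status, ")")
  list(set = which(unlist(sol$x) > 0.5), exact = sol$status == 0)
}
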