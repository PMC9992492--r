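new_input_config <- function(g, ell, inputs, matched_links, method,
                             certified, core = NULL) {
  inputs <- sort(unique(as.integer(inputs)))
  lcc <- if (length(inputs)) longest_control_chain(g, inputs) else Inf
  structure(list(
    n = g$n, ell = ell, inputs = inputs,
    matching = structure(list(
      n = g$n, matched_links = matched_links,
      unmatched_minus = inputs, size = nrow(matched_links)),
      class = "lcc_matching"),
    achieved_lcc = lcc, method = method,
    certified_optimal = isTRUE(certified), core = core),
    class = "input_config")
}

#' @export
print.input_config <- function(x, ...) {
  cat(sprintf("<input_config> %s: %d / %d input nodes, LCC %s (budget %s)%s\n",
              x$method, length(x$inputs), x$n, format(x$achieved_lcc),
              format(x$ell),
              if (x$certified_optimal) ", optimal" else ""))
  invisible(x)
}

#' @export
summary.input_config <- function(object, ...) {
  cat(sprintf("LCC-constrained input configuration (method: %s)\n",
              object$method))
  cat(sprintf("  nodes: %d, budget l = %s\n", object$n, format(object$ell)))
  cat(sprintf("  inputs (%d): %s\n", length(object$inputs),
              paste(head(object$inputs, 25), collapse = " ")))
  cat(sprintf("  achieved LCC: %s\n", format(object$achieved_lcc)))
  cat(sprintf("  matched links: %d\n", object$matching$size))
  cat(sprintf("  certified optimal: %s\n", object$certified_optimal))
  if (!is.null(object$core))
    cat(sprintf("  core at stall: %d bipartite + %d accessibility edges (combined fraction %.4g), %d heuristic steps\n",
                object$core$m_core_edges, object$core$ds_core_edges,
                object$core$combined_core_fraction,
                object$core$heuristic_steps_used))
  invisible(object)
}

#' Serialize an input configuration to JSON
#'
#' @param cfg an `input_config` object.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
config_to_json <- function(cfg, path = NULL) {
  x <- list(inputs = cfg$inputs,
            matched_links = apply(cfg$matching$matched_links, 1, identity,
                                  simplify = FALSE),
            achieved_lcc = if (is.finite(cfg$achieved_lcc))
              cfg$achieved_lcc else "Inf",
            method = cfg$method,
            certified_optimal = cfg$certified_optimal)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Minimum input set under an LCC constraint
#'
#' Front end dispatching to the exact integer-programming solver
#' ([solve_ilp()]), the exhaustive-search oracle
#' ([brute_force_min_inputs()]), or the coupled leaf-removal approximation
#' ([approx_min_inputs()]).
#'
#' @param g a [dnet] object.
#' @param ell LCC budget (positive integer or `Inf`).
#' @param method `"greedy"`, `"ilp"`, or `"brute"`.
#' @param seed optional integer seed (greedy tie-breaking).
#' @param ... passed to the backend solver.
#' @return An `input_config` object.
#' @examples
#' min_inputs(chain_net(6), ell = 2)
#' @export
min_inputs <- function(g, ell, method = c("greedy", "ilp", "brute"),
                       seed = NULL, ...) {
  method <- match.arg(method)
  switch(method,
         greedy = approx_min_inputs(g, ell, seed = seed, ...),
         ilp = solve_ilp(g, ell, ...),
         brute = brute_force_min_inputs(g, ell))
}
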