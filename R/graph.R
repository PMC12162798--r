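## Signed interaction-graph inference.

#' Infer the signed interaction graph of a Boolean network
#'
#' An edge `u -> v` is present exactly when `u` is an essential input of the
#' update function of `v` (flipping `u` changes the output in some context).
#' The sign is `+1` (activating) when every flip of `u` from 0 to 1 can only
#' increase the output, `-1` (inhibiting) when it can only decrease it, and
#' `0` (ambiguous) when both directions occur, determined by exhaustive flip
#' analysis over the function's input cube.
#'
#' @param net A `boolean_network`.
#' @return An object of class `interaction_graph`: a list with `nodes`
#'   (character), `edges` (data frame with columns `from`, `to`, `sign`),
#'   and per-node `in_degree` / `out_degree`.
#' @export
interaction_graph <- function(net) {
  from <- character(0); to <- character(0); sign <- integer(0)
  for (v in net$variables) {
    fn <- net$functions[[v]]
    k <- length(fn$inputs)
    if (k == 0L) next
    idx <- 0:(2L^k - 1L)
    for (j in seq_len(k)) {
      b <- 2L^(j - 1L)
      low <- idx[bitwAnd(idx, b) == 0L]
      f0 <- fn$tt[low + 1L]
      f1 <- fn$tt[low + b + 1L]
      inc <- any(f1 > f0)
      dec <- any(f1 < f0)
      if (!inc && !dec) next  # non-essential (cannot happen after normalize)
      from <- c(from, fn$inputs[j]); to <- c(to, v)
      sign <- c(sign, if (inc && dec) 0L else if (inc) 1L else -1L)
    }
  }
  edges <- data.frame(from = from, to = to, sign = sign,
                      stringsAsFactors = FALSE)
  nodes <- net$variables
  structure(list(
    nodes = nodes,
    edges = edges,
    in_degree = stats::setNames(
      as.integer(table(factor(edges$to, levels = nodes))), nodes),
    out_degree = stats::setNames(
      as.integer(table(factor(edges$from, levels = nodes))), nodes)
  ), class = "interaction_graph")
}

#' Construct an interaction graph directly from an edge table
#'
#' Mainly for tests and for structural queries on graphs that do not come
#' from a network.
#'
#' @param nodes Character vector of node names.
#' @param edges Data frame with columns `from`, `to`, `sign`.
#' @return An `interaction_graph`.
#' @export
make_interaction_graph <- function(nodes, edges) {
  stopifnot(all(c("from", "to", "sign") %in% names(edges)))
  stopifnot(all(edges$from %in% nodes), all(edges$to %in% nodes))
  structure(list(
    nodes = nodes,
    edges = data.frame(from = as.character(edges$from),
                       to = as.character(edges$to),
                       sign = as.integer(edges$sign),
                       stringsAsFactors = FALSE),
    in_degree = stats::setNames(
      as.integer(table(factor(edges$to, levels = nodes))), nodes),
    out_degree = stats::setNames(
      as.integer(table(factor(edges$from, levels = nodes))), nodes)
  ), class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("Interaction graph:", length(x$nodes), "node(s),",
      nrow(x$edges), "edge(s)\n")
  if (nrow(x$edges) > 0L) {
    sym <- c(`-1` = "-|", `0` = "-?", `1` = "->")
    cat(paste0("  ", x$edges$from, " ", sym[as.character(x$edges$sign)],
               " ", x$edges$to, collapse = "\n"), "\n")
  }
  invisible(x)
}

## adjacency list of node-index successors
ig_adj <- function(ig) {
  n <- length(ig$nodes)
  fi <- match(ig$edges$from, ig$nodes)
  ti <- match(ig$edges$to, ig$nodes)
  adj <- rep(list(integer(0)), n)
  for (e in seq_along(fi)) adj[[fi[e]]] <- c(adj[[fi[e]]], ti[e])
  adj
}
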