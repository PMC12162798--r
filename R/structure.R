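## Interaction-graph-level criteria that rule motif-avoidant attractors in or
## out: cycle-sign analysis and linear-cut (L-cut) testing.
##
## Sign conventions: an ambiguous edge (sign 0) counts as both positive and
## negative, so a cycle containing one is both non-negative and non-positive.

#' Enumerate the simple cycles of an interaction graph
#'
#' Depth-first enumeration anchored at the smallest vertex of each cycle;
#' self-loops are length-1 cycles. Intended for the small graphs this package
#' works with.
#'
#' @param ig An `interaction_graph`.
#' @param max_cycles Abort beyond this many cycles (runaway guard).
#' @return List of integer vectors of node indices (cycle order, no repeat of
#'   the closing vertex).
#' @export
simple_cycles <- function(ig, max_cycles = 1e6) {
  n <- length(ig$nodes)
  adj <- ig_adj(ig)
  cycles <- list()
  for (s in seq_len(n)) {
    path <- integer(0)
    onpath <- rep(FALSE, n)
    dfs <- function(v) {
      path[length(path) + 1L] <<- v
      onpath[v] <<- TRUE
      for (w in adj[[v]]) {
        if (w == s) {
          cycles[[length(cycles) + 1L]] <<- path
          if (length(cycles) > max_cycles) stop("too many cycles")
        } else if (w > s && !onpath[w]) {
          dfs(w)
        }
      }
      onpath[v] <<- FALSE
      path <<- path[-length(path)]
      invisible(NULL)
    }
    dfs(s)
  }
  cycles
}

## edge signs along a cycle (in cycle order)
cycle_sign <- function(ig, cycle) {
  key <- paste(ig$edges$from, ig$edges$to, sep = "\r")
  signs <- stats::setNames(ig$edges$sign, key)
  nxt <- c(cycle[-1L], cycle[1L])
  es <- signs[paste(ig$nodes[cycle], ig$nodes[nxt], sep = "\r")]
  list(has_ambiguous = any(es == 0L), raw = unname(es))
}

#' Cycle-sign summary of an interaction graph
#'
#' Computes whether the graph has any cycle, any non-negative cycle (sign
#' product +1 or containing an ambiguous edge), any non-positive cycle (sign
#' product -1 or ambiguous), and whether some vertex on a non-positive cycle
#' has a directed path (length >= 0) to a vertex on a non-negative cycle.
#' Flags are exact, via exhaustive simple-cycle enumeration.
#'
#' @param ig An `interaction_graph`.
#' @return A list of class `cycle_sign_summary` with logical flags
#'   `has_cycle`, `has_nonnegative_cycle`, `has_nonpositive_cycle`,
#'   `path_nonpos_to_nonneg` and the vertex name sets
#'   `vertices_nonpositive`, `vertices_nonnegative`.
#' @export
cycle_sign_summary <- function(ig) {
  cycles <- simple_cycles(ig)
  v_nonpos <- integer(0)
  v_nonneg <- integer(0)
  for (cy in cycles) {
    cs <- cycle_sign(ig, cy)
    raw <- cs$raw
    prod_nonzero <- prod(raw[raw != 0L])
    nonneg <- cs$has_ambiguous || prod_nonzero == 1
    nonpos <- cs$has_ambiguous || prod_nonzero == -1
    if (nonneg) v_nonneg <- union(v_nonneg, cy)
    if (nonpos) v_nonpos <- union(v_nonpos, cy)
  }
  path_flag <- FALSE
  if (length(v_nonpos) > 0L && length(v_nonneg) > 0L) {
    reach <- reach_set(ig, v_nonpos)
    path_flag <- length(intersect(reach, v_nonneg)) > 0L
  }
  structure(list(
    has_cycle = length(cycles) > 0L,
    has_nonnegative_cycle = length(v_nonneg) > 0L,
    has_nonpositive_cycle = length(v_nonpos) > 0L,
    path_nonpos_to_nonneg = path_flag,
    vertices_nonpositive = ig$nodes[sort(v_nonpos)],
    vertices_nonnegative = ig$nodes[sort(v_nonneg)]
  ), class = "cycle_sign_summary")
}

#' @export
print.cycle_sign_summary <- function(x, ...) {
  cat("cycles:", x$has_cycle,
      "| non-negative:", x$has_nonnegative_cycle,
      "| non-positive:", x$has_nonpositive_cycle,
      "| path non-pos -> non-neg:", x$path_nonpos_to_nonneg, "\n")
  invisible(x)
}

## vertices reachable from `seed` (indices), including the seed
reach_set <- function(ig, seed) {
  adj <- ig_adj(ig)
  seen <- rep(FALSE, length(ig$nodes))
  seen[seed] <- TRUE
  frontier <- seed
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

#' Non-positive cycle detection via the parity-doubled graph
#'
#' Secondary engine: each vertex is split into an even- and an odd-parity
#' copy; positive edges stay within a layer, negative edges cross layers and
#' ambiguous edges do both. A non-positive cycle exists iff some odd copy is
#' reachable from the corresponding even copy. (The analogous construction is
#' not sound for non-negative cycles: an even closed walk need not contain an
#' even simple cycle.)
#'
#' @param ig An `interaction_graph`.
#' @return Logical scalar.
#' @export
has_nonpositive_cycle_parity <- function(ig) {
  n <- length(ig$nodes)
  if (nrow(ig$edges) == 0L) return(FALSE)
  fi <- match(ig$edges$from, ig$nodes)
  ti <- match(ig$edges$to, ig$nodes)
  sg <- ig$edges$sign
  ## vertex (v, parity) -> index v + parity * n
  from <- integer(0); to <- integer(0)
  for (e in seq_along(fi)) {
    if (sg[e] >= 0L) {  # positive (or ambiguous): parity preserved
      from <- c(from, fi[e], fi[e] + n)
      to <- c(to, ti[e], ti[e] + n)
    }
    if (sg[e] <= 0L) {  # negative (or ambiguous): parity flipped
      from <- c(from, fi[e], fi[e] + n)
      to <- c(to, ti[e] + n, ti[e])
    }
  }
  g <- igraph::make_graph(rbind(from, to), n = 2L * n, directed = TRUE)
  for (v in seq_len(n)) {
    if ((v + n) %in% igraph::subcomponent(g, v, mode = "out")) return(TRUE)
  }
  FALSE
}

#' Test whether an interaction graph admits a linear cut
#'
#' A linear node has in-degree one and out-degree one (self-loops count for
#' both). The graph is L-cuttable when a linear node occurs on every cycle
#' (including self-edges) and on every path with at least one edge from a
#' node with two or more targets to a node with two or more regulators
#' (degrees measured in the original graph). In an L-cuttable Boolean network
#' the attractors are in one-to-one correspondence with the minimal trap
#' spaces, so such networks cannot have motif-avoidant attractors; in
#' particular a network in which every edge has been linearly extended is
#' always L-cuttable.
#'
#' @param ig An `interaction_graph` (signs are ignored).
#' @return Logical scalar.
#' @export
is_l_cuttable <- function(ig) {
  n <- length(ig$nodes)
  if (n == 0L) return(TRUE)
  linear <- ig$in_degree == 1L & ig$out_degree == 1L
  keep <- which(!linear)
  fi <- match(ig$edges$from, ig$nodes)
  ti <- match(ig$edges$to, ig$nodes)
  inH <- fi %in% keep & ti %in% keep
  hf <- fi[inH]; ht <- ti[inH]
  ## every cycle must contain a linear node: remainder must be acyclic
  if (any(hf == ht)) return(FALSE)  # self-loop on a non-linear node
  if (length(hf) > 0L) {
    g <- igraph::make_graph(rbind(match(hf, keep), match(ht, keep)),
                            n = length(keep), directed = TRUE)
    if (!igraph::is_dag(g)) return(FALSE)
  }
  ## no linear-free path (>= 1 edge) from a multi-target to a multi-regulator
  multi_out <- which(ig$out_degree >= 2L)
  multi_in <- which(ig$in_degree >= 2L)
  if (length(multi_out) == 0L || length(multi_in) == 0L) return(TRUE)
  adjH <- rep(list(integer(0)), n)
  for (e in seq_along(hf)) adjH[[hf[e]]] <- c(adjH[[hf[e]]], ht[e])
  for (u in intersect(multi_out, keep)) {
    ## BFS from the successors of u (paths of length >= 1)
    seen <- rep(FALSE, n)
    frontier <- adjH[[u]]
    seen[frontier] <- TRUE
    while (length(frontier) > 0L) {
      if (any(frontier %in% multi_in)) return(FALSE)
      nxt <- unique(unlist(adjH[frontier]))
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
    }
  }
  TRUE
}

#' Structural exclusion of motif-avoidant attractors
#'
#' Checks, in order, the known interaction-graph criteria that rule out MAAs:
#' no cycles; only positive cycles; only negative cycles; no path from a
#' non-positive cycle to a non-negative cycle; L-cuttability. Returns the
#' first criterion satisfied. `excluded = TRUE` guarantees that
#' [find_maas()] returns no MAA.
#'
#' @param ig An `interaction_graph`.
#' @return List with `excluded` (logical), `reason` (character or `NA`) and
#'   the `cycle_sign_summary`.
#' @export
maa_excluded_by_structure <- function(ig) {
  s <- cycle_sign_summary(ig)
  reason <- NA_character_
  if (!s$has_cycle) {
    reason <- "no cycles"
  } else if (!s$has_nonpositive_cycle) {
    reason <- "only positive cycles"
  } else if (!s$has_nonnegative_cycle) {
    reason <- "only negative cycles"
  } else if (!s$path_nonpos_to_nonneg) {
    reason <- "no path from a non-positive cycle to a non-negative cycle"
  } else if (is_l_cuttable(ig)) {
    reason <- "L-cuttable"
  }
  list(excluded = !is.na(reason), reason = reason, summary = s)
}
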