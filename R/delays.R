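## Linear (delay) extension of interaction-graph edges, memory-state
## analysis, projected state-transition graphs, minimal delay-set search and
## the closed-form delay-count bounds.

#' Linearly extend a set of edges with delay nodes
#'
#' Each edge `u -> v` is replaced by `u -> d_u_v -> v`: a fresh variable
#' `d_u_v` copies the value of `u`, and `u` is replaced by `d_u_v` in the
#' input list of `v`. Variable order is originals first, then delay nodes in
#' edge-sorted order. With `rewire = FALSE` the delay node is added but the
#' target keeps reading its parent directly (a non-functional delay: a pure
#' sink copy, useful as a control in memory-state analysis).
#'
#' @param net A `boolean_network`.
#' @param delays Data frame (or 2-column matrix) with columns `from`, `to`;
#'   every row must be an essential edge of `net`.
#' @param rewire Rewire the target function through the delay node
#'   (default `TRUE`).
#' @return The extended `boolean_network`, with attribute `"delays"`
#'   describing the added nodes.
#' @export
linear_extend <- function(net, delays, rewire = TRUE) {
  delays <- as.data.frame(delays, stringsAsFactors = FALSE)
  if (ncol(delays) < 2L) stop("delays must have columns from, to")
  names(delays)[1:2] <- c("from", "to")
  delays <- unique(delays[, c("from", "to")])
  ig <- interaction_graph(net)
  key <- paste(ig$edges$from, ig$edges$to, sep = "\r")
  want <- paste(delays$from, delays$to, sep = "\r")
  missing <- !(want %in% key)
  if (any(missing)) {
    stop("not an essential edge: ",
         paste(delays$from[missing], "->", delays$to[missing],
               collapse = ", "))
  }
  ord <- order(match(delays$from, net$variables),
               match(delays$to, net$variables))
  delays <- delays[ord, , drop = FALSE]
  dnames <- paste("d", delays$from, delays$to, sep = "_")
  if (any(dnames %in% net$variables)) {
    stop("delay variable name collision: ",
         paste(intersect(dnames, net$variables), collapse = ", "))
  }
  vars <- c(net$variables, dnames)
  fns <- net$functions
  for (r in seq_len(nrow(delays))) {
    u <- delays$from[r]; v <- delays$to[r]; d <- dnames[r]
    fns[[d]] <- list(inputs = u, tt = c(0L, 1L))
    if (rewire) {
      fns[[v]]$inputs[fns[[v]]$inputs == u] <- d
    }
  }
  ext <- boolean_network(vars, fns, normalize = FALSE)
  attr(ext, "delays") <- data.frame(from = delays$from, to = delays$to,
                                    var = dnames, rewired = rewire,
                                    stringsAsFactors = FALSE)
  attr(ext, "n_original") <- n_vars(net)
  ext
}

## canonical states of an extended network: every delay variable equals its
## parent. Returns a logical vector over state codes 0:(2^n_ext - 1).
canonical_mask <- function(ext) {
  dl <- attr(ext, "delays")
  n <- n_vars(ext)
  states <- 0:(2L^n - 1L)
  ok <- rep(TRUE, length(states))
  for (r in seq_len(nrow(dl))) {
    di <- match(dl$var[r], ext$variables)
    pi <- match(dl$from[r], ext$variables)
    ok <- ok & state_bit(states, di) == state_bit(states, pi)
  }
  ok
}

## project extended state codes onto the original variables (originals come
## first in the extension's variable order)
project_states <- function(ext, states) {
  n0 <- attr(ext, "n_original")
  bitwAnd(states, 2L^n0 - 1L)
}

#' Classify gained and lost transitions of memory states
#'
#' For every memory state of a delay-extended network (a state in which some
#' delay node disagrees with its parent), compares its outgoing transitions
#' on the original variables with the transitions of the projected state in
#' the original system. A transition is `gained` when it exists only in the
#' extension and `lost` when it exists only in the original. Canonical states
#' never appear: their transitions on original variables always agree with
#' the original system.
#'
#' @param net The original `boolean_network`.
#' @param delays Edge set as in [linear_extend()].
#' @param rewire Passed to [linear_extend()].
#' @return List with data frames `gained` and `lost`, each with columns
#'   `state` (extended state string), `variable`, `projected_from`,
#'   `projected_to`.
#' @export
classify_memory_transitions <- function(net, delays, rewire = TRUE) {
  ext <- linear_extend(net, delays, rewire = rewire)
  n0 <- n_vars(net)
  next_orig <- lapply(net$variables, function(v) {
    eval_var_states(net, v, 0:(2L^n0 - 1L))
  })
  nE <- n_vars(ext)
  if (nE > MAX_STG_VARS) stop("extended network exceeds the STG size guard")
  statesE <- 0:(2L^nE - 1L)
  canon <- canonical_mask(ext)
  proj <- project_states(ext, statesE)
  gained <- list(); lost <- list()
  for (i in seq_len(n0)) {
    v <- net$variables[i]
    nbE <- eval_var_states(ext, v, statesE)
    curE <- state_bit(statesE, i)
    changeE <- nbE != curE
    changeO <- next_orig[[i]][proj + 1L] != curE
    g <- which(changeE & !changeO & !canon)
    l <- which(!changeE & changeO & !canon)
    if (length(g) > 0L) {
      gained[[length(gained) + 1L]] <- data.frame(
        state = state_to_string(statesE[g], nE), variable = v,
        projected_from = state_to_string(proj[g], n0),
        projected_to = state_to_string(bitwXor(proj[g], 2L^(i - 1L)), n0),
        stringsAsFactors = FALSE)
    }
    if (length(l) > 0L) {
      lost[[length(lost) + 1L]] <- data.frame(
        state = state_to_string(statesE[l], nE), variable = v,
        projected_from = state_to_string(proj[l], n0),
        projected_to = state_to_string(bitwXor(proj[l], 2L^(i - 1L)), n0),
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(state = character(0), variable = character(0),
                      projected_from = character(0),
                      projected_to = character(0), stringsAsFactors = FALSE)
  list(gained = if (length(gained)) do.call(rbind, gained) else empty,
       lost = if (length(lost)) do.call(rbind, lost) else empty)
}

#' Projected state-transition graph of a delay extension
#'
#' Two original states are connected when the corresponding canonical states
#' of the delayed system are connected by a path passing through no other
#' canonical state. Self-edges are excluded. The projected STG always
#' contains every edge of the original asynchronous STG (canonical states
#' retain original connectivity); edges absent from the original STG are
#' classed `gained`, each with one witness path through memory states.
#'
#' @param net The original `boolean_network`.
#' @param delays Edge set as in [linear_extend()]; may have zero rows.
#' @return Object of class `projected_stg`: list with `n_vars`, `edges`
#'   (data frame `from`, `to`, `class`) and `witnesses` (named list of
#'   extended-state-string paths for gained edges).
#' @export
projected_stg <- function(net, delays) {
  n0 <- n_vars(net)
  stg0 <- build_stg(net, "asynchronous")
  orig_key <- paste(stg0$from, stg0$to)
  delays <- as.data.frame(delays, stringsAsFactors = FALSE)
  if (nrow(delays) == 0L) {
    edges <- data.frame(from = state_to_string(stg0$from, n0),
                        to = state_to_string(stg0$to, n0),
                        class = "original", stringsAsFactors = FALSE)
    return(structure(list(n_vars = n0, edges = edges, witnesses = list()),
                     class = "projected_stg"))
  }
  ext <- linear_extend(net, delays)
  nE <- n_vars(ext)
  if (nE > MAX_STG_VARS) stop("extended network exceeds the STG size guard")
  stgE <- build_stg(ext, "asynchronous")
  canon <- canonical_mask(ext)
  proj <- project_states(ext, 0:(2L^nE - 1L))
  succ <- split(stgE$to, factor(stgE$from, levels = 0:(2L^nE - 1L)))
  canonical_states <- which(canon) - 1L
  from_p <- integer(0); to_p <- integer(0)
  witnesses <- list()
  for (s in canonical_states) {
    ## BFS through memory-only interiors
    parent <- new.env()
    frontier <- succ[[s + 1L]]
    for (w in frontier) assign(as.character(w), s, envir = parent)
    reached <- integer(0)
    visited_mem <- logical(2L^nE)
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (w in frontier) {
        if (canon[w + 1L]) {
          if (w != s) reached <- c(reached, w)
        } else if (!visited_mem[w + 1L]) {
          visited_mem[w + 1L] <- TRUE
          for (w2 in succ[[w + 1L]]) {
            if (!exists(as.character(w2), envir = parent, inherits = FALSE)) {
              assign(as.character(w2), w, envir = parent)
            }
            if (canon[w2 + 1L]) {
              if (w2 != s) reached <- c(reached, w2)
            } else {
              nxt <- c(nxt, w2)
            }
          }
        }
      }
      frontier <- unique(nxt[!visited_mem[nxt + 1L]])
    }
    reached <- unique(reached)
    reached <- reached[project_states(ext, reached) != proj[s + 1L]]
    for (t in reached) {
      pf <- proj[s + 1L]; pt <- proj[t + 1L]
      from_p <- c(from_p, pf); to_p <- c(to_p, pt)
      if (!(paste(pf, pt) %in% orig_key)) {
        ## reconstruct one witness path
        path <- t
        w <- t
        while (w != s) {
          w <- get(as.character(w), envir = parent)
          path <- c(w, path)
        }
        witnesses[[paste(state_to_string(pf, n0), "->",
                         state_to_string(pt, n0))]] <-
          state_to_string(path, nE)
      }
    }
  }
  keep <- !duplicated(paste(from_p, to_p))
  from_p <- from_p[keep]; to_p <- to_p[keep]
  cls <- ifelse(paste(from_p, to_p) %in% orig_key, "original", "gained")
  edges <- data.frame(from = state_to_string(from_p, n0),
                      to = state_to_string(to_p, n0),
                      class = cls, stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(n_vars = n0, edges = edges, witnesses = witnesses),
            class = "projected_stg")
}

#' @export
print.projected_stg <- function(x, ...) {
  cat("Projected STG on", 2^x$n_vars, "states:",
      sum(x$edges$class == "original"), "original edge(s),",
      sum(x$edges$class == "gained"), "gained edge(s)\n")
  invisible(x)
}

#' Single-delay fragility survey of a motif-avoidant attractor
#'
#' For each essential incoming edge of each oscillating variable of the MAA,
#' builds the one-delay extension and tests whether the extended network is
#' free of motif-avoidant attractors.
#'
#' @param net A `boolean_network`.
#' @param report An `maa_report` with `is_motif_avoidant = TRUE` (as returned
#'   by [find_maas()]).
#' @return Data frame with columns `from`, `to`, `eliminates`; attribute
#'   `"n_success"` holds the number of successful edges.
#' @export
single_delay_survey <- function(net, report) {
  if (!inherits(report, "maa_report") || !report$is_motif_avoidant) {
    stop("report is not a motif-avoidant attractor")
  }
  osc <- report$attractor$oscillating
  ig <- interaction_graph(net)
  edges <- ig$edges[ig$edges$to %in% osc, c("from", "to"), drop = FALSE]
  eliminates <- logical(nrow(edges))
  for (r in seq_len(nrow(edges))) {
    ext <- linear_extend(net, edges[r, , drop = FALSE])
    eliminates[r] <- length(find_maas(ext)) == 0L
  }
  out <- cbind(edges, eliminates = eliminates)
  rownames(out) <- NULL
  attr(out, "n_success") <- sum(eliminates)
  out
}

#' Minimal number of delays eliminating the MAA, by exhaustive search
#'
#' Enumerates subsets of the interaction-graph edges in increasing
#' cardinality (then lexicographic edge order) and extends each subset with
#' delay nodes, until an extension leaves the network free of motif-avoidant
#' attractors. Necessity is certified by having exhausted all smaller
#' subsets.
#'
#' @param net A `boolean_network` with at least one MAA.
#' @param limit Largest subset cardinality to try.
#' @return List with `size` (or `NA` when the limit is exhausted), `witness`
#'   (edge data frame), `certified_lower_bound` and `subsets_tested`.
#' @export
minimal_delay_set_size <- function(net, limit = 6L) {
  if (length(find_maas(net)) == 0L) stop("network has no MAA")
  ig <- interaction_graph(net)
  edges <- ig$edges[, c("from", "to"), drop = FALSE]
  ne <- nrow(edges)
  tested <- 0L
  for (size in seq_len(min(limit, ne))) {
    for (pick in utils::combn(ne, size, simplify = FALSE)) {
      tested <- tested + 1L
      ext <- linear_extend(net, edges[pick, , drop = FALSE])
      if (n_vars(ext) > MAX_STG_VARS) next
      if (length(find_maas(ext)) == 0L) {
        return(list(size = size, witness = edges[pick, , drop = FALSE],
                    certified_lower_bound = size,
                    subsets_tested = tested))
      }
    }
  }
  list(size = NA_integer_, witness = NULL,
       certified_lower_bound = min(limit, ne) + 1L, subsets_tested = tested)
}

#' Upper bound on the number of delays needed to eliminate an MAA
#'
#' For an MAA with `d` oscillating variables, minimal restricted disagreement
#' `m` with the avoided minimal trap space, and `M` free variables in the
#' smallest trap space containing both the attractor and the avoided trap
#' space, the bound is `(M - d) * (M - 1) + m * (m + 1) / 2`. With `M = d`
#' and `m = 1` the bound is 1: a single linear extension (of the
#' self-regulation of the disagreeing variable) suffices.
#'
#' @param b Named vector or list with entries `M` (or `N`), `d`, `m`.
#' @return Numeric scalar.
#' @export
delay_upper_bound <- function(b) {
  b <- as.list(b)
  M <- b$M %||% b$N
  d <- b$d; m <- b$m
  if (is.null(M) || is.null(d) || is.null(m)) stop("need M (or N), d, m")
  if (!(2 <= d && d <= M)) stop("invalid inputs: need 2 <= d <= M")
  if (!(1 <= m && m < d)) stop("invalid inputs: need 1 <= m < d")
  (M - d) * (M - 1) + m * (m + 1) / 2
}

#' Worst-case delay bound for a complete interaction graph
#'
#' With `E_max = N^2` edges and maximal disagreement `m = d - 1`, the delay
#' bound specializes to `E_max - (sqrt(E_max) - d/2) * (d + 1)`, strictly
#' smaller than `E_max`.
#'
#' @param E_max Number of edges; must be a perfect square `N^2`.
#' @param d Number of oscillating variables, `2 <= d <= sqrt(E_max)`.
#' @return Numeric scalar, equal to `delay_upper_bound(c(M = N, d = d,
#'   m = d - 1))`.
#' @export
worst_case_bound <- function(E_max, d) {
  N <- sqrt(E_max)
  if (abs(N - round(N)) > 1e-9) stop("E_max must be a perfect square")
  N <- round(N)
  if (!(2 <= d && d <= N)) stop("need 2 <= d <= sqrt(E_max)")
  E_max - (N - d / 2) * (d + 1)
}
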