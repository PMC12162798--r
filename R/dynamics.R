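## Explicit state-transition graphs, attractors, trap spaces and
## motif-avoidant attractor (MAA) classification.

MAX_STG_VARS <- 22L
MAX_BRANCH_VARS <- 28L

#' Build the explicit state-transition graph of a Boolean network
#'
#' Under asynchronous update there is one edge per single-variable update that
#' changes the state; non-changing self-transitions are omitted, so fixed
#' points are the states with zero outgoing edges. Under synchronous update
#' every state has exactly one successor (self-edges on fixed points are
#' kept).
#'
#' @param net A `boolean_network` with at most 22 variables.
#' @param scheme `"asynchronous"` (default) or `"synchronous"`.
#' @return An object of class `stg`: list with `n_vars`, `n_states`, integer
#'   vectors `from` / `to` (0-based state codes) and `scheme`.
#' @export
build_stg <- function(net, scheme = c("asynchronous", "synchronous")) {
  scheme <- match.arg(scheme)
  n <- n_vars(net)
  if (n > MAX_STG_VARS) {
    stop("explicit STG limited to ", MAX_STG_VARS, " variables (got ", n, ")")
  }
  states <- 0:(2L^n - 1L)
  idxs <- lapply(net$variables, function(v) {
    match(net$functions[[v]]$inputs, net$variables)
  })
  if (scheme == "asynchronous") {
    from <- integer(0); to <- integer(0)
    for (i in seq_len(n)) {
      nb <- eval_var_states(net, net$variables[i], states, idxs[[i]])
      changed <- which(nb != state_bit(states, i))
      if (length(changed) > 0L) {
        from <- c(from, states[changed])
        to <- c(to, bitwXor(states[changed], 2L^(i - 1L)))
      }
    }
  } else {
    succ <- integer(length(states))
    for (i in seq_len(n)) {
      nb <- eval_var_states(net, net$variables[i], states, idxs[[i]])
      succ <- succ + nb * 2L^(i - 1L)
    }
    from <- states
    to <- succ
  }
  structure(list(n_vars = n, n_states = length(states),
                 from = from, to = to, scheme = scheme),
            class = "stg")
}

#' @export
print.stg <- function(x, ...) {
  cat("State transition graph (", x$scheme, "): ", x$n_states, " states, ",
      length(x$from), " transitions\n", sep = "")
  invisible(x)
}

#' Successor states of a state in an STG
#' @param stg An `stg`.
#' @param state Integer state code.
#' @return Integer vector of successor state codes.
#' @export
stg_successors <- function(stg, state) sort(stg$to[stg$from == state])

## terminal strongly connected components of an edge list over 0:(n_states-1)
terminal_sccs <- function(n_states, from, to) {
  if (length(from) == 0L) {
    return(as.list(0:(n_states - 1L)))
  }
  g <- igraph::make_graph(rbind(from + 1L, to + 1L), n = n_states,
                          directed = TRUE)
  memb <- igraph::components(g, mode = "strong")$membership
  cross <- memb[from + 1L] != memb[to + 1L]
  nonterm <- unique(memb[from + 1L][cross])
  term <- setdiff(unique(memb), nonterm)
  states_in_term <- which(memb %in% term) - 1L
  unname(split(states_in_term, memb[states_in_term + 1L]))
}

#' Attractors of a Boolean network
#'
#' Attractors are the terminal strongly connected components of the
#' state-transition graph: point attractors (a single state) or complex
#' attractors (several states). The result is ordered by the
#' lexicographically smallest member state string.
#'
#' @param net A `boolean_network`.
#' @param scheme Update scheme, as in [build_stg()].
#' @param stg Optionally a pre-built STG for `net` (avoids recomputation).
#' @return List of objects of class `attractor`, each with `states` (sorted
#'   integer codes), `state_strings`, `scheme`, `oscillating` (character) and
#'   `kind` (`"point"` or `"complex"`).
#' @export
attractors <- function(net, scheme = c("asynchronous", "synchronous"),
                       stg = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(stg)) stg <- build_stg(net, scheme)
  n <- n_vars(net)
  comps <- terminal_sccs(stg$n_states, stg$from, stg$to)
  if (scheme == "synchronous") {
    ## every state has an out-edge; terminal SCCs with one state are fixed
    ## points (self-loop); nothing to filter
  }
  atts <- lapply(comps, function(states) {
    states <- sort(states)
    osc <- net$variables[vapply(seq_len(n), function(i) {
      b <- state_bit(states, i)
      any(b == 0L) && any(b == 1L)
    }, logical(1))]
    structure(list(states = states,
                   state_strings = state_to_string(states, n),
                   scheme = scheme,
                   oscillating = osc,
                   kind = if (length(states) == 1L) "point" else "complex"),
              class = "attractor")
  })
  atts[order(vapply(atts, function(a) min(a$state_strings), character(1)))]
}

#' @export
print.attractor <- function(x, ...) {
  cat(x$kind, " attractor (", x$scheme, "), ", length(x$states),
      " state(s): ", paste(x$state_strings, collapse = " "), "\n", sep = "")
  invisible(x)
}

## ---- subspaces -------------------------------------------------------------

## A subspace is an integer vector of length N with entries 0, 1 or NA (free),
## in variable declaration order.

#' Parse a subspace string such as `"01*"`
#' @param str Character scalar over `0`, `1`, `*`.
#' @return Integer vector with `NA` marking free variables.
#' @export
parse_subspace <- function(str) {
  ch <- strsplit(str, "")[[1]]
  stopifnot(all(ch %in% c("0", "1", "*")))
  out <- rep(NA_integer_, length(ch))
  out[ch != "*"] <- as.integer(ch[ch != "*"])
  out
}

#' Format a subspace as a string
#' @param sub Integer vector with `NA` for free variables.
#' @return Character scalar such as `"01*"`.
#' @export
format_subspace <- function(sub) {
  paste(ifelse(is.na(sub), "*", as.character(sub)), collapse = "")
}

#' Number of free variables of a subspace
#' @param sub A subspace vector.
#' @return Integer scalar.
#' @export
free_count <- function(sub) sum(is.na(sub))

## states (integer codes) belonging to a subspace
subspace_states <- function(sub) {
  n <- length(sub)
  free <- which(is.na(sub))
  base <- sum(2L^(which(sub == 1L) - 1L))
  if (length(free) == 0L) return(base)
  combos <- 0:(2L^length(free) - 1L)
  out <- rep(base, length(combos))
  for (j in seq_along(free)) {
    out <- out + bitwAnd(bitwShiftR(combos, j - 1L), 1L) * 2L^(free[j] - 1L)
  }
  sort(out)
}

## TRUE if sub1 is contained in sub2 (sub1 at least as constrained, agreeing
## on sub2's fixed variables)
subspace_contains <- function(sub2, sub1) {
  fixed2 <- which(!is.na(sub2))
  all(!is.na(sub1[fixed2]) & sub1[fixed2] == sub2[fixed2])
}

## is f_v restricted to `sub` constantly equal to `value`?
restricted_constant <- function(net, v, sub, value) {
  fn <- net$functions[[v]]
  k <- length(fn$inputs)
  if (k == 0L) return(fn$tt[1L] == value)
  idx <- match(fn$inputs, net$variables)
  fixedvals <- sub[idx]
  freepos <- which(is.na(fixedvals))
  base <- sum(2L^(which(fixedvals == 1L) - 1L))
  if (length(freepos) == 0L) return(fn$tt[base + 1L] == value)
  combos <- 0:(2L^length(freepos) - 1L)
  pos <- rep(base, length(combos))
  for (j in seq_along(freepos)) {
    pos <- pos + bitwAnd(bitwShiftR(combos, j - 1L), 1L) *
      2L^(freepos[j] - 1L)
  }
  all(fn$tt[pos + 1L] == value)
}

#' Is a subspace a trap space?
#'
#' A subspace is a trap space when its states cannot be left by the dynamics,
#' equivalently when the update function of every fixed variable is constantly
#' equal to the fixed value on the subspace. The predicate is evaluated on the
#' restricted input cube of each function and is independent of the update
#' scheme.
#'
#' @param net A `boolean_network`.
#' @param sub A subspace vector (or string such as `"1*0"`).
#' @return Logical scalar.
#' @export
is_trap_space <- function(net, sub) {
  if (is.character(sub)) sub <- parse_subspace(sub)
  stopifnot(length(sub) == n_vars(net))
  for (i in which(!is.na(sub))) {
    if (!restricted_constant(net, net$variables[i], sub, sub[i])) return(FALSE)
  }
  TRUE
}

#' Smallest trap space enclosing a set of states
#'
#' Starts from the componentwise span of the states and repeatedly frees any
#' fixed variable whose update function violates the fixed value somewhere in
#' the current subspace. Because trap spaces are closed under intersection,
#' the fixpoint is the unique inclusion-smallest trap space containing the
#' set.
#'
#' @param net A `boolean_network`.
#' @param states Integer vector of state codes (or character state strings).
#' @return A subspace vector.
#' @export
smallest_enclosing_trap_space <- function(net, states) {
  if (is.character(states)) states <- string_to_state(states)
  stopifnot(length(states) >= 1L)
  n <- n_vars(net)
  sub <- vapply(seq_len(n), function(i) {
    b <- state_bit(states, i)
    if (all(b == 1L)) 1L else if (all(b == 0L)) 0L else NA_integer_
  }, integer(1))
  trap_closure(net, sub)
}

## free violated fixed variables until the subspace is a trap space
trap_closure <- function(net, sub) {
  repeat {
    changed <- FALSE
    for (i in which(!is.na(sub))) {
      if (!restricted_constant(net, net$variables[i], sub, sub[i])) {
        sub[i] <- NA_integer_
        changed <- TRUE
      }
    }
    if (!changed) return(sub)
  }
}

## keep the inclusion-minimal subspaces of a list
minimal_subspaces <- function(subs) {
  if (length(subs) <= 1L) return(subs)
  keys <- vapply(subs, format_subspace, character(1))
  subs <- subs[!duplicated(keys)]
  keep <- rep(TRUE, length(subs))
  for (i in seq_along(subs)) {
    for (j in seq_along(subs)) {
      if (i != j && keep[i] &&
          subspace_contains(subs[[i]], subs[[j]]) &&
          !identical(subs[[i]], subs[[j]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  subs[keep]
}

#' All minimal trap spaces of a Boolean network
#'
#' Three interchangeable engines are provided: `"branching"` (default), a
#' depth-first search over partial assignments in `{0, 1, free}` with
#' restricted-function consistency pruning; `"brute"`, full enumeration of all
#' `3^N` subspaces (the oracle, limited to 12 variables); and `"attractor"`,
#' which builds the asynchronous STG and returns the inclusion-minimal
#' smallest enclosing trap spaces of the attractors (exact whenever the
#' explicit STG fits in memory, since every trap space contains an attractor
#' and a minimal trap space equals the enclosing trap space of any attractor
#' it contains).
#'
#' @param net A `boolean_network`.
#' @param method `"branching"`, `"brute"` or `"attractor"`.
#' @return List of subspace vectors, ordered by their string form.
#' @export
minimal_trap_spaces <- function(net,
                                method = c("branching", "brute", "attractor")) {
  method <- match.arg(method)
  n <- n_vars(net)
  subs <- switch(method,
    brute = {
      if (n > 12L) stop("brute-force engine limited to 12 variables")
      all_traps <- list()
      vals <- c(0L, 1L, NA_integer_)
      total <- 3L^n
      for (code in 0:(total - 1L)) {
        sub <- integer(n)
        c0 <- code
        for (i in seq_len(n)) {
          sub[i] <- vals[(c0 %% 3L) + 1L]
          c0 <- c0 %/% 3L
        }
        if (is_trap_space(net, sub)) {
          all_traps[[length(all_traps) + 1L]] <- sub
        }
      }
      minimal_subspaces(all_traps)
    },
    branching = {
      if (n > MAX_BRANCH_VARS) {
        stop("branching engine limited to ", MAX_BRANCH_VARS, " variables")
      }
      found <- list()
      sub <- rep(NA_integer_, n)
      recurse <- function(i) {
        if (i > n) {
          if (is_trap_space(net, sub)) {
            found[[length(found) + 1L]] <<- sub
          }
          return(invisible(NULL))
        }
        for (val in list(0L, 1L, NA_integer_)) {
          sub[i] <<- val
          ## prune: a fixed variable whose restricted function is constantly
          ## the opposite value can never recover by fixing more variables
          ok <- TRUE
          for (jj in which(!is.na(sub[seq_len(i)]))) {
            if (restricted_constant(net, net$variables[jj], sub,
                                    1L - sub[jj])) {
              ok <- FALSE
              break
            }
          }
          if (ok) recurse(i + 1L)
        }
        sub[i] <<- NA_integer_
        invisible(NULL)
      }
      recurse(1L)
      minimal_subspaces(found)
    },
    attractor = {
      atts <- attractors(net, "asynchronous")
      minimal_subspaces(lapply(atts, function(a) {
        smallest_enclosing_trap_space(net, a$states)
      }))
    })
  subs[order(vapply(subs, format_subspace, character(1)))]
}

#' Is a trap space inclusion-minimal?
#'
#' Searches for a proper trap space strictly inside `sub` by branching over
#' its free variables (the fixed variables stay fixed). A trap space is
#' minimal exactly when no such proper sub-trap-space exists.
#'
#' @param net A `boolean_network`.
#' @param sub A trap space (vector or string).
#' @return Logical scalar.
#' @export
is_minimal_trap_space <- function(net, sub) {
  if (is.character(sub)) sub <- parse_subspace(sub)
  if (!is_trap_space(net, sub)) stop("subspace is not a trap space")
  free <- which(is.na(sub))
  if (length(free) == 0L) return(TRUE)
  found <- FALSE
  recurse <- function(j, cur, any_fixed) {
    if (found) return(invisible(NULL))
    if (j > length(free)) {
      if (any_fixed && is_trap_space(net, cur)) found <<- TRUE
      return(invisible(NULL))
    }
    i <- free[j]
    for (val in list(0L, 1L, NA_integer_)) {
      cur[i] <- val
      ok <- TRUE
      if (!is.na(val) &&
          restricted_constant(net, net$variables[i], cur, 1L - val)) {
        ok <- FALSE
      }
      if (ok) recurse(j + 1L, cur, any_fixed || !is.na(val))
      if (found) return(invisible(NULL))
    }
    invisible(NULL)
  }
  recurse(1L, sub, FALSE)
  !found
}

## ---- MAA detection ---------------------------------------------------------

#' Find motif-avoidant attractors
#'
#' A motif-avoidant attractor (MAA) is a complex asynchronous attractor whose
#' smallest enclosing trap space is not a minimal trap space; equivalently, a
#' complex attractor contained in no minimal trap space. For every MAA the
#' report carries, per avoided minimal trap space, the metrics `M` (free
#' variables of the smallest trap space containing both the attractor and the
#' avoided trap space), `d` (number of oscillating variables) and `m` (the
#' minimal disagreement of an attractor state with the fixed variables of the
#' avoided trap space, restricted to the oscillating variables), together with
#' the induced delay-count upper bound.
#'
#' @param net A `boolean_network` within the explicit-STG size guard.
#' @param include_all Also return reports for complex attractors that are not
#'   motif-avoidant (default `FALSE`).
#' @return List of objects of class `maa_report`, ordered like [attractors()].
#' @export
find_maas <- function(net, include_all = FALSE) {
  atts <- attractors(net, "asynchronous")
  enclosing <- lapply(atts, function(a) {
    smallest_enclosing_trap_space(net, a$states)
  })
  mts <- minimal_subspaces(enclosing)
  mts_keys <- vapply(mts, format_subspace, character(1))
  reports <- list()
  for (ai in seq_along(atts)) {
    a <- atts[[ai]]
    if (a$kind != "complex") next
    tsp <- enclosing[[ai]]
    is_ma <- !(format_subspace(tsp) %in% mts_keys)
    if (!is_ma && !include_all) next
    span <- {
      n <- n_vars(net)
      vapply(seq_len(n), function(i) {
        b <- state_bit(a$states, i)
        if (all(b == 1L)) 1L else if (all(b == 0L)) 0L else NA_integer_
      }, integer(1))
    }
    metrics <- NULL
    if (is_ma) {
      rows <- lapply(mts, function(tmin) {
        md <- maa_metrics(net, a, tmin)
        ## the closed-form bound requires 2 <= d <= M and 1 <= m < d; an MAA
        ## can disagree with a trap space only on non-oscillating variables
        ## (m = 0), in which case the bound does not apply
        bd <- tryCatch(delay_upper_bound(md), error = function(e) NA_real_)
        data.frame(trap_space = format_subspace(tmin),
                   M = md[["M"]], d = md[["d"]], m = md[["m"]],
                   bound = bd,
                   stringsAsFactors = FALSE)
      })
      metrics <- do.call(rbind, rows)
      metrics <- metrics[order(metrics$bound, metrics$trap_space), ,
                         drop = FALSE]
      rownames(metrics) <- NULL
    }
    reports[[length(reports) + 1L]] <- structure(
      list(attractor = a,
           enclosing_subspace = span,
           enclosing_trap_space = tsp,
           is_motif_avoidant = is_ma,
           minimal_trap_spaces = mts,
           metrics = metrics),
      class = "maa_report")
  }
  reports
}

#' @export
print.maa_report <- function(x, ...) {
  cat(if (x$is_motif_avoidant) "Motif-avoidant" else "Trapped",
      "complex attractor:",
      paste(x$attractor$state_strings, collapse = " "), "\n")
  cat("  enclosing trap space:", format_subspace(x$enclosing_trap_space), "\n")
  if (!is.null(x$metrics)) {
    cat("  metrics per avoided minimal trap space:\n")
    print(x$metrics)
  }
  invisible(x)
}

#' Metrics (M, d, m) of an MAA relative to an avoided minimal trap space
#'
#' @param net A `boolean_network`.
#' @param attractor A complex `attractor` object (or integer state vector).
#' @param tmin A minimal trap space disjoint from the attractor.
#' @return Named numeric vector `c(M = , d = , m = )`.
#' @export
maa_metrics <- function(net, attractor, tmin) {
  if (is.character(tmin)) tmin <- parse_subspace(tmin)
  if (inherits(attractor, "attractor")) {
    states <- attractor$states
  } else {
    states <- as.integer(attractor)
  }
  if (length(states) < 2L) stop("attractor is not complex")
  if (!is_trap_space(net, tmin)) stop("tmin is not a trap space")
  if (!is_minimal_trap_space(net, tmin)) stop("tmin is not minimal")
  tmin_states <- subspace_states(tmin)
  if (any(states %in% tmin_states)) stop("tmin is not disjoint from attractor")
  n <- n_vars(net)
  osc <- which(vapply(seq_len(n), function(i) {
    b <- state_bit(states, i)
    any(b == 0L) && any(b == 1L)
  }, logical(1)))
  ## span of attractor states together with the trap space, then closure
  sub <- vapply(seq_len(n), function(i) {
    b <- state_bit(states, i)
    vals <- unique(c(b, tmin[i]))
    vals <- vals[!is.na(vals)]
    if (is.na(tmin[i])) return(NA_integer_)
    if (length(unique(vals)) == 1L) vals[1L] else NA_integer_
  }, integer(1))
  joint <- trap_closure(net, sub)
  M <- free_count(joint)
  d <- length(osc)
  fixed_osc <- osc[!is.na(tmin[osc])]
  m <- min(vapply(states, function(s) {
    sum(state_bit(s, fixed_osc) != tmin[fixed_osc])
  }, integer(1)))
  c(M = M, d = d, m = m)
}
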