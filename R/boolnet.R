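#' @keywords internal
"_PACKAGE"

## Truth-table convention used throughout the package:
## a function with inputs (i1, ..., ik) has a truth table `tt` of length 2^k,
## where entry `j` (1-based) gives the output for the input assignment encoded
## by the bits of `j - 1`, with input 1 as the least significant bit.

#' Construct a Boolean network
#'
#' A Boolean network is an ordered set of binary variables, each equipped with
#' an update function given as a truth table over an ordered list of input
#' variables. On construction every function is normalized: inputs that never
#' affect the output (non-essential inputs) are pruned, so that the declared
#' inputs of a function are exactly its essential dependencies. Degrees,
#' self-regulation and the interaction graph are therefore semantic properties
#' of the update functions, not syntactic artifacts of how they were written.
#'
#' @param variables Character vector of variable names (declaration order is
#'   the state order used in state strings such as `"01*"`).
#' @param functions Named list, one entry per variable, each a list with
#'   elements `inputs` (character vector of variable names, possibly empty)
#'   and `tt` (integer vector of 0/1 of length `2^length(inputs)`).
#' @param normalize Prune non-essential inputs (default `TRUE`).
#' @return An object of class `boolean_network`.
#' @export
boolean_network <- function(variables, functions, normalize = TRUE) {
  variables <- as.character(variables)
  ## the empty network (0 variables) is a legal degenerate case, produced by
  ## maximal reduction of fully constant networks
  if (anyDuplicated(variables)) {
    stop("duplicate variable names: ",
         paste(unique(variables[duplicated(variables)]), collapse = ", "))
  }
  if (!all(variables %in% names(functions))) {
    stop("missing update function for: ",
         paste(setdiff(variables, names(functions)), collapse = ", "))
  }
  functions <- functions[variables]
  for (v in variables) {
    fn <- functions[[v]]
    if (!is.list(fn) || is.null(fn$tt)) stop("malformed function for ", v)
    ins <- as.character(fn$inputs %||% character(0))
    bad <- setdiff(ins, variables)
    if (length(bad) > 0L) {
      stop("function for ", v, " uses undeclared variable(s): ",
           paste(bad, collapse = ", "))
    }
    if (anyDuplicated(ins)) stop("duplicate inputs in function for ", v)
    tt <- as.integer(fn$tt)
    if (length(tt) != 2L^length(ins) || !all(tt %in% c(0L, 1L))) {
      stop("truth table for ", v, " must contain 0/1 and have length 2^k")
    }
    functions[[v]] <- list(inputs = ins, tt = tt)
  }
  net <- structure(list(variables = variables, functions = functions),
                   class = "boolean_network")
  if (normalize) net <- normalize_network(net)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of variables of a Boolean network
#' @param net A `boolean_network`.
#' @return Integer scalar.
#' @export
n_vars <- function(net) length(net$variables)

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean network with", n_vars(x), "variable(s)\n")
  for (v in x$variables) {
    fn <- x$functions[[v]]
    cat(" ", v, ", ", function_to_expression(fn$inputs, fn$tt), "\n", sep = "")
  }
  invisible(x)
}

#' @export
format.boolean_network <- function(x, ...) write_bnet(x)

#' @exportS3Method base::all.equal
all.equal.boolean_network <- function(target, current, ...) {
  ## compare the semantic content only (bookkeeping attributes such as the
  ## generator's pruning count or an extension's delay table are ignored)
  all.equal(list(variables = target$variables, functions = target$functions),
            list(variables = current$variables,
                 functions = current$functions), ...)
}

## ---- truth-table utilities -------------------------------------------------

## which of the k inputs are essential (flipping them changes the output
## somewhere); vectorized over the table
tt_essential <- function(tt, k) {
  if (k == 0L) return(logical(0))
  idx <- 0:(2L^k - 1L)
  vapply(seq_len(k), function(j) {
    b <- 2L^(j - 1L)
    low <- idx[bitwAnd(idx, b) == 0L]
    any(tt[low + 1L] != tt[low + b + 1L])
  }, logical(1))
}

## restrict a truth table to a subset of its inputs (others fixed to 0;
## only valid when the dropped inputs are non-essential)
tt_project <- function(tt, k, keep) {
  k2 <- length(keep)
  if (k2 == k) return(tt)
  if (k2 == 0L) return(tt[1L])
  idx2 <- 0:(2L^k2 - 1L)
  full <- integer(length(idx2))
  for (j in seq_len(k2)) {
    full <- full + bitwAnd(bitwShiftR(idx2, j - 1L), 1L) * 2L^(keep[j] - 1L)
  }
  tt[full + 1L]
}

normalize_function <- function(inputs, tt) {
  k <- length(inputs)
  ess <- tt_essential(tt, k)
  if (all(ess)) return(list(inputs = inputs, tt = tt))
  keep <- which(ess)
  list(inputs = inputs[keep], tt = tt_project(tt, k, keep))
}

#' Prune non-essential inputs from every update function
#'
#' Also reorders every input list into variable declaration order (permuting
#' the truth table accordingly), so that normalized networks have a canonical
#' form and serialization round-trips are exact.
#'
#' @param net A `boolean_network`.
#' @return The normalized network.
#' @export
normalize_network <- function(net) {
  net$functions <- lapply(net$functions, function(fn) {
    fn <- normalize_function(fn$inputs, fn$tt)
    reorder_function_inputs(fn, net$variables)
  })
  net
}

## put a function's inputs into declaration order, permuting the table
reorder_function_inputs <- function(fn, variables) {
  k <- length(fn$inputs)
  if (k <= 1L) return(fn)
  ord <- order(match(fn$inputs, variables))
  if (all(ord == seq_len(k))) return(fn)
  newin <- fn$inputs[ord]
  idx <- 0:(2L^k - 1L)
  oldpos <- integer(length(idx))
  for (j in seq_len(k)) {
    ## bit j of the new assignment is the value of newin[j], which sat at
    ## position ord[j] in the old input list
    oldpos <- oldpos + bitwAnd(bitwShiftR(idx, j - 1L), 1L) * 2L^(ord[j] - 1L)
  }
  list(inputs = newin, tt = fn$tt[oldpos + 1L])
}

## evaluate variable v of `net` on a vector of (0-based) integer states
## idx: precomputed match(inputs, variables); returns 0/1 vector
eval_var_states <- function(net, v, states, idx = NULL) {
  fn <- net$functions[[v]]
  if (is.null(idx)) idx <- match(fn$inputs, net$variables)
  k <- length(idx)
  if (k == 0L) return(rep(fn$tt[1L], length(states)))
  pos <- integer(length(states))
  for (j in seq_len(k)) {
    pos <- pos + bitwAnd(bitwShiftR(states, idx[j] - 1L), 1L) * 2L^(j - 1L)
  }
  fn$tt[pos + 1L]
}

## evaluate a single full state given as an integer vector of variable values
eval_var_assignment <- function(net, v, assignment) {
  fn <- net$functions[[v]]
  if (length(fn$inputs) == 0L) return(fn$tt[1L])
  vals <- assignment[match(fn$inputs, net$variables)]
  fn$tt[sum(vals * 2L^(seq_along(vals) - 1L)) + 1L]
}

## bit i (1-based variable index) of 0-based integer states
state_bit <- function(states, i) bitwAnd(bitwShiftR(states, i - 1L), 1L)

#' Convert integer state codes to state strings
#'
#' States are encoded as integers in `0:(2^N - 1)` with variable `i` stored in
#' bit `i - 1`. State strings print variables in declaration order, e.g. state
#' `"01"` has the first variable OFF and the second ON.
#'
#' @param states Integer vector of state codes.
#' @param n Number of variables.
#' @return Character vector of `n`-character 0/1 strings.
#' @export
state_to_string <- function(states, n) {
  vapply(states, function(s) {
    paste(state_bit(s, seq_len(n)), collapse = "")
  }, character(1))
}

#' Convert state strings to integer state codes
#' @param strings Character vector of 0/1 strings.
#' @return Integer vector of state codes.
#' @export
string_to_state <- function(strings) {
  vapply(strings, function(str) {
    bits <- as.integer(strsplit(str, "")[[1]])
    as.integer(sum(bits * 2L^(seq_along(bits) - 1L)))
  }, integer(1), USE.NAMES = FALSE)
}

## deterministic ordering key for a set of states: the lexicographically
## smallest state string (equals numeric order of bit-reversed codes)
state_lex_key <- function(states, n) min(state_to_string(states, n))
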