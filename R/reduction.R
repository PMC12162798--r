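## Node-deletion reduction and constant percolation.

#' Delete a non-self-regulating variable from a Boolean network
#'
#' The variable's update function is substituted into the functions of every
#' variable it regulates; all affected functions are re-normalized, so
#' substitution identities (such as `X | !X == 1`) can turn targets into
#' constants. Deleting a freshly added delay node recovers the unextended
#' network exactly.
#'
#' @param net A `boolean_network`.
#' @param v Name of a variable with no essential self-input.
#' @return The reduced `boolean_network` (possibly empty).
#' @export
delete_node <- function(net, v) {
  if (!(v %in% net$variables)) stop("unknown variable: ", v)
  fv <- net$functions[[v]]
  if (v %in% fv$inputs) stop("variable ", v, " has an essential self-input")
  keep <- setdiff(net$variables, v)
  newfns <- vector("list", length(keep))
  names(newfns) <- keep
  for (w in keep) {
    fw <- net$functions[[w]]
    if (!(v %in% fw$inputs)) {
      newfns[[w]] <- fw
      next
    }
    newfns[[w]] <- substitute_function(fw, v, fv)
  }
  net$variables <- keep
  net$functions <- newfns
  attr(net, "delays") <- NULL
  attr(net, "n_original") <- NULL
  normalize_network(net)
}

## substitute function `fv` for input `v` of function `fw`; inputs of the
## result are ordered as (inputs(fw) \ v) followed by new inputs from fv
substitute_function <- function(fw, v, fv) {
  others <- setdiff(fw$inputs, v)
  newin <- c(others, setdiff(fv$inputs, others))
  k <- length(newin)
  if (k > MAX_IN_DEGREE) {
    stop("substitution exceeds the in-degree limit of ", MAX_IN_DEGREE)
  }
  combos <- 0:(max(2L^k, 1L) - 1L)
  bit_at <- function(name) {
    j <- match(name, newin)
    bitwAnd(bitwShiftR(combos, j - 1L), 1L)
  }
  ## value of v under each assignment
  if (length(fv$inputs) == 0L) {
    valv <- rep(fv$tt[1L], length(combos))
  } else {
    pos <- integer(length(combos))
    for (j in seq_along(fv$inputs)) {
      pos <- pos + bit_at(fv$inputs[j]) * 2L^(j - 1L)
    }
    valv <- fv$tt[pos + 1L]
  }
  ## value of w with v replaced by valv
  posw <- integer(length(combos))
  for (j in seq_along(fw$inputs)) {
    b <- if (fw$inputs[j] == v) valv else bit_at(fw$inputs[j])
    posw <- posw + b * 2L^(j - 1L)
  }
  list(inputs = newin, tt = fw$tt[posw + 1L])
}

#' Maximal node-deletion reduction
#'
#' Repeatedly deletes a variable without essential self-input until every
#' remaining variable self-regulates (or the network is empty). The default
#' policy picks the eligible variable with the fewest essential inputs,
#' breaking ties by declaration order. Candidate deletions that would push
#' some target function past the in-degree limit are passed over; if no
#' eligible variable can be deleted within the limit the trace is marked
#' `skipped`.
#'
#' @param net A `boolean_network`.
#' @return Object of class `reduction_trace`: list with `steps` (data frame
#'   of deleted variable and resulting size), `final` (the reduced network)
#'   and `skipped` (logical guard flag).
#' @export
reduce_max <- function(net) {
  steps_var <- character(0)
  steps_size <- integer(0)
  skipped <- FALSE
  repeat {
    eligible <- net$variables[vapply(net$variables, function(v) {
      !(v %in% net$functions[[v]]$inputs)
    }, logical(1))]
    if (length(eligible) == 0L) break
    nin <- vapply(eligible, function(v) length(net$functions[[v]]$inputs),
                  integer(1))
    eligible <- eligible[order(nin, match(eligible, net$variables))]
    deleted <- FALSE
    for (v in eligible) {
      if (!deletion_within_guard(net, v)) next
      net <- delete_node(net, v)
      steps_var <- c(steps_var, v)
      steps_size <- c(steps_size, n_vars(net))
      deleted <- TRUE
      break
    }
    if (!deleted) {
      skipped <- TRUE
      break
    }
  }
  structure(list(
    steps = data.frame(variable = steps_var, size_after = steps_size,
                       stringsAsFactors = FALSE),
    final = net,
    skipped = skipped
  ), class = "reduction_trace")
}

deletion_within_guard <- function(net, v) {
  fv <- net$functions[[v]]
  for (w in setdiff(net$variables, v)) {
    fw <- net$functions[[w]]
    if (!(v %in% fw$inputs)) next
    newin <- union(setdiff(fw$inputs, v), fv$inputs)
    if (length(newin) > MAX_IN_DEGREE) return(FALSE)
  }
  TRUE
}

#' @export
print.reduction_trace <- function(x, ...) {
  cat("Reduction trace:", nrow(x$steps), "deletion(s);",
      "final size", n_vars(x$final),
      if (x$skipped) "(skipped: in-degree guard)" else "", "\n")
  if (nrow(x$steps) > 0L) print(x$steps)
  invisible(x)
}

#' Percolate constant values through a Boolean network
#'
#' Substitutes the given constant assignment into every update function,
#' removes the assigned variables, then repeatedly substitutes and removes
#' any variable whose function has become constant, until a fixpoint. The
#' assignment is taken at face value; it is not required to be consistent
#' with the assigned variables' own functions.
#'
#' @param net A `boolean_network`.
#' @param assignment Named integer vector of 0/1 values for a subset of
#'   variables.
#' @return The percolated `boolean_network` (possibly empty).
#' @export
percolate <- function(net, assignment) {
  bad <- setdiff(names(assignment), net$variables)
  if (length(bad) > 0L) {
    stop("assignment references unknown variable(s): ",
         paste(bad, collapse = ", "))
  }
  pending <- as.integer(assignment)
  names(pending) <- names(assignment)
  while (length(pending) > 0L) {
    keep <- setdiff(net$variables, names(pending))
    newfns <- lapply(stats::setNames(keep, keep), function(w) {
      fw <- net$functions[[w]]
      fixed <- intersect(fw$inputs, names(pending))
      if (length(fixed) == 0L) return(fw)
      restrict_function(fw, pending[fixed])
    })
    net$variables <- keep
    net$functions <- newfns
    net <- normalize_network(net)
    pending <- unlist(lapply(stats::setNames(keep, keep), function(w) {
      fw <- net$functions[[w]]
      if (length(fw$inputs) == 0L) fw$tt[1L] else NULL
    }))
    if (is.null(pending)) pending <- integer(0)
  }
  net
}

## restrict a function by fixing some of its inputs to constants
restrict_function <- function(fn, fixvals) {
  keep <- setdiff(fn$inputs, names(fixvals))
  k2 <- length(keep)
  combos <- 0:(max(2L^k2, 1L) - 1L)
  pos <- integer(length(combos))
  for (j in seq_along(fn$inputs)) {
    nm <- fn$inputs[j]
    b <- if (nm %in% names(fixvals)) {
      rep(as.integer(fixvals[[nm]]), length(combos))
    } else {
      bitwAnd(bitwShiftR(combos, match(nm, keep) - 1L), 1L)
    }
    pos <- pos + b * 2L^(j - 1L)
  }
  list(inputs = keep, tt = fn$tt[pos + 1L])
}
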