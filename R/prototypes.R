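## Exhaustive survey of prototypical (template) MAAs in small networks with
## the point minimal trap space 11..1.
##
## Enumeration device: for an n-variable network, the asynchronous STG is
## fully determined by n "edge bytes" e_i whose bit s says whether updating
## variable i changes state s (tt_i = e_i XOR pattern_i, where pattern_i has
## bit s equal to bit i of s). Requiring f_i(11..1) = 1 for all i fixes the
## top bit of every edge byte to 0, so all networks with fixed point 11..1
## correspond exactly to the e-codes below. Reachability over all networks at
## once is computed with bit-parallel closure on 2^n-bit masks.

#' Survey prototypical motif-avoidant attractors in n-variable networks
#'
#' Enumerates every n-variable Boolean network whose only minimal trap space
#' is the point 11..1 and that has a motif-avoidant attractor, keeps the MAAs
#' whose internal transition structure is edge-minimal (removing any single
#' transition among attractor states destroys the attractor, i.e. every
#' internal edge is critical for its strong connectivity), and groups the
#' resulting attractor patterns up to variable relabeling (the permutations
#' are the only relabeling/negation symmetries that fix the trap space
#' 11..1). For each template class a representative network is analyzed:
#' metrics (M, d, m) against the avoided trap space and the single-edge
#' linear extensions that eliminate the MAA.
#'
#' @param n Number of variables (2 or 3; the enumeration is exhaustive over
#'   `2^(n * (2^n - 1))` networks).
#' @return List with `n_classes`, `classes` (per class: `states`, `edges`,
#'   `M`, `d`, `m`, `eliminating_edges`, `network`), and `convention`
#'   describing the grouping.
#' @export
prototype_maa_survey <- function(n = 3L) {
  n <- as.integer(n)
  stopifnot(n %in% c(2L, 3L))
  ns <- 2L^n
  trap <- ns - 1L
  pattern <- vapply(seq_len(n), function(i) {
    s <- 0:(ns - 1L)
    sum(2L^s[bitwAnd(bitwShiftR(s, i - 1L), 1L) == 1L])
  }, numeric(1))
  pattern <- as.integer(pattern)
  ne_codes <- 2L^(ns - 1L)
  total <- ne_codes^n
  code <- 0:(total - 1L)
  e <- lapply(seq_len(n), function(i) {
    as.integer((code %/% ne_codes^(i - 1L)) %% ne_codes)
  })
  ## bit-parallel reachability closure across all networks
  M <- lapply(0:(ns - 1L), function(s) rep(2L^s, total))
  for (sweep in seq_len(ns)) {
    for (s in 0:(ns - 1L)) {
      acc <- M[[s + 1L]]
      for (i in seq_len(n)) {
        b <- bitwAnd(bitwShiftR(e[[i]], s), 1L)
        t <- bitwXor(s, 2L^(i - 1L))
        acc <- bitwOr(acc, M[[t + 1L]] * b)
      }
      M[[s + 1L]] <- acc
    }
  }
  ## R_s: bit t set when s is reachable from t
  R <- lapply(0:(ns - 1L), function(s) {
    acc <- integer(total)
    for (t in 0:(ns - 1L)) {
      acc <- acc + bitwAnd(bitwShiftR(M[[t + 1L]], s), 1L) * 2L^t
    }
    acc
  })
  mask_all <- 2L^ns - 1L
  pc <- popcount(0:mask_all)
  has_complex <- rep(FALSE, total)
  terminal <- vector("list", ns)
  scc <- vector("list", ns)
  for (s in 0:(ns - 1L)) {
    terminal[[s + 1L]] <- bitwAnd(M[[s + 1L]],
                                  bitwXor(R[[s + 1L]], mask_all)) == 0L
    scc[[s + 1L]] <- bitwAnd(M[[s + 1L]], R[[s + 1L]])
    if (s != trap) {
      has_complex <- has_complex |
        (terminal[[s + 1L]] & pc[scc[[s + 1L]] + 1L] >= 2L)
    }
  }
  ## the only minimal trap space must be the point 11..1: no subspace fixing
  ## some variable to 0 may be a trap space
  tt <- lapply(seq_len(n), function(i) bitwXor(e[[i]], pattern[i]))
  bad <- rep(FALSE, total)
  for (scode in 0:(3L^n - 1L)) {
    sub <- integer(n)
    c0 <- scode
    for (i in seq_len(n)) {
      sub[i] <- c(0L, 1L, NA_integer_)[(c0 %% 3L) + 1L]
      c0 <- c0 %/% 3L
    }
    fixed <- which(!is.na(sub))
    if (length(fixed) == 0L || all(sub[fixed] == 1L)) next
    states <- 0:(ns - 1L)
    inT <- rep(TRUE, ns)
    for (i in fixed) inT <- inT & state_bit(states, i) == sub[i]
    maskT <- sum(2L^states[inT])
    is_trap <- rep(TRUE, total)
    for (i in fixed) {
      want <- if (sub[i] == 1L) maskT else 0L
      is_trap <- is_trap & bitwAnd(tt[[i]], as.integer(maskT)) == want
    }
    bad <- bad | is_trap
  }
  qualifies <- has_complex & !bad
  n_candidates <- sum(qualifies)

  ## collect distinct MAA patterns. Because the attractor is terminal, the
  ## internal transitions are exactly the change-bits of each variable
  ## restricted to the attractor mask, so (amask, e_1 & amask, ...) encodes
  ## the pattern; this keys all patterns fully vectorized.
  pat_key <- numeric(0)
  pat_index <- integer(0)
  for (s in 0:(ns - 1L)) {
    if (s == trap) next
    sel <- qualifies & terminal[[s + 1L]] & pc[scc[[s + 1L]] + 1L] >= 2L
    if (!any(sel)) next
    amask <- scc[[s + 1L]][sel]
    key <- amask
    for (i in seq_len(n)) key <- key * 256 + bitwAnd(e[[i]][sel], amask)
    pat_key <- c(pat_key, key)
    pat_index <- c(pat_index, which(sel))
  }
  first <- !duplicated(pat_key)
  pat_key <- pat_key[first]
  pat_index <- pat_index[first]
  patterns <- lapply(seq_along(pat_key), function(j) {
    key <- pat_key[j]
    ein <- integer(n)
    for (i in rev(seq_len(n))) {
      ein[i] <- as.integer(key %% 256)
      key <- key %/% 256
    }
    amask <- as.integer(key)
    astates <- which(bitwAnd(bitwShiftR(amask, 0:(ns - 1L)), 1L) == 1L) - 1L
    edges <- integer(0)  # encoded s * n + (i - 1)
    for (st in astates) {
      for (i in seq_len(n)) {
        if (bitwAnd(bitwShiftR(ein[i], st), 1L) == 1L) {
          edges <- c(edges, st * n + (i - 1L))
        }
      }
    }
    list(amask = amask, astates = astates, edges = sort(edges),
         net_index = pat_index[j])
  })

  ## edge-minimality: every internal edge critical for strong connectivity
  ## (bitmask Warshall closure over the <= 2^n attractor states)
  strongly_connected <- function(astates, edges, amask) {
    reach <- 2L^(0:(ns - 1L))
    for (ed in edges) {
      s <- ed %/% n
      t <- bitwXor(s, 2L^(ed %% n))
      reach[s + 1L] <- bitwOr(reach[s + 1L], 2L^t)
    }
    for (k in astates) {
      bk <- 2L^k
      for (s in astates) {
        if (bitwAnd(reach[s + 1L], bk) != 0L) {
          reach[s + 1L] <- bitwOr(reach[s + 1L], reach[k + 1L])
        }
      }
    }
    all(bitwAnd(reach[astates + 1L], amask) == amask)
  }
  minimal <- Filter(function(p) {
    for (j in seq_along(p$edges)) {
      if (strongly_connected(p$astates, p$edges[-j], p$amask)) return(FALSE)
    }
    TRUE
  }, patterns)

  ## group up to variable permutation
  perms <- perms_of(n)
  canon_key <- function(p) {
    keys <- vapply(perms, function(pm) {
      ast2 <- vapply(p$astates, function(s) permute_state(s, pm, n), integer(1))
      ed2 <- vapply(p$edges, function(ed) {
        s <- ed %/% n
        i <- ed %% n + 1L
        permute_state(s, pm, n) * n + (match(i, pm) - 1L)
      }, integer(1))
      paste(paste(sort(ast2), collapse = ","),
            paste(sort(ed2), collapse = ","), sep = "|")
    }, character(1))
    min(keys)
  }
  keys <- vapply(minimal, canon_key, character(1))
  classes <- lapply(split(minimal, keys), function(group) group[[1L]])

  ## analyze one representative per class
  vars <- LETTERS[seq_len(n)]
  out_classes <- lapply(classes, function(p) {
    fns <- lapply(stats::setNames(seq_len(n), vars), function(i) {
      list(inputs = vars, tt = bitwAnd(bitwShiftR(tt[[i]][p$net_index],
                                                  0:(ns - 1L)), 1L))
    })
    net <- boolean_network(vars, fns)
    reports <- find_maas(net)
    rp <- NULL
    for (r in reports) {
      if (setequal(r$attractor$states, p$astates)) rp <- r
    }
    md <- if (!is.null(rp)) rp$metrics[1L, c("M", "d", "m")] else NULL
    ig <- interaction_graph(net)
    elim <- logical(nrow(ig$edges))
    for (r in seq_len(nrow(ig$edges))) {
      ext <- linear_extend(net, ig$edges[r, c("from", "to"), drop = FALSE])
      elim[r] <- length(find_maas(ext)) == 0L
    }
    list(states = state_to_string(p$astates, n),
         edges = data.frame(
           from = state_to_string(p$edges %/% n, n),
           variable = vars[p$edges %% n + 1L]),
         M = md$M, d = md$d, m = md$m,
         eliminating_edges = ig$edges[elim, c("from", "to"), drop = FALSE],
         network = net)
  })
  list(n_classes = length(out_classes),
       classes = out_classes,
       n_networks_enumerated = total,
       n_candidate_networks = n_candidates,
       convention = paste("patterns = (attractor states, internal",
                          "transitions), edge-minimal, grouped up to",
                          "variable permutation; trap space fixed at 11..1"))
}

perms_of <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- perms_of(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

## relabel a state under a variable permutation: bit j of the result is bit
## pm[j] of s
permute_state <- function(s, pm, n) {
  bits <- bitwAnd(bitwShiftR(s, pm - 1L), 1L)
  as.integer(sum(bits * 2L^(seq_len(n) - 1L)))
}
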