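test_that("deleting a fresh delay node undoes the extension", {
  for (net in list(net_2var_maa(), star_network(3), net_embedded_maa())) {
    ig <- interaction_graph(net)
    e <- ig$edges[2, c("from", "to"), drop = FALSE]
    ext <- linear_extend(net, e)
    expect_same_network(delete_node(ext, paste("d", e$from, e$to, sep = "_")),
                        net)
  }
})

test_that("reducing the linear node of the hidden-MAA chain creates the 2-variable MAA", {
  net <- net_hidden_maa()
  expect_length(find_maas(net), 0)
  red <- delete_node(net, "C")
  expect_same_network(red, net_2var_maa())
  expect_length(find_maas(red), 1)
})

test_that("deleting a constant node percolates its value", {
  net <- parse_bnet("A, 1\nB, A & C\nC, C")
  red <- delete_node(net, "A")
  expect_equal(red$functions$B, list(inputs = "C", tt = c(0L, 1L)))
})

test_that("delete_node enforces the no-self-input precondition", {
  expect_error(delete_node(net_2var_maa(), "A"), "self-input")
  expect_error(delete_node(net_mutual(), "Z"), "unknown variable")
})

test_that("maximal reduction follows the fewest-inputs policy to a fixpoint", {
  tr <- reduce_max(net_mutual())
  expect_equal(n_vars(tr$final), 1L)
  expect_false(tr$skipped)
  # the surviving variable self-regulates via the substituted loop
  v <- tr$final$variables
  expect_equal(tr$final$functions[[v]]$inputs, v)

  # fully constant network reduces to the empty network
  tr2 <- reduce_max(parse_bnet("A, 1\nB, 0\nC, A"))
  expect_equal(n_vars(tr2$final), 0L)

  # star networks are already maximally reduced: every variable has an
  # essential self-input
  for (N in 2:4) {
    tr3 <- reduce_max(star_network(N))
    expect_equal(nrow(tr3$steps), 0L)
    expect_equal(n_vars(tr3$final), N)
  }
})

test_that("percolation fixes, propagates and removes constants", {
  casc <- parse_bnet("A, A\nB, A\nC, B")
  out <- percolate(casc, c(A = 1L))
  expect_equal(n_vars(out), 0L)

  # a value inconsistent with a self-sustaining loop leaves the loop intact;
  # C collapses to the constant 0 and percolates away
  loop <- parse_bnet("A, A\nB, B\nC, A & B")
  out2 <- percolate(loop, c(B = 0L))
  expect_equal(out2$variables, "A")
  expect_equal(out2$functions$A, list(inputs = "A", tt = c(0L, 1L)))

  expect_error(percolate(loop, c(Z = 1L)), "unknown variable")
})

test_that("percolation never adds essential edges", {
  set.seed(17)
  for (i in 1:20) {
    net <- generate_critical_rbn(6, 2, p = 0.5)
    pick <- sample(net$variables, 2)
    before <- interaction_graph(net)$edges
    out <- percolate(net, stats::setNames(sample(0:1, 2, replace = TRUE),
                                          pick))
    if (n_vars(out) == 0L) next
    after <- interaction_graph(out)$edges
    expect_true(all(paste(after$from, after$to) %in%
                    paste(before$from, before$to)))
  }
})

test_that("fixed points are preserved bijectively under maximal reduction", {
  nets <- random_corpus(60, seed = 9090)
  for (net in nets) {
    if (n_vars(net) == 0L || n_vars(net) > 8L) next
    tr <- reduce_max(net)
    if (tr$skipped) next
    fps0 <- Filter(function(a) a$kind == "point", attractors(net))
    red <- tr$final
    if (n_vars(red) == 0L) {
      expect_lte(length(fps0), 1L)
      next
    }
    fps1 <- Filter(function(a) a$kind == "point", attractors(red))
    expect_equal(length(fps0), length(fps1))
    # projection of original fixed points onto surviving variables
    kept <- match(red$variables, net$variables)
    proj <- sort(vapply(fps0, function(a) {
      as.integer(sum(state_bit(a$states, kept) * 2L^(seq_along(kept) - 1L)))
    }, integer(1)))
    expect_equal(proj, sort(vapply(fps1, function(a) a$states, integer(1))))
  }
})

test_that("reduced transitions lift to trajectories of the original network", {
  # deleting v maps a reduced transition to >= 1 original transition from the
  # representative state (v set to its updated value)
  nets <- random_corpus(30, seed = 6060)
  for (net in nets) {
    if (n_vars(net) < 2L || n_vars(net) > 6L) next
    cand <- Filter(function(v) !(v %in% net$functions[[v]]$inputs),
                   net$variables)
    if (length(cand) == 0L) next
    v <- cand[[1]]
    red <- delete_node(net, v)
    if (n_vars(red) == 0L) next
    stgR <- build_stg(red, "asynchronous")
    kept <- match(red$variables, net$variables)
    vi <- match(v, net$variables)
    stgO <- build_stg(net, "asynchronous")
    okey <- paste(stgO$from, stgO$to)
    lift <- function(sR) {
      ## representative state: v takes its updated value
      bits <- integer(n_vars(net))
      bits[kept] <- state_bit(sR, seq_along(kept))
      bits[vi] <- eval_var_assignment(net, v, bits)
      sum(bits * 2L^(seq_len(n_vars(net)) - 1L))
    }
    ok <- TRUE
    for (e in seq_along(stgR$from)) {
      ## the reduced transition flips one kept variable; from the
      ## representative state the original network performs the same flip
      sO <- lift(stgR$from[e])
      wk <- which(bitwXor(stgR$from[e], stgR$to[e]) ==
                  2L^(seq_along(kept) - 1L))
      tO <- bitwXor(sO, 2L^(kept[wk] - 1L))
      ok <- ok && (paste(sO, tO) %in% okey)
    }
    expect_true(ok)
  }
})

test_that("reduction can create and destroy motif avoidance", {
  # creation: the hidden-MAA chain (above) gains an MAA when C is deleted
  expect_length(find_maas(net_hidden_maa()), 0)
  expect_length(find_maas(delete_node(net_hidden_maa(), "C")), 1)

  # destruction: the synthetic fixture loses its MAA when A is deleted;
  # the oscillation survives but is trapped in a minimal trap space
  net <- net_reduction_kills_maa()
  expect_gte(length(find_maas(net)), 1)
  red <- delete_node(net, "A")
  expect_length(find_maas(red), 0)
  complex <- Filter(function(a) a$kind == "complex", attractors(red))
  expect_gte(length(complex), 1)
})
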