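test_that("STG construction matches the update semantics", {
  net <- net_mutual()
  sy <- build_stg(net, "synchronous")
  succ_of <- function(stg, s) stg_successors(stg, string_to_state(s))
  expect_equal(succ_of(sy, "01"), string_to_state("10"))
  expect_equal(succ_of(sy, "10"), string_to_state("01"))

  as <- build_stg(net, "asynchronous")
  expect_setequal(succ_of(as, "01"), string_to_state(c("00", "11")))
  # fixed points have zero outgoing asynchronous edges
  expect_length(succ_of(as, "00"), 0)
  expect_length(succ_of(as, "11"), 0)

  # constant network: every state flows into the unique fixed point
  cnet <- parse_bnet("A, 1\nB, 0")
  ast <- build_stg(cnet, "asynchronous")
  g <- igraph::make_graph(rbind(ast$from + 1L, ast$to + 1L), n = 4)
  fp <- string_to_state("10") + 1L
  for (s in 1:4) {
    expect_true(fp %in% igraph::subcomponent(g, s, mode = "out"))
  }
})

test_that("attractors are the terminal SCCs, per scheme", {
  net <- net_mutual()
  as_at <- attractors(net, "asynchronous")
  expect_length(as_at, 2)
  expect_equal(sort(vapply(as_at, function(a) a$state_strings, character(1))),
               c("00", "11"))

  sy_at <- attractors(net, "synchronous")
  expect_length(sy_at, 3)
  kinds <- vapply(sy_at, function(a) a$kind, character(1))
  expect_equal(sum(kinds == "complex"), 1L)
  cyc <- sy_at[[which(kinds == "complex")]]
  expect_setequal(cyc$state_strings, c("01", "10"))
  expect_setequal(cyc$oscillating, c("A", "B"))

  m <- attractors(net_2var_maa())
  expect_length(m, 2)
  sizes <- sort(vapply(m, function(a) length(a$states), integer(1)))
  expect_equal(sizes, c(1L, 3L))
})

test_that("trap-space predicate works by restricted-cube evaluation", {
  star2 <- net_2var_maa()
  expect_true(is_trap_space(star2, "**"))
  expect_true(is_trap_space(star2, "11"))
  expect_false(is_trap_space(star2, "0*"))
  expect_false(is_trap_space(net_mutual(), "0*"))
  expect_true(is_trap_space(net_mutual(), "00"))
})

test_that("smallest enclosing trap space is the closure of the span", {
  star2 <- net_2var_maa()
  expect_equal(format_subspace(smallest_enclosing_trap_space(star2, "11")),
               "11")
  expect_equal(format_subspace(
    smallest_enclosing_trap_space(star2, c("00", "01", "10"))), "**")
  star3 <- star_network(3)
  expect_equal(format_subspace(smallest_enclosing_trap_space(
    star3, c("000", "100", "010", "001"))), "***")
})

test_that("minimal trap spaces: fixtures and engine agreement", {
  expect_equal(vapply(minimal_trap_spaces(net_mutual()), format_subspace,
                      character(1)), c("00", "11"))
  expect_equal(vapply(minimal_trap_spaces(net_2var_maa()), format_subspace,
                      character(1)), "11")
  expect_equal(vapply(minimal_trap_spaces(parse_bnet("A, 1\nB, 0")),
                      format_subspace, character(1)), "10")

  # the three engines agree on a random corpus
  nets <- random_corpus(40, seed = 1001)
  for (net in nets) {
    if (n_vars(net) == 0L || n_vars(net) > 8L) next
    br <- vapply(minimal_trap_spaces(net, "branching"), format_subspace,
                 character(1))
    bf <- vapply(minimal_trap_spaces(net, "brute"), format_subspace,
                 character(1))
    at <- vapply(minimal_trap_spaces(net, "attractor"), format_subspace,
                 character(1))
    expect_equal(br, bf)
    expect_equal(br, at)
  }
})

test_that("every minimal trap space contains at least one attractor", {
  nets <- random_corpus(80, seed = 2002)
  for (net in nets) {
    if (n_vars(net) == 0L || n_vars(net) > 8L) next
    atts <- attractors(net)
    for (sub in minimal_trap_spaces(net, "branching")) {
      states <- subspace_states(sub)
      expect_true(any(vapply(atts, function(a) all(a$states %in% states),
                             logical(1))))
    }
  }
})

test_that("MAA detection matches the fixtures", {
  expect_length(find_maas(net_mutual()), 0)

  reps <- find_maas(net_2var_maa())
  expect_length(reps, 1)
  expect_setequal(reps[[1]]$attractor$state_strings, c("00", "01", "10"))
  expect_equal(format_subspace(reps[[1]]$enclosing_trap_space), "**")
  expect_equal(unlist(reps[[1]]$metrics[1, c("M", "d", "m")]),
               c(M = 2, d = 2, m = 1))

  for (N in 2:5) {
    reps <- find_maas(star_network(N))
    expect_length(reps, 1)
    expect_length(reps[[1]]$attractor$states, N + 1)
    expect_equal(unlist(reps[[1]]$metrics[1, c("M", "d", "m")]),
                 c(M = N, d = N, m = N - 1))
  }
})

test_that("motif avoidance equals exclusion from every minimal trap space", {
  nets <- c(list(net_2var_maa(), star_network(3), net_embedded_maa(),
                 net_six_cycle_maa(), net_reduction_kills_maa()),
            random_corpus(60, seed = 3003))
  for (net in nets) {
    if (n_vars(net) == 0L || n_vars(net) > 8L) next
    mts <- minimal_trap_spaces(net, "branching")
    for (rp in find_maas(net, include_all = TRUE)) {
      contained <- any(vapply(mts, function(sub) {
        all(rp$attractor$states %in% subspace_states(sub))
      }, logical(1)))
      expect_equal(rp$is_motif_avoidant, !contained)
      if (rp$is_motif_avoidant) {
        # at least two variables must oscillate
        expect_gte(length(rp$attractor$oscillating), 2)
        # and the enclosing trap space must not be minimal
        expect_false(is_minimal_trap_space(net, rp$enclosing_trap_space))
      }
    }
  }
})

test_that("maa_metrics validates its preconditions", {
  star2 <- net_2var_maa()
  fp <- attractors(star2)[[2]]  # the 11 fixed point
  expect_equal(fp$kind, "point")
  expect_error(maa_metrics(star2, fp, "11"), "not complex")
  maa <- find_maas(star2)[[1]]$attractor
  expect_error(maa_metrics(star2, maa, "0*"), "not a trap space")
  expect_error(maa_metrics(star2, maa, "**"), "not minimal")
})
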