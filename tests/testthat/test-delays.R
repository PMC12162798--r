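test_that("linear extension builds the documented extended network", {
  star2 <- net_2var_maa()
  ig <- interaction_graph(star2)
  ext <- linear_extend(star2, ig$edges[, c("from", "to")])
  expect_equal(n_vars(ext), 6L)
  expect_true(is_l_cuttable(interaction_graph(ext)))
  expect_length(find_maas(ext), 0)

  # extending then deleting the delay node is the identity
  e <- data.frame(from = "A", to = "B")
  expect_same_network(delete_node(linear_extend(star2, e), "d_A_B"), star2)
  expect_error(linear_extend(net_mutual(), data.frame(from = "A", to = "A")),
               "not an essential edge")

  # a delay on A -> B makes the all-ones state reachable from all-zeros
  ext1 <- linear_extend(star2, e)
  stg <- build_stg(ext1, "asynchronous")
  g <- igraph::make_graph(rbind(stg$from + 1L, stg$to + 1L),
                          n = stg$n_states)
  zero <- 1L
  ones <- stg$n_states
  expect_true(ones %in% igraph::subcomponent(g, zero, mode = "out"))
  # ... which is impossible in the unextended system
  stg0 <- build_stg(star2, "asynchronous")
  g0 <- igraph::make_graph(rbind(stg0$from + 1L, stg0$to + 1L), n = 4)
  expect_false(4 %in% igraph::subcomponent(g0, 1, mode = "out"))
})

test_that("extension preserves fixed points and minimal trap space count", {
  for (net in list(net_2var_maa(), star_network(3), net_embedded_maa())) {
    ig <- interaction_graph(net)
    ext <- linear_extend(net, ig$edges[1:2, c("from", "to")])
    fp0 <- Filter(function(a) a$kind == "point", attractors(net))
    fp1 <- Filter(function(a) a$kind == "point", attractors(ext))
    expect_equal(length(fp0), length(fp1))
    expect_equal(length(minimal_trap_spaces(net, "branching")),
                 length(minimal_trap_spaces(ext, "branching")))
  }
})

test_that("single-delay survey matches the star family", {
  star2 <- net_2var_maa()
  sv <- single_delay_survey(star2, find_maas(star2)[[1]])
  expect_equal(nrow(sv), 4L)
  expect_true(all(sv$eliminates))

  star3 <- star_network(3)
  sv3 <- single_delay_survey(star3, find_maas(star3)[[1]])
  expect_equal(attr(sv3, "n_success"), 0L)

  # precondition: the report must be an MAA
  expect_error(single_delay_survey(net_mutual(), list()), "not a motif")
})

test_that("exhaustive minimal delay search certifies the small star members", {
  r2 <- minimal_delay_set_size(net_2var_maa())
  expect_equal(r2$size, 1L)
  r3 <- minimal_delay_set_size(star_network(3))
  expect_equal(r3$size, 2L)
  expect_error(minimal_delay_set_size(net_mutual()), "no MAA")
  # exhausting the limit reports a certified lower bound
  r0 <- minimal_delay_set_size(star_network(3), limit = 1L)
  expect_true(is.na(r0$size))
  expect_equal(r0$certified_lower_bound, 2L)
})

test_that("delay bounds evaluate the closed forms", {
  expect_equal(delay_upper_bound(c(M = 2, d = 2, m = 1)), 1)
  expect_equal(delay_upper_bound(c(N = 4, d = 3, m = 1)), 4)
  for (N in 2:6) {
    expect_equal(delay_upper_bound(c(M = N, d = N, m = N - 1)),
                 N * (N - 1) / 2)
  }
  expect_error(delay_upper_bound(c(M = 3, d = 2, m = 2)), "m < d")
  expect_error(delay_upper_bound(c(M = 2, d = 3, m = 1)), "d <= M")

  expect_equal(worst_case_bound(4, 2), 1)
  expect_error(worst_case_bound(5, 2), "perfect square")
  # algebraic identity with the general bound at m = d - 1
  for (N in 2:10) {
    for (d in 2:N) {
      expect_equal(worst_case_bound(N^2, d),
                   delay_upper_bound(c(M = N, d = d, m = d - 1)))
      expect_lt(worst_case_bound(N^2, d), N^2)
    }
  }
})

test_that("memory-state transition classification separates gained and lost", {
  star2 <- net_2var_maa()
  selfA <- data.frame(from = "A", to = "A")

  # non-functional delay: no gained and no lost transitions
  cm0 <- classify_memory_transitions(star2, selfA, rewire = FALSE)
  expect_equal(nrow(cm0$gained), 0L)
  expect_equal(nrow(cm0$lost), 0L)

  # functional delay on the self-edge of A: gained transitions exist and
  # enable reaching the trap space
  cm <- classify_memory_transitions(star2, selfA)
  expect_gt(nrow(cm$gained), 0)
  expect_true("11" %in% cm$gained$projected_to)

  # sources are always memory states (delay bit differs from parent)
  ext <- linear_extend(star2, selfA)
  for (df in list(cm$gained, cm$lost)) {
    for (s in df$state) {
      bits <- as.integer(strsplit(s, "")[[1]])
      expect_true(bits[1] != bits[3])  # A vs d_A_A
    }
  }
})

test_that("projected STG keeps original edges and classifies gained ones", {
  star2 <- net_2var_maa()
  # empty delay set: identical to the original STG
  p0 <- projected_stg(star2, data.frame(from = character(0),
                                        to = character(0)))
  expect_true(all(p0$edges$class == "original"))
  expect_equal(nrow(p0$edges), 4L)

  stg0 <- build_stg(star2, "asynchronous")
  okey <- paste(state_to_string(stg0$from, 2), state_to_string(stg0$to, 2))
  ig <- interaction_graph(star2)
  for (r in seq_len(nrow(ig$edges))) {
    p <- projected_stg(star2, ig$edges[r, c("from", "to")])
    # every original edge is retained
    expect_true(all(okey %in% paste(p$edges$from, p$edges$to)))
    # no self-edges
    expect_false(any(p$edges$from == p$edges$to))
    # one delay eliminates this MAA, so some gained edge must open a path
    # from the attractor towards the trap space
    expect_gt(sum(p$edges$class == "gained"), 0)
    # every gained edge carries a witness path through memory states
    gained <- p$edges[p$edges$class == "gained", ]
    expect_equal(length(p$witnesses), nrow(gained))
  }
})

test_that("projected connectivity is monotone in the delay set", {
  star2 <- net_2var_maa()
  ig <- interaction_graph(star2)
  d1 <- ig$edges[1, c("from", "to")]
  d2 <- ig$edges[1:2, c("from", "to")]
  p1 <- projected_stg(star2, d1)
  p2 <- projected_stg(star2, d2)
  expect_true(all(paste(p1$edges$from, p1$edges$to) %in%
                  paste(p2$edges$from, p2$edges$to)))
})

test_that("full linear extension eliminates every fixture MAA", {
  for (net in list(net_2var_maa(), star_network(3), net_embedded_maa(),
                   net_six_cycle_maa(), net_reduction_kills_maa())) {
    expect_gte(length(find_maas(net)), 1)
    ig <- interaction_graph(net)
    ext <- linear_extend(net, ig$edges[, c("from", "to")])
    expect_length(find_maas(ext), 0)
  }
})

test_that("an MAA with M = d and m = 1 is eliminated by some single delay", {
  # fixtures known to satisfy the hypothesis
  net <- net_embedded_maa()
  rp <- find_maas(net)[[1]]
  md <- rp$metrics[1, ]
  expect_true(md$M > md$d || (md$d == 2 && md$m == 1))
  # hypothesis M = d, m = 1 holds for the 2-variable MAA
  sv <- single_delay_survey(net_2var_maa(), find_maas(net_2var_maa())[[1]])
  expect_gt(attr(sv, "n_success"), 0)
  # and for qualifying MAAs discovered in a random corpus
  nets <- random_corpus(120, seed = 7777)
  checked <- 0L
  for (cand in nets) {
    if (n_vars(cand) == 0L || n_vars(cand) > 7L) next
    for (rp in find_maas(cand)) {
      qual <- any(rp$metrics$M == rp$metrics$d & rp$metrics$m == 1)
      if (!qual) next
      checked <- checked + 1L
      sv <- single_delay_survey(cand, rp)
      expect_gt(attr(sv, "n_success"), 0)
    }
  }
  expect_gte(checked, 1)
})
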