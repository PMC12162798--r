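# Fixture networks built in code.

# mutual activation: A copies B and vice versa; synchronous 2-cycle MAA that
# vanishes under asynchronous update
net_mutual <- function() parse_bnet("A, B\nB, A")

# the unique 2-variable MAA network (both functions XNOR)
net_2var_maa <- function() star_network(2)

# 3-variable chain hiding the 2-variable MAA behind a linear node C on the
# A -> B edge; deleting C recovers the canonical 2-variable MAA
net_hidden_maa <- function() {
  parse_bnet("A, !A & !B | A & B\nB, !C & !B | C & B\nC, A")
}

# 2-variable MAA embedded in the **0 subspace with trap space 111
net_embedded_maa <- function() {
  parse_bnet("A, !A & !B | A & B | C\nB, !A & !B | A & B | C\nC, A & B")
}

# synthetic fixture (found by randomized search, frozen here): the original
# 3-variable network has an MAA; deleting A leaves a 2-state oscillation
# trapped inside the minimal trap space *0 -- node deletion destroys the MAA
# by creating a new stable motif, mirroring the mechanism in which newly
# coincident influences percolate to a constant
net_reduction_kills_maa <- function() {
  parse_bnet(paste(
    "A, !B",
    "B, A & !B & !C | A & B & !C | !A & B & C | A & B & C",
    "C, A & B & !C | !A & !B & C | A & !B & C | A & B & C",
    sep = "\n"))
}

# 3-variable MAA forming a single 6-cycle of one-bit transitions
# 000 -> 100 -> 110 -> 010 -> 011 -> 001 -> 000, with fixed point 111 and
# 101 -> 111 as the escape of the non-attractor state
net_six_cycle_maa <- function() {
  vars <- c("A", "B", "C")
  boolean_network(vars, list(
    A = list(inputs = vars, tt = c(1L, 1L, 0L, 0L, 0L, 1L, 0L, 1L)),
    B = list(inputs = vars, tt = c(0L, 1L, 1L, 1L, 0L, 1L, 0L, 1L)),
    C = list(inputs = vars, tt = c(0L, 0L, 1L, 0L, 0L, 1L, 1L, 1L))))
}

# random critical RBN corpus shared by property tests; mixes sparse and
# dense small networks
random_corpus <- function(n_networks, seed = 424242L) {
  set.seed(seed)
  lapply(seq_len(n_networks), function(i) {
    N <- sample(3:8, 1)
    K <- sample(seq_len(min(N, 3)), 1)
    if (i %% 10 == 0) {  # every tenth network is dense
      N <- sample(3:5, 1)
      K <- N
    }
    generate_critical_rbn(N, K)
  })
}

expect_same_network <- function(a, b) {
  expect_true(isTRUE(all.equal(a, b)))
}
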