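#!/usr/bin/env Rscript
# Robustness of motif avoidance to delays (linear extensions): star-family
# minimal delay counts against the closed-form bound, the projected STG of
# the two-variable MAA, and single-delay fragility in critical RBNs.
# Writes results/star_delays.tsv and results/fragility.tsv.

suppressPackageStartupMessages(library(motifavoid))
dir.create("results", showWarnings = FALSE)

cat("## Star family: exhaustive minimal delay sets vs the upper bound\n\n")
rows <- lapply(2:4, function(N) {
  res <- minimal_delay_set_size(star_network(N), limit = 6L)
  bound <- delay_upper_bound(c(M = N, d = N, m = N - 1))
  cat(sprintf("N=%d: minimal delays %d (floor(N^2/4) = %d), upper bound %g, subsets tested %d\n",
              N, res$size, floor(N^2 / 4), bound, res$subsets_tested))
  data.frame(N = N, minimal_delays = res$size,
             closed_form = floor(N^2 / 4), upper_bound = bound,
             subsets_tested = res$subsets_tested)
})
write.table(do.call(rbind, rows), "results/star_delays.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("\n## Projected STG of the two-variable MAA with a delay on A -> A\n\n")
p <- projected_stg(star_network(2), data.frame(from = "A", to = "A"))
print(p$edges)
cat("\nGained edges open paths from the attractor towards the trap space 11,\n")
cat("which is why a single delay suffices here.\n")

cat("\n## Single-delay fragility of MAAs in critical RBNs (N = 10)\n\n")
frag_rows <- lapply(c(3L, 10L), function(K) {
  res <- fragility_experiment(ensemble_config(10, K, seed = 1L),
                              maa_target = 25L, max_samples = 3e4)
  cat(sprintf("K=%2d: %d MAAs from %d samples; resistant to every single delay: %.2f; embeds 2-var pattern: %.2f\n",
              K, nrow(res$records), res$samples, res$resistant_fraction,
              mean(res$records$embedded_2var)))
  data.frame(N = 10, K = K, maas = nrow(res$records),
             samples = res$samples,
             resistant_fraction = res$resistant_fraction,
             embedded_2var_fraction = mean(res$records$embedded_2var))
})
write.table(do.call(rbind, frag_rows), "results/fragility.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nMost MAAs die to a single well-placed delay; resistance grows with\n")
cat("density but stays a minority even at K = 10.\n")
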