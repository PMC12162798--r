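#!/usr/bin/env Rscript
# Canalization measures (sensitivity, effective connectivity) of the eight
# rules behind the prototypical MAA networks, compared with the critical
# three-input random ensemble. Writes results/canalization.tsv.

suppressPackageStartupMessages(library(motifavoid))
dir.create("results", showWarnings = FALSE)

rules <- c("A & B | !A & !B",
           "A | B & C",
           "!A & !B | A & B & C",
           "A & !B | !B & !C | A & C",
           "A & B | B & C | A & C",
           "A & !B | !A & !C | A & B & C",
           "!A & !C | !B & !C | A & B & C",
           "A & B & C | !A & !B & !C")

tab <- data.frame(
  rule = rules,
  sensitivity = vapply(rules, sensitivity, numeric(1)),
  effective_connectivity = vapply(rules, effective_connectivity, numeric(1)),
  row.names = NULL)

k3 <- tab[-1, ]  # three-input rules
ens <- ensemble_canalization(3, mode = "exact")
tab <- rbind(tab,
             data.frame(rule = "average of k=3 rules above",
                        sensitivity = mean(k3$sensitivity),
                        effective_connectivity =
                          mean(k3$effective_connectivity)),
             data.frame(rule = "k=3 critical ensemble (exact expectation)",
                        sensitivity = ens$mean_sensitivity,
                        effective_connectivity =
                          ens$mean_effective_connectivity))

write.table(format(tab, digits = 6), "results/canalization.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(tab, digits = 6)
cat("\nThe MAA-generating rules are markedly less canalizing than the\n",
    "critical ensemble: their average sensitivity (",
    round(mean(k3$sensitivity), 3), ") exceeds the critical value 1, and\n",
    "their effective connectivity (", round(mean(k3$effective_connectivity), 3),
    ") exceeds the ensemble expectation (",
    round(ens$mean_effective_connectivity, 3), ").\n", sep = "")
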