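#!/usr/bin/env Rscript
# Library complexity and composition arithmetic.
#
# How big is the sequence space a SELEX experiment samples from, and how
# little of it does a bench-scale pool cover? A 1 nmol pool holds ~6e14
# molecules against 4^30 ~ 1.15e18 natural N30 sequences; adding Ds as a
# fifth letter inflates the space to 5^30 ~ 9.3e20. The doped (DR) design
# concentrates only a fifth of its molecules on the two-Ds compositions that
# selections actually exploit.

suppressPackageStartupMessages(library(ubselex))
dir.create("results", showWarnings = FALSE)

spaces <- data.frame(
  description = c("natural N30", "five-letter N30",
                  "42-mer DP sublibrary (2 Ds fixed)", "five-letter 42-mer"),
  alphabet = c(4, 5, 4, 5),
  randomized_nt = c(30, 30, 40, 42))
spaces$sequence_space <- mapply(function(a, l) {
  as.numeric(sequence_space(a, l))
}, spaces$alphabet, spaces$randomized_nt)
spaces$pool_coverage_1nmol <- nmol_to_molecules(1) / spaces$sequence_space

write.table(format(spaces, digits = 4), "results/sequence_spaces.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("1 nmol =", format(nmol_to_molecules(1), digits = 3), "molecules\n")
cat(sprintf("a 1 nmol natural N30 pool covers %.2g of its sequence space\n\n",
            spaces$pool_coverage_1nmol[1]))

# Ds-count composition of the doped N30 design (10% Ds per position)
comp <- data.frame(n_ds = 0:8)
comp$probability <- ub_count_pmf(30, 0.10, comp$n_ds)
comp$percent <- round(100 * comp$probability, 1)
write.table(comp, "results/dr_ds_composition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Doped N30 Ds-count composition (first rows):\n")
print(head(comp, 5), row.names = FALSE)
cat(sprintf("\n=> only %.1f%% of DR molecules carry exactly two Ds bases;\n",
            comp$percent[comp$n_ds == 2]))
cat(sprintf("   %.1f%% carry four or more (poorly amplified in PCR).\n",
            100 * (1 - sum(ub_count_pmf(30, 0.10, 0:3)))))
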