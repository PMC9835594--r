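#!/usr/bin/env Rscript
# Required numbers and expected occurrences for the reported aptamer panel.
#
# For each selection campaign whose motif parameters are published as text,
# compute the required number R (sequence-space size per expected candidate)
# and, where the library inputs are complete, the expected occurrence O of
# candidates in the initial pool. O >> 1 marks selections that were likely
# to succeed; O << 1 marks the "beginners' luck" campaigns.

suppressPackageStartupMessages(library(ubselex))
dir.create("results", showWarnings = FALSE)

tab <- panel_occurrence_table()
write.table(format(tab, digits = 3), "results/occurrence_table.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(format(tab[, c("aptamer", "library", "n_essential_natural",
                     "n_essential_ub", "n_stem_bp", "required_number",
                     "occurrence_printed", "p_at_least_one")], digits = 3),
      row.names = FALSE)

cat("\nKey readings:\n")
cat(sprintf(" - pegaptanib precursor: ~%d candidates in 1 nmol of N30\n",
            round(tab$occurrence_printed[tab$aptamer == "pegaptanib_precursor"])))
cat(sprintf(" - anti-DEN4-NS1: ~%.1f candidates in the pooled DP library\n",
            tab$occurrence_printed[tab$aptamer == "anti_DEN4_NS1"]))
cat(sprintf(" - anti-vWF (DR): ~%.0f candidates under the power-of-five reading\n",
            tab$occurrence_printed[tab$aptamer == "anti_vWF"]))

# inverse question: what pool complexity would put one expected anti-DEN4
# candidate in the library even if only one sublibrary hit?
den4 <- ds_aptamer_panel()$anti_DEN4_NS1
need <- required_complexity(den4$motif, synthetic_dp_set(), 1, hits = 1)
cat(sprintf("\nComplexity for O = 1 with a single hit sublibrary: %.2g molecules\n",
            need))
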