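#!/usr/bin/env Rscript
# Head-to-head discrimination of the cycling models on the two statistics
# where they disagree: terminator-resistant synthesis linearity, and the
# trend of successive fragment lengths when the lagging polymerase is slowed
# below the fork rate (collision fragments must each close the full distance
# to the previous fragment while the fork runs ahead, so lengths grow
# geometrically -- the opposite of constant observed lengths).

suppressPackageStartupMessages(library(okacycle))
dir.create("results", showWarnings = FALSE)

tpl <- make_minicircle(seed = 1)
cmp <- compare_models(tpl, replicates = 10, base_seed = 1)
write.table(format(cmp$terminator, digits = 4),
            "results/model_comparison_terminator.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(format(cmp$slow_lagging, digits = 4),
            "results/model_comparison_slow_lagging.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(cmp$terminator, digits = 3)
print(cmp$slow_lagging, digits = 3)
cat("\nVerdict:", cmp$verdict, "\n")
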