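#!/usr/bin/env Rscript
# Chain-terminator titration: sweep ddGTP at 0/1/2/4 uM under the signaling
# and collision cycling models. Signaling predicts progressively shorter
# Okazaki fragments with sustained (ensemble-linear) lagging synthesis;
# collision predicts arrest after the first terminator stall because release
# from a ddNMP-terminated chain takes minutes.

suppressPackageStartupMessages(library(okacycle))
dir.create("results", showWarnings = FALSE)

tpl <- make_minicircle(seed = 1)
d <- run_ddgtp_titration(tpl, ddgtp_values = c(0, 1, 2, 4),
                         models = c("signaling", "collision"),
                         replicates = 50, duration = 60, base_seed = 1)
write.table(format(d, digits = 4), "results/ddgtp_titration.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(d, digits = 3)

sig <- d[d$model == "signaling", ]
cat(sprintf(
  "\nSignaling: mean length falls %.0f -> %.0f nt (0 -> 4 uM ddGTP) while the ensemble\nsynthesis curve stays linear (R^2 = %.3f at 4 uM). Leading synthesis is untouched.\n",
  sig$mean_frag_len[1], sig$mean_frag_len[4], sig$r2_ensemble[4]))
col <- d[d$model == "collision" & d$ddGTP == 4, ]
cat(sprintf(
  "Collision at 4 uM: %.2f fragments per run; only %.0f%% more synthesis after the first stall.\n",
  col$n_fragments, 100 * col$post_stall_added_frac))
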