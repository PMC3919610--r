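#!/usr/bin/env Rscript
# The utilization / priming-frequency table, two ways:
# (1) the bench arithmetic applied to the measured count pairs (G+U in
#     elongated and unelongated primers, leading-strand dC), reproducing the
#     printed percentages, ratios and G+U per fragment;
# (2) the same statistics emerging from simulated forks, where primer G+U
#     comes from template composition under each 12-mer and leading dC from
#     the traversed template.

suppressPackageStartupMessages(library(okacycle))
dir.create("results", showWarnings = FALSE)

rows <- list(
  dGTP_100 = data.frame(eGU = c(650, 630, 810), uGU = c(380, 290, 380),
                        dC_lead = c(54000, 53000, 82000), filled = 1500),
  dGDPNP_240 = data.frame(eGU = c(460, 820, 600), uGU = c(470, 330, 420),
                          dC_lead = c(44000, 45000, 57000), filled = 1400),
  dGDPNP_30 = data.frame(eGU = c(360, 380, 540), uGU = c(410, 400, 420),
                         dC_lead = c(23000, 23000, 25000), filled = 1200))

bench <- do.call(rbind, lapply(names(rows), function(nm) {
  r <- rows[[nm]]
  rep <- table1_report(r, frac_dC = 0.45, filled_length = r$filled[1])
  data.frame(condition = nm,
             efficiencies = paste(rep$efficiency, collapse = "/"),
             avg_efficiency_pct = rep$avg_efficiency,
             avg_ratio = sprintf("%.4f", rep$avg_ratio),
             filled_length = r$filled[1],
             gu_per_fragment = rep$gu_per_fragment)
}))
write.table(bench, "results/table1_bench.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(bench, row.names = FALSE)
cat("(The 30 uM average prints 51 here: mean(47,49,56) rounds to 51 under\n",
    "either averaging convention.)\n", sep = "")

# emergent version from simulated forks (dGTP condition, 120 s, 20 seeds)
tpl <- make_minicircle(seed = 1)
em <- do.call(rbind, lapply(1:20, function(s) {
  q <- quantify_simulation(simulate_fork(sim_config(tpl, duration = 120,
                                                    seed = 100 + s)))
  as.data.frame(q)
}))
summary_row <- data.frame(
  mean_utilization_pct = mean(em$utilization_pct),
  mean_ratio = mean(em$ratio_raw),
  mean_filled_length = mean(em$filled_length),
  gu_per_fragment_median = median(em$gu_per_fragment))
write.table(format(cbind(seed = 101:120, em), digits = 4),
            "results/table1_emergent_runs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(format(summary_row, digits = 4),
            "results/table1_emergent_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(summary_row, digits = 3)
cat(sprintf(
  "\nEmergent G+U per fragment is %d (12-mer primers on the default template:\n12 x (C+A fraction) x 0.45/0.489 = %.1f per elongated primer).\n",
  median(em$gu_per_fragment), 12 * (303 / 409) * 0.45 / (200 / 409)))
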