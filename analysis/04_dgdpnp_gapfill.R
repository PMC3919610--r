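#!/usr/bin/env Rscript
# dGDPNP substitution and the gap-fill assay: throttling the insertion rate
# opposite C shortens Okazaki fragments, and extending their 3' ends with a
# non-displacing polymerase restores them all to the inter-primer spacing --
# the shortened fragments are followed by gaps, as the signaling model
# requires. Also renders synthetic densitometry lanes and checks the molar
# mean statistic against the direct fragment populations.

suppressPackageStartupMessages(library(okacycle))
dir.create("results", showWarnings = FALSE)

tpl <- make_minicircle(seed = 1)
d <- run_dgdpnp_series(tpl, replicates = 20, duration = 60, base_seed = 1)
write.table(format(d, digits = 4), "results/dgdpnp_series.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(d, digits = 3)

# One representative lane per condition, with the leading-strand smear.
# Quantification uses a noiseless render: no background subtraction is
# modeled, and a flat noise floor feeds the 1/length denominator of the
# molar mean at the short end of the grid. The written (display) lanes keep
# the default noise. The grid extends to 10 nt because 30 uM dGDPNP
# fragments run far below a normal Okazaki window.
conds <- list(dGTP_100 = list(dGTP = 100), dGDPNP_240 = list(dGDPNP = 240),
              dGDPNP_30 = list(dGDPNP = 30))
lane_summary <- do.call(rbind, lapply(names(conds), function(nm) {
  r <- simulate_fork(sim_config(tpl, pools = conds[[nm]], duration = 60,
                                seed = 42))
  display <- add_leading_smear(
    render_lane(r$fragments, seed = 42, meta = nm, range = c(10, 50000)),
    r$leading_extent, r$leading_dCMP_count)
  write_lane(display, file.path("results", paste0("lane_", nm, ".tsv")))
  quant <- render_lane(r$fragments, noise_frac = 0, range = c(10, 50000))
  data.frame(condition = nm,
             molar_mean_lane = molar_mean_length(quant, cutoff = 8000),
             molar_mean_direct = molar_mean_direct(r$fragments$length))
}))
write.table(format(lane_summary, digits = 4), "results/lane_molar_means.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(lane_summary, digits = 3)

cat(sprintf(
  "\nFilled lengths stay within %.1f%% of the control across conditions (the\ninter-primer spacing), while raw lengths drop %.0f-fold at 30 uM dGDPNP.\n",
  100 * max(abs(d$filled_mean_len / d$filled_mean_len[1] - 1)),
  d$raw_mean_len[1] / d$raw_mean_len[3]))
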