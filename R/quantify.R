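# Quantification statistics for Okazaki fragment gels.
#
# Internal radiolabeling makes a fragment's signal proportional to
# (molar amount) x (label per fragment), biasing density-weighted length
# averages toward long products. The molar mean removes that bias:
# with n_i = density_i / L_i,
#     L = sum(L_i * n_i) / sum(n_i) = sum(density_i) / sum(density_i / L_i).
# Primer utilization and priming-frequency ratios follow the bench assay's
# table arithmetic exactly, including its rounding conventions.

# round half away from zero, the convention of the printed tables
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Molar (number-weighted) mean fragment length from a lane profile
#'
#' `L = sum(density_i) / sum(density_i / L_i)` over bins strictly below
#' `cutoff`; the cutoff excludes leading-strand products. Scale-invariant in
#' the densities.
#'
#' @param profile A `lane_profile`.
#' @param cutoff Upper length bound in nt (default 8 kb; 20 kb is used when
#'   quantifying lanes whose Okazaki fragments run long).
#' @return Molar mean length in nt.
#' @export
molar_mean_length <- function(profile, cutoff = 8000) {
  sel <- profile$bin_lengths < cutoff
  d <- profile$density[sel]
  if (!any(d > 0)) stop("empty-signal error: no density below cutoff")
  sum(d) / sum(d / profile$bin_lengths[sel])
}

#' Molar mean length directly from a fragment population
#'
#' The number-weighted mean, `sum(L_i * n_i) / sum(n_i)`: the oracle that
#' [molar_mean_length()] must reproduce from a rendered lane.
#'
#' @param lengths Fragment lengths in nt (one entry per molecule).
#' @return Mean length in nt.
#' @export
molar_mean_direct <- function(lengths) {
  if (!length(lengths)) stop("empty fragment set")
  mean(lengths)
}

#' Primer utilization efficiency
#'
#' `100 * eGU / (eGU + uGU)`, rounded to the nearest integer percent, where
#' `eGU`/`uGU` are the G+U counts in elongated and unelongated primers.
#'
#' @param eGU,uGU Label counts in elongated / unelongated primers.
#' @return Integer percent.
#' @export
utilization_efficiency <- function(eGU, uGU) {
  if (eGU + uGU <= 0) stop("undefined-input error: no primer signal")
  round_half_up(100 * eGU / (eGU + uGU))
}

#' Priming-frequency ratio (G+U in elongated primers per leading-strand dNMP)
#'
#' `eGU / (dC_lead / frac_dC)`: the leading-strand dCMP count is converted to
#' total leading dNMP through the template's C fraction, then the elongated
#' primers' G+U label is expressed per leading nucleotide.
#'
#' @param eGU G+U count in elongated primers.
#' @param dC_lead dCMP count in the leading strand.
#' @param frac_dC Fraction of leading-strand nucleotides that are dC
#'   (default 0.45, the analysis constant used with this template).
#' @param round Round to 4 decimals (the table convention)?
#' @return Dimensionless ratio.
#' @export
priming_ratio <- function(eGU, dC_lead, frac_dC = 0.45, round = TRUE) {
  if (dC_lead <= 0 || frac_dC <= 0 || frac_dC > 1)
    stop("invalid denominator for priming ratio")
  r <- eGU / (dC_lead / frac_dC)
  if (round) round_half_up(r, 4) else r
}

#' G+U residues per Okazaki fragment
#'
#' `round(ratio * filled_length)`: the priming ratio times the gap-filled
#' fragment length gives the primer label content per fragment.
#'
#' @param ratio Priming-frequency ratio.
#' @param filled_length Gap-filled Okazaki fragment length, nt.
#' @return Integer count.
#' @export
gu_per_fragment <- function(ratio, filled_length) {
  stopifnot(ratio >= 0, filled_length > 0)
  round_half_up(ratio * filled_length)
}

#' Primer utilization / priming-frequency table from replicate counts
#'
#' Reproduces the bench table's arithmetic: per-row utilization efficiencies
#' are integer-rounded and then averaged (and re-rounded); per-row priming
#' ratios are shown rounded to 4 decimals but averaged unrounded (then
#' rounded); the G+U per fragment comes from the rounded average ratio times
#' the gap-filled length. Spread is reported as the sample SD of the per-row
#' values (the printed "+/-" convention is ambiguous and not reproduced
#' exactly).
#'
#' @param rows Data frame with columns `eGU`, `uGU`, `dC_lead` (one row per
#'   replicate).
#' @param frac_dC Leading-strand dC fraction.
#' @param filled_length Gap-filled fragment length, nt (omit for `NA`
#'   G+U per fragment).
#' @return List of class `quant_report` with per-row vectors and averaged
#'   columns.
#' @export
table1_report <- function(rows, frac_dC = 0.45, filled_length = NULL) {
  stopifnot(nrow(rows) >= 1, all(c("eGU", "uGU", "dC_lead") %in% names(rows)))
  eff <- mapply(utilization_efficiency, rows$eGU, rows$uGU)
  ratio_raw <- mapply(priming_ratio, rows$eGU, rows$dC_lead,
                      MoreArgs = list(frac_dC = frac_dC, round = FALSE))
  avg_ratio <- round_half_up(mean(ratio_raw), 4)
  structure(list(
    efficiency = eff,
    avg_efficiency = round_half_up(mean(eff)),
    sd_efficiency = if (length(eff) > 1) stats::sd(eff) else NA_real_,
    ratio = round_half_up(ratio_raw, 4),
    ratio_raw = ratio_raw,
    avg_ratio = avg_ratio,
    sd_ratio = if (length(ratio_raw) > 1) stats::sd(ratio_raw) else NA_real_,
    filled_length = filled_length,
    gu_per_fragment = if (!is.null(filled_length))
      gu_per_fragment(avg_ratio, filled_length) else NA_integer_,
    frac_dC = frac_dC
  ), class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat(sprintf("primer utilization: %s%% -> average %d%%\n",
              paste(x$efficiency, collapse = "/"), x$avg_efficiency))
  cat(sprintf("priming ratio: %s -> average %.4f\n",
              paste(sprintf("%.4f", x$ratio), collapse = "/"), x$avg_ratio))
  if (!is.na(x$gu_per_fragment))
    cat(sprintf("G+U per fragment (filled length %g nt): %d\n",
                x$filled_length, x$gu_per_fragment))
  invisible(x)
}

#' Emergent utilization / priming statistics from a simulation
#'
#' Maps a `sim_result` onto the counts the bench assay measures: G+U label in
#' elongated (used) and unelongated primers, leading-strand dCMP, and the
#' gap-filled mean fragment length, then applies [table1_report()]'s
#' arithmetic to a single emergent row.
#'
#' @param result A `sim_result` (dnag priming; RNA primers carry the G+U
#'   label).
#' @param frac_dC Leading-strand dC fraction used in the ratio.
#' @return List with `eGU`, `uGU`, `dC_lead`, `utilization_pct`,
#'   `ratio_raw`, `filled_length`, `gu_per_fragment`.
#' @export
quantify_simulation <- function(result, frac_dC = 0.45) {
  pr <- result$primers
  eGU <- sum(pr$gu_count[pr$used])
  uGU <- sum(pr$gu_count[!pr$used])
  dC <- result$leading_dCMP_count
  filled <- gap_fill(result)
  fl <- mean(filled$filled_length)
  ratio <- priming_ratio(eGU, dC, frac_dC, round = FALSE)
  list(eGU = eGU, uGU = uGU, dC_lead = dC,
       utilization_pct = utilization_efficiency(eGU, uGU),
       ratio_raw = ratio, filled_length = fl,
       gu_per_fragment = gu_per_fragment(ratio, fl))
}
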