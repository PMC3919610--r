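---
title: "Modeling lagging-strand polymerase cycling on a rolling-circle fork"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling lagging-strand polymerase cycling on a rolling-circle fork}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(okacycle)
```

## The question

During lagging-strand DNA replication, a highly processive replicase must
release its template and recycle to a new primer every few thousand
nucleotides. Two triggers have been proposed. In the **collision model**,
the polymerase releases when it runs into the 5' end of the previous Okazaki
fragment, converting the gap to a nick. In the **signaling model**, the
availability of a newly synthesized primer at the fork triggers release,
even mid-fragment. The measured release kinetics make collision implausible
(half-life on a nick about 2 min; release from a dideoxy-terminated chain in
a gap 6 to 11 min), but the two models also make sharply different
predictions that can be probed by selectively perturbing lagging-strand
synthesis. This package implements that experimental logic in silico: a
discrete-event single-fork simulator with both cycling rules, plus the
quantification statistics used on the corresponding gels.

## The template

Rolling-circle replication of a 409-nt minicircle yields a concatemeric
lagging-strand template: an endless repeat of one circular sequence. The
design places 200 C but only 4 G on the lagging-strand template (a 50:1 C:G
ratio, the remaining 205 positions split 103 A / 102 T), so that G-analog
perturbants — the chain terminator ddGTP and the slow substrate dGDPNP — act
almost exclusively on the lagging strand while the G-poor leading-strand
template is untouched. `make_minicircle()` builds such templates with exact
composition and seed-controlled base order; the true 409-mer sequence is not
public, so only its composition is reproduced. Note one deliberate
inconsistency kept from the original analysis: the generated template is
48.9% C, but the quantification constant "fraction dC in the leading strand"
is 0.45, the value used in the bench arithmetic; the two play different
roles and are not reconciled.

Coordinates are 0-based positions on the infinite concatemer, increasing
with fork movement; circular position is `pos %% 409`. Each Okazaki fragment
is reported as a half-open interval `[start, end)` whose `end` is the primer
(5') side; the 3' end extends toward *decreasing* coordinates, i.e. toward
the 5' terminus of the previously synthesized fragment, which is where a
nick can form. The first fragment of a run extends to the template origin
(position 0) — it is bounded by the start of the tail rather than by a
fragment, which is why ladder statistics exclude it.

## Kinetics

All rate laws live in `kinetic_params()`:

* **Elongation.** Insertion opposite template C is Michaelis–Menten in the
  G-nucleotide pool: `v_max · c/(Km + c)`, with `Km` 2 µM for dGTP
  (v_max = v_sat = 570 nt/s) and 40 µM for dGDPNP. All other positions run
  at `v_sat`. The mean velocity over a template with C fraction `f_C` is the
  harmonic mixture `1/(f_C/r_C + (1-f_C)/v_sat)` (`composite_velocity()`).
* **dGDPNP chemistry.** The analog also slows the chemical step. Rather than
  fitting two loose anchors, the chemistry-limited rate `v_chem_dGDPNP` is
  calibrated in closed form to a single anchor: the composite velocity on a
  25% C template at 30 µM dGDPNP equals 23 nt/s, a ~25-fold slowing from
  570 nt/s. The calibration then *predicts* a 10-to-13-fold slowing at
  240 µM, close to but not forced onto the reported ~10-fold; the same
  calibration predicts ~13 nt/s on the 45% C lagging template.
* **ddGTP termination.** At each template C the terminator competes with
  dGTP: `p = (f_sel·ddGTP/dGTP)/(1 + f_sel·ddGTP/dGTP)`. No direct
  discrimination ratio is available, so `f_sel` is calibrated so that 4 µM
  ddGTP against 100 µM dGTP halves the expected length of a 1500-nt
  fragment, `E[min(run, 1500)] = 750`, where the run length is geometric in
  the number of C positions survived. The calibrated default is
  `f_sel ≈ 0.054` (ddGTP inserted ~18-fold less efficiently than dGTP).
* **Release.** Exponential with half-life 120 s after nick formation and
  480 s (the midpoint of the 6–11 min range) in a terminator stall;
  signal-induced release is a constant latency, default 0 s, because the
  signal acts fast relative to fragment synthesis. Both latencies
  (`signaling_latency`, `reinit_latency`) are exposed for sensitivity runs.
* **Fork coupling.** The lagging polymerase's rates are multiplied by
  `alpha_lag`, default 1. See *Limitations*: several observations imply the
  fork-coupled lagging polymerase is much faster than the isolated-enzyme
  expectation, but no measured value exists, so the package treats
  `alpha_lag` as a free parameter rather than claiming one.

## The fork simulator

`simulate_fork()` runs one fork: the leading polymerase advances
continuously at `v_lead` = 420 nt/s; primers are deposited either by primase
at the fork (Poisson in time, rate `v_lead/target_spacing`, default spacing
1500 nt — the physiological 1–2 kb range) or by a synthetic 15-mer that
anneals at one circular position on each fork passage with probability
`p_anneal` (default 0.23, making the mean spacing 409/0.23 ≈ 1780 nt, the
level that matches primase-primed fragment lengths). A single lagging
polymerase (the dimeric-replisome assumption) elongates base by base with
deterministic dwell `1/rate`; the stochastic elements are primer deposition,
per-C terminator incorporation, and release clocks, all drawn from one
seeded stream, so runs are exactly reproducible. Fragment termination is
resolved at base boundaries.

Cycling rules:

* **signaling** — each new primer deposition releases the polymerase
  (wherever it is) and it reinitiates at the most recently deposited unused
  primer; older unused primers are abandoned and scored unutilized. A
  polymerase that completes its fragment (nick) first waits idle for the
  next primer.
* **collision** — release only through the slow exponential clocks (nick or
  stall); unused primers do not block extension, only the previous
  fragment's 5' end does.
* **hybrid** — whichever trigger fires first.

Primer G+U content (primase inserts G opposite C, U opposite A) is read off
the template under each 12-mer footprint, which ties the utilization
statistics to template composition: the expected G+U per elongated primer is
12 × (303/409) ≈ 8.9, and after the 0.45/0.489 dC-fraction conversion the
emergent "G+U per Okazaki fragment" is ~8.2, matching the bench value 8 ± 1
without any fitted parameter.

The simulator maintains an exact bookkeeping identity: fragment lengths plus
gap lengths plus the unprimed slack behind the fork equal the leading
extent, asserted across randomized configurations in the test suite.

## Gap fill, gels, and statistics

`gap_fill()` reproduces the non-displacing-polymerase assay with pure
interval arithmetic: each fragment's 3' end is extended to the 5' end of the
fragment before it (never past it), so filled lengths equal inter-primer
spacings regardless of how slowly the fragments were synthesized — the
signature by which shortened-but-regularly-primed populations reveal their
gaps. Fill targets the downstream primer's 5' end; its 3' end would differ
by one primer length and is not resolvable from the assay. Populations
containing ddGMP are refused, mirroring the bench constraint that no
suitable exonuclease-competent, non-displacing polymerase was found.

`render_lane()` emulates alkaline-gel densitometry only as far as the
statistics require: each fragment contributes signal equal to its labeled
nucleotide count (dGMP for the standard lagging-strand label — internal
labeling makes longer fragments proportionally hotter), spread as a Gaussian
in log10(length) (σ = 0.02 by default) on a log-spaced grid, plus seeded
truncated-Gaussian noise. Mobility nonlinearity, background, and image
processing are out of scope.

`molar_mean_length()` computes `L = Σ density / Σ (density/length)` below a
cutoff (8 kb by default, excluding leading-strand products; 20 kb available
for long-running lanes). When density ∝ molar amount × length this is the
number-weighted (molar) mean, the estimator that removes the
label-per-length bias; `molar_mean_direct()` is its oracle on the underlying
population, and the two agree within 2% on noiseless lanes.
`utilization_efficiency()`, `priming_ratio()`, `gu_per_fragment()` and
`table1_report()` implement the bench table's arithmetic, including its
rounding conventions, which were reverse-engineered from the printed values:
utilization percentages are rounded per row and then averaged; priming
ratios are averaged unrounded and then rounded to 4 decimals. One printed
average (the 30 µM dGDPNP utilization) is 50 where the rows give 51 under
either convention; the package reports 51. The printed "±" spreads are
ambiguous (sample vs population SD); the package reports sample SD and does
not gate on it.

## Numerical and design choices

* Per-base dwell is deterministic (`1/rate`); stochastic per-base dwell
  would not change the observables tracked here and would slow the
  simulator ~100-fold.
* Cumulative synthesis curves are reconstructed from per-fragment elongation
  episodes with linear interpolation inside an episode; the sub-second
  C/non-C dwell alternation is averaged out.
* Ties between a completion and a simultaneous signal resolve as completion
  (nick); a termination tied with completion resolves as termination.
* Linearity of terminator-resistant synthesis is assessed on the
  ensemble-mean curve of replicate forks (`ensemble_linearity()`), because
  the bulk incorporation assay sums many forks; a single fork is a bursty
  staircase (per-run R² ≈ 0.94 under default priming) while the ensemble is
  linear (R² > 0.99). Both statistics are reported.
* The collision arrest statistic is referenced to each run's first
  terminator stall and pooled across runs; 50 replicates of 120 s give the
  pooled denominator enough mass, since only the ~16% minority of stalled
  polymerases releases within two minutes.
* Replicate seeds are `base_seed + index`, so every sweep is auditable and
  reruns are byte-identical.
* Problem sizes throughout (60–120 s runs, 900 s for the slow-lagging
  geometry, 20–50 replicates) were chosen so each statistic's Monte-Carlo
  error is well inside the margins being tested.

## Limitations

* **The fork-coupled lagging rate.** With `alpha_lag = 1` the lagging
  polymerase outpaces the fork only 1.34-fold, so under Poisson priming
  ~40% of fragments are signal-truncated before completing, leaving a gap
  fraction of roughly `v_lead/(v_lead + v_lag)` ≈ 0.43 even without
  perturbants and pulling raw exogenous-primer fragment lengths below the
  inter-primer spacing. The observed gapless balanced synthesis and sharp
  409-nt ladder instead imply a lagging polymerase fast enough to finish
  before the next primer appears — the same inference the release-kinetics
  argument reaches. The package therefore (i) demonstrates the exactly
  gapless regime under regular priming (a primer every circle passage with
  `v_lag ≥ v_lead`), and (ii) keeps `alpha_lag` free for sensitivity
  analysis rather than fitting it to gels that are not available as raw
  data.
* **What the synthetic gels do not contain.** No background, lane warping,
  mobility nonlinearity or image noise; the flat noise floor of
  `render_lane()` feeds the `1/length` denominator of the molar mean at the
  short end of the grid, so quantification in the analysis scripts uses
  noiseless renders. Sub-50-nt species (produced under 30 µM dGDPNP) fall
  below a normal Okazaki gel window; the lane grid must be extended to
  cover them.
* **Scope.** Helicase loading, SSB dynamics, multi-fork ensembles sharing
  protein pools, exonucleolytic proofreading and the molecular identity of
  the signal sensor are not modeled; the pre-elongation labeling window is
  ignored (all synthesis is counted). Passing the property suite shows the
  model reproduces the qualitative experimental signatures under the stated
  conditions, not that it quantitatively describes real gels.
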