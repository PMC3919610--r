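# Rate laws for the replication-fork model.
#
# Elongation opposite template C follows Michaelis-Menten kinetics in the
# G-nucleotide pool (dGTP or its beta,gamma-non-hydrolyzable analog dGDPNP);
# all other template positions are taken at the saturated rate. Chain
# termination by ddGMP is a per-C Bernoulli competition between ddGTP and
# dGTP, and polymerase release after completion (nick) or terminator stall
# is exponential with the measured half-lives.

#' Kinetic parameter set for the fork simulator
#'
#' All rates are nt/s, concentrations uM, times s.
#'
#' @param v_sat Elongation rate at saturating dNTPs (570 nt/s).
#' @param v_lead Leading-strand rate on the minicircle (420 nt/s).
#' @param Km_dGTP,Km_dGDPNP Michaelis constants for insertion opposite C
#'   (2 uM and 40 uM).
#' @param v_chem_dGDPNP Chemistry-limited maximal insertion rate opposite C
#'   with dGDPNP. `NULL` (default) calibrates it so that the composite
#'   velocity on a 25% C template at 30 uM dGDPNP equals 23 nt/s
#'   (see [calibrate_dgdpnp()]).
#' @param f_sel ddGTP-vs-dGTP selection factor. `NULL` (default) calibrates it
#'   so that 4 uM ddGTP against 100 uM dGTP halves the expected length of a
#'   1500-nt Okazaki fragment (see [calibrate_ddgtp_selectivity()]).
#' @param t_half_nick Release half-life of the holoenzyme from a completed
#'   fragment (nick), 120 s.
#' @param t_half_stall Release half-life from a ddNMP-terminated chain within
#'   a gap; default 480 s, the midpoint of the measured 6-11 min range.
#' @param alpha_lag Fork-coupled lagging-strand acceleration multiplier
#'   applied to lagging-polymerase insertion rates. The coupled-fork rate is
#'   not directly measurable, so this ships as a free parameter with
#'   default 1; values below 1 are allowed for model-discrimination runs but
#'   draw a warning.
#' @param signaling_latency Delay between new-primer deposition and
#'   signal-induced release (s, default 0).
#' @param reinit_latency Delay between release and initiation at the next
#'   primer (s, default 0).
#' @return A list of class `kinetic_params`.
#' @export
kinetic_params <- function(v_sat = 570, v_lead = 420,
                           Km_dGTP = 2, Km_dGDPNP = 40,
                           v_chem_dGDPNP = NULL, f_sel = NULL,
                           t_half_nick = 120, t_half_stall = 480,
                           alpha_lag = 1, signaling_latency = 0,
                           reinit_latency = 0) {
  stopifnot(v_sat > 0, v_lead > 0, Km_dGTP > 0, Km_dGDPNP > 0,
            t_half_nick > 0, t_half_stall > 0,
            signaling_latency >= 0, reinit_latency >= 0)
  if (alpha_lag < 1)
    warning("alpha_lag < 1: lagging polymerase slower than the uncoupled rate")
  p <- structure(
    list(v_sat = v_sat, v_lead = v_lead, Km_dGTP = Km_dGTP,
         Km_dGDPNP = Km_dGDPNP, v_chem_dGDPNP = v_chem_dGDPNP,
         f_sel = f_sel, t_half_nick = t_half_nick,
         t_half_stall = t_half_stall, alpha_lag = alpha_lag,
         signaling_latency = signaling_latency,
         reinit_latency = reinit_latency),
    class = "kinetic_params")
  if (is.null(p$v_chem_dGDPNP)) p <- calibrate_dgdpnp(p)
  if (is.null(p$f_sel)) p$f_sel <- calibrate_ddgtp_selectivity(p)
  stopifnot(p$v_chem_dGDPNP > 0, p$f_sel >= 0)
  p
}

#' Insertion rate opposite a template C
#'
#' Michaelis-Menten rate `v_max * conc / (Km + conc)` with
#' `v_max = v_sat` for dGTP and `v_max = v_chem_dGDPNP` for dGDPNP.
#' For the fork-coupled lagging polymerase the rate is additionally
#' multiplied by `alpha_lag`.
#'
#' @param conc Nucleotide concentration, uM (>= 0).
#' @param species `"dGTP"` or `"dGDPNP"`.
#' @param params A [kinetic_params()] set.
#' @param fork_coupled Apply the lagging acceleration multiplier?
#' @return Rate in nt/s.
#' @export
insertion_rate_opposite_c <- function(conc, species = c("dGTP", "dGDPNP"),
                                      params = kinetic_params(),
                                      fork_coupled = FALSE) {
  species <- match.arg(species)
  if (any(conc < 0)) stop("parameter error: negative concentration")
  vmax <- switch(species, dGTP = params$v_sat, dGDPNP = params$v_chem_dGDPNP)
  Km <- switch(species, dGTP = params$Km_dGTP, dGDPNP = params$Km_dGDPNP)
  r <- vmax * conc / (Km + conc)
  if (fork_coupled) r <- r * params$alpha_lag
  r
}

#' Composite elongation velocity over a mixed-composition template
#'
#' Harmonic mixture of per-base dwell times: C positions proceed at `r_C`,
#' all other positions at `v_sat`, giving
#' `1 / (f_C / r_C + (1 - f_C) / v_sat)`. With `r_C = 0` and `f_C > 0` the
#' polymerase is stalled (velocity 0, not an error).
#'
#' @param f_C Fraction of template positions that are C, in `[0, 1]`.
#' @param r_C Insertion rate opposite C, nt/s.
#' @param params A [kinetic_params()] set.
#' @return Mean velocity in nt/s.
#' @export
composite_velocity <- function(f_C, r_C, params = kinetic_params()) {
  stopifnot(f_C >= 0, f_C <= 1, r_C >= 0)
  if (f_C == 0) return(params$v_sat)
  if (r_C == 0) return(0)
  1 / (f_C / r_C + (1 - f_C) / params$v_sat)
}

#' Calibrate the dGDPNP chemistry-limited rate
#'
#' Sets `v_chem_dGDPNP` so that the composite velocity on a template with
#' C fraction `f_C` at dGDPNP concentration `conc` equals `target_rate`.
#' The anchor is the measured slowing of primer extension on an M13 template
#' (~25% C) from 570 nt/s with dGTP to 23 nt/s with 30 uM dGDPNP. The
#' inversion is closed form:
#' `r_C = f_C / (1/target - (1 - f_C)/v_sat)`, then
#' `v_chem = r_C * (Km + conc) / conc`.
#'
#' @param params A [kinetic_params()] set (its `v_chem_dGDPNP` is replaced).
#' @param target_rate Composite target velocity, nt/s.
#' @param f_C C fraction of the calibration template.
#' @param conc dGDPNP concentration, uM.
#' @return `params` with `v_chem_dGDPNP` set.
#' @export
calibrate_dgdpnp <- function(params, target_rate = 23, f_C = 0.25, conc = 30) {
  if (target_rate >= params$v_sat)
    stop("calibration error: target rate must be below v_sat")
  stopifnot(target_rate > 0, f_C > 0, f_C <= 1, conc > 0)
  r_C <- f_C / (1 / target_rate - (1 - f_C) / params$v_sat)
  params$v_chem_dGDPNP <- r_C * (params$Km_dGDPNP + conc) / conc
  params
}

#' Probability of ddGMP chain termination per template C
#'
#' Competition between ddGTP and dGTP for insertion opposite C:
#' `p = (f_sel * ddGTP/dGTP) / (1 + f_sel * ddGTP/dGTP)`. `p = 0` with no
#' ddGTP; `p = 1` if ddGTP is present without any dGTP.
#'
#' @param ddGTP_conc,dGTP_conc Concentrations, uM.
#' @param params A [kinetic_params()] set.
#' @return Termination probability per C encountered.
#' @export
ddgmp_termination_prob <- function(ddGTP_conc, dGTP_conc,
                                   params = kinetic_params()) {
  stopifnot(ddGTP_conc >= 0, dGTP_conc >= 0)
  if (ddGTP_conc == 0) return(0)
  if (dGTP_conc == 0) return(1)
  x <- params$f_sel * ddGTP_conc / dGTP_conc
  x / (1 + x)
}

# Expected synthesized length before either ddGMP termination or reaching a
# boundary `spacing` nt away, on a template with C fraction f_C and per-C
# termination probability p. The number of C positions survived is geometric;
# run length in nt is the C count divided by the C density, capped at spacing.
expected_terminated_length <- function(p, f_C, spacing) {
  if (p <= 0) return(spacing)
  m <- floor(spacing * f_C)
  (1 - (1 - p)^m) / (p * f_C)
}

#' Calibrate the ddGTP selection factor
#'
#' Sets `f_sel` so that with `ddGTP` against `dGTP` the expected Okazaki
#' fragment length `E[min(run, spacing)]` is half of `spacing`, reproducing
#' the observed ~2-fold shortening of ~1500-nt fragments at 4 uM ddGTP. The
#' per-C termination probability solving the anchor is found with a root
#' finder and converted back through the competition formula.
#'
#' @param params A [kinetic_params()] set.
#' @param ddGTP,dGTP Anchor concentrations, uM.
#' @param spacing Unperturbed fragment length, nt.
#' @param f_C Template C fraction (default: the 409-nt minicircle's 200/409).
#' @return The calibrated `f_sel` (dimensionless).
#' @export
calibrate_ddgtp_selectivity <- function(params, ddGTP = 4, dGTP = 100,
                                        spacing = 1500, f_C = 200 / 409) {
  g <- function(p) expected_terminated_length(p, f_C, spacing) - spacing / 2
  p <- stats::uniroot(g, c(1e-9, 0.999), tol = 1e-12)$root
  p / (1 - p) * dGTP / ddGTP
}

#' Sample polymerase release times
#'
#' Release after converting a gap to a nick, or from a ddNMP-terminated
#' stall, is exponential with the corresponding half-life; signal-induced
#' release is a constant latency.
#'
#' @param context `"nick"`, `"stall"` or `"signal"`.
#' @param params A [kinetic_params()] set.
#' @param n Number of samples.
#' @return Numeric vector of release times in seconds.
#' @export
sample_release_time <- function(context = c("nick", "stall", "signal"),
                                params = kinetic_params(), n = 1) {
  context <- match.arg(context)
  switch(context,
         nick = stats::rexp(n, rate = log(2) / params$t_half_nick),
         stall = stats::rexp(n, rate = log(2) / params$t_half_stall),
         signal = rep(params$signaling_latency, n))
}
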