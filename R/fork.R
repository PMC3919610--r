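# Discrete-event simulation of one coupled replication fork.
#
# Coordinates: 0-based positions on the infinite concatemer, increasing in
# the direction of fork movement; position p was exposed when the leading
# polymerase (at v_lead nt/s) reached it. A primer deposited when the fork is
# at p occupies [p - primer_len, p), its 5' end fork-proximal. The lagging
# polymerase extends the primer 3' end toward DECREASING coordinates, i.e.
# toward the 5' end of the previously synthesized Okazaki fragment, and a
# nick forms when it reaches that fragment's 5' terminus. Exported intervals
# are therefore half-open [start, end) with `end` the primer (5') side and
# `start` the 3'-extension side.
#
# Cycling rules:
#   signaling -- each new primer deposition releases the polymerase (after
#     `signaling_latency`), wherever it is; after `reinit_latency` it
#     initiates at the most recently deposited unused primer. A polymerase
#     that completes a fragment first waits idle for the next primer.
#   collision -- release only through the slow exponential clocks: after
#     nick formation (t_half_nick) or in a terminator stall (t_half_stall).
#   hybrid    -- whichever trigger fires first wins.

#' Configuration for a single-fork simulation
#'
#' @param template A [make_minicircle()] template.
#' @param model Cycling model: `"signaling"`, `"collision"` or `"hybrid"`.
#' @param priming_mode `"dnag"` (primase at the fork, Poisson in time) or
#'   `"exogenous"` (synthetic primer annealing at the template's unique site
#'   on each passage of the fork).
#' @param target_spacing Desired mean inter-primer distance in nt for dnag
#'   mode; sets `primase_rate = v_lead / target_spacing` unless
#'   `primase_rate` is given. Default 1500 nt, the physiological 1-2 kb range.
#' @param primase_rate Priming events per second at the fork (dnag mode).
#' @param p_anneal Probability that a usable exogenous primer is present on a
#'   given passage of the unique site (default 0.23, tuned so the mean
#'   fragment length ~ 409/0.23 ~ 1800 nt matches the primase-primed system).
#' @param primer_len_dnag,primer_len_exo Primer lengths, nt (12-mer RNA for
#'   primase, 15-mer DNA for the synthetic primer).
#' @param pools Named list of nucleotide concentrations in uM:
#'   `dGTP`, `ddGTP`, `dGDPNP`. At least one of dGTP/dGDPNP must be positive;
#'   when dGDPNP is used dGTP is 0 (full substitution, as in the assay).
#' @param duration Simulated time in seconds.
#' @param seed Integer seed; runs are fully reproducible.
#' @param params A [kinetic_params()] set.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(template,
                       model = c("signaling", "collision", "hybrid"),
                       priming_mode = c("dnag", "exogenous"),
                       target_spacing = 1500, primase_rate = NULL,
                       p_anneal = 0.23,
                       primer_len_dnag = 12L, primer_len_exo = 15L,
                       pools = list(dGTP = 100, ddGTP = 0, dGDPNP = 0),
                       duration = 60, seed = 1L,
                       params = kinetic_params()) {
  model <- match.arg(model)
  priming_mode <- match.arg(priming_mode)
  stopifnot(inherits(template, "minicircle"), duration > 0,
            p_anneal >= 0, p_anneal <= 1)
  pools <- utils::modifyList(list(dGTP = 0, ddGTP = 0, dGDPNP = 0), pools)
  if (pools$dGTP <= 0 && pools$dGDPNP <= 0)
    stop("pools must include dGTP > 0 or dGDPNP > 0")
  if (is.null(primase_rate)) primase_rate <- params$v_lead / target_spacing
  stopifnot(primase_rate > 0)
  structure(
    list(template = template, model = model, priming_mode = priming_mode,
         target_spacing = target_spacing, primase_rate = primase_rate,
         p_anneal = p_anneal, primer_len_dnag = as.integer(primer_len_dnag),
         primer_len_exo = as.integer(primer_len_exo), pools = pools,
         duration = duration, seed = as.integer(seed), params = params),
    class = "sim_config")
}

#' Primer deposition by DnaG primase at the fork
#'
#' Poisson process in time with rate `primase_rate`; each primer's 5' end
#' sits at the fork position at deposition. The primer G+U content is the
#' number of template positions under its footprint that are C or A (primase
#' inserts G opposite C and U opposite A).
#'
#' @param duration Simulated time, s.
#' @param v_lead Leading/fork rate, nt/s.
#' @param primase_rate Priming events per second.
#' @param template A `minicircle`.
#' @param primer_len Primer length, nt.
#' @return Data frame with columns `time`, `top` (5' end position), `len`,
#'   `gu_count`. Draws from the current RNG stream.
#' @export
deposit_primers_dnag <- function(duration, v_lead, primase_rate, template,
                                 primer_len = 12L) {
  stopifnot(primase_rate > 0)
  ts <- numeric(0); t <- 0
  repeat {
    k <- max(16L, ceiling((duration - t) * primase_rate * 1.5))
    tt <- t + cumsum(stats::rexp(k, primase_rate))
    ts <- c(ts, tt)
    t <- tt[k]
    if (t > duration) break
  }
  ts <- ts[ts <= duration]
  top <- floor(v_lead * ts)
  keep <- top >= primer_len          # enough exposed template to anneal on
  ts <- ts[keep]; top <- top[keep]
  gu <- if (length(top)) count_template_ca(template, top - primer_len, top) else integer(0)
  data.frame(time = ts, top = as.integer(top), len = as.integer(primer_len),
             gu_count = as.integer(gu))
}

#' Exogenous primer annealing at the unique site
#'
#' On each passage of the fork over the template's unique site, an
#' independent Bernoulli(`p_anneal`) decides whether a usable synthetic
#' primer is annealed there, so inter-primer spacings are exact multiples of
#' the circle length. DNA primers carry no G+U label.
#'
#' @inheritParams deposit_primers_dnag
#' @param p_anneal Per-passage annealing probability.
#' @return Data frame as in [deposit_primers_dnag()].
#' @export
deposit_primers_exogenous <- function(duration, v_lead, p_anneal, template,
                                      primer_len = 15L) {
  stopifnot(p_anneal >= 0, p_anneal <= 1)
  L <- template$length
  u0 <- template$unique_site
  if (u0 < primer_len) u0 <- u0 + L     # first full footprint on the concatemer
  extent <- floor(v_lead * duration)
  if (extent < u0 || p_anneal == 0)
    return(data.frame(time = numeric(0), top = integer(0), len = integer(0),
                      gu_count = integer(0)))
  tops <- seq.int(u0, extent, by = L)
  keep <- stats::runif(length(tops)) < p_anneal
  tops <- tops[keep]
  data.frame(time = tops / v_lead, top = as.integer(tops),
             len = as.integer(primer_len),
             gu_count = integer(length(tops)))
}

#' Simulate one coupled replication fork
#'
#' Event-driven simulation of leading-strand progression, primer deposition,
#' lagging-strand elongation with Michaelis-Menten dwell times and per-C
#' ddGMP termination, and polymerase cycling under the configured model.
#' Within a fragment, per-base dwell is deterministic (`1/rate`); the
#' stochastic elements are primer deposition, ddGMP termination and release
#' clocks, all drawn from the seeded stream, so identical configurations give
#' identical results.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_result`: list with `config`, `fragments`
#'   (data frame: `start`, `end`, `length`, `primer_top`, `primer_len`,
#'   `gu_count`, `ext_nt` (nucleotides polymerized beyond the primer),
#'   `dGMP_count`, `terminated_by`
#'   (`nick`/`ddGMP`/`signal`/`timeout`), `t_init`, `completed_at`),
#'   `primers` (deposition log with `used` flag), `gaps` (intervals left
#'   unreplicated behind the fork; `behind` is `FALSE` for the slack under a
#'   fragment still elongating when the run ended), `segments` (elongation episodes for
#'   time-course reconstruction), `leading_extent` (nt) and
#'   `leading_dCMP_count`.
#' @export
simulate_fork <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$params
  tpl <- config$template
  L <- tpl$length
  duration <- config$duration
  v_lead <- p$v_lead

  # lagging-strand per-base rates
  if (config$pools$dGDPNP > 0) {
    r_C <- insertion_rate_opposite_c(config$pools$dGDPNP, "dGDPNP", p,
                                     fork_coupled = TRUE)
  } else {
    r_C <- insertion_rate_opposite_c(config$pools$dGTP, "dGTP", p,
                                     fork_coupled = TRUE)
  }
  r_other <- p$v_sat * p$alpha_lag
  p_dd <- ddgmp_termination_prob(config$pools$ddGTP, config$pools$dGTP, p)

  prim <- switch(config$priming_mode,
    dnag = deposit_primers_dnag(duration, v_lead, config$primase_rate, tpl,
                                config$primer_len_dnag),
    exogenous = deposit_primers_exogenous(duration, v_lead, config$p_anneal,
                                          tpl, config$primer_len_exo))
  np <- nrow(prim)
  used <- logical(np)
  is_c_circ <- tpl$bases == "C"

  next_dep_after <- function(t) {
    i <- findInterval(t, prim$time) + 1L
    if (i <= np) prim$time[i] else Inf
  }
  signal_models <- c("signaling", "hybrid")

  frag <- vector("list", 256L); nf <- 0L
  seg <- vector("list", 256L); ns <- 0L
  prev_top <- 0L
  t_free <- p$reinit_latency
  guard <- 0L

  repeat {
    guard <- guard + 1L
    if (guard > 1e6L) stop("event guard tripped: too many episodes")
    # pick the most recently deposited unused primer able to seed a fragment
    cand <- which(!used & prim$time <= t_free & prim$top > prev_top)
    if (!length(cand)) {
      tn <- next_dep_after(t_free)
      if (!is.finite(tn) || tn >= duration) break
      t_free <- tn + p$reinit_latency
      next
    }
    i <- cand[length(cand)]
    t_init <- t_free
    if (t_init >= duration) break
    used[i] <- TRUE
    hi <- prim$top[i]
    plen <- prim$len[i]
    lo_start <- max(hi - plen, prev_top)   # primer 3' end (clamped at last fragment)
    target <- prev_top
    nb_max <- lo_start - target

    if (nb_max > 0L) {
      pos_path <- seq.int(lo_start - 1L, target, by = -1L)
      isC <- is_c_circ[(pos_path %% L) + 1L]
      tcum <- cumsum(ifelse(isC, 1 / r_C, 1 / r_other))
      t_comp <- t_init + tcum[nb_max]
    } else {
      pos_path <- integer(0); isC <- logical(0); tcum <- numeric(0)
      t_comp <- t_init
    }

    t_term <- Inf; term_i <- NA_integer_
    if (p_dd > 0 && any(isC)) {
      k <- stats::rgeom(1L, p_dd)
      ci <- which(isC)
      if (k + 1L <= length(ci)) {
        term_i <- ci[k + 1L]
        t_term <- t_init + tcum[term_i]
      }
    }
    t_sig <- if (config$model %in% signal_models)
      next_dep_after(t_init) + p$signaling_latency else Inf

    # first event wins; ties resolve termination > completion > signal > timeout
    evs <- c(term = t_term, comp = t_comp, sig = t_sig, timeout = duration)
    ev <- names(evs)[which.min(evs)]

    if (ev == "timeout") {
      nb_done <- sum(tcum <= duration - t_init)
      lo <- lo_start - nb_done
      nf <- nf + 1L
      frag[[nf]] <- list(start = lo, end = hi, primer_top = hi,
                         primer_len = plen, gu_count = prim$gu_count[i],
                         ext_nt = nb_done, terminated_by = "timeout",
                         t_init = t_init, completed_at = NA_real_)
      ns <- ns + 1L; seg[[ns]] <- c(t_init, duration, nb_done)
      prev_top <- hi
      break
    }

    if (ev == "term") {
      lo <- pos_path[term_i]
      t_ev <- t_term
      how <- "ddGMP"
      nb_done <- term_i
    } else if (ev == "comp") {
      lo <- target
      t_ev <- t_comp
      how <- "nick"
      nb_done <- nb_max
    } else { # signal-induced release mid-elongation
      nb_done <- sum(tcum <= t_sig - t_init)
      lo <- lo_start - nb_done
      t_ev <- t_sig
      how <- "signal"
    }
    nf <- nf + 1L
    frag[[nf]] <- list(start = lo, end = hi, primer_top = hi,
                       primer_len = plen, gu_count = prim$gu_count[i],
                       ext_nt = nb_done, terminated_by = how, t_init = t_init,
                       completed_at = t_ev)
    ns <- ns + 1L; seg[[ns]] <- c(t_init, t_ev, nb_done)
    prev_top <- hi

    # release and reinitiation
    if (how == "signal") {
      t_rel <- t_ev
    } else {
      ctx <- if (how == "nick") "nick" else "stall"
      t_exp <- if (config$model %in% c("collision", "hybrid"))
        t_ev + sample_release_time(ctx, p, 1L) else Inf
      # first deposition after initiation whose signal arrives at/after t_ev
      # (a signal still in transit when the fragment ends is not lost)
      t_sig2 <- if (config$model %in% signal_models)
        max(t_ev, next_dep_after(t_init) + p$signaling_latency) else Inf
      t_rel <- min(t_exp, t_sig2)
    }
    if (!is.finite(t_rel) || t_rel >= duration) break
    t_free <- t_rel + p$reinit_latency
  }

  fragments <- if (nf) {
    d <- do.call(rbind, lapply(frag[seq_len(nf)], as.data.frame))
    d$length <- d$end - d$start
    d$dGMP_count <- count_template_c(tpl, d$start, pmax(d$start, d$end - d$primer_len))
    d[, c("start", "end", "length", "primer_top", "primer_len", "gu_count",
          "ext_nt", "dGMP_count", "terminated_by", "t_init", "completed_at")]
  } else {
    data.frame(start = integer(0), end = integer(0), length = integer(0),
               primer_top = integer(0), primer_len = integer(0),
               gu_count = integer(0), ext_nt = integer(0),
               dGMP_count = integer(0), terminated_by = character(0),
               t_init = numeric(0), completed_at = numeric(0))
  }
  gaps <- if (nf) {
    gs <- c(0L, fragments$end[-nf])      # fill target of each fragment
    sel <- fragments$start > gs
    data.frame(start = gs[sel], end = fragments$start[sel],
               length = fragments$start[sel] - gs[sel],
               fragment = which(sel),
               behind = fragments$terminated_by[sel] != "timeout")
  } else {
    data.frame(start = integer(0), end = integer(0), length = integer(0),
               fragment = integer(0), behind = logical(0))
  }
  segments <- if (ns) {
    m <- do.call(rbind, seg[seq_len(ns)])
    data.frame(t0 = m[, 1], t1 = m[, 2], nt = m[, 3])
  } else data.frame(t0 = numeric(0), t1 = numeric(0), nt = numeric(0))

  leading_extent <- floor(v_lead * duration)
  prim$used <- used
  structure(
    list(config = config, fragments = fragments, primers = prim, gaps = gaps,
         segments = segments, leading_extent = leading_extent,
         leading_dCMP_count = count_template_c(tpl, 0L, leading_extent)),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "fork simulation (%s / %s): %.0f s, leading %d nt\n  %d fragments (mean %.0f nt), %d/%d primers used, %d gaps (%d nt total)\n",
    x$config$model, x$config$priming_mode, x$config$duration,
    x$leading_extent, nrow(x$fragments),
    if (nrow(x$fragments)) mean(x$fragments$length) else NA,
    sum(x$primers$used), nrow(x$primers), nrow(x$gaps), sum(x$gaps$length)))
  invisible(x)
}

#' Radiolabel incorporation totals
#'
#' Leading-strand synthesis is monitored through dCMP incorporation (opposite
#' the leading template's G, equivalently opposite C of the lagging-strand
#' template sequence); lagging-strand synthesis through dGMP in fragment
#' extensions (primer-covered positions excluded).
#'
#' @param result A `sim_result`.
#' @param strand `"leading"` or `"lagging"`.
#' @return Labeled-nucleotide count.
#' @export
incorporation_totals <- function(result, strand = c("leading", "lagging")) {
  strand <- match.arg(strand)
  switch(strand,
         leading = result$leading_dCMP_count,
         lagging = sum(result$fragments$dGMP_count))
}

#' Cumulative lagging-strand synthesis over time
#'
#' Reconstructs the cumulative number of lagging-strand nucleotides
#' synthesized by each time point from the per-fragment elongation episodes
#' (linear interpolation within an episode; the sub-second alternation
#' between C and non-C dwell times is averaged out).
#'
#' @param result A `sim_result`.
#' @param times Numeric vector of time points (s).
#' @return Numeric vector of cumulative nt synthesized.
#' @export
lagging_curve <- function(result, times) {
  s <- result$segments
  if (!nrow(s)) return(rep(0, length(times)))
  vapply(times, function(t) {
    f <- pmin(pmax((t - s$t0) / pmax(s$t1 - s$t0, 1e-12), 0), 1)
    sum(f * s$nt)
  }, numeric(1))
}

#' Export the simulation event log as TSV
#'
#' One row per primer deposition and per elongation episode, time-stamped.
#'
#' @param result A `sim_result`.
#' @param path Output path.
#' @return The event data frame, invisibly.
#' @export
export_events <- function(result, path) {
  ev <- rbind(
    data.frame(time = result$primers$time, event = "primer_deposited",
               value = result$primers$top),
    data.frame(time = result$segments$t0, event = "elongation_start",
               value = result$segments$nt),
    data.frame(time = result$segments$t1, event = "elongation_stop",
               value = result$segments$nt))
  ev <- ev[order(ev$time), ]
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ev)
}
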