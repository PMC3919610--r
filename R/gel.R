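# Synthetic alkaline-agarose densitometry.
#
# Denaturing-gel lanes are emulated just far enough to exercise the
# quantification statistics: each radiolabeled fragment contributes signal
# proportional to its labeled-nucleotide count, spread log-normally around
# its true length on a log-spaced length grid, plus seeded truncated-Gaussian
# noise. No mobility nonlinearity, background or image model is attempted.

#' Render a densitometry lane from a fragment population
#'
#' Signal per fragment equals its labeled-nucleotide count (for the standard
#' alpha-32P-dGTP label on the lagging strand, the fragment's dGMP count:
#' internal labeling makes longer fragments proportionally hotter, the bias
#' the molar-mean statistic later removes). The band is a Gaussian in
#' log10(length) with standard deviation `band_sigma_log10`; `0` collapses the
#' band into the nearest bin.
#'
#' @param lengths Fragment lengths in nt, or a fragment data frame with
#'   `length` and `dGMP_count` columns (e.g. `sim_result$fragments`), in which
#'   case weights default to the dGMP count.
#' @param weights Per-fragment signal weights; defaults to `lengths` (uniform
#'   labeling density) for bare length input.
#' @param label Label species annotation (`"dGTP"`, `"dCTP"`, `"dATP"`).
#' @param n_bins Number of length bins.
#' @param range Length range covered by the grid, nt.
#' @param band_sigma_log10 Band spread in log10(length).
#' @param noise_frac Additive Gaussian noise sigma as a fraction of the peak
#'   signal, truncated at zero.
#' @param seed Optional integer seed for the noise draw (caller RNG
#'   preserved).
#' @param meta Free-text condition annotation.
#' @return Object of class `lane_profile`: list with `bin_lengths`
#'   (strictly increasing), `density`, `label`, `meta`.
#' @export
render_lane <- function(lengths, weights = NULL, label = "dGTP",
                        n_bins = 200L, range = c(50, 50000),
                        band_sigma_log10 = 0.02, noise_frac = 0.01,
                        seed = NULL, meta = "") {
  if (is.data.frame(lengths)) {
    if (is.null(weights) && "dGMP_count" %in% names(lengths))
      weights <- lengths$dGMP_count
    lengths <- lengths$length
  }
  if (is.null(weights)) weights <- lengths
  stopifnot(length(weights) == length(lengths), all(weights >= 0))
  lg <- seq(log10(range[1]), log10(range[2]), length.out = n_bins)
  h <- lg[2] - lg[1]
  density <- numeric(n_bins)
  if (!length(lengths)) {
    warning("empty fragment list: rendering a noise-only lane")
  } else {
    if (any(lengths <= 0)) stop("fragment lengths must be positive")
    qs <- stats::quantile(lengths, c(0.005, 0.995))
    if (qs[1] < range[1] || qs[2] > range[2])
      warning("lane range does not cover the 0.5-99.5 percentile of input lengths")
    ll <- log10(lengths)
    if (band_sigma_log10 <= 0) {
      idx <- pmin(pmax(round((ll - lg[1]) / h) + 1, 1), n_bins)
      for (j in seq_along(idx)) density[idx[j]] <- density[idx[j]] + weights[j]
    } else {
      # n_bins x n_frag matrix of band contributions
      M <- stats::dnorm(outer(lg, ll, "-"), sd = band_sigma_log10) * h
      density <- as.vector(M %*% weights)
    }
  }
  if (noise_frac > 0 && max(density) > 0) {
    noise <- local_seed(if (is.null(seed)) 0L else seed,
                        stats::rnorm(n_bins, 0, noise_frac * max(density)))
    density <- pmax(density + noise, 0)
  }
  structure(list(bin_lengths = 10^lg, density = density,
                 label = label, meta = meta),
            class = "lane_profile")
}

#' Add a leading-strand high-molecular-weight smear to a lane
#'
#' Leading-strand rolling-circle products run far above the Okazaki fragment
#' range; this adds their signal uniformly (in log-length) across bins above
#' `cutoff` up to `leading_extent`, so the statistic's below-cutoff behaviour
#' can be exercised. Bins at or below the cutoff are untouched, hence the
#' below-cutoff molar mean is invariant under this operation.
#'
#' @param profile A `lane_profile`.
#' @param leading_extent Leading-strand product length, nt; values at or
#'   below `cutoff` leave the profile unchanged.
#' @param weight Total signal to add (e.g. the leading dCMP count).
#' @param cutoff Lower length bound for the smear, nt.
#' @return The modified `lane_profile`.
#' @export
add_leading_smear <- function(profile, leading_extent, weight, cutoff = 8000) {
  stopifnot(inherits(profile, "lane_profile"), weight >= 0)
  if (leading_extent <= cutoff || weight == 0) return(profile)
  sel <- profile$bin_lengths > cutoff & profile$bin_lengths <= leading_extent
  if (!any(sel)) sel <- which.max(profile$bin_lengths)
  profile$density[sel] <- profile$density[sel] + weight / sum(sel)
  profile
}

#' Write / read a lane profile as two-column TSV
#'
#' Columns `length_nt` and `density`; `label` and `meta` round-trip through
#' `#`-prefixed header lines. Reading rejects non-monotone length grids.
#'
#' @param profile A `lane_profile`.
#' @param path File path.
#' @return `read_lane` returns a `lane_profile`; `write_lane` returns `path`
#'   invisibly.
#' @export
write_lane <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# label=%s", profile$label),
               sprintf("# meta=%s", profile$meta)), con)
  utils::write.table(
    data.frame(length_nt = profile$bin_lengths, density = profile$density),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lane
#' @export
read_lane <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("format error: empty or missing lane file: ", path)
  hdr <- readLines(path, n = 10)
  lab <- sub("^# label=", "", grep("^# label=", hdr, value = TRUE)[1])
  meta <- sub("^# meta=", "", grep("^# meta=", hdr, value = TRUE)[1])
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!all(c("length_nt", "density") %in% names(d)))
    stop("format error: lane TSV must have length_nt and density columns")
  if (any(diff(d$length_nt) <= 0))
    stop("format error: lane lengths must be strictly increasing")
  structure(list(bin_lengths = d$length_nt, density = d$density,
                 label = if (is.na(lab)) "" else lab,
                 meta = if (is.na(meta)) "" else meta),
            class = "lane_profile")
}
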