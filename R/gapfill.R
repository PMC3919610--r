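# In-silico gap-fill assay.
#
# After deproteinization, a non-strand-displacing polymerase extends each
# Okazaki fragment's free 3' end until it abuts the 5' terminus of the
# previously synthesized fragment (the template-origin end for the first
# fragment). Filling is exact interval arithmetic -- only the endpoint
# matters -- and reveals how much of each inter-primer interval the fork-bound
# polymerase had left unreplicated.

#' Extend fragment 3' ends to close the gaps between fragments
#'
#' Each fragment's `start` (its 3'-extension side) is moved down to the 5'
#' end of the fragment before it, never past it (no strand displacement), so
#' filled fragments tile the concatemer between consecutive used primers and
#' the filled length equals the inter-primer spacing. Runs containing ddGMP
#' are refused: a ddGMP-blocked 3' terminus cannot be extended, and no
#' polymerase that removes ddGMP exonucleolytically without strand
#' displacement is available, mirroring the bench assay's constraint.
#' The operation is idempotent: filling a filled set changes nothing.
#'
#' @param result A `sim_result` from [simulate_fork()].
#' @return Data frame of class `filled_fragments` with the original
#'   `start`/`end`/`length` plus `filled_start`, `filled_length` and
#'   `gap_filled` (nt added).
#' @export
gap_fill <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  if (result$config$pools$ddGTP > 0)
    stop("gap fill refused: ddGMP-terminated 3' ends are not extendable")
  fr <- result$fragments
  if (!nrow(fr)) stop("gap fill requires at least one fragment")
  out <- fill_intervals(fr$start, fr$end)
  res <- cbind(fr[, c("start", "end", "length")], out)
  class(res) <- c("filled_fragments", class(res))
  res
}

#' @rdname gap_fill
#' @param start,end Fragment intervals sorted in synthesis order (half-open,
#'   `end` = primer 5' side), non-overlapping.
#' @export
fill_intervals <- function(start, end) {
  stopifnot(length(start) == length(end), all(end > start))
  targets <- c(0L, end[-length(end)])
  if (any(start < targets))
    stop("invariant violation: overlapping fragments")
  data.frame(filled_start = targets,
             filled_length = end - targets,
             gap_filled = start - targets)
}

#' Summary statistics of a gap-filled fragment set
#'
#' @param filled A `filled_fragments` data frame from [gap_fill()].
#' @return List with `mean_gap` (nt), `mean_filled_length` (nt, equals the
#'   mean spacing between consecutive used primers) and
#'   `gap_fraction = mean_gap / mean_filled_length`.
#' @export
gap_stats <- function(filled) {
  if (is.null(nrow(filled)) || !nrow(filled)) stop("empty-input error: no filled fragments")
  mg <- mean(filled$gap_filled)
  ml <- mean(filled$filled_length)
  list(mean_gap = mg, mean_filled_length = ml, gap_fraction = mg / ml)
}
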