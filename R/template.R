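# Minicircle templates and the concatemer coordinate system.
#
# Rolling-circle replication copies a small circular duplex over and over, so
# the lagging-strand template is an effectively infinite concatemer of one
# short sequence. All fork coordinates in this package are 0-based positions
# on that concatemer; the circular position is simply `pos %% length`.

#' Generate a minicircle template with a prescribed base composition
#'
#' Builds the lagging-strand template of a rolling-circle minicircle: a
#' circular sequence with exact requested counts of C and G, the remaining
#' positions split as evenly as possible between A and T (A gets the odd
#' base), in an order randomized by `seed`. The default composition is a
#' 409-nt circle with 200 C and 4 G, i.e. a 50:1 C:G ratio, so that G-analog
#' perturbants (ddGTP, dGDPNP) act almost exclusively on lagging-strand
#' synthesis while the G-poor leading-strand template is untouched.
#'
#' @param length Circle length in nt.
#' @param n_C,n_G Number of C and G bases in the lagging-strand template.
#' @param seed Integer seed controlling the base order (composition is exact
#'   for any seed). The caller's RNG state is preserved.
#' @param unique_site 0-based circular position of the annealing site used by
#'   the exogenous-primer mode; must lie in `[0, length)`.
#' @return An object of class `minicircle` with fields `length`, `seq`
#'   (uppercase character scalar), `bases` (per-position character vector),
#'   `counts` (named A/C/G/T counts), and `unique_site`.
#' @examples
#' tpl <- make_minicircle()
#' tpl$counts[["C"]] / tpl$counts[["G"]]  # 50
#' @export
make_minicircle <- function(length = 409L, n_C = 200L, n_G = 4L, seed = 1L,
                            unique_site = 200L) {
  length <- as.integer(length); n_C <- as.integer(n_C); n_G <- as.integer(n_G)
  if (length < 1L) stop("template length must be >= 1")
  if (n_C < 0L || n_G < 0L || n_C + n_G > length)
    stop("composition error: n_C + n_G exceeds template length")
  if (unique_site < 0L || unique_site >= length)
    stop("unique_site must lie in [0, length)")
  rem <- length - n_C - n_G
  n_A <- as.integer(ceiling(rem / 2))
  n_T <- rem - n_A
  bases <- c(rep("C", n_C), rep("G", n_G), rep("A", n_A), rep("T", n_T))
  bases <- local_seed(seed, sample(bases, length(bases)))
  new_minicircle(bases, unique_site = as.integer(unique_site))
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's state.
local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

new_minicircle <- function(bases, unique_site = 0L) {
  counts <- c(A = sum(bases == "A"), C = sum(bases == "C"),
              G = sum(bases == "G"), T = sum(bases == "T"))
  structure(
    list(
      length = length(bases),
      seq = paste(bases, collapse = ""),
      bases = bases,
      counts = counts,
      unique_site = unique_site,
      # cumulative per-circle counts used for O(1) range queries on the
      # concatemer: cum_X[i+1] = count of X in circular positions [0, i)
      cum_C = c(0L, cumsum(bases == "C")),
      cum_CA = c(0L, cumsum(bases %in% c("C", "A")))
    ),
    class = "minicircle"
  )
}

#' @export
print.minicircle <- function(x, ...) {
  cat(sprintf("minicircle template: %d nt, C:G = %d:%d (A %d, T %d), unique site %d\n",
              x$length, x$counts[["C"]], x$counts[["G"]],
              x$counts[["A"]], x$counts[["T"]], x$unique_site))
  invisible(x)
}

#' Base at a linear position on the rolling-circle concatemer
#'
#' @param template A `minicircle`.
#' @param linear_pos Vector of 0-based non-negative positions on the
#'   concatemer.
#' @return Character vector of bases; position `p` maps to circular position
#'   `p %% length`.
#' @export
concatemer_base <- function(template, linear_pos) {
  if (any(linear_pos < 0)) stop("coordinate error: negative concatemer position")
  template$bases[(linear_pos %% template$length) + 1L]
}

# Count of C (or C+A) template bases in the half-open concatemer interval
# [from, to). Used for label accounting (dGMP opposite C) and for primer
# G+U content (primase inserts G opposite C and U opposite A).
count_template_c <- function(template, from, to) .count_range(template$cum_C, template$length, from, to)
count_template_ca <- function(template, from, to) .count_range(template$cum_CA, template$length, from, to)

.count_range <- function(cum, L, from, to) {
  if (any(from < 0) || any(to < from)) stop("coordinate error: invalid interval")
  total <- cum[L + 1L]
  f <- function(x) (x %/% L) * total + cum[(x %% L) + 1L]
  f(to) - f(from)
}

#' Write / read a minicircle template as single-record FASTA
#'
#' The FASTA header encodes the circle length and the exogenous-primer
#' annealing site as `minicircle|len=<L>|site=<u>`; sequence lines are wrapped
#' at 70 columns. Reading normalizes lowercase bases to uppercase and rejects
#' multi-record files, empty files and non-ACGT sequences.
#'
#' @param template A `minicircle`.
#' @param path File path.
#' @return `read_minicircle_fasta` returns a `minicircle`;
#'   `write_minicircle_fasta` returns `path` invisibly.
#' @export
write_minicircle_fasta <- function(template, path) {
  x <- Biostrings::DNAStringSet(template$seq)
  names(x) <- sprintf("minicircle|len=%d|site=%d", template$length, template$unique_site)
  Biostrings::writeXStringSet(x, filepath = path, width = 70L)
  invisible(path)
}

#' @rdname write_minicircle_fasta
#' @export
read_minicircle_fasta <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("format error: empty or missing FASTA file: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 1L)
    stop("format error: expected a single FASTA record, found ", length(x))
  seq <- toupper(as.character(x[[1]]))
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("format error: non-ACGT characters in template sequence")
  hdr <- names(x)[1]
  site <- 0L
  m <- regmatches(hdr, regexec("site=([0-9]+)", hdr))[[1]]
  if (length(m) == 2L) site <- as.integer(m[2])
  m <- regmatches(hdr, regexec("len=([0-9]+)", hdr))[[1]]
  if (length(m) == 2L && as.integer(m[2]) != length(bases))
    stop("format error: header length does not match sequence length")
  new_minicircle(bases, unique_site = site)
}

#' Export fragment, primer and gap intervals as a BED-like TSV
#'
#' Intervals are 0-based half-open on the concatemer, with columns
#' `chrom` (constant `"concatemer"`), `start`, `end`, `name`, `kind`.
#'
#' @param result A `sim_result` from [simulate_fork()].
#' @param path Output TSV path.
#' @return The exported data frame, invisibly.
#' @export
export_fragments_bed <- function(result, path) {
  fr <- result$fragments; pr <- result$primers; gp <- result$gaps
  rows <- rbind(
    if (nrow(fr)) data.frame(chrom = "concatemer", start = fr$start, end = fr$end,
                             name = sprintf("frag_%d", seq_len(nrow(fr))),
                             kind = "fragment"),
    if (nrow(pr)) data.frame(chrom = "concatemer", start = pr$top - pr$len, end = pr$top,
                             name = sprintf("primer_%d", seq_len(nrow(pr))),
                             kind = ifelse(pr$used, "primer_used", "primer_unused")),
    if (nrow(gp)) data.frame(chrom = "concatemer", start = gp$start, end = gp$end,
                             name = sprintf("gap_%d", seq_len(nrow(gp))),
                             kind = "gap")
  )
  if (is.null(rows))
    rows <- data.frame(chrom = character(), start = integer(), end = integer(),
                       name = character(), kind = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}

#' @rdname export_fragments_bed
#' @export
read_intervals_bed <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
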