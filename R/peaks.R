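#' Construct a named peak set
#'
#' A peak set is a sorted interval table with overlapping (or bookended)
#' intervals merged on construction, carrying a sample label for use in
#' intersection analyses.
#'
#' @param intervals Interval `data.frame` (chrom/start/end, 0-based
#'   half-open) or a BED file path.
#' @param name Sample label for this set.
#' @return A `data.frame` of class `c("peak_set", "data.frame")` with
#'   attribute `name`.
#' @export
peak_set <- function(intervals, name = "peaks") {
  if (is.character(intervals) && length(intervals) == 1L)
    intervals <- read_bed(intervals, min_columns = 3L)
  if (nrow(intervals) > 0L)
    intervals <- granges_to_intervals(
      GenomicRanges::reduce(interval_granges(intervals)))
  out <- intervals[order(intervals$chrom, intervals$start, intervals$end),
                   c("chrom", "start", "end"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "name") <- name
  class(out) <- c("peak_set", "data.frame")
  out
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("Peak set '%s': %d merged intervals on %d chromosome(s)\n",
              attr(x, "name"), nrow(x), length(unique(x$chrom))))
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

as_peak_set <- function(x, name) {
  if (inherits(x, "peak_set")) x else peak_set(x, name = name)
}

#' Directional overlap fraction between two peak sets
#'
#' Fraction of intervals in `a` overlapping at least one interval of `b` by
#' at least `min_overlap_bp` bases, and vice versa.  The measure is
#' asymmetric, so both directions are returned.
#'
#' @param a,b Peak sets (interval `data.frame`s, [peak_set()]s or BED
#'   paths); both non-empty.
#' @param min_overlap_bp Minimum shared bases for an overlap (default 1).
#' @return Named numeric vector `c(a_to_b = ..., b_to_a = ...)`.
#' @export
overlap_fraction <- function(a, b, min_overlap_bp = 1L) {
  a <- as_peak_set(a, "a"); b <- as_peak_set(b, "b")
  if (nrow(a) == 0L || nrow(b) == 0L)
    fr_stop("overlap fraction is undefined for an empty peak set")
  ga <- interval_granges(a); gb <- interval_granges(b)
  c(a_to_b = mean(IRanges::overlapsAny(ga, gb,
                                       minoverlap = min_overlap_bp)),
    b_to_a = mean(IRanges::overlapsAny(gb, ga,
                                       minoverlap = min_overlap_bp)))
}

#' Upset-style intersection counts across peak sets
#'
#' Two counting modes.  `mode = "region"`: the union of all sets is merged
#' into connected regions (any two intervals sharing a base, or bookended in
#' base space, are connected); each region is labelled with the subset of
#' sets contributing to it and regions are counted per membership pattern.
#' `mode = "reference"`: each interval of the designated reference set is
#' counted by which other sets overlap it — the framing used when asking how
#' many of one sample's peaks are shared with the others.  Both modes
#' return disjoint, exhaustive pattern counts plus per-set totals.
#'
#' @param sets Named list of >= 2 peak sets (interval `data.frame`s,
#'   [peak_set()]s or BED paths).
#' @param mode `"region"` (default) or `"reference"`.
#' @param reference Name of the reference set (mode `"reference"` only;
#'   defaults to the first set).
#' @param min_overlap_bp Overlap predicate, shared with
#'   [overlap_fraction()].
#' @return A list with `patterns` (`data.frame` of `pattern` — set names
#'   joined by `"&"` — and `count`), `totals` (named vector of merged-peak
#'   counts per set) and `mode`.
#' @export
upset_counts <- function(sets, mode = c("region", "reference"),
                         reference = NULL, min_overlap_bp = 1L) {
  mode <- match.arg(mode)
  if (!is.list(sets) || length(sets) < 2L)
    fr_stop("at least two peak sets are required")
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    fr_stop("peak sets must have unique non-empty names")
  sets <- lapply(nm, function(n) as_peak_set(sets[[n]], n))
  names(sets) <- nm
  grs <- lapply(sets, interval_granges)
  totals <- vapply(sets, nrow, integer(1))
  if (mode == "region") {
    union <- GenomicRanges::reduce(do.call(c, unname(grs)))
    member <- vapply(grs, function(g)
      IRanges::overlapsAny(union, g, minoverlap = min_overlap_bp),
      logical(length(union)))
    member <- matrix(member, nrow = length(union),
                     dimnames = list(NULL, nm))
  } else {
    if (is.null(reference)) reference <- nm[1L]
    if (!reference %in% nm) fr_stop("unknown reference set: ", reference)
    ref_gr <- grs[[reference]]
    member <- vapply(nm, function(n) {
      if (n == reference) rep(TRUE, length(ref_gr))
      else IRanges::overlapsAny(ref_gr, grs[[n]],
                                minoverlap = min_overlap_bp)
    }, logical(length(ref_gr)))
    member <- matrix(member, nrow = length(ref_gr),
                     dimnames = list(NULL, nm))
  }
  # canonical label: member names in lexicographic order, so patterns are
  # comparable regardless of input set order
  pattern <- apply(member, 1L, function(row)
    paste(sort(nm[row]), collapse = "&"))
  tab <- table(pattern)
  patterns <- data.frame(pattern = names(tab), count = as.integer(tab),
                         stringsAsFactors = FALSE)
  patterns <- patterns[order(-patterns$count, patterns$pattern), ,
                       drop = FALSE]
  rownames(patterns) <- NULL
  list(patterns = patterns, totals = totals, mode = mode)
}

#' Fraction of cells with signal per peak
#'
#' For each peak, the fraction of the supplied cell barcodes with at least
#' one fragment overlapping the peak — the per-peak signal-presence measure
#' used for cross-sample correlation scatter plots.
#'
#' @param fragments Fragment `data.frame`.
#' @param peaks Peak intervals (not merged here; one value per input row).
#' @param cells Non-empty character vector of barcodes (the denominator).
#' @return Numeric vector, one value in [0, 1] per peak row.
#' @export
fraction_cells_with_signal <- function(fragments, peaks, cells) {
  fragments <- check_fragment_frame(fragments)
  if (missing(cells) || length(cells) == 0L)
    fr_stop("a non-empty cell set is required")
  cells <- unique(cells)
  keep <- fragments$barcode %in% cells
  frg <- fragments[keep, , drop = FALSE]
  if (nrow(frg) == 0L) return(numeric(nrow(peaks)))
  hits <- GenomicRanges::findOverlaps(interval_granges(peaks),
                                      frag_granges(frg))
  pairs <- unique(data.frame(peak = S4Vectors::queryHits(hits),
                             barcode = frg$barcode[
                               S4Vectors::subjectHits(hits)]))
  tabulate(pairs$peak, nbins = nrow(peaks)) / length(cells)
}

#' Correlate per-peak signal-presence vectors between two samples
#'
#' Pearson and Spearman correlation of two per-peak
#' fraction-of-cells-with-signal vectors aligned on a shared (union) peak
#' set, plus the paired per-peak table for scatter export.  Zero-variance
#' input yields `NA` coefficients (undefined, not an error).
#'
#' @param x,y Numeric vectors of equal length (one value per union peak).
#' @param called_in Optional character vector flagging, per peak, which
#'   input set(s) called it (carried into the table for plotting).
#' @return A list with `pearson`, `spearman`, `n` and `table`.
#' @export
signal_presence_correlation <- function(x, y, called_in = NULL) {
  if (length(x) != length(y))
    fr_stop("signal vectors differ in length (", length(x), " vs ",
            length(y), ")")
  if (!is.null(called_in) && length(called_in) != length(x))
    fr_stop("called_in must align with the peak vectors")
  pearson <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
    else cor(x, y, method = "pearson")
  spearman <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
    else cor(x, y, method = "spearman")
  tab <- data.frame(x = x, y = y)
  if (!is.null(called_in)) tab$called_in <- called_in
  list(pearson = pearson, spearman = spearman, n = length(x), table = tab)
}
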