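#' Fraction of fragments in peaks (FRIP)
#'
#' Fraction of fragments overlapping any merged peak by at least one base
#' (half-open interval intersection).  Overlapping peaks are merged before
#' counting, so FRIP is invariant under peak-set order and under splitting a
#' peak into adjacent pieces covering the same bases.  With
#' `weighting = "reads"` the fraction is weighted by the support column.
#'
#' @param fragments Fragment `data.frame`.
#' @param peaks Interval `data.frame` (chrom/start/end, 0-based half-open)
#'   or [peak_set()].
#' @param weighting `"fragments"` (default) or `"reads"`.
#' @return A scalar in [0, 1]; 0 when the peak set is empty.
#' @export
frip <- function(fragments, peaks, weighting = c("fragments", "reads")) {
  weighting <- match.arg(weighting)
  fragments <- check_fragment_frame(fragments)
  if (nrow(fragments) == 0L)
    fr_stop("FRIP is undefined on an empty fragment stream")
  if (is.null(peaks) || nrow(peaks) == 0L) return(0)
  pk <- GenomicRanges::reduce(interval_granges(peaks))
  ov <- IRanges::overlapsAny(frag_granges(fragments), pk)
  if (weighting == "reads") sum(fragments$support[ov]) / sum(fragments$support)
  else mean(ov)
}

#' TSS enrichment score and aggregate profile
#'
#' ENCODE-style aggregate: both ends of every fragment are Tn5 insertion
#' events; insertions are counted at each offset in `[-flank, +flank]`
#' around every TSS (offset sign flipped for minus-strand TSS) and summed
#' into one profile.  The profile is normalised by the mean count over the
#' outermost `edge` positions at both ends (the distal background), smoothed
#' with a centred moving average of width `smooth_window`, and the score is
#' the maximum of the smoothed normalised profile.  A flat insertion density
#' therefore scores ~1; enrichment at the TSS scores > 1.
#'
#' When the background is exactly 0 it is floored at
#' `total insertions in window / (window width * 1000)` so the score stays
#' finite while still signalling strong enrichment.
#'
#' @param fragments Fragment `data.frame`.
#' @param tss TSS `data.frame` (`chrom`, `position`, `strand`), e.g. from
#'   [read_tss()].
#' @param flank Half-width of the window around each TSS (bp).
#' @param edge Number of outermost positions per side used as background.
#' @param smooth_window Width of the centred moving average (bp, odd).
#' @return A list with `score`, `profile` (normalised, unsmoothed, length
#'   `2 * flank + 1`), `smoothed`, `positions` (offsets) and `background`
#'   (raw mean edge count).
#' @export
tss_enrichment <- function(fragments, tss, flank = 2000L, edge = 100L,
                           smooth_window = 21L) {
  fragments <- check_fragment_frame(fragments)
  if (nrow(tss) == 0L) fr_stop("at least one TSS is required")
  counts <- tss_offset_counts(fragments, tss, flank)
  if (sum(counts) == 0)
    fr_stop("no fragment insertions fall within any TSS window; ",
            "TSS enrichment is undefined")
  width <- 2L * flank + 1L
  background <- mean(c(counts[seq_len(edge)],
                       counts[seq.int(width - edge + 1L, width)]))
  if (background == 0)
    background <- sum(counts) / (width * 1000)
  norm <- counts / background
  smoothed <- as.numeric(stats::filter(norm, rep(1 / smooth_window,
                                                 smooth_window),
                                       sides = 2))
  list(score = max(smoothed, na.rm = TRUE),
       profile = norm,
       smoothed = smoothed,
       positions = seq.int(-flank, flank),
       background = background)
}

# raw insertion counts per offset in [-flank, flank], strand-flipped,
# aggregated over all TSS.  Insertion sites are start and end - 1 (the two
# covered cut positions of a half-open fragment).
tss_offset_counts <- function(fragments, tss, flank) {
  site <- c(fragments$start, fragments$end - 1L)
  site_chrom <- c(fragments$chrom, fragments$chrom)
  pts <- GenomicRanges::GRanges(site_chrom,
                                IRanges::IRanges(site + 1L, site + 1L))
  win <- GenomicRanges::GRanges(tss$chrom,
                                IRanges::IRanges(tss$position - flank + 1L,
                                                 tss$position + flank + 1L))
  hits <- GenomicRanges::findOverlaps(pts, win)
  off <- site[S4Vectors::queryHits(hits)] -
    tss$position[S4Vectors::subjectHits(hits)]
  flip <- tss$strand[S4Vectors::subjectHits(hits)] == "-"
  off[flip] <- -off[flip]
  tabulate(off + flank + 1L, nbins = 2L * flank + 1L)
}

#' Nucleosome signal score
#'
#' Ratio of mono-nucleosome-length fragments (`nfr_max` < length <=
#' `mono_max`) to nucleosome-free fragments (length <= `nfr_max`), the
#' standard proxy for the nucleosomal banding pattern.  Fragment length is
#' `end - start` (half-open).
#'
#' @param fragments Fragment `data.frame`.
#' @param nfr_max Upper bound of the nucleosome-free class (bp, default
#'   147, one nucleosomal wrap).
#' @param mono_max Upper bound of the mono-nucleosome class (bp, default
#'   294).
#' @return A scalar, or `NA` when no fragment is <= `nfr_max` (the score is
#'   undefined, not an error).
#' @export
nucleosome_signal <- function(fragments, nfr_max = 147L, mono_max = 294L) {
  fragments <- check_fragment_frame(fragments)
  len <- fragments$end - fragments$start
  n_nfr <- sum(len <= nfr_max)
  if (n_nfr == 0L) return(NA_real_)
  sum(len > nfr_max & len <= mono_max) / n_nfr
}

#' Mitochondrial fragment fraction
#'
#' Support-weighted fraction of fragments on mitochondrial contigs.
#'
#' @param fragments Fragment `data.frame` (non-empty).
#' @param mito_names Chromosome names treated as mitochondrial.
#' @return A scalar in [0, 1].
#' @export
mito_fraction <- function(fragments, mito_names = c("chrM", "MT")) {
  fragments <- check_fragment_frame(fragments)
  if (nrow(fragments) == 0L)
    fr_stop("mitochondrial fraction is undefined on an empty stream")
  sum(fragments$support[fragments$chrom %in% mito_names]) /
    sum(fragments$support)
}

#' Fragment-length histogram
#'
#' Counts per 1-bp length bin; lengths above `max_length` are pooled into an
#' overflow bin recorded at `max_length + 1`.  The counts always sum to the
#' number of fragments.
#'
#' @param fragments Fragment `data.frame`.
#' @param max_length Largest length given its own bin (bp).
#' @return A `data.frame` with columns `length` and `count`, sparse (only
#'   occupied bins), sorted by length; attribute `overflow_bin` gives the
#'   length value that encodes the overflow pool.
#' @export
fragment_length_histogram <- function(fragments, max_length = 1000L) {
  fragments <- check_fragment_frame(fragments)
  if (nrow(fragments) == 0L) {
    out <- data.frame(length = integer(), count = integer())
    attr(out, "overflow_bin") <- max_length + 1L
    return(out)
  }
  len <- pmin(fragments$end - fragments$start, max_length + 1L)
  tab <- table(len)
  out <- data.frame(length = as.integer(names(tab)),
                    count = as.integer(tab))
  out <- out[order(out$length), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "overflow_bin") <- max_length + 1L
  out
}

#' Pooled QC report
#'
#' Computes all pooled QC metrics in one pass: FRIP (when peaks are given),
#' TSS enrichment (when TSS are given), nucleosome signal, mitochondrial
#' fraction, fragment count and the fragment-length histogram.
#'
#' @param fragments Fragment `data.frame` (non-empty).
#' @param peaks Optional peak intervals.
#' @param tss Optional TSS table.
#' @param max_length Histogram cap, see [fragment_length_histogram()].
#' @param ... Passed to [tss_enrichment()].
#' @return An object of class `"qc_report"`.
#' @export
qc_report <- function(fragments, peaks = NULL, tss = NULL,
                      max_length = 1000L, ...) {
  fragments <- check_fragment_frame(fragments)
  if (nrow(fragments) == 0L)
    fr_stop("QC metrics are undefined on an empty fragment stream")
  structure(list(
    n_fragments = nrow(fragments),
    frip = if (is.null(peaks)) NA_real_ else frip(fragments, peaks),
    tss_enrichment = if (is.null(tss)) NA_real_
      else tss_enrichment(fragments, tss, ...)$score,
    nucleosome_signal = nucleosome_signal(fragments),
    mito_fraction = mito_fraction(fragments),
    length_histogram = fragment_length_histogram(fragments, max_length)
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("ATAC QC report\n")
  cat(sprintf("  fragments:          %d\n", x$n_fragments))
  cat(sprintf("  FRIP:               %s\n", fmt_or_na(x$frip)))
  cat(sprintf("  TSS enrichment:     %s\n", fmt_or_na(x$tss_enrichment)))
  cat(sprintf("  nucleosome signal:  %s\n", fmt_or_na(x$nucleosome_signal)))
  cat(sprintf("  mito fraction:      %s\n", fmt_or_na(x$mito_fraction)))
  invisible(x)
}

#' Per-cell QC metrics
#'
#' Computes, for each requested barcode, the fragment count, summed read
#' support, FRIP, mitochondrial fraction, nucleosome signal and a per-cell
#' TSS score.  The per-cell TSS score deliberately differs from the pooled
#' score: it is the mean normalised insertion density over the central
#' `+/- centre` bp (not the smoothed maximum), which is far less noisy at
#' per-cell depth.  Cells in `cells` with no fragments get a row with
#' `n_fragments = 0` and `NA` metrics.
#'
#' @param fragments Fragment `data.frame` (pooled over the cells of one
#'   sample).
#' @param peaks Optional peak intervals (enables per-cell FRIP).
#' @param tss Optional TSS table (enables per-cell TSS score).
#' @param cells Character vector of barcodes to report (non-empty).
#' @param flank,edge Window geometry for the TSS score, as in
#'   [tss_enrichment()].
#' @param centre Half-width of the central window for the per-cell TSS
#'   score (bp).
#' @param mito_names Mitochondrial contig names.
#' @return A `data.frame`, one row per barcode in `cells`.
#' @export
per_cell_qc <- function(fragments, peaks = NULL, tss = NULL, cells,
                        flank = 2000L, edge = 100L, centre = 100L,
                        mito_names = c("chrM", "MT")) {
  fragments <- check_fragment_frame(fragments)
  if (missing(cells) || length(cells) == 0L)
    fr_stop("a non-empty set of cell barcodes is required")
  dt <- as.data.table(fragments)[barcode %in% cells]
  dt[, len := end - start]
  dt[, mito := chrom %in% mito_names]
  if (!is.null(peaks) && nrow(peaks) > 0L && nrow(dt) > 0L) {
    pk <- GenomicRanges::reduce(interval_granges(peaks))
    ov <- IRanges::overlapsAny(frag_granges(as.data.frame(dt)), pk)
    dt[, in_peak := ov]
  } else dt[, in_peak := NA]
  per <- dt[, list(
    n_fragments = .N,
    total_support = sum(support),
    frip = if (anyNA(in_peak)) NA_real_ else mean(in_peak),
    mito_fraction = sum(support[mito]) / sum(support),
    nucleosome_signal = {
      n_nfr <- sum(len <= 147L)
      if (n_nfr == 0L) NA_real_ else sum(len > 147L & len <= 294L) / n_nfr
    }
  ), by = "barcode"]
  out <- merge(data.table(barcode = unique(cells)), per, by = "barcode",
               all.x = TRUE)
  out[is.na(n_fragments), `:=`(n_fragments = 0L, total_support = 0L)]
  if (!is.null(tss) && nrow(tss) > 0L)
    out <- merge(out, per_cell_tss(dt, tss, flank, edge, centre),
                 by = "barcode", all.x = TRUE)
  else out[, tss_score := NA_real_]
  setorder(out, barcode)
  as.data.frame(out)
}

# per-cell TSS: central insertion density / edge background density,
# background floored as in the pooled metric
per_cell_tss <- function(dt, tss, flank, edge, centre) {
  frg <- as.data.frame(dt)
  site <- c(frg$start, frg$end - 1L)
  site_chrom <- c(frg$chrom, frg$chrom)
  site_bc <- c(frg$barcode, frg$barcode)
  pts <- GenomicRanges::GRanges(site_chrom,
                                IRanges::IRanges(site + 1L, site + 1L))
  win <- GenomicRanges::GRanges(tss$chrom,
                                IRanges::IRanges(tss$position - flank + 1L,
                                                 tss$position + flank + 1L))
  hits <- GenomicRanges::findOverlaps(pts, win)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  off <- site[q] - tss$position[s]
  flip <- tss$strand[s] == "-"
  off[flip] <- -off[flip]
  hd <- data.table(barcode = site_bc[q], off = off)
  width <- 2L * flank + 1L
  res <- hd[, {
    n_centre <- sum(abs(off) <= centre)
    n_edge <- sum(off < -flank + edge | off > flank - edge)
    bg <- n_edge / (2 * edge)
    if (bg == 0) bg <- .N / (width * 1000)
    list(tss_score = (n_centre / (2 * centre + 1)) / bg)
  }, by = "barcode"]
  res
}

#' Filter cells on QC thresholds
#'
#' Keeps the rows of a [per_cell_qc()] table passing user-supplied lower and
#' upper bounds on any metric column.  Bounds are inclusive; rows with `NA`
#' in a thresholded metric fail that threshold.
#'
#' @param qc A per-cell QC `data.frame`.
#' @param min,max Named lists of bounds, e.g.
#'   `min = list(n_fragments = 1000, frip = 0.3)`.
#' @return The filtered `data.frame`.
#' @export
filter_cells <- function(qc, min = list(), max = list()) {
  keep <- rep(TRUE, nrow(qc))
  for (m in names(min)) {
    if (!m %in% names(qc)) fr_stop("unknown QC metric: ", m)
    keep <- keep & !is.na(qc[[m]]) & qc[[m]] >= min[[m]]
  }
  for (m in names(max)) {
    if (!m %in% names(qc)) fr_stop("unknown QC metric: ", m)
    keep <- keep & !is.na(qc[[m]]) & qc[[m]] <= max[[m]]
  }
  qc[keep, , drop = FALSE]
}
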