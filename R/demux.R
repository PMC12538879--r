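#' Build the cell-barcode x sample fragment count matrix
#'
#' Counts, for every cell barcode c and sample s, the number of fragment
#' records N_cs observed for that barcode in that sample's fragment file
#' (`weighting = "fragments"`, the definition used by the fragment-ratio
#' classifier) or the summed read support (`weighting = "reads"`, for
#' sensitivity analysis).  Barcodes absent from a sample get an explicit 0;
#' barcodes observed nowhere are not stored.
#'
#' @param fragments Named list with one element per sample: a fragment
#'   `data.frame` (see [read_fragments()]) or a file path.  At least two
#'   samples with distinct names are required — demultiplexing is undefined
#'   for a single sample.
#' @param weighting `"fragments"` (count records; default) or `"reads"`
#'   (sum the support column).
#' @param strip_suffix Strip trailing `-<digits>` GEM-group suffixes before
#'   matching barcodes across samples (default `TRUE`).
#' @return An integer matrix with one row per barcode (rownames) and one
#'   column per sample (colnames, in input order).
#' @export
count_matrix <- function(fragments, weighting = c("fragments", "reads"),
                         strip_suffix = TRUE) {
  weighting <- match.arg(weighting)
  fragments <- load_fragment_list(fragments)
  samples <- names(fragments)
  long <- data.table::rbindlist(lapply(samples, function(s) {
    f <- fragments[[s]]
    bc <- if (strip_suffix) strip_barcode_suffix(f$barcode) else f$barcode
    data.table::data.table(barcode = bc,
                           sample = s,
                           w = if (weighting == "reads") f$support
                               else rep(1L, nrow(f)))
  }))
  if (nrow(long) == 0L)
    return(matrix(integer(), nrow = 0L, ncol = length(samples),
                  dimnames = list(character(), samples)))
  agg <- long[, list(n = sum(w)), by = c("barcode", "sample")]
  barcodes <- sort(unique(agg$barcode))
  mat <- matrix(0L, nrow = length(barcodes), ncol = length(samples),
                dimnames = list(barcodes, samples))
  mat[cbind(match(agg$barcode, barcodes), match(agg$sample, samples))] <-
    as.integer(agg$n)
  mat
}

# read paths on demand, enforce naming preconditions
load_fragment_list <- function(fragments) {
  if (!is.list(fragments) || length(fragments) < 2L)
    fr_stop("at least two samples are required (got ",
            if (is.list(fragments)) length(fragments) else 1L,
            "); demultiplexing is undefined for a single sample")
  nm <- names(fragments)
  if (is.null(nm) || any(!nzchar(nm)))
    fr_stop("every sample must be named")
  if (anyDuplicated(nm))
    fr_stop("duplicate sample identifiers: ",
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
  lapply(fragments, function(x) {
    if (is.character(x) && length(x) == 1L) read_fragments(x, validate = FALSE)
    else check_fragment_frame(x)
  })
}

#' Compute per-barcode fragment ratios
#'
#' For each barcode c the fragment ratio is r = max_s N_cs / sum_s N_cs; the
#' best sample is the argmax.  Ties at the argmax are broken towards the
#' lexicographically smallest sample identifier (such barcodes have r <= 0.5
#' and are necessarily ambiguous at any threshold above 0.5, so the rule
#' affects reporting only).
#'
#' @param counts Count matrix from [count_matrix()].
#' @return A `data.frame` with columns `cell_barcode`, `best_sample`,
#'   `fragment_ratio`, `total_fragments` and `status` (`NA` until
#'   [assign_samples()] is applied), one row per barcode, in matrix row
#'   order.
#' @export
fragment_ratio <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) == 0L || ncol(counts) < 2L)
    fr_stop("counts must be a non-empty matrix with >= 2 sample columns")
  samples <- colnames(counts)
  lex <- order(samples)
  best_lex <- max.col(counts[, lex, drop = FALSE], ties.method = "first")
  best <- lex[best_lex]
  totals <- rowSums(counts)
  if (any(totals < 1))
    fr_stop("every barcode row must have at least one fragment")
  best_n <- counts[cbind(seq_len(nrow(counts)), best)]
  data.frame(cell_barcode = rownames(counts),
             best_sample = samples[best],
             fragment_ratio = best_n / totals,
             total_fragments = as.integer(totals),
             status = NA_character_,
             stringsAsFactors = FALSE)
}

#' Assign barcodes to samples by fragment-ratio thresholding
#'
#' A barcode is `"low_count"` when its total fragment count is below
#' `min_fragments`; otherwise `"assigned"` when its fragment ratio strictly
#' exceeds `threshold` (r equal to the threshold is ambiguous, matching the
#' r > 0.6 rule); otherwise `"ambiguous"`.
#'
#' @param records Output of [fragment_ratio()].
#' @param threshold Fragment-ratio threshold in (0, 1]; default 0.6.
#' @param min_fragments Minimum total fragments for a barcode to be
#'   classifiable; default 100.
#' @return `records` with the `status` column filled in.
#' @export
assign_samples <- function(records, threshold = 0.6, min_fragments = 100) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    fr_stop("threshold must lie in (0, 1]")
  if (!is.numeric(min_fragments) || min_fragments < 0)
    fr_stop("min_fragments must be a non-negative integer")
  status <- ifelse(records$total_fragments < min_fragments, "low_count",
                   ifelse(records$fragment_ratio > threshold, "assigned",
                          "ambiguous"))
  records$status <- status
  records
}

#' Sample multiplicity of each barcode (simple incidence model)
#'
#' The incidence model keeps only barcodes observed in exactly one sample.
#' This function returns the per-barcode sample multiplicity (number of
#' samples with N_cs > 0) and the fraction of barcodes with multiplicity 1 —
#' the retention the incidence baseline would achieve.
#'
#' @param counts Count matrix from [count_matrix()].
#' @return A list with `multiplicity` (named integer vector) and
#'   `unique_fraction` (scalar).
#' @export
incidence_model <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) == 0L)
    fr_stop("counts must be a non-empty matrix")
  mult <- as.integer(rowSums(counts > 0L))
  names(mult) <- rownames(counts)
  list(multiplicity = mult, unique_fraction = mean(mult == 1L))
}

#' Fit the fragment-ratio demultiplexing classifier
#'
#' The one-stop fitting function: builds the count matrix, computes fragment
#' ratios, applies the threshold/minimum-count rule and the incidence-model
#' baseline, and returns a classed object with `print`, `summary`, `plot`
#' and `as.data.frame` methods.
#'
#' @inheritParams count_matrix
#' @inheritParams assign_samples
#' @return An object of class `"fr_demux"`: a list with `counts` (barcode x
#'   sample matrix), `assignments` (per-barcode table), `incidence`,
#'   `samples`, and the configuration used.
#' @examples
#' a <- data.frame(chrom = "chr1", start = c(0, 10, 20), end = c(5, 15, 25),
#'                 barcode = "ACGTACGTACGTACGT", support = 1L)
#' b <- a[1, ]
#' fit <- fr_demux(list(A = a, B = b), min_fragments = 0)
#' summary(fit)
#' @export
fr_demux <- function(fragments, threshold = 0.6, min_fragments = 100,
                     weighting = c("fragments", "reads"),
                     strip_suffix = TRUE) {
  weighting <- match.arg(weighting)
  fragments <- load_fragment_list(fragments)
  counts <- count_matrix(fragments, weighting = weighting,
                         strip_suffix = strip_suffix)
  if (nrow(counts) == 0L)
    fr_stop("no fragments found in any sample")
  rec <- assign_samples(fragment_ratio(counts), threshold = threshold,
                        min_fragments = min_fragments)
  structure(list(counts = counts,
                 assignments = rec,
                 incidence = incidence_model(counts),
                 samples = colnames(counts),
                 threshold = threshold,
                 min_fragments = min_fragments,
                 weighting = weighting,
                 strip_suffix = strip_suffix,
                 call = match.call()),
            class = "fr_demux")
}

#' @export
print.fr_demux <- function(x, ...) {
  n <- nrow(x$assignments)
  tab <- table(factor(x$assignments$status,
                      levels = c("assigned", "ambiguous", "low_count")))
  cat("Fragment-ratio demultiplexing fit\n")
  cat(sprintf("  %d cell barcodes across %d samples (%s)\n",
              n, length(x$samples), paste(x$samples, collapse = ", ")))
  cat(sprintf("  threshold r > %g, min fragments %g, weighting '%s'\n",
              x$threshold, x$min_fragments, x$weighting))
  for (s in names(tab))
    cat(sprintf("  %-10s %8d  (%.1f%%)\n", s, tab[[s]], 100 * tab[[s]] / n))
  cat(sprintf("  incidence-model unique fraction: %.1f%%\n",
              100 * x$incidence$unique_fraction))
  invisible(x)
}

#' Summarise a fragment-ratio demultiplexing fit
#'
#' @param object An `fr_demux` fit.
#' @param ... Unused.
#' @return An object of class `"summary.fr_demux"`: status counts and
#'   fractions, incidence-model unique fraction, per-sample assigned-cell
#'   counts and per-sample fragment-ratio quartiles (computed over barcodes
#'   whose best sample is that sample).
#' @export
summary.fr_demux <- function(object, ...) {
  rec <- object$assignments
  n <- nrow(rec)
  status_counts <- table(factor(rec$status,
                                levels = c("assigned", "ambiguous",
                                           "low_count")))
  per_sample_assigned <- vapply(object$samples, function(s)
    sum(rec$status == "assigned" & rec$best_sample == s), integer(1))
  fr_quartiles <- t(vapply(object$samples, function(s) {
    r <- rec$fragment_ratio[rec$best_sample == s]
    if (length(r) == 0L) rep(NA_real_, 5L)
    else quantile(r, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  }, numeric(5)))
  colnames(fr_quartiles) <- c("min", "q25", "median", "q75", "max")
  sc <- stats::setNames(as.integer(status_counts), names(status_counts))
  structure(list(n_barcodes = n,
                 status_counts = sc,
                 status_fractions = sc / n,
                 assigned_fraction = status_counts[["assigned"]] / n,
                 incidence_unique_fraction = object$incidence$unique_fraction,
                 per_sample_assigned = per_sample_assigned,
                 fr_quartiles = fr_quartiles,
                 threshold = object$threshold,
                 min_fragments = object$min_fragments),
            class = "summary.fr_demux")
}

#' @export
print.summary.fr_demux <- function(x, ...) {
  cat("Fragment-ratio demultiplexing summary\n")
  cat(sprintf("  %d barcodes; threshold r > %g; min fragments %g\n",
              x$n_barcodes, x$threshold, x$min_fragments))
  for (s in names(x$status_counts))
    cat(sprintf("  %-10s %8d  (%.1f%%)\n", s, x$status_counts[[s]],
                100 * x$status_fractions[[s]]))
  cat(sprintf("  incidence-model unique fraction: %.1f%%\n",
              100 * x$incidence_unique_fraction))
  cat("  assigned cells per sample:\n")
  for (s in names(x$per_sample_assigned))
    cat(sprintf("    %-12s %8d\n", s, x$per_sample_assigned[[s]]))
  invisible(x)
}

#' @export
as.data.frame.fr_demux <- function(x, ...) {
  cbind(x$assignments,
        as.data.frame(x$counts)[match(x$assignments$cell_barcode,
                                      rownames(x$counts)), , drop = FALSE],
        row.names = NULL)
}

#' Plot fragment-ratio distributions per best sample
#'
#' Boxplots of the per-barcode fragment ratio grouped by best sample, with a
#' dashed line at the assignment threshold — the standard visual for judging
#' how cleanly barcodes separate from the hopping background.
#'
#' @param x An `fr_demux` fit.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.fr_demux <- function(x, ...) {
  rec <- x$assignments
  boxplot(fragment_ratio ~ factor(best_sample, levels = x$samples),
          data = rec, xlab = "best sample", ylab = "fragment ratio",
          ylim = c(0, 1), ...)
  abline(h = x$threshold, lty = 2)
  invisible(x)
}

#' Full demultiplexing report
#'
#' Assembles the per-barcode table (including per-sample counts) and the
#' summary statistics in one list, convenient for export.
#'
#' @param fit An `fr_demux` fit.
#' @return A list with `table` (per-barcode data.frame with one count column
#'   per sample) and `summary` (see [summary.fr_demux()]).
#' @export
demux_report <- function(fit) {
  stopifnot(inherits(fit, "fr_demux"))
  list(table = as.data.frame(fit), summary = summary(fit))
}

#' Split fragment files according to an assignment
#'
#' For each assigned barcode, only the fragments observed in its assigned
#' sample's input are emitted to that sample's output; the same barcode's
#' fragments in *other* samples' files are hopping artifacts and go to the
#' discard stream (set `merge_hopped = TRUE` to merge them into the assigned
#' sample instead).  All fragments of ambiguous and low-count barcodes are
#' discarded.  Every input fragment appears in exactly one output.
#'
#' @param fragments Named list of per-sample fragment tables or paths — the
#'   same inputs the assignment was computed from.
#' @param fit An `fr_demux` fit (or a data.frame of assignments with columns
#'   `cell_barcode`, `best_sample`, `status`).
#' @param merge_hopped Merge an assigned barcode's hopped fragments into its
#'   assigned sample instead of discarding them (default `FALSE`).
#' @param strip_suffix Barcode suffix handling; defaults to the fit's
#'   setting.
#' @return A list with `samples` (named list of fragment data.frames) and
#'   `discard` (fragment data.frame).
#' @export
split_fragments <- function(fragments, fit, merge_hopped = FALSE,
                            strip_suffix = NULL) {
  assignments <- if (inherits(fit, "fr_demux")) fit$assignments else fit
  if (is.null(strip_suffix))
    strip_suffix <- if (inherits(fit, "fr_demux")) fit$strip_suffix else TRUE
  fragments <- load_fragment_list(fragments)
  samples <- names(fragments)
  assigned_to <- assignments$best_sample
  names(assigned_to) <- assignments$cell_barcode
  is_assigned <- assignments$status == "assigned"
  names(is_assigned) <- assignments$cell_barcode
  out <- stats::setNames(vector("list", length(samples)), samples)
  for (s in samples) out[[s]] <- list()
  discard <- list()
  for (s in samples) {
    f <- fragments[[s]]
    bc <- if (strip_suffix) strip_barcode_suffix(f$barcode) else f$barcode
    unknown <- !(bc %in% assignments$cell_barcode)
    if (any(unknown))
      fr_stop("fragments carry ", sum(unknown),
              " barcode(s) absent from the assignment table (first: ",
              bc[which(unknown)[1L]], ")")
    ok <- is_assigned[bc]
    dest <- assigned_to[bc]
    keep_here <- ok & dest == s
    if (merge_hopped) {
      for (d in samples) {
        idx <- which(ok & dest == d)
        if (length(idx)) out[[d]][[length(out[[d]]) + 1L]] <- f[idx, ]
      }
      discard[[length(discard) + 1L]] <- f[!ok, , drop = FALSE]
    } else {
      out[[s]][[length(out[[s]]) + 1L]] <- f[keep_here, , drop = FALSE]
      discard[[length(discard) + 1L]] <- f[!keep_here, , drop = FALSE]
    }
  }
  bind <- function(lst) {
    if (length(lst) == 0L) empty_fragments()
    else as.data.frame(data.table::rbindlist(lst))
  }
  list(samples = lapply(out, bind), discard = bind(discard))
}
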