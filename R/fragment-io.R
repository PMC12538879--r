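#' Read a fragments file (10x scATAC dialect)
#'
#' Reads a tab-separated fragments file with columns chrom, start, end,
#' cell barcode and support count (number of read pairs supporting the
#' fragment).  Coordinates are 0-based half-open and are returned unchanged;
#' no Tn5 offset correction is applied (upstream pipelines have already done
#' so).  Gzip compression is detected from the file content (magic bytes),
#' not the extension.  Lines starting with `#` are skipped.
#'
#' @param path Path to a fragments file, plain or gzip-compressed.
#' @param validate If `TRUE` (default) malformed lines abort with an error
#'   naming the offending line number.  If `FALSE` malformed lines are
#'   counted, skipped, and reported via `message()`.
#'
#' A line is malformed when it has fewer than five tab-separated fields, its
#' coordinates are not integers with `0 <= start < end`, its support count is
#' not a positive integer, or its barcode is empty / contains characters
#' outside `ACGTN` (an optional trailing `-<digits>` GEM-group suffix is
#' allowed).
#'
#' @return A `data.frame` with columns `chrom` (character), `start`, `end`
#'   (integer, 0-based half-open), `barcode` (character) and `support`
#'   (integer).
#' @seealso [write_fragments()], [read_bed()]
#' @export
read_fragments <- function(path, validate = TRUE) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    fr_stop("fragments file not found: ", path)
  con <- gzfile(path, "rt")   # reads plain files too; compression sniffed from magic bytes
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  body <- lines[keep]
  if (length(body) == 0L)
    return(empty_fragments())
  parts <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  if (length(parts) < 5L)
    parts <- c(parts, rep(list(rep(NA_character_, length(body))),
                          5L - length(parts)))
  chrom   <- parts[[1L]]
  start   <- suppressWarnings(as.integer(parts[[2L]]))
  end     <- suppressWarnings(as.integer(parts[[3L]]))
  barcode <- parts[[4L]]
  support <- suppressWarnings(as.integer(parts[[5L]]))
  bad <- is.na(chrom) | !nzchar(chrom) |
    is.na(start) | is.na(end) | start < 0L | start >= end |
    is.na(support) | support < 1L |
    is.na(barcode) | !grepl("^[ACGTN]+(-[0-9]+)?$", barcode)
  if (any(bad)) {
    if (validate) {
      line_no <- which(keep)[which(bad)[1L]]
      fr_stop("malformed fragment record at line ", line_no, ": ",
              lines[line_no])
    }
    message("read_fragments: skipped ", sum(bad), " malformed line(s) in ",
            path)
  }
  ok <- !bad
  data.frame(chrom = chrom[ok], start = start[ok], end = end[ok],
             barcode = barcode[ok], support = support[ok],
             stringsAsFactors = FALSE)
}

empty_fragments <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             barcode = character(), support = integer(),
             stringsAsFactors = FALSE)
}

#' Write a fragments file
#'
#' Writes fragments in the 5-column tab-separated fragments.tsv dialect, in
#' the row order given (sorting is the caller's concern).  Output is plain
#' gzip when `compress = TRUE`; no bgzf/tabix support.
#'
#' @param fragments A fragment `data.frame` as returned by
#'   [read_fragments()].
#' @param path Output path; its directory must exist.
#' @param compress Write gzip-compressed output (default `FALSE`).
#' @return Invisibly, the number of records written.
#' @export
write_fragments <- function(fragments, path, compress = FALSE) {
  fragments <- check_fragment_frame(fragments)
  dir <- dirname(path)
  if (!dir.exists(dir)) fr_stop("output directory does not exist: ", dir)
  con <- if (compress) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(fragments) > 0L)
    writeLines(paste(fragments$chrom, fragments$start, fragments$end,
                     fragments$barcode, fragments$support, sep = "\t"), con)
  else
    writeLines(character(0), con)
  invisible(nrow(fragments))
}

# coerce/validate a fragment data.frame (structure only, not per-row content)
check_fragment_frame <- function(fragments) {
  need <- c("chrom", "start", "end", "barcode", "support")
  if (!is.data.frame(fragments) || !all(need %in% names(fragments)))
    fr_stop("fragments must be a data.frame with columns ",
            paste(need, collapse = ", "))
  fragments
}

#' Read a BED file of genomic intervals
#'
#' BED-style, 0-based half-open.  With `min_columns = 6` the name, score and
#' strand columns are parsed and returned (strand restricted to `+`/`-`);
#' with `min_columns = 3` any extra columns are ignored.  Intervals are
#' returned sorted by (chrom, start, end).  `#`, `track` and `browser` lines
#' are skipped; gzip input is detected from content.
#'
#' @param path Path to a BED file.
#' @param min_columns Either 3 or 6; lines with fewer columns are an error.
#' @return A sorted `data.frame` with columns `chrom`, `start`, `end` and,
#'   for `min_columns = 6`, `name` and `strand`.
#' @export
read_bed <- function(path, min_columns = 3L) {
  if (!file.exists(path)) fr_stop("BED file not found: ", path)
  if (!min_columns %in% c(3L, 6L)) fr_stop("min_columns must be 3 or 6")
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  body <- lines[keep]
  if (length(body) == 0L) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
    if (min_columns == 6L) { out$name <- character(); out$strand <- character() }
    return(out)
  }
  parts <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  if (length(parts) < min_columns) {
    fr_stop("BED line with fewer than ", min_columns, " columns at line ",
            which(keep)[1L])
  }
  short <- is.na(parts[[min_columns]])
  if (any(short)) {
    line_no <- which(keep)[which(short)[1L]]
    fr_stop("BED line with fewer than ", min_columns,
            " columns at line ", line_no)
  }
  start <- suppressWarnings(as.integer(parts[[2L]]))
  end   <- suppressWarnings(as.integer(parts[[3L]]))
  bad <- is.na(start) | is.na(end) | start < 0L | start >= end
  if (any(bad)) {
    line_no <- which(keep)[which(bad)[1L]]
    fr_stop("invalid BED interval at line ", line_no, ": ", lines[line_no])
  }
  out <- data.frame(chrom = parts[[1L]], start = start, end = end,
                    stringsAsFactors = FALSE)
  if (min_columns == 6L) {
    strand <- parts[[6L]]
    if (!all(strand %in% c("+", "-"))) {
      line_no <- which(keep)[which(!strand %in% c("+", "-"))[1L]]
      fr_stop("BED strand must be '+' or '-' at line ", line_no)
    }
    out$name <- parts[[4L]]
    out$strand <- strand
  }
  out[order(out$chrom, out$start, out$end), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Read transcription start sites from a BED6 file
#'
#' Each record yields one strand-aware TSS anchor: the 0-based position is
#' `start` for `+`-strand entries and `end - 1` for `-`-strand entries (for
#' 1-bp records the two coincide).
#'
#' @param path Path to a 6-column BED file.
#' @return A `data.frame` with columns `chrom`, `position` (0-based) and
#'   `strand`.
#' @export
read_tss <- function(path) {
  bed <- read_bed(path, min_columns = 6L)
  data.frame(chrom = bed$chrom,
             position = ifelse(bed$strand == "+", bed$start, bed$end - 1L),
             strand = bed$strand, stringsAsFactors = FALSE)
}

#' Strip a GEM-group suffix from cell barcodes
#'
#' Per-sample pipeline runs append `-<digits>` suffixes (e.g. `"-1"`) to the
#' same GEM barcode; stripping them makes barcodes comparable across samples.
#'
#' @param x Character vector of barcodes.
#' @return `x` with any trailing `-<digits>` removed.
#' @export
strip_barcode_suffix <- function(x) sub("-[0-9]+$", "", x)

# ---- internal GRanges bridges (surface stays 0-based half-open) ----

frag_granges <- function(fragments) {
  GenomicRanges::GRanges(fragments$chrom,
                         IRanges::IRanges(fragments$start + 1L,
                                          fragments$end))
}

interval_granges <- function(intervals) {
  GenomicRanges::GRanges(intervals$chrom,
                         IRanges::IRanges(intervals$start + 1L,
                                          intervals$end))
}

granges_to_intervals <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}
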