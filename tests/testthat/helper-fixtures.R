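# builders for in-code fixtures; no fixture files

make_frags <- function(start, end, barcode = "ACGTACGTACGTACGT",
                       chrom = "chr1", support = 1L) {
  n <- max(length(start), length(end), length(barcode))
  data.frame(chrom = rep_len(chrom, n),
             start = as.integer(rep_len(start, n)),
             end = as.integer(rep_len(end, n)),
             barcode = rep_len(barcode, n),
             support = as.integer(rep_len(support, n)),
             stringsAsFactors = FALSE)
}

make_intervals <- function(start, end, chrom = "chr1") {
  data.frame(chrom = rep_len(chrom, length(start)),
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

# random barcode pool for generated cases
rand_bc <- function(n, len = 8L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

# turn a barcode x sample count matrix into per-sample fragment frames
# (each count becomes that many unit-support fragments at arbitrary coords)
counts_to_fragments <- function(mat) {
  samples <- colnames(mat)
  out <- lapply(samples, function(s) {
    reps <- mat[, s]
    bc <- rep(rownames(mat), reps)
    n <- length(bc)
    if (n == 0L)
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), barcode = character(),
                        support = integer(), stringsAsFactors = FALSE))
    make_frags(start = seq_len(n) * 10L, end = seq_len(n) * 10L + 5L,
               barcode = bc)
  })
  names(out) <- samples
  out
}

small_sim <- function(...) {
  args <- utils::modifyList(
    list(n_samples = 3L, cells_per_sample = 40L, mean_fragments = 150,
         genome_length = 2e6L, n_peaks = 100L, seed = 101L),
    list(...))
  do.call(sim_config, args)
}
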