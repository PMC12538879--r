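#' Configuration for the synthetic multiplexed scATAC experiment
#'
#' Defines the generative model: S samples are tagmented with sample-specific
#' Tn5 barcodes and pooled; each cell barcode belongs to one true sample (or,
#' for doublet GEMs, to two); free Tn5 inserts entering GEMs after pooling
#' relabel a fraction of each cell's fragments with the wrong sample barcode
#' ("hopping"), spreading one barcode across several per-sample fragment
#' files.  Coordinates live on one synthetic autosome (`chr1`) plus a `chrM`
#' contig; no sequence content is generated.
#'
#' Defaults mirror a ten-plex droplet experiment: 10 samples x 500 cells,
#' per-cell fragment depth negative-binomial with mean 2000 (overdispersed,
#' `dispersion` is the NB size parameter), per-fragment hop probability 0.2,
#' 5% cross-sample doublets with mixing proportion uniform in [0.3, 0.7],
#' 500 non-overlapping 500-bp peaks on a 10-Mb genome with a TSS at each
#' peak centre, fragment lengths from a nucleosome-free/mono-nucleosome
#' normal mixture truncated at 20 bp, and a 10% mitochondrial fragment
#' fraction.
#'
#' @param n_samples Number of multiplexed samples (>= 2).
#' @param cells_per_sample True cells per sample.
#' @param hop_rate Per-fragment probability of carrying a wrong sample
#'   barcode, in [0, 1).
#' @param doublet_rate Probability that a barcode is a cross-sample doublet,
#'   in [0, 1).
#' @param mean_fragments,dispersion Negative-binomial per-cell fragment
#'   count model (mean and size).
#' @param genome_length Length of the synthetic autosome (bp).
#' @param n_peaks,peak_width Number and width of non-overlapping peaks.
#' @param frip_target Probability a (non-mitochondrial) fragment midpoint
#'   falls inside a random peak, in (0, 1).
#' @param peak_weight_shape Shape of the Gamma(shape, 1) accessibility
#'   weight drawn once per peak and shared by all samples and cells: peaks
#'   differ in how often fragments land in them, as real peaks span orders
#'   of magnitude in accessibility.  Small values give strong heterogeneity;
#'   large values approach uniform peak usage.
#' @param nfr_length_mean,nfr_length_sd,mono_length_mean,mono_length_sd,nfr_weight
#'   Two-component normal fragment-length mixture (bp); lengths truncated at
#'   >= 20 bp.
#' @param mito_fraction Probability a fragment is placed on `chrM`, in
#'   [0, 1).
#' @param mito_length Length of the `chrM` contig (bp).
#' @param seed Integer seed; the simulation is fully deterministic given the
#'   seed.
#' @return An object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_samples = 10L, cells_per_sample = 500L,
                       hop_rate = 0.2, doublet_rate = 0.05,
                       mean_fragments = 2000, dispersion = 2,
                       genome_length = 1e7, n_peaks = 500L,
                       peak_width = 500L, frip_target = 0.5,
                       peak_weight_shape = 1,
                       nfr_length_mean = 70, nfr_length_sd = 20,
                       mono_length_mean = 200, mono_length_sd = 30,
                       nfr_weight = 0.6, mito_fraction = 0.1,
                       mito_length = 16569L, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              cells_per_sample = as.integer(cells_per_sample),
              hop_rate = hop_rate, doublet_rate = doublet_rate,
              mean_fragments = mean_fragments, dispersion = dispersion,
              genome_length = as.integer(genome_length),
              n_peaks = as.integer(n_peaks),
              peak_width = as.integer(peak_width),
              frip_target = frip_target,
              peak_weight_shape = peak_weight_shape,
              nfr_length_mean = nfr_length_mean,
              nfr_length_sd = nfr_length_sd,
              mono_length_mean = mono_length_mean,
              mono_length_sd = mono_length_sd,
              nfr_weight = nfr_weight, mito_fraction = mito_fraction,
              mito_length = as.integer(mito_length),
              seed = as.integer(seed))
  if (cfg$n_samples < 2L) fr_stop("n_samples must be >= 2")
  if (cfg$cells_per_sample < 1L) fr_stop("cells_per_sample must be >= 1")
  for (p in c("hop_rate", "doublet_rate", "mito_fraction"))
    if (cfg[[p]] < 0 || cfg[[p]] >= 1)
      fr_stop(p, " must lie in [0, 1)")
  if (cfg$frip_target <= 0 || cfg$frip_target >= 1)
    fr_stop("frip_target must lie in (0, 1)")
  if (cfg$peak_weight_shape <= 0)
    fr_stop("peak_weight_shape must be positive")
  if (cfg$nfr_weight <= 0 || cfg$nfr_weight >= 1)
    fr_stop("nfr_weight must lie in (0, 1)")
  if (cfg$mean_fragments <= 0 || cfg$dispersion <= 0)
    fr_stop("mean_fragments and dispersion must be positive")
  if (cfg$n_peaks < 1L || cfg$peak_width < 1L)
    fr_stop("n_peaks and peak_width must be positive")
  if (as.numeric(cfg$n_peaks) * (cfg$peak_width + 1L) >= cfg$genome_length)
    fr_stop("infeasible peak placement: n_peaks * peak_width must be well ",
            "below genome_length")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic multiplexed scATAC configuration\n")
  cat(sprintf("  %d samples x %d cells, NB(mean %g, size %g) fragments/cell\n",
              x$n_samples, x$cells_per_sample, x$mean_fragments,
              x$dispersion))
  cat(sprintf("  hop rate %g, doublet rate %g, seed %d\n",
              x$hop_rate, x$doublet_rate, x$seed))
  cat(sprintf("  genome %d bp, %d peaks of %d bp, FRIP target %g, mito %g\n",
              x$genome_length, x$n_peaks, x$peak_width, x$frip_target,
              x$mito_fraction))
  invisible(x)
}

#' Simulate a multiplexed scATAC experiment with barcode hopping
#'
#' Generative procedure (all draws from one seeded stream, in this order):
#' (1) place `n_peaks` non-overlapping peaks uniformly on `chr1`, draw one
#' accessibility weight per peak, and put one TSS at each peak centre with
#' random strand; (2) create unique random 16-mer cell
#' barcodes, each with a true sample; with probability `doublet_rate` a
#' barcode is a cross-sample doublet whose fragments come from two samples
#' with mixing proportion uniform in [0.3, 0.7]; (3) draw per-cell fragment
#' counts from the negative binomial; (4) per fragment, with probability
#' `mito_fraction` place it on `chrM`, otherwise with probability
#' `frip_target` centre it uniformly inside a peak drawn by accessibility
#' weight, else uniformly outside peaks; lengths come from the nucleosome-free/mono-nucleosome
#' normal mixture truncated at 20 bp; (5) with probability `hop_rate` a
#' fragment's sample label is replaced by a uniform draw over the other
#' samples (doublet fragments hop from their emitting component's sample);
#' (6) fragments are routed to per-sample tables by their observed label.
#'
#' The global RNG state is saved and restored, so the simulation does not
#' perturb the caller's random stream.
#'
#' @param config A [sim_config()].
#' @param keep_fragment_log Also return the per-fragment bookkeeping table
#'   (cell index, emitting sample, observed sample) — exact hop accounting
#'   for validation; off by default as it doubles memory.
#' @return An object of class `"fr_sim"`: a list with `fragments` (named
#'   list of per-sample fragment data.frames), `truth` (per-barcode table:
#'   `cell_barcode`, `true_sample`, `second_sample`, `is_doublet`,
#'   `n_fragments_total`, `n_fragments_hopped`), `peaks`, `tss`, `config`
#'   and optionally `fragment_log`.
#' @export
simulate_fragments <- function(config = sim_config(),
                               keep_fragment_log = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(config$seed)
  S <- config$n_samples
  samples <- sprintf("S%02d", seq_len(S))

  # (1) peaks: uniform non-overlapping placement with >= 1 bp separation
  w <- config$peak_width
  slack <- config$genome_length - config$n_peaks * (w + 1L)
  peak_start <- sort(as.integer(floor(runif(config$n_peaks, 0, slack + 1)))) +
    (seq_len(config$n_peaks) - 1L) * (w + 1L)
  peaks <- data.frame(chrom = "chr1", start = peak_start,
                      end = peak_start + w, stringsAsFactors = FALSE)
  peak_weight <- rgamma(config$n_peaks, shape = config$peak_weight_shape)
  peak_weight <- peak_weight / sum(peak_weight)
  tss <- data.frame(chrom = "chr1",
                    position = peak_start + w %/% 2L,
                    strand = sample(c("+", "-"), config$n_peaks,
                                    replace = TRUE),
                    stringsAsFactors = FALSE)

  # (2) cells
  n_cells <- S * config$cells_per_sample
  barcodes <- random_barcodes(n_cells)
  true_idx <- rep(seq_len(S), each = config$cells_per_sample)
  is_doublet <- runif(n_cells) < config$doublet_rate
  second_idx <- rep(NA_integer_, n_cells)
  if (any(is_doublet)) {
    r <- sample.int(S - 1L, sum(is_doublet), replace = TRUE)
    t1 <- true_idx[is_doublet]
    second_idx[is_doublet] <- r + (r >= t1)
  }
  mix <- rep(NA_real_, n_cells)
  mix[is_doublet] <- runif(sum(is_doublet), 0.3, 0.7)

  # (3) per-cell depth
  nf <- rnbinom(n_cells, size = config$dispersion, mu = config$mean_fragments)

  # (4)-(5) per-fragment draws, fully vectorised
  cell <- rep.int(seq_len(n_cells), nf)
  N <- length(cell)
  emit <- true_idx[cell]
  dbl <- is_doublet[cell]
  if (any(dbl)) {
    use_second <- rep(FALSE, N)
    use_second[dbl] <- runif(sum(dbl)) >= mix[cell[dbl]]
    emit[use_second] <- second_idx[cell[use_second]]
  }
  mito <- runif(N) < config$mito_fraction
  nfr <- runif(N) < config$nfr_weight
  len <- numeric(N)
  len[nfr] <- rnorm(sum(nfr), config$nfr_length_mean, config$nfr_length_sd)
  len[!nfr] <- rnorm(sum(!nfr), config$mono_length_mean,
                     config$mono_length_sd)
  len <- pmax(20L, as.integer(round(len)))
  # placement on chr1
  in_peak <- runif(N) < config$frip_target
  pk <- sample.int(config$n_peaks, N, replace = TRUE, prob = peak_weight)
  mid_peak <- peak_start[pk] + as.integer(floor(runif(N) * w))
  mid_bg <- draw_outside_peaks(N, peak_start, w, config$genome_length)
  mid <- ifelse(in_peak, mid_peak, mid_bg)
  start <- mid - len %/% 2L
  start <- pmax(0L, pmin(start, config$genome_length - len))
  # mitochondrial placement overrides
  if (any(mito)) {
    lm <- pmin(len[mito], config$mito_length - 1L)
    len[mito] <- lm
    start[mito] <- as.integer(floor(runif(sum(mito)) *
                                      (config$mito_length - lm)))
  }
  end <- start + len
  chrom <- ifelse(mito, "chrM", "chr1")
  # (5) hopping
  obs <- emit
  hopped <- runif(N) < config$hop_rate
  if (any(hopped)) {
    r <- sample.int(S - 1L, sum(hopped), replace = TRUE)
    e <- emit[hopped]
    obs[hopped] <- r + (r >= e)
  }

  # (6) routing + truth
  frag_by_sample <- split(seq_len(N), factor(obs, levels = seq_len(S)))
  fragments <- stats::setNames(lapply(frag_by_sample, function(idx) {
    data.frame(chrom = chrom[idx], start = as.integer(start[idx]),
               end = as.integer(end[idx]), barcode = barcodes[cell[idx]],
               support = rep(1L, length(idx)), stringsAsFactors = FALSE)
  }), samples)
  truth <- data.frame(cell_barcode = barcodes,
                      true_sample = samples[true_idx],
                      second_sample = ifelse(is.na(second_idx), NA_character_,
                                             samples[second_idx]),
                      is_doublet = is_doublet,
                      n_fragments_total = as.integer(nf),
                      n_fragments_hopped = tabulate(cell[hopped], n_cells),
                      stringsAsFactors = FALSE)
  out <- list(fragments = fragments, truth = truth, peaks = peaks,
              tss = tss, config = config)
  if (keep_fragment_log)
    out$fragment_log <- data.frame(cell = cell,
                                   emit_sample = samples[emit],
                                   obs_sample = samples[obs],
                                   hopped = hopped)
  structure(out, class = "fr_sim")
}

#' @export
print.fr_sim <- function(x, ...) {
  cat("Simulated multiplexed scATAC experiment\n")
  cat(sprintf("  %d samples, %d cell barcodes, %d fragments (%d hopped)\n",
              length(x$fragments), nrow(x$truth),
              sum(x$truth$n_fragments_total),
              sum(x$truth$n_fragments_hopped)))
  cat(sprintf("  %d peaks, %d TSS; seed %d\n", nrow(x$peaks), nrow(x$tss),
              x$config$seed))
  invisible(x)
}

# unique random 16-mers; collision probability at 4^16 is negligible but
# handled anyway
random_barcodes <- function(n) {
  gen <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), 16L * k, replace = TRUE),
                nrow = k)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  bc <- gen(n)
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- gen(length(dup))
  }
  bc
}

# uniform draw over the complement of the peak footprint on chr1
draw_outside_peaks <- function(n, peak_start, width, genome_length) {
  gap_start <- c(0L, peak_start + width)
  gap_end <- c(peak_start, genome_length)
  gap_len <- gap_end - gap_start
  keep <- gap_len > 0L
  gap_start <- gap_start[keep]; gap_len <- gap_len[keep]
  cum <- cumsum(as.numeric(gap_len))
  u <- runif(n, 0, cum[length(cum)])
  idx <- findInterval(u, c(0, cum[-length(cum)]))
  as.integer(gap_start[idx] + floor(u - c(0, cum)[idx]))
}

#' Write a simulated experiment to disk
#'
#' Emits `<sample>.fragments.tsv(.gz)`, `truth.tsv`, `peaks.bed`, `tss.bed`
#' and `config.resolved.yaml` under `dir`.
#'
#' @param sim An `fr_sim` object from [simulate_fragments()].
#' @param dir Output directory (created if missing).
#' @param compress Gzip the fragment files (default `TRUE`).
#' @return Invisibly, the named vector of paths written.
#' @export
write_simulation <- function(sim, dir, compress = TRUE) {
  stopifnot(inherits(sim, "fr_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in names(sim$fragments)) {
    p <- file.path(dir, paste0(s, ".fragments.tsv",
                               if (compress) ".gz" else ""))
    write_fragments(sim$fragments[[s]], p, compress = compress)
    paths[s] <- p
  }
  tp <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["truth"] <- tp
  pb <- file.path(dir, "peaks.bed")
  writeLines(paste(sim$peaks$chrom, sim$peaks$start, sim$peaks$end,
                   sep = "\t"), pb)
  paths["peaks"] <- pb
  tb <- file.path(dir, "tss.bed")
  writeLines(paste(sim$tss$chrom, sim$tss$position, sim$tss$position + 1L,
                   sprintf("tss_%d", seq_len(nrow(sim$tss))), 0L,
                   sim$tss$strand, sep = "\t"), tb)
  paths["tss"] <- tb
  cy <- file.path(dir, "config.resolved.yaml")
  yaml::write_yaml(unclass(sim$config), cy)
  paths["config"] <- cy
  invisible(paths)
}

#' Score an assignment against simulation ground truth
#'
#' Compares a fragment-ratio assignment with the simulator's truth table.
#' Barcodes evaluated are those present in the assignment (truth barcodes
#' that generated zero fragments can never be observed); assignment barcodes
#' missing from the truth are a consistency error.
#'
#' @param fit An `fr_demux` fit, or an assignments `data.frame` with columns
#'   `cell_barcode`, `best_sample`, `status` (and per-sample count columns
#'   if the incidence baseline should be recomputed).
#' @param truth Truth table from [simulate_fragments()] (or read from
#'   `truth.tsv`).
#' @return An object of class `"fr_eval"`: `n_evaluated`,
#'   `assigned_fraction`, `singlet_precision` (fraction of assigned singlets
#'   assigned to their true sample; `NA` when no singlet is assigned),
#'   `singlet_recall` (fraction of all evaluated singlets assigned
#'   correctly), `doublet_assigned_fraction` (doublet leak-through; `NA`
#'   when no doublets), and `incidence_unique_fraction` (when available).
#' @export
evaluate_assignment <- function(fit, truth) {
  if (inherits(fit, "fr_demux")) {
    rec <- fit$assignments
    incidence <- fit$incidence$unique_fraction
  } else {
    rec <- fit
    incidence <- incidence_from_assignment_table(rec)
  }
  need <- c("cell_barcode", "best_sample", "status")
  if (!all(need %in% names(rec)))
    fr_stop("assignments must have columns ", paste(need, collapse = ", "))
  m <- match(rec$cell_barcode, truth$cell_barcode)
  if (anyNA(m))
    fr_stop(sum(is.na(m)), " assigned barcode(s) absent from the truth ",
            "table (first: ", rec$cell_barcode[which(is.na(m))[1L]], ")")
  tru <- truth[m, ]
  assigned <- rec$status == "assigned"
  singlet <- !tru$is_doublet
  correct <- assigned & rec$best_sample == tru$true_sample
  n_assigned_singlet <- sum(assigned & singlet)
  structure(list(
    n_evaluated = nrow(rec),
    assigned_fraction = mean(assigned),
    singlet_precision = if (n_assigned_singlet == 0L) NA_real_
      else sum(correct & singlet) / n_assigned_singlet,
    singlet_recall = if (sum(singlet) == 0L) NA_real_
      else sum(correct & singlet) / sum(singlet),
    doublet_assigned_fraction = if (sum(!singlet) == 0L) NA_real_
      else mean(assigned[!singlet]),
    incidence_unique_fraction = incidence
  ), class = "fr_eval")
}

# recompute incidence multiplicity from the per-sample count columns of an
# exported assignments table, when present
incidence_from_assignment_table <- function(rec) {
  fixed <- c("cell_barcode", "best_sample", "fragment_ratio",
             "total_fragments", "status")
  extra <- setdiff(names(rec), fixed)
  extra <- extra[vapply(rec[extra], is.numeric, logical(1))]
  if (length(extra) < 2L) return(NA_real_)
  mean(rowSums(as.matrix(rec[extra]) > 0) == 1L)
}

#' @export
print.fr_eval <- function(x, ...) {
  cat("Assignment evaluation against simulation truth\n")
  cat(sprintf("  barcodes evaluated:        %d\n", x$n_evaluated))
  cat(sprintf("  assigned fraction:         %.4f\n", x$assigned_fraction))
  cat(sprintf("  singlet precision:         %s\n", fmt_or_na(x$singlet_precision)))
  cat(sprintf("  singlet recall:            %s\n", fmt_or_na(x$singlet_recall)))
  cat(sprintf("  doublet assigned fraction: %s\n",
              fmt_or_na(x$doublet_assigned_fraction)))
  cat(sprintf("  incidence unique fraction: %s\n",
              fmt_or_na(x$incidence_unique_fraction)))
  invisible(x)
}

fmt_or_na <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
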