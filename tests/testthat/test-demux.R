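# independent first-principles oracle: assignment recomputed by explicit
# loops over raw per-sample barcode lists
oracle_assign <- function(barcode_lists, threshold, min_fragments) {
  samples <- names(barcode_lists)
  bcs <- sort(unique(unlist(barcode_lists, use.names = FALSE)))
  do.call(rbind, lapply(bcs, function(b) {
    n <- vapply(samples, function(s) sum(barcode_lists[[s]] == b),
                numeric(1))
    tot <- sum(n)
    lex <- sort(samples)
    n_lex <- n[lex]
    best <- lex[which.max(n_lex)]       # which.max takes the first maximum
    r <- max(n) / tot
    status <- if (tot < min_fragments) "low_count"
      else if (r > threshold) "assigned" else "ambiguous"
    data.frame(cell_barcode = b, best_sample = best, fragment_ratio = r,
               total_fragments = tot, status = status,
               stringsAsFactors = FALSE)
  }))
}

test_that("count matrix counts records or read support, zero-fills and validates", {
  a <- make_frags(start = c(1, 2), end = c(10, 20), barcode = "ACGT")
  b <- make_frags(start = 1, end = 10, barcode = "ACGT")
  m <- count_matrix(list(A = a, B = b))
  expect_identical(m, matrix(c(2L, 1L), 1, 2,
                             dimnames = list("ACGT", c("A", "B"))))

  # barcode seen only in one sample keeps an explicit zero elsewhere
  a2 <- rbind(a, make_frags(start = 5, end = 9, barcode = "TTTT"))
  m2 <- count_matrix(list(A = a2, B = b))
  expect_equal(m2["TTTT", ], c(A = 1L, B = 0L))

  # read weighting sums the support column
  a3 <- make_frags(start = c(1, 2), end = c(10, 20), barcode = "ACGT",
                   support = c(3L, 2L))
  m3 <- count_matrix(list(A = a3, B = b), weighting = "reads")
  expect_equal(m3["ACGT", "A"], 5L)

  # GEM-group suffixes unify across samples by default, not with keep
  a4 <- make_frags(start = 1, end = 2, barcode = "ACGT-1")
  b4 <- make_frags(start = 1, end = 2, barcode = "ACGT-2")
  expect_equal(rownames(count_matrix(list(A = a4, B = b4))), "ACGT")
  expect_equal(nrow(count_matrix(list(A = a4, B = b4),
                                 strip_suffix = FALSE)), 2L)

  expect_error(count_matrix(list(A = a)), "at least two samples")
  expect_error(count_matrix(stats::setNames(list(a, b), c("A", "A"))),
               "duplicate")
})

test_that("fragment ratio evaluates r = N_best / total with lexicographic ties", {
  m <- matrix(c(70L, 30L), 1, 2, dimnames = list("ACGT", c("A", "B")))
  rec <- fragment_ratio(m)
  expect_equal(rec$best_sample, "A")
  expect_equal(rec$fragment_ratio, 0.7)
  expect_equal(rec$total_fragments, 70L + 30L)

  # exact tie: lexicographically smallest sample id, r = 0.5
  mt <- matrix(c(50L, 50L), 1, 2, dimnames = list("ACGT", c("B", "A")))
  rt <- fragment_ratio(mt)
  expect_equal(rt$best_sample, "A")
  expect_equal(rt$fragment_ratio, 0.5)
  # a tie can never be assigned at any threshold above 0.5
  expect_equal(assign_samples(rt, threshold = 0.6,
                              min_fragments = 0)$status, "ambiguous")

  # single-sample barcode has r = 1 regardless of the other columns
  m1 <- matrix(c(1L, 0L, 0L), 1, 3,
               dimnames = list("ACGT", c("A", "B", "C")))
  expect_equal(fragment_ratio(m1)$fragment_ratio, 1)
})

test_that("assignment applies the strict > threshold and the count floor", {
  rec <- data.frame(cell_barcode = c("a", "b", "c"),
                    best_sample = "A",
                    fragment_ratio = c(0.61, 0.6, 0.95),
                    total_fragments = c(1000L, 1000L, 10L),
                    status = NA_character_)
  got <- assign_samples(rec, threshold = 0.6, min_fragments = 100)
  expect_equal(got$status, c("assigned", "ambiguous", "low_count"))
  expect_error(assign_samples(rec, threshold = 1.5), "threshold")
})

test_that("incidence model reports sample multiplicity and unique fraction", {
  m <- matrix(c(5L, 5L, 2L,
                0L, 1L, 0L,
                0L, 2L, 0L), 3, 3,
              dimnames = list(c("b1", "b2", "b3"), c("A", "B", "C")))
  inc <- incidence_model(m)
  expect_equal(unname(inc$multiplicity), c(1L, 3L, 1L))
  expect_equal(inc$unique_fraction, 2 / 3)
})

test_that("fragment_ratio/assign agree with the first-principles oracle on random small inputs", {
  set.seed(7)
  for (case in 1:25) {
    n_s <- sample(2:4, 1)
    n_b <- sample(1:5, 1)
    samples <- sample(LETTERS, n_s)
    bcs <- rand_bc(n_b)
    mat <- matrix(sample(0:10, n_s * n_b, replace = TRUE), n_b, n_s,
                  dimnames = list(bcs, samples))
    mat <- mat[rowSums(mat) > 0, , drop = FALSE]
    if (nrow(mat) == 0) next
    threshold <- sample(c(0.5, 0.6, 0.8), 1)
    minf <- sample(c(0, 5, 15), 1)
    barcode_lists <- lapply(samples, function(s)
      rep(rownames(mat), mat[, s]))
    names(barcode_lists) <- samples
    want <- oracle_assign(barcode_lists, threshold, minf)

    fit <- fr_demux(counts_to_fragments(mat), threshold = threshold,
                    min_fragments = minf)
    got <- fit$assignments[order(fit$assignments$cell_barcode), ]
    rownames(got) <- NULL
    expect_equal(got, want[order(want$cell_barcode), ],
                 ignore_attr = TRUE)
    # per-sample ratio vectors are a normalised distribution per barcode
    ratios <- fit$counts / rowSums(fit$counts)
    expect_true(all(abs(rowSums(ratios) - 1) < 1e-12))
  }
})

test_that("raising the threshold never increases the number assigned", {
  set.seed(11)
  mat <- matrix(sample(0:20, 40 * 4, replace = TRUE), 40, 4,
                dimnames = list(rand_bc(40), c("A", "B", "C", "D")))
  mat <- mat[rowSums(mat) > 0, ]
  rec <- fragment_ratio(mat)
  counts <- vapply(seq(0.1, 1, by = 0.05), function(th)
    sum(assign_samples(rec, threshold = th,
                       min_fragments = 0)$status == "assigned"),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("assigned barcodes are a superset of incidence-unique barcodes", {
  set.seed(13)
  mat <- matrix(rpois(60 * 3, 1.2), 60, 3,
                dimnames = list(rand_bc(60), c("A", "B", "C")))
  mat <- mat[rowSums(mat) > 0, ]
  mode(mat) <- "integer"
  rec <- assign_samples(fragment_ratio(mat), threshold = 1 - 1e-9,
                        min_fragments = 0)
  inc <- incidence_model(mat)
  unique_bc <- names(inc$multiplicity)[inc$multiplicity == 1L]
  assigned_bc <- rec$cell_barcode[rec$status == "assigned"]
  # every multiplicity-1 barcode has r = 1 and is assigned
  expect_true(all(unique_bc %in% assigned_bc))
  expect_true(all(rec$fragment_ratio[match(unique_bc,
                                           rec$cell_barcode)] == 1))
})

test_that("split_fragments routes assigned cells and conserves every fragment", {
  # one barcode 70/30 split, one 50/50 tie, one only in B
  a <- rbind(make_frags(start = 1:7, end = 11:17, barcode = "AAAA"),
             make_frags(start = 1:5, end = 21:25, barcode = "CCCC"))
  b <- rbind(make_frags(start = 1:3, end = 31:33, barcode = "AAAA"),
             make_frags(start = 1:5, end = 41:45, barcode = "CCCC"),
             make_frags(start = 1:4, end = 51:54, barcode = "GGGG"))
  fit <- fr_demux(list(A = a, B = b), min_fragments = 0)
  parts <- split_fragments(list(A = a, B = b), fit)
  # AAAA assigned to A: its 7 A-fragments kept, its 3 hopped B-fragments discarded
  expect_equal(nrow(parts$samples$A), 7L)
  expect_true(all(parts$samples$A$barcode == "AAAA"))
  # GGGG r = 1 in B
  expect_equal(sum(parts$samples$B$barcode == "GGGG"), 4L)
  # ambiguous CCCC fully discarded
  expect_equal(sum(parts$discard$barcode == "CCCC"), 10L)
  # conservation: in = out + discard
  n_in <- nrow(a) + nrow(b)
  n_out <- sum(vapply(parts$samples, nrow, integer(1))) + nrow(parts$discard)
  expect_equal(n_out, n_in)

  # merge_hopped moves an assigned barcode's foreign fragments instead
  merged <- split_fragments(list(A = a, B = b), fit, merge_hopped = TRUE)
  expect_equal(sum(merged$samples$A$barcode == "AAAA"), 10L)
  expect_equal(sum(vapply(merged$samples, nrow, integer(1))) +
                 nrow(merged$discard), n_in)

  # unknown barcode in the fragment input is a consistency error
  bad <- rbind(a, make_frags(start = 1, end = 2, barcode = "TTTT"))
  expect_error(split_fragments(list(A = bad, B = b), fit),
               "absent from the assignment")
})

test_that("the demux report summarises status fractions and per-sample counts", {
  set.seed(3)
  bcs <- rand_bc(10)
  # 9 clean single-sample barcodes, 1 perfect tie
  a <- make_frags(start = 1:9, end = 11:19, barcode = rep(bcs[1:5],
                                                          length.out = 9))
  b <- make_frags(start = 1:9, end = 11:19, barcode = rep(bcs[6:9],
                                                          length.out = 9))
  tie <- make_frags(start = 1, end = 2, barcode = bcs[10])
  fit <- fr_demux(list(A = rbind(a, tie), B = rbind(b, tie)),
                  min_fragments = 0)
  s <- summary(fit)
  expect_equal(s$n_barcodes, 10L)
  expect_equal(unname(s$status_counts["assigned"]), 9L)
  expect_equal(unname(s$assigned_fraction), 0.9)
  expect_equal(sum(s$per_sample_assigned), 9L)
  expect_true(all(c("min", "median", "max") %in% colnames(s$fr_quartiles)))
  expect_output(print(s), "incidence-model unique fraction")

  # no-hopping limit: all single-sample, assigned = incidence unique = 1
  fit2 <- fr_demux(list(A = a, B = b), min_fragments = 0)
  s2 <- summary(fit2)
  expect_equal(unname(s2$assigned_fraction), 1)
  expect_equal(s2$incidence_unique_fraction, 1)

  tab <- as.data.frame(fit)
  expect_true(all(c("A", "B") %in% names(tab)))
  expect_equal(nrow(tab), 10L)
})

test_that("FR thresholding recovers more barcodes than the incidence baseline under hopping", {
  sim <- simulate_fragments(small_sim(hop_rate = 0.2, seed = 1L))
  fit <- fr_demux(sim$fragments, min_fragments = 0)
  s <- summary(fit)
  expect_gt(s$assigned_fraction, s$incidence_unique_fraction)
})

test_that("fit methods print and plot without error", {
  sim <- simulate_fragments(small_sim(seed = 5L))
  fit <- fr_demux(sim$fragments, min_fragments = 0)
  expect_output(print(fit), "Fragment-ratio demultiplexing fit")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})
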