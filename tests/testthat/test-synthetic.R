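test_that("reference generation validates arguments and is fully reproducible from the seed", {
  expect_error(make_reference(0, 5, seed = 1), "n_precursors")
  expect_error(make_reference(2, -1, seed = 1), "n_decoys")
  t1 <- make_reference(3, 6, seed = 77)
  t2 <- make_reference(3, 6, seed = 77)
  expect_identical(t1, t2)
  expect_identical(nrow(t1$precursors), 3L)
  # minimal case: one precursor, no decoys
  t3 <- make_reference(1, 0, seed = 7)
  expect_identical(nrow(t3$precursors), 1L)
  expect_true(all(lengths(t3$decoys) == 0))
  # the caller's RNG stream is untouched
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(make_reference(1, 0, seed = 9)); b <- runif(1)
  expect_identical(a, b)
})

test_that("every planted precursor passes the discovery criteria on its excised window", {
  truth <- small_truth()
  g <- truth$genome[[1]]
  for (i in seq_len(nrow(truth$precursors))) {
    p <- truth$precursors[i, ]
    w <- extract_window(g, p$mature_start - 1L, p$mature_end,
                        strand = p$strand, window = 250)
    ev <- evaluate_precursor(w$sequence, w$mature_start, w$mature_end)
    expect_true(ev$pass)
  }
  # each planted mature is within two mismatches of exactly one reference
  refs <- mature_reference()
  for (m in truth$mature_set$sequence) {
    mm <- vapply(refs, function(r) mirseed:::.slide_mismatches(m, r, 2), 0)
    expect_identical(sum(mm <= 2), 1L)
  }
})

test_that("library simulation validates inputs and reads carry insert plus adapter", {
  truth <- small_truth()
  expect_error(simulate_library(truth, "HT", "flooded", seed = 1),
               "condition")
  expect_error(simulate_library(truth, "XX", "drought", seed = 1),
               "genotype")
  expect_error(simulate_library(truth, "HT", "drought", depth = 0,
                                seed = 1), "depth")
  expect_error(simulate_library(truth, "HT", "drought", depth = 10,
                                adapter = "ACGT", seed = 1), "adapter")
  lib <- simulate_library(truth, "HT", "drought", depth = 5000, seed = 2)
  expect_true(all(nchar(lib$reads) == 36))
  lib2 <- simulate_library(truth, "HT", "drought", depth = 5000, seed = 2)
  expect_identical(lib$reads, lib2$reads)
  # FASTQ round trip
  path <- withr::local_tempfile(fileext = ".fastq")
  lib3 <- simulate_library(truth, "LT", "irrigated", depth = 1000,
                           seed = 3, fastq = path)
  expect_identical(unname(read_fastq(path)), unname(lib3$reads))
})

test_that("simulated counts follow depth x baseline x fold change", {
  truth <- small_truth()
  depth <- 1e5
  # average over seeded replicates approaches the planted expectation
  reps <- lapply(1:40, function(r)
    simulate_counts(truth, "LT", "drought", depth, seed = 100 + r))
  avg <- Reduce(`+`, reps) / length(reps)
  expected <- depth * mirseed:::.expected_tpm(truth, "LT", "drought") / 1e6
  expect_equal(unname(avg), unname(expected), tolerance = 0.1)
  # irrigated libraries ignore the planted fold changes
  base <- depth * setNames(truth$baseline$tpm, truth$baseline$name) / 1e6
  reps0 <- lapply(1:40, function(r)
    simulate_counts(truth, "LT", "irrigated", depth, seed = 500 + r))
  avg0 <- Reduce(`+`, reps0) / length(reps0)
  expect_equal(unname(avg0), unname(base), tolerance = 0.1)
  # negative-binomial option inflates the variance
  nb <- vapply(1:200, function(r)
    simulate_counts(truth, "HT", "irrigated", depth, seed = 900 + r,
                    dispersion = 0.5)[[1]], 0L)
  po <- vapply(1:200, function(r)
    simulate_counts(truth, "HT", "irrigated", depth, seed = 2000 + r)[[1]],
    0L)
  expect_gt(var(as.numeric(nb)), 2 * var(as.numeric(po)))
})

test_that("transcriptome generation enforces capacity and span bookkeeping", {
  truth <- small_truth()
  expect_error(make_transcriptome_with_targets(truth, 2, seed = 1),
               "n_transcripts")
  tt <- make_transcriptome_with_targets(truth, 10, seed = 5)
  expect_identical(nrow(tt$sites), nrow(truth$mature_set))
  for (i in seq_len(nrow(tt$sites))) {
    s <- tt$sites[i, ]
    frag <- substr(tt$transcripts[[s$transcript]], s$start, s$end)
    mseq <- truth$mature_set$sequence[truth$mature_set$name == s$mirna]
    expect_equal(expectation_score(mseq, frag), s$expected_e)
  }
})
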