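test_that("expectation scoring reproduces the published worked alignments", {
  # single non-seed mismatch at miRNA position 17 -> 1.0, cleavage
  expect_equal(expectation_score("UGGAGAAGCAGGGCACGUGC",
                                 "GCAGGUGCCCUGCUUCUCCA"), 1)
  expect_identical(inhibition_type("UGGAGAAGCAGGGCACGUGC",
                                   "GCAGGUGCCCUGCUUCUCCA"), "Cleavage")
  # single mismatch at miRNA position 1 -> 1.0
  expect_equal(expectation_score("CUCCAAAGGGAUCGCAUUG",
                                 "CAAUGCGAUCCCUUUGGAU"), 1)
  # perfect complement -> 0
  m <- "UGGAGAAGCAGGGCACGUGC"
  expect_equal(expectation_score(m, as_rna(revcomp(m))), 0)
  expect_error(expectation_score("ACGU", "ACGUA"), "length")
})

test_that("penalties are doubled in the seed region and wobble costs half a mismatch", {
  m <- "GGGAGAAGCAGGGCACGUGC"
  site <- as_rna(revcomp(m))
  sv <- strsplit(site, "")[[1]]
  L <- length(sv)
  flip <- function(pos, base) {
    v <- sv; v[L - pos + 1] <- base; paste(v, collapse = "")
  }
  # non-seed mismatch (position 16): 1.0; seed mismatch (position 5): 2.0
  expect_equal(expectation_score(m, flip(16, "C")), 1)
  expect_equal(expectation_score(m, flip(5, "G")), 2)
  # wobble: G:U at a non-seed G (position 1) costs 0.5; in-seed 1.0
  expect_equal(expectation_score(m, flip(1, "U")), 0.5)
  m2 <- "AGGAGAAGCAGGGCACGUGC"
  site2 <- as_rna(revcomp(m2))
  sv2 <- strsplit(site2, "")[[1]]
  sv2[L - 3 + 1] <- "U" # miRNA position 3 is G -> G:U in seed
  expect_equal(expectation_score(m2, paste(sv2, collapse = "")), 1)
})

test_that("E is monotone under WC -> wobble -> mismatch degradation", {
  set.seed(51)
  for (i in 1:20) {
    m <- random_dna(21)
    site <- revcomp(m)
    e0 <- expectation_score(m, site)
    expect_equal(e0, 0)
    sv <- strsplit(site, "")[[1]]
    p <- sample(21, 1)
    mb <- substr(m, p, p)
    tpos <- 21 - p + 1
    if (mb %in% c("G", "T")) {
      svw <- sv; svw[tpos] <- if (mb == "G") "T" else "G"
      ew <- expectation_score(m, paste(svw, collapse = ""))
      expect_gt(ew, e0)
      svm <- sv
      svm[tpos] <- setdiff(c("A", "C", "G", "T"),
                           c(sv[tpos], svw[tpos], mb))[1]
      em <- expectation_score(m, paste(svm, collapse = ""))
      expect_gte(em, ew)
    }
  }
})

test_that("the central-pairing rule separates cleavage from translational inhibition", {
  m <- "UGGAGAAGCAGGGCACGUGC"
  site <- as_rna(revcomp(m))
  sv <- strsplit(site, "")[[1]]
  L <- length(sv)
  expect_identical(inhibition_type(m, site), "Cleavage")
  # engineered central mismatch at miRNA position 10 -> translation
  sv10 <- sv; sv10[L - 10 + 1] <- "A"
  expect_identical(inhibition_type(m, paste(sv10, collapse = "")),
                   "Translation")
  # defect at position 8 leaves positions 9-11 intact -> cleavage
  sv8 <- sv; sv8[L - 8 + 1] <- "C"
  expect_identical(inhibition_type(m, paste(sv8, collapse = "")),
                   "Cleavage")
})

test_that("scanning equals per-window scoring and recovers planted sites at their spans", {
  set.seed(52)
  m <- random_dna(21)
  tx <- c(tx1 = random_dna(3000))
  hits <- scan_targets(m, tx, e_max = 1e9, mirna_name = "m")
  expect_identical(nrow(hits), nchar(tx[[1]]) - 21L + 1L)
  # oracle: score every window with the scalar R implementation
  idx <- sample(nrow(hits), 60)
  for (i in idx) {
    frag <- substr(tx, hits$start[i], hits$end[i])
    expect_equal(hits$expectation[i], expectation_score(m, frag))
  }
  # planted transcriptome: every site recovered at its span and layout
  truth <- small_truth()
  tt <- make_transcriptome_with_targets(truth, nrow(truth$mature_set) + 2,
                                        seed = 53)
  for (i in seq_len(nrow(tt$sites))) {
    s <- tt$sites[i, ]
    mseq <- truth$mature_set$sequence[truth$mature_set$name == s$mirna]
    got <- scan_targets(mseq, tt$transcripts, e_max = 3)
    row <- got[got$transcript == s$transcript & got$start == s$start, ]
    expect_identical(nrow(row), 1L)
    expect_equal(row$expectation, s$expected_e)
  }
  # determinism of the generator
  tt2 <- make_transcriptome_with_targets(truth, nrow(truth$mature_set) + 2,
                                         seed = 53)
  expect_identical(tt, tt2)
})
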