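test_that("window excision centers the read, truncates at ends, and mirrors on the minus strand", {
  set.seed(21)
  ref <- random_dna(10000)
  # 21 nt read centered: mature sits at offsets 115..135 of the window
  w <- extract_window(ref, 5000, 5021, window = 250)
  expect_identical(nchar(w$sequence), 250L)
  expect_identical(w$mature_start, 115L)
  expect_identical(w$mature_end, 135L)
  expect_identical(substr(w$sequence, w$mature_start, w$mature_end),
                   substr(ref, 5001, 5021))
  # left truncation near the reference start
  w2 <- extract_window(ref, 50, 71, window = 250)
  expect_identical(w2$win_start, 0L)
  expect_identical(substr(w2$sequence, w2$mature_start, w2$mature_end),
                   substr(ref, 51, 71))
  # minus-strand excision equals the reverse complement of the plus window
  w3 <- extract_window(ref, 5000, 5021, strand = "-", window = 250)
  expect_identical(w3$sequence, revcomp(w$sequence))
  expect_identical(substr(w3$sequence, w3$mature_start, w3$mature_end),
                   revcomp(substr(ref, 5001, 5021)))
  expect_error(extract_window(ref, -5, 21), "outside")
  expect_error(extract_window(ref, 9990, 10021), "outside")
})

test_that("folding reproduces hand-checked structures and rejects bad input", {
  expect_identical(fold("AAAAAAAAAA")$mfe, 0)
  f <- fold("GGGGGAAAACCCCC")
  expect_identical(f$structure, "(((((....)))))")
  expect_identical(f$mfe, -15)
  # GU wobbles count -1 (all-wobble chain, checked against enumeration)
  expect_identical(fold("TTTTTAAAGGGGG")$mfe,
                   oracle_enum_mfe("TTTTTAAAGGGGG"))
  expect_error(fold("ACGTACGTN"), "at least 10")
  expect_error(fold("ACGTACGTNN"), "alphabet")
  # structure length always matches, brackets balanced
  set.seed(22)
  for (i in 1:20) {
    s <- random_dna(sample(10:60, 1))
    f <- fold(s)
    expect_identical(nchar(f$structure), nchar(s))
    expect_silent(mirseed:::pair_table(f$structure))
    expect_lte(f$mfe, 0)
  }
})

test_that("DP minimum equals exhaustive enumeration over all structures (short sequences)", {
  set.seed(23)
  for (i in 1:60) {
    s <- random_dna(sample(10:18, 1))
    expect_equal(fold(s)$mfe, oracle_enum_mfe(s), tolerance = 1e-12)
  }
})

test_that("appending unpairable bases never lowers the folding energy", {
  set.seed(24)
  for (i in 1:20) {
    # G-free sequence: appended C runs cannot pair with anything
    s <- paste(sample(c("A", "C", "T"), 15, replace = TRUE), collapse = "")
    expect_gte(fold(paste0(s, "CCCCC"))$mfe, fold(s)$mfe)
  }
})

test_that("gc_content is an exact percentage", {
  expect_identical(gc_content("GCGC"), 100)
  expect_identical(gc_content("AUAU"), 0)
  set.seed(25)
  s <- random_dna(137)
  v <- strsplit(s, "")[[1]]
  expect_equal(gc_content(s), 100 * sum(v %in% c("G", "C")) / 137)
  expect_error(gc_content(""), "empty")
})

test_that("star location counts unpaired mature positions and flags loop-crossing matures", {
  # hand-written perfect 21/21 duplex with an 8 nt terminal loop
  db <- paste0(strrep("(", 21), strrep(".", 8), strrep(")", 21))
  st <- locate_star(db, 1, 21)
  expect_identical(st$star_mismatches, 0L)
  expect_true(st$in_one_arm)
  expect_identical(st$arm, "5p")
  # the star span covers the pairing arm plus the 2 nt 3' overhang
  expect_identical(st$star_start, 30L)
  expect_identical(st$star_end, 50L)
  # 3p mature mirrors to a 5p star
  st3p <- locate_star(db, 30, 50)
  expect_identical(st3p$arm, "3p")
  expect_identical(st3p$star_start, 1L)
  # a mature spanning the terminal loop is not in one arm
  st2 <- locate_star(db, 15, 35)
  expect_false(st2$in_one_arm)
  # engineered bulges in the generator are recovered exactly
  truth <- small_truth()
  g <- truth$genome[[1]]
  for (i in seq_len(nrow(truth$precursors))) {
    p <- truth$precursors[i, ]
    w <- extract_window(g, p$mature_start - 1L, p$mature_end,
                        strand = p$strand)
    ev <- evaluate_precursor(w$sequence, w$mature_start, w$mature_end)
    expect_identical(ev$star_mismatches, p$defects)
  }
})

test_that("the verdict is the conjunction of the four switchable criteria", {
  mature <- "TGGAGAAGCAGGGCACGTGCA"
  hp <- paste0(mature, "GAGAGAGA", revcomp(mature))
  ev <- evaluate_precursor(hp, 1, nchar(mature))
  expect_true(ev$pass)
  expect_identical(ev$failed, character(0))
  # G/C bound violation is reported by name (tighten the bound so the
  # same structure trips only the gc criterion)
  ev2 <- evaluate_precursor(hp, 1, nchar(mature), gc_min = 30, gc_max = 40)
  expect_false(ev2$pass)
  expect_identical(ev2$failed, "gc")
  # star boundary: at most six unpaired mature positions pass, seven fail
  ev3 <- evaluate_precursor(hp, 1, nchar(mature), criteria = "star")
  expect_true(ev3$pass) # near-perfect duplex stays within the bound
  ev4 <- evaluate_precursor(hp, 1, nchar(mature), criteria = "star",
                            max_star_mismatch = -1)
  expect_false(ev4$pass)
  # random candidates: pass equals conjunction of individual criteria
  set.seed(26)
  for (i in 1:10) {
    s <- random_dna(80)
    full <- evaluate_precursor(s, 30, 50)
    singles <- vapply(c("hairpin", "star", "mfe", "gc"), function(cr)
      evaluate_precursor(s, 30, 50, criteria = cr)$pass, TRUE)
    expect_identical(full$pass, all(singles))
  }
})

test_that("discovery over mapped loci evaluates each locus once and keeps verdicts", {
  truth <- small_truth()
  idx <- build_index(truth$genome)
  hits <- map_reads(truth$mature_set$sequence, idx)
  cand <- discover_hairpins(hits, truth$genome)
  expect_identical(nrow(cand), nrow(truth$mature_set))
  expect_true(all(cand$pass))
  # a random unrelated locus normally fails
  set.seed(27)
  fake <- data.frame(query = "X", ref = "chr1", start = 500L, end = 521L,
                     strand = "+", mismatches = 0L,
                     stringsAsFactors = FALSE)
  cand2 <- discover_hairpins(fake, truth$genome)
  expect_identical(nrow(cand2), 1L)
})
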