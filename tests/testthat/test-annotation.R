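test_that("reads classify by precedence with sense/antisense handling and partition the library", {
  db <- tiny_db()
  cc <- collapse_reads(c(
    rep(substr(db$rRNA, 1, 20), 3),          # rRNA substring
    rep(db$miRNA, 2),                        # exact mature
    substr(db$exon, 3, 24),                  # sense exon
    revcomp(substr(db$exon, 5, 26)),         # antisense exon
    rep("TGCATGCATGCATGCATG", 4)))           # nothing
  cls <- classify_reads(cc, db)
  got <- setNames(cls$category, cls$sequence)
  expect_identical(unname(got[substr(db$rRNA, 1, 20)]), "rRNA")
  expect_identical(unname(got[db$miRNA]), "miRNA")
  expect_identical(unname(got[substr(db$exon, 3, 24)]), "sense_exon")
  expect_identical(unname(got[revcomp(substr(db$exon, 5, 26))]),
                   "antisense_exon")
  expect_identical(unname(got["TGCATGCATGCATGCATG"]), "unannotated")
  tab <- category_table(cls)
  tot <- tab$total_count[tab$category == "total"]
  expect_equal(tot, sum(cc$count))
  expect_equal(sum(tab$total_count[tab$category != "total"]), tot)
  expect_error(classify_reads(cc, db, precedence = c("rRNA", "rRNA")),
               "precedence")
})

test_that("a read matching several sets lands in the first precedence category only", {
  # sequence present in both the rRNA and the exon set
  shared <- "ACGTACGTACGTACGTAC"
  db <- annotation_db(list(rRNA = paste0(shared, "GGGG"),
                           exon = paste0("TTTT", shared)))
  cc <- collapse_reads(rep(shared, 2))
  expect_identical(classify_reads(cc, db)$category, "rRNA")
  expect_identical(
    classify_reads(cc, db,
                   precedence = c("sense_exon", "rRNA"))$category,
    "sense_exon")
})

test_that("synthetic libraries classify back to their planted categories", {
  truth <- small_truth()
  lib <- simulate_library(truth, "LT", "drought", depth = 20000, seed = 9)
  pp <- preprocess_library(lib$reads, adapter = "TGGAATTCTCGGGTGCCAAGG")
  cls <- classify_reads(pp$collapsed, truth$annotations)
  tab <- category_table(cls)
  # every planted mature that was sequenced is classified as miRNA
  mat <- truth$mature_set$sequence
  seen <- cls[cls$sequence %in% mat, ]
  expect_true(all(seen$category == "miRNA"))
  # miRNA total equals the simulated mature counts that survived filtering
  expect_identical(
    as.integer(tab$total_count[tab$category == "miRNA"]),
    as.integer(sum(seen$count)))
  # partition property
  expect_equal(sum(tab$total_count[tab$category != "total"]), pp$N)
})

test_that("size distributions weigh by count (redundant) or presence (nonredundant)", {
  cc <- data.frame(sequence = c(random_dna(21), random_dna(21),
                                random_dna(24)),
                   count = c(10L, 3L, 5L), length = c(21L, 21L, 24L),
                   stringsAsFactors = FALSE)
  red <- size_distribution(cc, "redundant")
  nred <- size_distribution(cc, "nonredundant")
  expect_equal(red[["21"]], 13)
  expect_equal(red[["24"]], 5)
  expect_equal(nred[["21"]], 2)
  expect_equal(sum(red), sum(cc$count))
  expect_length(size_distribution(collapse_reads(character(0))), 0)
  # synthetic libraries have the planted 21 nt mode
  lib <- simulate_library(small_truth(), "HT", "irrigated", depth = 30000,
                          seed = 4)
  pp <- preprocess_library(lib$reads, adapter = "TGGAATTCTCGGGTGCCAAGG")
  h <- size_distribution(pp$collapsed, "redundant")
  expect_identical(names(which.max(h)), "21")
})

test_that("first-nucleotide composition is count-weighted and recovers the planted U/A bias", {
  cc <- data.frame(sequence = c(paste0("T", random_dna(20)),
                                paste0("A", random_dna(20))),
                   count = c(3L, 1L), length = c(21L, 21L),
                   stringsAsFactors = FALSE)
  fr <- first_nt_composition(cc, 21)
  expect_equal(unname(fr["U"]), 0.75)
  expect_equal(unname(fr["A"]), 0.25)
  expect_equal(sum(fr), 1)
  expect_length(first_nt_composition(cc, 25), 0)
  # background generator plants ~40% U + ~40% A at position one of 21-mers
  set.seed(0)
  lib <- simulate_library(small_truth(), "HT", "irrigated", depth = 60000,
                          seed = 12, background_frac = 1, decoy_fracs = c())
  pp <- preprocess_library(lib$reads, adapter = "TGGAATTCTCGGGTGCCAAGG")
  bg <- pp$collapsed[!pp$collapsed$sequence %in%
                       small_truth()$mature_set$sequence, ]
  fr <- first_nt_composition(bg, 21)
  expect_gt(fr[["U"]] + fr[["A"]], 0.7)
  expect_lt(fr[["U"]] + fr[["A"]], 0.9)
})
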