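# Shared fixtures, built once per test run. Generation is seeded, so
# every run sees identical truth.

.fixture_env <- new.env(parent = emptyenv())

small_truth <- function() {
  if (is.null(.fixture_env$truth))
    .fixture_env$truth <- mirseed::make_reference(6, 12, seed = 101)
  .fixture_env$truth
}

# Simulate a 2-genotype x 2-condition set of libraries and wrap them
# into a pipeline manifest with in-memory reads.
make_manifest <- function(truth, depth, seed0, day = 2) {
  spec <- expand.grid(genotype = c("HT", "LT"),
                      condition = c("irrigated", "drought"),
                      stringsAsFactors = FALSE)
  reads <- vector("list", nrow(spec))
  ids <- character(nrow(spec))
  for (i in seq_len(nrow(spec))) {
    lib <- mirseed::simulate_library(truth, spec$genotype[i],
                                     spec$condition[i], day = day,
                                     depth = depth, seed = seed0 + i)
    reads[[i]] <- unname(lib$reads)
    ids[i] <- paste0(spec$genotype[i],
                     toupper(substr(spec$condition[i], 1, 1)), day)
  }
  m <- data.frame(library_id = ids, genotype = spec$genotype,
                  condition = spec$condition, day = day,
                  stringsAsFactors = FALSE)
  m$reads <- I(reads)
  m
}

# A tiny annotation database with known content for classification
# tests (sequences long enough to contain 18-27 nt reads).
tiny_db <- function() {
  mirseed::annotation_db(list(
    rRNA = "ACGTACGTACGTACGTACGTACGTACGTACGT",
    tRNA = "TTTTCCCCAAAAGGGGTTTTCCCCAAAAGGGG",
    miRNA = "TGGAGAAGCAGGGCACGTGCA",
    # deliberately not reverse-complement-palindromic, so the sense and
    # antisense exon categories stay distinguishable
    exon = "AACCAAGGAACCAAGGAACCAAGGAACCAAGG"))
}
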