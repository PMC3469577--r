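#' Expectation penalty of a miRNA/target alignment
#'
#' Scores an ungapped antiparallel duplex between a miRNA (5'->3') and a
#' target site fragment (5'->3' as read on the transcript): miRNA
#' position i faces target position (length - i + 1). Penalties per
#' position: Watson-Crick 0, G:U wobble `wobble`, mismatch `mm`; the
#' penalty is multiplied by `seed_mult` at miRNA positions
#' `seed_span[1]..seed_span[2]` counted from the miRNA 5' end. A perfect
#' complement scores 0.
#'
#' @param mirna miRNA sequence, 5'->3' (RNA or DNA).
#' @param target_site Target fragment of the same length, 5'->3'.
#' @param mm,wobble,seed_mult Penalty weights.
#' @param seed_span Two integers, the seed region on the miRNA.
#' @return Expectation score E >= 0.
#' @examples
#' expectation_score("UGGAGAAGCAGGGCACGUGC", "GCAGGUGCCCUGCUUCUCCA") # 1.0
#' @export
expectation_score <- function(mirna, target_site, mm = 1, wobble = 0.5,
                              seed_mult = 2, seed_span = c(2, 13)) {
  cls <- .pair_classes(mirna, target_site)
  pen <- ifelse(cls == "WC", 0, ifelse(cls == "wobble", wobble, mm))
  i <- seq_along(pen)
  seed <- i >= seed_span[1] & i <= seed_span[2]
  sum(ifelse(seed, seed_mult * pen, pen))
}

# Per-position pairing classes of the antiparallel duplex, indexed by
# miRNA position from the 5' end.
.pair_classes <- function(mirna, target_site) {
  m <- as_dna(mirna)
  t <- as_dna(target_site)
  if (nchar(m) != nchar(t))
    stop("length mismatch: ungapped scoring needs equal-length fragments")
  mc <- strsplit(m, "", fixed = TRUE)[[1]]
  tc <- rev(strsplit(t, "", fixed = TRUE)[[1]])
  wc <- (mc == "A" & tc == "T") | (mc == "T" & tc == "A") |
    (mc == "G" & tc == "C") | (mc == "C" & tc == "G")
  wob <- (mc == "G" & tc == "T") | (mc == "T" & tc == "G")
  ifelse(wc, "WC", ifelse(wob, "wobble", "mismatch"))
}

#' Cleavage vs translational-inhibition call for a target alignment
#'
#' The central-site rule: a duplex with any non-Watson-Crick position
#' facing miRNA positions 9-11 is called translational inhibition
#' (cleavage requires intact central pairing); otherwise cleavage.
#'
#' @param mirna,target_site Aligned fragments as in
#'   [expectation_score()].
#' @param central_span Central miRNA positions checked, default 9-11.
#' @return `"Cleavage"` or `"Translation"`.
#' @export
inhibition_type <- function(mirna, target_site, central_span = c(9, 11)) {
  cls <- .pair_classes(mirna, target_site)
  i <- seq_along(cls)
  central <- i >= central_span[1] & i <= min(central_span[2], length(cls))
  if (any(cls[central] != "WC")) "Translation" else "Cleavage"
}

#' Scan transcripts for miRNA target sites
#'
#' Scores every window of every transcript with the expectation penalty
#' scheme and reports sites with `E <= e_max`. The transcript sense
#' strand is taken as authoritative: supply coding-strand sequences.
#'
#' @param mirna Single miRNA sequence, 5'->3'.
#' @param transcripts Named character vector of transcript sequences
#'   (sense strand), or a FASTA path.
#' @param e_max Maximum expectation score reported.
#' @param mirna_name Optional label carried into the output.
#' @param mm,wobble,seed_mult,seed_span Penalty parameters, as in
#'   [expectation_score()].
#' @return Data frame: `mirna`, `transcript`, `start`, `end` (1-based
#'   inclusive on the transcript), `expectation`, `mirna_fragment` and
#'   `target_fragment` (both 5'->3', RNA alphabet), `inhibition`.
#' @export
scan_targets <- function(mirna, transcripts, e_max = 3.0,
                         mirna_name = "miRNA", mm = 1, wobble = 0.5,
                         seed_mult = 2, seed_span = c(2, 13)) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      is.null(names(transcripts)) && file.exists(transcripts))
    transcripts <- read_fasta(transcripts)
  m <- as_dna(mirna)
  L <- nchar(m)
  rows <- lapply(seq_along(transcripts), function(ti) {
    tx <- as_dna(transcripts[[ti]])
    if (nchar(tx) < L) return(NULL)
    sc <- expectation_scan_cpp(m, tx, mm, wobble,
                               as.integer(seed_span[1]),
                               as.integer(seed_span[2]), seed_mult)
    hit <- which(sc <= e_max)
    if (length(hit) == 0L) return(NULL)
    frag <- substr(rep(tx, length(hit)), hit, hit + L - 1L)
    data.frame(mirna = mirna_name,
               transcript = names(transcripts)[ti],
               start = hit, end = hit + L - 1L,
               expectation = sc[hit],
               mirna_fragment = as_rna(m),
               target_fragment = as_rna(frag),
               inhibition = vapply(frag, function(f)
                 inhibition_type(m, f), ""),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(mirna = character(0), transcript = character(0),
                      start = integer(0), end = integer(0),
                      expectation = numeric(0),
                      mirna_fragment = character(0),
                      target_fragment = character(0),
                      inhibition = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
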