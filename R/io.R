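#' Read and write small-RNA sequence files
#'
#' Thin wrappers around Biostrings readers/writers that return plain
#' uppercase character vectors in the DNA alphabet, the internal storage
#' convention of the package.
#'
#' @param path File path.
#' @return `read_fastq()` and `read_fasta()` return a named character
#'   vector of sequences (DNA alphabet, uppercase).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fastq
#' @export
read_fasta <- function(path) {
  # read as raw strings so RNA (U) input survives, then store as DNA
  x <- Biostrings::readBStringSet(path, format = "fasta")
  setNames(as_dna(as.character(x)), names(x))
}

#' @rdname read_fastq
#' @param seqs Named character vector of sequences (DNA or RNA; stored
#'   as DNA on disk).
#' @param qual_char Single Phred+33 character used as the constant
#'   quality for every base written to FASTQ.
#' @export
write_fastq <- function(seqs, path, qual_char = "I") {
  seqs <- as_dna(seqs)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    names(seqs) <- paste0("read_", seq_along(seqs))
  x <- Biostrings::DNAStringSet(seqs)
  q <- Biostrings::BStringSet(strrep(qual_char, nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname read_fastq
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_dna(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Trim a 3' sequencing adapter from reads
#'
#' Removes, from each read, the longest suffix that is an exact prefix of
#' the adapter (requiring at least `min_overlap` matching bases), or
#' everything from the first full internal occurrence of the adapter
#' onwards. Reads with no adapter hit are kept whole; a read whose
#' adapter starts at position 1 trims to the empty string and is then
#' dropped by the length filter.
#'
#' @param reads Character vector of reads (DNA alphabet).
#' @param adapter Adapter sequence, 5' end first (DNA alphabet).
#' @param min_overlap Minimum read-suffix/adapter-prefix overlap, >= 6.
#' @return Character vector of trimmed reads, same length as `reads`.
#' @examples
#' trim_adapter("ACGTACGTTGGAATTC", "TGGAATTCTCGG")
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 6) {
  if (missing(adapter) || length(adapter) != 1L || is.na(adapter) ||
      nchar(adapter) == 0L)
    stop("'adapter' must be a single non-empty sequence")
  check_flag(min_overlap >= 6, "'min_overlap' must be >= 6")
  reads <- as_dna(reads)
  adapter <- as_dna(adapter)
  out <- reads
  # full internal occurrence (also covers a complete adapter at the end)
  hit <- regexpr(adapter, out, fixed = TRUE)
  full <- which(hit > 0L)
  out[full] <- substr(out[full], 1L, hit[full] - 1L)
  # partial adapter running off the 3' end: longest overlap wins
  todo <- setdiff(seq_along(out), full)
  n <- nchar(out)
  ov_max <- min(nchar(adapter) - 1L,
                if (length(todo)) max(n[todo]) else 0L)
  for (ov in (if (ov_max >= min_overlap) ov_max:min_overlap else integer(0))) {
    if (length(todo) == 0L) break
    cand <- todo[n[todo] >= ov]
    if (length(cand) == 0L) next
    m <- substr(out[cand], n[cand] - ov + 1L, n[cand]) ==
      substr(adapter, 1L, ov)
    trim <- cand[m]
    out[trim] <- substr(out[trim], 1L, n[trim] - ov)
    todo <- setdiff(todo, trim)
  }
  out
}

#' Length-filter small RNA reads
#'
#' Retains reads with `min_len <= length <= max_len`. The defaults keep
#' 18-27 nt inserts: shorter reads are discarded as adapter artefacts and
#' the upper bound matches the gel size selection of typical small-RNA
#' protocols.
#'
#' @param x Character vector of reads, or a collapsed-read data frame
#'   with a `length` column (see [collapse_reads()]).
#' @param min_len,max_len Inclusive length bounds in nt.
#' @return Filtered object of the same type; counts are unchanged.
#' @export
filter_length <- function(x, min_len = 18, max_len = 27) {
  check_flag(min_len <= max_len, "'min_len' must be <= 'max_len'")
  if (is.data.frame(x)) return(x[x$length >= min_len & x$length <= max_len, ,
                                 drop = FALSE])
  x[nchar(x) >= min_len & nchar(x) <= max_len]
}

# Reads containing N are removed before collapsing: an ambiguous base
# breaks the exact-match and mismatch accounting of every later stage.
discard_ambiguous <- function(reads) reads[!grepl("N", reads, fixed = TRUE)]

#' Collapse reads to unique sequences with counts
#'
#' @param reads Character vector of (already length-filtered) reads.
#' @return A data frame with columns `sequence` (DNA), `count` and
#'   `length`, ordered by decreasing count then sequence. The counts sum
#'   to `length(reads)`.
#' @examples
#' collapse_reads(c("ACGTACGTACGTACGTAC", "ACGTACGTACGTACGTAC",
#'                  "TTTTACGTACGTACGTAC"))
#' @export
collapse_reads <- function(reads) {
  if (length(reads) == 0L)
    return(data.frame(sequence = character(0), count = integer(0),
                      length = integer(0), stringsAsFactors = FALSE))
  reads <- as_dna(reads)
  r <- rle(sort(reads, method = "radix"))
  out <- data.frame(sequence = r$values, count = r$lengths,
                    length = nchar(r$values), stringsAsFactors = FALSE)
  out <- out[order_radix(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read/write collapsed reads as FASTA with count-bearing headers
#'
#' The header dialect is `>seq<rank>_x<count>` so that collapsed files
#' interoperate with miRDeep-style tools; the round trip is lossless.
#'
#' @param collapsed Collapsed-read data frame from [collapse_reads()].
#' @param path File path.
#' @return `read_collapsed_fasta()` returns a collapsed-read data frame.
#' @export
write_collapsed_fasta <- function(collapsed, path) {
  ids <- sprintf("seq%d_x%d", seq_len(nrow(collapsed)), collapsed$count)
  write_fasta(setNames(collapsed$sequence, ids), path)
}

#' @rdname write_collapsed_fasta
#' @export
read_collapsed_fasta <- function(path) {
  x <- read_fasta(path)
  cnt <- suppressWarnings(as.integer(sub("^.*_x(\\d+)\\s*$", "\\1", names(x))))
  if (anyNA(cnt))
    stop("malformed collapsed FASTA header: expected '>seq<rank>_x<count>'")
  out <- data.frame(sequence = unname(x), count = cnt, length = nchar(x),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Preprocess one small-RNA library
#'
#' Runs the full read preprocessing of a library: adapter trimming,
#' removal of ambiguous (N-containing) reads, length filtering and
#' collapsing. The retained total `N` is the library size used both as
#' the TPM denominator and as the library size of the Audic-Claverie
#' test.
#'
#' @param reads Character vector of raw reads, or a FASTQ path.
#' @param adapter 3' adapter sequence.
#' @param min_overlap Minimum adapter overlap for trimming.
#' @param min_len,max_len Length bounds applied after trimming.
#' @return A list with `collapsed` (data frame), `N` (total retained
#'   reads), `n_raw`, and `n_dropped_length`.
#' @export
preprocess_library <- function(reads, adapter, min_overlap = 6,
                               min_len = 18, max_len = 27) {
  if (length(reads) == 1L && !is.na(reads) && file.exists(reads))
    reads <- read_fastq(reads)
  n_raw <- length(reads)
  trimmed <- trim_adapter(reads, adapter, min_overlap)
  trimmed <- discard_ambiguous(trimmed)
  kept <- filter_length(trimmed, min_len, max_len)
  collapsed <- collapse_reads(kept)
  stopifnot(sum(collapsed$count) == length(kept))
  list(collapsed = collapsed, N = length(kept), n_raw = n_raw,
       n_dropped_length = length(trimmed) - length(kept))
}
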