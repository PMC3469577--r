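#' Convert between the RNA and DNA alphabets
#'
#' Sequences are stored internally in the DNA alphabet and reported in the
#' RNA alphabet, matching the convention of mature miRNA catalogues.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector with `U` mapped to `T` (`as_dna`) or `T`
#'   mapped to `U` (`as_rna`); input is uppercased.
#' @examples
#' as_dna("ucagGAAAG")
#' as_rna("TCAGGAAAG")
#' @export
as_dna <- function(x) chartr("U", "T", toupper(x))

#' @rdname as_dna
#' @export
as_rna <- function(x) chartr("T", "U", toupper(x))

#' Reverse complement of DNA/RNA sequences
#'
#' @param x Character vector of sequences (RNA input is converted to DNA
#'   first; output is DNA).
#' @return Character vector of reverse complements, DNA alphabet.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(as_dna(x))))
}

# Half-up rounding, used for all report-time rounding so that printed
# tables are reproducible independently of the IEC 60559 banker's rule.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Fixed-format two-decimal string used in written reports.
fmt2 <- function(x) formatC(round_half_up(x, 2), format = "f", digits = 2)

# Evaluate `expr` under `seed`, restoring the caller's RNG state
# afterwards. All generator randomness flows through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stable (C-locale) ordering helper so that written reports are
# byte-identical across platforms and locales.
order_radix <- function(...) order(..., method = "radix")

check_flag <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# All sequences of substrings of length `len` of `seqs` (character),
# with their source index and 1-based start. Used by classification and
# by the exact-mapping fast path.
substrings_of <- function(seqs, len) {
  n <- nchar(seqs)
  keep <- which(n >= len)
  if (length(keep) == 0L)
    return(list(sub = character(0), src = integer(0), pos = integer(0)))
  starts <- lapply(keep, function(i) seq_len(n[i] - len + 1L))
  src <- rep(keep, lengths(starts))
  pos <- unlist(starts, use.names = FALSE)
  list(sub = substr(seqs[src], pos, pos + len - 1L),
       src = src, pos = pos)
}
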