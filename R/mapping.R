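#' Build a k-mer index of a reference
#'
#' Indexes every k-mer of the plus strand of each reference sequence;
#' minus-strand hits are found at query time by looking up the reverse
#' complement of the read. The index also caches full-length substring
#' tables lazily, which back the vectorized exact-matching fast path of
#' [map_reads()].
#'
#' @param reference Named character vector of reference sequences (DNA),
#'   or a FASTA path.
#' @param k Seed length, >= 8.
#' @return An object of class `kmer_index`.
#' @export
build_index <- function(reference, k = 12) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference))
    reference <- read_fasta(reference)
  check_flag(k >= 8, "'k' must be >= 8")
  reference <- as_dna(reference)
  if (length(reference) == 0L || all(nchar(reference) == 0L))
    stop("empty reference")
  if (is.null(names(reference)))
    names(reference) <- paste0("ref_", seq_along(reference))
  s <- substrings_of(reference, k)
  km <- split(seq_along(s$sub), s$sub)
  structure(list(reference = reference, k = as.integer(k),
                 kmer = km, src = s$src, pos = s$pos,
                 cache = new.env(parent = emptyenv())),
            class = "kmer_index")
}

#' Look up one k-mer in the index
#'
#' @param index A `kmer_index`.
#' @param kmer Single k-mer (plus strand).
#' @return Data frame of `ref` and 1-based `pos` of every occurrence.
#' @export
query_index <- function(index, kmer) {
  idx <- index$kmer[[as_dna(kmer)]]
  data.frame(ref = names(index$reference)[index$src[idx]],
             pos = index$pos[idx], stringsAsFactors = FALSE)
}

# Full-length substring table for one read length, cached on the index.
.length_table <- function(index, L) {
  key <- paste0("L", L)
  tab <- index$cache[[key]]
  if (is.null(tab)) {
    s <- substrings_of(index$reference, L)
    tab <- list(keys = character(0), groups = list(),
                src = s$src, pos = s$pos)
    if (length(s$sub)) {
      g <- split(seq_along(s$sub), s$sub)
      tab$keys <- names(g)
      tab$groups <- unname(g)
    }
    index$cache[[key]] <- tab
  }
  tab
}

#' Map collapsed reads to the reference
#'
#' Finds all full-length placements of each read with at most
#' `max_mismatches` substitutions, on both strands. The default of zero
#' mismatches follows the convention of homology-seeded precursor
#' discovery tools: the mismatch allowance of the naming step does not
#' apply to mapping. Reads with more than `max_hits` placements are
#' flagged multi-mapped, excluded from the result, and listed in the
#' `multimapped` attribute so that they are never nominated as precursor
#' loci.
#'
#' With `max_mismatches = 0` matching is done by vectorized lookup in a
#' per-length substring table. With mismatches the k-mer seeds are used
#' pigeonhole-style (one exact seed must survive); reads too short to
#' guarantee a seed fall back to scanning every position.
#'
#' @param seqs Character vector of read sequences (DNA).
#' @param index A `kmer_index` from [build_index()].
#' @param max_mismatches Maximum substitutions over the full read.
#' @param max_hits Multi-mapping cap.
#' @return Data frame with columns `query`, `ref`, `start`, `end`
#'   (0-based half-open), `strand`, `mismatches`; attribute
#'   `multimapped` holds the excluded read sequences.
#' @export
map_reads <- function(seqs, index, max_mismatches = 0, max_hits = 15) {
  stopifnot(inherits(index, "kmer_index"))
  seqs <- as_dna(seqs)
  empty <- data.frame(query = character(0), ref = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  if (length(seqs) == 0L) {
    attr(empty, "multimapped") <- character(0)
    return(empty)
  }
  if (any(nchar(seqs) < index$k))
    stop("reads shorter than the index seed length k = ", index$k)
  hits <- if (max_mismatches == 0L) .map_exact(seqs, index)
          else .map_seeded(seqs, index, max_mismatches)
  # multi-mapping cap, counted per read over both strands
  nh <- table(hits$query)
  over <- names(nh)[nh > max_hits]
  out <- hits[!(hits$query %in% over), , drop = FALSE]
  out <- out[order_radix(out$query, out$ref, out$start, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "multimapped") <- over
  out
}

.map_exact <- function(seqs, index) {
  res <- vector("list", 2L)
  names(res) <- c("+", "-")
  for (strand in c("+", "-")) {
    q <- if (strand == "+") seqs else revcomp(seqs)
    parts <- list()
    for (L in sort(unique(nchar(q)))) {
      sel <- which(nchar(q) == L)
      tab <- .length_table(index, L)
      if (length(tab$keys) == 0L) next
      m <- match(q[sel], tab$keys)
      ok <- which(!is.na(m))
      if (length(ok) == 0L) next
      idx_list <- tab$groups[m[ok]]
      reps <- lengths(idx_list)
      flat <- unlist(idx_list, use.names = FALSE)
      parts[[as.character(L)]] <- data.frame(
        query = rep(seqs[sel[ok]], reps),
        ref = names(index$reference)[tab$src[flat]],
        start = tab$pos[flat] - 1L,
        end = tab$pos[flat] - 1L + L,
        strand = strand,
        mismatches = 0L,
        stringsAsFactors = FALSE)
    }
    res[[strand]] <- do.call(rbind, parts)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(query = character(0), ref = character(0),
                                      start = integer(0), end = integer(0),
                                      strand = character(0),
                                      mismatches = integer(0),
                                      stringsAsFactors = FALSE)
  unique(out)
}

.map_seeded <- function(seqs, index, max_mm) {
  k <- index$k
  refs <- index$reference
  parts <- list()
  for (i in seq_along(seqs)) {
    read <- seqs[i]
    L <- nchar(read)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") read else revcomp(read)
      n_seeds <- max_mm + 1L
      if (n_seeds * k <= L) {
        offs <- (seq_len(n_seeds) - 1L) * k
        cand <- list()
        for (o in offs) {
          seed <- substr(q, o + 1L, o + k)
          idx <- index$kmer[[seed]]
          if (is.null(idx)) next
          cand[[length(cand) + 1L]] <- data.frame(
            src = index$src[idx], pos = index$pos[idx] - o,
            stringsAsFactors = FALSE)
        }
        cand <- unique(do.call(rbind, cand))
      } else {
        # pigeonhole unsatisfiable for this read: scan every placement
        cand <- do.call(rbind, lapply(seq_along(refs), function(ri) {
          np <- nchar(refs[ri]) - L + 1L
          if (np < 1L) return(NULL)
          data.frame(src = ri, pos = seq_len(np), stringsAsFactors = FALSE)
        }))
      }
      if (is.null(cand) || nrow(cand) == 0L) next
      ok <- cand$pos >= 1L & cand$pos + L - 1L <= nchar(refs[cand$src])
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) == 0L) next
      win <- substr(refs[cand$src], cand$pos, cand$pos + L - 1L)
      mm <- hamming_cpp(win, q)
      keep <- which(!is.na(mm) & mm <= max_mm)
      if (length(keep) == 0L) next
      parts[[length(parts) + 1L]] <- data.frame(
        query = read,
        ref = names(refs)[cand$src[keep]],
        start = cand$pos[keep] - 1L,
        end = cand$pos[keep] - 1L + L,
        strand = strand,
        mismatches = as.integer(mm[keep]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, parts)
  if (is.null(out)) out <- data.frame(query = character(0), ref = character(0),
                                      start = integer(0), end = integer(0),
                                      strand = character(0),
                                      mismatches = integer(0),
                                      stringsAsFactors = FALSE)
  unique(out)
}
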