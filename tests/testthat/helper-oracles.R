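# Independent oracles used across the suite. Each recomputes a quantity
# by a different route than the implementation under test.

# Pair energy of the folding model, duplicated here on purpose so the
# test path does not share code with the package.
oracle_pair_e <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) return(-3)
  if (key %in% c("AT", "TA")) return(-2)
  if (key %in% c("GT", "TG")) return(-1)
  NA_real_
}

# Energies of EVERY valid secondary structure of a short sequence
# (minimum hairpin loop 3, no pseudoknots), by exhaustive enumeration:
# interval [i,j] contributes either structures with i unpaired, or, for
# every admissible partner k, the cross-sum of all left and right
# substructure energies. The minimum of the returned vector is the
# enumeration MFE; the vector length is the structure count.
oracle_enum_energies <- function(seq) {
  ch <- strsplit(mirseed::as_dna(seq), "", fixed = TRUE)[[1]]
  n <- length(ch)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < 4L) return(0)
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- rec(i + 1L, j)
    for (k in (i + 4L):j) {
      e <- oracle_pair_e(ch[i], ch[k])
      if (is.na(e)) next
      left <- if (k - 1L >= i + 1L) rec(i + 1L, k - 1L) else 0
      right <- if (k + 1L <= j) rec(k + 1L, j) else 0
      out <- c(out, as.vector(outer(left, right, "+")) + e)
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

oracle_enum_mfe <- function(seq) min(oracle_enum_energies(seq))

# Brute-force read placement: every position of every reference, both
# strands, with per-position mismatch counting on raw character
# vectors. Returns the same column layout as map_reads().
oracle_brute_map <- function(read, refs, max_mm = 0) {
  rows <- list()
  for (ri in seq_along(refs)) {
    refv <- strsplit(refs[[ri]], "", fixed = TRUE)[[1]]
    for (strand in c("+", "-")) {
      q <- if (strand == "+") read else mirseed::revcomp(read)
      qv <- strsplit(q, "", fixed = TRUE)[[1]]
      L <- length(qv)
      np <- length(refv) - L + 1L
      if (np < 1L) next
      for (p in seq_len(np)) {
        mm <- sum(refv[p:(p + L - 1L)] != qv)
        if (mm <= max_mm)
          rows[[length(rows) + 1L]] <- data.frame(
            query = read, ref = names(refs)[ri], start = p - 1L,
            end = p - 1L + L, strand = strand, mismatches = mm,
            stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(query = character(0), ref = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  out <- out[order(out$query, out$ref, out$start, out$strand,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact-match placement oracle via base gregexpr (independent string
# machinery), used for large references.
oracle_exact_map <- function(read, refs) {
  rows <- list()
  for (ri in seq_along(refs)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") read else mirseed::revcomp(read)
      hit <- gregexpr(q, refs[[ri]], fixed = TRUE)[[1]]
      if (hit[1] == -1L) next
      # gregexpr skips overlapping matches; rescan from each hit + 1
      pos <- integer(0)
      from <- 1L
      repeat {
        h <- regexpr(q, substr(refs[[ri]], from, nchar(refs[[ri]])),
                     fixed = TRUE)
        if (h == -1L) break
        pos <- c(pos, from + h - 1L)
        from <- from + h
      }
      rows[[length(rows) + 1L]] <- data.frame(
        query = read, ref = names(refs)[ri], start = pos - 1L,
        end = pos - 1L + nchar(q), strand = strand, mismatches = 0L,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(query = character(0), ref = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  out <- out[order(out$query, out$ref, out$start, out$strand,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Audic-Claverie oracle through the negative-binomial identity:
# p(y|x) is the NB(size = x + 1, prob = N1/(N1+N2)) pmf, so the tails
# come from pnbinom (regularized incomplete beta internally) -- a
# completely different computational route than the package's
# log-space summation.
oracle_ac_p <- function(x, y, N1, N2) {
  pr <- N1 / (N1 + N2)
  lower <- pnbinom(y, size = x + 1, prob = pr)
  upper <- if (y == 0) 1 else pnbinom(y - 1, size = x + 1, prob = pr,
                                      lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
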