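#' Excise a precursor candidate window around a mapped read
#'
#' Extracts a window (default 250 nt) centered on the mapped read,
#' truncated at the reference ends. Minus-strand loci yield the reverse
#' complement of the excised region, with the mature offset recomputed
#' so that the returned coordinates are always on the window's own
#' 5'->3' orientation.
#'
#' @param reference Single reference sequence (character, DNA) or a
#'   named vector from which `ref` selects one.
#' @param start,end Read locus, 0-based half-open on the plus strand.
#' @param strand `"+"` or `"-"`.
#' @param window Window width in nt.
#' @param ref Name of the reference sequence when `reference` is a
#'   vector.
#' @return List with `sequence`, `win_start`/`win_end` (0-based half-open
#'   plus-strand coordinates of the excision), `mature_start`/`mature_end`
#'   (1-based inclusive within the window) and `strand`.
#' @export
extract_window <- function(reference, start, end, strand = "+",
                           window = 250, ref = NULL) {
  if (!is.null(ref)) reference <- reference[[ref]]
  reference <- as_dna(reference)
  n <- nchar(reference)
  if (start < 0 || end > n || start >= end)
    stop("locus outside reference")
  read_len <- end - start
  pad <- window - read_len
  left <- pad %/% 2L
  win_start <- max(0L, start - left)
  win_end <- min(n, win_start + window)
  win_start <- max(0L, win_end - window) # re-greedy if right-truncated
  seq <- substr(reference, win_start + 1L, win_end)
  m1 <- start - win_start + 1L
  m2 <- end - win_start
  if (strand == "-") {
    seq <- revcomp(seq)
    L <- nchar(seq)
    new_m1 <- L - m2 + 1L
    new_m2 <- L - m1 + 1L
    m1 <- new_m1; m2 <- new_m2
  }
  list(sequence = seq, win_start = as.integer(win_start),
       win_end = as.integer(win_end), mature_start = as.integer(m1),
       mature_end = as.integer(m2), strand = strand)
}

#' Predict the minimum-energy secondary structure of an RNA sequence
#'
#' Dynamic-programming fold under a simple pair-sum energy model:
#' GC -3.0, AU -2.0, GU -1.0 (model units per pair), a minimum hairpin
#' loop of 3 unpaired bases, and no pseudoknots. The model is chosen for
#' determinism and desk-scale verifiability (the DP optimum can be
#' checked by exhaustive enumeration); it is not a nearest-neighbor
#' thermodynamic model, so absolute energies are not comparable with
#' published RNAfold values. Traceback ties prefer pairing the outermost
#' base over leaving it unpaired, then the smallest pairing partner,
#' which makes the reported structure platform-independent.
#'
#' @param sequence Single sequence, RNA or DNA alphabet, length >= 10.
#' @param min_loop Minimum number of unpaired bases in a hairpin loop.
#' @return List with `structure` (dot-bracket) and `mfe` (<= 0; 0 for a
#'   structure with no pairs).
#' @examples
#' fold("GGGGGAAAACCCCC") # 5 GC pairs, mfe -15
#' @export
fold <- function(sequence, min_loop = 3) {
  check_flag(length(sequence) == 1L && !is.na(sequence),
             "'sequence' must be a single string")
  s <- as_dna(sequence)
  check_flag(nchar(s) >= 10, "'sequence' must be at least 10 nt")
  if (grepl("[^ACGT]", s)) stop("alphabet violation: only A,C,G,T/U allowed")
  res <- fold_cpp(s, as.integer(min_loop))
  stopifnot(nchar(res$structure) == nchar(s))
  res
}

#' G/C content of a sequence, percent
#'
#' @param sequence Single sequence or character vector.
#' @return Numeric vector, 100 x (G+C)/length.
#' @export
gc_content <- function(sequence) {
  s <- as_dna(sequence)
  check_flag(all(nchar(s) > 0), "empty sequence")
  gc <- nchar(gsub("[^GC]", "", s))
  100 * gc / nchar(s)
}

# Partner table of a dot-bracket string: integer vector with the 1-based
# pairing partner of each position, NA if unpaired.
pair_table <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  pt <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  pt
}

#' Locate the star strand of a mature miRNA in a folded window
#'
#' The star span is the stretch of positions that pair with the mature
#' under the predicted structure, extended by the customary 2 nt
#' 3' overhang at the star's 3' end. `star_mismatches` counts the mature
#' positions left unpaired in the structure -- the quantity bounded by
#' the "at most six mismatches with the star" acceptance criterion.
#' A mature whose paired partners fall on both sides of the mature span
#' (i.e. the mature crosses the terminal loop) is reported as not lying
#' in one arm.
#'
#' @param structure Dot-bracket string of the folded window.
#' @param mature_start,mature_end 1-based inclusive mature span within
#'   the window.
#' @return List with `star_start`, `star_end`, `star_mismatches`, `arm`
#'   (`"5p"`/`"3p"`), `in_one_arm`, and `monotone` (single-duplex check:
#'   partners strictly decrease along the mature).
#' @export
locate_star <- function(structure, mature_start, mature_end) {
  pt <- pair_table(structure)
  n <- length(pt)
  check_flag(mature_start >= 1 && mature_end <= n &&
               mature_start <= mature_end, "mature span outside structure")
  mpos <- mature_start:mature_end
  partners <- pt[mpos]
  paired <- !is.na(partners)
  star_mm <- sum(!paired)
  if (!any(paired)) {
    return(list(star_start = NA_integer_, star_end = NA_integer_,
                star_mismatches = star_mm, arm = NA_character_,
                in_one_arm = FALSE, monotone = FALSE))
  }
  pp <- partners[paired]
  internal <- any(pp >= mature_start & pp <= mature_end)
  all_up <- all(pp < mature_start)
  all_down <- all(pp > mature_end)
  in_one_arm <- !internal && (all_up || all_down)
  monotone <- !is.unsorted(rev(pp), strictly = TRUE)
  arm <- if (!in_one_arm) NA_character_ else if (all_down) "5p" else "3p"
  star_lo <- min(pp)
  star_hi <- max(pp)
  # 2 nt 3' overhang at the star's 3' end (its higher coordinate),
  # clamped to the window and to the mature span
  star_hi <- min(star_hi + 2L, n)
  if (all_up) star_hi <- min(star_hi, mature_start - 1L)
  list(star_start = star_lo, star_end = star_hi, star_mismatches = star_mm,
       arm = arm, in_one_arm = in_one_arm, monotone = monotone)
}

#' Apply the precursor acceptance criteria to a candidate window
#'
#' The four criteria: (1) the window folds into a characteristic
#' stem-loop with the mature in one arm -- operationalized as at least
#' `min_paired_frac` of mature positions paired, all partners on one
#' side of the mature, and a single duplex path (strictly monotone
#' partners); (2) at most `max_star_mismatch` mature positions unpaired
#' against the star; (3) negative folding energy; (4) G/C content
#' within `[gc_min, gc_max]` percent. The verdict is the conjunction of
#' the enabled criteria and lists every violated one.
#'
#' @param sequence Candidate window sequence (RNA or DNA).
#' @param mature_start,mature_end 1-based inclusive mature span within
#'   `sequence`.
#' @param gc_min,gc_max G/C bounds, percent.
#' @param max_star_mismatch Maximum unpaired mature positions.
#' @param min_paired_frac Minimum fraction of mature positions paired
#'   for the stem-loop criterion.
#' @param criteria Which criteria to enforce (subset of `"hairpin"`,
#'   `"star"`, `"mfe"`, `"gc"`); the verdict is their conjunction.
#' @return Object of class `hairpin_candidate`: a list with `pass`,
#'   `failed`, `structure`, `mfe`, `gc`, the mature/star spans, `arm`
#'   and `star_mismatches`.
#' @export
evaluate_precursor <- function(sequence, mature_start, mature_end,
                               gc_min = 30, gc_max = 70,
                               max_star_mismatch = 6,
                               min_paired_frac = 0.6,
                               criteria = c("hairpin", "star", "mfe", "gc")) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  fd <- fold(sequence)
  gc <- gc_content(sequence)
  st <- locate_star(fd$structure, mature_start, mature_end)
  n_mat <- mature_end - mature_start + 1L
  paired_frac <- 1 - st$star_mismatches / n_mat
  failed <- character(0)
  if ("hairpin" %in% criteria &&
      !(st$in_one_arm && st$monotone && paired_frac >= min_paired_frac))
    failed <- c(failed, "hairpin")
  if ("star" %in% criteria && st$star_mismatches > max_star_mismatch)
    failed <- c(failed, "star")
  if ("mfe" %in% criteria && !(fd$mfe < 0))
    failed <- c(failed, "mfe")
  if ("gc" %in% criteria && !(gc >= gc_min && gc <= gc_max))
    failed <- c(failed, "gc")
  structure(list(pass = length(failed) == 0L, failed = failed,
                 sequence = as_dna(sequence), structure = fd$structure,
                 mfe = fd$mfe, gc = gc,
                 mature_start = mature_start, mature_end = mature_end,
                 star_start = st$star_start, star_end = st$star_end,
                 star_mismatches = st$star_mismatches, arm = st$arm),
            class = "hairpin_candidate")
}

#' @export
print.hairpin_candidate <- function(x, ...) {
  cat("hairpin candidate:", if (x$pass) "PASS" else
    paste("FAIL", paste(x$failed, collapse = ",")), "\n")
  cat(sprintf("  mfe %.1f  gc %.1f%%  star mismatches %d  arm %s\n",
              x$mfe, x$gc, x$star_mismatches,
              if (is.na(x$arm)) "-" else x$arm))
  invisible(x)
}

#' Discover hairpin precursors around mapped read loci
#'
#' For each mapped locus, excises the window, folds it, and applies the
#' precursor acceptance criteria; duplicate (ref, window, strand) loci
#' are evaluated once.
#'
#' @param hits Mapping data frame from [map_reads()].
#' @param reference Named character vector of reference sequences.
#' @param window Window width, nt.
#' @param ... Passed to [evaluate_precursor()].
#' @return Data frame of candidates: locus columns, `mature_seq`,
#'   `structure`, `mfe`, `gc`, `star_mismatches`, `pass`, `failed`.
#' @export
discover_hairpins <- function(hits, reference, window = 250, ...) {
  reference <- as_dna(reference)
  if (nrow(hits) == 0L)
    return(data.frame(query = character(0), ref = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), win_start = integer(0),
                      win_end = integer(0), mfe = numeric(0),
                      gc = numeric(0), star_mismatches = integer(0),
                      pass = logical(0), failed = character(0),
                      structure = character(0), stringsAsFactors = FALSE))
  key <- !duplicated(hits[c("query", "ref", "start", "strand")])
  loci <- hits[key, , drop = FALSE]
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    h <- loci[i, ]
    w <- extract_window(reference[[h$ref]], h$start, h$end,
                        strand = h$strand, window = window)
    ev <- evaluate_precursor(w$sequence, w$mature_start, w$mature_end, ...)
    data.frame(query = h$query, ref = h$ref, start = h$start, end = h$end,
               strand = h$strand, win_start = w$win_start,
               win_end = w$win_end, mfe = ev$mfe, gc = ev$gc,
               star_mismatches = ev$star_mismatches, pass = ev$pass,
               failed = paste(ev$failed, collapse = ","),
               structure = ev$structure, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
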