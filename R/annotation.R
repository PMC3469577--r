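#' Default classification precedence
#'
#' Reads are assigned to the first matching category in this order.
#' Structural RNA categories come first so that rRNA/tRNA contamination
#' cannot inflate the miRNA counts; the order is a configuration knob.
#'
#' @return Character vector of category labels (the terminal
#'   `unannotated` class is implicit).
#' @export
default_precedence <- function() {
  c("rRNA", "tRNA", "snRNA", "snoRNA", "miRNA", "siRNA",
    "sense_exon", "antisense_exon")
}

# Which annotation set backs each category, and on which strand the
# read must match it.
.category_source <- list(
  rRNA = list(set = "rRNA", strand = "+"),
  tRNA = list(set = "tRNA", strand = "+"),
  snRNA = list(set = "snRNA", strand = "+"),
  snoRNA = list(set = "snoRNA", strand = "+"),
  miRNA = list(set = "miRNA", strand = "+"),
  siRNA = list(set = "siRNA", strand = "+"),
  sense_exon = list(set = "exon", strand = "+"),
  antisense_exon = list(set = "exon", strand = "-")
)

#' Build an annotation database for read classification
#'
#' @param sets Named list. Each element is either a character vector of
#'   sequences or a FASTA path; allowed names are `rRNA`, `tRNA`,
#'   `snRNA`, `snoRNA`, `miRNA`, `siRNA` and `exon` (the exon set serves
#'   both the sense and the antisense exon categories).
#' @return A named list of DNA character vectors, class `annotation_db`.
#' @export
annotation_db <- function(sets) {
  allowed <- c("rRNA", "tRNA", "snRNA", "snoRNA", "miRNA", "siRNA", "exon")
  if (is.null(names(sets)) || !all(names(sets) %in% allowed))
    stop("annotation sets must be named from: ",
         paste(allowed, collapse = ", "))
  db <- lapply(sets, function(s) {
    if (is.character(s) && length(s) == 1L && file.exists(s))
      s <- read_fasta(s)
    s <- as_dna(unname(s))
    if (any(grepl("[^ACGTN]", s)))
      stop("malformed annotation record: non-nucleotide characters")
    s
  })
  structure(db, class = "annotation_db")
}

#' Classify collapsed reads into annotation categories
#'
#' Each unique read is assigned to the first category in `precedence`
#' whose annotation set contains the read as an exact, full-read-length
#' substring (the reverse complement of the read for the antisense exon
#' category). Unmatched reads are `unannotated`. Because assignment
#' stops at the first hit, every read lands in exactly one category and
#' category totals partition the library size.
#'
#' @param collapsed Collapsed-read data frame (see [collapse_reads()]).
#' @param db An [annotation_db()] (or bare named list of sequence sets).
#' @param precedence Ordered category labels covering each category at
#'   most once; see [default_precedence()].
#' @return `collapsed` with an added `category` column.
#' @export
classify_reads <- function(collapsed, db, precedence = default_precedence()) {
  if (!inherits(db, "annotation_db")) db <- annotation_db(db)
  bad <- setdiff(precedence, names(.category_source))
  if (length(bad) || anyDuplicated(precedence))
    stop("'precedence' must list known categories exactly once")
  category <- rep("unannotated", nrow(collapsed))
  if (nrow(collapsed) == 0L) {
    collapsed$category <- character(0)
    return(collapsed)
  }
  lens <- sort(unique(collapsed$length))
  for (cat in precedence) {
    src <- .category_source[[cat]]
    seqs <- db[[src$set]]
    if (is.null(seqs) || length(seqs) == 0L) next
    open <- which(category == "unannotated")
    if (length(open) == 0L) break
    query <- collapsed$sequence[open]
    if (src$strand == "-") query <- revcomp(query)
    for (L in lens) {
      sel <- open[collapsed$length[open] == L]
      if (length(sel) == 0L) next
      subs <- unique(substrings_of(seqs, L)$sub)
      if (length(subs) == 0L) next
      hit <- !is.na(match(query[match(sel, open)], subs))
      category[sel[hit]] <- cat
    }
  }
  collapsed$category <- category
  collapsed
}

#' Category summary table of a classified library
#'
#' Mirrors the standard deep-sequencing summary layout: per category the
#' number of unique sequences, the number of total reads, and both as
#' percentages of the library, plus a totals row. Percentages are
#' half-up rounded to two decimals.
#'
#' @param classified Output of [classify_reads()].
#' @return Data frame with columns `category`, `unique_count`,
#'   `unique_percent`, `total_count`, `total_percent`.
#' @export
category_table <- function(classified) {
  cats <- c(sort(names(.category_source)), "unannotated")
  uniq <- vapply(cats, function(ct) sum(classified$category == ct), 0L)
  tot <- vapply(cats, function(ct)
    sum(classified$count[classified$category == ct]), 0)
  n_uniq <- nrow(classified)
  n_tot <- sum(classified$count)
  out <- data.frame(
    category = cats,
    unique_count = unname(uniq),
    unique_percent = if (n_uniq > 0) round_half_up(100 * unname(uniq) / n_uniq)
                     else rep(NA_real_, length(cats)),
    total_count = unname(tot),
    total_percent = if (n_tot > 0) round_half_up(100 * unname(tot) / n_tot)
                    else rep(NA_real_, length(cats)),
    stringsAsFactors = FALSE)
  totals <- data.frame(category = "total", unique_count = n_uniq,
                       unique_percent = NA_real_, total_count = n_tot,
                       total_percent = NA_real_, stringsAsFactors = FALSE)
  rbind(out, totals)
}

#' Read-length distribution of a collapsed library
#'
#' @param collapsed Collapsed-read data frame.
#' @param mode `"redundant"` weighs each unique sequence by its count;
#'   `"nonredundant"` weighs each unique sequence once.
#' @return Named numeric vector, lengths (nt) to read counts; empty for
#'   empty input.
#' @export
size_distribution <- function(collapsed,
                              mode = c("redundant", "nonredundant")) {
  mode <- match.arg(mode)
  if (nrow(collapsed) == 0L) return(setNames(numeric(0), character(0)))
  w <- if (mode == "redundant") collapsed$count else rep(1L, nrow(collapsed))
  agg <- tapply(w, collapsed$length, sum)
  setNames(as.numeric(agg), names(agg))
}

#' First-nucleotide composition at a given read length
#'
#' Count-weighted fractions of A/C/G/U at the first position among reads
#' of length `length` (the 21 nt class is where plant AGO loading makes
#' the 5' nucleotide informative).
#'
#' @param collapsed Collapsed-read data frame.
#' @param length Read length to restrict to, nt.
#' @return Named numeric vector over `A`, `C`, `G`, `U` summing to 1, or
#'   an empty numeric vector if no read has the requested length.
#' @export
first_nt_composition <- function(collapsed, length = 21) {
  sel <- collapsed[collapsed$length == length, , drop = FALSE]
  if (nrow(sel) == 0L) return(setNames(numeric(0), character(0)))
  first <- as_rna(substr(sel$sequence, 1L, 1L))
  tot <- vapply(c("A", "C", "G", "U"),
                function(b) sum(sel$count[first == b]), 0)
  tot / sum(sel$count)
}
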