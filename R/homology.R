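#' Extract the miRNA family from a reference mature name
#'
#' `sbi-MIR164b` and `osa-miR164a-5p` both map to family `miR164`.
#'
#' @param name Character vector of miRBase-style names.
#' @return Character vector of family labels, `NA` when no family number
#'   is present.
#' @export
mirna_family <- function(name) {
  m <- regmatches(name, regexpr("MIR[0-9]+", toupper(name)))
  out <- rep(NA_character_, length(name))
  hit <- regexpr("MIR[0-9]+", toupper(name)) > 0
  out[hit] <- sub("MIR", "miR", m)
  out
}

# Minimum mismatch count of an ungapped sliding comparison. The
# candidate may shift against the reference by up to `max_len_diff`
# positions on either side; candidate bases that fall outside the
# reference are counted as mismatches, unaligned reference overhang is
# free. Returns Inf when the length difference exceeds the allowance.
.slide_mismatches <- function(candidate, reference, max_len_diff = 2) {
  lc <- nchar(candidate); lr <- nchar(reference)
  if (abs(lc - lr) > max_len_diff) return(Inf)
  cc <- strsplit(candidate, "", fixed = TRUE)[[1]]
  rr <- strsplit(reference, "", fixed = TRUE)[[1]]
  best <- Inf
  for (s in seq(-max_len_diff, lr - lc + max_len_diff)) {
    ci <- seq_len(lc)
    ri <- ci + s
    inside <- ri >= 1L & ri <= lr
    mm <- sum(cc[inside] != rr[ri[inside]]) + sum(!inside)
    if (mm < best) best <- mm
  }
  as.numeric(best)
}

#' Match a candidate mature sequence against a reference mature set
#'
#' Ungapped comparison of the candidate against every reference mature
#' at every offset within the length-difference allowance; the
#' references achieving the overall minimum mismatch count (when it is
#' `<= max_mm`) are returned. Two mismatches against the reference set
#' is the customary homology bound for cross-species naming.
#'
#' @param candidate Single candidate mature sequence (RNA or DNA).
#' @param reference_set Named character vector of reference matures
#'   (miRBase-style names), or a FASTA path.
#' @param max_mm Maximum mismatches for an assignment.
#' @param max_len_diff Maximum length difference between candidate and
#'   reference.
#' @return Data frame of `name`, `family`, `mismatches` for all best
#'   matches; zero rows when nothing is within `max_mm`.
#' @export
match_mature <- function(candidate, reference_set, max_mm = 2,
                         max_len_diff = 2) {
  if (is.character(reference_set) && length(reference_set) == 1L &&
      file.exists(reference_set))
    reference_set <- read_fasta(reference_set)
  if (length(reference_set) == 0L) stop("empty reference set")
  candidate <- as_dna(candidate)
  refs <- as_dna(reference_set)
  mm <- vapply(refs, function(r)
    .slide_mismatches(candidate, r, max_len_diff), 0)
  best <- min(mm)
  if (!is.finite(best) || best > max_mm)
    return(data.frame(name = character(0), family = character(0),
                      mismatches = numeric(0), stringsAsFactors = FALSE))
  sel <- which(mm == best)
  data.frame(name = names(refs)[sel],
             family = mirna_family(names(refs)[sel]),
             mismatches = unname(mm[sel]), stringsAsFactors = FALSE)
}

#' Assign species names to matched mature sequences
#'
#' Families represented by a single distinct sequence are named
#' `<prefix>-miR<family>`; families with several distinct sequences get
#' `seq1..seqN` suffixes, numbered by descending total read count and
#' then lexicographically by sequence, so that naming is deterministic.
#' A candidate within the mismatch bound of several families is named by
#' the lower-mismatch family; on an exact tie it is flagged ambiguous
#' (and named by the alphabetically first family so the row is still
#' visible in reports).
#'
#' @param assignments Data frame with one row per candidate sequence:
#'   columns `sequence`, `family`, `mismatches`, `count` and optionally
#'   `ambiguous`.
#' @param prefix Species prefix for assigned names.
#' @return `assignments` with an `assigned_name` column added.
#' @export
assign_names <- function(assignments, prefix = "ssp") {
  if (nrow(assignments) == 0L) {
    assignments$assigned_name <- character(0)
    return(assignments)
  }
  assignments$assigned_name <- NA_character_
  for (fam in unique(assignments$family)) {
    sel <- which(assignments$family == fam)
    fam_label <- sub("^miR", "", fam)
    seqs <- unique(assignments$sequence[sel])
    if (length(seqs) == 1L) {
      assignments$assigned_name[sel] <- sprintf("%s-miR%s", prefix, fam_label)
    } else {
      tot <- vapply(seqs, function(s)
        sum(assignments$count[sel][assignments$sequence[sel] == s]), 0)
      ord <- order_radix(-tot, seqs)
      rank <- match(assignments$sequence[sel], seqs[ord])
      assignments$assigned_name[sel] <-
        sprintf("%s-miR%sseq%d", prefix, fam_label, rank)
    }
  }
  assignments
}

#' Name candidate matures by homology to a reference set
#'
#' Convenience wrapper: matches every candidate with [match_mature()],
#' resolves family ties, and applies the naming scheme of
#' [assign_names()].
#'
#' @param candidates Data frame with `sequence` and `count` columns
#'   (one row per distinct mature sequence).
#' @param reference_set Named character vector of reference matures.
#' @param max_mm,max_len_diff Passed to [match_mature()].
#' @param prefix Species prefix.
#' @return Data frame of named candidates: `sequence`, `count`,
#'   `family`, `matched_refs`, `mismatches`, `ambiguous`,
#'   `assigned_name`. Candidates with no match are dropped.
#' @export
name_by_homology <- function(candidates, reference_set, max_mm = 2,
                             max_len_diff = 2, prefix = "ssp") {
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    m <- match_mature(candidates$sequence[i], reference_set, max_mm,
                      max_len_diff)
    if (nrow(m) == 0L) return(NULL)
    fams <- sort(unique(m$family))
    data.frame(sequence = candidates$sequence[i],
               count = candidates$count[i],
               family = fams[1],
               matched_refs = paste(sort(m$name), collapse = ";"),
               mismatches = m$mismatches[1],
               ambiguous = length(fams) > 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(sequence = character(0), count = numeric(0),
                      family = character(0), matched_refs = character(0),
                      mismatches = numeric(0), ambiguous = logical(0),
                      assigned_name = character(0), stringsAsFactors = FALSE))
  assign_names(out, prefix = prefix)
}
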