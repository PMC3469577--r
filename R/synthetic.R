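#' The bundled reference set of mature miRNAs
#'
#' Loads the sorghum-like reference mature set shipped with the package
#' (grass miRNA families; names follow the miRBase precursor style).
#' This set is both the homology anchor of the naming stage and the
#' template pool of the synthetic generator.
#'
#' @param path FASTA path; defaults to the bundled set.
#' @return Named character vector of mature sequences (DNA alphabet).
#' @export
mature_reference <- function(path = system.file("extdata",
                                                "sorghum_mature_mirnas.fa",
                                                package = "mirseed")) {
  read_fasta(path)
}

# Bases that can pair (including G:U wobble) with `b`; used to engineer
# non-pairing star defects.
.nonpairing_base <- function(b) {
  avoid <- switch(b,
                  A = "T",       # A pairs T only
                  C = "G",       # C pairs G only
                  G = c("C", "T"),
                  T = c("A", "G"))
  sample(setdiff(c("A", "C", "G", "T"), c(avoid, b)), 1L)
}

.random_dna <- function(n, len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
          collapse = ""), "")
}

.mutate_at <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

# One planted mature: a reference mature with `n_mut` substitutions at
# interior positions, emulating cross-species divergence while staying
# within the 2-mismatch homology bound.
.plant_mature <- function(ref_seq, n_mut) {
  s <- ref_seq
  if (n_mut > 0) {
    pos <- sample(3:(nchar(s) - 2L), n_mut)
    for (p in pos) {
      cur <- substr(s, p, p)
      s <- .mutate_at(s, p, sample(setdiff(c("A", "C", "G", "T"), cur), 1L))
    }
  }
  s
}

# Build one precursor around a mature: mature arm + loop + star arm,
# with `defects` engineered non-pairing star positions (isolated,
# interior), so the folded hairpin leaves exactly those mature
# positions unpaired.
.build_precursor <- function(mature, arm, loop_len, defects) {
  loop <- .random_dna(1L, loop_len, gc = 0.3)
  star <- revcomp(mature)
  L <- nchar(mature)
  if (defects > 0) {
    # candidate mature positions: interior, pairwise non-adjacent
    ok <- FALSE
    for (try in 1:20) {
      pos <- sort(sample(5:(L - 4L), defects))
      if (defects == 1L || min(diff(pos)) >= 3L) { ok <- TRUE; break }
    }
    if (!ok) pos <- seq(5L, by = 3L, length.out = defects)
    for (p in pos) {
      mat_base <- substr(mature, p, p)
      star_pos <- L - p + 1L  # position in star pairing mature position p
      star <- .mutate_at(star, star_pos, .nonpairing_base(mat_base))
    }
  }
  if (arm == "5p") paste0(mature, loop, star) else paste0(star, loop, mature)
}

#' Generate a synthetic reference with planted precursors and decoys
#'
#' Builds a toy genome carrying `n_precursors` hairpin precursors at
#' recorded loci and strands, per-category decoy annotation sets, a
#' planted mature set derived from the bundled reference matures (each
#' planted mature is within two mismatches of exactly one reference
#' name), per-miRNA expression baselines and planted drought/irrigated
#' fold changes. Every planted precursor is checked during generation
#' against the full discovery path -- the 250 nt window excised from the
#' genome around the mature must pass [evaluate_precursor()] -- so
#' recovery failures downstream indicate pipeline defects, not
#' generation artefacts.
#'
#' All randomness flows through `seed`; the caller's RNG state is left
#' untouched and repeated calls are bit-identical.
#'
#' @param n_precursors Number of planted precursors (>= 1; at most two
#'   variants per reference family).
#' @param n_decoys Number of decoy annotation sequences spread over the
#'   rRNA/tRNA/snRNA/snoRNA/exon/siRNA categories (>= 0).
#' @param seed Integer RNG seed.
#' @param n_de Number of miRNAs with a planted drought response.
#' @param fc_magnitudes Planted |fold change| pool for responsive
#'   miRNAs, echoing the 2-19x range reported for drought-responsive
#'   sugarcane miRNAs.
#' @param baseline_range Log-uniform TPM baseline range for planted
#'   miRNAs; responsive miRNAs draw from `de_baseline_range`.
#' @param de_baseline_range TPM baseline range of responsive miRNAs.
#' @param window Window width used for the generation-time criteria
#'   check (matching the discovery stage).
#' @return Object of class `synthetic_truth`: a list with `genome`,
#'   `precursors` (data frame of loci and spans, 1-based inclusive,
#'   plus-strand coordinates), `mature_set`, `baseline`, `planted_fc`
#'   (per genotype), `decoys`, `annotations` (an [annotation_db()]),
#'   `seed` and `params`.
#' @export
make_reference <- function(n_precursors = 30, n_decoys = 50, seed = 1,
                           n_de = 8,
                           fc_magnitudes = c(2.5, 3, 3.5, 4, 5, 6, 10, 18),
                           baseline_range = c(100, 10000),
                           de_baseline_range = c(200, 5000),
                           window = 250) {
  check_flag(n_precursors >= 1, "'n_precursors' must be >= 1")
  check_flag(n_decoys >= 0, "'n_decoys' must be >= 0")
  refs <- mature_reference()
  if (n_precursors > 2L * length(refs))
    stop("at most ", 2L * length(refs), " precursors supported")
  with_seed(seed, {
    ref_idx <- rep(seq_along(refs), length.out = n_precursors)
    variant <- ave(ref_idx, ref_idx, FUN = seq_along)
    matures <- character(n_precursors)
    for (i in seq_len(n_precursors)) {
      repeat {
        m <- .plant_mature(refs[[ref_idx[i]]], n_mut = variant[i] - 1L)
        mm <- vapply(refs, function(r) .slide_mismatches(m, r, 2), 0)
        if (sum(mm <= 2) == 1L && which.min(mm) == ref_idx[i] &&
            !(m %in% matures)) break
      }
      matures[i] <- m
    }
    mat_names <- sprintf("pln-%s%s", sub("^sbi-", "", names(refs)[ref_idx]),
                         ifelse(variant > 1L, paste0(".v", variant), ""))
    # genome scaffold with one precursor per 2 kb slot
    slot <- 2000L
    genome_len <- n_precursors * slot + 2L * slot
    genome <- .random_dna(1L, genome_len, gc = 0.42)
    prec <- vector("list", n_precursors)
    for (i in seq_len(n_precursors)) {
      placed <- FALSE
      for (try in 1:100) {
        arm <- sample(c("5p", "3p"), 1L)
        defects <- sample(0:3, 1L)
        loop_len <- sample(8:12, 1L)
        p_seq <- .build_precursor(matures[i], arm, loop_len, defects)
        offset <- slot + (i - 1L) * slot + sample(0:600, 1L)
        strand <- sample(c("+", "-"), 1L)
        emb <- if (strand == "+") p_seq else revcomp(p_seq)
        g2 <- paste0(substr(genome, 1L, offset),
                     emb,
                     substr(genome, offset + nchar(p_seq) + 1L, genome_len))
        # plus-strand coordinates of the mature within the embedding
        L <- nchar(matures[i])
        pl <- nchar(p_seq)
        rel <- if (arm == "5p") c(1L, L) else c(pl - L + 1L, pl)
        if (strand == "-") rel <- c(pl - rel[2] + 1L, pl - rel[1] + 1L)
        m1 <- offset + rel[1]          # 1-based inclusive
        m2 <- offset + rel[2]
        # the mature must occur exactly once genome-wide (either strand)
        n_occ <- length(gregexpr(matures[i], g2, fixed = TRUE)[[1]])
        if (attr(gregexpr(matures[i], g2, fixed = TRUE)[[1]],
                 "match.length")[1] == -1L) n_occ <- 0L
        rc_hits <- gregexpr(revcomp(matures[i]), g2, fixed = TRUE)[[1]]
        n_occ <- n_occ + if (rc_hits[1] == -1L) 0L else length(rc_hits)
        if (n_occ != 1L) next
        w <- extract_window(g2, m1 - 1L, m2, strand = strand,
                            window = window)
        ev <- evaluate_precursor(w$sequence, w$mature_start, w$mature_end)
        if (!ev$pass || ev$star_mismatches != defects) next
        genome <- g2
        prec[[i]] <- data.frame(
          name = mat_names[i], mature = matures[i],
          ref_name = names(refs)[ref_idx[i]], arm = arm,
          defects = defects, chrom = "chr1",
          prec_start = offset + 1L, prec_end = offset + pl,
          mature_start = m1, mature_end = m2, strand = strand,
          precursor = p_seq, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place precursor ", i, " under the criteria")
    }
    precursors <- do.call(rbind, prec)
    # decoy annotation sets (not on the genome: decoy reads are drawn
    # from these sequences directly)
    decoy_spec <- data.frame(
      set = c("rRNA", "tRNA", "snRNA", "snoRNA", "exon", "siRNA"),
      len = c(120L, 76L, 150L, 100L, 300L, 24L), stringsAsFactors = FALSE)
    decoys <- setNames(vector("list", nrow(decoy_spec)), decoy_spec$set)
    if (n_decoys > 0) {
      cat_of <- rep(seq_len(nrow(decoy_spec)), length.out = n_decoys)
      for (ci in seq_len(nrow(decoy_spec))) {
        k <- sum(cat_of == ci)
        if (k == 0L) { decoys[[ci]] <- character(0); next }
        out <- character(0)
        while (length(out) < k) {
          s <- .random_dna(1L, decoy_spec$len[ci])
          if (any(vapply(matures, function(m)
            grepl(m, s, fixed = TRUE), TRUE))) next
          out <- c(out, s)
        }
        decoys[[ci]] <- setNames(out, sprintf("%s_decoy_%d",
                                              decoy_spec$set[ci],
                                              seq_len(k)))
      }
    } else decoys <- lapply(decoys, function(x) character(0))
    # expression baselines and planted drought fold changes
    lb <- log(baseline_range)
    baseline <- exp(runif(n_precursors, lb[1], lb[2]))
    n_de <- min(n_de, n_precursors)
    de_idx <- sort(sample(seq_len(n_precursors), n_de))
    ldb <- log(de_baseline_range)
    baseline[de_idx] <- exp(runif(n_de, ldb[1], ldb[2]))
    mags <- rep_len(fc_magnitudes, n_de)
    fc_rows <- list()
    for (g in c("HT", "LT")) {
      signs <- sample(c(-1, 1), n_de, replace = TRUE)
      fc_rows[[g]] <- data.frame(name = mat_names[de_idx],
                                 genotype = rep(g, n_de),
                                 fc = signs * mags, stringsAsFactors = FALSE)
    }
    planted_fc <- do.call(rbind, fc_rows)
    rownames(planted_fc) <- NULL
    annotations <- annotation_db(c(decoys, list(miRNA = matures)))
    truth <- list(
      genome = setNames(genome, "chr1"),
      precursors = precursors,
      mature_set = data.frame(name = mat_names, sequence = matures,
                              ref_name = names(refs)[ref_idx],
                              stringsAsFactors = FALSE),
      baseline = data.frame(name = mat_names, tpm = baseline,
                            stringsAsFactors = FALSE),
      planted_fc = planted_fc,
      decoys = decoys,
      annotations = annotations,
      target_sites = NULL,
      seed = as.integer(seed),
      params = list(n_precursors = n_precursors, n_decoys = n_decoys,
                    n_de = n_de, window = window,
                    baseline_range = baseline_range,
                    de_baseline_range = de_baseline_range))
    class(truth) <- "synthetic_truth"
    truth
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic truth:", nrow(x$precursors), "planted precursors,",
      sum(lengths(x$decoys)), "decoys, seed", x$seed, "\n")
  invisible(x)
}

# Expected TPM of each planted miRNA under a condition: the planted
# fold change acts on the drought libraries, with the signed convention
# (negative fc divides the baseline).
.expected_tpm <- function(truth, genotype, condition) {
  tpm <- setNames(truth$baseline$tpm, truth$baseline$name)
  if (condition == "drought") {
    fc <- truth$planted_fc[truth$planted_fc$genotype == genotype, ]
    mult <- ifelse(fc$fc >= 0, fc$fc, 1 / abs(fc$fc))
    tpm[fc$name] <- tpm[fc$name] * mult
  }
  tpm
}

#' Simulate per-miRNA read counts for one library
#'
#' Draws the planted miRNA counts of one library at the count level
#' (without synthesizing reads): the expected count of each miRNA is
#' `depth x baseline TPM / 1e6`, times the planted fold change in
#' drought libraries. The default count model is Poisson thinning, the
#' sampling model assumed by the Audic-Claverie test; a negative
#' binomial with the given `dispersion` is available as a robustness
#' knob.
#'
#' @param truth A `synthetic_truth`.
#' @param genotype `"HT"` or `"LT"`.
#' @param condition `"irrigated"` or `"drought"`.
#' @param depth Library depth (expected total reads), >= 1.
#' @param seed Integer seed.
#' @param dispersion `NULL` for Poisson; otherwise the NB dispersion
#'   (variance = mu + dispersion * mu^2).
#' @return Named integer vector of counts per planted miRNA.
#' @export
simulate_counts <- function(truth, genotype, condition, depth, seed,
                            dispersion = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  check_flag(genotype %in% c("HT", "LT"), "unknown genotype label")
  check_flag(condition %in% c("irrigated", "drought"),
             "unknown condition label")
  check_flag(depth >= 1, "'depth' must be >= 1")
  with_seed(seed, {
    mu <- depth * .expected_tpm(truth, genotype, condition) / 1e6
    n <- length(mu)
    cnt <- if (is.null(dispersion)) rpois(n, mu)
           else rnbinom(n, mu = mu, size = 1 / dispersion)
    setNames(as.integer(cnt), names(mu))
  })
}

# Length distribution of background inserts (16-27 nt): mode at 21 nt
# with a secondary 24 nt mode, as in plant small-RNA libraries.
.bg_length_probs <- function() {
  setNames(c(0.02, 0.02, 0.05, 0.06, 0.08, 0.28,
             0.08, 0.07, 0.18, 0.08, 0.05, 0.03), 16:27)
}

.random_background <- function(n) {
  if (n == 0L) return(character(0))
  probs <- .bg_length_probs()
  lens <- sample(as.integer(names(probs)), n, replace = TRUE, prob = probs)
  reads <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    "")
  # 21 nt class: 40% U / 40% A / 10% C / 10% G at the first position
  is21 <- which(lens == 21L)
  if (length(is21)) {
    first <- sample(c("T", "A", "C", "G"), length(is21), replace = TRUE,
                    prob = c(0.4, 0.4, 0.1, 0.1))
    reads[is21] <- paste0(first, substr(reads[is21], 2L, 21L))
  }
  reads
}

# Default expected fraction of the library per decoy category; the
# remainder (after miRNAs and the 50% unannotated background) stays
# unassigned so that depth is an expectation, not an exact total.
.decoy_fracs <- function() {
  c(rRNA = 0.08, tRNA = 0.07, sense_exon = 0.055, antisense_exon = 0.01,
    siRNA = 0.04, snRNA = 0.003, snoRNA = 0.001)
}

.decoy_reads <- function(decoys, n, category) {
  src_set <- switch(category,
                    sense_exon = , antisense_exon = decoys$exon,
                    decoys[[category]])
  if (n == 0L || length(src_set) == 0L) return(character(0))
  if (category == "siRNA")
    return(unname(sample(src_set, n, replace = TRUE)))
  src <- sample(seq_along(src_set), n, replace = TRUE)
  lens <- sample(19:24, n, replace = TRUE)
  starts <- vapply(seq_len(n), function(i)
    sample.int(nchar(src_set[src[i]]) - lens[i] + 1L, 1L), 0L)
  out <- substr(src_set[src], starts, starts + lens - 1L)
  if (category == "antisense_exon") out <- revcomp(out)
  unname(out)
}

#' Simulate one small-RNA sequencing library
#'
#' Synthesizes a library of reads as insert + 3' adapter prefix,
#' truncated to the machine read length: planted miRNA reads at their
#' baseline x fold-change abundances (Poisson counts by default),
#' decoy reads from each annotation category at fixed expected
#' fractions, and unannotated background (uniform random 16-27-mers,
#' 21 nt mode with a secondary 24 nt mode) at 50% of depth. Adapters
#' are appended at the 3' end only: reads are sequenced from the insert
#' start, so the 5' adapter never appears in the read.
#'
#' @inheritParams simulate_counts
#' @param adapter 3' adapter sequence, length >= 8.
#' @param read_length Machine read length; inserts shorter than this
#'   run into the adapter.
#' @param background_frac Expected unannotated fraction of depth.
#' @param decoy_fracs Named expected fractions per decoy category.
#' @param fastq Optional path; when given the library is also written
#'   as Phred+33 FASTQ with constant quality `I`.
#' @return Object of class `synthetic_library`: list with `reads`
#'   (with adapter), `mirna_counts` (truth bookkeeping), `n`, `library`
#'   metadata and `fastq` (path or `NULL`).
#' @export
simulate_library <- function(truth, genotype, condition, day = 2,
                             depth = 2e5,
                             adapter = "TGGAATTCTCGGGTGCCAAGG",
                             seed = 1, read_length = 36,
                             dispersion = NULL, background_frac = 0.5,
                             decoy_fracs = .decoy_fracs(), fastq = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  check_flag(genotype %in% c("HT", "LT"), "unknown genotype label")
  check_flag(condition %in% c("irrigated", "drought"),
             "unknown condition label")
  check_flag(depth >= 1, "'depth' must be >= 1")
  check_flag(nchar(adapter) >= 8, "'adapter' must be at least 8 nt")
  adapter <- as_dna(adapter)
  with_seed(seed, {
    mu <- depth * .expected_tpm(truth, genotype, condition) / 1e6
    cnt <- if (is.null(dispersion)) rpois(length(mu), mu)
           else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    mirna_counts <- setNames(as.integer(cnt), names(mu))
    mat_seq <- setNames(truth$mature_set$sequence, truth$mature_set$name)
    inserts <- rep(unname(mat_seq[names(mirna_counts)]), mirna_counts)
    for (categ in names(decoy_fracs)) {
      k <- rpois(1L, depth * decoy_fracs[[categ]])
      inserts <- c(inserts, .decoy_reads(truth$decoys, k, categ))
    }
    inserts <- c(inserts, .random_background(rpois(1L,
                                                   depth * background_frac)))
    inserts <- inserts[sample.int(length(inserts))]
    reads <- substr(paste0(inserts, strrep(adapter,
                                           ceiling(read_length /
                                                     nchar(adapter)) + 1L)),
                    1L, read_length)
    names(reads) <- sprintf("read_%d", seq_along(reads))
    path <- NULL
    if (!is.null(fastq)) path <- write_fastq(reads, fastq)
    structure(list(reads = reads, mirna_counts = mirna_counts,
                   n = length(reads),
                   library = list(genotype = genotype,
                                  condition = condition, day = day,
                                  depth = depth, seed = as.integer(seed)),
                   fastq = path),
              class = "synthetic_library")
  })
}

#' @export
print.synthetic_library <- function(x, ...) {
  cat(sprintf("synthetic library %s/%s day %s: %d reads (seed %d)\n",
              x$library$genotype, x$library$condition, x$library$day,
              x$n, x$library$seed))
  invisible(x)
}

#' Generate a transcriptome with planted miRNA target sites
#'
#' Embeds, for each planted miRNA (up to `n_transcripts`), one target
#' site into a random transcript at a recorded 1-based span. Site
#' layouts cycle through `"perfect"` (exact reverse complement,
#' expectation 0), `"mismatch"` (one engineered non-seed mismatch,
#' expectation 1) and `"wobble"` (one non-seed G:U, expectation 0.5;
#' falls back to `"mismatch"` when the miRNA offers no non-seed G).
#' Overlapping spans are rejected during placement.
#'
#' @param truth A `synthetic_truth`.
#' @param n_transcripts Number of transcripts (>= number of planted
#'   sites).
#' @param seed Integer seed.
#' @param tx_len Transcript length, nt.
#' @param layouts Site layout cycle.
#' @return List with `transcripts` (named character vector) and `sites`
#'   (data frame: `mirna`, `transcript`, `start`, `end`, `layout`,
#'   `expected_e`).
#' @export
make_transcriptome_with_targets <- function(truth, n_transcripts, seed,
                                            tx_len = 1200,
                                            layouts = c("perfect",
                                                        "mismatch",
                                                        "wobble")) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n_sites <- nrow(truth$mature_set)
  check_flag(n_transcripts >= n_sites,
             "'n_transcripts' must be >= number of planted sites")
  layouts <- match.arg(layouts, several.ok = TRUE)
  with_seed(seed, {
    txs <- .random_dna(n_transcripts, tx_len, gc = 0.45)
    names(txs) <- sprintf("tx_%d", seq_len(n_transcripts))
    rows <- vector("list", n_sites)
    for (i in seq_len(n_sites)) {
      m <- truth$mature_set$sequence[i]
      L <- nchar(m)
      layout <- layouts[(i - 1L) %% length(layouts) + 1L]
      site <- revcomp(m)
      expected <- 0
      nonseed <- setdiff(seq_len(L), 2:13)
      if (layout == "wobble") {
        gpos <- nonseed[substr(rep(m, length(nonseed)), nonseed,
                               nonseed) == "G"]
        if (length(gpos) == 0L) layout <- "mismatch"
        else {
          p <- if (length(gpos) == 1L) gpos else sample(gpos, 1L)
          site <- .mutate_at(site, L - p + 1L, "T")  # G:C -> G:U wobble
          expected <- 0.5
        }
      }
      if (layout == "mismatch") {
        p <- if (length(nonseed) == 1L) nonseed else sample(nonseed, 1L)
        mat_base <- substr(m, p, p)
        site <- .mutate_at(site, L - p + 1L, .nonpairing_base(mat_base))
        expected <- 1
      }
      start <- sample(50:(tx_len - L - 50L), 1L)
      tx <- txs[[i]]
      txs[[i]] <- paste0(substr(tx, 1L, start - 1L), site,
                         substr(tx, start + L, tx_len))
      rows[[i]] <- data.frame(mirna = truth$mature_set$name[i],
                              transcript = names(txs)[i],
                              start = start, end = start + L - 1L,
                              layout = layout, expected_e = expected,
                              stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, rows)
    # reject accidental overlaps (one site per transcript by
    # construction, so only identical spans could collide)
    if (anyDuplicated(sites[c("transcript", "start")]))
      stop("span collision among planted target sites")
    list(transcripts = txs, sites = sites)
  })
}
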