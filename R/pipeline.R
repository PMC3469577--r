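#' Build and validate a pipeline configuration
#'
#' Collects every threshold of the analysis in one validated list. The
#' defaults are the working values of the whole pipeline: 18-27 nt
#' length window, 250 nt precursor window, at most six star mismatches,
#' G/C between 30 and 70 percent, two homology mismatches, |FC| > 2
#' with p < 0.05, and a target expectation cutoff of 3.
#'
#' @param min_len,max_len Read length bounds, nt.
#' @param min_overlap Minimum adapter overlap for trimming.
#' @param adapter 3' adapter sequence.
#' @param window Precursor window width, nt.
#' @param k Mapping seed length.
#' @param max_mismatches Mapping mismatch bound.
#' @param max_hits Multi-mapping cap.
#' @param max_star_mismatch Maximum unpaired mature positions.
#' @param gc_min,gc_max G/C bounds, percent.
#' @param min_paired_frac Stem-loop criterion: minimum fraction of
#'   mature positions paired.
#' @param homology_max_mm,max_len_diff Homology naming bounds.
#' @param fc_min,alpha Differential-expression filter.
#' @param e_max Target expectation cutoff.
#' @param prefix Species prefix for assigned names.
#' @param seed Integer seed recorded in the provenance record.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(min_len = 18, max_len = 27, min_overlap = 6,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       window = 250, k = 12, max_mismatches = 0,
                       max_hits = 15, max_star_mismatch = 6,
                       gc_min = 30, gc_max = 70, min_paired_frac = 0.6,
                       homology_max_mm = 2, max_len_diff = 2,
                       fc_min = 2, alpha = 0.05, e_max = 3,
                       prefix = "ssp", seed = 1) {
  cfg <- list(min_len = min_len, max_len = max_len,
              min_overlap = min_overlap, adapter = as_dna(adapter),
              window = window, k = k, max_mismatches = max_mismatches,
              max_hits = max_hits, max_star_mismatch = max_star_mismatch,
              gc_min = gc_min, gc_max = gc_max,
              min_paired_frac = min_paired_frac,
              homology_max_mm = homology_max_mm,
              max_len_diff = max_len_diff, fc_min = fc_min, alpha = alpha,
              e_max = e_max, prefix = prefix, seed = as.integer(seed))
  check_flag(cfg$min_len >= 1 && cfg$min_len <= cfg$max_len,
             "invalid length bounds")
  check_flag(cfg$min_overlap >= 6, "'min_overlap' must be >= 6")
  check_flag(cfg$window >= 50, "'window' must be >= 50")
  check_flag(cfg$k >= 8, "'k' must be >= 8")
  check_flag(cfg$max_mismatches >= 0, "'max_mismatches' must be >= 0")
  check_flag(cfg$max_hits >= 1, "'max_hits' must be >= 1")
  check_flag(cfg$max_star_mismatch >= 0, "'max_star_mismatch' must be >= 0")
  check_flag(cfg$gc_min >= 0 && cfg$gc_max <= 100 &&
               cfg$gc_min < cfg$gc_max, "invalid G/C bounds")
  check_flag(cfg$min_paired_frac > 0 && cfg$min_paired_frac <= 1,
             "'min_paired_frac' must be in (0, 1]")
  check_flag(cfg$homology_max_mm >= 0 && cfg$max_len_diff >= 0,
             "invalid homology bounds")
  check_flag(cfg$fc_min >= 1, "'fc_min' must be >= 1")
  check_flag(cfg$alpha > 0 && cfg$alpha < 1, "'alpha' must be in (0, 1)")
  check_flag(cfg$e_max >= 0, "'e_max' must be >= 0")
  class(cfg) <- "run_config"
  cfg
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# GFF3 emission of passing precursor windows (1-based inclusive).
.write_gff3 <- function(precursors, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(precursors) > 0) {
    lines <- sprintf(
      "%s\tmirseed\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;mfe=%s;gc=%s",
      precursors$ref, precursors$win_start + 1L, precursors$win_end,
      precursors$strand, precursors$assigned_name,
      fmt2(precursors$mfe), fmt2(precursors$gc))
    writeLines(lines, con)
  }
  path
}

#' Run the full small-RNA analysis pipeline
#'
#' Orchestrates preprocess -> classify -> map -> discover -> name ->
#' quantify -> differential expression -> targets over a manifest of
#' libraries, writes one TSV report per stage plus a JSON provenance
#' record into `out_dir`, and returns the result tables. Between
#' stages, read-count conservation is asserted (category totals must
#' partition each library) so that bookkeeping bugs abort loudly
#' instead of silently skewing the tables.
#'
#' Differential expression is evaluated for every (genotype, day) pair
#' of the manifest that has both a drought and an irrigated library,
#' mirroring the four drought-vs-irrigated contrasts of a 2-genotype x
#' 2-timepoint design.
#'
#' @param manifest Data frame with columns `library_id`, `genotype`,
#'   `condition` (`"irrigated"`/`"drought"`), `day`, and either `fastq`
#'   (paths) or a list column `reads`.
#' @param genome Named character vector of reference sequences, or a
#'   FASTA path.
#' @param annotations An [annotation_db()] (or named list of sets).
#' @param mature_ref Reference mature set for homology naming (named
#'   character vector or FASTA path).
#' @param config A [run_config()].
#' @param transcripts Optional transcript set for target scanning.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `libraries`, `categories`,
#'   `precursors`, `assignments`, `expression`, `diffexp`, `targets`
#'   and `files`.
#' @export
run_pipeline <- function(manifest, genome, annotations, mature_ref,
                         config = run_config(), transcripts = NULL,
                         out_dir) {
  stopifnot(inherits(config, "run_config"))
  need <- c("library_id", "genotype", "condition", "day")
  check_flag(all(need %in% names(manifest)), "incomplete manifest")
  check_flag(!anyDuplicated(manifest$library_id),
             "duplicate library ids in manifest")
  check_flag(all(manifest$condition %in% c("irrigated", "drought")),
             "unknown condition label in manifest")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  genome <- as_dna(genome)
  if (!inherits(annotations, "annotation_db"))
    annotations <- annotation_db(annotations)
  if (is.character(mature_ref) && length(mature_ref) == 1L &&
      file.exists(mature_ref))
    mature_ref <- read_fasta(mature_ref)

  # stage 1-2: preprocess and classify each library
  libs <- list()
  cat_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$library_id[i]
    reads <- if ("reads" %in% names(manifest)) manifest$reads[[i]]
             else read_fastq(manifest$fastq[i])
    pp <- preprocess_library(reads, config$adapter, config$min_overlap,
                             config$min_len, config$max_len)
    cls <- classify_reads(pp$collapsed, annotations)
    tab <- category_table(cls)
    conserved <- tab$total_count[tab$category == "total"] == pp$N
    check_flag(conserved, paste0("category totals do not partition ",
                                 "library ", id))
    libs[[id]] <- list(meta = manifest[i, need], collapsed = cls, N = pp$N)
    tab <- cbind(library = id, tab, stringsAsFactors = FALSE)
    cat_rows[[id]] <- tab
  }
  categories <- do.call(rbind, c(cat_rows, list(make.row.names = FALSE)))

  # stage 3-4: pooled unique reads -> mapping -> hairpin discovery
  pooled <- collapse_reads(rep(
    unlist(lapply(libs, function(l) l$collapsed$sequence), use.names = FALSE),
    unlist(lapply(libs, function(l) l$collapsed$count), use.names = FALSE)))
  index <- build_index(genome, k = config$k)
  mappable <- pooled[pooled$length >= config$k, , drop = FALSE]
  hits <- map_reads(mappable$sequence, index,
                    max_mismatches = config$max_mismatches,
                    max_hits = config$max_hits)
  candidates <- discover_hairpins(hits, genome, window = config$window,
                                  gc_min = config$gc_min,
                                  gc_max = config$gc_max,
                                  max_star_mismatch =
                                    config$max_star_mismatch,
                                  min_paired_frac = config$min_paired_frac)
  passing <- candidates[candidates$pass, , drop = FALSE]

  # stage 5: homology naming of distinct passing matures
  mat_seqs <- unique(passing$query)
  mat_counts <- vapply(mat_seqs, function(s)
    sum(pooled$count[pooled$sequence == s]), 0)
  assignments <- name_by_homology(
    data.frame(sequence = mat_seqs, count = unname(mat_counts),
               stringsAsFactors = FALSE),
    mature_ref, max_mm = config$homology_max_mm,
    max_len_diff = config$max_len_diff, prefix = config$prefix)
  passing <- merge(passing, assignments[c("sequence", "assigned_name")],
                   by.x = "query", by.y = "sequence")
  passing <- passing[order_radix(passing$assigned_name, passing$start), ,
                     drop = FALSE]

  # stage 6: per-library quantification of named matures
  expr <- assignments[order_radix(assignments$assigned_name),
                      c("assigned_name", "family", "sequence", "count"),
                      drop = FALSE]
  names(expr)[names(expr) == "count"] <- "total_count"
  for (id in names(libs)) {
    cc <- libs[[id]]$collapsed
    m <- match(expr$sequence, cc$sequence)
    expr[[paste0("count_", id)]] <- ifelse(is.na(m), 0L, cc$count[m])
    expr[[paste0("tpm_", id)]] <-
      tpm(expr[[paste0("count_", id)]], libs[[id]]$N)
  }
  rownames(expr) <- NULL

  # stage 7: drought-vs-irrigated contrasts per (genotype, day)
  meta <- do.call(rbind, lapply(libs, function(l) l$meta))
  de_rows <- list()
  for (g in unique(meta$genotype)) for (d in unique(meta$day)) {
    trt <- rownames(meta)[meta$genotype == g & meta$day == d &
                            meta$condition == "drought"]
    ctl <- rownames(meta)[meta$genotype == g & meta$day == d &
                            meta$condition == "irrigated"]
    if (length(trt) != 1L || length(ctl) != 1L) next
    rec <- data.frame(name = expr$assigned_name,
                      sequence = expr$sequence,
                      count_treated = expr[[paste0("count_", trt)]],
                      count_control = expr[[paste0("count_", ctl)]],
                      stringsAsFactors = FALSE)
    de <- call_differential(rec, libs[[trt]]$N, libs[[ctl]]$N,
                            fc_min = config$fc_min, alpha = config$alpha)
    de <- cbind(contrast = sprintf("%sD/%sI_day%s", g, g, d),
                genotype = g, day = d, de, stringsAsFactors = FALSE)
    de_rows[[length(de_rows) + 1L]] <- de
  }
  diffexp <- do.call(rbind, c(de_rows, list(make.row.names = FALSE)))

  # stage 8: target scanning
  targets <- NULL
  if (!is.null(transcripts)) {
    tx <- if (is.character(transcripts) && length(transcripts) == 1L &&
              file.exists(transcripts)) read_fasta(transcripts)
          else as_dna(transcripts)
    tg <- lapply(seq_len(nrow(assignments)), function(i)
      scan_targets(assignments$sequence[i], tx, e_max = config$e_max,
                   mirna_name = assignments$assigned_name[i]))
    targets <- do.call(rbind, c(tg, list(make.row.names = FALSE)))
  }

  # reports (all rounding centralized, two decimals half-up)
  files <- c(
    categories = .write_tsv(categories, file.path(out_dir,
                                                  "categories.tsv")),
    assignments = .write_tsv(assignments,
                             file.path(out_dir, "assignments.tsv")))
  prec_rep <- passing
  if (nrow(prec_rep) > 0) {
    prec_rep$mfe <- fmt2(prec_rep$mfe)
    prec_rep$gc <- fmt2(prec_rep$gc)
    prec_rep$start <- prec_rep$start + 1L   # report 1-based inclusive
    prec_rep$win_start <- prec_rep$win_start + 1L
  }
  files["precursors"] <- .write_tsv(prec_rep,
                                    file.path(out_dir, "precursors.tsv"))
  files["precursors_gff3"] <- .write_gff3(passing,
                                          file.path(out_dir,
                                                    "precursors.gff3"))
  expr_rep <- expr
  tpm_cols <- grep("^tpm_", names(expr_rep))
  for (j in tpm_cols) expr_rep[[j]] <- fmt2(expr_rep[[j]])
  files["expression"] <- .write_tsv(expr_rep,
                                    file.path(out_dir, "expression.tsv"))
  if (!is.null(diffexp) && nrow(diffexp) > 0) {
    de_rep <- diffexp
    de_rep$tpm_treated <- fmt2(de_rep$tpm_treated)
    de_rep$tpm_control <- fmt2(de_rep$tpm_control)
    de_rep$fc <- fmt2(de_rep$fc)
    de_rep$p <- formatC(de_rep$p, format = "g", digits = 4)
    files["diffexp"] <- .write_tsv(de_rep,
                                   file.path(out_dir, "diffexp.tsv"))
  }
  if (!is.null(targets)) {
    tg_rep <- targets
    if (nrow(tg_rep) > 0) tg_rep$expectation <- fmt2(tg_rep$expectation)
    files["targets"] <- .write_tsv(tg_rep,
                                   file.path(out_dir, "targets.tsv"))
  }
  prov <- list(package = "mirseed",
               version = as.character(packageVersion("mirseed")),
               config = unclass(config),
               manifest = manifest[need],
               library_sizes = setNames(
                 vapply(libs, function(l) l$N, 0), names(libs)),
               n_multimapped = length(attr(hits, "multimapped")))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files["provenance"] <- file.path(out_dir, "provenance.json")

  invisible(list(libraries = lapply(libs, function(l)
    list(meta = l$meta, N = l$N)),
    categories = categories, precursors = passing,
    candidates = candidates, assignments = assignments,
    expression = expr, diffexp = diffexp, targets = targets,
    files = files))
}
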