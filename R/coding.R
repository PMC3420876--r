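# Three-criterion coding-potential filter: transcript length, longest
# complete ORF, translated homology with known proteins. Stages are applied
# strictly in that order and each transcript receives exactly one status.

#' Pipeline configuration
#'
#' All tunable thresholds of the pipeline in one place. Defaults are the
#' standard operating point: 200 nt minimum transcript length (the
#' conventional lncRNA cutoff), 120 aa maximum complete ORF, e-value 0.001
#' for protein homology, 500 nt gene-model flanks, and coverage tier
#' boundaries at 98% and 50%.
#'
#' @param min_len_nt Minimum transcript length in nucleotides (kept when
#'   `length_nt >= min_len_nt`).
#' @param max_orf_aa Maximum longest-ORF size in amino acids (kept when
#'   `longest_orf_aa <= max_orf_aa`; 120 aa equals a 363 bp span including
#'   the stop codon).
#' @param evalue_max Homology threshold; a best hit with
#'   `evalue <= evalue_max` marks the transcript as coding.
#' @param smallrna_word_size Seed length used by BLAST-style short-sequence
#'   matching; retained for provenance but irrelevant once full-length exact
#'   matching is required.
#' @param flank_nt Gene-model flank width in nucleotides.
#' @param tier_hi,tier_lo Coverage tier boundaries as fractions; `tier_hi` is
#'   exclusive (high tier is coverage `> tier_hi`), `tier_lo` inclusive.
#' @param seed_k Seed k-mer length of the genomic aligner.
#' @param min_block_score Minimum ungapped block score retained by the
#'   genomic aligner (match +1, mismatch -2).
#' @param xdrop X-drop termination threshold for ungapped extension.
#' @param spliced_min_blocks,spliced_min_block_nt,spliced_min_gap_nt
#'   Operational definition of a spliced placement: at least
#'   `spliced_min_blocks` chained blocks of at least `spliced_min_block_nt`
#'   each, with every subject gap at least `spliced_min_gap_nt`.
#' @param max_chain_gap_nt Maximum subject gap allowed between consecutive
#'   blocks of one chain.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_len_nt = 200L, max_orf_aa = 120L,
                            evalue_max = 0.001, smallrna_word_size = 7L,
                            flank_nt = 500L, tier_hi = 0.98, tier_lo = 0.50,
                            seed_k = 11L, min_block_score = 25,
                            xdrop = 20, spliced_min_blocks = 2L,
                            spliced_min_block_nt = 20L,
                            spliced_min_gap_nt = 50L,
                            max_chain_gap_nt = 10000L) {
  vals <- as.list(environment())
  num <- unlist(vals[c(
    "min_len_nt", "max_orf_aa", "evalue_max", "smallrna_word_size",
    "flank_nt", "tier_hi", "tier_lo"
  )])
  if (any(num <= 0)) abort("all pipeline thresholds must be positive")
  if (!(tier_lo < tier_hi && tier_hi < 1)) {
    abort("tier boundaries must satisfy tier_lo < tier_hi < 1")
  }
  structure(vals, class = "pipeline_config")
}

# Karlin-Altschul constants for ungapped BLOSUM62 scoring
KA_LAMBDA <- 0.3176
KA_K <- 0.134

#' Convert a raw local-alignment score to a bit score and e-value
#'
#' Karlin-Altschul statistics with ungapped BLOSUM62 constants
#' (lambda = 0.3176, K = 0.134): `bits = (lambda * S - ln K) / ln 2` and
#' `E = m * n * 2^-bits`. An increase of one bit halves the e-value.
#'
#' @param raw_score Raw alignment score(s) in scoring-matrix units.
#' @param m Query length in residues.
#' @param n Total database size in residues.
#' @return A tibble with columns `bitscore`, `evalue`.
#' @export
karlin_altschul <- function(raw_score, m, n) {
  bits <- (KA_LAMBDA * raw_score - log(KA_K)) / log(2)
  tibble(bitscore = bits, evalue = m * n * 2^(-bits))
}

#' Length filter (criterion 1)
#'
#' Keeps transcripts at least `min_len_nt` nucleotides long; shorter ones
#' receive status `too_short`.
#'
#' @param ts A transcript tibble.
#' @param cfg A [pipeline_config()].
#' @return A list with `pass` (transcript tibble) and `fail` (verdict tibble
#'   with columns `transcript_id`, `status`, `orf_aa`, `best_protein`,
#'   `evalue`).
#' @export
filter_by_length <- function(ts, cfg = pipeline_config()) {
  assert_transcript_set(ts)
  keep <- ts$length_nt >= cfg$min_len_nt
  list(
    pass = ts[keep, , drop = FALSE],
    fail = verdict_tbl(ts$id[!keep], "too_short")
  )
}

#' Longest-ORF filter (criterion 2)
#'
#' Keeps transcripts whose longest complete forward-strand ORF is at most
#' `max_orf_aa` amino acids; larger ORFs mark the transcript `coding_orf`.
#'
#' @inheritParams filter_by_length
#' @param policy An [orf_policy()].
#' @return A list with `pass` (transcript tibble, with an `orf_aa` column
#'   added) and `fail` (verdict tibble).
#' @export
filter_by_orf <- function(ts, cfg = pipeline_config(), policy = orf_policy()) {
  assert_transcript_set(ts)
  orf_aa <- vapply(ts$seq, longest_orf_aa, integer(1), policy = policy,
                   USE.NAMES = FALSE)
  keep <- orf_aa <= cfg$max_orf_aa
  pass <- ts[keep, , drop = FALSE]
  pass$orf_aa <- orf_aa[keep]
  list(
    pass = pass,
    fail = verdict_tbl(ts$id[!keep], "coding_orf", orf_aa = orf_aa[!keep])
  )
}

verdict_tbl <- function(id, status, orf_aa = NA_integer_,
                        best_protein = NA_character_, evalue = NA_real_) {
  tibble(
    transcript_id = id,
    status = rep_len(status, length(id)),
    orf_aa = rep_len(as.integer(orf_aa), length(id)),
    best_protein = rep_len(best_protein, length(id)),
    evalue = rep_len(evalue, length(id))
  )
}

#' Read a protein FASTA file
#'
#' Upper-cases sequences; the 20 standard residues plus `B`, `Z`, `J`, `U`,
#' `X` and `*` are accepted.
#'
#' @param path Path to a protein FASTA file.
#' @return A tibble with columns `id`, `seq`, `length_aa`.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1)
  seqs <- toupper(as.character(x))
  if (length(seqs)) {
    if (anyDuplicated(ids)) {
      abort(paste0("duplicate protein id: ", ids[duplicated(ids)][1]))
    }
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYBZJUX*]", seqs)
    if (any(bad)) abort(paste0("invalid protein characters in '", ids[bad][1], "'"))
  }
  tibble(id = ids, seq = unname(seqs), length_aa = nchar(unname(seqs)))
}

#' Translated homology search (criterion 3)
#'
#' Translates the three forward frames of each transcript (reverse-strand
#' frames are never searched) and aligns each frame peptide locally against
#' every database protein (Smith-Waterman, BLOSUM62, affine gaps open 11 /
#' extend 1). Raw scores are converted to bit scores and e-values with
#' ungapped Karlin-Altschul constants, `m` being the frame peptide length and
#' `n` the total database residue count. The single best hit per transcript
#' is reported (lowest e-value, ties broken by higher raw score then
#' lexicographic protein id), provided its e-value is at most
#' `report_evalue_max`.
#'
#' @param ts A transcript tibble.
#' @param proteins A protein tibble from [read_protein_fasta()].
#' @param cfg A [pipeline_config()].
#' @param report_evalue_max Reporting ceiling for e-values (default 10).
#' @return A tibble with columns `transcript_id`, `protein_id`, `raw_score`,
#'   `bitscore`, `evalue`, `query_frame` (one row per transcript with a
#'   reportable hit).
#' @export
search_translated <- function(ts, proteins, cfg = pipeline_config(),
                              report_evalue_max = 10) {
  assert_transcript_set(ts)
  if (nrow(proteins) == 0) abort("protein database is empty")
  if (nrow(ts) == 0) return(empty_hits())

  frames <- tidyr::expand_grid(i = seq_len(nrow(ts)), frame = 0:2) |>
    mutate(
      transcript_id = ts$id[.data$i],
      peptide = purrr::map2_chr(.data$i, .data$frame,
                                ~ translate_frame(ts$seq[.x], .y)),
      m = nchar(.data$peptide)
    ) |>
    filter(.data$m > 0)
  if (nrow(frames) == 0) return(empty_hits())

  pats <- Biostrings::AAStringSet(frames$peptide)
  n_db <- sum(proteins$length_aa)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())

  per_protein <- lapply(seq_len(nrow(proteins)), function(j) {
    sc <- Biostrings::pairwiseAlignment(
      pats, Biostrings::AAString(proteins$seq[j]),
      type = "local", substitutionMatrix = mat,
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE
    )
    tibble(
      transcript_id = frames$transcript_id,
      protein_id = proteins$id[j],
      raw_score = sc,
      query_frame = frames$frame,
      m = frames$m
    )
  })
  hits <- bind_rows(per_protein)
  ka <- karlin_altschul(hits$raw_score, hits$m, n_db)
  hits$bitscore <- ka$bitscore
  hits$evalue <- ka$evalue
  hits |>
    arrange(.data$evalue, dplyr::desc(.data$raw_score), .data$protein_id) |>
    group_by(.data$transcript_id) |>
    slice(1) |>
    ungroup() |>
    filter(.data$evalue <= report_evalue_max) |>
    select("transcript_id", "protein_id", "raw_score", "bitscore",
           "evalue", "query_frame")
}

empty_hits <- function() {
  tibble(
    transcript_id = character(), protein_id = character(),
    raw_score = numeric(), bitscore = numeric(), evalue = numeric(),
    query_frame = integer()
  )
}

#' Import externally computed translated-search hits
#'
#' Adapter for BLAST tabular output (outfmt-6-like) so an external BLASTX run
#' can substitute for the built-in search. Expects tab-separated columns
#' `qseqid`, `sseqid`, `bitscore`, `evalue`, `qframe` with no header. Only
#' the best hit per transcript (lowest e-value, then highest bit score, then
#' lexicographic subject id) is retained.
#'
#' @param path Path to the tabular file.
#' @return A hit tibble as from [search_translated()] (`raw_score` is `NA`
#'   for imported hits).
#' @export
import_external_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(parts)
  if (any(nfld != 5)) {
    abort(paste0("malformed hit row at line ", which(nfld != 5)[1],
                 ": expected 5 tab-separated fields"))
  }
  m <- do.call(rbind, parts)
  bitscore <- suppressWarnings(as.numeric(m[, 3]))
  evalue <- suppressWarnings(as.numeric(m[, 4]))
  qframe <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(bitscore) | is.na(evalue) | is.na(qframe))
  if (length(bad)) {
    abort(paste0("malformed hit row at line ", bad[1], ": non-numeric field"))
  }
  tibble(
    transcript_id = m[, 1], protein_id = m[, 2],
    raw_score = NA_real_, bitscore = bitscore, evalue = evalue,
    query_frame = qframe
  ) |>
    arrange(.data$evalue, dplyr::desc(.data$bitscore), .data$protein_id) |>
    group_by(.data$transcript_id) |>
    slice(1) |>
    ungroup()
}

#' Export hits in the external tabular layout
#'
#' @param hits A hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  readr::write_tsv(
    hits |> select("transcript_id", "protein_id", "bitscore", "evalue",
                   "query_frame"),
    path,
    col_names = FALSE
  )
  invisible(path)
}

#' Homology verdict (criterion 3 decision)
#'
#' For transcripts that already passed the length and ORF filters: status
#' `coding_homology` if the transcript has a hit with
#' `evalue <= evalue_max` (boundary equality counts as coding, the
#' conservative choice), otherwise `noncoding`.
#'
#' @param ts A transcript tibble (with an `orf_aa` column if available).
#' @param hits A hit tibble from [search_translated()] or
#'   [import_external_hits()].
#' @param cfg A [pipeline_config()].
#' @return A verdict tibble with one row per transcript.
#' @export
classify_coding <- function(ts, hits, cfg = pipeline_config()) {
  assert_transcript_set(ts)
  orf_aa <- if ("orf_aa" %in% names(ts)) ts$orf_aa else NA_integer_
  best <- hits[match(ts$id, hits$transcript_id), , drop = FALSE]
  is_coding <- !is.na(best$evalue) & best$evalue <= cfg$evalue_max
  tibble(
    transcript_id = ts$id,
    status = ifelse(is_coding, "coding_homology", "noncoding"),
    orf_aa = as.integer(orf_aa),
    best_protein = best$protein_id,
    evalue = best$evalue
  )
}

#' Run the full three-criterion coding-potential filter
#'
#' Applies the length, ORF and homology filters sequentially (the order is
#' fixed) and returns one verdict per input transcript. The four statuses
#' `too_short`, `coding_orf`, `coding_homology`, `noncoding` partition the
#' input.
#'
#' @param ts A transcript tibble.
#' @param proteins A protein tibble, or `NULL` when `hits` is supplied.
#' @param cfg A [pipeline_config()].
#' @param hits Optional precomputed hit tibble (external search adapter);
#'   when given, `proteins` is ignored.
#' @param policy An [orf_policy()].
#' @return A verdict tibble (`transcript_id`, `status`, `orf_aa`,
#'   `best_protein`, `evalue`) in input order, with a `counts` attribute
#'   giving the per-status ledger.
#' @export
classify_coding_potential <- function(ts, proteins = NULL,
                                      cfg = pipeline_config(), hits = NULL,
                                      policy = orf_policy()) {
  st1 <- filter_by_length(ts, cfg)
  st2 <- filter_by_orf(st1$pass, cfg, policy)
  if (is.null(hits)) {
    if (is.null(proteins)) {
      abort("supply either a protein database or a precomputed hits table")
    }
    hits <- search_translated(st2$pass, proteins, cfg)
  }
  st3 <- classify_coding(st2$pass, hits, cfg)
  verdicts <- bind_rows(st1$fail, st2$fail, st3)
  verdicts <- verdicts[match(ts$id, verdicts$transcript_id), , drop = FALSE]
  attr(verdicts, "counts") <- table(factor(
    verdicts$status,
    levels = c("too_short", "coding_orf", "coding_homology", "noncoding")
  ))
  verdicts
}

#' Combine two noncoding callsets
#'
#' Standard set algebra over the id sets produced by two independent methods
#' (for example this pipeline and an external coding-potential classifier):
#' the union is the comprehensive candidate set, the intersection the most
#' stringent one.
#'
#' @param a,b Character vectors of transcript ids (or data frames with an
#'   `id` column).
#' @param label_a,label_b Method labels used in the summary.
#' @return A list with `union`, `intersection`, `only_a`, `only_b`
#'   (character vectors) and `summary` (a tibble of set sizes satisfying
#'   inclusion-exclusion).
#' @export
combine_callsets <- function(a, b, label_a = "method_a", label_b = "method_b") {
  ids <- function(x) if (is.data.frame(x)) unique(as.character(x$id)) else unique(as.character(x))
  a <- ids(a)
  b <- ids(b)
  res <- list(
    union = union(a, b),
    intersection = intersect(a, b),
    only_a = setdiff(a, b),
    only_b = setdiff(b, a)
  )
  res$summary <- tibble(
    set = c(label_a, label_b, "intersection", "union"),
    n = c(length(a), length(b), length(res$intersection), length(res$union))
  )
  res
}
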