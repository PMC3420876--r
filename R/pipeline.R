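# End-to-end orchestration: contaminant removal, coding-potential filter,
# callset combination, small-RNA precursor classification, genome
# localization, summaries and the run manifest.

#' Run the full lncRNA discovery pipeline
#'
#' Applies, in order: contaminant removal, the three-criterion
#' coding-potential filter, optional combination with a second method's
#' noncoding callset, small-RNA precursor classification with miRNA > shRNA
#' > siRNA precedence, reclassification of miRNA precursors that
#' sense-overlap a protein-coding gene body, auxiliary small-RNA tagging,
#' genome localization, and the class-by-location summary.
#'
#' @param transcripts Transcript tibble (from [read_fasta()]).
#' @param proteins Protein tibble, or `NULL` when `hits` is given.
#' @param mirna,shrna,sirna Small-RNA tibbles for the three sets.
#' @param genes Gene-model tibble ([read_gene_models()]); `NULL` skips
#'   localization.
#' @param genome Genome tibble; required with `genes`.
#' @param contaminants Optional contaminant tibble.
#' @param aux Optional auxiliary small-RNA tibble (e.g. Mop1-sensitive
#'   siRNAs); matches are tagged `aux`.
#' @param callset_b Optional character vector of noncoding ids from a second
#'   method; the candidate set becomes the union restricted to known
#'   transcripts.
#' @param hits Optional precomputed protein hit tibble.
#' @param cfg A [pipeline_config()].
#' @return An object of class `lnc_pipeline`: a list with `verdicts`,
#'   `candidates`, `classes`, `matches`, `multi_hit`, `localization`,
#'   `summary`, `removed`, `callsets`, `config`, `manifest`. Use [tidy()]
#'   for the per-transcript table and [glance()] for the one-row ledger.
#' @export
run_lnc_pipeline <- function(transcripts, proteins = NULL,
                             mirna, shrna, sirna,
                             genes = NULL, genome = NULL,
                             contaminants = NULL, aux = NULL,
                             callset_b = NULL, hits = NULL,
                             cfg = pipeline_config()) {
  n_input <- nrow(transcripts)
  removed <- tibble(id = character(), reason = character())
  if (!is.null(contaminants) && nrow(contaminants) > 0) {
    dec <- remove_contaminants(transcripts, contaminants)
    transcripts <- dec$kept
    removed <- dec$removed
  }

  verdicts <- classify_coding_potential(transcripts, proteins, cfg,
                                        hits = hits)
  noncoding_ids <- verdicts$transcript_id[verdicts$status == "noncoding"]

  callsets <- NULL
  cand_ids <- noncoding_ids
  if (!is.null(callset_b)) {
    callsets <- combine_callsets(noncoding_ids, callset_b,
                                 "pipeline", "external")
    cand_ids <- intersect(transcripts$id, callsets$union)
  }
  candidates <- transcripts |> filter(.data$id %in% cand_ids)

  mi_idx <- build_smallrna_index(mirna, "miRNA", c(18L, 23L))
  sh_idx <- build_smallrna_index(shrna, "shRNA", c(18L, 30L))
  si_idx <- build_smallrna_index(sirna, "siRNA", c(18L, 30L))
  classes <- classify_precursors(candidates, mi_idx, sh_idx, si_idx)
  matches <- attr(classes, "matches")

  localization <- NULL
  if (!is.null(genes) && !is.null(genome)) {
    localization <- localize_transcripts(candidates, genes, genome, cfg)
    # miRNA precursors sense-overlapping a protein-coding gene body
    body <- localization |>
      filter(.data$location == "genic", .data$orientation == "sense") |>
      left_join(genes |> select("gene_id", "gene_start", "gene_end"),
                by = "gene_id") |>
      filter(.data$s_end > .data$gene_start, .data$s_start < .data$gene_end)
    classes <- reclassify_mirna_hits(classes, body$transcript_id)
  }

  if (!is.null(aux) && nrow(aux) > 0) {
    aux_idx <- build_smallrna_index(aux, "aux", c(18L, 30L))
    classes <- annotate_aux(classes, candidates, aux_idx, "aux",
                            localization = localization)
  }

  summary <- if (!is.null(localization)) {
    summarize_candidates(classes, localization, candidates)
  } else {
    NULL
  }

  manifest <- list(
    n_input = n_input,
    n_contaminants_removed = nrow(removed),
    coding_counts = as.list(attr(verdicts, "counts")),
    n_candidates = nrow(candidates),
    class_counts = as.list(table(classes$klass)),
    location_counts = if (!is.null(localization)) {
      as.list(table(localization$location))
    } else {
      NULL
    },
    config = unclass(cfg),
    version = as.character(utils::packageVersion("lncscout"))
  )

  structure(
    list(
      verdicts = verdicts, candidates = candidates, classes = classes,
      matches = matches, multi_hit = count_multi_hit(classes),
      localization = localization, summary = summary, removed = removed,
      callsets = callsets, config = cfg, manifest = manifest
    ),
    class = "lnc_pipeline"
  )
}

#' @export
print.lnc_pipeline <- function(x, ...) {
  cat("<lnc_pipeline>\n")
  cat("  input transcripts: ", x$manifest$n_input, "\n", sep = "")
  cat("  contaminants removed: ", x$manifest$n_contaminants_removed, "\n",
      sep = "")
  cc <- x$manifest$coding_counts
  cat("  coding filter: ", paste(names(cc), unlist(cc), sep = "=",
                                 collapse = ", "), "\n", sep = "")
  kc <- x$manifest$class_counts
  cat("  classes: ", paste(names(kc), unlist(kc), sep = "=",
                           collapse = ", "), "\n", sep = "")
  if (!is.null(x$manifest$location_counts)) {
    lc <- x$manifest$location_counts
    cat("  locations: ", paste(names(lc), unlist(lc), sep = "=",
                               collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Per-transcript tidy table of a pipeline run
#'
#' One row per input transcript surviving contaminant removal, joining the
#' coding verdict with (for noncoding candidates) precursor class and
#' localization.
#'
#' @param x An `lnc_pipeline` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lnc_pipeline <- function(x, ...) {
  out <- x$verdicts |>
    left_join(x$classes |> select("transcript_id", "klass",
                                  "n_distinct_smallrnas"),
              by = "transcript_id")
  if (!is.null(x$localization)) {
    out <- out |>
      left_join(x$localization |>
                  select("transcript_id", "location", "gene_id", "coverage",
                         "tier", "category", "orientation", "spliced"),
                by = "transcript_id")
  }
  out
}

#' One-row ledger of a pipeline run
#'
#' @param x An `lnc_pipeline` object.
#' @param ... Unused.
#' @return A one-row tibble of stage counts.
#' @export
glance.lnc_pipeline <- function(x, ...) {
  m <- x$manifest
  tibble(
    n_input = m$n_input,
    n_contaminants_removed = m$n_contaminants_removed,
    n_too_short = m$coding_counts$too_short %||% 0L,
    n_coding_orf = m$coding_counts$coding_orf %||% 0L,
    n_coding_homology = m$coding_counts$coding_homology %||% 0L,
    n_noncoding = m$coding_counts$noncoding %||% 0L,
    n_candidates = m$n_candidates,
    n_smallrna_precursor = sum(unlist(m$class_counts[setdiff(
      names(m$class_counts), "lncRNA"
    )])),
    n_genic = m$location_counts$genic %||% NA_integer_,
    n_intergenic = m$location_counts$intergenic %||% NA_integer_
  )
}

#' Bar chart of precursor class sizes
#'
#' @param classes A classification tibble (or `lnc_pipeline` object).
#' @return A ggplot object.
#' @export
plot_class_counts <- function(classes) {
  if (inherits(classes, "lnc_pipeline")) classes <- classes$classes
  classes |>
    count(.data$klass) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$klass, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "transcripts",
                  title = "Precursor classification") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Stacked bar chart of genic/intergenic localization per class
#'
#' @param x An `lnc_pipeline` object with localization.
#' @return A ggplot object.
#' @export
plot_localization <- function(x) {
  stopifnot(inherits(x, "lnc_pipeline"), !is.null(x$localization))
  x$classes |>
    left_join(x$localization |> select("transcript_id", "location"),
              by = "transcript_id") |>
    count(.data$klass, .data$location) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$klass, y = .data$n,
                                 fill = .data$location)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "transcripts",
                  title = "Genic vs intergenic localization") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Default plot for a pipeline run
#'
#' @param object An `lnc_pipeline` object.
#' @param ... Unused.
#' @return A ggplot object ([plot_localization()] when localization was run,
#'   else [plot_class_counts()]).
#' @export
autoplot.lnc_pipeline <- function(object, ...) {
  if (!is.null(object$localization)) plot_localization(object)
  else plot_class_counts(object$classes)
}

#' Write the run manifest as JSON
#'
#' @param x An `lnc_pipeline` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  jsonlite::write_json(x$manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write per-transcript verdicts as TSV
#'
#' @param verdicts A verdict tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_verdicts_tsv <- function(verdicts, path) {
  readr::write_tsv(verdicts, path)
  invisible(path)
}

#' Write the precursor class table as TSV
#'
#' @param classes A classification tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classes_tsv <- function(classes, path) {
  out <- classes
  if ("aux_tags" %in% names(out)) {
    out$aux_tags <- vapply(out$aux_tags, paste, character(1), collapse = ";")
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write the localization table as TSV
#'
#' @param loc A localization tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localization_tsv <- function(loc, path) {
  readr::write_tsv(loc, path)
  invisible(path)
}
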