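# Sequence-composition and ledger summaries.

#' GC content of a nucleotide sequence
#'
#' `(G + C) / (A + C + G + T)`; `N`s are excluded from both numerator and
#' denominator (exclusion, not counting N as AT, is the unbiased choice).
#' An empty or all-N sequence yields 0 with an `all_n` attribute flag.
#'
#' @param seq Character vector of nucleotide strings.
#' @return Numeric vector of fractions in `[0, 1]`; attribute `all_n` marks
#'   entries with no unambiguous base.
#' @export
#' @examples
#' gc_content(c("GGCC", "ATAT", "ANGC"))
gc_content <- function(seq) {
  seq <- toupper(seq)
  gc <- nchar(gsub("[^GC]", "", seq))
  acgt <- nchar(gsub("[^ACGT]", "", seq))
  out <- ifelse(acgt > 0, gc / acgt, 0)
  attr(out, "all_n") <- acgt == 0
  out
}

#' Class-by-location summary table with derived percentages
#'
#' Builds the per-(class, location) ledger over all classified, localized
#' candidates: transcript counts, total length, mean length, and GC fraction
#' (computed over the concatenated bases of the cell). Derived percentages:
#' the small-RNA-containing share of all candidates (one decimal place) and
#' the genic share within each class (whole percent). Raw fractions are
#' retained alongside the rounded values.
#'
#' @param classes A classification tibble from [classify_precursors()] (or
#'   after [reclassify_mirna_hits()]).
#' @param localizations A localization tibble from
#'   [localize_transcripts()].
#' @param candidates The candidate transcript tibble.
#' @return A list with `table` (tibble `klass`, `location`, `n_transcripts`,
#'   `total_nt`, `mean_len`, `gc_fraction`), `smallrna_share` (list with
#'   `fraction`, `pct`), and `genic_share_by_class` (tibble `klass`,
#'   `fraction`, `pct`).
#' @export
summarize_candidates <- function(classes, localizations, candidates) {
  assert_transcript_set(candidates, "candidates")
  missing <- setdiff(candidates$id, classes$transcript_id)
  if (length(missing)) {
    abort(paste0("candidate without classification: ", missing[1]))
  }
  missing_loc <- setdiff(candidates$id, localizations$transcript_id)
  if (length(missing_loc)) {
    abort(paste0("candidate without localization: ", missing_loc[1]))
  }
  dat <- candidates |>
    left_join(classes |> select("transcript_id", "klass"),
              by = c(id = "transcript_id")) |>
    left_join(localizations |> select("transcript_id", "location"),
              by = c(id = "transcript_id"))
  tab <- dat |>
    group_by(.data$klass, .data$location) |>
    summarise(
      n_transcripts = n(),
      total_nt = sum(.data$length_nt),
      mean_len = mean(.data$length_nt),
      gc_fraction = as.numeric(gc_content(paste(.data$seq, collapse = ""))),
      .groups = "drop"
    )
  precursor_classes <- c(
    "miRNA_precursor", "shRNA_precursor", "siRNA_precursor",
    "genic_siRNA_precursor_reclassified"
  )
  n_total <- nrow(dat)
  n_small <- sum(dat$klass %in% precursor_classes)
  genic <- dat |>
    group_by(.data$klass) |>
    summarise(
      fraction = mean(.data$location == "genic"),
      .groups = "drop"
    ) |>
    mutate(pct = round_half_up(100 * .data$fraction, 0))
  list(
    table = tab,
    smallrna_share = list(
      fraction = if (n_total > 0) n_small / n_total else NA_real_,
      pct = if (n_total > 0) round_half_up(100 * n_small / n_total, 1) else NA_real_
    ),
    genic_share_by_class = genic
  )
}

# round half away from zero to `digits` decimal places (printed-precision
# convention for prose percentages; base round() is half-to-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write the class-by-location summary as TSV
#'
#' @param summary A [summarize_candidates()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summary, path) {
  readr::write_tsv(summary$table, path)
  invisible(path)
}
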