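#' ORF scanning policy
#'
#' Controls which codons start and stop an open reading frame. Defaults match
#' the forward-strand, complete-ORF definition used by the coding-potential
#' filter: ATG starts, the three standard stops, forward frames only.
#'
#' @param start_codons Character vector of start codons (default `"ATG"`).
#' @param stop_codons Character vector of stop codons
#'   (default `c("TAA","TAG","TGA")`).
#' @param forward_only Logical; reverse-strand ORFs are never scanned when
#'   `TRUE` (the default, and the only supported mode).
#' @return A list of class `orf_policy`.
#' @export
orf_policy <- function(start_codons = "ATG",
                       stop_codons = c("TAA", "TAG", "TGA"),
                       forward_only = TRUE) {
  start_codons <- toupper(start_codons)
  stop_codons <- toupper(stop_codons)
  if (!length(start_codons) || !length(stop_codons)) {
    abort("start and stop codon sets must be non-empty")
  }
  if (length(intersect(start_codons, stop_codons))) {
    abort("start and stop codon sets must be disjoint")
  }
  structure(
    list(
      start_codons = start_codons, stop_codons = stop_codons,
      forward_only = isTRUE(forward_only)
    ),
    class = "orf_policy"
  )
}

#' Find all maximal complete ORFs on the forward strand
#'
#' A complete ORF starts with a start codon, ends at the first in-frame stop
#' codon lying inside the sequence, and contains no internal stop. Only
#' maximal ORFs are reported: a start codon in-frame inside a reported ORF
#' necessarily reaches the same stop and is suppressed. A codon containing
#' `N` is neither a start nor a stop and neither begins nor terminates an
#' ORF. The three forward frames are scanned; coordinates are 0-based
#' half-open and `end_nt` is one past the last base of the stop codon.
#'
#' @param seq A single nucleotide string over `{A,C,G,T,N}`.
#' @param policy An [orf_policy()].
#' @return A tibble with columns `start_nt`, `end_nt`, `frame`, `aa_len`
#'   (peptide length excluding the stop codon), sorted by `start_nt`.
#' @export
#' @examples
#' find_complete_orfs("ATGAAATAG")
find_complete_orfs <- function(seq, policy = orf_policy()) {
  seq <- toupper(seq)
  n <- nchar(seq)
  out <- list()
  for (frame in 0:2) {
    n_codons <- (n - frame) %/% 3
    if (n_codons < 2) next
    starts_at <- frame + 3 * (seq_len(n_codons) - 1)        # 0-based codon offsets
    codons <- substring(seq, starts_at + 1, starts_at + 3)
    is_start <- codons %in% policy$start_codons
    is_stop <- codons %in% policy$stop_codons
    # segment index: which stop-delimited segment each codon belongs to
    seg <- cumsum(is_stop) - is_stop  # stops belong to the segment they close
    stop_idx <- which(is_stop)
    if (!length(stop_idx)) next
    for (si in stop_idx) {
      in_seg <- which(seg == seg[si] & seq_along(codons) < si)
      cand <- in_seg[is_start[in_seg]]
      if (!length(cand)) next
      first_start <- min(cand)
      s0 <- starts_at[first_start]
      e0 <- starts_at[si] + 3
      out[[length(out) + 1]] <- tibble(
        start_nt = s0, end_nt = e0, frame = frame,
        aa_len = as.integer((e0 - s0 - 3) / 3)
      )
    }
  }
  if (!length(out)) {
    return(tibble(
      start_nt = integer(), end_nt = integer(),
      frame = integer(), aa_len = integer()
    ))
  }
  bind_rows(out) |> arrange(.data$start_nt, .data$end_nt)
}

#' Longest complete ORF length in amino acids
#'
#' The maximum `aa_len` over [find_complete_orfs()]; `0` when the sequence
#' contains no complete ORF (known noncoding transcripts such as enod40
#' genuinely have none).
#'
#' @inheritParams find_complete_orfs
#' @return A single integer.
#' @export
longest_orf_aa <- function(seq, policy = orf_policy()) {
  hits <- find_complete_orfs(seq, policy)
  if (nrow(hits) == 0) 0L else max(hits$aa_len)
}

GENETIC_CODE_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  # codons enumerated with the third base varying fastest within each block
  codons <- apply(expand.grid(b3 = bases, b2 = bases, b1 = bases)[, 3:1], 1, paste, collapse = "")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  setNames(aas, codons)
})

#' Translate one forward frame
#'
#' Standard genetic code; codons containing `N` translate to `X`, stop codons
#' render as `*`, and a trailing partial codon is dropped.
#'
#' @param seq A nucleotide string.
#' @param frame Frame offset, one of 0, 1, 2.
#' @return The peptide string.
#' @export
#' @examples
#' translate_frame("ATGAAATAG", 0)
translate_frame <- function(seq, frame = 0) {
  stopifnot(frame %in% 0:2)
  seq <- toupper(seq)
  n_codons <- (nchar(seq) - frame) %/% 3
  if (is.na(n_codons) || n_codons < 1) return("")
  at <- frame + 3 * (seq_len(n_codons) - 1)
  codons <- substring(seq, at + 1, at + 3)
  aa <- unname(GENETIC_CODE_TABLE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
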