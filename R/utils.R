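# Shared low-level helpers. All coordinates in this package are 0-based,
# half-open; conversion to/from 1-based formats happens only at the GFF3/BED
# boundary.

IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U")

#' Reverse complement of a nucleotide string
#'
#' Plain-character reverse complement over the `{A,C,G,T,N}` alphabet.
#' `N` complements to `N`.
#'
#' @param seq A character vector of nucleotide strings.
#' @return A character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(seq) {
  stringr::str_to_upper(chartr("ACGTN", "TGCAN", vapply(seq, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)))
}

# Validate and normalise raw sequence strings: uppercase, ambiguity codes other
# than N collapse to N (warning), anything outside IUPAC is a hard error.
normalize_nt <- function(seq, ids) {
  seq <- stringr::str_to_upper(seq)
  seq <- gsub("U", "T", seq, fixed = TRUE)
  ambig <- paste(setdiff(IUPAC_AMBIG, "U"), collapse = "")
  has_ambig <- grepl(paste0("[", ambig, "]"), seq)
  if (any(has_ambig)) {
    warn(paste0(
      "IUPAC ambiguity codes other than N found in ",
      sum(has_ambig), " record(s); converted to N (first: ",
      ids[which(has_ambig)[1]], ")"
    ))
    seq[has_ambig] <- gsub(paste0("[", ambig, "]"), "N", seq[has_ambig])
  }
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    abort(paste0(
      "non-nucleotide characters in record '", ids[which(bad)[1]], "'"
    ))
  }
  seq
}

# tibble constructor shared by read_fasta() and the simulator
new_transcript_set <- function(id, seq, source_label = "") {
  ts <- tibble(id = as.character(id), seq = as.character(seq)) |>
    mutate(length_nt = nchar(.data$seq))
  attr(ts, "source_label") <- source_label
  ts
}

assert_transcript_set <- function(ts, arg = "ts") {
  if (!is.data.frame(ts) || !all(c("id", "seq") %in% names(ts))) {
    abort(paste0("`", arg, "` must be a data frame with columns id, seq"))
  }
  if (anyDuplicated(ts$id)) {
    abort(paste0("duplicate transcript id: ", ts$id[duplicated(ts$id)][1]))
  }
  invisible(ts)
}

# Seeded RNG scope: runs code under a local RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
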