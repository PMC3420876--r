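#' Read transcript sequences from a FASTA file
#'
#' Reads a nucleotide FASTA file into a transcript tibble. The header token
#' before the first whitespace becomes the transcript `id`; sequences are
#' upper-cased on ingestion and `U` is converted to `T`. IUPAC ambiguity codes
#' other than `N` are collapsed to `N` with a warning; `N` never matches
#' anything in downstream exact-match or alignment scoring. Any other
#' character, a duplicate id, or an empty sequence record is a hard error.
#'
#' @param path Path to a FASTA file.
#' @param source_label Optional label recorded as an attribute of the result.
#' @return A tibble with columns `id`, `seq`, `length_nt`, in file order.
#' @seealso [write_fasta()], [remove_contaminants()]
#' @export
read_fasta <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1)
  if (length(ids) && anyNA(ids)) abort("FASTA record with empty header")
  seqs <- as.character(x)
  if (length(seqs)) {
    if (any(nchar(seqs) == 0)) {
      abort(paste0("empty sequence record: ", ids[nchar(seqs) == 0][1]))
    }
    if (anyDuplicated(ids)) {
      abort(paste0("duplicate transcript id: ", ids[duplicated(ids)][1]))
    }
    seqs <- normalize_nt(seqs, ids)
  }
  new_transcript_set(ids, unname(seqs), source_label = source_label)
}

#' Write a transcript tibble to FASTA
#'
#' Standard FASTA output with 60-column line wrapping. Round-trips with
#' [read_fasta()] on `(id, seq)` pairs.
#'
#' @param ts A transcript tibble (columns `id`, `seq`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ts, path) {
  assert_transcript_set(ts)
  x <- Biostrings::BStringSet(setNames(ts$seq, ts$id))
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}

#' Remove contaminating sequences from a transcript set
#'
#' A record is removed if and only if its full sequence string equals a
#' contaminant's full sequence string (exact, case-insensitive). Matching is
#' on sequence content, not on record ids; survivors keep their input order.
#'
#' @param ts A transcript tibble.
#' @param contaminants A transcript tibble of contaminant sequences.
#' @return A list with elements `kept` (transcript tibble) and `removed`
#'   (tibble with columns `id`, `reason`), such that
#'   `nrow(kept) + nrow(removed) == nrow(ts)`.
#' @export
remove_contaminants <- function(ts, contaminants) {
  assert_transcript_set(ts)
  assert_transcript_set(contaminants, "contaminants")
  hit <- toupper(ts$seq) %in% toupper(contaminants$seq)
  list(
    kept = ts[!hit, , drop = FALSE],
    removed = tibble(
      id = ts$id[hit],
      reason = rep("matches_contaminant", sum(hit))
    )
  )
}

#' Write a removal report as TSV
#'
#' @param removed The `removed` tibble from [remove_contaminants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_removal_report <- function(removed, path) {
  readr::write_tsv(removed, path)
  invisible(path)
}

#' Read gene models from GFF3 plus a genome FASTA
#'
#' Builds one gene model per `gene` feature: exons (and `CDS`,
#' `five_prime_UTR`, `three_prime_UTR` sub-features attached to the gene
#' directly or through an intermediate mRNA), introns inferred as the gaps
#' between consecutive exons, and up/downstream flanks of at most `flank_nt`
#' bases, truncated at chromosome ends. The upstream flank is on the 5' side
#' of the gene with respect to its strand. All coordinates in the returned
#' tibble are 0-based half-open; the GFF3 1-based inclusive convention is
#' converted at this boundary.
#'
#' @param gff_path Path to a GFF3 file with gene/exon/CDS/UTR features.
#' @param genome_path Path to the genome FASTA containing every chromosome
#'   referenced by the GFF3.
#' @param flank_nt Flank width in nucleotides (default 500).
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `gene_start`, `gene_end`, `chrom_len`, and list-columns `exons`,
#'   `introns`, `utr5`, `utr3`, `cds`, `flank_up`, `flank_down`, each a
#'   two-column matrix `(start, end)`.
#' @export
read_gene_models <- function(gff_path, genome_path, flank_nt = 500) {
  flank_nt <- as.integer(flank_nt)
  gff <- rtracklayer::import(gff_path, format = "gff3")
  genome <- read_fasta(genome_path)
  chrom_len <- setNames(genome$length_nt, genome$id)

  meta <- as.data.frame(gff)
  meta$type <- as.character(meta$type)
  genes <- meta[meta$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) {
    return(empty_gene_model_set())
  }
  gene_ids <- as.character(genes$ID)

  # map every feature to its owning gene: direct Parent, or Parent via mRNA
  parent1 <- vapply(meta$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_, character(1))
  tx_rows <- meta$type %in% c("mRNA", "transcript")
  tx_parent <- setNames(parent1[tx_rows], as.character(meta$ID[tx_rows]))
  owner <- ifelse(parent1 %in% gene_ids, parent1, unname(tx_parent[parent1]))

  rows <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- gene_ids[i]
    chrom <- as.character(genes$seqnames[i])
    if (!chrom %in% names(chrom_len)) {
      abort(paste0("chromosome '", chrom, "' of gene ", gid, " missing from genome"))
    }
    clen <- chrom_len[[chrom]]
    g0 <- genes$start[i] - 1L
    g1 <- genes$end[i]
    strand <- as.character(genes$strand[i])
    if (!strand %in% c("+", "-")) strand <- "+"

    feat <- function(type) {
      sel <- meta$type == type & !is.na(owner) & owner == gid
      iv <- cbind(start = meta$start[sel] - 1L, end = meta$end[sel])
      iv[order(iv[, 1]), , drop = FALSE]
    }
    exons <- feat("exon")
    if (nrow(exons) == 0) exons <- cbind(start = g0, end = g1)
    if (any(exons[, 1] < g0) || any(exons[, 2] > g1)) {
      abort(paste0("exon outside gene bounds for gene ", gid))
    }
    introns <- if (nrow(exons) > 1) {
      cbind(start = exons[-nrow(exons), 2], end = exons[-1, 1])
    } else {
      matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
    }
    left <- cbind(start = max(0L, g0 - flank_nt), end = g0)
    right <- cbind(start = g1, end = min(clen, g1 + flank_nt))
    tibble(
      gene_id = gid, chrom = chrom, strand = strand,
      gene_start = g0, gene_end = g1, chrom_len = clen,
      exons = list(exons), introns = list(introns),
      utr5 = list(feat("five_prime_UTR")), utr3 = list(feat("three_prime_UTR")),
      cds = list(feat("CDS")),
      flank_up = list(if (strand == "+") left else right),
      flank_down = list(if (strand == "+") right else left)
    )
  })
  out <- bind_rows(rows)
  attr(out, "flank_nt") <- flank_nt
  out
}

empty_gene_model_set <- function() {
  tibble(
    gene_id = character(), chrom = character(), strand = character(),
    gene_start = integer(), gene_end = integer(), chrom_len = integer(),
    exons = list(), introns = list(), utr5 = list(), utr3 = list(),
    cds = list(), flank_up = list(), flank_down = list()
  )
}

# genomic extent of the full gene region (body + both flanks), 0-based half-open
gene_region_bounds <- function(gene_row) {
  c(
    min(gene_row$flank_up[[1]][, 1], gene_row$flank_down[[1]][, 1], gene_row$gene_start),
    max(gene_row$flank_up[[1]][, 2], gene_row$flank_down[[1]][, 2], gene_row$gene_end)
  )
}
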