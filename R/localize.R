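# Genome localization of noncoding candidates: genic vs intergenic calls,
# gene-body coverage tiers, sub-genic categories, and orientation relative to
# the host gene.

interval_overlap_len <- function(a0, a1, b0, b1) {
  pmax(0, pmin(a1, b1) - pmax(a0, b0))
}

footprint_of <- function(chain) {
  c(min(chain$blocks$s_start), max(chain$blocks$s_end))
}

#' Gene-body coverage, tier and spliced flag for a genic chain
#'
#' Coverage is the fraction of gene-body bases (UTR start to UTR end; flanks
#' excluded from the denominator) covered by at least one chain block. A
#' chain is spliced when it has at least `spliced_min_blocks` blocks, each at
#' least `spliced_min_block_nt` long, with every subject gap at least
#' `spliced_min_gap_nt`. Tier is `high` when coverage exceeds `tier_hi` or
#' the chain is spliced, `mid` when coverage lies in `[tier_lo, tier_hi]`
#' (both ends inclusive), and `low` otherwise.
#'
#' @param chain An [chain_blocks()] result.
#' @param gene A single-row gene-model tibble.
#' @param cfg A [pipeline_config()].
#' @return A list with `coverage`, `tier`, `spliced`.
#' @export
coverage_and_tier <- function(chain, gene, cfg = pipeline_config()) {
  b <- chain$blocks
  body_len <- gene$gene_end - gene$gene_start
  cov_len <- sum(interval_overlap_len(
    b$s_start, b$s_end, gene$gene_start, gene$gene_end
  ))
  coverage <- if (body_len > 0) cov_len / body_len else 0
  lens <- b$s_end - b$s_start
  spliced <- chain$n_blocks >= cfg$spliced_min_blocks &&
    all(lens >= cfg$spliced_min_block_nt) &&
    length(chain$subject_gaps) > 0 &&
    all(chain$subject_gaps >= cfg$spliced_min_gap_nt)
  tier <- if (coverage > cfg$tier_hi || spliced) {
    "high"
  } else if (coverage >= cfg$tier_lo) {
    "mid"
  } else {
    "low"
  }
  list(coverage = coverage, tier = tier, spliced = spliced)
}

touches <- function(fp, iv) {
  nrow(iv) > 0 && any(interval_overlap_len(fp[1], fp[2], iv[, 1], iv[, 2]) > 0)
}

within_one <- function(fp, iv) {
  nrow(iv) > 0 && any(fp[1] >= iv[, 1] & fp[2] <= iv[, 2])
}

#' Sub-genic category of a genic placement
#'
#' Uses the footprint (subject extent) of the highest-scoring chain on the
#' gene's features. High tier: `spliced_over_gene` for spliced chains, else
#' `spans_upstream_to_downstream` when the footprint reaches both flanks,
#' else `spans_utr5_to_utr3`. Mid tier: the first matching of
#' `includes_upstream`, `includes_downstream`, `includes_utr5`,
#' `includes_utr3`, else `internal`. Low tier: `within_<feature>` when the
#' footprint lies wholly inside one feature interval (upstream/downstream
#' flank, UTR, intron, CDS); otherwise a `spans_multiple_*` category
#' subdivided by whether the footprint reaches the upstream or downstream
#' flank.
#'
#' @param chain The chain used for the genic call.
#' @param gene A single-row gene-model tibble.
#' @param tier Coverage tier from [coverage_and_tier()].
#' @param spliced Spliced flag from [coverage_and_tier()].
#' @return A category string.
#' @export
subgenic_category <- function(chain, gene, tier, spliced = FALSE) {
  fp <- footprint_of(chain)
  region <- gene_region_bounds(gene)
  if (fp[2] <= region[1] || fp[1] >= region[2]) {
    abort("chain footprint is disjoint from the gene region")
  }
  fu <- gene$flank_up[[1]]
  fd <- gene$flank_down[[1]]
  utr5 <- gene$utr5[[1]]
  utr3 <- gene$utr3[[1]]
  if (tier == "high") {
    if (spliced) return("spliced_over_gene")
    if (touches(fp, fu) && touches(fp, fd)) {
      return("spans_upstream_to_downstream")
    }
    return("spans_utr5_to_utr3")
  }
  if (tier == "mid") {
    if (touches(fp, fu)) return("includes_upstream")
    if (touches(fp, fd)) return("includes_downstream")
    if (touches(fp, utr5)) return("includes_utr5")
    if (touches(fp, utr3)) return("includes_utr3")
    return("internal")
  }
  # low tier
  if (within_one(fp, fu)) return("within_upstream")
  if (within_one(fp, fd)) return("within_downstream")
  if (within_one(fp, utr5)) return("within_utr5")
  if (within_one(fp, utr3)) return("within_utr3")
  if (within_one(fp, gene$introns[[1]])) return("within_intron")
  if (within_one(fp, gene$cds[[1]])) return("within_cds")
  if (touches(fp, fu)) return("spans_multiple_including_upstream")
  if (touches(fp, fd)) return("spans_multiple_including_downstream")
  "spans_multiple_internal"
}

#' Orientation of a placement relative to its host gene
#'
#' @param chain_strand Chain strand, `"+"` or `"-"` (genome forward
#'   convention).
#' @param gene_strand Annotated gene strand.
#' @return `"sense"` when the strands agree, else `"antisense"`.
#' @export
orientation_call <- function(chain_strand, gene_strand) {
  if (chain_strand == gene_strand) "sense" else "antisense"
}

empty_localization <- function() {
  tibble(
    transcript_id = character(), location = character(),
    gene_id = character(), coverage = double(), tier = character(),
    category = character(), orientation = character(), spliced = logical(),
    chain_score = double(), chrom = character(), strand = character(),
    s_start = integer(), s_end = integer()
  )
}

#' Localize one transcript in the genome
#'
#' Aligns the transcript to the genome, chains blocks per chromosome and
#' strand, and calls the placement `genic` when the best chain restricted to
#' some gene-model region (gene body plus flanks) scores at least as high as
#' the best genome-wide chain; `intergenic` when the genome aligns but no
#' gene region qualifies; `unmapped` when nothing aligns. Among qualifying
#' genes the winner has the highest chain score, ties broken by higher
#' coverage then lexicographic gene id.
#'
#' @param transcript_id Transcript id for the output.
#' @param seq Transcript sequence.
#' @param genes A gene-model tibble from [read_gene_models()].
#' @param index A [build_genome_index()] over the same genome.
#' @param cfg A [pipeline_config()].
#' @return A one-row localization tibble: `transcript_id`, `location`,
#'   `gene_id`, `coverage`, `tier`, `category`, `orientation`, `spliced`,
#'   `chain_score`, `chrom`, `strand`, `s_start`, `s_end`.
#' @export
locate_transcript <- function(transcript_id, seq, genes, index,
                              cfg = pipeline_config()) {
  blocks <- align_to_genome(seq, index, cfg)
  na_row <- tibble(
    transcript_id = transcript_id, location = "unmapped",
    gene_id = NA_character_, coverage = NA_real_, tier = NA_character_,
    category = NA_character_, orientation = NA_character_, spliced = NA,
    chain_score = NA_real_, chrom = NA_character_, strand = NA_character_,
    s_start = NA_integer_, s_end = NA_integer_
  )
  if (nrow(blocks) == 0) return(na_row)

  chains <- blocks |>
    group_by(.data$chrom, .data$strand) |>
    dplyr::group_map(~ chain_blocks(.x |> mutate(
      chrom = .y$chrom, strand = .y$strand
    ), cfg$max_chain_gap_nt))
  best_overall <- max(vapply(chains, `[[`, numeric(1), "total_score"))

  best_gene <- NULL
  for (gi in seq_len(nrow(genes))) {
    gene <- genes[gi, ]
    region <- gene_region_bounds(gene)
    gb <- blocks |>
      filter(.data$chrom == gene$chrom,
             .data$s_start >= region[1], .data$s_end <= region[2])
    if (nrow(gb) == 0) next
    for (st in unique(gb$strand)) {
      ch <- chain_blocks(gb |> filter(.data$strand == st), cfg$max_chain_gap_nt)
      ct <- coverage_and_tier(ch, gene, cfg)
      cand <- list(gene = gene, chain = ch, strand = st, ct = ct)
      if (is.null(best_gene) ||
          ch$total_score > best_gene$chain$total_score ||
          (ch$total_score == best_gene$chain$total_score &&
           (ct$coverage > best_gene$ct$coverage ||
            (ct$coverage == best_gene$ct$coverage &&
             gene$gene_id < best_gene$gene$gene_id)))) {
        best_gene <- cand
      }
    }
  }

  if (!is.null(best_gene) &&
      best_gene$chain$total_score >= best_overall) {
    g <- best_gene$gene
    ch <- best_gene$chain
    ct <- best_gene$ct
    fp <- footprint_of(ch)
    return(tibble(
      transcript_id = transcript_id, location = "genic",
      gene_id = g$gene_id, coverage = ct$coverage, tier = ct$tier,
      category = subgenic_category(ch, g, ct$tier, ct$spliced),
      orientation = orientation_call(best_gene$strand, g$strand),
      spliced = ct$spliced, chain_score = ch$total_score,
      chrom = g$chrom, strand = best_gene$strand,
      s_start = as.integer(fp[1]), s_end = as.integer(fp[2])
    ))
  }

  # intergenic: report the best genome-wide chain's footprint
  bi <- which.max(vapply(chains, `[[`, numeric(1), "total_score"))
  ch <- chains[[bi]]
  fp <- footprint_of(ch)
  tibble(
    transcript_id = transcript_id, location = "intergenic",
    gene_id = NA_character_, coverage = NA_real_, tier = NA_character_,
    category = NA_character_, orientation = NA_character_,
    spliced = NA, chain_score = ch$total_score,
    chrom = ch$blocks$chrom[1], strand = ch$blocks$strand[1],
    s_start = as.integer(fp[1]), s_end = as.integer(fp[2])
  )
}

#' Localize a set of candidates
#'
#' Vectorized driver over [locate_transcript()]; builds the genome index
#' once.
#'
#' @param candidates A transcript tibble.
#' @param genes A gene-model tibble.
#' @param genome A genome tibble (chromosome sequences).
#' @param cfg A [pipeline_config()].
#' @return A localization tibble with one row per candidate.
#' @export
localize_transcripts <- function(candidates, genes, genome,
                                 cfg = pipeline_config()) {
  assert_transcript_set(candidates, "candidates")
  if (nrow(candidates) == 0) return(empty_localization())
  index <- build_genome_index(genome, k = cfg$seed_k)
  bind_rows(lapply(seq_len(nrow(candidates)), function(i) {
    locate_transcript(candidates$id[i], candidates$seq[i], genes, index, cfg)
  }))
}

#' Export candidate placements as a BED track
#'
#' 0-based half-open BED with name, score (chain score, capped at 1000) and
#' strand.
#'
#' @param loc A localization tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localization_bed <- function(loc, path) {
  mapped <- loc |> filter(.data$location != "unmapped")
  bed <- tibble(
    chrom = mapped$chrom,
    start = mapped$s_start,
    end = mapped$s_end,
    name = mapped$transcript_id,
    score = pmin(1000, round(mapped$chain_score)),
    strand = mapped$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
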