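# helpers building synthetic chains and gene rows for the pure interval logic
mk_chain <- function(blocks_df, strand = "+") {
  blocks_df$chrom <- blocks_df$chrom %||% "chr1"
  structure(
    list(
      blocks = blocks_df, total_score = sum(blocks_df$score),
      n_blocks = nrow(blocks_df),
      subject_gaps = if (nrow(blocks_df) > 1) {
        blocks_df$s_start[-1] - blocks_df$s_end[-nrow(blocks_df)]
      } else {
        numeric(0)
      }
    ),
    class = "alignment_chain"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mk_block <- function(s_start, s_end, q_start = 0L, strand = "+") {
  tibble::tibble(
    chrom = "chr1", strand = strand, q_start = q_start,
    q_end = q_start + (s_end - s_start),
    s_start = s_start, s_end = s_end,
    score = s_end - s_start, identity = 1
  )
}

# a deterministic gene row: body [1000, 2000), 3 exons, UTRs 150 nt
mk_gene <- function(strand = "+") {
  exons <- cbind(start = c(1000L, 1400L, 1800L), end = c(1300L, 1700L, 2000L))
  introns <- cbind(start = c(1300L, 1700L), end = c(1400L, 1800L))
  left_u <- cbind(start = 1000L, end = 1150L)
  right_u <- cbind(start = 1850L, end = 2000L)
  cds <- cbind(start = c(1150L, 1400L, 1800L), end = c(1300L, 1700L, 1850L))
  left_f <- cbind(start = 500L, end = 1000L)
  right_f <- cbind(start = 2000L, end = 2500L)
  tibble::tibble(
    gene_id = "gX", chrom = "chr1", strand = strand,
    gene_start = 1000L, gene_end = 2000L, chrom_len = 10000L,
    exons = list(exons), introns = list(introns),
    utr5 = list(if (strand == "+") left_u else right_u),
    utr3 = list(if (strand == "+") right_u else left_u),
    cds = list(cds),
    flank_up = list(if (strand == "+") left_f else right_f),
    flank_down = list(if (strand == "+") right_f else left_f)
  )
}

test_that("coverage, tier boundaries and the spliced flag are exact", {
  g <- mk_gene()
  cfg <- pipeline_config()

  full <- coverage_and_tier(mk_chain(mk_block(1000L, 2000L)), g, cfg)
  expect_equal(full$coverage, 1)
  expect_equal(full$tier, "high")
  expect_false(full$spliced)

  sixty <- coverage_and_tier(mk_chain(mk_block(1100L, 1700L)), g, cfg)
  expect_equal(sixty$coverage, 0.6)
  expect_equal(sixty$tier, "mid")

  # boundaries: coverage exactly tier_hi (unspliced) and tier_lo are mid
  at_hi <- coverage_and_tier(mk_chain(mk_block(1000L, 1980L)), g, cfg)
  expect_equal(at_hi$coverage, 0.98)
  expect_equal(at_hi$tier, "mid")
  at_lo <- coverage_and_tier(mk_chain(mk_block(1000L, 1500L)), g, cfg)
  expect_equal(at_lo$coverage, 0.5)
  expect_equal(at_lo$tier, "mid")
  below <- coverage_and_tier(mk_chain(mk_block(1000L, 1499L)), g, cfg)
  expect_equal(below$tier, "low")

  # two exon-sized blocks with a large gap: spliced, hence high
  spl <- coverage_and_tier(
    mk_chain(dplyr::bind_rows(mk_block(1000L, 1300L),
                              mk_block(1400L, 1700L, q_start = 300L))),
    g, cfg
  )
  expect_true(spl$spliced)
  expect_equal(spl$tier, "high")

  # coverage of a sub-chain never increases
  expect_lte(
    coverage_and_tier(mk_chain(mk_block(1000L, 1300L)), g, cfg)$coverage,
    spl$coverage
  )
})

test_that("sub-genic categories follow the tiered footprint rules", {
  g <- mk_gene()

  high_ud <- mk_chain(mk_block(800L, 2200L))
  expect_equal(subgenic_category(high_ud, g, "high", FALSE),
               "spans_upstream_to_downstream")
  high_utr <- mk_chain(mk_block(1000L, 2000L))
  expect_equal(subgenic_category(high_utr, g, "high", FALSE),
               "spans_utr5_to_utr3")
  expect_equal(subgenic_category(high_utr, g, "high", TRUE),
               "spliced_over_gene")

  mid_up <- mk_chain(mk_block(900L, 1600L))
  expect_equal(subgenic_category(mid_up, g, "mid", FALSE), "includes_upstream")
  mid_u5 <- mk_chain(mk_block(1050L, 1650L))
  expect_equal(subgenic_category(mid_u5, g, "mid", FALSE), "includes_utr5")
  mid_int <- mk_chain(mk_block(1160L, 1760L))
  expect_equal(subgenic_category(mid_int, g, "mid", FALSE), "internal")

  expect_equal(subgenic_category(mk_chain(mk_block(1310L, 1390L)), g, "low",
                                 FALSE), "within_intron")
  expect_equal(subgenic_category(mk_chain(mk_block(600L, 900L)), g, "low",
                                 FALSE), "within_upstream")
  expect_equal(subgenic_category(mk_chain(mk_block(1160L, 1290L)), g, "low",
                                 FALSE), "within_cds")
  expect_equal(subgenic_category(mk_chain(mk_block(1100L, 1350L)), g, "low",
                                 FALSE), "spans_multiple_internal")
  expect_equal(subgenic_category(mk_chain(mk_block(900L, 1200L)), g, "low",
                                 FALSE), "spans_multiple_including_upstream")

  expect_error(
    subgenic_category(mk_chain(mk_block(5000L, 5200L)), g, "low", FALSE),
    "disjoint"
  )
})

test_that("orientation is the agreement of chain and gene strand", {
  expect_equal(orientation_call("+", "+"), "sense")
  expect_equal(orientation_call("-", "+"), "antisense")
  # flipping the gene strand flips the call
  g_plus <- mk_gene("+")
  g_minus <- mk_gene("-")
  expect_false(
    orientation_call("+", g_plus$strand) == orientation_call("+", g_minus$strand)
  )
})

test_that("planted placements localize to the right gene and location", {
  toy <- toy_locus()
  g <- toy$genes[2, ]
  cfg <- pipeline_config()
  chrom_seq <- toy$genome$seq[toy$genome$id == g$chrom]

  # verbatim copy from the first intron (3-exon genes have introns)
  gi <- which(vapply(seq_len(nrow(toy$genes)),
                     function(i) nrow(toy$genes$introns[[i]]) > 0, logical(1)))
  g <- toy$genes[gi[1], ]
  intr <- g$introns[[1]][1, ]
  q_in <- substr(chrom_seq, intr[1] + 1, intr[2])
  loc <- locate_transcript("q_in", q_in, toy$genes, toy$index, cfg)
  expect_equal(loc$location, "genic")
  expect_equal(loc$gene_id, g$gene_id)
  expect_equal(loc$category, "within_intron")
  expect_equal(loc$orientation, "sense")

  # antisense copy
  loc_a <- locate_transcript("q_anti", revcomp(q_in), toy$genes, toy$index, cfg)
  expect_equal(loc_a$location, "genic")
  expect_equal(loc_a$orientation, "antisense")

  # copy from far outside every gene region
  bounds <- vapply(seq_len(nrow(toy$genes)), function(i) {
    c(toy$genes$gene_start[i] - 600, toy$genes$gene_end[i] + 600)
  }, numeric(2))
  far <- 25000
  while (any(far >= bounds[1, ] & far <= bounds[2, ])) far <- far + 500
  q_out <- substr(chrom_seq, far + 1, far + 400)
  loc_o <- locate_transcript("q_out", q_out, toy$genes, toy$index, cfg)
  expect_equal(loc_o$location, "intergenic")

  # garbage never maps
  withr::with_seed(2, q_bad <- rand_nt(300))
  loc_b <- locate_transcript("q_bad", q_bad, toy$genes, toy$index, cfg)
  expect_equal(loc_b$location, "unmapped")
})

test_that("locations partition the candidate set", {
  r <- get_run()
  loc <- r$localization
  expect_equal(nrow(loc), nrow(r$candidates))
  expect_equal(sum(table(loc$location)), nrow(r$candidates))
  expect_true(all(loc$coverage >= 0 & loc$coverage <= 1, na.rm = TRUE))
  expect_true(all(!is.na(loc$gene_id[loc$location == "genic"])))
  expect_true(all(is.na(loc$gene_id[loc$location != "genic"])))
})
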