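# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

# full-size synthetic study (default design) and the pipeline run over it
get_study <- function() {
  if (is.null(.fixture_env$study)) {
    dir <- file.path(tempdir(), "lncscout_study")
    .fixture_env$study <- simulate_lnc_study(dir, seed = 101L)
  }
  .fixture_env$study
}

get_run <- function() {
  if (is.null(.fixture_env$run)) {
    s <- get_study()
    .fixture_env$run <- run_lnc_pipeline(
      transcripts = s$transcripts,
      proteins = s$proteins,
      mirna = s$smallrna$miRNA,
      shrna = s$smallrna$shRNA,
      sirna = s$smallrna$siRNA,
      genes = s$genes,
      genome = s$genome,
      contaminants = s$contaminants,
      aux = s$smallrna$aux,
      callset_b = s$callset_b
    )
  }
  .fixture_env$run
}

# reduced design for fast pipeline-level tests
small_design <- function() {
  lnc_design(
    n_too_short = 2, n_coding_orf = 3, n_coding_homology = 2,
    n_intergenic = 14,
    genic_plan = tibble::tibble(
      category = c("spans_utr5_to_utr3", "within_intron", "spliced_over_gene",
                   "includes_upstream", "within_upstream", "within_cds"),
      orientation = c("sense", "antisense", "sense", "antisense", "sense",
                      "antisense")
    ),
    n_mirna = 3, n_shrna = 3, n_sirna = 6,
    n_decoy_proteins = 5, n_decoy_smallrna = 2, n_contaminants = 5
  )
}

get_small_study <- function() {
  if (is.null(.fixture_env$small)) {
    dir <- file.path(tempdir(), "lncscout_small")
    .fixture_env$small <- simulate_lnc_study(
      dir, seed = 7L, design = small_design(),
      n_chrom = 2, chrom_len = 60000L, n_genes = 12
    )
  }
  .fixture_env$small
}

expected_class_of <- function(truth) {
  klmap <- c(miRNA = "miRNA_precursor", shRNA = "shRNA_precursor",
             siRNA = "siRNA_precursor", lncRNA = "lncRNA")
  ifelse(
    truth$true_class == "miRNA" & truth$true_location == "genic" &
      truth$true_orientation == "sense",
    "genic_siRNA_precursor_reclassified",
    unname(klmap[truth$true_class])
  )
}

# one-gene toy locus used by localization unit tests
toy_locus <- function(seed = 5) {
  if (!is.null(.fixture_env$toy)) return(.fixture_env$toy)
  res <- withr::with_seed(seed, {
    genome <- make_genome(1, 30000L)
    genes <- make_gene_models(genome, 3)
    list(genome = genome, genes = genes,
         index = build_genome_index(genome))
  })
  .fixture_env$toy <- res
  res
}
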