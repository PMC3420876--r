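---
title: "Methods: identifying and classifying long noncoding RNAs with lncscout"
author: "lncscout maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and classifying long noncoding RNAs with lncscout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Plant transcriptomes contain many polyadenylated transcripts with no evident
protein-coding capacity. Some act as intact long noncoding RNAs (lncRNAs),
others are precursors that are processed into small regulatory RNAs (miRNAs,
hairpin-derived shRNAs, siRNAs of the RNA-directed DNA methylation pathway).
`lncscout` implements a complete discovery pipeline for such transcripts:

1. **Coding-potential filtering** — three sequential criteria decide whether
   a transcript is plausibly noncoding.
2. **Small-RNA precursor classification** — exact full-length matching
   against miRNA/shRNA/siRNA sets, with class precedence.
3. **Genome localization** — genic versus intergenic placement relative to
   gene models, gene-body coverage tiers, sub-genic categories, and
   sense/antisense orientation.

Every stage takes a tibble and returns a tibble, so runs compose with the
pipe; `run_lnc_pipeline()` orchestrates the whole analysis and its result
supports `tidy()`, `glance()` and `autoplot()`.

## The coding-potential filter

Transcripts are judged by three criteria in a fixed order; each transcript
receives exactly one status, so the four statuses partition the input (a
ledger property the tests enforce).

**Criterion 1 — length.** Transcripts shorter than `min_len_nt` (default
200 nt) are `too_short`. 200 nt is the conventional boundary separating
lncRNAs from the classes of short RNAs (miRNAs, piRNAs, promoter- and
terminator-associated RNAs).

**Criterion 2 — longest complete ORF.** A complete ORF starts at `ATG`,
ends at the first in-frame stop *inside* the sequence, and contains no
internal stop. Only the three forward frames are scanned — the pipeline
assumes oriented cDNA input — and only maximal ORFs are reported (an
in-frame internal `ATG` necessarily reaches the same stop). Codons
containing `N` are neither starts nor stops and never terminate an ORF.
Transcripts whose longest ORF exceeds `max_orf_aa` (default 120 aa) are
`coding_orf`. The amino-acid count excludes the stop codon, so the 120 aa
threshold corresponds to a 363 bp nucleotide span including the stop.
Well-characterized lncRNAs motivate the default: of fourteen
literature-curated examples (shipped in
`inst/extdata/known_lncrna_orf_aa.tsv`), only three carry an ORF above
120 aa, while a well-annotated protein-coding control set has ORFs of
103 aa and up — 120 aa retains most true lncRNAs at an acceptable
protein-coding carry-through.

**Criterion 3 — translated homology.** The three forward-frame
translations (stops rendered `*`, `N`-codons `X`) are aligned locally
against a protein reference with Smith–Waterman scoring (BLOSUM62, affine
gaps open 11 / extend 1; the alignment engine is
`Biostrings::pairwiseAlignment`, cross-checked in the tests against an
independent full-matrix DP oracle). Raw scores are converted with
Karlin–Altschul statistics using the ungapped BLOSUM62 constants
$\lambda = 0.3176$, $K = 0.134$:

$$S' = \frac{\lambda S - \ln K}{\ln 2}, \qquad E = m\,n\,2^{-S'}$$

with $m$ the frame peptide length and $n$ the total database residues. The
best hit per transcript is kept (lowest e-value, ties by higher raw score,
then lexicographic protein id — determinism matters more than the
tie-break itself). A hit at $E \le$ `evalue_max` (default 0.001; boundary
equality counts as coding, the conservative choice) makes the transcript
`coding_homology`; otherwise it is `noncoding`. Applying ungapped constants
to gapped alignments slightly overstates significance; this is adequate at
fixture-scale databases, and `import_external_hits()` accepts tabular
output of an external translated search (e.g. BLASTX against Swissprot)
as the fidelity path for real data.

Two independent methods can be merged with `combine_callsets()`
(`union`, `intersection`, `only_a`, `only_b` under exact
inclusion–exclusion): the union is the comprehensive candidate set, the
intersection the stringent one.

## Small-RNA precursor classification

A candidate is a precursor of a small RNA only if it contains the *complete*
small-RNA sequence exactly. `match_small_rnas()` therefore implements exact
full-length substring containment on either strand, over a length-partitioned
deduplicated index (`build_smallrna_index()`; miRNA lengths 18–23 nt,
shRNA/siRNA 18–30 nt by default). This is mathematically the same contract
as a seeded 100%-identity BLASTN search followed by a full-length filter,
but deterministic and simpler; the suite proves equivalence against a naive
sliding-window oracle. `N` never matches anything.

Classification applies sequential precedence **miRNA > shRNA > siRNA**: any
miRNA match decides the class regardless of other matches; class assignment
is therefore independent of index iteration order (a tested invariant).
Candidates matching nothing are intact lncRNAs. `n_distinct_smallrnas`
counts distinct small-RNA *sequences* (a small RNA occurring twice in one
transcript counts once), feeding the per-class multi-hit table
(`count_multi_hit()`).

Two refinements mirror downstream curation steps:

* `reclassify_mirna_hits()` — a miRNA-matching candidate whose genomic
  placement sense-overlaps a protein-coding gene body is more plausibly a
  genic siRNA precursor and is relabelled
  `genic_siRNA_precursor_reclassified`. The rule touches only the miRNA
  class.
* `annotate_aux()` — tags candidates containing members of an auxiliary
  small-RNA set (for instance siRNAs whose accumulation depends on an
  RNA-dependent RNA polymerase such as maize Mop1), with a
  class-by-location summary.

## Genome localization

### Alignment and chaining

`align_to_genome()` is a seed-and-extend aligner: exact k-mer seeds
(`seed_k`, default 11) looked up in a precomputed genome index, extended
ungapped in both directions with x-drop termination (`xdrop`, default 20)
under match +1 / mismatch −2 scoring. Blocks scoring below
`min_block_score` (default 25) are discarded — 25 demands a ~25 nt
near-exact run, which random sequence essentially never produces at
fixture scale, so surviving blocks reflect planted or genuine homology.
Both strands are searched by also seeding the reverse-complemented query;
minus-strand block query coordinates refer to the reverse-complemented
query so query and subject positions increase together.

Extension across an exon–intron junction can overrun by a few lucky bases.
The aligner therefore returns *non-redundant* blocks: where two blocks
overlap on the query, the lower-scoring block is trimmed (and rescored, and
dropped if it falls below `min_block_score`). Chains built from these
blocks are strictly monotone and non-overlapping in both query and subject.
`chain_blocks()` finds the maximum-total-score colinear chain by dynamic
programming over blocks sorted by subject start, with subject gaps capped
at `max_chain_gap_nt` (default 10 kb, generous against intron-scale gaps);
the tests verify it against brute-force chain enumeration.

### Genic versus intergenic

A gene model is the transcribed region — 5′UTR, exons, introns, 3′UTR —
plus `flank_nt` (default 500 nt) up- and downstream, truncated at
chromosome ends. `locate_transcript()` calls a candidate **genic** when the
best chain over blocks contained in some gene region scores at least as
high as the best genome-wide chain (ties go to the gene — placement
"within a gene model" is preferred); **intergenic** when the genome aligns
but no gene region qualifies; **unmapped** otherwise. Among genes, the
winner has the highest chain score, ties broken by higher coverage then
lexicographic gene id.

### Coverage tiers, categories, orientation

Coverage is the fraction of **gene-body** bases (UTR start to UTR end;
flanks excluded from the denominator) covered by at least one chain block.
Keeping flanks out of the denominator is what makes the high-tier
distinction between "spans upstream-to-downstream" and "spans 5′UTR-to-3′UTR"
well defined; it is the package's chosen reading where the convention was
genuinely open, and the main place a different convention would shift
numbers on real data.

A placement is **spliced** when the chain has at least `spliced_min_blocks`
(2) blocks, each at least `spliced_min_block_nt` (20 nt), with every
subject gap at least `spliced_min_gap_nt` (50 nt). These are operational
constants — "spliced" has no standard alignment-level definition — and are
exposed in `pipeline_config()`.

Tiers: **high** if coverage > `tier_hi` (0.98, strict) *or* spliced;
**mid** if coverage lies in `[tier_lo, tier_hi]` = [0.50, 0.98], both ends
inclusive; **low** otherwise. The category then refines the tier using the
footprint (subject extent) of the winning chain:

| tier | categories |
|------|------------|
| high | `spliced_over_gene`; `spans_upstream_to_downstream` (footprint reaches both flanks); else `spans_utr5_to_utr3` |
| mid  | first match of `includes_upstream`, `includes_downstream`, `includes_utr5`, `includes_utr3`; else `internal` |
| low  | `within_<feature>` when wholly inside one feature interval (upstream/downstream flank, UTR, intron, CDS); else `spans_multiple_including_upstream` / `_including_downstream` / `_internal` |

The mid-tier check order (flanks before UTRs) is a deterministic precedence
for footprints that touch several features; it is documented rather than
configurable. Orientation is simply **sense** when the chain strand equals
the annotated gene strand, **antisense** otherwise.

All coordinates are 0-based half-open internally; GFF3 (1-based inclusive)
is converted at the parsing boundary and BED exports are 0-based.

## The synthetic study generator

`simulate_lnc_study()` emits everything the pipeline consumes — genome
FASTA, GFF3 gene models, transcript/contaminant/protein FASTA, per-class
small-RNA FASTA, a second-method callset, and a planted-truth table — from
one integer seed driving a single RNG stream, so identical seeds give
byte-identical bundles.

The default design defines the study conditions: 3 chromosomes × 120 kb of
uniform random sequence; 40 genes (exon counts cycling 1–4; exons
260–450 nt, introns 250–400 nt, UTRs 230–320 nt; ≥ 2.2 kb inter-gene
spacing so 500 nt flanks never collide); 10 sub-length transcripts; 25
long-ORF coding transcripts whose translations enter the protein set; 8
homology-coding transcripts carrying an 80 aa peptide embedded verbatim in
a database protein; one genic noncoding candidate per sub-genic category ×
orientation (34 in all, each on its own gene); 130 intergenic candidates;
and an overlay of 12 miRNA / 30 shRNA / 80 siRNA precursors embedding 1–4
small RNAs sampled from their own sequence (every third one
reverse-complemented so antisense matching is exercised), the remainder
intact lncRNAs. One of 20 contaminants is planted into the transcript set.
The sizes keep a full generate-classify-localize cycle around a minute on
one core while covering every label the pipeline can produce.

Planted labels are guaranteed **by construction**, not merely with high
probability: candidate windows are rejection-sampled until the planted
transcript has longest ORF ≤ 120 aa *and* no protein hit at E ≤ 0.001
(otherwise a genome copy could accidentally look coding); each planted
small RNA is verified to occur — on either strand — in its source
transcript only, and decoy small RNAs/proteins are verified to match no
candidate. Genes are assigned fewest-exons-first so categories needing
intron or middle-exon structure always find a suitable gene. Infeasible
designs fail loudly rather than degrade.

What the generator does *not* emulate: repeat content and GC landscape of
a real plant genome, expression levels, sequencing error, splice-isoform
diversity, or mutations between transcript and genome (a `mutation_rate`
knob is reserved but fixed at 0). Passing the recovery suite therefore
shows the logic is exact on clean data; it does not bound accuracy on
noisy real data, where the external-BLAST adapter and real references are
the intended path.

## Numerical and degenerate-input choices

* Ambiguity codes other than `N` collapse to `N` on ingestion (with a
  warning); `N` never matches in exact matching and always mismatches in
  alignment scoring. Empty FASTA files and empty candidate sets flow
  through as empty tibbles.
* GC content excludes `N` from numerator and denominator (the unbiased
  choice); all-`N` input yields 0 with a flag.
* Prose-style percentages are rounded half away from zero at the printed
  precision (one decimal for shares of the candidate set, whole percents
  for per-class shares); raw fractions are always retained.
* Contaminant removal compares full sequence strings case-insensitively,
  never record ids.
* Ties anywhere (best hit, best gene, chain choice) break
  deterministically, so reruns are byte-stable.

## Problem sizes used by the checks

The test suite exercises the ORF scanner against an exhaustive
start/stop-pair oracle on 2,000 random sequences, the exact matcher against
a sliding-window oracle on 1,000 transcript/index pairs, the aligner
against a Smith–Waterman DP oracle on 200 ungapped-optimal instances, and
chaining against brute-force enumeration on block sets of up to 15; the
end-to-end recovery checks run the full default study (208 transcripts,
164 candidates). `scripts/acceptance.R` regenerates the study under the
given seed and recomputes every recovery rate from scratch.

## Known limitations

* E-values from the built-in search are ungapped-calibrated; absolute
  values are approximate for gapped alignments (ranking is unaffected at
  these scales).
* One canonical model per gene; overlapping or multi-isoform loci are not
  resolved beyond the deterministic tie-break.
* The aligner is built for fixture-scale genomes (≤ a few Mb); it has no
  whole-genome performance engineering.
* shRNA labels are taken from the input set; no hairpin/secondary-structure
  prediction is attempted. Repetitive-element and motif analyses are out of
  scope (external masked-base counts can be tabulated but not produced).
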