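# lncscout

Identification and genomic classification of long noncoding RNAs (lncRNAs)
from transcript sets, written for plant transcriptomes where many noncoding
transcripts are precursors of small regulatory RNAs.

`lncscout` is aimed at analysts who have a set of assembled, genome-mapped
transcripts (full-length cDNAs or comparable) and want to know which of them
are plausibly noncoding, which of those are small-RNA precursors, and where
they sit relative to annotated genes. Everything is tibble-in / tibble-out,
so stages compose with the pipe; a thin command-line front end
(`inst/cli/lncscout.R`) wraps the same functions.

## The method

**1. Coding-potential filter** — three sequential criteria partition the
input into `too_short`, `coding_orf`, `coding_homology`, and `noncoding`:

* transcript length ≥ 200 nt;
* longest complete forward-strand ORF (ATG … in-sequence stop, no internal
  stop) ≤ 120 aa — equivalently a 363 bp span including the stop;
* no local alignment of any forward-frame translation against the protein
  reference at *E* ≤ 0.001, with Smith–Waterman scoring (BLOSUM62, gap open
  11 / extend 1) and Karlin–Altschul statistics

  S′ = (λS − ln K)/ln 2,  E = m·n·2^(−S′),  λ = 0.3176, K = 0.134.

Callsets from two methods (e.g. this filter and an external SVM classifier)
combine by set algebra: the union is the comprehensive candidate set, the
intersection the stringent one.

**2. Small-RNA precursor classification** — a candidate containing the
*complete* sequence of a known small RNA, exactly, on either strand, is a
precursor; class precedence is miRNA > shRNA > siRNA, candidates matching
nothing remain intact lncRNAs. miRNA-matching candidates that sense-overlap
a protein-coding gene body are reclassified as genic siRNA precursors, and
an auxiliary set (e.g. RNA-dependent-RNA-polymerase-dependent siRNAs) can
be used for tagging.

**3. Genome localization** — a seed-and-extend aligner (11-mer seeds,
ungapped x-drop extension, +1/−2) plus colinear chaining place each
candidate as genic (within a gene model: UTRs, exons, introns ± 500 nt
flanks), intergenic, or unmapped. Genic placements get a gene-body coverage
tier (>98% or spliced / 50–98% / <50%), a sub-genic category
(`spliced_over_gene`, `spans_upstream_to_downstream`, `within_intron`,
`within_cds`, …), and sense/antisense orientation.

A deterministic generator (`simulate_lnc_study()`) builds a toy genome,
gene models, proteins, small-RNA sets and transcripts with planted ground
truth for **every** decision above, so the whole pipeline is testable end
to end. See the methods vignette (`vignettes/lncscout-methods.Rmd`) for
the full model description and design rationale.

## Worked example

```r
library(lncscout)

study <- simulate_lnc_study(tempfile("study"), seed = 1)
res <- run_lnc_pipeline(
  transcripts  = study$transcripts,
  proteins     = study$proteins,
  mirna        = study$smallrna$miRNA,
  shrna        = study$smallrna$shRNA,
  sirna        = study$smallrna$siRNA,
  genes        = study$genes,
  genome       = study$genome,
  contaminants = study$contaminants,
  aux          = study$smallrna$aux,
  callset_b    = study$callset_b
)
res
#> <lnc_pipeline>
#>   input transcripts: 208
#>   contaminants removed: 1
#>   coding filter: too_short=10, coding_orf=25, coding_homology=8, noncoding=164
#>   classes: genic_siRNA_precursor_reclassified=1, lncRNA=42, miRNA_precursor=11, shRNA_precursor=30, siRNA_precursor=80
#>   locations: genic=34, intergenic=130
```

Of 208 input transcripts, one matched a contaminant sequence and was
removed; 10 were under 200 nt, 25 carried an ORF over 120 aa, 8 had a
significant protein homolog, and 164 survived as noncoding candidates.
Among those, 121 contain at least one known small RNA (11 miRNA + 30 shRNA
+ 80 siRNA precursors, plus 1 miRNA-matching candidate reclassified as a
genic siRNA precursor), and 34 of the 164 placements are genic. Per-class
location counts come from the tidy table:

```r
library(dplyr)
tidy(res) |> filter(status == "noncoding") |> count(klass, location)
#> # A tibble: 9 × 3
#>   klass                              location       n
#>   <chr>                              <chr>      <int>
#> 1 genic_siRNA_precursor_reclassified genic          1
#> 2 lncRNA                             genic         12
#> 3 lncRNA                             intergenic    30
#> 4 miRNA_precursor                    genic          1
#> 5 miRNA_precursor                    intergenic    10
#> 6 shRNA_precursor                    genic          5
#> 7 shRNA_precursor                    intergenic    25
#> 8 siRNA_precursor                    genic         15
#> 9 siRNA_precursor                    intergenic    65
```

`glance(res)` gives the one-row ledger, `autoplot(res)` the class-by-location
bar chart, and the `write_*` helpers export verdicts, classes, localizations
(TSV/BED) and the run manifest (JSON).

Because the study is planted, every one of these calls can be checked
against `study$truth` — on noiseless fixtures recovery of coding status,
precursor class, location, coverage tier, sub-genic category and
orientation is exactly 100%.

## Command line

```sh
Rscript inst/cli/lncscout.R simulate --seed 1 --out simdata
Rscript inst/cli/lncscout.R run-all --dir simdata --out run_out
Rscript inst/cli/lncscout.R filter --fasta tx.fa --proteins prot.fa --out filt
```

Subcommands: `simulate`, `filter`, `combine`, `classify`, `localize`,
`stats`, `run-all`; thresholds are exposed as flags (`--min-len`,
`--max-orf-aa`, `--evalue`, `--flank`, `--tier-hi`, `--tier-lo`).

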