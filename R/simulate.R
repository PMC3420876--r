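# Deterministic synthetic study generator. Produces a toy genome, gene
# models, a protein reference, small-RNA sets and a transcript set in which
# every pipeline decision (coding status, precursor class, genic/intergenic
# location, coverage tier, sub-genic category, orientation) is planted and
# exactly recoverable: windows are rejection-sampled so that no planted
# noncoding transcript carries an ORF above the coding threshold, and every
# planted small RNA is verified to occur in its source transcript only.

#' Generate a random genome
#'
#' Uniform random nucleotides per chromosome, reproducible under `seed`.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length(s) in nt (recycled), each at least
#'   10 kb.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return A transcript-style tibble of chromosome sequences (ids
#'   `chr1`...).
#' @export
make_genome <- function(n_chrom = 3, chrom_len = 120000L, seed = NULL) {
  gen <- function() {
    lens <- rep_len(as.integer(chrom_len), n_chrom)
    if (any(lens < 10000)) abort("chromosome length must be at least 10 kb")
    new_transcript_set(
      paste0("chr", seq_len(n_chrom)),
      vapply(lens, random_nt, character(1)),
      source_label = "synthetic_genome"
    )
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Generate gene models on a genome
#'
#' Places `n_genes` non-overlapping genes left to right with inter-gene
#' spacing of at least 2,200 nt (so 500 nt flanks never overlap a
#' neighbouring gene). Exon counts cycle 1-4; exons are 260-450 nt, introns
#' 250-400 nt, and terminal exons carry 5'/3' UTRs of 230-320 nt. Strands
#' alternate deterministically with the gene index parity randomised once.
#'
#' @param genome A genome tibble from [make_genome()].
#' @param n_genes Number of genes to place.
#' @param flank_nt Flank width attached to each model.
#' @param seed Optional integer seed.
#' @return A gene-model tibble in the [read_gene_models()] layout.
#' @export
make_gene_models <- function(genome, n_genes = 40, flank_nt = 500L,
                             seed = NULL) {
  gen <- function() {
    rows <- list()
    gi <- 0L
    flip <- sample(0:1, 1)
    for (ci in seq_len(nrow(genome))) {
      clen <- genome$length_nt[ci]
      x <- 600L + sample(0:200, 1)
      while (gi < n_genes) {
        n_exons <- (gi %% 4L) + 1L
        exon_len <- sample(260:450, n_exons, replace = TRUE)
        intron_len <- if (n_exons > 1) sample(250:400, n_exons - 1, replace = TRUE) else integer(0)
        u5 <- sample(230:320, 1)
        u3 <- sample(230:320, 1)
        # terminal exons must hold their UTR plus >= 120 nt of CDS
        exon_len[1] <- max(exon_len[1], u5 + 120L)
        exon_len[n_exons] <- max(exon_len[n_exons], u3 + 120L)
        if (n_exons == 1) exon_len[1] <- max(exon_len[1], u5 + u3 + 120L)
        glen <- sum(exon_len) + sum(intron_len)
        if (x + glen + flank_nt + 100 > clen) break
        gs <- x
        starts <- gs + cumsum(c(0L, head(exon_len, -1) + intron_len))
        exons <- cbind(start = starts, end = starts + exon_len)
        ge <- gs + glen
        strand <- if ((gi + flip) %% 2 == 0) "+" else "-"
        introns <- if (n_exons > 1) {
          cbind(start = exons[-n_exons, 2], end = exons[-1, 1])
        } else {
          matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
        }
        left_u <- cbind(start = gs, end = gs + (if (strand == "+") u5 else u3))
        right_u <- cbind(start = ge - (if (strand == "+") u3 else u5), end = ge)
        utr5 <- if (strand == "+") left_u else right_u
        utr3 <- if (strand == "+") right_u else left_u
        # CDS: exon bases outside the two UTR spans
        cds <- lapply(seq_len(n_exons), function(e) {
          s <- max(exons[e, 1], left_u[1, 2])
          en <- min(exons[e, 2], right_u[1, 1])
          if (en > s) c(s, en) else NULL
        })
        cds <- do.call(rbind, cds[!vapply(cds, is.null, logical(1))])
        colnames(cds) <- c("start", "end")
        left_f <- cbind(start = max(0L, gs - flank_nt), end = gs)
        right_f <- cbind(start = ge, end = min(clen, ge + flank_nt))
        gi <- gi + 1L
        rows[[gi]] <- tibble(
          gene_id = sprintf("g%03d", gi), chrom = genome$id[ci],
          strand = strand, gene_start = gs, gene_end = ge, chrom_len = clen,
          exons = list(exons), introns = list(introns),
          utr5 = list(utr5), utr3 = list(utr3), cds = list(cds),
          flank_up = list(if (strand == "+") left_f else right_f),
          flank_down = list(if (strand == "+") right_f else left_f)
        )
        x <- ge + flank_nt + flank_nt + 1200L + sample(0:1000, 1)
      }
      if (gi >= n_genes) break
    }
    if (gi < n_genes) {
      abort(paste0("cannot place ", n_genes, " genes on this genome"))
    }
    out <- bind_rows(rows)
    attr(out, "flank_nt") <- as.integer(flank_nt)
    out
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Write gene models as GFF3
#'
#' Emits gene/exon/CDS/five_prime_UTR/three_prime_UTR features (1-based
#' inclusive coordinates) with sub-features carrying `Parent=` the gene id.
#'
#' @param genes A gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    row <- function(type, s, e, attrs) {
      paste(g$chrom, "lncscout_sim", type, s + 1L, e, ".", g$strand, ".",
            attrs, sep = "\t")
    }
    lines <- c(lines, row("gene", g$gene_start, g$gene_end,
                          paste0("ID=", g$gene_id)))
    emit <- function(type, iv) {
      if (is.null(iv) || nrow(iv) == 0) return(character(0))
      vapply(seq_len(nrow(iv)), function(k) {
        row(type, iv[k, 1], iv[k, 2],
            paste0("ID=", g$gene_id, ".", type, k, ";Parent=", g$gene_id))
      }, character(1))
    }
    lines <- c(lines, emit("exon", g$exons[[1]]), emit("CDS", g$cds[[1]]),
               emit("five_prime_UTR", g$utr5[[1]]),
               emit("three_prime_UTR", g$utr3[[1]]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Planting design for the synthetic study
#'
#' Counts per planted label combination. Defaults define the standard study
#' conditions: 10 sub-length transcripts, 25 long-ORF coding transcripts,
#' 8 homology-coding transcripts, one genic noncoding candidate per
#' (sub-genic category x orientation) pair, and 130 intergenic candidates;
#' precursor classes are overlaid as 12 miRNA, 30 shRNA and 80 siRNA
#' precursors, the remainder intact lncRNAs. No mutation noise
#' (`mutation_rate` is reserved and must currently be 0, so planted labels
#' are exact).
#'
#' @param n_too_short,n_coding_orf,n_coding_homology Coding-filter plants.
#' @param n_intergenic Number of intergenic noncoding candidates.
#' @param genic_plan Tibble with columns `category`, `orientation`; default
#'   one candidate per combination.
#' @param n_mirna,n_shrna,n_sirna Precursor class sizes.
#' @param n_decoy_proteins Unrelated proteins added to the reference set.
#' @param n_decoy_smallrna Decoy small RNAs per set (match no candidate).
#' @param n_contaminants Contaminant pool size; exactly one contaminant is
#'   planted into the transcript set.
#' @param mutation_rate Reserved; must be 0.
#' @return A list of class `lnc_design`.
#' @export
lnc_design <- function(n_too_short = 10, n_coding_orf = 25,
                       n_coding_homology = 8, n_intergenic = 130,
                       genic_plan = NULL, n_mirna = 12, n_shrna = 30,
                       n_sirna = 80, n_decoy_proteins = 15,
                       n_decoy_smallrna = 5, n_contaminants = 20,
                       mutation_rate = 0) {
  if (mutation_rate != 0) abort("mutation_rate is reserved and must be 0")
  if (is.null(genic_plan)) {
    genic_plan <- tidyr::expand_grid(
      category = c(
        "spliced_over_gene", "spans_upstream_to_downstream",
        "spans_utr5_to_utr3",
        "includes_upstream", "includes_downstream", "includes_utr5",
        "includes_utr3", "internal",
        "within_upstream", "within_downstream", "within_utr5",
        "within_utr3", "within_intron", "within_cds",
        "spans_multiple_including_upstream",
        "spans_multiple_including_downstream", "spans_multiple_internal"
      ),
      orientation = c("sense", "antisense")
    )
  }
  structure(as.list(environment()), class = "lnc_design")
}

CATEGORY_MIN_EXONS <- c(
  spliced_over_gene = 2, spans_upstream_to_downstream = 1,
  spans_utr5_to_utr3 = 1,
  includes_upstream = 2, includes_downstream = 2, includes_utr5 = 2,
  includes_utr3 = 2, internal = 3,
  within_upstream = 1, within_downstream = 1, within_utr5 = 2,
  within_utr3 = 2, within_intron = 2, within_cds = 3,
  spans_multiple_including_upstream = 2,
  spans_multiple_including_downstream = 2, spans_multiple_internal = 2
)

# build the genomic window (or exon set) realizing one category on a gene;
# returns list(window=c(s,e)) or list(exons=matrix) or NULL if infeasible
category_window <- function(g, category) {
  gs <- g$gene_start
  ge <- g$gene_end
  body <- ge - gs
  fu <- g$flank_up[[1]]
  fd <- g$flank_down[[1]]
  u5 <- g$utr5[[1]]
  u3 <- g$utr3[[1]]
  left_utr_len <- if (u5[1, 1] == gs) u5[1, 2] - u5[1, 1] else u3[1, 2] - u3[1, 1]
  right_utr_len <- if (u5[1, 2] == ge) u5[1, 2] - u5[1, 1] else u3[1, 2] - u3[1, 1]
  into <- function(flank) {
    # a depth 120..460 into the given flank, respecting truncation
    w <- min(460L, flank[1, 2] - flank[1, 1])
    if (w < 120) return(NULL)
    sample(120:w, 1)
  }
  side_window <- function(flank, c_body) {
    d <- into(flank)
    if (is.null(d)) return(NULL)
    if (flank[1, 2] <= gs) c(gs - d, gs + c_body) else c(ge - c_body, ge + d)
  }
  switch(category,
    spans_upstream_to_downstream = {
      dl <- into(if (fu[1, 2] <= gs) fu else fd)
      dr <- into(if (fu[1, 1] >= ge) fu else fd)
      if (is.null(dl) || is.null(dr)) return(NULL)
      list(window = c(gs - dl, ge + dr))
    },
    spans_utr5_to_utr3 = {
      a <- sample(0:5, 1)
      b <- sample(0:5, 1)
      list(window = c(gs + a, ge - b))
    },
    spliced_over_gene = {
      if (nrow(g$exons[[1]]) < 2) return(NULL)
      list(exons = g$exons[[1]])
    },
    includes_upstream = side_window_wrap(side_window(fu, round(0.62 * body))),
    includes_downstream = side_window_wrap(side_window(fd, round(0.62 * body))),
    includes_utr5 = {
      c_body <- round(0.62 * body)
      if (u5[1, 1] == gs) {
        if (c_body > body - right_utr_len - 15) return(NULL)
        list(window = c(gs + sample(0:15, 1), gs + c_body))
      } else {
        if (c_body > body - left_utr_len - 15) return(NULL)
        list(window = c(ge - c_body, ge - sample(0:15, 1)))
      }
    },
    includes_utr3 = {
      c_body <- round(0.62 * body)
      if (u3[1, 1] == gs) {
        if (c_body > body - right_utr_len - 15) return(NULL)
        list(window = c(gs + sample(0:15, 1), gs + c_body))
      } else {
        if (c_body > body - left_utr_len - 15) return(NULL)
        list(window = c(ge - c_body, ge - sample(0:15, 1)))
      }
    },
    internal = {
      c_body <- round(0.55 * body)
      i0 <- gs + left_utr_len + 12L
      i1 <- ge - right_utr_len - 12L
      if (i1 - i0 < c_body + 10) return(NULL)
      s <- i0 + sample(0:min(40L, i1 - i0 - c_body), 1)
      list(window = c(s, s + c_body))
    },
    within_upstream = within_window(fu, body),
    within_downstream = within_window(fd, body),
    within_utr5 = within_window(u5, body),
    within_utr3 = within_window(u3, body),
    within_intron = {
      iv <- g$introns[[1]]
      if (nrow(iv) == 0) return(NULL)
      within_window(iv[which.max(iv[, 2] - iv[, 1]), , drop = FALSE], body)
    },
    within_cds = {
      ex <- g$exons[[1]]
      if (nrow(ex) < 3) return(NULL)
      within_window(ex[2, , drop = FALSE], body)  # a middle exon is pure CDS
    },
    spans_multiple_including_upstream = {
      d <- into(fu)
      if (is.null(d)) return(NULL)
      c_body <- min(round(0.3 * body), 320L)
      if (fu[1, 2] <= gs) list(window = c(gs - d, gs + c_body))
      else list(window = c(ge - c_body, ge + d))
    },
    spans_multiple_including_downstream = {
      d <- into(fd)
      if (is.null(d)) return(NULL)
      c_body <- min(round(0.3 * body), 320L)
      if (fd[1, 2] <= gs) list(window = c(gs - d, gs + c_body))
      else list(window = c(ge - c_body, ge + d))
    },
    spans_multiple_internal = {
      # cross the boundary between the left UTR and the CDS
      b <- gs + left_utr_len
      w <- c(b - 130L, b + 190L)
      if (w[1] < gs + 5 || w[2] > ge - right_utr_len - 5) return(NULL)
      list(window = w)
    },
    abort(paste0("unknown category: ", category))
  )
}

side_window_wrap <- function(w) if (is.null(w)) NULL else list(window = w)

within_window <- function(iv, body) {
  len_iv <- iv[1, 2] - iv[1, 1]
  if (len_iv < 215) return(NULL)
  len <- min(len_iv - 10L, sample(200:380, 1))
  if (len / body >= 0.5 && body > 0) len <- min(len, floor(0.45 * body))
  if (len < 200) return(NULL)
  s <- iv[1, 1] + sample(0:(len_iv - len - 5), 1) + 2L
  list(window = c(s, s + len))
}

subseq_nt <- function(seq, s, e) substr(seq, s + 1, e)

# sequence with no complete ORF longer than max_aa on the forward strand
orf_ok <- function(seq, max_aa = 120L) longest_orf_aa(seq) <= max_aa

#' Plant transcripts with ground-truth labels
#'
#' Realizes an [lnc_design()] on a genome and gene set. Coding transcripts
#' receive a >120 aa ORF whose translation enters the protein set;
#' homology-coding transcripts receive an 80 aa ORF embedded verbatim in a
#' database protein; genic/intergenic noncoding candidates are copied
#' (sense or reverse-complemented) from the planned genomic windows; small
#' RNAs are sampled from their precursor transcripts and verified unique to
#' them. Every genic candidate occupies its own gene. Infeasible designs are
#' a hard error.
#'
#' @param genome A genome tibble.
#' @param genes A gene-model tibble from [make_gene_models()].
#' @param design An [lnc_design()].
#' @param seed Optional integer seed.
#' @return A list: `transcripts`, `proteins`, `contaminants`, `smallrna`
#'   (list of tibbles `miRNA`, `shRNA`, `siRNA`, `aux`), `truth` (planted
#'   label tibble), `callset_b` (character vector of ids).
#' @export
plant_transcripts <- function(genome, genes, design = lnc_design(),
                              seed = NULL) {
  gen <- function() plant_transcripts_impl(genome, genes, design)
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

plant_transcripts_impl <- function(genome, genes, design) {
  gseq <- setNames(genome$seq, genome$id)
  tx <- list()    # id -> seq
  truth <- list()
  add_tx <- function(id, seq, ...) {
    tx[[id]] <<- seq
    truth[[id]] <<- tibble(transcript_id = id, ...)
  }

  # --- coding-filter plants -------------------------------------------------
  for (i in seq_len(design$n_too_short)) {
    add_tx(sprintf("ts_%03d", i), random_nt(sample(60:199, 1)),
           true_status = "too_short", true_class = NA_character_,
           true_location = NA_character_, true_gene = NA_character_,
           true_tier = NA_character_, true_category = NA_character_,
           true_orientation = NA_character_, planted_smallrna_ids = "")
  }
  proteins <- list()
  for (i in seq_len(design$n_coding_orf)) {
    repeat {
      n_aa <- sample(130:200, 1)
      body <- make_orf_nt(n_aa)
      seqc <- paste0(random_nt(sample(60:150, 1)), body,
                     random_nt(sample(60:150, 1)))
      if (longest_orf_aa(seqc) >= 121) break
    }
    id <- sprintf("co_%03d", i)
    proteins[[paste0("prot_orf_", i)]] <- translate_frame(body, 0)
    proteins[[paste0("prot_orf_", i)]] <-
      sub("\\*$", "", proteins[[paste0("prot_orf_", i)]])
    add_tx(id, seqc,
           true_status = "coding_orf", true_class = NA_character_,
           true_location = NA_character_, true_gene = NA_character_,
           true_tier = NA_character_, true_category = NA_character_,
           true_orientation = NA_character_, planted_smallrna_ids = "")
  }
  for (i in seq_len(design$n_coding_homology)) {
    repeat {
      body <- make_orf_nt(80)
      seqc <- paste0(random_nt(sample(60:150, 1)), body,
                     random_nt(sample(60:150, 1)))
      if (orf_ok(seqc)) break
    }
    pep <- sub("\\*$", "", translate_frame(body, 0))
    proteins[[paste0("prot_hom_", i)]] <- paste0(
      random_aa(sample(30:60, 1)), pep, random_aa(sample(30:60, 1))
    )
    add_tx(sprintf("ch_%03d", i), seqc,
           true_status = "coding_homology", true_class = NA_character_,
           true_location = NA_character_, true_gene = NA_character_,
           true_tier = NA_character_, true_category = NA_character_,
           true_orientation = NA_character_, planted_smallrna_ids = "")
  }
  for (i in seq_len(design$n_decoy_proteins)) {
    proteins[[paste0("prot_decoy_", i)]] <- random_aa(sample(200:300, 1))
  }

  # noncoding plants must carry no significant protein homology, so the label
  # is guaranteed by construction (mirrors the ORF rejection above)
  prot_tbl <- tibble(
    id = names(proteins), seq = unlist(proteins, use.names = FALSE),
    length_aa = nchar(unlist(proteins, use.names = FALSE))
  )
  cfg0 <- pipeline_config()
  no_hit <- function(seqc) {
    h <- search_translated(
      tibble(id = "q", seq = seqc, length_nt = nchar(seqc)), prot_tbl, cfg0
    )
    nrow(h) == 0 || all(h$evalue > cfg0$evalue_max)
  }

  # --- genic noncoding candidates ------------------------------------------
  plan <- design$genic_plan
  used_genes <- character(0)
  genic_ids <- character(0)
  n_ex <- vapply(genes$exons, nrow, integer(1))
  # fewest exons first so structurally demanding categories keep their genes
  gene_order <- order(n_ex, sample(seq_len(nrow(genes))))
  for (pi in seq_len(nrow(plan))) {
    cat_ <- plan$category[pi]
    orient <- plan$orientation[pi]
    placed <- FALSE
    for (gi in gene_order) {
      g <- genes[gi, ]
      if (g$gene_id %in% used_genes) next
      if (nrow(g$exons[[1]]) < CATEGORY_MIN_EXONS[[cat_]]) next
      for (try in 1:25) {
        w <- category_window(g, cat_)
        if (is.null(w)) break
        base <- if (!is.null(w$exons)) {
          paste(vapply(seq_len(nrow(w$exons)), function(k) {
            subseq_nt(gseq[[g$chrom]], w$exons[k, 1], w$exons[k, 2])
          }, character(1)), collapse = "")
        } else {
          subseq_nt(gseq[[g$chrom]], w$window[1], w$window[2])
        }
        chain_strand <- if (orient == "sense") g$strand else
          (if (g$strand == "+") "-" else "+")
        seqc <- if (chain_strand == "+") base else revcomp(base)
        if (nchar(seqc) < 200 || !orf_ok(seqc) || !no_hit(seqc)) next
        id <- sprintf("gn_%03d", length(genic_ids) + 1L)
        genic_ids <- c(genic_ids, id)
        tier <- category_tier(cat_)
        add_tx(id, seqc,
               true_status = "noncoding", true_class = NA_character_,
               true_location = "genic", true_gene = g$gene_id,
               true_tier = tier, true_category = cat_,
               true_orientation = orient, planted_smallrna_ids = "")
        used_genes <- c(used_genes, g$gene_id)
        placed <- TRUE
        break
      }
      if (placed) break
    }
    if (!placed) {
      abort(paste0("design infeasible: cannot place genic category ", cat_))
    }
  }

  # --- intergenic noncoding candidates -------------------------------------
  free <- intergenic_intervals(genome, genes, margin = 40L)
  inter_ids <- character(0)
  fi <- 1L
  cursor <- if (nrow(free)) free$start[1] else 0L
  for (i in seq_len(design$n_intergenic)) {
    placed <- FALSE
    while (fi <= nrow(free)) {
      len <- sample(250:800, 1)
      if (cursor + len <= free$end[fi]) {
        sq <- subseq_nt(gseq[[free$chrom[fi]]], cursor, cursor + len)
        strand <- if (i %% 2 == 0) "+" else "-"
        seqc <- if (strand == "+") sq else revcomp(sq)
        if (orf_ok(seqc) && no_hit(seqc)) {
          id <- sprintf("in_%03d", i)
          inter_ids <- c(inter_ids, id)
          add_tx(id, seqc,
                 true_status = "noncoding", true_class = NA_character_,
                 true_location = "intergenic", true_gene = NA_character_,
                 true_tier = NA_character_, true_category = NA_character_,
                 true_orientation = NA_character_, planted_smallrna_ids = "")
          cursor <- cursor + len + 60L
          placed <- TRUE
          break
        }
        cursor <- cursor + 37L
      } else {
        fi <- fi + 1L
        if (fi <= nrow(free)) cursor <- free$start[fi]
      }
    }
    if (!placed) abort("design infeasible: ran out of intergenic space")
  }

  # --- precursor class overlay ---------------------------------------------
  truth_tbl <- bind_rows(truth)
  cls <- assign_classes(truth_tbl, genic_ids, inter_ids, design)
  truth_tbl$true_class[match(cls$transcript_id, truth_tbl$transcript_id)] <-
    cls$true_class

  smallrna <- plant_smallrnas(tx, cls, design)
  truth_tbl$planted_smallrna_ids[
    match(names(smallrna$by_tx), truth_tbl$transcript_id)
  ] <- vapply(smallrna$by_tx, paste, character(1), collapse = ";")

  # --- contaminants ---------------------------------------------------------
  contaminants <- new_transcript_set(
    sprintf("contam_%02d", seq_len(design$n_contaminants)),
    vapply(sample(300:600, design$n_contaminants, replace = TRUE),
           random_nt, character(1)),
    source_label = "synthetic_contaminants"
  )
  tx[["tx_contam"]] <- contaminants$seq[1]
  truth_tbl <- bind_rows(truth_tbl, tibble(
    transcript_id = "tx_contam", true_status = "contaminant",
    true_class = NA_character_, true_location = NA_character_,
    true_gene = NA_character_, true_tier = NA_character_,
    true_category = NA_character_, true_orientation = NA_character_,
    planted_smallrna_ids = ""
  ))

  transcripts <- new_transcript_set(names(tx), unlist(tx, use.names = FALSE),
                                    source_label = "synthetic_transcripts")
  # interleave deterministically so file order does not encode the label
  ord <- with_fixed_order(transcripts$id)
  transcripts <- transcripts[ord, , drop = FALSE]

  list(
    transcripts = transcripts,
    proteins = tibble(
      id = names(proteins), seq = unlist(proteins, use.names = FALSE),
      length_aa = nchar(unlist(proteins, use.names = FALSE))
    ),
    contaminants = contaminants,
    smallrna = smallrna$sets,
    truth = truth_tbl,
    callset_b = truth_tbl$transcript_id[truth_tbl$true_status == "noncoding"]
  )
}

# deterministic pseudo-shuffle of record order (stable across platforms)
with_fixed_order <- function(ids) order(vapply(ids, function(s) {
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 997L
}, numeric(1)), ids)

category_tier <- function(category) {
  if (category %in% c("spliced_over_gene", "spans_upstream_to_downstream",
                      "spans_utr5_to_utr3")) {
    "high"
  } else if (category %in% c("includes_upstream", "includes_downstream",
                             "includes_utr5", "includes_utr3", "internal")) {
    "mid"
  } else {
    "low"
  }
}

make_orf_nt <- function(n_aa) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(codons, c(stops, "ATG"))
  paste0("ATG", paste(sample(sense, n_aa - 1, replace = TRUE), collapse = ""),
         sample(stops, 1))
}

random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# free genomic intervals lying wholly outside every gene region (+flanks)
intergenic_intervals <- function(genome, genes, margin = 40L) {
  out <- list()
  for (ci in seq_len(nrow(genome))) {
    chrom <- genome$id[ci]
    clen <- genome$length_nt[ci]
    gsub_ <- genes |> filter(.data$chrom == !!chrom)
    regions <- if (nrow(gsub_)) {
      t(vapply(seq_len(nrow(gsub_)), function(i) {
        gene_region_bounds(gsub_[i, ])
      }, numeric(2)))
    } else {
      matrix(numeric(0), 0, 2)
    }
    regions <- regions[order(regions[, 1]), , drop = FALSE]
    cur <- margin
    for (k in seq_len(nrow(regions))) {
      if (regions[k, 1] - margin - cur > 300) {
        out[[length(out) + 1]] <- tibble(
          chrom = chrom, start = cur, end = regions[k, 1] - margin
        )
      }
      cur <- max(cur, regions[k, 2] + margin)
    }
    if (clen - margin - cur > 300) {
      out[[length(out) + 1]] <- tibble(chrom = chrom, start = cur,
                                       end = clen - margin)
    }
  }
  bind_rows(out)
}

assign_classes <- function(truth_tbl, genic_ids, inter_ids, design) {
  cand <- truth_tbl |> filter(.data$true_status == "noncoding")
  klass <- setNames(rep("lncRNA", nrow(cand)), cand$transcript_id)
  genic <- truth_tbl |> filter(.data$transcript_id %in% genic_ids)

  # one genic sense body-overlapping miRNA precursor (reclassification bait)
  bait <- genic |> filter(.data$true_orientation == "sense",
                          .data$true_category == "spans_utr5_to_utr3")
  anti <- genic |> filter(.data$true_orientation == "antisense",
                          .data$true_category == "within_intron")
  mi_genic <- c(head(bait$transcript_id, 1), head(anti$transcript_id, 1))
  n_mi_inter <- max(0L, design$n_mirna - length(mi_genic))
  mi_ids <- c(mi_genic, head(inter_ids, n_mi_inter))
  klass[mi_ids] <- "miRNA"

  rest_inter <- setdiff(inter_ids, mi_ids)
  rest_genic <- setdiff(genic_ids, mi_ids)
  n_sh_genic <- min(5L, length(rest_genic), design$n_shrna)
  sh_ids <- c(head(rest_genic, n_sh_genic),
              head(rest_inter, max(0L, design$n_shrna - n_sh_genic)))
  klass[sh_ids] <- "shRNA"
  rest_inter <- setdiff(rest_inter, sh_ids)
  rest_genic <- setdiff(rest_genic, sh_ids)
  n_si_genic <- min(15L, length(rest_genic), design$n_sirna)
  si_ids <- c(head(rest_genic, n_si_genic),
              head(rest_inter, max(0L, design$n_sirna - n_si_genic)))
  klass[si_ids] <- "siRNA"
  if (length(sh_ids) < design$n_shrna || length(si_ids) < design$n_sirna) {
    abort("design infeasible: not enough candidates for the precursor classes")
  }

  tibble(transcript_id = names(klass), true_class = unname(klass))
}

plant_smallrnas <- function(tx, cls, design) {
  cand_seqs <- unlist(tx[cls$transcript_id], use.names = TRUE)
  cand_rc <- vapply(cand_seqs, revcomp, character(1))
  occurs_in <- function(s) {
    names(cand_seqs)[grepl(s, cand_seqs, fixed = TRUE) |
                       grepl(s, cand_rc, fixed = TRUE)]
  }

  sets <- list(miRNA = list(), shRNA = list(), siRNA = list())
  by_tx <- list()
  counters <- c(miRNA = 0L, shRNA = 0L, siRNA = 0L)
  n_per <- list(miRNA = c(1L, 2L), shRNA = c(1L, 2L, 3L),
                siRNA = c(1L, 2L, 3L, 4L))
  len_rng <- list(miRNA = 20:22, shRNA = 18:30, siRNA = 18:30)
  planted <- 0L
  for (i in seq_len(nrow(cls))) {
    kl <- cls$true_class[i]
    if (kl == "lncRNA") next
    id <- cls$transcript_id[i]
    seqc <- tx[[id]]
    n <- nchar(seqc)
    cyc <- n_per[[kl]]
    k <- cyc[(sum(cls$true_class[seq_len(i)] == kl) - 1) %% length(cyc) + 1]
    seg <- floor(n / k)
    ids_here <- character(0)
    for (j in seq_len(k)) {
      s <- NULL
      for (try in 1:30) {  # resample on the (rare) non-unique draw
        L <- sample(len_rng[[kl]], 1)
        lo <- (j - 1) * seg
        hi <- j * seg - L - 1
        if (hi < lo) break
        off <- lo + sample(0:(hi - lo), 1)
        cand <- substr(seqc, off + 1, off + L)
        if (identical(occurs_in(cand), id)) {
          s <- cand
          break
        }
      }
      if (is.null(s)) next
      planted <- planted + 1L
      counters[kl] <- counters[kl] + 1L
      sid <- sprintf("%s_%04d", tolower(substr(kl, 1, 2)), counters[kl])
      # store every third one as its reverse complement (antisense match)
      if (planted %% 3 == 0) s <- revcomp(s)
      sets[[kl]][[sid]] <- s
      ids_here <- c(ids_here, sid)
    }
    if (!length(ids_here)) {
      abort(paste0("could not plant any small RNA in ", id))
    }
    by_tx[[id]] <- ids_here
  }
  # decoys: random sequences matching no candidate
  decoy <- function(len_pool, prefix, n) {
    out <- list()
    for (d in seq_len(n)) {
      repeat {
        s <- random_nt(sample(len_pool, 1))
        if (length(occurs_in(s)) == 0) break
      }
      out[[sprintf("%s_decoy_%02d", prefix, d)]] <- s
    }
    out
  }
  sets$miRNA <- c(sets$miRNA, decoy(20:22, "mi", design$n_decoy_smallrna))
  sets$shRNA <- c(sets$shRNA, decoy(18:30, "sh", design$n_decoy_smallrna))
  sets$siRNA <- c(sets$siRNA, decoy(18:30, "si", design$n_decoy_smallrna))

  # auxiliary set: every second planted siRNA, plus decoys
  si_planted <- sets$siRNA[grepl("^si_\\d", names(sets$siRNA))]
  aux <- si_planted[seq_along(si_planted) %% 2 == 1]
  names(aux) <- sub("^si_", "aux_", names(aux))
  aux <- c(aux, decoy(18:30, "aux", 3))

  as_set <- function(lst, label) {
    new_transcript_set(names(lst), unlist(lst, use.names = FALSE),
                       source_label = label)
  }
  list(
    sets = list(
      miRNA = as_set(sets$miRNA, "miRNA"),
      shRNA = as_set(sets$shRNA, "shRNA"),
      siRNA = as_set(sets$siRNA, "siRNA"),
      aux = as_set(aux, "aux")
    ),
    by_tx = by_tx
  )
}

#' Generate and write a complete synthetic study
#'
#' Runs [make_genome()], [make_gene_models()] and [plant_transcripts()] under
#' one seed and writes every pipeline input to `dir`: `genome.fa`,
#' `genes.gff3`, `transcripts.fa`, `contaminants.fa`, `proteins.fa`,
#' `smallrna_{mirna,shrna,sirna,aux}.fa`, `callset_b.txt` and the planted
#' label table `truth.tsv`. Identical seeds give byte-identical outputs.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving every random choice.
#' @param design An [lnc_design()].
#' @param n_chrom,chrom_len,n_genes Genome shape.
#' @return Invisibly, a list with the generated objects and file `paths`.
#' @export
simulate_lnc_study <- function(dir, seed = 1L, design = lnc_design(),
                               n_chrom = 3, chrom_len = 120000L,
                               n_genes = 40) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- with_seed(seed, {
    genome <- make_genome(n_chrom, chrom_len)
    genes <- make_gene_models(genome, n_genes)
    c(list(genome = genome, genes = genes),
      plant_transcripts(genome, genes, design))
  })
  p <- function(f) file.path(dir, f)
  write_fasta(res$genome, p("genome.fa"))
  write_gff3(res$genes, p("genes.gff3"))
  write_fasta(res$transcripts, p("transcripts.fa"))
  write_fasta(res$contaminants, p("contaminants.fa"))
  prot <- Biostrings::BStringSet(setNames(res$proteins$seq, res$proteins$id))
  Biostrings::writeXStringSet(prot, p("proteins.fa"), width = 60)
  write_fasta(res$smallrna$miRNA, p("smallrna_mirna.fa"))
  write_fasta(res$smallrna$shRNA, p("smallrna_shrna.fa"))
  write_fasta(res$smallrna$siRNA, p("smallrna_sirna.fa"))
  write_fasta(res$smallrna$aux, p("smallrna_aux.fa"))
  writeLines(res$callset_b, p("callset_b.txt"))
  readr::write_tsv(res$truth, p("truth.tsv"))
  res$paths <- setNames(
    file.path(dir, c("genome.fa", "genes.gff3", "transcripts.fa",
                     "contaminants.fa", "proteins.fa", "smallrna_mirna.fa",
                     "smallrna_shrna.fa", "smallrna_sirna.fa",
                     "smallrna_aux.fa", "callset_b.txt", "truth.tsv")),
    c("genome", "gff", "transcripts", "contaminants", "proteins",
      "mirna", "shrna", "sirna", "aux", "callset_b", "truth")
  )
  invisible(res)
}
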