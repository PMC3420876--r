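mk_set <- function(seqs, ids = sprintf("s%02d", seq_along(seqs))) {
  tibble::tibble(id = ids, seq = seqs, length_nt = nchar(seqs))
}

test_that("index partitions by length and deduplicates", {
  idx <- build_smallrna_index(
    mk_set(c(rand_nt(21), rand_nt(21), rand_nt(24))), "siRNA"
  )
  expect_equal(vapply(idx$by_length, nrow, integer(1)),
               c("21" = 2L, "24" = 1L))

  empty <- build_smallrna_index(mk_set(character(0), character(0)), "siRNA")
  expect_equal(nrow(empty$entries), 0)

  s <- rand_nt(22)
  dup <- build_smallrna_index(mk_set(c(s, s), c("a", "b")), "siRNA")
  expect_equal(nrow(dup$entries), 1)
  expect_setequal(dup$entries$ids[[1]], c("a", "b"))

  expect_error(
    build_smallrna_index(mk_set(rand_nt(31)), "siRNA", c(18, 30)),
    "outside"
  )
})

test_that("planted small RNAs are found at the right offset and strand", {
  withr::with_seed(14, {
    t <- rand_nt(500)
    s21 <- substr(t, 101, 121)
    s24 <- rand_nt(24)
  })
  t2 <- paste0(substr(t, 1, 300), revcomp(s24), substr(t, 301, 500))
  idx <- build_smallrna_index(mk_set(c(s21, s24), c("m1", "m2")), "siRNA")

  m <- match_small_rnas("t", t, idx)
  sense <- m[m$smallrna_id == "m1", ]
  expect_equal(sense$offset, 100L)
  expect_equal(sense$strand, "sense")

  m2 <- match_small_rnas("t2", t2, idx)
  anti <- m2[m2$smallrna_id == "m2", ]
  expect_equal(anti$strand, "antisense")
  expect_equal(anti$offset, 300L)
  # the invariant: revcomp of the transcript substring equals the small RNA
  expect_equal(revcomp(substr(t2, anti$offset + 1, anti$offset + 24)), s24)
})

test_that("matcher equals the naive sliding-window oracle", {
  withr::with_seed(99, {
    for (i in 1:200) {
      t <- rand_nt(sample(60:150, 1), with_n = i %% 7 == 0)
      seqs <- vapply(sample(18:30, 6, replace = TRUE), rand_nt, character(1))
      # plant some true matches (sense and antisense)
      if (nchar(t) >= 80) {
        seqs[1] <- substr(t, 11, 11 + 19)
        seqs[2] <- revcomp(substr(t, 41, 41 + 21))
      }
      names(seqs) <- sprintf("s%02d", seq_along(seqs))
      idx <- build_smallrna_index(mk_set(unname(seqs), names(seqs)), "siRNA")
      got <- match_small_rnas("t", t, idx)
      want <- oracle_smallrna_matches(t, seqs)
      key <- function(d) sort(paste(d$smallrna_seq, d$offset, d$strand))
      expect_equal(key(got), key(want), info = t)
    }
  })
})

test_that("matching is strand-symmetric", {
  withr::with_seed(4, {
    t <- rand_nt(300)
    seqs <- c(substr(t, 21, 40), revcomp(substr(t, 101, 125)), rand_nt(22))
  })
  idx <- build_smallrna_index(mk_set(seqs), "siRNA")
  m_fwd <- match_small_rnas("t", t, idx)
  m_rev <- match_small_rnas("t", revcomp(t), idx)
  flip <- c(sense = "antisense", antisense = "sense")
  expect_setequal(
    paste(m_fwd$smallrna_seq, unname(flip[m_fwd$strand])),
    paste(m_rev$smallrna_seq, m_rev$strand)
  )
})

test_that("classification follows miRNA > shRNA > siRNA precedence", {
  withr::with_seed(23, {
    t <- rand_nt(600)
    mi <- substr(t, 51, 71)
    si <- c(substr(t, 101, 124), substr(t, 201, 222), substr(t, 301, 330))
    t_none <- rand_nt(400)
  })
  cand <- mk_set(c(t, t_none), c("hit", "none"))
  mi_idx <- build_smallrna_index(mk_set(mi, "mi1"), "miRNA", c(18, 23))
  sh_idx <- build_smallrna_index(mk_set(rand_nt(25), "sh1"), "shRNA")
  si_idx <- build_smallrna_index(mk_set(si, paste0("si", 1:3)), "siRNA")

  pc <- classify_precursors(cand, mi_idx, sh_idx, si_idx)
  expect_equal(pc$klass[pc$transcript_id == "hit"], "miRNA_precursor")
  expect_equal(pc$n_distinct_smallrnas[pc$transcript_id == "hit"], 4L)
  expect_equal(pc$klass[pc$transcript_id == "none"], "lncRNA")
  expect_equal(pc$n_distinct_smallrnas[pc$transcript_id == "none"], 0L)

  # shuffling index contents never changes any class
  si_shuf <- build_smallrna_index(mk_set(rev(si), paste0("si", 3:1)), "siRNA")
  pc2 <- classify_precursors(cand, mi_idx, sh_idx, si_shuf)
  expect_equal(pc2$klass, pc$klass)
})

test_that("class assignment partitions the candidate set", {
  r <- get_run()
  pc <- r$classes
  expect_equal(nrow(pc), nrow(r$candidates))
  expect_equal(sum(table(pc$klass)), nrow(r$candidates))
  expect_equal(anyDuplicated(pc$transcript_id), 0L)
  # n_distinct == 0 exactly for intact lncRNAs
  expect_equal(pc$klass == "lncRNA", pc$n_distinct_smallrnas == 0)
})

test_that("miRNA reclassification mirrors the mRNA-overlap ledger", {
  pc <- tibble::tibble(
    transcript_id = sprintf("t%02d", 1:21),
    klass = c(rep("miRNA_precursor", 20), "shRNA_precursor"),
    n_distinct_smallrnas = rep(1L, 21)
  )
  out <- reclassify_mirna_hits(pc, "t07")
  expect_equal(sum(out$klass == "miRNA_precursor"), 19)
  expect_equal(out$klass[out$transcript_id == "t07"],
               "genic_siRNA_precursor_reclassified")

  expect_equal(reclassify_mirna_hits(pc, character(0)), pc)
  # the rule applies to the miRNA class only
  out2 <- reclassify_mirna_hits(pc, "t21")
  expect_equal(out2$klass[out2$transcript_id == "t21"], "shRNA_precursor")
})

test_that("multi-hit counting is consistent", {
  pc <- tibble::tibble(
    transcript_id = sprintf("t%02d", 1:6),
    klass = c("miRNA_precursor", "miRNA_precursor", "siRNA_precursor",
              "siRNA_precursor", "siRNA_precursor", "lncRNA"),
    n_distinct_smallrnas = c(1L, 1L, 3L, 3L, 3L, 0L)
  )
  tab <- count_multi_hit(pc)
  expect_equal(tab$n_multi_smallrna[tab$klass == "miRNA_precursor"], 0L)
  expect_equal(tab$n_multi_smallrna[tab$klass == "siRNA_precursor"], 3L)
  expect_true(all(tab$n_multi_smallrna <= tab$n_transcripts))
})

test_that("auxiliary tagging marks exactly the embedding transcripts", {
  withr::with_seed(55, {
    t1 <- rand_nt(400)
    t2 <- rand_nt(400)
    aux_seq <- substr(t1, 101, 124)
  })
  cand <- mk_set(c(t1, t2), c("t1", "t2"))
  pc <- tibble::tibble(
    transcript_id = c("t1", "t2"),
    klass = c("siRNA_precursor", "siRNA_precursor"),
    n_distinct_smallrnas = c(1L, 1L)
  )
  aux_idx <- build_smallrna_index(mk_set(aux_seq, "aux1"), "aux")
  out <- annotate_aux(pc, cand, aux_idx, "mop1")
  expect_equal(out$aux_tags[[1]], "mop1")
  expect_equal(out$aux_tags[[2]], character(0))

  # empty auxiliary set -> no tags
  empty_idx <- build_smallrna_index(mk_set(character(0), character(0)), "aux")
  none <- annotate_aux(pc, cand, empty_idx, "mop1")
  expect_true(all(lengths(none$aux_tags) == 0))

  # summary rows sum to the tagged total
  loc <- tibble::tibble(transcript_id = c("t1", "t2"),
                        location = c("genic", "intergenic"))
  out2 <- annotate_aux(pc, cand, aux_idx, "mop1", localization = loc)
  summ <- attr(out2, "aux_summary")
  expect_equal(sum(summ$n_tagged),
               sum(vapply(out2$aux_tags, function(x) "mop1" %in% x, logical(1))))
})
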