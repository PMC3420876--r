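test_that("length filter keeps >= 200 nt and partitions the input", {
  ts <- tibble::tibble(
    id = c("a", "b", "c"),
    seq = c(rand_nt(199), rand_nt(200), rand_nt(500))
  )
  ts$length_nt <- nchar(ts$seq)
  res <- filter_by_length(ts)
  expect_equal(res$pass$id, c("b", "c"))
  expect_equal(res$fail$transcript_id, "a")
  expect_equal(res$fail$status, "too_short")

  empty <- ts[0, ]
  res0 <- filter_by_length(empty)
  expect_equal(nrow(res0$pass) + nrow(res0$fail), 0)

  withr::with_seed(2, {
    rnd <- tibble::tibble(
      id = sprintf("r%02d", 1:40),
      seq = vapply(sample(100:400, 40, replace = TRUE), rand_nt, character(1))
    )
    rnd$length_nt <- nchar(rnd$seq)
  })
  r <- filter_by_length(rnd)
  expect_equal(nrow(r$pass) + nrow(r$fail), 40)
})

test_that("ORF filter reproduces the known-lncRNA threshold counts", {
  withr::with_seed(77, {
    ts <- tibble::tibble(
      id = names(KNOWN_LNCRNA_ORF_AA),
      seq = vapply(KNOWN_LNCRNA_ORF_AA, make_seq_with_orf, character(1))
    )
    ts$length_nt <- nchar(ts$seq)
  })
  res <- filter_by_orf(ts, pipeline_config(max_orf_aa = 120))
  expect_equal(nrow(res$fail), 3)  # XIST, TSIX, KCNQ1QT exceed 120 aa
  expect_setequal(res$fail$transcript_id, c("XIST", "TSIX", "KCNQ1QT"))
  expect_equal(sort(res$fail$orf_aa), c(136L, 151L, 289L))

  # lowering the threshold to 102 aa excludes three additional transcripts
  res102 <- filter_by_orf(ts, pipeline_config(max_orf_aa = 102))
  expect_equal(nrow(res102$fail), 6)
  expect_setequal(
    setdiff(res102$fail$transcript_id, res$fail$transcript_id),
    c("RepA", "HOTAIR", "AIR")
  )

  # a transcript with no ORF passes
  expect_equal(res$pass$orf_aa[res$pass$id == "enod40"], 0L)
})

test_that("translated search recovers a planted exact peptide", {
  withr::with_seed(5, {
    pep <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 50,
                        replace = TRUE), collapse = "")
    # reverse-translate with one fixed codon per residue
    rt <- vapply(strsplit(pep, "")[[1]], function(a) {
      names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a][1]
    }, character(1))
    ts <- tibble::tibble(id = "q", seq = paste(rt, collapse = ""))
    ts$length_nt <- nchar(ts$seq)
    prot <- tibble::tibble(
      id = c("target", "decoy"),
      seq = c(paste0(rand_aa_str(40), pep, rand_aa_str(40)), rand_aa_str(200))
    )
    prot$length_aa <- nchar(prot$seq)
  })
  hits <- search_translated(ts, prot)
  expect_equal(hits$protein_id, "target")
  expect_equal(hits$query_frame, 0L)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  self <- sum(BLOSUM62[cbind(strsplit(pep, "")[[1]], strsplit(pep, "")[[1]])])
  expect_equal(hits$raw_score, self)
  expect_lt(hits$evalue, 1e-10)
})

test_that("random transcripts have no significant hit against random proteins", {
  withr::with_seed(31, {
    ts <- tibble::tibble(
      id = sprintf("r%02d", 1:10),
      seq = vapply(rep(600, 10), rand_nt, character(1))
    )
    ts$length_nt <- nchar(ts$seq)
    prot <- tibble::tibble(
      id = sprintf("p%02d", 1:10),
      seq = vapply(rep(250, 10), rand_aa_str, character(1))
    )
    prot$length_aa <- nchar(prot$seq)
  })
  hits <- search_translated(ts, prot)
  expect_true(all(hits$evalue > 0.001))
})

test_that("e-value halves per added bit and empty databases error", {
  e0 <- karlin_altschul(0, 100, 1000)
  s1 <- (e0$bitscore + 1 - (-log(0.134) / log(2))) * log(2) / 0.3176
  e1 <- karlin_altschul(s1, 100, 1000)
  expect_equal(e1$evalue, e0$evalue / 2, tolerance = 1e-9)

  ts <- tibble::tibble(id = "a", seq = rand_nt(300), length_nt = 300L)
  expect_error(search_translated(ts, tibble::tibble()[0, ]), "empty")
})

test_that("local protein alignment scores match an affine-gap DP oracle", {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  withr::with_seed(8, {
    for (i in 1:25) {
      n <- sample(20:60, 1)
      a <- rand_aa_str(n)
      b <- if (i %% 3 == 0) {
        # related pair: embed a slice of a
        paste0(rand_aa_str(10), substr(a, 5, n - 4), rand_aa_str(10))
      } else {
        rand_aa_str(sample(20:60, 1))
      }
      got <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
        substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1,
        scoreOnly = TRUE
      )
      want <- sw_protein_score(a, b, BLOSUM62)
      expect_equal(got, want, info = paste(a, b))
    }
  })
})

test_that("external hit import keeps the best row and rejects malformed input", {
  f <- withr::local_tempfile(lines = c(
    "t1\tpA\t55.1\t1e-5\t1",
    "t1\tpB\t60.0\t1e-8\t2",
    "t1\tpC\t40.0\t2e-3\t1",
    "t2\tpA\t30.0\t0.5\t3"
  ))
  hits <- import_external_hits(f)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$protein_id[hits$transcript_id == "t1"], "pB")

  empty <- withr::local_tempfile(lines = character(0))
  expect_equal(nrow(import_external_hits(empty)), 0)

  bad <- withr::local_tempfile(lines = c("t1\tpA\t55.1\t1e-5\t1", "t2\tonly"))
  expect_error(import_external_hits(bad), "line 2")

  # round-trip through the built-in exporter
  out <- withr::local_tempfile()
  write_hits_tsv(hits, out)
  back <- import_external_hits(out)
  expect_equal(back$transcript_id, hits$transcript_id)
  expect_equal(back$evalue, hits$evalue)
})

test_that("homology verdict applies the inclusive coding boundary", {
  ts <- tibble::tibble(id = c("a", "b", "c"), seq = rep("ACGT", 3),
                       length_nt = rep(4L, 3))
  hits <- tibble::tibble(
    transcript_id = c("a", "b"), protein_id = c("p", "p"),
    raw_score = c(NA, NA), bitscore = c(10, 10),
    evalue = c(0.0009, 0.0011), query_frame = c(0L, 0L)
  )
  v <- classify_coding(ts, hits)
  expect_equal(v$status, c("coding_homology", "noncoding", "noncoding"))

  # monotone in the threshold: tightening never shrinks the noncoding set
  v_tight <- classify_coding(ts, hits, pipeline_config(evalue_max = 1e-6))
  expect_true(all(v$status[v_tight$status != "noncoding"] != "noncoding"))
  expect_gte(sum(v_tight$status == "noncoding"),
             sum(v$status == "noncoding"))
})

test_that("the three-stage filter partitions every input transcript", {
  withr::with_seed(21, {
    ts <- tibble::tibble(
      id = c("short1", "orfy", "plain1", "plain2"),
      seq = c(rand_nt(150),
              paste0(rand_nt(30), make_seq_with_orf(150), rand_nt(30)),
              rand_nt(400), rand_nt(300))
    )
    ts$length_nt <- nchar(ts$seq)
    prot <- tibble::tibble(id = "p1", seq = rand_aa_str(200), length_aa = 200L)
  })
  v <- classify_coding_potential(ts, prot)
  expect_equal(nrow(v), 4)
  expect_equal(v$transcript_id, ts$id)
  expect_equal(sum(attr(v, "counts")), 4)
  expect_equal(v$status[1], "too_short")
  expect_equal(v$status[2], "coding_orf")
})

test_that("callset combination obeys inclusion-exclusion", {
  withr::with_seed(10, {
    pool <- sprintf("id%05d", sample(1e5, 3000))
    shared <- pool[1:1223]
    a <- c(shared, pool[1224:(1223 + 579)])          # 1,802 ids
    b <- c(shared, pool[(1223 + 580):(1223 + 579 + 690)])  # 1,913 ids
  })
  res <- combine_callsets(a, b)
  expect_length(a, 1802)
  expect_length(b, 1913)
  expect_length(res$intersection, 1223)
  expect_length(res$union, 2492)
  expect_equal(length(res$union),
               length(a) + length(b) - length(res$intersection))

  same <- combine_callsets(a, a)
  expect_setequal(same$union, a)
  expect_setequal(same$intersection, a)

  disj <- combine_callsets(c("x", "y"), c("z"))
  expect_length(disj$intersection, 0)
  expect_length(disj$union, 3)
})
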