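# Independent oracles used across the suite. Each reimplements the checked
# contract by brute force, sharing no code with the package internals.

rand_nt <- function(n, with_n = FALSE) {
  pool <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  prob <- if (with_n) c(rep(0.24, 4), 0.04) else NULL
  paste(sample(pool, n, replace = TRUE, prob = prob), collapse = "")
}

rand_aa_str <- function(n) paste(
  sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
  collapse = ""
)

# ---- ORF oracle: test every candidate (start, stop) pair ---------------------
oracle_orfs <- function(seq, start_codons = "ATG",
                        stop_codons = c("TAA", "TAG", "TGA")) {
  n <- nchar(seq)
  codon_at <- function(i) substr(seq, i + 1, i + 3)  # 0-based offset
  hits <- list()
  for (frame in 0:2) {
    offs <- seq(frame, n - 3, by = 3)
    if (frame > n - 3) next
    for (s in offs) {
      if (!codon_at(s) %in% start_codons) next
      # maximality: an in-frame start preceded (since the last stop) by
      # another start is not maximal; walk back
      maximal <- TRUE
      p <- s - 3
      while (p >= 0) {
        cp <- codon_at(p)
        if (cp %in% stop_codons) break
        if (cp %in% start_codons) {
          maximal <- FALSE
          break
        }
        p <- p - 3
      }
      if (!maximal) next
      e <- s + 3
      while (e + 3 <= n) {
        ce <- codon_at(e)
        if (ce %in% stop_codons) {
          hits[[length(hits) + 1]] <-
            c(start_nt = s, end_nt = e + 3, frame = frame,
              aa_len = (e - s) / 3)
          break
        }
        e <- e + 3
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start_nt = integer(), end_nt = integer(),
                      frame = integer(), aa_len = integer()))
  }
  out <- as.data.frame(do.call(rbind, hits))
  out[order(out$start_nt, out$end_nt), , drop = FALSE]
}

# ---- exact small-RNA match oracle: sliding window ---------------------------
oracle_smallrna_matches <- function(tseq, smallrnas) {
  # smallrnas: named character vector (id -> seq)
  n <- nchar(tseq)
  rc1 <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }
  out <- list()
  for (id in names(smallrnas)) {
    s <- smallrnas[[id]]
    L <- nchar(s)
    if (L > n || grepl("N", s)) next
    for (off in 0:(n - L)) {
      win <- substr(tseq, off + 1, off + L)
      if (grepl("N", win)) next
      if (win == s) {
        out[[length(out) + 1]] <- data.frame(
          smallrna_seq = s, offset = off, strand = "sense"
        )
      }
      if (rc1(win) == s) {
        out[[length(out) + 1]] <- data.frame(
          smallrna_seq = s, offset = off, strand = "antisense"
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(smallrna_seq = character(), offset = integer(),
                      strand = character()))
  }
  do.call(rbind, out)
}

# ---- Smith-Waterman oracles -------------------------------------------------
# nucleotide SW, match +1 / mismatch -2, linear gap -3; rows vectorized with
# the running-max trick, so gaps of every length are considered
sw_nt_score <- function(a, b, match = 1, mismatch = -2, gap = -3) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(bv)
  jidx <- seq_len(n)
  h_prev <- numeric(n + 1)
  colbest <- rep(-Inf, n + 1)
  best <- 0
  for (i in seq_along(av)) {
    s <- ifelse(bv == av[i] & av[i] != "N" & bv != "N", match, mismatch)
    colbest <- pmax(colbest + gap, h_prev + gap)
    h0 <- pmax(0, c(0, h_prev[jidx] + s), colbest)
    h0[1] <- 0
    adj <- h0 - gap * c(0, jidx)
    run <- cummax(adj)
    h <- pmax(h0, gap * c(0, jidx) + c(-Inf, run[jidx]))
    h[1] <- 0
    best <- max(best, h)
    h_prev <- h
  }
  best
}

# affine-gap protein SW (BLOSUM62-style matrix), open 11 / extend 1: a gap of
# length L costs 11 + L; gaps are taken directly from H with a running max
sw_protein_score <- function(a, b, mat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(bv)
  jidx <- seq_len(n)
  h_prev <- numeric(n + 1)
  colbest <- rep(-Inf, n + 1)  # max over k<i of H[k,j] - open - ext*(i-k)
  best <- 0
  for (i in seq_along(av)) {
    s <- mat[av[i], bv]
    colbest <- pmax(colbest - ext, h_prev - open - ext)
    h0 <- pmax(0, c(0, h_prev[jidx] + s), colbest)
    h0[1] <- 0
    adj <- h0 + ext * c(0, jidx)
    run <- cummax(adj)
    h <- pmax(h0, -open - ext * c(0, jidx) + c(-Inf, run[jidx]))
    h[1] <- 0
    best <- max(best, h)
    h_prev <- h
  }
  best
}

# ---- chain oracle: enumerate every subset of blocks -------------------------
oracle_best_chain <- function(blocks, max_gap = 10000) {
  n <- nrow(blocks)
  b <- blocks[order(blocks$s_start, blocks$s_end), , drop = FALSE]
  best <- 0
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    ok <- TRUE
    if (length(idx) > 1) {
      for (t in 2:length(idx)) {
        i <- idx[t]
        j <- idx[t - 1]
        gap <- b$s_start[i] - b$s_end[j]
        if (gap < 0 || gap > max_gap || b$q_start[i] < b$q_end[j]) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) best <- max(best, sum(b$score[idx]))
  }
  best
}

# ---- constructed sequences with a known longest ORF -------------------------
# T-free padding cannot form starts or stops; rejection keeps alternative
# frames below the target
make_seq_with_orf <- function(aa_len, pad = 30) {
  pad_nt <- function(n) paste(sample(c("A", "C", "G"), n, replace = TRUE),
                              collapse = "")
  if (aa_len == 0) return(pad_nt(max(pad * 3, 120)))
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(codons, c(stops, "ATG"))
  repeat {
    body <- paste0(
      "ATG",
      paste(sample(sense, aa_len - 1, replace = TRUE), collapse = ""),
      sample(stops, 1)
    )
    s <- paste0(pad_nt(pad), body, pad_nt(pad))
    if (lncscout::longest_orf_aa(s) == aa_len) return(s)
  }
}

# ORF sizes of well-characterized lncRNAs reported in the literature
KNOWN_LNCRNA_ORF_AA <- c(
  enod40 = 0, COLDAIR = 34, COOLAIR_short = 38, COOLAIR_long = 43,
  linc1257 = 68, NRON = 71, HOTTIP = 86, NEAT1 = 97, RepA = 105,
  HOTAIR = 106, AIR = 112, XIST = 136, TSIX = 151, KCNQ1QT = 289
)
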