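# Seed-and-extend ungapped local alignment against a genome, and colinear
# chaining of the resulting blocks. Scoring is match +1 / mismatch -2 with
# x-drop termination; N fails every comparison. Coordinates are 0-based
# half-open. For minus-strand blocks, query coordinates refer to the
# reverse-complemented query so that query and subject positions increase
# together within a block and a chain.

#' Build a k-mer seed index over a genome
#'
#' Indexes every forward-strand k-mer of every chromosome. Queries are
#' searched on both strands by also seeding their reverse complement.
#'
#' @param genome A transcript-style tibble of chromosome sequences.
#' @param k Seed length (default 11).
#' @return A list of class `genome_index` with the keyed seed table and
#'   per-chromosome character vectors.
#' @export
build_genome_index <- function(genome, k = 11L) {
  assert_transcript_set(genome, "genome")
  chars <- lapply(seq_len(nrow(genome)), function(i) {
    strsplit(toupper(genome$seq[i]), "", fixed = TRUE)[[1]]
  })
  names(chars) <- genome$id
  tabs <- lapply(seq_len(nrow(genome)), function(i) {
    s <- toupper(genome$seq[i])
    n <- nchar(s)
    if (n < k) return(NULL)
    pos <- 0:(n - k)
    data.table::data.table(
      kmer = substring(s, pos + 1, pos + k),
      chrom = genome$id[i],
      spos = pos
    )
  })
  seeds <- data.table::rbindlist(tabs)
  seeds <- seeds[!grepl("N", seeds$kmer, fixed = TRUE)]
  data.table::setkey(seeds, kmer)
  structure(
    list(seeds = seeds, chars = chars, k = as.integer(k),
         chrom_len = setNames(nchar(genome$seq), genome$id)),
    class = "genome_index"
  )
}

# x-drop extension over a logical match vector; returns c(left, right) as a
# 0-based half-open sub-range of the vector maximizing the +1/-2 score seen
# from the seed outwards, stopping when the score drops more than `xdrop`
# below the running best.
xdrop_extend <- function(is_match, seed_lo, seed_hi, xdrop) {
  sc <- ifelse(is_match, 1, -2)
  n <- length(sc)
  # rightwards from seed_hi (1-based index seed_hi+1 onward)
  right <- seed_hi
  if (seed_hi < n) {
    cs <- cumsum(sc[(seed_hi + 1):n])
    best <- cummax(c(0, cs))[-1]
    stop_at <- which(best - cs > xdrop)
    lim <- if (length(stop_at)) stop_at[1] else length(cs)
    if (lim > 0) {
      seg <- cs[1:lim]
      if (max(seg) > 0) right <- seed_hi + which.max(seg)
    }
  }
  left <- seed_lo
  if (seed_lo > 0) {
    cs <- cumsum(rev(sc[1:seed_lo]))
    best <- cummax(c(0, cs))[-1]
    stop_at <- which(best - cs > xdrop)
    lim <- if (length(stop_at)) stop_at[1] else length(cs)
    if (lim > 0) {
      seg <- cs[1:lim]
      if (max(seg) > 0) left <- seed_lo - which.max(seg)
    }
  }
  c(left, right)
}

# all maximal blocks for one query orientation against the index
blocks_one_strand <- function(qchars, index, strand, min_score, xdrop) {
  k <- index$k
  qn <- length(qchars)
  if (qn < k) return(NULL)
  qstr <- paste(qchars, collapse = "")
  qpos <- 0:(qn - k)
  qk <- substring(qstr, qpos + 1, qpos + k)
  keep <- !grepl("N", qk, fixed = TRUE)
  if (!any(keep)) return(NULL)
  qdt <- data.table::data.table(kmer = qk[keep], qpos = qpos[keep])
  hits <- index$seeds[qdt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0) return(NULL)
  hits[, "diag" := hits$spos - hits$qpos]
  out <- list()
  for (grp in split(hits, by = c("chrom", "diag"))) {
    chrom <- grp$chrom[1]
    diag <- grp$diag[1]
    schars <- index$chars[[chrom]]
    sn <- length(schars)
    # overlapping extent of the diagonal: query i aligns subject i + diag
    q_lo <- max(0L, -diag)
    q_hi <- min(qn, sn - diag)
    if (q_hi - q_lo < k) next
    qi <- (q_lo + 1):q_hi
    is_match <- qchars[qi] == schars[qi + diag] &
      qchars[qi] != "N" & schars[qi + diag] != "N"
    seen <- matrix(integer(0), 0, 2)
    for (sp in sort(unique(grp$qpos))) {
      lo <- sp - q_lo
      hi <- lo + k
      if (nrow(seen) && any(sp - q_lo >= seen[, 1] & hi <= seen[, 2])) next
      ext <- xdrop_extend(is_match, lo, hi, xdrop)
      seen <- rbind(seen, ext)
      b0 <- ext[1]
      b1 <- ext[2]
      m <- sum(is_match[(b0 + 1):b1])
      len <- b1 - b0
      score <- m - 2 * (len - m)
      if (score < min_score) next
      out[[length(out) + 1]] <- tibble(
        chrom = chrom, strand = strand,
        q_start = q_lo + b0, q_end = q_lo + b1,
        s_start = q_lo + b0 + diag, s_end = q_lo + b1 + diag,
        score = score, identity = m / len
      )
    }
  }
  if (!length(out)) NULL else bind_rows(out) |> distinct()
}

# greedy non-redundancy: keep blocks in decreasing score order, trimming a
# lower-scoring block where it overlaps an accepted block's query range on
# the same strand (rescored after trimming), dropping it if contained or if
# it falls below min_score. This resolves the few-base overruns that x-drop
# extension produces across splice junctions.
resolve_query_overlaps <- function(blocks, qchars_by_strand, index, min_score) {
  if (is.null(blocks) || nrow(blocks) <= 1) return(blocks)
  blocks <- blocks |> arrange(dplyr::desc(.data$score), .data$chrom, .data$s_start)
  kept <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    ok <- TRUE
    for (a in kept) {
      if (a$strand != b$strand) next
      if (b$q_start >= a$q_end || b$q_end <= a$q_start) next
      if (b$q_start >= a$q_start && b$q_end <= a$q_end) {
        ok <- FALSE
        break
      }
      if (b$q_start < a$q_end && b$q_end > a$q_end) {
        trim <- a$q_end - b$q_start
        b$q_start <- b$q_start + trim
        b$s_start <- b$s_start + trim
      } else if (b$q_end > a$q_start && b$q_start < a$q_start) {
        trim <- b$q_end - a$q_start
        b$q_end <- b$q_end - trim
        b$s_end <- b$s_end - trim
      }
      if (b$q_end - b$q_start < 1) {
        ok <- FALSE
        break
      }
      qc <- qchars_by_strand[[b$strand]]
      sc <- index$chars[[b$chrom]]
      qi <- (b$q_start + 1):b$q_end
      is_match <- qc[qi] == sc[qi + (b$s_start - b$q_start)] & qc[qi] != "N"
      m <- sum(is_match)
      b$score <- m - 2 * (length(qi) - m)
      b$identity <- m / length(qi)
      if (b$score < min_score) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept[[length(kept) + 1]] <- b
  }
  bind_rows(kept)
}

#' Align a query transcript against an indexed genome
#'
#' Seed (exact k-mers) and ungapped x-drop extension on both strands;
#' maximal-scoring non-redundant blocks with score at least
#' `min_block_score` are returned (match +1, mismatch -2). Minus-strand
#' block query coordinates refer to the reverse-complemented query.
#'
#' @param seq Query nucleotide string.
#' @param index A [build_genome_index()].
#' @param cfg A [pipeline_config()] (supplies `min_block_score` and
#'   `xdrop`).
#' @return A tibble of blocks: `chrom`, `strand`, `q_start`, `q_end`,
#'   `s_start`, `s_end`, `score`, `identity`; zero rows when nothing aligns.
#' @export
align_to_genome <- function(seq, index, cfg = pipeline_config()) {
  seq <- toupper(seq)
  qchars <- strsplit(seq, "", fixed = TRUE)[[1]]
  rchars <- strsplit(revcomp(seq), "", fixed = TRUE)[[1]]
  blocks <- bind_rows(
    blocks_one_strand(qchars, index, "+", cfg$min_block_score, cfg$xdrop),
    blocks_one_strand(rchars, index, "-", cfg$min_block_score, cfg$xdrop)
  )
  if (nrow(blocks) == 0) {
    return(tibble(
      chrom = character(), strand = character(), q_start = integer(),
      q_end = integer(), s_start = integer(), s_end = integer(),
      score = numeric(), identity = numeric()
    ))
  }
  resolve_query_overlaps(
    blocks, list("+" = qchars, "-" = rchars), index, cfg$min_block_score
  ) |>
    arrange(.data$chrom, .data$strand, .data$s_start)
}

#' Align a query against a single subject sequence
#'
#' Convenience wrapper over [align_to_genome()] for one subject.
#'
#' @param seq Query nucleotide string.
#' @param subject Subject nucleotide string.
#' @param subject_id Id used in the `chrom` column.
#' @param cfg A [pipeline_config()].
#' @return A block tibble as from [align_to_genome()].
#' @export
align_local <- function(seq, subject, subject_id = "subject",
                        cfg = pipeline_config()) {
  if (!nchar(subject)) abort("subject sequence is empty")
  idx <- build_genome_index(new_transcript_set(subject_id, subject),
                            k = cfg$seed_k)
  align_to_genome(seq, idx, cfg)
}

#' Chain colinear alignment blocks
#'
#' Maximum-total-score chain of blocks on one subject and strand, computed by
#' dynamic programming over blocks sorted by subject start. Consecutive chain
#' blocks must be strictly non-overlapping and monotone in both query and
#' subject, with subject gaps at most `max_chain_gap_nt`.
#'
#' @param blocks A block tibble (single `chrom` and `strand`).
#' @param max_chain_gap_nt Maximum allowed subject gap between consecutive
#'   blocks.
#' @return A list of class `alignment_chain`: `blocks` (the chained subset,
#'   in order), `total_score`, `n_blocks`, `subject_gaps`; `NULL` for empty
#'   input.
#' @export
chain_blocks <- function(blocks, max_chain_gap_nt = 10000L) {
  if (is.null(blocks) || nrow(blocks) == 0) return(NULL)
  if (length(unique(blocks$chrom)) > 1 || length(unique(blocks$strand)) > 1) {
    abort("chain_blocks() expects blocks on one subject and one strand")
  }
  b <- blocks |> arrange(.data$s_start, .data$s_end)
  n <- nrow(b)
  best <- b$score
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      gap <- b$s_start[i] - b$s_end[j]
      if (gap < 0 || gap > max_chain_gap_nt) next
      if (b$q_start[i] < b$q_end[j]) next
      cand <- best[j] + b$score[i]
      if (cand > best[i]) {
        best[i] <- cand
        prev[i] <- j
      }
    }
  }
  end <- which.max(best)
  path <- integer(0)
  i <- end
  while (!is.na(i)) {
    path <- c(i, path)
    i <- prev[i]
  }
  chain <- b[path, , drop = FALSE]
  gaps <- if (nrow(chain) > 1) {
    chain$s_start[-1] - chain$s_end[-nrow(chain)]
  } else {
    numeric(0)
  }
  structure(
    list(
      blocks = chain, total_score = best[end],
      n_blocks = nrow(chain), subject_gaps = gaps
    ),
    class = "alignment_chain"
  )
}
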