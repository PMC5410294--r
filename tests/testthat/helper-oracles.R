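# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own algorithms: plain substring scans, explicit
# structure enumeration, direct hypergeometric summation, exhaustive window
# enumeration.

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Every perfect-match placement of `tag` on both strands of every chromosome,
## by scanning every offset. 0-based half-open, tie-break order.
oracle_scan <- function(tag, genome) {
  out <- list()
  w <- nchar(tag)
  rc <- oracle_revcomp(tag)
  for (chrom in sort(names(genome))) {
    g <- genome[[chrom]]
    n <- nchar(g)
    if (n < w) next
    for (s in 0:(n - w)) {
      win <- substr(g, s + 1, s + w)
      if (win == tag) {
        out[[length(out) + 1]] <- data.frame(chrom = chrom, start = s,
                                             end = s + w, strand = "+")
      }
      if (win == rc) {
        out[[length(out) + 1]] <- data.frame(chrom = chrom, start = s,
                                             end = s + w, strand = "-")
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start, df$strand), , drop = FALSE]
}

oracle_can_pair <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

## Exhaustively enumerate every valid nested structure (pair set) of a short
## sequence and return the maximum pair count. Pure recursion over explicit
## structures; no memoization, no shared code with the DP.
oracle_max_pairs <- function(seq, min_loop = 3) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  rec <- function(i, j) {
    # all structures on positions i..j (1-based), as a vector of pair counts
    if (j - i < min_loop + 1) return(0L)
    counts <- rec(i + 1, j)                  # i unpaired
    for (k in seq(i + min_loop + 1, j)) {
      if (oracle_can_pair(ch[i], ch[k])) {
        cnt_in <- rec(i + 1, k - 1)
        cnt_out <- if (k < j) rec(k + 1, j) else 0L
        counts <- c(counts, 1L + as.vector(outer(cnt_in, cnt_out, "+")))
      }
    }
    counts
  }
  max(rec(1, n))
}

## Two-sided Fisher p by direct summation of hypergeometric probabilities of
## all tables with the observed margins.
oracle_fisher_p <- function(a, ta, b, tb) {
  m <- a + b                    # first-column margin
  n1 <- ta                      # row totals
  lo <- max(0, m - tb)
  hi <- min(m, ta)
  probs <- dhyper(lo:hi, ta, tb, m)
  p_obs <- dhyper(a, ta, tb, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Tag ids belonging to at least one qualifying window: every pair of hits
## (window from start_i to end_j) is enumerated.
oracle_cluster_members <- function(hits, max_span = 10000, min_unique = 16) {
  members <- character(0)
  for (chrom in unique(hits$chrom)) {
    h <- hits[hits$chrom == chrom, , drop = FALSE]
    h <- h[order(h$start, h$end), , drop = FALSE]
    n <- nrow(h)
    for (i in seq_len(n)) {
      for (j in i:n) {
        inside <- h$start >= h$start[i] & h$end <= h$end[j]
        if (h$end[j] - h$start[i] < max_span &&
            length(unique(h$tag_id[inside])) >= min_unique) {
          members <- c(members, h$tag_id[inside])
        }
      }
    }
  }
  sort(unique(members))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Validity check for a predicted pair set: pairable bases, min loop, each
## position in at most one pair, no crossing pairs.
expect_valid_structure <- function(pairs, seq, min_loop = 3) {
  ch <- strsplit(seq, "")[[1]]
  if (nrow(pairs) == 0) return(invisible(TRUE))
  expect_true(all(pairs[, 2] - pairs[, 1] >= min_loop + 1))
  expect_true(all(mapply(function(i, j) oracle_can_pair(ch[i + 1], ch[j + 1]),
                         pairs[, 1], pairs[, 2])))
  expect_equal(anyDuplicated(c(pairs[, 1], pairs[, 2])), 0)
  if (nrow(pairs) > 1) {
    for (p in seq_len(nrow(pairs) - 1)) {
      for (q in (p + 1):nrow(pairs)) {
        i <- pairs[p, 1]; j <- pairs[p, 2]
        k <- pairs[q, 1]; l <- pairs[q, 2]
        crossing <- (i < k & k < j & j < l) | (k < i & i < l & l < j)
        expect_false(crossing)
      }
    }
  }
  invisible(TRUE)
}
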