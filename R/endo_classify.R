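#' Classify endo-siRNA candidates as TE-siRNAs
#'
#' A candidate whose sequence perfectly matches (either strand) any record of
#' the repeat library is labelled TE with that record's family. Ties across
#' families are broken by record order in the library (first wins).
#'
#' @param tags Candidate tag table (columns `tag_id`, `sequence`).
#' @param repeat_library Named character vector of repeat sequences; each name
#'   must carry a `family=<LTR|SINE|L1|ERV|...>` tag.
#' @return Data frame of calls: tag_id, subclass ("TE"), family, locus
#'   (matching repeat record id).
#' @export
classify_te <- function(tags, repeat_library) {
  ids <- names(repeat_library)
  fam <- regmatches(ids, regexpr("family=[^ ]+", ids))
  if (length(fam) != length(ids) || any(!grepl("family=", ids))) {
    bad <- ids[!grepl("family=", ids)][1]
    stopf("repeat record '%s' has no parsable family= tag", bad)
  }
  fam <- sub("family=", "", fam)
  locus <- sub(" .*$", "", ids)
  calls <- list()
  for (i in seq_len(nrow(tags))) {
    hit <- match_reference(tags$sequence[i], repeat_library)
    if (!is.na(hit)) {
      k <- match(hit, ids)
      calls[[length(calls) + 1L]] <- data.frame(
        tag_id = tags$tag_id[i], subclass = "TE", family = fam[k],
        locus = locus[k], stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(empty_calls())
  do.call(rbind, calls)
}

empty_calls <- function() {
  data.frame(tag_id = character(0), subclass = character(0),
             family = character(0), locus = character(0),
             stringsAsFactors = FALSE)
}

#' Find genomic small-RNA clusters
#'
#' Clusters are maximal runs of hits built greedily left-to-right per
#' chromosome: the current run is extended while the span from the first hit
#' start to the candidate hit end stays strictly below `max_span` nt; a run is
#' emitted as a cluster iff it contains at least `min_unique` distinct tag
#' sequences. Successive runs are disjoint.
#'
#' @param hits Hit table (tag_id, chrom, start, end, strand).
#' @param max_span Maximum cluster span in nt (exclusive bound).
#' @param min_unique Minimum distinct tag sequences per cluster.
#' @return List with `clusters` (cluster_id, chrom, start, end, n_hits,
#'   n_unique) and `members` (cluster_id, tag_id).
#' @export
find_clusters <- function(hits, max_span = 10000L, min_unique = 16L) {
  clusters <- list()
  members <- list()
  cid <- 0L
  for (chrom in sort(unique(hits$chrom))) {
    h <- hits[hits$chrom == chrom, , drop = FALSE]
    h <- h[order(h$start, h$end), , drop = FALSE]
    i <- 1L
    n <- nrow(h)
    while (i <= n) {
      j <- i
      while (j + 1L <= n && h$end[j + 1L] - h$start[i] < max_span) j <- j + 1L
      run <- h[i:j, , drop = FALSE]
      if (length(unique(run$tag_id)) >= min_unique) {
        cid <- cid + 1L
        id <- sprintf("cluster_%d", cid)
        clusters[[cid]] <- data.frame(
          cluster_id = id, chrom = chrom, start = min(run$start),
          end = max(run$end), n_hits = nrow(run),
          n_unique = length(unique(run$tag_id)), stringsAsFactors = FALSE)
        members[[cid]] <- data.frame(cluster_id = id, tag_id = run$tag_id,
                                     stringsAsFactors = FALSE)
      }
      i <- j + 1L
    }
  }
  list(
    clusters = if (length(clusters)) do.call(rbind, clusters) else
      data.frame(cluster_id = character(0), chrom = character(0),
                 start = integer(0), end = integer(0), n_hits = integer(0),
                 n_unique = integer(0), stringsAsFactors = FALSE),
    members = if (length(members)) do.call(rbind, members) else
      data.frame(cluster_id = character(0), tag_id = character(0),
                 stringsAsFactors = FALSE))
}

#' Call Lhp-siRNAs from a folded cluster region
#'
#' The cluster region qualifies as a long hairpin iff its paired fraction is
#' at least `min_paired_fraction` and both arms are at least `min_arm` nt.
#' Qualifying tags are those whose hit interval lies entirely within the 5' or
#' 3' arm.
#'
#' @param cluster One row of the `clusters` table from [find_clusters()].
#' @param hairpin A [fold_region()] structure computed on the cluster region.
#' @param hits Hit table restricted or not (filtered to the cluster span
#'   internally).
#' @param min_paired_fraction,min_arm Long-hairpin qualification thresholds.
#' @return Data frame of calls (tag_id, subclass "Lhp", family "", locus =
#'   cluster id); empty when the region does not qualify.
#' @export
classify_lhp <- function(cluster, hairpin, hits,
                         min_paired_fraction = 0.5, min_arm = 20L) {
  if (is.null(hairpin$arm5) ||
      hairpin$paired_fraction < min_paired_fraction ||
      diff(hairpin$arm5) < min_arm || diff(hairpin$arm3) < min_arm) {
    return(empty_calls())
  }
  h <- hits[hits$chrom == cluster$chrom & hits$start >= cluster$start &
              hits$end <= cluster$end, , drop = FALSE]
  rel_start <- h$start - cluster$start
  rel_end <- h$end - cluster$start
  in_arm <- (rel_start >= hairpin$arm5[1] & rel_end <= hairpin$arm5[2]) |
    (rel_start >= hairpin$arm3[1] & rel_end <= hairpin$arm3[2])
  if (!any(in_arm)) return(empty_calls())
  data.frame(tag_id = unique(h$tag_id[in_arm]), subclass = "Lhp", family = "",
             locus = cluster$cluster_id, stringsAsFactors = FALSE)
}

#' Detect inverted-complement regions within an mRNA
#'
#' Searches an mRNA for a pair of arms such that the first arm is (nearly) the
#' reverse complement of the second. Candidate arm pairs are seeded by exact
#' inverted `seed_k`-mer matches grouped by antidiagonal, then refined and
#' scored by local alignment of the first arm against the reverse complement
#' of the second (match `match`, mismatch `mismatch`, gap open `gap_open`,
#' gap extend `gap_ext`). Pairs with aligned length at least `min_len` and
#' identity at least `min_identity` are reported; arm projections must not
#' overlap on the mRNA (a self-complementary palindromic stretch is split at
#' its centre into two adjacent arms); overlapping reported regions are merged
#' keeping the higher-scoring one.
#'
#' @param mrna mRNA sequence (>= 60 nt).
#' @param min_len Minimum aligned arm length.
#' @param min_identity Minimum fraction of reverse-complement-matched
#'   positions.
#' @param match,mismatch,gap_open,gap_ext blastn-like local alignment scores.
#' @param seed_k Seed k-mer length.
#' @param mrna_id Id recorded in the output.
#' @return Data frame of IC regions: mrna_id, arm1_start, arm1_end,
#'   arm2_start, arm2_end (0-based half-open, arm1 before arm2), region_length
#'   (arm length), identity, score.
#' @export
find_inverted_complement <- function(mrna, min_len = 30L, min_identity = 0.8,
                                     match = 2L, mismatch = -3L,
                                     gap_open = 5L, gap_ext = 2L,
                                     seed_k = 12L, mrna_id = "mrna") {
  assert_dna(mrna, "mRNA")
  L <- nchar(mrna)
  if (L < 60L) stopf("mRNA too short for the IC search (%d nt < 60)", L)
  chars <- strsplit(mrna, "")[[1]]
  kmers <- substring(mrna, 1:(L - seed_k + 1L), seed_k:L)
  rc_kmers <- revcomp(kmers)
  pos_by_kmer <- split(seq_along(kmers), kmers)
  ## seeds (i, j), 0-based arm starts: mrna[i..i+k) == revcomp(mrna[j..j+k))
  seeds_i <- integer(0)
  seeds_j <- integer(0)
  for (j in seq_along(rc_kmers)) {
    ii <- pos_by_kmer[[rc_kmers[j]]]
    if (!is.null(ii)) {
      seeds_i <- c(seeds_i, ii - 1L)
      seeds_j <- c(seeds_j, rep(j - 1L, length(ii)))
    }
  }
  ## canonical order (arm1 at or before arm2) and antidiagonal grouping
  keep <- seeds_i <= seeds_j
  seeds_i <- seeds_i[keep]; seeds_j <- seeds_j[keep]
  if (!length(seeds_i)) return(empty_ic(mrna_id))
  d <- seeds_i + seeds_j
  cand <- list()
  for (dg in unique(d)) {
    ii <- sort(unique(seeds_i[d == dg]))
    ## merge seed runs, bridging gaps from isolated mismatches
    grp <- cumsum(c(1L, diff(ii) > 3L * seed_k))
    for (g in split(ii, grp)) {
      i_min <- g[1]; i_max <- g[length(g)]
      a1 <- c(i_min, i_max + seed_k)          # arm1, 0-based half-open
      a2 <- c(dg - i_max, dg - i_min + seed_k) # arm2 via antidiagonal
      cand[[length(cand) + 1L]] <- list(arm1 = a1, arm2 = a2)
    }
  }
  regions <- list()
  for (cd in cand) {
    a1 <- cd$arm1; a2 <- cd$arm2
    if (a1[2] > a2[1]) {
      ## self-complementary palindromic stretch: split at the centre
      lo <- min(a1[1], a2[1]); hi <- max(a1[2], a2[2])
      mid <- lo + (hi - lo) %/% 2L
      a1 <- c(lo, mid); a2 <- c(mid, hi)
      m <- min(diff(a1), diff(a2))
      a1 <- c(mid - m, mid); a2 <- c(mid, mid + m)
      if (m < min_len) next
      s1 <- substr(mrna, a1[1] + 1L, a1[2])
      s2 <- substr(mrna, a2[1] + 1L, a2[2])
      idn <- mean(strsplit(s1, "")[[1]] == strsplit(revcomp(s2), "")[[1]])
      if (idn < min_identity) next
      regions[[length(regions) + 1L]] <- data.frame(
        mrna_id = mrna_id, arm1_start = a1[1], arm1_end = a1[2],
        arm2_start = a2[1], arm2_end = a2[2], region_length = m,
        identity = idn, score = match * round(idn * m), stringsAsFactors = FALSE)
      next
    }
    ## pad and refine by local alignment of arm1 vs revcomp(arm2)
    pad <- 15L
    w1 <- c(max(0L, a1[1] - pad), min(a2[1], a1[2] + pad))
    w2 <- c(max(a1[2], a2[1] - pad), min(L, a2[2] + pad))
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(substr(mrna, w1[1] + 1L, w1[2])),
      Biostrings::reverseComplement(
        Biostrings::DNAString(substr(mrna, w2[1] + 1L, w2[2]))),
      type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = match, mismatch = mismatch, baseOnly = TRUE),
      gapOpening = abs(gap_open), gapExtension = abs(gap_ext))
    alen <- nchar(as.character(Biostrings::pattern(aln)))  # incl. gap columns
    if (alen < min_len) next
    idn <- Biostrings::nmatch(aln) / alen
    if (idn < min_identity) next
    q <- c(Biostrings::start(Biostrings::pattern(aln)),
           Biostrings::end(Biostrings::pattern(aln)))
    s <- c(Biostrings::start(Biostrings::subject(aln)),
           Biostrings::end(Biostrings::subject(aln)))
    w2_len <- w2[2] - w2[1]
    arm1 <- c(w1[1] + q[1] - 1L, w1[1] + q[2])           # 0-based half-open
    arm2 <- c(w2[1] + w2_len - s[2], w2[1] + w2_len - s[1] + 1L)
    if (arm1[2] > arm2[1]) next                           # overlap: discard
    m <- min(diff(arm1), diff(arm2))
    regions[[length(regions) + 1L]] <- data.frame(
      mrna_id = mrna_id, arm1_start = arm1[1], arm1_end = arm1[1] + m,
      arm2_start = arm2[2] - m, arm2_end = arm2[2], region_length = m,
      identity = idn, score = Biostrings::score(aln), stringsAsFactors = FALSE)
  }
  if (!length(regions)) return(empty_ic(mrna_id))
  out <- do.call(rbind, regions)
  merge_ic_regions(out)
}

empty_ic <- function(mrna_id) {
  data.frame(mrna_id = character(0), arm1_start = integer(0),
             arm1_end = integer(0), arm2_start = integer(0),
             arm2_end = integer(0), region_length = integer(0),
             identity = numeric(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

## Overlapping reported regions collapse to the higher-scoring one.
merge_ic_regions <- function(regions) {
  regions <- regions[order(-regions$score), , drop = FALSE]
  kept <- list()
  overlaps <- function(a, b) {
    span_a <- c(a$arm1_start, a$arm2_end)
    span_b <- c(b$arm1_start, b$arm2_end)
    span_a[1] < span_b[2] && span_b[1] < span_a[2]
  }
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, , drop = FALSE]
    if (!any(vapply(kept, function(k) overlaps(k, r), logical(1)))) {
      kept[[length(kept) + 1L]] <- r
    }
  }
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  out[order(out$arm1_start), , drop = FALSE]
}

#' Assign IC-siRNA calls from mRNA placements
#'
#' Tags whose perfect-match placement on an mRNA lies entirely within arm1 or
#' arm2 of an inverted-complement region of that mRNA get subclass IC.
#'
#' @param mrna_hits Hit table of candidate tags mapped against the mRNA set
#'   (the `chrom` column holds mRNA ids; see [map_tags()]).
#' @param regions IC region table from [find_inverted_complement()].
#' @return Call data frame (tag_id, subclass "IC", family "", locus = mRNA id).
#' @export
assign_ic <- function(mrna_hits, regions) {
  calls <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    h <- mrna_hits[mrna_hits$chrom == r$mrna_id, , drop = FALSE]
    inside <- (h$start >= r$arm1_start & h$end <= r$arm1_end) |
      (h$start >= r$arm2_start & h$end <= r$arm2_end)
    if (any(inside)) {
      calls[[length(calls) + 1L]] <- data.frame(
        tag_id = unique(h$tag_id[inside]), subclass = "IC", family = "",
        locus = r$mrna_id, stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(empty_calls())
  unique(do.call(rbind, calls))
}

#' Reconcile subclass calls into final annotations
#'
#' Endo-siRNA candidates with at least one subclass call become `endo_siRNA`
#' with subclass priority TE > Lhp > IC when several apply; candidates with no
#' call revert to `unknown`. Other tiers pass through unchanged.
#'
#' @param annotations Tier annotation table from [annotate_tiers()].
#' @param calls Call table (rbind of [classify_te()], [classify_lhp()],
#'   [assign_ic()] outputs).
#' @return Final annotation data frame: tag_id, label, subclass, family,
#'   locus, evidence.
#' @export
finalize_labels <- function(annotations, calls) {
  priority <- c(TE = 1L, Lhp = 2L, IC = 3L)
  out <- annotations
  out$subclass <- ""
  out$family <- ""
  out$locus <- ""
  cand <- out$label == "endo_siRNA_candidate"
  for (i in which(cand)) {
    cc <- calls[calls$tag_id == out$tag_id[i], , drop = FALSE]
    if (nrow(cc)) {
      cc <- cc[order(priority[cc$subclass]), , drop = FALSE]
      out$label[i] <- "endo_siRNA"
      out$subclass[i] <- cc$subclass[1]
      out$family[i] <- cc$family[1]
      out$locus[i] <- cc$locus[1]
    } else {
      out$label[i] <- "unknown"
    }
  }
  out[, c("tag_id", "label", "subclass", "family", "locus", "evidence")]
}
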