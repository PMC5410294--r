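#' Specify a toy genome with planted small-RNA features
#'
#' Builds the validated specification consumed by [build_toy_genome()]. The
#' genome is a single random chromosome into which copies of transposable
#' elements, long-hairpin loci, inverted-complement (IC) mRNAs, an L1
#' retrotransposon locus with an antisense-promoter homology block, and
#' free-standing miRNA/piRNA/unknown tag sites are planted at stated,
#' non-overlapping positions.
#'
#' Positions are 0-based offsets on the toy chromosome. Every planted feature
#' carries the number of distinct small-RNA tags to plant inside it; tags are
#' exact substrings of their feature, which guarantees perfect-match
#' mappability downstream.
#'
#' @param genome_length Chromosome length in nt.
#' @param seed Integer seed; the whole construction is deterministic in it.
#' @param te_copies List of `list(family, length, position)` with family one of
#'   LTR, SINE, L1, ERV. Each copy is also emitted into the repeat library.
#' @param hairpin_loci List of `list(arm, loop, position, n_tags)`; each locus
#'   is an exact inverted repeat (arm, loop, reverse-complement arm) with
#'   `n_tags` tags spread over the two arms, pinned so the first tag starts at
#'   the locus start and the last ends at the locus end.
#' @param ic_mrnas List of `list(length, arm, spacer, position, n_tags,
#'   n_decoys)`; each mRNA contains segment S, a spacer, then the reverse
#'   complement of S; `n_tags` tags are planted inside the arms and `n_decoys`
#'   inside the spacer.
#' @param l1_locus `NULL`, or a list with fields `position`, `utr5`, `orf1`,
#'   `orf2`, `utr3` (lengths in nt), `asp_block` (promoter-coordinate interval,
#'   e.g. `c(-365, -1)`), `orf2_sub_offset` (offset of the homologous
#'   sub-interval within ORF2), `asl1_span` (promoter coordinates, e.g.
#'   `c(93, -490)`), `n_duplex_tags`, `n_decoy_tags`. The upstream sequence at
#'   `asp_block` is planted as the exact reverse complement of the ORF2
#'   sub-interval; the element itself is emitted into the repeat library with
#'   family L1.
#' @param mirna_sites,pirna_sites,unknown_sites Lists of
#'   `list(position, length)` single-tag sites. miRNA sites are emitted into
#'   the miRNA reference set; piRNA sites into the piRNA reference set when
#'   their length is 25 or less (otherwise the >24 nt length rule annotates
#'   them); unknown sites match no reference.
#' @param lib_names Library names for the intended abundance columns.
#' @param abundance Default intended abundance of every planted tag in every
#'   library; individual feature entries may override with their own
#'   `abundance` field (scalar or named by library).
#' @param chrom Chromosome name.
#' @return A validated spec object of class `toy_genome_spec`.
#' @export
toy_genome_spec <- function(genome_length, seed,
                            te_copies = list(),
                            hairpin_loci = list(),
                            ic_mrnas = list(),
                            l1_locus = NULL,
                            mirna_sites = list(),
                            pirna_sites = list(),
                            unknown_sites = list(),
                            lib_names = c("sperm", "oocyte", "zygote"),
                            abundance = 50,
                            chrom = "chr1") {
  spec <- structure(list(
    genome_length = as.integer(genome_length), seed = as.integer(seed),
    te_copies = te_copies, hairpin_loci = hairpin_loci, ic_mrnas = ic_mrnas,
    l1_locus = l1_locus, mirna_sites = mirna_sites,
    pirna_sites = pirna_sites, unknown_sites = unknown_sites,
    lib_names = lib_names, abundance = abundance, chrom = chrom
  ), class = "toy_genome_spec")
  validate_toy_genome_spec(spec)
  spec
}

feature_intervals <- function(spec) {
  iv <- list()
  add <- function(id, start, len) {
    iv[[length(iv) + 1L]] <<- list(id = id, start = as.integer(start),
                                   end = as.integer(start + len))
  }
  for (i in seq_along(spec$te_copies)) {
    te <- spec$te_copies[[i]]
    add(sprintf("te_%d_%s", i, te$family), te$position, te$length)
  }
  for (i in seq_along(spec$hairpin_loci)) {
    h <- spec$hairpin_loci[[i]]
    add(sprintf("hairpin_%d", i), h$position, 2L * h$arm + h$loop)
  }
  for (i in seq_along(spec$ic_mrnas)) {
    m <- spec$ic_mrnas[[i]]
    add(sprintf("ic_mrna_%d", i), m$position, m$length)
  }
  if (!is.null(spec$l1_locus)) {
    l1 <- spec$l1_locus
    len <- l1$utr5 + l1$orf1 + l1$orf2 + l1$utr3
    ## the upstream homology block is part of the planted footprint
    up <- max(-min(l1$asp_block), 0L)
    add("l1_1", l1$position - up, len + up)
  }
  for (kind in c("mirna", "pirna", "unknown")) {
    sites <- spec[[paste0(kind, "_sites")]]
    for (i in seq_along(sites)) {
      add(sprintf("%s_%d", kind, i), sites[[i]]$position, sites[[i]]$length)
    }
  }
  iv
}

validate_toy_genome_spec <- function(spec) {
  if (spec$genome_length <= 0L) stopf("genome_length must be positive")
  for (h in spec$hairpin_loci) {
    if (h$arm <= 0L || h$loop <= 0L) stopf("hairpin arm and loop must be positive")
  }
  for (m in spec$ic_mrnas) {
    if (m$arm <= 0L || m$spacer < 0L) stopf("IC arm must be positive, spacer non-negative")
    if (m$length < 2L * m$arm + m$spacer) {
      stopf("IC mRNA length %d too short for arms %d + spacer %d",
            m$length, m$arm, m$spacer)
    }
  }
  iv <- feature_intervals(spec)
  for (x in iv) {
    if (x$start < 0L || x$end > spec$genome_length) {
      stopf("feature %s [%d, %d) lies outside the genome [0, %d)",
            x$id, x$start, x$end, spec$genome_length)
    }
  }
  if (length(iv) > 1L) {
    ord <- order(vapply(iv, `[[`, integer(1), "start"))
    iv <- iv[ord]
    for (k in seq_len(length(iv) - 1L)) {
      if (iv[[k]]$end > iv[[k + 1L]]$start) {
        stopf("planted features overlap: %s [%d, %d) and %s [%d, %d)",
              iv[[k]]$id, iv[[k]]$start, iv[[k]]$end,
              iv[[k + 1L]]$id, iv[[k + 1L]]$start, iv[[k + 1L]]$end)
      }
    }
  }
  invisible(spec)
}

## Evenly spaced 0-based start offsets for n tags of length tag_len placed in
## [0, span), pinned so the first starts at 0 and the last ends at span.
spread_offsets <- function(n, span, tag_len) {
  if (n == 1L) return(0L)
  as.integer(round(seq(0L, span - tag_len, length.out = n)))
}

resolve_abundance <- function(feature, spec) {
  ab <- feature$abundance %||% spec$abundance
  if (length(ab) == 1L && is.null(names(ab))) {
    ab <- setNames(rep(as.numeric(ab), length(spec$lib_names)), spec$lib_names)
  }
  if (!all(spec$lib_names %in% names(ab))) {
    stopf("abundance must name every library: %s",
          paste(spec$lib_names, collapse = ", "))
  }
  ab[spec$lib_names]
}

#' Build a toy genome with planted features and a truth table
#'
#' Deterministically (in `spec$seed`) constructs the genome sequence, the
#' feature annotation table, the reference sets, and a truth table giving each
#' planted tag's sequence, source feature and intended final label.
#'
#' @param spec A [toy_genome_spec()].
#' @return A list with elements `genome` (named character, one chromosome),
#'   `features` (BED-style data frame), `truth` (data frame: tag_id, sequence,
#'   feature_id, label, family, one `abund_<lib>` column per library),
#'   `repeat_library`, `mirna_ref`, `pirna_ref`, `structural_ref` (named
#'   character vectors; headers of the repeat library carry `family=` tags),
#'   `mrnas` (named character), and `l1` (list of L1 model inputs: tss,
#'   strand, element/ORF2 coordinates, `asl1_span`, `asp_block`).
#' @export
build_toy_genome <- function(spec) {
  validate_toy_genome_spec(spec)
  set.seed(spec$seed)
  g <- sample(DNA_BASES, spec$genome_length, replace = TRUE)

  feats <- list()
  truth <- list()
  rep_lib <- character(0)
  mirna_ref <- character(0)
  pirna_ref <- character(0)
  mrnas <- character(0)
  l1_model <- NULL

  add_feat <- function(id, start, end, strand = "+") {
    feats[[length(feats) + 1L]] <<- data.frame(
      chrom = spec$chrom, start = start, end = end, name = id, score = 0,
      strand = strand, stringsAsFactors = FALSE)
  }
  add_truth <- function(seq, feature_id, label, family = "", feature = list()) {
    ab <- resolve_abundance(feature, spec)
    row <- data.frame(tag_id = paste0("tag_", seq), sequence = seq,
                      feature_id = feature_id, label = label, family = family,
                      stringsAsFactors = FALSE)
    for (lib in spec$lib_names) row[[paste0("abund_", lib)]] <- ab[[lib]]
    truth[[length(truth) + 1L]] <<- row
  }
  plant <- function(start, seq_chars) {
    g[(start + 1L):(start + length(seq_chars))] <<- seq_chars
  }
  ## Break chance complementarity just outside a planted homology arm pair:
  ## force position a + dir*t to equal position b - dir*t for t = 0..k-1
  ## (equal bases never complement), so local alignments cannot profitably
  ## extend past the planted arm boundary in either direction.
  guard_edges <- function(a, b, dir, k = 8L) {
    for (t in 0:(k - 1L)) {
      ia <- a + dir * t; ib <- b - dir * t
      if (ia < 0L || ib < 0L || ia >= spec$genome_length ||
          ib >= spec$genome_length || ia == ib) break
      g[ia + 1L] <<- g[ib + 1L]
    }
  }
  sub_g <- function(start, len) {
    paste(g[(start + 1L):(start + len)], collapse = "")
  }

  ## TE copies: a fresh random consensus per copy, inserted verbatim and
  ## recorded in the repeat library under its family tag.
  for (i in seq_along(spec$te_copies)) {
    te <- spec$te_copies[[i]]
    id <- sprintf("te_%d_%s", i, te$family)
    consensus <- random_dna(te$length)
    plant(te$position, strsplit(consensus, "")[[1]])
    add_feat(id, te$position, te$position + te$length)
    rep_lib[[sprintf("%s family=%s", id, te$family)]] <- consensus
    n_tags <- te$n_tags %||% 0L
    if (n_tags > 0L) {
      offs <- spread_offsets(n_tags, te$length, 21L)
      for (o in offs) {
        add_truth(substr(consensus, o + 1L, o + 21L), id,
                  "TE-siRNA", te$family, feature = te)
      }
    }
  }

  ## Hairpin loci: arm + loop + near-revcomp(arm); tags spread over the two
  ## arms, pinned to the locus ends so the cluster span equals the locus
  ## length. The 3' arm carries one substitution per 10 nt (the mirror base,
  ## which can never pair, not even by G.U wobble) so that, as in real long
  ## hairpins, every tag has a unique perfect-match placement: tags from one
  ## arm do not also match the reverse complement of the other.
  for (i in seq_along(spec$hairpin_loci)) {
    h <- spec$hairpin_loci[[i]]
    id <- sprintf("hairpin_%d", i)
    arm_seq <- random_dna(h$arm)
    loop_seq <- random_dna(h$loop)
    arm5_chars <- strsplit(arm_seq, "")[[1]]
    arm3_chars <- strsplit(revcomp(arm_seq), "")[[1]]
    for (j in seq(10L, h$arm, by = 20L)) {
      arm3_chars[j] <- arm5_chars[h$arm - j + 1L]
    }
    locus <- paste0(arm_seq, loop_seq, paste(arm3_chars, collapse = ""))
    plant(h$position, strsplit(locus, "")[[1]])
    total <- 2L * h$arm + h$loop
    add_feat(id, h$position, h$position + total)
    tag_len <- 21L
    n5 <- ceiling(h$n_tags / 2)
    n3 <- h$n_tags - n5
    ## keep tags out of the innermost 15% of each arm: base-pair maximization
    ## can trade the bubble-weakened helix ends nearest the loop for denser
    ## loop-internal pairings, so the detected arms may fall a little short of
    ## the planted ones there; the outermost tags still pin the cluster span
    margin <- as.integer(ceiling(0.15 * h$arm))
    offs <- c(spread_offsets(n5, h$arm - margin, tag_len),
              if (n3 > 0L) h$arm + h$loop + margin +
                spread_offsets(n3, h$arm - margin, tag_len))
    for (o in offs) {
      add_truth(substr(locus, o + 1L, o + tag_len), id, "Lhp-siRNA", feature = h)
    }
  }

  ## IC mRNAs: prefix + S + spacer + revcomp(S) + suffix, planted on the
  ## genome and recorded as an mRNA sequence for the IC search.
  for (i in seq_along(spec$ic_mrnas)) {
    m <- spec$ic_mrnas[[i]]
    id <- sprintf("ic_mrna_%d", i)
    core <- 2L * m$arm + m$spacer
    pre_len <- (m$length - core) %/% 2L
    s_seq <- random_dna(m$arm)
    mrna <- paste0(random_dna(pre_len), s_seq, random_dna(m$spacer),
                   revcomp(s_seq), random_dna(m$length - core - pre_len))
    plant(m$position, strsplit(mrna, "")[[1]])
    add_feat(id, m$position, m$position + m$length)
    ## arm coordinates on the genome; guard both extension directions
    p1 <- m$position + pre_len
    p2 <- m$position + pre_len + m$arm + m$spacer
    guard_edges(p1 - 1L, p2 + m$arm, dir = -1L,
                k = min(8L, pre_len, m$length - core - pre_len))
    guard_edges(p1 + m$arm, p2 - 1L, dir = 1L, k = min(8L, m$spacer %/% 2L))
    mrna <- sub_g(m$position, m$length)
    mrnas[[id]] <- mrna
    tag_len <- 21L
    arm1_off <- pre_len
    arm2_off <- pre_len + m$arm + m$spacer
    n1 <- ceiling(m$n_tags / 2)
    n2 <- m$n_tags - n1
    offs <- c(arm1_off + spread_offsets(n1, m$arm, tag_len),
              if (n2 > 0L) arm2_off + spread_offsets(n2, m$arm, tag_len))
    for (o in offs) {
      add_truth(substr(mrna, o + 1L, o + tag_len), id, "IC-siRNA", feature = m)
    }
    n_dec <- m$n_decoys %||% 0L
    if (n_dec > 0L) {
      if (m$spacer < tag_len) stopf("spacer too short for decoy tags")
      doffs <- pre_len + m$arm + spread_offsets(n_dec, m$spacer, tag_len)
      for (o in doffs) add_truth(substr(mrna, o + 1L, o + tag_len), id, "unknown", feature = m)
    }
  }

  ## L1 locus: 5'UTR + ORF1 + ORF2 + 3'UTR on the + strand; the upstream block
  ## at asp_block (promoter coordinates) is the exact reverse complement of
  ## the ORF2 sub-interval, so the antisense-promoter transcript carries a
  ## stretch complementary to the L1 mRNA.
  if (!is.null(spec$l1_locus)) {
    l1 <- spec$l1_locus
    id <- "l1_1"
    len <- l1$utr5 + l1$orf1 + l1$orf2 + l1$utr3
    body <- random_dna(len)
    plant(l1$position, strsplit(body, "")[[1]])
    add_feat(id, l1$position, l1$position + len)
    rep_lib[[sprintf("%s family=L1", id)]] <- body

    block_len <- l1$asp_block[2] - l1$asp_block[1] + 1L  # promoter coords, no 0
    orf2_start <- l1$utr5 + l1$orf1                       # element-relative
    sub_start <- orf2_start + l1$orf2_sub_offset
    sub_seq <- substr(body, sub_start + 1L, sub_start + block_len)
    tss <- l1$position                                    # + strand: element start
    up_start <- promoter_to_offset(l1$asp_block[1], tss, "+")
    plant(up_start, strsplit(revcomp(sub_seq), "")[[1]])
    ## guard against chance extension of the upstream homology block
    sub_g_start <- l1$position + sub_start
    guard_edges(up_start - 1L, sub_g_start + block_len, dir = -1L)
    guard_edges(up_start + block_len, sub_g_start - 1L, dir = 1L)
    body <- sub_g(l1$position, len)
    rep_lib[[sprintf("%s family=L1", id)]] <- body
    sub_seq <- substr(body, sub_start + 1L, sub_start + block_len)

    tag_len <- 21L
    offs <- spread_offsets(l1$n_duplex_tags, block_len, tag_len)
    strands <- rep(c("+", "-"), length.out = l1$n_duplex_tags)
    for (k in seq_along(offs)) {
      s <- substr(sub_seq, offs[k] + 1L, offs[k] + tag_len)
      add_truth(if (strands[k] == "+") s else revcomp(s), id, "L1-siRNA", "L1", feature = l1)
    }
    n_dec <- l1$n_decoy_tags %||% 0L
    if (n_dec > 0L) {
      ## decoys inside ORF2 but outside the homologous sub-interval
      dec_span <- l1$orf2_sub_offset
      if (dec_span < tag_len) stopf("no room for L1 decoy tags before the ORF2 sub-interval")
      doffs <- orf2_start + spread_offsets(n_dec, dec_span, tag_len)
      for (o in doffs) {
        add_truth(substr(body, o + 1L, o + tag_len), id, "TE-siRNA", "L1", feature = l1)
      }
    }
    l1_model <- list(
      chrom = spec$chrom, strand = "+", tss = tss,
      element_start = l1$position, element_end = l1$position + len,
      orf2_start = l1$position + orf2_start,
      orf2_end = l1$position + orf2_start + l1$orf2,
      utr3_start = l1$position + orf2_start + l1$orf2,
      utr3_end = l1$position + len,
      asl1_span = l1$asl1_span, asp_block = l1$asp_block,
      orf2_sub = c(sub_start, sub_start + block_len)  # element-relative
    )
  }

  ## Free-standing single-tag sites.
  for (i in seq_along(spec$mirna_sites)) {
    s <- spec$mirna_sites[[i]]
    id <- sprintf("mirna_%d", i)
    seq <- sub_g(s$position, s$length)
    add_feat(id, s$position, s$position + s$length)
    mirna_ref[[id]] <- seq
    add_truth(seq, id, "miRNA", feature = s)
  }
  for (i in seq_along(spec$pirna_sites)) {
    s <- spec$pirna_sites[[i]]
    id <- sprintf("pirna_%d", i)
    seq <- sub_g(s$position, s$length)
    add_feat(id, s$position, s$position + s$length)
    if (s$length <= 24L) pirna_ref[[id]] <- seq
    add_truth(seq, id, "piRNA", feature = s)
  }
  for (i in seq_along(spec$unknown_sites)) {
    s <- spec$unknown_sites[[i]]
    id <- sprintf("unknown_%d", i)
    seq <- sub_g(s$position, s$length)
    add_feat(id, s$position, s$position + s$length)
    add_truth(seq, id, "unknown", feature = s)
  }

  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(tag_id = character(0), sequence = character(0),
               feature_id = character(0), label = character(0),
               family = character(0), stringsAsFactors = FALSE)
  if (anyDuplicated(truth_df$sequence)) {
    stopf("planted tag sequences collide; choose a different seed or layout")
  }
  genome <- setNames(paste(g, collapse = ""), spec$chrom)
  for (seq in truth_df$sequence) {
    stopifnot(grepl(seq, genome[[1]], fixed = TRUE) ||
                grepl(revcomp(seq), genome[[1]], fixed = TRUE))
  }
  list(genome = genome,
       features = if (length(feats)) do.call(rbind, feats) else NULL,
       truth = truth_df, repeat_library = rep_lib,
       mirna_ref = mirna_ref, pirna_ref = pirna_ref,
       structural_ref = character(0), mrnas = mrnas, l1 = l1_model)
}

#' Simulate stage-specific small-RNA FASTQ libraries
#'
#' Draws reads per library by multinomial sampling from the truth table's
#' intended abundances, adds a configurable fraction of background reads
#' sampled from random genome positions with a bimodal length mixture
#' (0.5 N(23, 1) + 0.5 N(27.5, 0.8), discretised and clipped to 18–30 nt,
#' matching the bimodal tag-length pattern of gamete/zygote libraries), and
#' appends a 3' adapter. Deterministic for a fixed seed.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param truth Truth table from [build_toy_genome()].
#' @param lib_names Libraries to simulate; each needs an `abund_<lib>` column.
#' @param depth Reads per library (recycled to `length(lib_names)`).
#' @param seed Integer seed.
#' @param out_dir Directory for `<lib>.fastq` files.
#' @param background_fraction Expected fraction of background reads.
#' @param adapter 3' adapter appended to every read ("" for none).
#' @return Named character vector of FASTQ paths.
#' @export
simulate_libraries <- function(genome, truth, lib_names, depth, seed,
                               out_dir = tempfile("simlib"),
                               background_fraction = 0.1,
                               adapter = "TGGAATTCTCGGGTGCCAAGG") {
  depth <- rep_len(as.integer(depth), length(lib_names))
  if (any(depth < 0L)) stopf("depths must be non-negative")
  if (nrow(truth) > 0L) {
    miss <- setdiff(paste0("abund_", lib_names), names(truth))
    if (length(miss)) stopf("unknown library name(s): no %s column(s) in truth",
                            paste(miss, collapse = ", "))
  }
  for (seq in truth$sequence) {
    if (!grepl(seq, genome[[1]], fixed = TRUE) &&
        !grepl(revcomp(seq), genome[[1]], fixed = TRUE)) {
      stopf("truth tag %s absent from genome", seq)
    }
  }
  if (nzchar(adapter) && nrow(truth) > 0L) {
    ## a planted tag containing the adapter probe would be truncated by the
    ## trimmer downstream; reject the world rather than corrupt the truth
    probe <- substr(adapter, 1L, 6L)
    bad <- grepl(probe, truth$sequence, fixed = TRUE)
    if (any(bad)) {
      stopf("planted tag %s contains the adapter prefix '%s'; choose a different seed or adapter",
            truth$sequence[which(bad)[1]], probe)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  glen <- nchar(genome[[1]])
  paths <- character(0)
  for (k in seq_along(lib_names)) {
    lib <- lib_names[k]
    n <- depth[k]
    reads <- character(0)
    if (n > 0L) {
      n_bg <- rbinom(1L, n, background_fraction)
      n_fg <- n - n_bg
      ab <- truth[[paste0("abund_", lib)]]
      if (n_fg > 0L && nrow(truth) > 0L && sum(ab) > 0) {
        counts <- as.integer(rmultinom(1L, n_fg, ab))
        reads <- rep(truth$sequence, counts)
      } else if (n_fg > 0L) {
        n_bg <- n  # nothing planted: all background
      }
      if (n_bg > 0L) {
        comp <- runif(n_bg) < 0.5
        lens <- ifelse(comp, rnorm(n_bg, 23, 1), rnorm(n_bg, 27.5, 0.8))
        lens <- pmin(pmax(as.integer(round(lens)), 18L), 30L)
        starts <- floor(runif(n_bg, 0, glen - lens))
        bg <- substring(genome[[1]], starts + 1L, starts + lens)
        minus <- runif(n_bg) < 0.5
        bg[minus] <- revcomp(bg[minus])
        reads <- c(reads, bg)
      }
      if (length(reads)) reads <- reads[sample.int(length(reads))]
    }
    if (length(reads) && nzchar(adapter)) reads <- paste0(reads, adapter)
    names(reads) <- if (length(reads)) sprintf("%s_read_%d", lib, seq_along(reads))
    path <- file.path(out_dir, paste0(lib, ".fastq"))
    write_fastq(reads, path)
    paths[[lib]] <- path
  }
  paths
}
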