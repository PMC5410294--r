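#' Convert a promoter coordinate to a 0-based genomic offset
#'
#' Promoter coordinates are signed integers with no position 0: +1 is the
#' first transcribed base at the transcription start site (TSS), -1 the first
#' base upstream of it. +k maps to k - 1 bases downstream of the TSS in the
#' transcription direction, -k to k bases upstream.
#'
#' @param coord Promoter coordinate(s), nonzero integers.
#' @param tss 0-based genomic offset of the TSS base.
#' @param strand "+" or "-": the element's transcription direction.
#' @return 0-based genomic offset(s).
#' @seealso [offset_to_promoter()] for the inverse.
#' @export
promoter_to_offset <- function(coord, tss, strand = "+") {
  if (any(coord == 0L)) stopf("promoter coordinate 0 does not exist")
  dir <- if (strand == "+") 1L else -1L
  ifelse(coord > 0L, tss + dir * (coord - 1L), tss + dir * coord)
}

#' Convert a 0-based genomic offset to a promoter coordinate
#'
#' Inverse of [promoter_to_offset()]; the pair is a bijection between genomic
#' offsets and nonzero signed coordinates.
#'
#' @param offset 0-based genomic offset(s).
#' @param tss 0-based genomic offset of the TSS base.
#' @param strand "+" or "-".
#' @return Promoter coordinate(s).
#' @export
offset_to_promoter <- function(offset, tss, strand = "+") {
  dir <- if (strand == "+") 1L else -1L
  d <- dir * (offset - tss)
  ifelse(d >= 0L, d + 1L, d)
}

## Linearise promoter coordinates (no zero) onto contiguous integers so that
## interval arithmetic is plain: -1 -> 0, +1 -> 1.
promoter_lin <- function(coord) ifelse(coord > 0L, coord, coord + 1L)

#' Extract upstream sequences of annotated L1 copies
#'
#' For a + strand copy, the `window` nt immediately 5' of the element start;
#' for a - strand copy, the reverse complement of the `window` nt 3' of the
#' element end. Sequences truncated by a chromosome end are flagged. In both
#' cases the returned sequence reads 5' to 3' away from the element, i.e. its
#' last base is promoter position -1.
#'
#' @param genome Named character vector of chromosomes, or FASTA path.
#' @param annotations 6-column BED path or data frame (see [read_bed()]) of L1
#'   copies with strand.
#' @param window Upstream window size in nt.
#' @return Data frame: name, chrom, start, end (genomic window, 0-based
#'   half-open), strand, truncated, sequence.
#' @export
extract_upstream <- function(genome, annotations, window = 3000L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (is.character(annotations)) annotations <- read_bed(annotations)
  out <- vector("list", nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    if (!a$chrom %in% names(genome)) stopf("unknown chromosome '%s'", a$chrom)
    clen <- nchar(genome[[a$chrom]])
    if (a$strand == "+") {
      ws <- max(0L, a$start - window); we <- a$start
    } else {
      ws <- a$end; we <- min(clen, a$end + window)
    }
    seq <- substr(genome[[a$chrom]], ws + 1L, we)
    if (a$strand == "-") seq <- revcomp(seq)
    out[[i]] <- data.frame(
      name = a$name, chrom = a$chrom, start = ws, end = we,
      strand = a$strand, truncated = (we - ws) < window, sequence = seq,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Locate antisense homology blocks in upstream sequences
#'
#' Each upstream sequence is locally aligned against the reverse complement of
#' the target region (ORF2 or 3' UTR of the L1 transcript), i.e. in antisense
#' orientation. Blocks with aligned length >= `min_len` and identity >=
#' `min_identity` are reported, with the upstream interval expressed in
#' promoter coordinates.
#'
#' @param upstreams Data frame from [extract_upstream()].
#' @param target Target region sequence (>= 100 nt), e.g. the ORF2 sequence in
#'   transcript orientation.
#' @param min_len Minimum aligned length.
#' @param min_identity Minimum fraction of matched positions.
#' @param match,mismatch,gap_open,gap_ext Local alignment scores.
#' @param target_offset 0-based offset of the target region on the transcript
#'   (added to the reported target interval).
#' @return Data frame of homology blocks: name (upstream id), up_from, up_to
#'   (promoter coordinates, up_from more upstream, both inclusive),
#'   target_start, target_end (0-based half-open on the transcript),
#'   length, identity, score, orientation ("antisense").
#' @export
find_homology <- function(upstreams, target, min_len = 50L, min_identity = 0.8,
                          match = 2L, mismatch = -3L, gap_open = 5L,
                          gap_ext = 2L, target_offset = 0L) {
  assert_dna(target, "target region")
  if (nchar(target) < 100L) stopf("target region too short (< 100 nt)")
  rc_target <- Biostrings::reverseComplement(Biostrings::DNAString(target))
  tlen <- nchar(target)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  blocks <- list()
  for (i in seq_len(nrow(upstreams))) {
    useq <- upstreams$sequence[i]
    if (nchar(useq) < min_len) next
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(useq), rc_target, type = "local",
      substitutionMatrix = submat,
      gapOpening = abs(gap_open), gapExtension = abs(gap_ext))
    alen <- nchar(as.character(Biostrings::pattern(aln)))  # incl. gap columns
    if (alen < min_len) next
    idn <- Biostrings::nmatch(aln) / alen
    if (idn < min_identity) next
    W <- nchar(useq)
    qs <- Biostrings::start(Biostrings::pattern(aln))
    qe <- Biostrings::end(Biostrings::pattern(aln))
    ss <- Biostrings::start(Biostrings::subject(aln))
    se <- Biostrings::end(Biostrings::subject(aln))
    ## upstream window position w (1-based) is promoter coordinate -(W - w + 1)
    blocks[[length(blocks) + 1L]] <- data.frame(
      name = upstreams$name[i],
      up_from = -(W - qs + 1L), up_to = -(W - qe + 1L),
      ## subject is revcomp(target): positions map back end-for-end
      target_start = target_offset + tlen - se,
      target_end = target_offset + tlen - ss + 1L,
      length = alen, identity = idn,
      score = Biostrings::score(aln), orientation = "antisense",
      stringsAsFactors = FALSE)
  }
  if (!length(blocks)) {
    return(data.frame(name = character(0), up_from = integer(0),
                      up_to = integer(0), target_start = integer(0),
                      target_end = integer(0), length = integer(0),
                      identity = numeric(0), score = numeric(0),
                      orientation = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, blocks)
}

#' Model the dsRNA duplex between an antisense-promoter transcript and L1
#'
#' The duplex length is the number of positions in the intersection of the
#' homology block's upstream interval with the antisense transcript's span,
#' both in promoter coordinates (no position 0). A zero-length intersection is
#' reported as an inactive duplex.
#'
#' @param asl1_span Promoter-coordinate pair `c(downstream_end, upstream_end)`,
#'   e.g. `c(93, -490)` for a transcript initiating at +93 and ending at -490.
#' @param block One row of the [find_homology()] table (or a list with
#'   `up_from`, `up_to`, `target_start`, `target_end`).
#' @return A list of class `dsrna_duplex`: `asl1_span`, `block`, `length`,
#'   `active`, and `sense_interval` (the 0-based half-open transcript interval
#'   of the duplex on the L1 sense side, trimmed to the intersection).
#' @export
build_duplex <- function(asl1_span, block) {
  if (any(asl1_span == 0L)) stopf("promoter coordinate 0 does not exist")
  span_lin <- sort(promoter_lin(asl1_span))
  blk_lin <- sort(promoter_lin(c(block$up_from, block$up_to)))
  lo <- max(span_lin[1], blk_lin[1])
  hi <- min(span_lin[2], blk_lin[2])
  len <- max(0L, hi - lo + 1L)
  sense <- NULL
  if (len > 0L) {
    ## positions cut from the block map end-for-end onto the target interval:
    ## the block end nearest the TSS corresponds to the target interval start
    cut_low <- lo - blk_lin[1]   # trimmed at the far-upstream end
    cut_high <- blk_lin[2] - hi  # trimmed at the TSS-proximal end
    sense <- c(block$target_start + cut_high, block$target_end - cut_low)
  }
  structure(list(asl1_span = asl1_span,
                 block = block, length = as.integer(len),
                 active = len > 0L, sense_interval = sense),
            class = "dsrna_duplex")
}

#' Assign L1-siRNAs to a dsRNA duplex
#'
#' Tags whose placement lies entirely within the duplex's sense-side interval
#' are assigned, labelled sense or antisense relative to the L1 transcript.
#'
#' @param hits Hit table of candidate tags placed on L1 transcript coordinates
#'   (or genomic coordinates, if `sense_interval` is genomic): tag_id, start,
#'   end, strand.
#' @param duplex A [build_duplex()] object (with `sense_interval` on the same
#'   coordinate system as `hits`).
#' @param l1_strand Strand of the L1 transcript on those coordinates.
#' @return Data frame: tag_id, start, end, strand_label ("sense"/"antisense").
#' @export
assign_l1_sirnas <- function(hits, duplex, l1_strand = "+") {
  if (!isTRUE(duplex$active)) {
    return(data.frame(tag_id = character(0), start = integer(0),
                      end = integer(0), strand_label = character(0),
                      stringsAsFactors = FALSE))
  }
  inside <- hits$start >= duplex$sense_interval[1] &
    hits$end <= duplex$sense_interval[2]
  h <- hits[inside, , drop = FALSE]
  data.frame(tag_id = h$tag_id, start = h$start, end = h$end,
             strand_label = ifelse(h$strand == l1_strand, "sense", "antisense"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Spliced PCR product length
#'
#' Length of the retrotransposition-assay PCR product after intron loss:
#' `product_with_intron - intron`.
#'
#' @param product_with_intron Product length from the intron-containing
#'   cassette, bp.
#' @param intron Intron length, bp.
#' @return Spliced product length in bp.
#' @export
spliced_product_length <- function(product_with_intron, intron) {
  if (intron < 0 || intron >= product_with_intron) {
    stopf("intron length must satisfy 0 <= intron < product")
  }
  product_with_intron - intron
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((ct_target_sample - ct_ref_sample) -
#'      (ct_target_calibrator - ct_ref_calibrator))`.
#'
#' @param ct_target_sample,ct_ref_sample Target and reference-gene Ct in the
#'   sample.
#' @param ct_target_calibrator,ct_ref_calibrator The same in the calibrator.
#' @return Relative expression (1.0 means no change).
#' @export
fold_change_ddct <- function(ct_target_sample, ct_ref_sample,
                             ct_target_calibrator, ct_ref_calibrator) {
  stopifnot(is.finite(ct_target_sample), is.finite(ct_ref_sample),
            is.finite(ct_target_calibrator), is.finite(ct_ref_calibrator))
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}
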