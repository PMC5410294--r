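#' Build an exact-match genome index
#'
#' Prepares a genome for exact-substring queries on both strands. Ambiguity
#' codes in the genome (e.g. N) never match a tag base, so positions
#' overlapping N runs are never reported.
#'
#' @param genome Named character vector of chromosome sequences, or a FASTA
#'   path.
#' @return An object of class `genome_index`.
#' @export
build_index <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome)) &&
      file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (length(genome) == 0L || all(!nzchar(genome))) {
    stopf("empty genome: no sequences to index")
  }
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stopf("genome sequences must be named")
  }
  chroms <- sort(names(genome))  # lexicographic tie-break order
  subjects <- lapply(genome[chroms], Biostrings::DNAString)
  structure(list(chroms = chroms, subjects = subjects,
                 lengths = vapply(subjects, length, integer(1))),
            class = "genome_index")
}

## All perfect-match placements of one sequence, in tie-break order
## (chrom lexicographic, start ascending, + before -). 0-based half-open.
match_all <- function(seq, index) {
  pat <- Biostrings::DNAString(seq)
  rc <- Biostrings::reverseComplement(pat)
  out <- list()
  for (chrom in index$chroms) {
    subj <- index$subjects[[chrom]]
    plus <- Biostrings::start(Biostrings::matchPattern(pat, subj, fixed = TRUE))
    minus <- Biostrings::start(Biostrings::matchPattern(rc, subj, fixed = TRUE))
    if (length(plus) || length(minus)) {
      df <- data.frame(
        chrom = chrom,
        start = c(plus, minus) - 1L,
        strand = rep(c("+", "-"), c(length(plus), length(minus))),
        stringsAsFactors = FALSE)
      df <- df[order(df$start, df$strand), , drop = FALSE]
      out[[chrom]] <- df
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0)))
  }
  res <- do.call(rbind, out)
  res$end <- res$start + nchar(seq)
  rownames(res) <- NULL
  res[, c("chrom", "start", "end", "strand")]
}

#' Place one tag on the genome by perfect match
#'
#' If the tag has one or more perfect-match placements, exactly one hit is
#' returned: the minimum under the total order (chromosome name lexicographic,
#' start ascending, + before -). This makes the single-reported-hit policy of
#' short-read aligners reproducible. A tag with no perfect match returns
#' `NULL` and is excluded downstream.
#'
#' @param sequence Tag sequence.
#' @param index A [build_index()] object.
#' @return One-row data frame (chrom, start, end, strand) or `NULL`.
#' @export
map_tag <- function(sequence, index) {
  assert_dna(sequence, "tag")
  hits <- match_all(sequence, index)
  if (nrow(hits) == 0L) return(NULL)
  hits[1L, , drop = FALSE]
}

#' Map a tag table onto the genome
#'
#' @param tags Tag table from [filter_and_collapse()] (columns `tag_id`,
#'   `sequence`).
#' @param index A [build_index()] object.
#' @return A list with `hits` (data frame: tag_id, chrom, start, end, strand;
#'   0-based half-open) and `unmapped` (character vector of tag ids with no
#'   perfect match).
#' @export
map_tags <- function(tags, index) {
  rows <- vector("list", nrow(tags))
  for (i in seq_len(nrow(tags))) {
    h <- map_tag(tags$sequence[i], index)
    if (!is.null(h)) {
      h$tag_id <- tags$tag_id[i]
      rows[[i]] <- h[, c("tag_id", "chrom", "start", "end", "strand")]
    }
  }
  hits <- do.call(rbind, rows)
  if (is.null(hits)) {
    hits <- data.frame(tag_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0))
  }
  rownames(hits) <- NULL
  list(hits = hits, unmapped = setdiff(tags$tag_id, hits$tag_id))
}

#' Write genome hits as 6-column BED
#'
#' @param hits Hit table from [map_tags()].
#' @param tags Tag table (for total counts used as the BED score).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_hits_bed <- function(hits, tags, path) {
  total <- rowSums(as.matrix(tags[, tag_count_cols(tags), drop = FALSE]))
  names(total) <- tags$tag_id
  bed <- data.frame(chrom = hits$chrom, start = hits$start, end = hits$end,
                    name = hits$tag_id,
                    score = as.integer(total[hits$tag_id]),
                    strand = hits$strand, stringsAsFactors = FALSE)
  write_bed(bed, path)
}
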