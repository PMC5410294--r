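#' Trim the 3' adapter from read sequences
#'
#' Removes, from each read, the leftmost occurrence of a prefix of the adapter
#' (minimum overlap `min_overlap` nt, exact match) together with everything 3'
#' of it. Reads without such an occurrence are returned unchanged; a read that
#' begins with the adapter trims to the empty string (and is later removed by
#' the length filter).
#'
#' @param reads Character vector of read sequences.
#' @param adapter Adapter sequence (3' end of reads). Empty string disables
#'   trimming.
#' @param min_overlap Minimum adapter prefix length that triggers trimming.
#' @return Character vector of trimmed reads.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 6L) {
  if (!nzchar(adapter)) return(reads)
  probe <- substr(adapter, 1L, min(min_overlap, nchar(adapter)))
  hit <- regexpr(probe, reads, fixed = TRUE)
  keep <- ifelse(hit > 0L, hit - 1L, nchar(reads))
  substr(reads, 1L, keep)
}

#' Filter and collapse raw reads into unique small-RNA tags
#'
#' Applies the read-filtering cascade: reads containing unknown nucleotides
#' (anything outside A/C/G/T) are removed; the 3' adapter is trimmed; trimmed
#' reads shorter than `min_len` or longer than `max_len` nt are discarded;
#' identical sequences are collapsed into one tag with per-library counts; and
#' tags whose count is less than or equal to `min_count` are removed (by
#' default judged on the total across libraries; set
#' `count_filter_scope = "per-library"` to zero out low per-library counts
#' instead, dropping tags that survive nowhere).
#'
#' @param reads_per_library Named list of character vectors of read sequences
#'   (one element per library), or a named character vector of FASTQ paths.
#' @param adapter 3' adapter sequence ("" disables trimming).
#' @param min_len,max_len Retained tag length bounds (inclusive).
#' @param min_count Tags with count `<= min_count` are removed.
#' @param count_filter_scope `"total"` or `"per-library"`.
#' @param min_overlap Adapter minimum overlap, see [trim_adapter()].
#' @return A list with `tags` (data frame: tag_id, sequence, length, one
#'   `count_<lib>` column per library) and `stats` (per-library read
#'   bookkeeping: input, removed_n, removed_length, removed_lowcount, kept;
#'   the four outcome columns sum to input).
#' @export
filter_and_collapse <- function(reads_per_library, adapter,
                                min_len = 18L, max_len = 30L,
                                min_count = 2L,
                                count_filter_scope = c("total", "per-library"),
                                min_overlap = 6L) {
  count_filter_scope <- match.arg(count_filter_scope)
  libs <- names(reads_per_library)
  if (is.null(libs) || anyDuplicated(libs) || any(!nzchar(libs))) {
    stopf("library names must be unique and non-empty")
  }
  if (is.character(reads_per_library)) {
    reads_per_library <- lapply(reads_per_library, read_fastq)
  }

  per_lib <- lapply(libs, function(lib) {
    reads <- toupper(as.character(reads_per_library[[lib]]))
    n_in <- length(reads)
    has_n <- grepl("[^ACGT]", reads)
    reads <- reads[!has_n]
    reads <- trim_adapter(reads, adapter, min_overlap)
    len <- nchar(reads)
    ok <- len >= min_len & len <= max_len
    list(kept = reads[ok], n_in = n_in, removed_n = sum(has_n),
         removed_length = sum(!ok))
  })
  names(per_lib) <- libs

  all_seq <- sort(unique(unlist(lapply(per_lib, `[[`, "kept"))))
  counts <- vapply(libs, function(lib) {
    tab <- table(factor(per_lib[[lib]]$kept, levels = all_seq))
    as.integer(tab)
  }, integer(length(all_seq)))
  counts <- matrix(counts, nrow = length(all_seq),
                   dimnames = list(NULL, libs))

  removed_lowcount <- setNames(integer(length(libs)), libs)
  if (length(all_seq)) {
    if (count_filter_scope == "total") {
      drop <- rowSums(counts) <= min_count
      removed_lowcount <- colSums(counts[drop, , drop = FALSE])
      counts <- counts[!drop, , drop = FALSE]
      all_seq <- all_seq[!drop]
    } else {
      low <- counts <= min_count
      removed_lowcount <- colSums(counts * low)
      counts[low] <- 0L
      keep <- rowSums(counts) > 0L
      counts <- counts[keep, , drop = FALSE]
      all_seq <- all_seq[keep]
    }
  }

  tags <- data.frame(tag_id = paste0("tag_", all_seq, recycle0 = TRUE),
                     sequence = all_seq,
                     length = nchar(all_seq), stringsAsFactors = FALSE)
  for (lib in libs) tags[[paste0("count_", lib)]] <- counts[, lib]

  stats <- data.frame(
    library = libs,
    input = vapply(per_lib, `[[`, integer(1), "n_in"),
    removed_n = vapply(per_lib, `[[`, integer(1), "removed_n"),
    removed_length = vapply(per_lib, `[[`, integer(1), "removed_length"),
    removed_lowcount = as.integer(removed_lowcount),
    stringsAsFactors = FALSE, row.names = NULL)
  stats$kept <- stats$input - stats$removed_n - stats$removed_length -
    stats$removed_lowcount
  list(tags = tags, stats = stats)
}

tag_count_cols <- function(tags) grep("^count_", names(tags), value = TRUE)

tag_libraries <- function(tags) sub("^count_", "", tag_count_cols(tags))

#' Write collapsed tags as FASTA with `tag_id_xN` headers
#'
#' @param tags Tag table from [filter_and_collapse()].
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_tag_fasta <- function(tags, path) {
  total <- rowSums(as.matrix(tags[, tag_count_cols(tags), drop = FALSE]))
  seqs <- setNames(tags$sequence, sprintf("%s_x%d", tags$tag_id, total))
  write_fasta(seqs, path)
}
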