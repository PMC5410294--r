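#' Is a tag homologous to a reference sequence?
#'
#' Homology is operationalised as exact substring containment: the tag must
#' occur verbatim in the reference or in its reverse complement. A mismatch
#' tolerance can be configured but defaults to 0 (perfect match).
#'
#' @param tag Tag sequence.
#' @param ref Reference sequence.
#' @param max_mismatch Allowed mismatches (0 = exact).
#' @return `TRUE` if the tag matches the reference on either strand.
#' @export
is_homologous <- function(tag, ref, max_mismatch = 0L) {
  if (nchar(tag) > nchar(ref)) return(FALSE)
  if (max_mismatch == 0L) {
    return(grepl(tag, ref, fixed = TRUE) || grepl(tag, revcomp(ref), fixed = TRUE))
  }
  subj <- Biostrings::DNAString(ref)
  pat <- Biostrings::DNAString(tag)
  Biostrings::countPattern(pat, subj, max.mismatch = max_mismatch) > 0L ||
    Biostrings::countPattern(Biostrings::reverseComplement(pat), subj,
                             max.mismatch = max_mismatch) > 0L
}

## id of the first reference record matching the tag (either strand), or NA.
match_reference <- function(tag, refs, max_mismatch = 0L) {
  for (i in seq_along(refs)) {
    if (is_homologous(tag, refs[[i]], max_mismatch)) {
      return(names(refs)[i] %||% as.character(i))
    }
  }
  NA_character_
}

#' Tiered annotation of mapped tags
#'
#' Assigns each mapped tag to exactly one class, applying the tiers in order
#' with first match winning:
#' 1. `structural_ncRNA` — homologous to a tRNA/rRNA/snRNA/snoRNA reference;
#' 2. `miRNA` — length 21–24 nt and homologous to a miRNA reference;
#' 3. `piRNA` — homologous to a piRNA reference, or length 25–30 nt;
#' 4. `endo_siRNA_candidate` — length 18–24 nt;
#' 5. `unknown` — anything else (unreachable for 18–30 nt tags; kept
#'    defensively).
#'
#' An empty reference set raises a warning and its tier is skipped.
#'
#' @param tags Tag table (columns `tag_id`, `sequence`).
#' @param refs List with elements `structural`, `mirna`, `pirna`: named
#'   character vectors of reference sequences (may be empty).
#' @param max_mismatch Homology mismatch tolerance (default 0 = perfect match).
#' @return Data frame: tag_id, label, evidence (matched reference id, a
#'   length-rule marker, or "").
#' @export
annotate_tiers <- function(tags, refs, max_mismatch = 0L) {
  refs <- list(structural = refs$structural %||% character(0),
               mirna = refs$mirna %||% character(0),
               pirna = refs$pirna %||% character(0))
  for (kind in names(refs)) {
    if (length(refs[[kind]]) == 0L) {
      warning(sprintf("empty %s reference set: tier skipped", kind),
              call. = FALSE)
    }
  }
  n <- nrow(tags)
  label <- character(n)
  evidence <- character(n)
  for (i in seq_len(n)) {
    seq <- tags$sequence[i]
    len <- nchar(seq)
    hit <- match_reference(seq, refs$structural, max_mismatch)
    if (!is.na(hit)) {
      label[i] <- "structural_ncRNA"; evidence[i] <- hit; next
    }
    if (len >= 21L && len <= 24L) {
      hit <- match_reference(seq, refs$mirna, max_mismatch)
      if (!is.na(hit)) { label[i] <- "miRNA"; evidence[i] <- hit; next }
    }
    hit <- match_reference(seq, refs$pirna, max_mismatch)
    if (!is.na(hit)) { label[i] <- "piRNA"; evidence[i] <- hit; next }
    if (len >= 25L && len <= 30L) {
      label[i] <- "piRNA"; evidence[i] <- "length>24"; next
    }
    if (len >= 18L && len <= 24L) {
      label[i] <- "endo_siRNA_candidate"; evidence[i] <- "length18-24"; next
    }
    label[i] <- "unknown"; evidence[i] <- ""
  }
  data.frame(tag_id = tags$tag_id, label = label, evidence = evidence,
             stringsAsFactors = FALSE)
}
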