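#' @useDynLib endosirna, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fisher.test rbinom rmultinom rnorm runif setNames
#' @importFrom utils read.table write.table
#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reverse complement of DNA strings
#'
#' Vectorised wrapper around [Biostrings::reverseComplement()] that takes and
#' returns plain character vectors, which is how sequences travel between the
#' tabular stages of the pipeline.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Round half away from zero (base round() is banker's rounding).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

## Percentage as printed in class-summary tables: integer, half away from zero.
int_percent <- function(part, total) {
  if (total == 0) return(0L)
  as.integer(round_half_away(100 * part / total))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stopf("%s contains non-ACGT characters (first offender: '%s')",
          what, x[which(bad)[1]])
  }
  invisible(x)
}

## Random DNA of length n under the current RNG state.
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = NA, check.names = FALSE)
}

#' Write intervals as 6-column BED
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (0-based half-open coordinates).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(df, path) {
  need <- c("chrom", "start", "end", "name", "score", "strand")
  missing <- setdiff(need, names(df))
  if (length(missing)) stopf("write_bed: missing columns: %s",
                             paste(missing, collapse = ", "))
  write.table(df[, need], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 6-column BED file with validation
#'
#' Minimal strict reader for the pipeline's own interchange format. Malformed
#' lines are rejected with their line number so problems in hand-edited
#' annotation files are locatable.
#'
#' @param path BED file path.
#' @return Data frame with columns chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 6L) stopf("malformed BED line %d: expected 6 fields, got %d",
                              i, length(f))
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end) || start < 0L || end <= start) {
      stopf("malformed BED line %d: bad interval [%s, %s)", i, f[2], f[3])
    }
    if (!f[6] %in% c("+", "-")) stopf("malformed BED line %d: bad strand '%s'",
                                      i, f[6])
    out[[i]] <- data.frame(chrom = f[1], start = start, end = end,
                           name = f[4], score = suppressWarnings(as.numeric(f[5])),
                           strand = f[6], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Read a FASTQ file into a character vector of sequences
#'
#' Strict 4-line-record reader; gzip-transparent via base connections.
#' Malformed records are rejected with the 1-based record index.
#'
#' @param path FASTQ path (optionally gzipped).
#' @return Character vector of read sequences (names = read ids).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) return(setNames(character(0), character(0)))
  if (n %% 4L != 0L) {
    stopf("malformed FASTQ record %d: truncated record at end of file",
          n %/% 4L + 1L)
  }
  ids <- lines[seq(1L, n, by = 4L)]
  seqs <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  quals <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(ids, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(quals))
  if (length(bad)) stopf("malformed FASTQ record %d", bad[1])
  setNames(toupper(seqs), sub("^@", "", ids))
}

#' Write sequences as FASTQ with constant quality
#'
#' @param seqs Character vector of sequences; names used as read ids (default
#'   `read_1 ...`).
#' @param path Output path.
#' @param qual_char Single quality character applied to every base.
#' @return The path, invisibly.
#' @export
write_fastq <- function(seqs, path, qual_char = "I") {
  ids <- names(seqs) %||% NULL
  if (is.null(ids) || any(!nzchar(ids))) ids <- paste0("read_", seq_along(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(seqs)) {
    rec <- paste0("@", ids, "\n", seqs, "\n+\n",
                  vapply(nchar(seqs), function(k)
                    strrep(qual_char, k), character(1)))
    writeLines(rec, con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs) %||% paste0("seq_", seq_along(seqs))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
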