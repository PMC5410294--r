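#' Counts per million with a pseudocount
#'
#' Library-size normalization used by the enrichment screen. A pseudocount of
#' 0.5 is added to both the count and the library total so that fold changes
#' between libraries are always finite.
#'
#' @param count Read count(s) of a tag in one library.
#' @param total Library total read count (> 0).
#' @param pseudocount Added to count and total (default 0.5).
#' @return Numeric CPM value(s).
#' @export
cpm <- function(count, total, pseudocount = 0.5) {
  if (any(total <= 0)) stopf("library total must be positive")
  (count + pseudocount) / (total + pseudocount) * 1e6
}

#' Two-sided exact test for count enrichment between two libraries
#'
#' Fisher's exact test on the 2x2 table
#' `[count_a, total_a - count_a; count_b, total_b - count_b]`: the two-sided
#' p-value sums hypergeometric probabilities less than or equal to the
#' probability of the observed table.
#'
#' @param count_a,total_a Tag count and library total in library a.
#' @param count_b,total_b Tag count and library total in library b.
#' @return Two-sided p-value.
#' @export
exact_enrichment_test <- function(count_a, total_a, count_b, total_b) {
  if (count_a > total_a || count_b > total_b || min(count_a, count_b) < 0) {
    stopf("counts must satisfy 0 <= count <= total")
  }
  tab <- matrix(c(count_a, total_a - count_a,
                  count_b, total_b - count_b), nrow = 2, byrow = TRUE)
  stats::fisher.test(tab)$p.value
}

#' Select tags enriched in a focal library
#'
#' A tag is selected iff, against EVERY comparator library, its fold difference
#' `cpm(focal) / cpm(comparator)` strictly exceeds `fold_threshold` and the
#' exact-test p-value is strictly below `p_threshold` (the screen
#' "FD > 2, p < 0.01" against both comparators).
#'
#' @param tags Tag table with one `count_<lib>` column per library.
#' @param focal Focal library name (e.g. "zygote").
#' @param comparators Character vector of comparator libraries (>= 1).
#' @param fold_threshold,p_threshold Strict selection thresholds.
#' @param adjust Optional multiple-testing correction across tags within each
#'   comparison ("none" by default, or "BH").
#' @return A list with `results` (one row per tag x comparator: tag_id,
#'   comparator, cpm_focal, cpm_comparator, fold, p_value, pass) and
#'   `selected` (tag ids passing against every comparator).
#' @export
select_enriched <- function(tags, focal, comparators,
                            fold_threshold = 2, p_threshold = 0.01,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (length(comparators) < 1L) stopf("need at least one comparator library")
  if (fold_threshold <= 0) stopf("fold threshold must be positive")
  libs <- c(focal, comparators)
  cols <- paste0("count_", libs)
  miss <- setdiff(cols, names(tags))
  if (length(miss)) stopf("missing count columns: %s", paste(miss, collapse = ", "))
  totals <- vapply(cols, function(cl) sum(tags[[cl]]), numeric(1))
  names(totals) <- libs
  res <- list()
  for (cmp in comparators) {
    ca <- tags[[paste0("count_", focal)]]
    cb <- tags[[paste0("count_", cmp)]]
    p <- vapply(seq_len(nrow(tags)), function(i) {
      exact_enrichment_test(ca[i], totals[[focal]], cb[i], totals[[cmp]])
    }, numeric(1))
    if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
    cpm_a <- cpm(ca, totals[[focal]])
    cpm_b <- cpm(cb, totals[[cmp]])
    fold <- cpm_a / cpm_b
    res[[cmp]] <- data.frame(
      tag_id = tags$tag_id, comparator = cmp, cpm_focal = cpm_a,
      cpm_comparator = cpm_b, fold = fold, p_value = p,
      pass = fold > fold_threshold & p < p_threshold,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  pass_all <- tapply(results$pass, results$tag_id, all)
  selected <- names(pass_all)[pass_all]
  ## keep the tag table order
  selected <- tags$tag_id[tags$tag_id %in% selected]
  list(results = results, selected = selected)
}
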