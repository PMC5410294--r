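#' Fold a cluster region by base-pair maximization
#'
#' Predicts a nested secondary structure for a genomic region by Nussinov
#' base-pair maximization over Watson-Crick pairs plus G.U wobble, with a
#' minimum loop of `min_loop` unpaired positions. The structure is summarised
#' as a hairpin: the two strands of the longest helix group (adjacent helices
#' separated by at most `helix_gap` unpaired positions on both strands are
#' merged) become the 5' and 3' arms, the region between them the loop.
#'
#' Base-pair maximization answers the qualitative question the classifier
#' needs — does this region fold back on itself as a long hairpin — without a
#' thermodynamic model; the O(n^3) dynamic program is practical up to a few
#' kb, which covers small-RNA cluster regions.
#'
#' @param region Region sequence (A/C/G/T).
#' @param min_loop Minimum unpaired positions inside any pair (default 3).
#' @param helix_gap Maximum unpaired gap bridged when merging helices into
#'   arms (default 4).
#' @return A list of class `hairpin_structure`: `length`, `pairs` (m x 2
#'   matrix of 0-based positions, i < j), `paired_fraction`
#'   (2 * npairs / length), `arm5`, `arm3`, `loop` (0-based half-open
#'   intervals, `NULL` when there are no pairs).
#' @export
fold_region <- function(region, min_loop = 3L, helix_gap = 4L) {
  assert_dna(region, "region")
  n <- nchar(region)
  if (n > 20000L) stopf("region length %d exceeds the 20 kb contract", n)
  pairs <- nussinov_pairs(region, min_loop)
  arms <- detect_arms(pairs, helix_gap)
  structure(list(
    length = n, pairs = pairs,
    paired_fraction = 2 * nrow(pairs) / n,
    arm5 = arms$arm5, arm3 = arms$arm3, loop = arms$loop
  ), class = "hairpin_structure")
}

## Group pairs into helices (runs of stacked pairs), merge helices whose gaps
## are <= helix_gap unpaired positions on both strands, and return the arm
## intervals of the group with the most pairs. 0-based half-open intervals.
detect_arms <- function(pairs, helix_gap = 4L) {
  if (nrow(pairs) == 0L) return(list(arm5 = NULL, arm3 = NULL, loop = NULL))
  ord <- order(pairs[, 1])
  pr <- pairs[ord, , drop = FALSE]
  ## helix membership: consecutive pairs (i, j), (i + 1, j - 1)
  helix_id <- cumsum(c(1L, diff(pr[, 1]) != 1L | diff(pr[, 2]) != -1L))
  helices <- lapply(split(seq_len(nrow(pr)), helix_id), function(rows) {
    list(i_min = pr[rows[1], 1], i_max = pr[rows[length(rows)], 1],
         j_min = pr[rows[length(rows)], 2], j_max = pr[rows[1], 2],
         n = length(rows))
  })
  ## merge nested-adjacent helices: helix b is just inside helix a when both
  ## strand gaps are small and b nests within a
  groups <- list()
  cur <- helices[[1]]
  cur$members <- list(helices[[1]])
  for (h in helices[-1]) {
    gap5 <- h$i_min - cur$i_max - 1L
    gap3 <- cur$j_min - h$j_max - 1L
    nested <- h$i_min > cur$i_max && h$j_max < cur$j_min
    if (nested && gap5 >= 0L && gap5 <= helix_gap && gap3 >= 0L &&
        gap3 <= helix_gap) {
      cur$i_max <- h$i_max; cur$j_min <- h$j_min
      cur$n <- cur$n + h$n
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- h
    }
  }
  groups[[length(groups) + 1L]] <- cur
  best <- groups[[which.max(vapply(groups, `[[`, numeric(1), "n"))]]
  list(arm5 = c(best$i_min, best$i_max + 1L),
       arm3 = c(best$j_min, best$j_max + 1L),
       loop = c(best$i_max + 1L, best$j_min))
}
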