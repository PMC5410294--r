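#' Class summary from per-class counts
#'
#' The bookkeeping arithmetic of a per-library class table: totals and integer
#' percentages (rounded half away from zero, so a 6.63% read share prints
#' as 7).
#'
#' @param sequences Named numeric vector of per-class sequence counts.
#' @param reads Named numeric vector of per-class read counts (same classes).
#' @return Data frame: class, sequences, seq_pct, reads, read_pct, with a
#'   final "total" row (percentages 0 when a total is 0).
#' @export
class_summary <- function(sequences, reads) {
  stopifnot(identical(names(sequences), names(reads)))
  tot_seq <- sum(sequences)
  tot_read <- sum(reads)
  df <- data.frame(
    class = c(names(sequences), "total"),
    sequences = c(sequences, tot_seq),
    seq_pct = c(vapply(sequences, int_percent, integer(1), total = tot_seq),
                if (tot_seq > 0) 100L else 0L),
    reads = c(reads, tot_read),
    read_pct = c(vapply(reads, int_percent, integer(1), total = tot_read),
                 if (tot_read > 0) 100L else 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  df
}

#' Summarize final annotations into a per-library class table
#'
#' Aggregates sequence counts (tags present in a library) and read counts per
#' class and library. Classes follow the conventional order miRNA, piRNA,
#' endo-siRNA, unknown (with structural_ncRNA inserted when present).
#'
#' @param final Final annotation table from [finalize_labels()].
#' @param tags Tag table with `count_<lib>` columns.
#' @return Data frame: library, class, sequences, seq_pct, reads, read_pct
#'   (including per-library total rows).
#' @export
summarize_classes <- function(final, tags) {
  stopifnot(all(final$tag_id %in% tags$tag_id))
  m <- merge(final[, c("tag_id", "label")], tags, by = "tag_id")
  label_to_class <- c(miRNA = "miRNA", piRNA = "piRNA",
                      endo_siRNA = "endo-siRNA",
                      structural_ncRNA = "structural_ncRNA",
                      unknown = "unknown")
  m$class <- label_to_class[m$label]
  classes <- c("miRNA", "piRNA", "endo-siRNA",
               if (any(m$class == "structural_ncRNA")) "structural_ncRNA",
               "unknown")
  out <- list()
  for (lib in tag_libraries(tags)) {
    cnt <- m[[paste0("count_", lib)]]
    seqs <- vapply(classes, function(cl)
      sum(m$class == cl & cnt > 0), numeric(1))
    reads <- vapply(classes, function(cl)
      sum(cnt[m$class == cl]), numeric(1))
    cs <- class_summary(setNames(seqs, classes), setNames(reads, classes))
    cs <- cbind(library = lib, cs)
    out[[lib]] <- cs
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default pipeline configuration
#'
#' Every tunable threshold of the pipeline with its default. Defaults follow
#' the filtering cascade (18–30 nt retained, total count > 2), the cluster
#' definition (more than 15 unique sequences within less than 10 kb), the
#' long-hairpin qualification (paired fraction >= 0.5, arms >= 20 nt), the
#' blastn-like inverted-complement search (+2/-3/-5/-2, length >= 30,
#' identity >= 0.8), the enrichment screen (FD > 2, p < 0.01, against every
#' comparator), and the L1 upstream scan (3000 nt window, blocks >= 50 nt at
#' identity >= 0.8).
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    adapter = "TGGAATTCTCGGGTGCCAAGG",
    min_overlap = 6L,
    min_len = 18L, max_len = 30L,
    min_count = 2L, count_filter_scope = "total",
    max_mismatch = 0L,
    cluster_max_span = 10000L, cluster_min_unique = 16L,
    cluster_scope = "all",
    fold_min_loop = 3L, fold_helix_gap = 4L, fold_max_len = 5000L,
    lhp_min_paired_fraction = 0.5, lhp_min_arm = 20L,
    ic_min_len = 30L, ic_min_identity = 0.8,
    ic_match = 2L, ic_mismatch = -3L, ic_gap_open = 5L, ic_gap_ext = 2L,
    ic_seed_k = 12L,
    fold_threshold = 2, p_threshold = 0.01, adjust = "none",
    l1_window = 3000L, l1_min_len = 50L, l1_min_identity = 0.8,
    seed = 1L
  )
}

validate_config <- function(config) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stopf("unknown config key(s): %s",
                             paste(unknown, collapse = ", "))
  config <- utils::modifyList(defaults, config)
  if (config$fold_threshold <= 0) stopf("fold threshold must be positive")
  if (config$p_threshold <= 0 || config$p_threshold > 1) {
    stopf("p threshold must be in (0, 1]")
  }
  if (config$min_len < 1L || config$max_len < config$min_len) {
    stopf("bad tag length bounds [%d, %d]", config$min_len, config$max_len)
  }
  if (config$cluster_max_span <= 0L || config$cluster_min_unique < 1L) {
    stopf("bad cluster parameters")
  }
  if (config$ic_min_identity <= 0 || config$ic_min_identity > 1 ||
      config$l1_min_identity <= 0 || config$l1_min_identity > 1) {
    stopf("identity thresholds must be in (0, 1]")
  }
  config
}

stage_log <- function(stage, n_in, n_out) {
  message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))
}

#' Run the whole classification pipeline
#'
#' Executes preprocess -> map -> annotate -> classify -> diffexpr -> l1scan ->
#' report on the given inputs, writing every stage's tables under `outdir`.
#' With a fixed `config$seed` the run is byte-reproducible.
#'
#' @param inputs A list with elements:
#'   `fastq` (named character vector of FASTQ paths, or a named list of read
#'   vectors), `genome` (named character vector or FASTA path),
#'   `refs` (list with `mirna`, `pirna`, `structural`: named character vectors
#'   or FASTA paths), `repeat_library` (named character vector with `family=`
#'   header tags, or FASTA path), `mrnas` (named character vector or FASTA
#'   path; optional), `l1` (optional list: `annotations` BED data frame or
#'   path, `reference` copy name, `orf2_offset` and `orf2_length`
#'   element-relative, `asl1_span` promoter-coordinate pair), `focal` and
#'   `comparators` (optional library names for the enrichment screen).
#' @param config Configuration list; missing keys take [default_config()]
#'   values.
#' @param outdir Output directory (created).
#' @return A list with all stage results: `tags`, `stats`, `hits`, `unmapped`,
#'   `annotations`, `calls`, `clusters`, `ic_regions`, `final`, `diff`,
#'   `l1` (upstreams, blocks, duplex, assignments), `summary`.
#' @export
run_pipeline <- function(inputs, config = list(), outdir = tempfile("endosirna")) {
  config <- validate_config(config)
  if (is.null(inputs$fastq) || is.null(inputs$genome)) {
    stopf("inputs must provide at least 'fastq' and 'genome'")
  }
  if (is.character(inputs$fastq)) {
    missing <- inputs$fastq[!file.exists(inputs$fastq)]
    if (length(missing)) stopf("missing FASTQ input(s): %s",
                               paste(missing, collapse = ", "))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  as_seqs <- function(x) {
    if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
        file.exists(x)) read_fasta(x) else x
  }

  ## preprocess
  pp <- filter_and_collapse(inputs$fastq, config$adapter,
                            min_len = config$min_len, max_len = config$max_len,
                            min_count = config$min_count,
                            count_filter_scope = config$count_filter_scope,
                            min_overlap = config$min_overlap)
  tags <- pp$tags
  stage_log("preprocess", sum(pp$stats$input), nrow(tags))
  write_tsv(tags, file.path(outdir, "tags.tsv"))
  write_tsv(pp$stats, file.path(outdir, "preprocess_stats.tsv"))
  write_tag_fasta(tags, file.path(outdir, "tags.fasta"))

  ## map
  index <- build_index(as_seqs(inputs$genome))
  mp <- map_tags(tags, index)
  hits <- mp$hits
  tags <- tags[tags$tag_id %in% hits$tag_id, , drop = FALSE]
  stage_log("map", nrow(pp$tags), nrow(hits))
  write_hits_bed(hits, tags, file.path(outdir, "hits.bed"))
  writeLines(mp$unmapped, file.path(outdir, "unmapped.txt"))

  ## annotate
  refs <- list(
    mirna = as_seqs(inputs$refs$mirna %||% character(0)),
    pirna = as_seqs(inputs$refs$pirna %||% character(0)),
    structural = as_seqs(inputs$refs$structural %||% character(0)))
  ann <- suppressWarnings(annotate_tiers(tags, refs, config$max_mismatch))
  stage_log("annotate", nrow(tags), nrow(ann))
  write_tsv(ann, file.path(outdir, "annotations.tsv"))

  ## classify
  cand <- tags[tags$tag_id %in% ann$tag_id[ann$label == "endo_siRNA_candidate"],
               , drop = FALSE]
  calls <- empty_calls()
  if (!is.null(inputs$repeat_library)) {
    calls <- rbind(calls, classify_te(cand, as_seqs(inputs$repeat_library)))
  }
  cluster_hits <- if (config$cluster_scope == "all") hits else
    hits[hits$tag_id %in% cand$tag_id, , drop = FALSE]
  cl <- find_clusters(cluster_hits, config$cluster_max_span,
                      config$cluster_min_unique)
  genome_seqs <- as_seqs(inputs$genome)
  for (i in seq_len(nrow(cl$clusters))) {
    cluster <- cl$clusters[i, ]
    if (cluster$end - cluster$start > config$fold_max_len) {
      warning(sprintf("cluster %s longer than fold_max_len: skipped",
                      cluster$cluster_id), call. = FALSE)
      next
    }
    region <- substr(genome_seqs[[cluster$chrom]], cluster$start + 1L,
                     cluster$end)
    hp <- fold_region(region, config$fold_min_loop, config$fold_helix_gap)
    lhp <- classify_lhp(cluster, hp, hits[hits$tag_id %in% cand$tag_id, ,
                                          drop = FALSE],
                        config$lhp_min_paired_fraction, config$lhp_min_arm)
    calls <- rbind(calls, lhp)
  }
  ic_regions <- NULL
  if (!is.null(inputs$mrnas)) {
    mrnas <- as_seqs(inputs$mrnas)
    regions <- list()
    for (mid in names(mrnas)) {
      regions[[mid]] <- find_inverted_complement(
        mrnas[[mid]], config$ic_min_len, config$ic_min_identity,
        config$ic_match, config$ic_mismatch, config$ic_gap_open,
        config$ic_gap_ext, config$ic_seed_k, mrna_id = mid)
    }
    ic_regions <- do.call(rbind, regions)
    rownames(ic_regions) <- NULL
    if (nrow(ic_regions) && nrow(cand)) {
      mrna_index <- build_index(mrnas)
      mrna_hits <- map_tags(cand, mrna_index)$hits
      calls <- rbind(calls, assign_ic(mrna_hits, ic_regions))
    }
    write_tsv(ic_regions, file.path(outdir, "ic_regions.tsv"))
  }
  final <- finalize_labels(ann, calls)
  stage_log("classify", nrow(cand), sum(final$label == "endo_siRNA"))
  write_tsv(cl$clusters, file.path(outdir, "clusters.tsv"))
  write_tsv(calls, file.path(outdir, "subclass_calls.tsv"))

  ## diffexpr (endo-siRNAs enriched in the focal library)
  diff <- NULL
  if (!is.null(inputs$focal) && length(inputs$comparators %||% character(0))) {
    endo <- tags[tags$tag_id %in% final$tag_id[final$label == "endo_siRNA"], ,
                 drop = FALSE]
    if (nrow(endo)) {
      diff <- select_enriched(endo, inputs$focal, inputs$comparators,
                              config$fold_threshold, config$p_threshold,
                              config$adjust)
      stage_log("diffexpr", nrow(endo), length(diff$selected))
      write_tsv(diff$results, file.path(outdir, "diff_results.tsv"))
      writeLines(diff$selected, file.path(outdir, "selected_tags.txt"))
    }
  }

  ## l1scan
  l1 <- NULL
  if (!is.null(inputs$l1)) {
    l1 <- run_l1scan(genome_seqs, inputs$l1, cand, config)
    stage_log("l1scan", nrow(cand), nrow(l1$assignments))
    write_tsv(l1$upstreams[, setdiff(names(l1$upstreams), "sequence")],
              file.path(outdir, "l1_upstreams.tsv"))
    write_fasta(setNames(l1$upstreams$sequence, l1$upstreams$name),
                file.path(outdir, "l1_upstreams.fasta"))
    write_tsv(l1$blocks, file.path(outdir, "l1_homology_blocks.tsv"))
    write_tsv(l1$assignments, file.path(outdir, "l1_sirna_assignments.tsv"))
    writeLines(sprintf("duplex_length\t%d", l1$duplex$length %||% 0L),
               file.path(outdir, "l1_duplex.tsv"))
  }

  ## report
  summary <- summarize_classes(final, tags)
  write_tsv(final, file.path(outdir, "final_annotations.tsv"))
  write_tsv(summary, file.path(outdir, "class_summary.tsv"))
  write_summary_md(summary, file.path(outdir, "summary.md"))
  stage_log("report", nrow(final), nrow(summary))

  list(tags = tags, stats = pp$stats, hits = hits, unmapped = mp$unmapped,
       annotations = ann, calls = calls, clusters = cl$clusters,
       cluster_members = cl$members, ic_regions = ic_regions, final = final,
       diff = diff, l1 = l1, summary = summary, outdir = outdir)
}

## The L1 antisense-promoter scan: upstream extraction over every annotated
## copy, antisense homology to the reference copy's ORF2, duplex construction
## with the asL1 span, and tag assignment on the reference element coordinates.
run_l1scan <- function(genome_seqs, l1_inputs, cand, config) {
  ann <- l1_inputs$annotations
  if (is.character(ann)) ann <- read_bed(ann)
  ups <- extract_upstream(genome_seqs, ann, config$l1_window)
  ref_name <- l1_inputs$reference %||% ann$name[1]
  ref <- ann[ann$name == ref_name, ]
  if (nrow(ref) != 1L) stopf("reference L1 copy '%s' not found", ref_name)
  if (ref$strand != "+") {
    stopf("the reference L1 copy must be on the + strand for transcript-coordinate mapping")
  }
  element <- substr(genome_seqs[[ref$chrom]], ref$start + 1L, ref$end)
  orf2 <- substr(element, l1_inputs$orf2_offset + 1L,
                 l1_inputs$orf2_offset + l1_inputs$orf2_length)
  blocks <- find_homology(ups, orf2, config$l1_min_len, config$l1_min_identity,
                          target_offset = l1_inputs$orf2_offset)
  duplex <- NULL
  assignments <- data.frame(tag_id = character(0), start = integer(0),
                            end = integer(0), strand_label = character(0),
                            stringsAsFactors = FALSE)
  if (nrow(blocks)) {
    best <- blocks[which.max(blocks$score), , drop = FALSE]
    duplex <- build_duplex(l1_inputs$asl1_span, best)
    if (nrow(cand)) {
      el_index <- build_index(setNames(element, ref_name))
      el_hits <- map_tags(cand, el_index)$hits
      assignments <- assign_l1_sirnas(el_hits, duplex, l1_strand = "+")
    }
  }
  list(upstreams = ups, blocks = blocks, duplex = duplex,
       assignments = assignments)
}

write_summary_md <- function(summary, path) {
  lines <- c("# Small-RNA class summary", "",
             "| library | class | sequences | seq % | reads | read % |",
             "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(summary))) {
    s <- summary[i, ]
    lines <- c(lines, sprintf("| %s | %s | %d | %d | %d | %d |",
                              s$library, s$class, s$sequences, s$seq_pct,
                              s$reads, s$read_pct))
  }
  writeLines(lines, path)
  invisible(path)
}
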