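mk_hits <- function(starts, len = 21, chrom = "chr1",
                    ids = paste0("t", seq_along(starts))) {
  data.frame(tag_id = ids, chrom = chrom, start = starts,
             end = starts + len, strand = "+", stringsAsFactors = FALSE)
}

test_that("TE classification matches repeat records on either strand, first record wins", {
  set.seed(31)
  l1 <- random_dna_str(400)
  ltr <- random_dna_str(300)
  lib <- setNames(c(l1, ltr), c("rep1 family=L1", "rep2 family=LTR"))
  tags <- data.frame(
    tag_id = c("a", "b", "c"),
    sequence = c(substr(l1, 50, 70),          # substring of the L1 record
                 revcomp(substr(ltr, 10, 30)), # revcomp of an LTR substring
                 random_dna_str(21)),          # matches nothing
    stringsAsFactors = FALSE)
  calls <- classify_te(tags, lib)
  expect_equal(calls$tag_id, c("a", "b"))
  expect_equal(calls$family, c("L1", "LTR"))
  expect_equal(calls$locus, c("rep1", "rep2"))

  ## ties across families resolve to the first record in file order
  lib2 <- setNames(c(l1, l1), c("rep1 family=L1", "rep2 family=ERV"))
  expect_equal(classify_te(tags[1, ], lib2)$family, "L1")

  expect_error(classify_te(tags, setNames(l1, "rep_noFamily")),
               "rep_noFamily")
})

test_that("cluster boundaries honour the strict span and unique-sequence rules", {
  ## 16 distinct tags, first start 0, last end 9999: span 9999 -> one cluster
  starts <- c(seq(0, 9000, length.out = 15), 9978)
  cl <- find_clusters(mk_hits(round(starts)))
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$n_unique, 16)

  ## 15 distinct tags within 1 kb: below the unique threshold
  cl2 <- find_clusters(mk_hits(round(seq(0, 900, length.out = 15))))
  expect_equal(nrow(cl2$clusters), 0)

  ## 16 distinct tags spanning exactly 10,000: excluded (strict <), and the
  ## exhaustive window oracle agrees
  starts3 <- round(c(seq(0, 9000, length.out = 15), 9979))
  hits3 <- mk_hits(starts3)
  expect_equal(max(hits3$end) - min(hits3$start), 10000)
  expect_equal(nrow(find_clusters(hits3)$clusters), 0)
  expect_length(oracle_cluster_members(hits3), 0)
})

test_that("cluster membership agrees with the exhaustive window oracle on separated layouts", {
  set.seed(17)
  for (rep in 1:4) {
    starts <- integer(0)
    base <- 0
    for (k in 1:3) {
      n <- sample(c(5, 16, 20), 1)
      width <- sample(c(2000, 9000), 1)
      starts <- c(starts, base + sort(sample(width, n)))
      base <- base + width + 12000      # clusters separated by > 10 kb
    }
    hits <- mk_hits(starts, ids = paste0("t", seq_along(starts)))
    got <- sort(unique(find_clusters(hits)$members$tag_id))
    expect_equal(got, oracle_cluster_members(hits))
  }
})

test_that("folding recovers a planted stem-loop exactly", {
  hp <- fold_region("GGGGGAAAACCCCC")
  expect_equal(nrow(hp$pairs), 5)
  expect_equal(hp$arm5, c(0, 5))
  expect_equal(hp$arm3, c(9, 14))
  expect_equal(hp$loop, c(5, 9))
  expect_equal(hp$paired_fraction, 10 / 14)

  polyA <- fold_region(strrep("A", 30))
  expect_equal(nrow(polyA$pairs), 0)
  expect_null(polyA$arm5)

  expect_error(fold_region("ACGTN"), "non-ACGT")
})

test_that("maximal pair counts equal exhaustive structure enumeration for short sequences", {
  set.seed(13)
  cases <- c("GGGGGAAAACCCCC",
             vapply(1:10, function(i) random_dna_str(sample(8:12, 1)), ""))
  for (s in cases) {
    hp <- fold_region(s)
    expect_equal(nrow(hp$pairs), oracle_max_pairs(s), info = s)
    expect_valid_structure(hp$pairs, s)
  }
})

test_that("Lhp calls require a qualifying hairpin and strict arm containment", {
  arm <- 30L
  region <- paste0("GGAGGTCAGTCAGGCATGCAAGCTTGGCAT", "AAAAAAAAAA",
                   revcomp("GGAGGTCAGTCAGGCATGCAAGCTTGGCAT"))
  hp <- fold_region(region)
  cluster <- data.frame(cluster_id = "cluster_1", chrom = "chr1",
                        start = 100L, end = 100L + nchar(region),
                        n_hits = 3L, n_unique = 16L, stringsAsFactors = FALSE)
  hits <- data.frame(
    tag_id = c("in5", "straddle", "in3"), chrom = "chr1",
    start = c(100L, 120L, 140L + 10L),
    end = c(121L, 141L, 140L + 30L),          # straddle crosses into the loop
    strand = "+", stringsAsFactors = FALSE)
  calls <- classify_lhp(cluster, hp, hits)
  expect_setequal(calls$tag_id, c("in5", "in3"))
  expect_true(all(calls$locus == "cluster_1"))

  ## an unpairable region yields no calls
  flat <- fold_region(strrep("A", 70))
  expect_equal(nrow(classify_lhp(cluster, flat, hits)), 0)

  ## paired fraction below threshold disqualifies the region
  expect_equal(nrow(classify_lhp(cluster, hp, hits,
                                 min_paired_fraction = 0.99)), 0)
})

test_that("inverted-complement search finds a planted 217 nt region and nothing in random mRNA", {
  set.seed(41)
  s <- random_dna_str(217)
  ## A-runs at the arm boundaries cannot complement each other, so the true
  ## inverted-complement region of this sequence is exactly the planted 217 nt
  mrna <- paste0(random_dna_str(92), strrep("A", 8), s,
                 strrep("A", 8), random_dna_str(134), strrep("A", 8),
                 revcomp(s), strrep("A", 8), random_dna_str(92))
  reg <- find_inverted_complement(mrna, mrna_id = "m1")
  expect_equal(nrow(reg), 1)
  expect_equal(reg$region_length, 217)
  expect_equal(reg$identity, 1)
  expect_equal(c(reg$arm1_start, reg$arm1_end), c(100, 317))
  expect_equal(c(reg$arm2_start, reg$arm2_end), c(467, 684))
  ## the reported arms really are reverse complements (direct recomputation)
  a1 <- substr(mrna, reg$arm1_start + 1, reg$arm1_end)
  a2 <- substr(mrna, reg$arm2_start + 1, reg$arm2_end)
  expect_identical(a1, revcomp(a2))

  ## fixed random 500 nt mRNA: no region, confirmed by a gapless window scan
  rnd <- random_dna_str(500)
  expect_equal(nrow(find_inverted_complement(rnd)), 0)
  rc <- revcomp(rnd)
  best <- 0
  for (i in 1:(500 - 29)) {
    w1 <- strsplit(substr(rnd, i, i + 29), "")[[1]]
    for (j in 1:(500 - 29)) {
      m <- mean(w1 == strsplit(substr(rc, j, j + 29), "")[[1]])
      if (m > best) best <- m
    }
  }
  expect_lt(best, 0.8)
})

test_that("a perfect palindrome yields adjacent, non-overlapping arms", {
  set.seed(43)
  s <- random_dna_str(60)
  ## A-run flanks cannot complement each other: the palindrome is exactly 120 nt
  mrna <- paste0(random_dna_str(76), strrep("A", 4), s, revcomp(s),
                 strrep("A", 4), random_dna_str(76))
  reg <- find_inverted_complement(mrna)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$arm1_end, reg$arm2_start)   # adjacent
  expect_equal(reg$region_length, 60)
  expect_gte(reg$identity, 0.99)
})

test_that("IC assignment requires strict containment in an arm", {
  regions <- data.frame(mrna_id = "m1", arm1_start = 100L, arm1_end = 160L,
                        arm2_start = 200L, arm2_end = 260L,
                        region_length = 60L, identity = 1, score = 120,
                        stringsAsFactors = FALSE)
  mrna_hits <- data.frame(
    tag_id = c("a", "b", "c", "d"), chrom = "m1",
    start = c(110L, 230L, 170L, 150L),
    end = c(131L, 251L, 191L, 171L),   # c in spacer, d half-in/half-out
    strand = c("+", "-", "+", "+"), stringsAsFactors = FALSE)
  calls <- assign_ic(mrna_hits, regions)
  expect_setequal(calls$tag_id, c("a", "b"))
  expect_true(all(calls$subclass == "IC"))
})

test_that("final labels apply the TE > Lhp > IC priority and default to unknown", {
  ann <- data.frame(tag_id = c("x", "y", "z"),
                    label = rep("endo_siRNA_candidate", 3),
                    evidence = "length18-24", stringsAsFactors = FALSE)
  calls <- rbind(
    data.frame(tag_id = "x", subclass = "Lhp", family = "", locus = "c1",
               stringsAsFactors = FALSE),
    data.frame(tag_id = "x", subclass = "TE", family = "L1", locus = "rep1",
               stringsAsFactors = FALSE),
    data.frame(tag_id = "y", subclass = "IC", family = "", locus = "m1",
               stringsAsFactors = FALSE))
  fin <- finalize_labels(ann, calls)
  expect_equal(fin$label, c("endo_siRNA", "endo_siRNA", "unknown"))
  expect_equal(fin$subclass, c("TE", "IC", ""))
  expect_equal(fin$family[1], "L1")
})
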