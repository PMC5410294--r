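test_that("promoter coordinates anchor at the TSS and form a bijection", {
  tss <- 5000L
  expect_equal(promoter_to_offset(1L, tss, "+"), 5000L)
  expect_equal(promoter_to_offset(-1L, tss, "+"), 4999L)
  expect_equal(promoter_to_offset(93L, tss, "+"), 5092L)
  expect_equal(promoter_to_offset(-365L, tss, "+"), 4635L)
  ## - strand: transcription runs leftwards
  expect_equal(promoter_to_offset(1L, tss, "-"), 5000L)
  expect_equal(promoter_to_offset(-1L, tss, "-"), 5001L)
  expect_equal(promoter_to_offset(10L, tss, "-"), 4991L)
  expect_error(promoter_to_offset(0L, tss, "+"), "0")

  set.seed(3)
  for (strand in c("+", "-")) {
    offs <- sample.int(20000L, 1000L) - 1L
    coords <- offset_to_promoter(offs, tss, strand)
    expect_true(all(coords != 0L))
    expect_equal(promoter_to_offset(coords, tss, strand), offs)
  }
  ## and coord -> offset -> coord on +/-10^4 without zero
  coords <- setdiff(-10000:10000, 0)
  expect_equal(offset_to_promoter(promoter_to_offset(coords, tss, "+"),
                                  tss, "+"), coords)
})

test_that("upstream extraction follows strand arithmetic and flags truncation", {
  set.seed(15)
  g <- setNames(random_dna_str(10000), "chr1")
  bed <- data.frame(chrom = "chr1", start = c(5000L, 100L), end = c(6000L, 900L),
                    name = c("plus_copy", "short_copy"), score = 0,
                    strand = "+", stringsAsFactors = FALSE)
  ups <- extract_upstream(g, bed, window = 3000L)
  expect_equal(ups$sequence[1], substr(g[[1]], 2001, 5000))
  expect_false(ups$truncated[1])
  expect_equal(nchar(ups$sequence[2]), 100)   # chromosome start intervenes
  expect_true(ups$truncated[2])

  minus <- data.frame(chrom = "chr1", start = 200L, end = 900L, name = "m",
                      score = 0, strand = "-", stringsAsFactors = FALSE)
  upm <- extract_upstream(g, minus, window = 3000L)
  expect_equal(upm$sequence, revcomp(substr(g[[1]], 901, 3900)))

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t900\tok\t0\t+", "chr1\t100"), bad)
  expect_error(extract_upstream(g, bad, 3000L), "line 2")
})

test_that("antisense homology blocks are located with promoter coordinates", {
  set.seed(25)
  orf2 <- random_dna_str(2000)
  sub <- substr(orf2, 801, 1165)               # 365 nt sub-interval
  upstream <- paste0(random_dna_str(3000 - 365), revcomp(sub))
  ups <- data.frame(name = "u1", chrom = "chr1", start = 0L, end = 3000L,
                    strand = "+", truncated = FALSE, sequence = upstream,
                    stringsAsFactors = FALSE)
  blocks <- find_homology(ups, orf2)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$up_from, -365L)
  expect_equal(blocks$up_to, -1L)
  expect_equal(blocks$identity, 1)
  expect_equal(c(blocks$target_start, blocks$target_end), c(800L, 1165L))
  expect_equal(blocks$orientation, "antisense")

  ## a random upstream sequence yields no block
  ups$sequence <- random_dna_str(3000)
  expect_equal(nrow(find_homology(ups, orf2)), 0)

  ## one mismatch in a 100 nt block: identity 0.99
  blk <- substr(orf2, 501, 600)
  m <- revcomp(blk)
  substr(m, 40, 40) <- setdiff(c("A", "C", "G", "T"), substr(m, 40, 40))[1]
  ups$sequence <- paste0(strrep("A", 200), m, strrep("A", 200))
  b2 <- find_homology(ups, orf2, min_len = 50)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$identity, 0.99, tolerance = 0.011)
  expect_lt(b2$identity, 1)
})

test_that("duplex length is the promoter-coordinate interval intersection", {
  blk <- list(up_from = -365L, up_to = -1L, target_start = 800L,
              target_end = 1165L)
  d <- build_duplex(c(93L, -490L), blk)
  expect_equal(d$length, 365L)
  expect_true(d$active)
  expect_equal(d$sense_interval, c(800L, 1165L))

  ## disjoint intervals: inactive zero-length duplex
  d0 <- build_duplex(c(93L, -100L),
                     list(up_from = -365L, up_to = -200L,
                          target_start = 800L, target_end = 966L))
  expect_equal(d0$length, 0L)
  expect_false(d0$active)

  ## partial overlap, verified by explicit position enumeration
  d200 <- build_duplex(c(93L, -200L), blk)
  axis <- setdiff(-10000:10000, 0)
  in_span <- axis <= 93 & axis >= -200
  in_blk <- axis <= -1 & axis >= -365
  expect_equal(d200$length, sum(in_span & in_blk))
  expect_equal(d200$length, 200L)
  ## trimming at the far-upstream end trims the target interval start side
  expect_equal(d200$sense_interval[2] - d200$sense_interval[1], 200L)

  ## symmetric in interval order and bounded by both lengths
  d_swap <- build_duplex(c(-490L, 93L), blk)
  expect_equal(d_swap$length, 365L)
  set.seed(5)
  for (k in 1:50) {
    span <- sort(sample(setdiff(-600:200, 0), 2))
    bf <- sort(sample(setdiff(-600:200, 0), 2))
    b <- list(up_from = bf[1], up_to = bf[2], target_start = 0L,
              target_end = sum(axis >= bf[1] & axis <= bf[2]))
    d <- build_duplex(c(span[2], span[1]), b)
    expected <- sum(axis >= max(span[1], bf[1]) &
                      axis <= min(span[2], bf[2]))  # explicit enumeration
    expect_equal(d$length, expected)
    expect_lte(d$length, sum(axis >= span[1] & axis <= span[2]))
    expect_lte(d$length, sum(axis >= bf[1] & axis <= bf[2]))
  }
})

test_that("L1-siRNA assignment requires strict containment and labels strands", {
  duplex <- build_duplex(c(93L, -490L),
                         list(up_from = -365L, up_to = -1L,
                              target_start = 1000L, target_end = 1365L))
  hits <- data.frame(
    tag_id = c("in_plus", "in_minus", "edge_out"),
    start = c(1000L, 1200L, 990L),
    end = c(1021L, 1221L, 1011L),
    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  asg <- assign_l1_sirnas(hits, duplex, l1_strand = "+")
  expect_setequal(asg$tag_id, c("in_plus", "in_minus"))
  expect_equal(asg$strand_label[asg$tag_id == "in_plus"], "sense")
  expect_equal(asg$strand_label[asg$tag_id == "in_minus"], "antisense")

  inactive <- build_duplex(c(93L, -100L),
                           list(up_from = -365L, up_to = -200L,
                                target_start = 1000L, target_end = 1166L))
  expect_equal(nrow(assign_l1_sirnas(hits, inactive)), 0)
})

test_that("assay arithmetic: spliced product and 2^-ddCt", {
  expect_equal(spliced_product_length(500, 200), 300)
  expect_equal(spliced_product_length(500, 0), 500)
  expect_error(spliced_product_length(500, 500), "intron")
  expect_equal(fold_change_ddct(20, 15, 22, 17), 1.0)   # ddCt = 0
  expect_equal(fold_change_ddct(21, 15, 22, 17), 0.5)   # ddCt = 1
  expect_equal(fold_change_ddct(20, 15, 24, 17), 4.0)   # ddCt = -2
})
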