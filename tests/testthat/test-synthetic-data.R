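test_that("toy genome construction is deterministic and plants exact structures", {
  spec <- toy_genome_spec(
    genome_length = 6000L, seed = 7L,
    hairpin_loci = list(list(arm = 30L, loop = 10L, position = 1000L,
                             n_tags = 2L)),
    ic_mrnas = list(list(length = 300L, arm = 60L, spacer = 40L,
                         position = 2000L, n_tags = 2L, n_decoys = 1L)),
    lib_names = "zygote")
  w1 <- build_toy_genome(spec)
  w2 <- build_toy_genome(spec)
  expect_identical(w1$genome, w2$genome)
  expect_identical(w1$truth, w2$truth)

  ## hairpin locus: 5' arm is an exact inverted repeat of the unmutated
  ## positions of the 3' arm; loop in between
  locus <- substr(w1$genome[[1]], 1001, 1070)
  arm5 <- substr(locus, 1, 30)
  arm3 <- substr(locus, 41, 70)
  rc_arm5 <- revcomp(arm5)
  mism <- which(strsplit(arm3, "")[[1]] != strsplit(rc_arm5, "")[[1]])
  expect_true(all(mism %in% seq(10L, 30L, by = 20L)))

  ## IC mRNA: arm2 is the exact reverse complement of arm1
  mrna <- w1$mrnas[["ic_mrna_1"]]
  pre <- (300 - (2 * 60 + 40)) %/% 2
  s1 <- substr(mrna, pre + 1, pre + 60)
  s2 <- substr(mrna, pre + 60 + 40 + 1, pre + 160)
  expect_identical(s2, revcomp(s1))
})

test_that("the L1 upstream block is the exact reverse complement of the stated ORF2 sub-interval", {
  spec <- toy_genome_spec(
    genome_length = 14000L, seed = 11L,
    l1_locus = list(position = 6000L, utr5 = 500L, orf1 = 1000L, orf2 = 2000L,
                    utr3 = 500L, asp_block = c(-365L, -1L),
                    orf2_sub_offset = 800L, asl1_span = c(93L, -490L),
                    n_duplex_tags = 9L, n_decoy_tags = 0L),
    lib_names = "zygote")
  w <- build_toy_genome(spec)
  g <- w$genome[[1]]
  tss <- 6000
  upstream_block <- substr(g, tss - 365 + 1, tss)       # promoter -365..-1
  sub_start <- tss + 500 + 1000 + 800                    # ORF2 sub-interval
  orf2_sub <- substr(g, sub_start + 1, sub_start + 365)
  expect_equal(nchar(upstream_block), 365)
  expect_identical(upstream_block, revcomp(orf2_sub))
  expect_equal(w$l1$asl1_span, c(93L, -490L))
})

test_that("overlapping planted features are rejected naming both features", {
  expect_error(
    toy_genome_spec(genome_length = 5000L, seed = 1L,
                    te_copies = list(list(family = "LTR", length = 400L,
                                          position = 1000L)),
                    hairpin_loci = list(list(arm = 100L, loop = 20L,
                                             position = 1200L, n_tags = 2L))),
    "te_1_LTR.*hairpin_1")
})

test_that("every planted tag occurs in the genome and labels come from the closed set", {
  fx_spec <- toy_genome_spec(
    genome_length = 20000L, seed = 3L,
    te_copies = list(list(family = "SINE", length = 300L, position = 1000L,
                          n_tags = 2L)),
    hairpin_loci = list(list(arm = 100L, loop = 30L, position = 5000L,
                             n_tags = 4L)),
    mirna_sites = list(list(position = 9000L, length = 22L)),
    pirna_sites = list(list(position = 9100L, length = 27L)),
    unknown_sites = list(list(position = 9200L, length = 20L)),
    lib_names = c("sperm", "zygote"))
  w <- build_toy_genome(fx_spec)
  for (s in w$truth$sequence) {
    expect_true(grepl(s, w$genome[[1]], fixed = TRUE) ||
                  grepl(revcomp(s), w$genome[[1]], fixed = TRUE))
  }
  expect_true(all(w$truth$label %in%
                    c("miRNA", "piRNA", "TE-siRNA", "Lhp-siRNA", "IC-siRNA",
                      "L1-siRNA", "unknown")))
})

test_that("simulated libraries are deterministic, respect depth 0 and empty adapter", {
  spec <- toy_genome_spec(genome_length = 3000L, seed = 5L,
                          unknown_sites = list(list(position = 1000L,
                                                    length = 20L)),
                          lib_names = "zygote")
  w <- build_toy_genome(spec)
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- simulate_libraries(w$genome, w$truth, "zygote", 500L, seed = 9L,
                           out_dir = d1)
  f2 <- simulate_libraries(w$genome, w$truth, "zygote", 500L, seed = 9L,
                           out_dir = d2)
  expect_identical(readLines(f1[["zygote"]]), readLines(f2[["zygote"]]))

  f0 <- simulate_libraries(w$genome, w$truth, "zygote", 0L, seed = 9L,
                           out_dir = tempfile())
  expect_length(read_fastq(f0[["zygote"]]), 0)

  fna <- simulate_libraries(w$genome, w$truth, "zygote", 50L, seed = 9L,
                            out_dir = tempfile(), adapter = "",
                            background_fraction = 0)
  reads <- read_fastq(fna[["zygote"]])
  expect_true(all(reads == w$truth$sequence[1]))

  expect_error(simulate_libraries(w$genome, w$truth, "oocyte", 10L, seed = 1L,
                                  out_dir = tempfile()),
               "unknown library")
})

test_that("planted counts follow the multinomial expectation", {
  spec <- toy_genome_spec(
    genome_length = 4000L, seed = 21L,
    unknown_sites = list(
      list(position = 1000L, length = 20L,
           abundance = c(sperm = 10, zygote = 100)),
      list(position = 1100L, length = 20L,
           abundance = c(sperm = 90, zygote = 100))),
    lib_names = c("sperm", "zygote"))
  w <- build_toy_genome(spec)
  depth <- 10000L
  fq <- simulate_libraries(w$genome, w$truth, c("sperm", "zygote"), depth,
                           seed = 33L, out_dir = tempfile(),
                           background_fraction = 0, adapter = "")
  for (lib in c("sperm", "zygote")) {
    reads <- read_fastq(fq[[lib]])
    ab <- w$truth[[paste0("abund_", lib)]]
    p <- ab / sum(ab)
    for (k in seq_len(nrow(w$truth))) {
      obs <- sum(reads == w$truth$sequence[k])
      expect_lt(abs(obs - depth * p[k]), 3 * sqrt(depth * p[k] * (1 - p[k])) + 1)
    }
  }
})

test_that("background read lengths are bimodal as configured", {
  spec <- toy_genome_spec(genome_length = 5000L, seed = 2L, lib_names = "x")
  w <- build_toy_genome(spec)
  depth <- 100000L
  fq <- simulate_libraries(w$genome, w$truth, "x", depth, seed = 4L,
                           out_dir = tempfile(), background_fraction = 1,
                           adapter = "")
  lens <- nchar(read_fastq(fq[["x"]]))
  expect_equal(length(lens), depth)
  ## expected mixture: 0.5 N(23, 1) + 0.5 N(27.5, 0.8), rounded, clipped 18-30
  band <- function(k, mu, sd) {
    lo <- if (k == 18) -Inf else k - 0.5
    hi <- if (k == 30) Inf else k + 0.5
    pnorm(hi, mu, sd) - pnorm(lo, mu, sd)
  }
  p <- vapply(18:30, function(k)
    0.5 * band(k, 23, 1) + 0.5 * band(k, 27.5, 0.8), numeric(1))
  obs <- tabulate(factor(lens, levels = 18:30), nbins = 13)
  keep <- p > 1e-8
  chi <- suppressWarnings(chisq.test(obs[keep], p = p[keep] / sum(p[keep])))
  expect_gt(chi$p.value, 0.01)
  ## modes at 23 (among 18-25) and 27-28 (among 26-30)
  expect_equal(which.max(obs[1:8]) + 17, 23)
  expect_true((which.max(obs[9:13]) + 25) %in% c(27, 28))
})

test_that("a planted tag containing the adapter prefix is rejected, not corrupted", {
  spec <- toy_genome_spec(genome_length = 3000L, seed = 1L,
                          unknown_sites = list(list(position = 100L,
                                                    length = 20L)),
                          lib_names = "x")
  w <- build_toy_genome(spec)
  w$truth$sequence[1] <- paste0("ACGTACG", "TGGAAT", "ACGTACG")
  ## make the altered tag present in the genome so only the adapter check fires
  g <- w$genome[[1]]
  substr(g, 101, 120) <- w$truth$sequence[1]
  w$genome[[1]] <- g
  expect_error(simulate_libraries(w$genome, w$truth, "x", 100L, seed = 1L,
                                  out_dir = tempfile()),
               "adapter prefix")
})
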