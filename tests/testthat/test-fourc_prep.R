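make_counts <- function(n_frag = 41, frag_len = 100, scores,
                        bait_frac = 0.5) {
  frag <- data.frame(fragment_id = seq_len(n_frag), chrom = "chr1",
                     start = (seq_len(n_frag) - 1) * frag_len,
                     end = seq_len(n_frag) * frag_len)
  samples <- data.frame(sample_id = colnames(scores),
                        condition = colnames(scores))
  new_fourc_counts(frag, samples = samples,
                   bait = list(chrom = "chr1",
                               pos = floor(n_frag * bait_frac) * frag_len + 1),
                   scores = scores)
}

test_that("digestion places fragment boundaries at motif starts", {
  m <- digest_genome(c(chr1 = "AAGATCAA"))
  expect_equal(m$start, c(0, 2))
  expect_equal(m$end, c(2, 8))
  expect_warning(m0 <- digest_genome(c(chr1 = "AAAATTTT")), "no 'GATC' site")
  expect_equal(nrow(m0), 1L)
  expect_equal(c(m0$start, m0$end), c(0, 8))
})

test_that("digestion of random sequence matches a brute-force motif scan", {
  set.seed(33)
  seqs <- paste(sample(c("A", "C", "G", "T"), 1e5, replace = TRUE),
                collapse = "")
  m <- digest_genome(c(chrR = seqs))
  # brute-force oracle: base-R string scan
  hits <- gregexpr("GATC", seqs, fixed = TRUE)[[1]]
  expect_equal(nrow(m), length(hits) + 1L)
  expect_equal(sum(m$end - m$start), 1e5)
  # round trip: fragments tile the chromosome exactly
  expect_equal(m$start[-1], m$end[-nrow(m)])
  expect_equal(m$start[1], 0)
  # boundaries sit at motif starts (0-based)
  expect_equal(m$start[-1], as.integer(hits) - 1L)
})

test_that("fragment scores are the mean of the two end counts", {
  expect_equal(score_fragments(10, 20), 15)
  expect_equal(score_fragments(0, 0), 0)
  set.seed(4)
  e1 <- matrix(rpois(60, 20), 10); e2 <- matrix(rpois(60, 20), 10)
  s <- score_fragments(e1, e2)
  for (i in seq_len(nrow(e1))) {
    for (j in seq_len(ncol(e1))) {
      expect_identical(s[i, j], (e1[i, j] + e2[i, j]) / 2)
    }
  }
  expect_error(score_fragments(-1, 3), "negative")
  # missing ends count as zero (dropout convention)
  expect_equal(score_fragments(NA, 10), 5)
})

test_that("QC fails at exactly 75% zero fragments (boundary included)", {
  sc <- cbind(all_zero = rep(0, 40), ok = rep(3, 40),
              at75 = c(rep(0, 30), rep(5, 10)),
              at72.5 = c(rep(0, 29), rep(5, 11)))
  cts <- make_counts(n_frag = 40, scores = sc)
  qc <- qc_sample(cts)
  expect_equal(qc$pass, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(qc$zero_fraction, c(1, 0, 0.75, 0.725))
  # window devoid of fragments errors
  far <- cts; far$bait$pos <- 1e9; far$fragments$mid <- far$fragments$mid
  expect_error(qc_sample(far), "no fragments")
})

test_that("QC is monotone: adding reads never flips pass to fail", {
  set.seed(5)
  sc <- matrix(rbinom(80, 1, 0.3) * rpois(80, 5), 40)
  colnames(sc) <- c("s1", "s2")
  cts <- make_counts(n_frag = 40, scores = sc)
  before <- qc_sample(cts)
  sc2 <- sc
  idx <- sample(length(sc2), 20)
  sc2[idx] <- sc2[idx] + 7
  cts2 <- make_counts(n_frag = 40, scores = sc2)
  after <- qc_sample(cts2)
  expect_true(all(!(before$pass & !after$pass) |
                    after$zero_fraction <= before$zero_fraction))
  expect_true(all(after$zero_fraction <= before$zero_fraction))
})

test_that("bait masking flags k fragments per side plus the bait", {
  sc <- matrix(5, 41, 2, dimnames = list(NULL, c("a", "b")))
  cts <- make_counts(n_frag = 41, scores = sc)
  m5 <- mask_bait_adjacent(cts, k = 5)
  expect_equal(sum(m5$masked), 11L)       # 5 + 5 + bait
  bf <- cts$bait$fragment
  expect_true(all(which(m5$masked) == (bf - 5):(bf + 5)))
  m0 <- mask_bait_adjacent(cts, k = 0)
  expect_equal(which(m0$masked), bf)
  # bait 3 fragments from the chromosome start: 3 + bait + 5 masked
  edge <- make_counts(n_frag = 41, scores = sc, bait_frac = 3 / 41)
  expect_warning(me <- mask_bait_adjacent(edge, k = 5), "fewer than k")
  expect_equal(sum(me$masked), 3L + 1L + 5L)
})

test_that("library normalization equalizes cis sums and is scale-invariant", {
  sc <- cbind(a = c(rep(2, 30), rep(4, 11)), b = c(rep(2, 30), rep(4, 11)))
  cts <- mask_bait_adjacent(make_counts(n_frag = 41, scores = sc))
  nrm <- normalize_library(cts)
  expect_equal(unname(nrm$norm_factors), c(1, 1))

  sc2 <- cbind(a = sc[, 1], b = 2 * sc[, 1])
  cts2 <- mask_bait_adjacent(make_counts(n_frag = 41, scores = sc2))
  nrm2 <- normalize_library(cts2)
  expect_equal(unname(nrm2$norm_factors), c(1.5, 0.75))
  cis <- !nrm2$masked
  s_after <- colSums(nrm2$scores[cis, ])
  expect_equal(unname(s_after[1]), unname(s_after[2]), tolerance = 1e-9)

  # global rescaling of all samples leaves the factors unchanged
  cts3 <- mask_bait_adjacent(make_counts(n_frag = 41, scores = 10 * sc2))
  expect_equal(normalize_library(cts3)$norm_factors, nrm2$norm_factors)

  # rank order within a sample is preserved
  expect_equal(order(nrm2$scores[, 2]), order(sc2[, 2]))

  zero <- make_counts(n_frag = 41, scores = cbind(a = rep(0, 41)))
  zero <- mask_bait_adjacent(zero)
  expect_error(normalize_library(zero), "zero cis sum")
})

test_that("cis_fraction matches direct summation", {
  n <- 10000  # 10 Mb of 1-kb fragments, bait mid-chromosome
  sc <- matrix(1, n, 1, dimnames = list(NULL, "u"))
  cts <- mask_bait_adjacent(make_counts(n_frag = n, frag_len = 1000,
                                        scores = sc))
  cts <- normalize_library(cts)
  cf <- cis_fraction(cts, window = 1e6)
  fr <- cts$fragments
  keep <- !cts$masked
  oracle <- sum(keep & abs(fr$mid - cts$bait$pos) <= 1e6) / sum(keep)
  expect_equal(unname(cf), oracle)
  expect_equal(unname(cf), 0.2, tolerance = 0.01)  # 2 Mb of 10 Mb

  # all signal inside the window
  sc2 <- matrix(0, n, 1, dimnames = list(NULL, "u"))
  sc2[abs(fr$mid - cts$bait$pos) <= 5e5] <- 2
  cts2 <- normalize_library(mask_bait_adjacent(
    make_counts(n_frag = n, frag_len = 1000, scores = sc2)))
  expect_equal(unname(cis_fraction(cts2, window = 1e6)), 1)
})

test_that("synthetic power-law profile cis fraction matches brute force", {
  cfg <- fourc_sim_config(chrom_length = 5e5, bait_pos = 2.5e5,
                          loop_center = 2.8e5, seed = 17)
  cts <- normalize_library(mask_bait_adjacent(simulate_4c(cfg)$counts))
  cf <- cis_fraction(cts, window = 5e4)
  fr <- cts$fragments
  keep <- !cts$masked
  inw <- keep & abs(fr$mid - cts$bait$pos) <= 5e4
  oracle <- colSums(cts$scores[inw, ]) / colSums(cts$scores[keep, ])
  expect_equal(unname(cf), unname(oracle))
})

test_that("count containers round-trip through TSV and BED writers run", {
  cfg <- fourc_sim_config(chrom_length = 5e4, bait_pos = 2.5e4,
                          loop_center = 3e4, timepoints = c(8, 20),
                          n_replicates = 2, seed = 2)
  cts <- simulate_4c(cfg)$counts
  tsv <- tempfile(fileext = ".tsv")
  write_fourc_tsv(cts, tsv)
  long <- read.delim(tsv)
  expect_equal(nrow(long), nrow(cts$fragments) * nrow(cts$samples))
  expect_equal(long$score, as.vector(cts$scores))
  bed <- tempfile(fileext = ".bed")
  write_fragment_bed(cts$fragments, bed)
  expect_equal(nrow(read.delim(bed, header = FALSE)), nrow(cts$fragments))
  bg <- tempfile(fileext = ".bedGraph")
  write_bedgraph(cts$fragments, cts$scores[, 1], bg)
  expect_true(file.exists(bg))
  unlink(c(tsv, paste0(tsv, ".samples.tsv"), bed, bg))
})
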