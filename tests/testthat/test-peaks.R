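## A 100-bp bin grid on one small chromosome, with one strong planted
## enrichment block.
.toyBins <- function(n_bins = 100L, chrom_len = n_bins * 100L) {
  GRanges("chr1", IRanges(seq(1L, by = 100L, length.out = n_bins),
                          width = 100L),
          seqinfo = Seqinfo("chr1", chrom_len))
}

test_that("the windowed Poisson caller finds a planted enrichment block", {
  bins <- .toyBins()
  dna <- rep(20, 100)
  rna <- rep(20, 100)
  rna[41:45] <- 200                     # 10-fold block at 4001..4500
  pk <- callPeaksReplicate(bins, dna, rna)
  expect_equal(length(pk), 1L)
  expect_true(start(pk) <= 4001 && end(pk) >= 4500)
  # flat libraries yield no peaks
  expect_equal(length(callPeaksReplicate(bins, dna, dna)), 0L)
})

test_that("min_fold gates marginal windows and errors are explicit", {
  bins <- .toyBins()
  dna <- rep(20, 100)
  rna <- rep(20, 100)
  rna[41:45] <- 55                      # < 2-fold over expectation
  expect_equal(length(callPeaksReplicate(bins, dna, rna, min_fold = 3)), 0L)
  expect_error(callPeaksReplicate(bins, dna[-1], rna), "mismatched")
  expect_error(callPeaksReplicate(bins, rep(0, 100), rna), "all-zero DNA")
})

test_that("peaks never extend past the chromosome end", {
  bins <- .toyBins(20L)                 # chr1 is 2000 bp
  dna <- rep(20, 20)
  rna <- rep(20, 20)
  rna[18:20] <- 300                     # enrichment at the right edge
  pk <- callPeaksReplicate(bins, dna, rna)
  expect_true(all(end(pk) <= 2000))
})

test_that("consensus requires support from two flasks and caps length", {
  p1 <- GRanges("chr1", IRanges(c(1000, 5000), width = 800))
  p2 <- GRanges("chr1", IRanges(1100, width = 700))   # overlaps first only
  cons <- buildConsensus(list(r1 = p1, r2 = p2), min_support = 2L)
  expect_equal(length(cons), 1L)
  expect_equal(mcols(cons)$support, 2L)
  expect_equal(mcols(cons)$id, "cons00001")
  # the singleton at 5000 comes back with min_support = 1
  cons1 <- buildConsensus(list(r1 = p1, r2 = p2), min_support = 1L)
  expect_equal(length(cons1), 2L)
  # a merged region longer than max_length is discarded
  long1 <- GRanges("chr1", IRanges(1, width = 9000))
  long2 <- GRanges("chr1", IRanges(8500, width = 9000))
  expect_equal(length(buildConsensus(list(a = long1, b = long2),
                                     max_length = 10000L)), 0L)
  expect_equal(length(buildConsensus(list(a = long1, b = long2),
                                     max_length = 20000L)), 1L)
  expect_error(buildConsensus(list()), "no replicate peak sets")
})

test_that("activity quantification reproduces the normalized log ratio", {
  bins <- .toyBins(10L)
  design <- data.frame(population = c("p1", "p2"),
                       sociality = c("social", "solitary"), batch = "b1",
                       row.names = c("r1", "r2"))
  dna <- matrix(10L, 10, 2, dimnames = list(NULL, c("r1", "r2")))
  rna <- dna
  rna[3:4, 1] <- 80L
  se <- StarrExperiment(bins, dna = dna, rna = rna, design = design)
  cons <- GRanges("chr1", IRanges(201, 400))  # bins 3 and 4
  mcols(cons)$id <- "consA"
  act <- quantifyActivity(cons, se)
  expect_s4_class(act, "StarrExperiment")
  expect_equal(unname(dnaCounts(act)[1, "r1"]), 20)
  expect_equal(unname(rnaCounts(act)[1, "r1"]), 160)
  rna_tot <- sum(rna[, 1]); dna_tot <- sum(dna[, 1])
  expected <- log2(((160 + 0.5) / rna_tot) / ((20 + 0.5) / dna_tot))
  expect_equal(unname(activityMatrix(act)[1, "r1"]), expected)
  expect_error(suppressWarnings(
    quantifyActivity(GRanges("chr2", IRanges(1, 10)), se)),
    "outside the count grid")
})

test_that("population presence demands peaks in enough flasks per population", {
  cons <- GRanges("chr1", IRanges(c(1000, 3000), width = 500))
  mcols(cons)$id <- c("cA", "cB")
  design <- data.frame(population = rep(c("p1", "p2"), each = 2),
                       sociality = rep(c("social", "solitary"), each = 2),
                       batch = rep(c("b1", "b2"), 2),
                       row.names = c("p1_r1", "p1_r2", "p2_r1", "p2_r2"))
  hitA <- GRanges("chr1", IRanges(1100, width = 100))
  peaks <- list(p1_r1 = hitA, p1_r2 = hitA,
                p2_r1 = GRanges(), p2_r2 = hitA)
  pres <- populationPresence(cons, peaks, design, min_replicates = 2L)
  expect_identical(dimnames(pres), list(c("cA", "cB"), c("p1", "p2")))
  expect_identical(unname(pres[, "p1"]), c(TRUE, FALSE))
  expect_identical(unname(pres[, "p2"]), c(FALSE, FALSE))
  pres1 <- populationPresence(cons, peaks, design, min_replicates = 1L)
  expect_true(pres1["cA", "p2"])
  expect_error(populationPresence(cons, list(zzz = hitA), design),
               "not in design")
})

test_that("the caller recovers planted enhancers on simulated data", {
  study <- smallStudy()
  peaks <- callPeaksAll(study$counts)
  cons <- buildConsensus(peaks)
  expect_gte(mean(overlapsAny(study$truths, cons)), 0.9)
  expect_gte(mean(overlapsAny(cons, study$truths)), 0.9)
})
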