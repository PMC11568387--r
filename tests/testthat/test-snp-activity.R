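## SNP table builder with per-replicate frequency columns for toyDesign().
.toySnps <- function(freqs, qual = 60, chrom = "chr1", pos = NULL) {
  n <- nrow(freqs)
  if (is.null(pos)) pos <- seq(1100, by = 1000, length.out = n)
  df <- data.frame(chrom = chrom, pos = pos,
                   id = sprintf("s%02d", seq_len(n)),
                   ref = "A", alt = "G", qual = qual)
  colnames(freqs) <- paste0("freq_", rownames(toyDesign()))
  cbind(df, freqs)
}

test_that("variant filters apply QUAL, missingness and MAF in order", {
  design <- toyDesign()
  base <- matrix(0.3, 5, nrow(design))
  base[2, ] <- 0.01                       # fails MAF
  base[3, 1:6] <- NA                      # 33% missing
  base[4, ] <- 0.05                       # exactly at the MAF bound: kept
  snps <- .toySnps(base, qual = c(60, 60, 60, 60, 10))
  out <- filterVariants(snps, maf_min = 0.05, max_missing = 0.25,
                        qual_min = 30)
  expect_setequal(out$id, c("s01", "s04"))
  # multiallelic / non-SNP rows are dropped first
  snps$alt[1] <- "GT"
  expect_false("s01" %in% filterVariants(snps)$id)
})

test_that("association finds a frequency-tracking SNP inside its enhancer", {
  design <- toyDesign()
  enh <- GRanges("chr1", IRanges(c(1000, 3000), width = 500))
  mcols(enh)$id <- c("eA", "eB")
  act <- matrix(0, 2, nrow(design),
                dimnames = list(NULL, rownames(design)))
  pop_act <- setNames(c(4, 3, 2, 1.5, 1, 0.5), unique(design$population))
  act[1, ] <- pop_act[design$population] +
    rnorm(nrow(design), 0, 0.01)
  act[2, ] <- rnorm(nrow(design), 0, 0.01)
  rownames(act) <- c("eA", "eB")
  fr <- rbind(0.1 + 0.15 * act[1, ],     # tracks eA activity
              rep(0.4, nrow(design)))    # constant: skipped
  set.seed(31)
  snps <- .toySnps(fr, pos = c(1100, 3100))
  res <- associateActivity(snps, act, enh, design = design)
  expect_equal(nrow(res), 1L)            # the constant SNP is skipped
  expect_identical(res$snp, "s01")
  expect_identical(res$enhancer, "eA")
  expect_gt(res$slope, 0)
  expect_lt(res$q_value, 0.01)
})

test_that("population aggregation defuses shared-pool pseudo-replication", {
  ## frequency and activity both vary by population but independently:
  ## with populations as units this is null; flask-level units would see
  ## 18 correlated points and often call it significant
  design <- toyDesign()
  enh <- GRanges("chr1", IRanges(1000, width = 500))
  mcols(enh)$id <- "eA"
  set.seed(41)
  n_null <- 200L
  p_hit <- 0L
  for (k in seq_len(n_null)) {
    act <- matrix(rnorm(6)[match(design$population,
                                 unique(design$population))] +
                    rnorm(18, 0, 0.05), 1,
                  dimnames = list("eA", rownames(design)))
    fr <- matrix(plogis(rnorm(6))[match(design$population,
                                        unique(design$population))] +
                   rnorm(18, 0, 0.01), 1)
    snps <- .toySnps(fr, pos = 1100)
    res <- associateActivity(snps, act, enh, design = design)
    if (nrow(res) && res$p_value < 0.05) p_hit <- p_hit + 1L
  }
  expect_lt(p_hit, n_null * 0.05 + 3 * sqrt(n_null * 0.05 * 0.95))
})

test_that("SNPs outside every enhancer are skipped with a warning", {
  design <- toyDesign()
  enh <- GRanges("chr1", IRanges(1000, width = 500))
  mcols(enh)$id <- "eA"
  act <- matrix(rnorm(18), 1, dimnames = list("eA", rownames(design)))
  snps <- .toySnps(matrix(runif(18), 1), pos = 99999)
  expect_warning(res <- associateActivity(snps, act, enh, design = design),
                 "outside every enhancer")
  expect_equal(nrow(res), 0L)
})

test_that("derived-allele direction flips with polarization", {
  assoc <- data.frame(snp = c("s1", "s2", "s3"),
                      slope = c(0.2, 0.2, 0.2))
  snps <- data.frame(id = c("s1", "s2", "s3"),
                     derived_allele = c("alt", "ref", "unresolved"))
  out <- directionOfEffect(assoc, snps)
  expect_identical(out$derived_direction,
                   c("increase", "decrease", "unresolved"))
})

test_that("the Pearson chi-square has no continuity correction", {
  tab <- rbind(c(8, 13), c(28, 24))
  r <- pearsonChisq(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(r$statistic, sum((tab - E)^2 / E))
  expect_equal(r$df, 1)
  # Yates-corrected value would differ
  expect_false(isTRUE(all.equal(r$statistic,
                                unname(chisq.test(tab)$statistic))))
  expect_error(pearsonChisq(rbind(c(0, 0), c(1, 2))), "empty row or column")
})

test_that("the direction-of-effect battery runs every documented test", {
  set.seed(51)
  n <- 90L
  sites <- data.frame(
    class = rep(c("social-biased DAE", "solitary-biased DAE", "non-DAE"),
                each = 30L),
    derived_direction = sample(c("increase", "decrease"), n, replace = TRUE),
    pbs_social = rexp(n, 10), pbs_solitary = rexp(n, 10))
  # plant a strong increase excess in the social class
  sites$derived_direction[1:24] <- "increase"
  r <- contingencyTests(sites)
  expect_s3_class(as.data.frame.matrix(r$table), "data.frame")
  expect_true(all(c("statistic", "df", "p_value") %in% names(r$chisq)))
  expect_equal(length(r$binomial), 3L)
  b_soc <- r$binomial[["social-biased DAE"]]
  expect_equal(b_soc$n, 30L)
  expect_gt(b_soc$frac_increase, 0.7)
  expect_equal(length(r$proportion_pairs), 3L)
  expect_true(length(r$kruskal) >= 1L)
  expect_error(contingencyTests(
    data.frame(class = "x", derived_direction = "unresolved")),
    "no sites with a resolved direction")
})
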