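test_that("simulated genome has consistent nested gene models", {
  ann <- smallStudy()$annotation
  type <- mcols(ann)$type
  expect_true(all(c("gene", "mRNA", "exon") %in% type))
  genes <- ann[type == "gene"]
  # genes do not overlap one another
  expect_equal(sum(countOverlaps(genes, genes) > 1L), 0L)
  # every child feature lies within its gene's span
  exons <- ann[type == "exon"]
  expect_true(all(overlapsAny(exons, genes, type = "within")))
  # widths within the generator's gene-size range
  expect_true(all(width(genes) >= 2000 & width(genes) <= 8000))
})

test_that("genome simulation fails loudly when chromosomes cannot hold genes", {
  cfg <- simConfig(n_chromosomes = 1L, chrom_length = 3000, n_genes = 5L,
                   n_enhancers = 1L, frac_causal_snps = 0)
  expect_error(simulateGenome(cfg), "too short")
})

test_that("planted enhancers are disjoint, sized and fully annotated", {
  study <- smallStudy()
  tr <- study$truths
  expect_gt(length(tr), 0L)
  expect_equal(sum(countOverlaps(tr, tr) > 1L), 0L)
  expect_true(all(width(tr) >= 300 & width(tr) <= 1500))
  m <- mcols(tr)
  expect_true(all(c("id", "base_activity", "active_in", "sociality_bias",
                    "planted_mechanism", "target_gene",
                    "expected_class_diff") %in% colnames(m)))
  expect_false(anyDuplicated(m$id) > 0)
  expect_true(all(m$base_activity >= 4 - 1e-9))
  expect_true(all(m$sociality_bias %in% c("none", "social", "solitary")))
  # biased enhancers are active everywhere so the shift is measurable
  pops <- names(smallConfig()@populations)
  biased <- m$sociality_bias != "none"
  expect_true(all(lengths(m$active_in[biased]) == length(pops)))
})

test_that("expected class difference is zero iff activity is class-symmetric", {
  tr <- smallStudy()$truths
  m <- mcols(tr)
  cls <- smallConfig()@populations
  balanced <- vapply(seq_along(tr), function(i) {
    ai <- m$active_in[[i]]
    sum(cls[ai] == "social") == sum(cls[ai] == "solitary")
  }, logical(1))
  symmetric <- balanced & m$sociality_bias == "none"
  expect_true(all(abs(m$expected_class_diff[symmetric]) < 1e-12))
  expect_true(all(abs(m$expected_class_diff[!symmetric]) > 0))
})

test_that("replicate activity matrix honours active populations and bias", {
  cfg <- smallConfig()
  study <- smallStudy()
  design <- study$design
  act <- truthActivityByReplicate(study$truths, cfg, design)
  expect_equal(dim(act), c(length(study$truths), nrow(design)))
  m <- mcols(study$truths)
  for (i in seq_along(study$truths)) {
    inactive <- !design$population %in% m$active_in[[i]]
    expect_true(all(act[i, inactive] == 1))
    expect_true(all(act[i, !inactive] >= 1))
  }
  # a planted bias shifts the favoured class by dae_effect on average
  biased <- which(m$sociality_bias != "none")
  if (length(biased)) {
    i <- biased[1]
    fav <- design$sociality == m$sociality_bias[i]
    expect_gt(mean(log2(act[i, fav])), mean(log2(act[i, !fav])))
  }
})

test_that("simulated counts line up with the design and stay reproducible", {
  study <- smallStudy()
  se <- study$counts
  expect_s4_class(se, "StarrExperiment")
  expect_identical(colnames(dnaCounts(se)), rownames(study$design))
  expect_true(all(dnaCounts(se) >= 0) && all(rnaCounts(se) >= 0))
  expect_equal(dim(metadata(se)$activity_by_replicate),
               c(length(study$truths), nrow(study$design)))
  # RNA is enriched over DNA inside active truth regions
  i <- which(lengths(mcols(study$truths)$active_in) > 0)[1]
  bins <- overlapsAny(rowRanges(se), study$truths[i])
  r <- names(which(metadata(se)$activity_by_replicate[i, ] > 2))[1]
  expect_gt(sum(rnaCounts(se)[bins, r]), 1.5 * sum(dnaCounts(se)[bins, r]))
})

test_that("variants carry coherent frequencies, genotypes and outgroup calls", {
  study <- smallStudy()
  v <- study$variants
  expect_gt(nrow(v$snps), 0L)
  fcols <- grep("^freq_", colnames(v$snps), value = TRUE)
  expect_setequal(sub("^freq_", "", fcols), rownames(study$design))
  fr <- as.matrix(v$snps[, fcols])
  expect_true(all(fr >= 0 & fr <= 1))
  expect_true(all(v$snps$ref != v$snps$alt))
  expect_true(all(v$snps$ancestral == v$snps$ref |
                    v$snps$ancestral == v$snps$alt))
  g <- v$genotypes
  expect_true(all(g$alt_social <= g$n_social))
  expect_true(all(g$alt_outgroup <= g$n_outgroup))
  # every SNP sits inside its recorded enhancer
  snp_gr <- GRanges(v$snps$chrom, IRanges(v$snps$pos, v$snps$pos))
  hit <- findOverlaps(snp_gr, study$truths, select = "first")
  expect_false(anyNA(hit))
  expect_identical(mcols(study$truths)$id[hit], v$snps$enhancer)
})

test_that("the whole study is a deterministic function of the seed", {
  cfg <- simConfig(n_chromosomes = 1L, chrom_length = 1e5, n_genes = 10L,
                   n_enhancers = 10L, depth = 1e5, n_convergent_genes = 0L,
                   seed = 7L)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(s1$truths, s2$truths)
  expect_identical(dnaCounts(s1$counts), dnaCounts(s2$counts))
  expect_identical(rnaCounts(s1$counts), rnaCounts(s2$counts))
  expect_identical(s1$variants$snps, s2$variants$snps)
  s3 <- simulateStudy(simConfig(n_chromosomes = 1L, chrom_length = 1e5,
                                n_genes = 10L, n_enhancers = 10L,
                                depth = 1e5, n_convergent_genes = 0L,
                                seed = 8L))
  expect_false(identical(rnaCounts(s1$counts), rnaCounts(s3$counts)))
})

test_that("stage child seeds separate the generator stages", {
  seeds <- vapply(c("genome", "enhancers", "activity", "counts",
                    "variants", "cnee"),
                  function(s) childSeed(1L, s), integer(1))
  expect_false(anyDuplicated(seeds) > 0)
  expect_error(childSeed(1L, "nonsense"), "unknown generator stage")
})

test_that("simulation config validates its inputs", {
  expect_error(simConfig(frac_conserved = 1.4))
  expect_error(simConfig(populations = c(a = "social", b = "social")),
               "sociality class")
  expect_error(simConfig(activity_range = c(16, 4)))
})
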