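## One forward gene with a clean model:
## gene g1 chr1:20001-28000 (+), exons 20001-21000 / 23001-24000 / 27001-28000
## => first intron 21001-23000, other intron 24001-27000
.toyAnnotation <- function(strand = "+") {
  if (strand == "+") {
    gr <- GRanges("chr1",
                  IRanges(c(20001, 20001, 20001, 23001, 27001, 20001, 27501),
                          c(28000, 28000, 21000, 24000, 28000, 20300, 28000)),
                  strand = strand,
                  type = c("gene", "mRNA", "exon", "exon", "exon",
                           "five_prime_UTR", "three_prime_UTR"),
                  ID = c("g1", "t1", "t1.e1", "t1.e2", "t1.e3",
                         "t1.u5", "t1.u3"),
                  Parent = c(NA, "g1", "t1", "t1", "t1", "t1", "t1"))
  } else {
    gr <- GRanges("chr1",
                  IRanges(c(20001, 20001, 20001, 23001, 27001, 27701, 20001),
                          c(28000, 28000, 21000, 24000, 28000, 28000, 20500)),
                  strand = strand,
                  type = c("gene", "mRNA", "exon", "exon", "exon",
                           "five_prime_UTR", "three_prime_UTR"),
                  ID = c("g1", "t1", "t1.e1", "t1.e2", "t1.e3",
                         "t1.u5", "t1.u3"),
                  Parent = c(NA, "g1", "t1", "t1", "t1", "t1", "t1"))
  }
  gr
}

.enh <- function(starts, ends, ids) {
  g <- GRanges("chr1", IRanges(starts, ends))
  mcols(g)$id <- ids
  g
}

test_that("feature priority ranks match the documented order", {
  pr <- featurePriority()
  expect_identical(names(pr)[order(pr)],
                   c("tss_flanks", "tss_upstream", "promoter",
                     "first_intron", "intron", "utr5", "utr3", "exon",
                     "upstream", "downstream", "intergenic"))
})

test_that("each positional class is recognized on a forward-strand gene", {
  ann <- .toyAnnotation("+")
  e <- .enh(
    c(19980, 19850, 16000, 21500, 25000, 20100, 27600, 23400, 12000, 30000,
      50000),
    c(20020, 19900, 16400, 21900, 25400, 20250, 27800, 23800, 12400, 30400,
      50400),
    c("at_tss", "up200", "prom", "fintron", "ointron", "in_utr5", "in_utr3",
      "in_exon", "far_up", "down", "nowhere"))
  calls <- classifyFeatures(e, ann)
  got <- setNames(calls$feature, calls$enhancer)
  expect_identical(unname(got["at_tss"]), "tss_flanks")
  expect_identical(unname(got["up200"]), "tss_upstream")
  expect_identical(unname(got["prom"]), "promoter")
  expect_identical(unname(got["fintron"]), "first_intron")
  expect_identical(unname(got["ointron"]), "intron")
  expect_identical(unname(got["in_utr5"]), "utr5")
  expect_identical(unname(got["in_utr3"]), "utr3")
  # exon 2 is not a UTR, so a contained enhancer is exonic
  expect_identical(unname(got["in_exon"]), "exon")
  expect_identical(unname(got["far_up"]), "upstream")
  expect_identical(unname(got["down"]), "downstream")
  expect_identical(unname(got["nowhere"]), "intergenic")
  expect_true(is.na(calls$gene[calls$enhancer == "nowhere"]))
})

test_that("TSS and upstream logic flips on the minus strand", {
  ann <- .toyAnnotation("-")
  e <- .enh(c(27990, 28100, 34000, 12000),
            c(28030, 28180, 34400, 12400),
            c("at_tss", "up200", "far_up", "down"))
  calls <- classifyFeatures(e, ann)
  got <- setNames(calls$feature, calls$enhancer)
  expect_identical(unname(got["at_tss"]), "tss_flanks")
  expect_identical(unname(got["up200"]), "tss_upstream")
  expect_identical(unname(got["far_up"]), "upstream")
  expect_identical(unname(got["down"]), "downstream")
  # minus-strand first intron is the one nearest the TSS (rightmost)
  fi <- classifyFeatures(.enh(25000, 25400, "fi"), ann)
  expect_identical(fi$feature, "first_intron")
})

test_that("the 10-kb association distance is inclusive at the boundary", {
  ann <- .toyAnnotation("+")
  at10k <- classifyFeatures(.enh(9001, 10001, "edge"), ann)   # gap = 10000
  expect_identical(at10k$feature, "upstream")
  beyond <- classifyFeatures(.enh(9000, 10000, "out"), ann)   # gap = 10001
  expect_identical(beyond$feature, "intergenic")
})

test_that("strict assignment keeps only the best-ranked gene ties", {
  ## two genes straddling one enhancer: downstream of g1, in g2's promoter
  ann <- c(.toyAnnotation("+"),
           GRanges("chr1", IRanges(32001, 36000), strand = "+",
                   type = "gene", ID = "g2", Parent = NA))
  e <- .enh(29000, 29400, "between")
  strict <- assignGenes(e, ann, mode = "strict")
  lenient <- assignGenes(e, ann, mode = "lenient")
  expect_equal(nrow(lenient), 2L)
  expect_equal(nrow(strict), 1L)
  expect_identical(strict$gene, "g2")     # promoter (3) beats downstream (10)
  expect_identical(strict$feature, "promoter")
})

test_that("malformed gene models are rejected", {
  bad <- GRanges("chr1", IRanges(c(1000, 1000, 900), c(2000, 2000, 1500)),
                 type = c("gene", "mRNA", "exon"),
                 ID = c("g", "t", "t.e1"), Parent = c(NA, "g", "t"))
  expect_error(classifyFeatures(.enh(1100, 1200, "e"), bad),
               "malformed gene model")
})

test_that("specificity summary and the redundancy trend add up", {
  presence <- matrix(c(TRUE, TRUE, TRUE, TRUE,   # e1 in all 4 pops
                       TRUE, FALSE, FALSE, FALSE,  # e2 in 1
                       TRUE, TRUE, FALSE, FALSE),  # e3 in 2
                     nrow = 3, byrow = TRUE,
                     dimnames = list(c("e1", "e2", "e3"),
                                     c("p1", "p2", "p3", "p4")))
  asg <- data.frame(enhancer = c("e1", "e2", "e3"),
                    gene = c("gA", "gA", "gB"))
  ss <- specificitySummary(presence, asg)
  ss <- ss[order(ss$gene), ]
  expect_identical(ss$gene, c("gA", "gB"))
  expect_identical(ss$max_specificity, c(4, 2))
  expect_identical(ss$n_assigned_enhancers, c(2L, 1L))
  tr <- multiEnhancerTrend(ss)
  expect_identical(tr$frac_multi_enhancer[tr$max_specificity == 4], 1)
  expect_identical(tr$frac_multi_enhancer[tr$max_specificity == 2], 0)
  expect_error(specificitySummary(presence,
                                  data.frame(enhancer = "zz", gene = "g")),
               "missing from presence")
})

test_that("convergent targets separate conserved from compensatory coverage", {
  design <- toyDesign()
  pops <- unique(design$population)
  mk <- function(...) {
    m <- matrix(FALSE, 1, 6, dimnames = list(NULL, pops))
    m[1, c(...)] <- TRUE
    m
  }
  presence <- rbind(mk("soc1", "soc2", "soc3"),          # one enh, all social
                    mk("soc1"), mk("soc2"), mk("soc3"),  # compensatory trio
                    mk("soc1", "sol1"))                  # mixed
  rownames(presence) <- paste0("e", 1:5)
  asg <- data.frame(enhancer = paste0("e", 1:5),
                    gene = c("gCons", "gComp", "gComp", "gComp", "gMix"))
  conv <- convergentTargets(presence, asg, design)
  conv <- setNames(split(conv, conv$gene), NULL)
  byg <- do.call(rbind, conv)
  rownames(byg) <- byg$gene
  expect_identical(byg["gCons", "convergence_class"], "social_only")
  expect_identical(byg["gCons", "mechanism"], "conserved")
  expect_identical(byg["gComp", "convergence_class"], "social_only")
  expect_identical(byg["gComp", "mechanism"], "compensatory")
  expect_identical(byg["gMix", "convergence_class"], "mixed")
  expect_identical(byg["gMix", "mechanism"], "n/a")
})
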