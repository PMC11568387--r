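test_that("log-odds scoring follows the pseudocount algebra", {
  pwm <- Pwm("perfect", matrix(c(1, 0, 0, 0), 4, 1), pseudocount = 0)
  lom <- logoddsMatrix(pwm)
  expect_equal(unname(lom[1, 1]), log2(1 / 0.25))   # 2 bits
  expect_identical(unname(lom[2, 1]), -Inf)
  pc <- Pwm("smoothed", matrix(c(1, 0, 0, 0), 4, 1), pseudocount = 0.04)
  expect_equal(unname(logoddsMatrix(pc)[2, 1]),
               log2((0.04 * 0.25 / 1.04) / 0.25))
  expect_error(logoddsMatrix(Pwm("bad", matrix(0.25, 4, 2),
                                 background = c(0, 0.5, 0.25, 0.25))),
               "> 0")
})

test_that("scanning scores the consensus and both strands correctly", {
  pwm <- toyPwm(6)
  cons <- consensusSeq(pwm)                      # "ACGTAC"
  hit <- scanWindow(cons, pwm)
  lom <- logoddsMatrix(pwm)
  # scores are discretized to 1e-3-bit bins, so compare loosely
  expect_equal(hit$score, sum(apply(lom, 2, max)), tolerance = 1e-3)
  expect_identical(hit$strand, "+")
  expect_equal(hit$offset, 1L)
  # the reverse complement scores identically on the minus strand
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(cons, "")[[1]]),
                                     collapse = ""))
  hit_rc <- scanWindow(rc, pwm)
  expect_equal(hit_rc$score, hit$score)
  expect_identical(hit_rc$strand, "-")
  # an embedded motif is found at the right offset
  emb <- paste0("TTTT", cons, "TTTT")
  expect_equal(scanWindow(emb, pwm)$offset, 5L)
  expect_error(scanWindow("ACG", pwm), "longer than sequence")
})

test_that("match p-values agree with brute-force enumeration", {
  set.seed(61)
  for (L in c(3L, 5L)) {
    m <- matrix(rexp(4 * L), 4, L)
    m <- sweep(m, 2, colSums(m), "/")
    pwm <- Pwm(paste0("rand", L), m)
    ints <- round(logoddsMatrix(pwm) / 1e-3)
    all_seqs <- do.call(expand.grid,
                        rep(list(c("A", "C", "G", "T")), L))
    scores <- apply(as.matrix(all_seqs), 1, function(ch)
      sum(ints[cbind(match(ch, c("A", "C", "G", "T")), seq_len(L))]))
    for (probe in c("ACGTACGT", "GGGCCCTT")) {
      sq <- substr(probe, 1, L)
      hit <- scanWindow(sq, pwm)
      thr <- round(hit$score / 1e-3)
      expect_equal(hit$p_value, mean(scores >= thr))
    }
  }
})

test_that("allele effects follow the gain/loss and ratio rules", {
  pwm <- toyPwm(8)
  cons <- consensusSeq(pwm)
  flank_l <- "TTATTGTTTATTGTTTATTGTT"
  flank_r <- "TTGATTTTGATTTTGATTTTGA"
  ref <- paste0(flank_l, cons, flank_r)
  broken <- cons
  substr(broken, 3, 3) <- "A"                    # G -> A at motif pos 3
  alt <- paste0(flank_l, broken, flank_r)
  eff <- alleleEffect(ref, alt, list(pwm))
  expect_identical(eff$effect, "loss")
  expect_lt(eff$p_ref, 1e-4)
  expect_gte(eff$p_alt, 1e-4)
  # swapped windows: the alternate allele creates the site
  expect_identical(alleleEffect(alt, ref, list(pwm))$effect, "gain")
  # derived-allele direction
  expect_identical(alleleEffect(ref, alt, list(pwm),
                                derived = "alt")$direction, "decrease")
  expect_error(alleleEffect(ref, chartr("AT", "TA", ref), list(pwm)),
               "exactly 1 position")
  # identical significance, small score change: no effect
  pwm2 <- toyPwm(8, p = 0.4)
  expect_identical(alleleEffect(ref, alt, list(pwm2), sig = 1e-12)$effect,
                   "none")
})

test_that("motif enrichment reduces to the hypergeometric tail", {
  pwm <- toyPwm(8)
  cons <- consensusSeq(pwm)
  with_site <- vapply(1:8, function(i)
    paste0(strrep("TA", 10), cons, strrep("AT", 10)), character(1))
  without <- vapply(1:12, function(i)
    paste0(strrep("TA", 10), strrep("TTAA", 4), strrep("AT", 10)),
    character(1))
  r <- motifEnrichment(with_site, c(with_site, without), list(pwm))
  expect_equal(r$fg_hits, 8L)
  expect_equal(r$bg_hits, 0L)
  expect_equal(r$p_value, phyper(7, 8, 12, 8, lower.tail = FALSE))
  expect_true(r$enriched)
  expect_error(motifEnrichment(character(0), without, list(pwm)),
               "empty foreground")
})

test_that("JASPAR and MEME motif files parse to normalized PWMs", {
  jaspar <- tempfile(fileext = ".pfm")
  writeLines(c(">M1 toy",
               "A [ 8 0 0 ]",
               "C [ 0 8 0 ]",
               "G [ 0 0 8 ]",
               "T [ 0 0 0 ]"), jaspar)
  pj <- readJasparPfm(jaspar)
  expect_identical(names(pj), "M1")
  expect_equal(unname(colSums(pj$M1@matrix)), rep(1, 3))
  expect_equal(unname(pj$M1@matrix[1, 1]), 1)

  meme <- tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "",
               "ALPHABET= ACGT", "",
               "Background letter frequencies",
               "A 0.3 C 0.2 G 0.2 T 0.3", "",
               "MOTIF M2",
               "letter-probability matrix: alength= 4 w= 2 nsites= 10",
               " 0.9 0.1 0.0 0.0",
               " 0.0 0.0 0.1 0.9"), meme)
  pm <- readMemeMotifs(meme)
  expect_identical(names(pm), "M2")
  expect_equal(motifLength(pm$M2), 2L)
  expect_equal(unname(pm$M2@background), c(0.3, 0.2, 0.2, 0.3))
  expect_equal(unname(pm$M2@matrix[, 1]), c(0.9, 0.1, 0, 0))
})

test_that("simulated allele windows plant recoverable disruptions", {
  pwm <- toyPwm(8)
  wins <- simulateAlleleWindows(pwm, n = 10L, seed = 3L)
  expect_equal(nrow(wins), 10L)
  expect_true(all(nchar(wins$window_ref) == 101L))
  diffs <- mapply(function(r, a)
    sum(strsplit(r, "")[[1]] != strsplit(a, "")[[1]]),
    wins$window_ref, wins$window_alt)
  expect_true(all(diffs == 1L))
  expect_identical(simulateAlleleWindows(pwm, n = 10L, seed = 3L), wins)
})
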