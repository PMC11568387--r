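suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

## Shared small simulation, computed once per test run.
.fixtures <- new.env(parent = emptyenv())

smallConfig <- function(...) {
  simConfig(n_chromosomes = 2L, chrom_length = 2e5, n_genes = 30L,
            n_enhancers = 30L, depth = 2e5, n_convergent_genes = 4L,
            seed = 42L, ...)
}

smallStudy <- function() {
  if (is.null(.fixtures$study))
    .fixtures$study <- simulateStudy(smallConfig())
  .fixtures$study
}

## A six-population, three-replicate design matching the package default.
toyDesign <- function(n_rep = 3L) {
  pops <- c(soc1 = "social", soc2 = "social", soc3 = "social",
            sol1 = "solitary", sol2 = "solitary", sol3 = "solitary")
  df <- expand.grid(rep = seq_len(n_rep), population = names(pops),
                    stringsAsFactors = FALSE)
  data.frame(population = df$population,
             sociality = unname(pops[df$population]),
             batch = paste0("b", df$rep),
             row.names = paste0(df$population, "_r", df$rep))
}

## StarrExperiment with a prescribed activity matrix: counts are dummies,
## the activity assay carries the signal.
activitySE <- function(activity, design = toyDesign()) {
  stopifnot(ncol(activity) == nrow(design))
  colnames(activity) <- rownames(design)
  gr <- GRanges("chr1", IRanges(seq_len(nrow(activity)) * 1000L, width = 500L))
  mcols(gr)$id <- sprintf("enh%03d", seq_len(nrow(activity)))
  dummy <- matrix(10L, nrow(activity), ncol(activity),
                  dimnames = dimnames(activity))
  StarrExperiment(gr, dna = dummy, rna = dummy, design = design,
                  activity = activity)
}

## A deterministic high-information PWM (consensus ACGT...).
toyPwm <- function(len = 6L, p = 0.97) {
  cons <- rep_len(1:4, len)
  m <- matrix((1 - p) / 3, 4, len)
  for (j in seq_len(len)) m[cons[j], j] <- p
  Pwm("toy", m)
}

consensusSeq <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm@matrix, 2, which.max)],
        collapse = "")
}
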