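#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import SummarizedExperiment
#' @importFrom GenomeInfoDb seqlengths seqlevels seqlevels<- seqinfo seqinfo<- Seqinfo
NULL

#' StarrExperiment: paired DNA/RNA fragment counts over genomic windows
#'
#' A container for STARR-seq count data, extending
#' [SummarizedExperiment::RangedSummarizedExperiment]. Rows are genomic
#' windows (or consensus enhancers), columns are replicates (flasks). Two
#' assays are mandatory: `"dna"` (input library fragment counts) and `"rna"`
#' (plasmid-derived mRNA fragment counts). After [quantifyActivity()] an
#' `"activity"` assay holds per-replicate log2 RNA/DNA fold-changes.
#'
#' The column data must describe the replicate design with columns
#' `population`, `sociality` (`"social"` or `"solitary"`) and `batch`; each
#' population must map to exactly one sociality class.
#'
#' @aliases StarrExperiment-class
#' @export
setClass("StarrExperiment",
  contains = "RangedSummarizedExperiment"
)

setValidity("StarrExperiment", function(object) {
  msg <- character()
  an <- assayNames(object)
  if (!all(c("dna", "rna") %in% an))
    msg <- c(msg, "assays must include 'dna' and 'rna'")
  cd <- colData(object)
  need <- c("population", "sociality", "batch")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  if (all(c("population", "sociality") %in% colnames(cd))) {
    if (!all(cd$sociality %in% c("social", "solitary")))
      msg <- c(msg, "sociality must be 'social' or 'solitary'")
    tab <- unique(data.frame(population = as.character(cd$population),
                             sociality = as.character(cd$sociality)))
    if (anyDuplicated(tab$population))
      msg <- c(msg, "each population must map to exactly one sociality class")
  }
  if ("dna" %in% an && "rna" %in% an) {
    if (any(assay(object, "dna") < 0) || any(assay(object, "rna") < 0))
      msg <- c(msg, "counts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StarrExperiment
#'
#' @param windows `GRanges` of count windows (or enhancer regions).
#' @param dna,rna integer matrices, one row per window, one column per
#'   replicate; column names are replicate ids.
#' @param design `data.frame` or `DataFrame` with one row per replicate and
#'   columns `population`, `sociality`, `batch`. Row order matches the count
#'   columns.
#' @param ... further assays passed on (e.g. `activity`).
#' @return A [StarrExperiment-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 101), width = 100))
#' design <- data.frame(population = c("p1", "p2"),
#'                      sociality = c("social", "solitary"), batch = "b1",
#'                      row.names = c("r1", "r2"))
#' dna <- matrix(10L, 2, 2, dimnames = list(NULL, rownames(design)))
#' se <- StarrExperiment(gr, dna = dna, rna = dna, design = design)
#' @export
StarrExperiment <- function(windows, dna, rna, design, ...) {
  stopifnot(is(windows, "GRanges"))
  design <- as(design, "DataFrame")
  if (is.null(rownames(design)) && !is.null(colnames(dna)))
    rownames(design) <- colnames(dna)
  se <- SummarizedExperiment(
    assays = c(list(dna = dna, rna = rna), list(...)),
    rowRanges = windows, colData = design
  )
  new("StarrExperiment", se)
}

#' @describeIn StarrExperiment DNA input counts matrix.
#' @param x A `StarrExperiment`.
#' @export
dnaCounts <- function(x) assay(x, "dna")

#' @describeIn StarrExperiment RNA (STARR library) counts matrix.
#' @export
rnaCounts <- function(x) assay(x, "rna")

#' @describeIn StarrExperiment per-replicate log2 activity matrix (present
#'   after [quantifyActivity()]).
#' @export
activityMatrix <- function(x) {
  if (!"activity" %in% assayNames(x))
    stop("no 'activity' assay; run quantifyActivity() first")
  assay(x, "activity")
}

#' @describeIn StarrExperiment the replicate design (population, sociality,
#'   batch) as a data.frame with replicate ids as row names.
#' @export
replicateDesign <- function(x) as.data.frame(colData(x))

setMethod("show", "StarrExperiment", function(object) {
  callNextMethod()
  cd <- colData(object)
  cat("design: ", length(unique(cd$population)), " populations (",
      sum(table(unique(data.frame(p = cd$population, s = cd$sociality))$s ==
            "social") > 0), ") | ",
      ncol(object), " replicates | batches: ",
      paste(unique(as.character(cd$batch)), collapse = ","), "\n", sep = "")
})

#' Simulation configuration for the synthetic STARR-seq study
#'
#' Holds every knob of the synthetic-data generator. Defaults emulate a
#' six-population (3 social + 3 solitary), three-replicate reporter-assay
#' design at desk scale: a small multi-chromosome genome, negative-binomial
#' fragment counts, planted enhancers with population-specific activity,
#' SNPs inside enhancers whose pooled allele frequencies may track activity,
#' per-population diploid genotypes for Fst, and an outgroup allele per site.
#'
#' @slot n_chromosomes,chrom_length genome shape (bp).
#' @slot n_genes,n_enhancers counts of planted features.
#' @slot populations named character vector: population name -> sociality
#'   class ("social"/"solitary").
#' @slot replicates_per_population flasks per population.
#' @slot frac_conserved fraction of enhancers active in all populations.
#' @slot frac_population_specific fraction active in exactly one population.
#' @slot frac_dae fraction with a sociality-linked activity shift.
#' @slot dae_effect multiplicative RNA shift in the favoured class.
#' @slot nb_dispersion negative-binomial dispersion alpha
#'   (variance = mu + alpha mu^2); 0 degenerates to Poisson.
#' @slot depth expected fragments per replicate (genome-wide).
#' @slot bin_size count-window width in bp.
#' @slot activity_range linear fold-enrichment range for active enhancers.
#' @slot rep_activity_sd per-replicate (flask) log2 activity jitter; the
#'   across-replicate activity variance that causal SNPs can track.
#' @slot n_snps_per_enhancer,frac_causal_snps,assoc_slope,freq_noise SNP layer.
#' @slot n_individuals diploid individuals per population for genotypes.
#' @slot drift Beta-drift concentration: per-population frequencies are drawn
#'   Beta(p0*k, (1-p0)*k) with k = (1-drift)/drift around the ancestral p0.
#' @slot outgroup_misid probability the recorded outgroup allele is not the
#'   true ancestral allele.
#' @slot frac_selected fraction of SNPs with a planted focal-group frequency
#'   shift (selection); selection_shift its magnitude.
#' @slot n_convergent_genes genes given class-restricted enhancer clusters
#'   (half social, half solitary; within each, half conserved mechanism, half
#'   compensatory) on top of `n_enhancers`.
#' @slot seed integer RNG seed; fans out to fixed per-stage child seeds.
#' @export
setClass("SimConfig", representation(
  n_chromosomes = "integer", chrom_length = "numeric",
  n_genes = "integer", n_enhancers = "integer",
  populations = "character", replicates_per_population = "integer",
  frac_conserved = "numeric", frac_population_specific = "numeric",
  frac_dae = "numeric", dae_effect = "numeric",
  nb_dispersion = "numeric", depth = "numeric", bin_size = "integer",
  activity_range = "numeric", rep_activity_sd = "numeric",
  n_snps_per_enhancer = "integer", frac_causal_snps = "numeric",
  assoc_slope = "numeric", freq_noise = "numeric",
  n_individuals = "integer", drift = "numeric",
  outgroup_misid = "numeric", frac_selected = "numeric",
  selection_shift = "numeric", n_convergent_genes = "integer",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  fr <- c(object@frac_conserved, object@frac_population_specific,
          object@frac_dae, object@frac_causal_snps, object@outgroup_misid,
          object@frac_selected)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "all fractions must lie in [0,1]")
  if (object@frac_conserved + object@frac_population_specific > 1)
    msg <- c(msg, "frac_conserved + frac_population_specific must be <= 1")
  if (any(c(object@n_chromosomes, object@n_genes, object@n_enhancers,
            object@replicates_per_population, object@n_snps_per_enhancer) < 0L))
    msg <- c(msg, "counts must be >= 0")
  soc <- object@populations
  if (!all(soc %in% c("social", "solitary")))
    msg <- c(msg, "population sociality must be 'social' or 'solitary'")
  if (sum(soc == "social") < 2L || sum(soc == "solitary") < 2L)
    msg <- c(msg, "need >= 2 populations of each sociality class")
  if (length(object@activity_range) != 2L ||
      any(object@activity_range < 1) ||
      diff(object@activity_range) < 0)
    msg <- c(msg, "activity_range must be two non-decreasing folds >= 1")
  if (object@dae_effect <= 0) msg <- c(msg, "dae_effect must be > 0")
  if (object@nb_dispersion < 0) msg <- c(msg, "nb_dispersion must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param n_chromosomes,chrom_length,n_genes,n_enhancers,populations,
#'   replicates_per_population,frac_conserved,frac_population_specific,
#'   frac_dae,dae_effect,nb_dispersion,depth,bin_size,activity_range,
#'   rep_activity_sd,n_snps_per_enhancer,frac_causal_snps,assoc_slope,
#'   freq_noise,n_individuals,drift,outgroup_misid,frac_selected,
#'   selection_shift,n_convergent_genes,seed see [SimConfig-class].
#' @return A validated `SimConfig`.
#' @examples
#' cfg <- simConfig(n_genes = 10L, n_enhancers = 20L, seed = 7L)
#' @export
simConfig <- function(n_chromosomes = 2L, chrom_length = 5e5,
                      n_genes = 80L, n_enhancers = 120L,
                      populations = c(soc1 = "social", soc2 = "social",
                                      soc3 = "social", sol1 = "solitary",
                                      sol2 = "solitary", sol3 = "solitary"),
                      replicates_per_population = 3L,
                      frac_conserved = 0.11, frac_population_specific = 0.40,
                      frac_dae = 0.05, dae_effect = 2,
                      nb_dispersion = 0.05, depth = 5e5, bin_size = 100L,
                      activity_range = c(4, 16), rep_activity_sd = 0.25,
                      n_snps_per_enhancer = 3L, frac_causal_snps = 0.3,
                      assoc_slope = 0.1, freq_noise = 0.02,
                      n_individuals = 20L, drift = 0.05,
                      outgroup_misid = 0.05, frac_selected = 0.02,
                      selection_shift = 0.35, n_convergent_genes = 8L,
                      seed = 1L) {
  new("SimConfig",
      n_chromosomes = as.integer(n_chromosomes), chrom_length = chrom_length,
      n_genes = as.integer(n_genes), n_enhancers = as.integer(n_enhancers),
      populations = populations,
      replicates_per_population = as.integer(replicates_per_population),
      frac_conserved = frac_conserved,
      frac_population_specific = frac_population_specific,
      frac_dae = frac_dae, dae_effect = dae_effect,
      nb_dispersion = nb_dispersion, depth = depth,
      bin_size = as.integer(bin_size), activity_range = activity_range,
      rep_activity_sd = rep_activity_sd,
      n_snps_per_enhancer = as.integer(n_snps_per_enhancer),
      frac_causal_snps = frac_causal_snps, assoc_slope = assoc_slope,
      freq_noise = freq_noise, n_individuals = as.integer(n_individuals),
      drift = drift, outgroup_misid = outgroup_misid,
      frac_selected = frac_selected, selection_shift = selection_shift,
      n_convergent_genes = as.integer(n_convergent_genes),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  soc <- object@populations
  cat("SimConfig: ", object@n_chromosomes, " chrom x ",
      format(object@chrom_length, big.mark = ","), " bp | ",
      object@n_genes, " genes | ", object@n_enhancers, " enhancers | ",
      sum(soc == "social"), " social + ", sum(soc == "solitary"),
      " solitary populations x ", object@replicates_per_population,
      " replicates | seed ", object@seed, "\n", sep = "")
})

#' Position weight matrix with background model
#'
#' A transcription-factor binding motif as per-position nucleotide
#' probabilities plus a background distribution and pseudocount. Scores are
#' log2 odds against the background (see [logoddsMatrix()]).
#'
#' @slot id motif identifier.
#' @slot matrix 4 x L probability matrix, rows A, C, G, T.
#' @slot background length-4 background probabilities (sums to 1).
#' @slot pseudocount probability pseudocount (fraction of background added
#'   to each position before renormalization).
#' @aliases Pwm-class
#' @export
setClass("Pwm", representation(
  id = "character", matrix = "matrix",
  background = "numeric", pseudocount = "numeric"
))

setValidity("Pwm", function(object) {
  m <- object@matrix
  msg <- character()
  if (nrow(m) != 4L) msg <- c(msg, "matrix must have 4 rows (A,C,G,T)")
  if (!isTRUE(all.equal(rep(1, ncol(m)), unname(colSums(m)),
                        tolerance = 1e-9)))
    msg <- c(msg, "each position's probabilities must sum to 1")
  if (abs(sum(object@background) - 1) > 1e-9)
    msg <- c(msg, "background must sum to 1")
  if (any(m < 0) || any(object@background < 0))
    msg <- c(msg, "probabilities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a Pwm
#'
#' @param id motif id.
#' @param matrix 4 x L matrix of counts or probabilities (rows A,C,G,T);
#'   columns are normalized to sum to 1.
#' @param background background nucleotide probabilities (default uniform).
#' @param pseudocount pseudocount fraction (default 0.01).
#' @return A [Pwm-class] object.
#' @examples
#' m <- matrix(c(1, 0, 0, 0, 0, 0, 0, 1), 4, 2) # consensus "AT"
#' pwm <- Pwm("toy", m)
#' @export
Pwm <- function(id, matrix, background = rep(0.25, 4), pseudocount = 0.01) {
  matrix <- sweep(matrix, 2, colSums(matrix), "/")
  rownames(matrix) <- c("A", "C", "G", "T")
  new("Pwm", id = id, matrix = matrix, background = background,
      pseudocount = pseudocount)
}

#' @describeIn Pwm motif length in bp.
#' @param x A `Pwm`.
#' @export
motifLength <- function(x) ncol(x@matrix)

setMethod("show", "Pwm", function(object) {
  cons <- paste(c("A", "C", "G", "T")[apply(object@matrix, 2, which.max)],
                collapse = "")
  cat("Pwm '", object@id, "': ", ncol(object@matrix),
      " bp, consensus ", cons, "\n", sep = "")
})
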