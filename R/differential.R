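#' @importFrom stats pt
NULL

## Per-replicate log2 activity from counts: library-size-normalized
## RNA/DNA ratio with a 0.5 pseudocount on both counts. Falls back to an
## existing "activity" assay when present so upstream normalization
## choices are respected.
.replicateActivity <- function(se) {
  if ("activity" %in% assayNames(se)) return(assay(se, "activity"))
  dna <- dnaCounts(se); rna <- rnaCounts(se)
  sd_ <- colSums(dna); sr <- colSums(rna)
  log2(sweep(rna + 0.5, 2, sr, "/") / sweep(dna + 0.5, 2, sd_, "/"))
}

#' Test enhancers for sociality-linked differential activity
#'
#' Per enhancer, replicate-level log2 activities (library-size-normalized
#' RNA/DNA ratios) are first averaged within populations, and the social
#' vs solitary difference of the population means is tested with a pooled
#' two-sample t-test. The population, not the flask, is the experimental
#' unit: flasks from one population share its regulatory genotype, so
#' treating them as independent overstates the degrees of freedom and
#' inflates the test whenever activity varies between populations within a
#' class (for example, population-specific enhancers). Averaging over
#' flasks also cancels batch, which crosses populations by design.
#' P-values are Benjamini-Hochberg corrected across enhancers.
#'
#' @param se A [StarrExperiment-class] of per-enhancer counts (rows =
#'   consensus enhancers), e.g. from [quantifyActivity()]; an existing
#'   `activity` assay is used directly when present.
#' @param q_threshold significance threshold on the BH q-value (default
#'   0.05).
#' @return data.frame (one row per enhancer, sorted as input) with columns
#'   `enhancer`, `interaction_estimate` (log2 units, positive = higher activity in
#'   social populations), `standard_error`, `statistic`, `p_value`,
#'   `q_value`, `bias` (`social`/`solitary`/`none`).
#' @export
fitDifferential <- function(se, q_threshold = 0.05) {
  design <- replicateDesign(se)
  pops <- unique(design$population)
  pop_class <- vapply(pops, function(p)
    as.character(design$sociality[design$population == p][1]), character(1))
  n1 <- sum(pop_class == "social"); n2 <- sum(pop_class == "solitary")
  if (n1 < 2L || n2 < 2L)
    stop("need >= 2 populations per sociality class")
  a <- .replicateActivity(se)
  grp <- factor(design$population, levels = pops)
  # enhancers x populations matrix of mean activities
  M <- t(apply(a, 1L, function(x) tapply(x, grp, mean)))
  if (length(pops) == 1L) M <- matrix(M, ncol = 1L)
  soc <- M[, pop_class == "social", drop = FALSE]
  sol <- M[, pop_class == "solitary", drop = FALSE]
  m1 <- rowMeans(soc); m2 <- rowMeans(sol)
  v1 <- apply(soc, 1L, var); v2 <- apply(sol, 1L, var)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / df
  est <- m1 - m2
  se_e <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- ifelse(se_e > 0, est / se_e, sign(est) * Inf)
  p <- 2 * pt(-abs(tstat), df)
  q <- p.adjust(p, method = "BH")
  ids <- mcols(rowRanges(se))$id
  if (is.null(ids)) ids <- sprintf("enh%05d", seq_len(nrow(a)))
  bias <- rep("none", length(p))
  sig <- !is.na(q) & q < q_threshold
  bias[sig & est > 0] <- "social"
  bias[sig & est < 0] <- "solitary"
  data.frame(enhancer = ids, interaction_estimate = est,
             standard_error = se_e, statistic = tstat,
             p_value = p, q_value = q, bias = bias, row.names = NULL)
}

#' Split significant enhancers by direction of bias
#'
#' @param results output of [fitDifferential()].
#' @return list with character vectors `social` and `solitary` of enhancer
#'   ids; their lengths sum to the number of significant results.
#' @export
classifyBias <- function(results) {
  list(social = results$enhancer[results$bias == "social"],
       solitary = results$enhancer[results$bias == "solitary"])
}
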