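#' @importFrom stats phyper sd
#' @importFrom utils combn
NULL

## Uniform re-placement of regions on a genome: each region keeps its length
## and lands on any chromosome that can hold it, with probability
## proportional to chromosome length. Overlap among placed regions is not
## prevented (uniform-shuffle null).
.randomizeRegions <- function(widths, chrom_lengths) {
  ok <- outer(widths, chrom_lengths, "<=")   # region x chrom feasibility
  if (any(rowSums(ok) == 0L))
    stop("region longer than every chromosome")
  chroms <- names(chrom_lengths)
  chosen <- integer(length(widths))
  for (i in seq_along(widths)) {
    feas <- which(ok[i, ])
    chosen[i] <- if (length(feas) == 1L) feas else
      sample(feas, 1L, prob = chrom_lengths[feas])
  }
  maxs <- chrom_lengths[chosen] - widths + 1
  starts <- floor(runif(length(widths), 1, maxs + 1))
  GRanges(chroms[chosen], IRanges(as.integer(starts), width = widths))
}

#' Permutation test of region-set overlap
#'
#' Counts regions of `A` overlapping (>= 1 bp) at least one region of `B`,
#' then re-places every region of `A` uniformly at random on the genome
#' `n_perm` times (length-preserving, chromosome chosen with probability
#' proportional to its length among chromosomes that fit) and recounts. The
#' enrichment p-value is `(1 + #[perm >= observed]) / (1 + n_perm)`.
#'
#' @param A,B `GRanges` region sets.
#' @param genome named numeric vector of chromosome lengths, or a `Seqinfo`.
#' @param n_perm number of permutations (>= 19; default 200).
#' @param seed integer RNG seed.
#' @return list with `observed_overlap`, `perm_mean`, `perm_sd`, `perm_min`,
#'   `perm_max`, `z_score`, `empirical_p`, `representation_factor`,
#'   `n_permutations`.
#' @export
permutationOverlapTest <- function(A, B, genome, n_perm = 200L, seed = 1L) {
  if (is(genome, "Seqinfo"))
    genome <- setNames(as.numeric(seqlengths(genome)), seqnames(genome))
  if (n_perm < 19L) stop("n_perm must be >= 19")
  observed <- sum(overlapsAny(A, B))
  widths <- width(A)
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_perm), function(k)
    sum(overlapsAny(.randomizeRegions(widths, genome), B)), numeric(1))
  pm <- mean(perm); ps <- sd(perm)
  list(observed_overlap = observed,
       perm_mean = pm, perm_sd = ps,
       perm_min = min(perm), perm_max = max(perm),
       z_score = if (ps > 0) (observed - pm) / ps else NA_real_,
       empirical_p = (1 + sum(perm >= observed)) / (1 + n_perm),
       representation_factor = if (pm > 0) observed / pm else NA_real_,
       n_permutations = n_perm)
}

#' Representation factor
#'
#' Ratio of observed overlap to the mean permuted overlap.
#'
#' @param observed observed overlap count.
#' @param perm_mean mean overlap across permutations (> 0).
#' @return `observed / perm_mean` (summaries report it to 2 decimals).
#' @examples
#' round(representationFactor(19219, 15094), 2)  # 1.27
#' @export
representationFactor <- function(observed, perm_mean) {
  if (perm_mean <= 0) stop("perm_mean must be > 0")
  observed / perm_mean
}

#' Hypergeometric gene-set overlap test
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' overlap between two gene sets drawn from a common universe, with fold
#' enrichment `n_overlap / (n_A * n_B / n_universe)`.
#'
#' @param A,B character vectors of gene ids, subsets of `universe`.
#' @param universe character vector of all eligible gene ids.
#' @return list with `n_A`, `n_B`, `n_universe`, `n_overlap`,
#'   `fold_enrichment`, `hypergeometric_p`.
#' @export
geneSetOverlapTest <- function(A, B, universe) {
  A <- unique(A); B <- unique(B); universe <- unique(universe)
  badA <- setdiff(A, universe); badB <- setdiff(B, universe)
  if (length(badA) || length(badB))
    stop("ids outside the universe: ",
         paste(utils::head(c(badA, badB), 5), collapse = ", "))
  k <- length(intersect(A, B))
  nA <- length(A); nB <- length(B); N <- length(universe)
  expected <- nA * nB / N
  list(n_A = nA, n_B = nB, n_universe = N, n_overlap = k,
       fold_enrichment = if (expected > 0) k / expected else NA_real_,
       hypergeometric_p = phyper(k - 1, nA, N - nA, nB, lower.tail = FALSE))
}

#' Monte-Carlo specific overlap of multiple gene lists
#'
#' For every combination of two or more lists, counts the genes common to
#' all lists of the combination and compares it with the distribution
#' obtained by redrawing each list (same size, uniform without replacement)
#' from the universe `n_mc` times. p-values use the +1 correction.
#'
#' @param lists named list (>= 2) of character vectors, subsets of
#'   `universe`.
#' @param universe character vector of all eligible ids.
#' @param n_mc Monte-Carlo draws (default 10000).
#' @param seed integer RNG seed.
#' @return data.frame with one row per combination: `combination`,
#'   `n_lists`, `observed`, `expected`, `p`.
#' @export
multiwaySpecificOverlap <- function(lists, universe, n_mc = 10000L,
                                    seed = 1L) {
  universe <- unique(universe)
  if (length(lists) < 2L) stop("need >= 2 lists")
  if (is.null(names(lists))) names(lists) <- paste0("L", seq_along(lists))
  sizes <- lengths(lists)
  if (any(sizes > length(universe)))
    stop("universe smaller than a list")
  bad <- unlist(lapply(lists, setdiff, y = universe))
  if (length(bad))
    stop("ids outside the universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  set.seed(as.integer(seed))
  combos <- unlist(lapply(2:length(lists), function(k)
    combn(names(lists), k, simplify = FALSE)), recursive = FALSE)
  # simulate once: for each draw, resample every list, then evaluate combos
  N <- length(universe)
  mc_counts <- matrix(0L, n_mc, length(combos))
  for (it in seq_len(n_mc)) {
    draw <- lapply(sizes, function(s) sample.int(N, s))
    for (ci in seq_along(combos)) {
      ids <- combos[[ci]]
      inter <- draw[[ids[1]]]
      for (nm in ids[-1]) inter <- intersect(inter, draw[[nm]])
      mc_counts[it, ci] <- length(inter)
    }
  }
  rows <- lapply(seq_along(combos), function(ci) {
    ids <- combos[[ci]]
    inter <- lists[[ids[1]]]
    for (nm in ids[-1]) inter <- intersect(inter, lists[[nm]])
    obs <- length(unique(inter))
    data.frame(combination = paste(ids, collapse = "&"),
               n_lists = length(ids), observed = obs,
               expected = mean(mc_counts[, ci]),
               p = (1 + sum(mc_counts[, ci] >= obs)) / (1 + n_mc))
  })
  do.call(rbind, rows)
}
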