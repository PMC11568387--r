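#' @importFrom stats ppois p.adjust
NULL

## Sliding-window sums of per-bin counts within one chromosome.
## w bins per window, step one bin.
.slide <- function(x, w) {
  if (length(x) < w) return(numeric(0))
  cs <- cumsum(c(0, x))
  cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
}

#' Call enhancer peaks for one replicate
#'
#' A windowed Poisson enrichment test over a fixed bin grid: counts are
#' summed in sliding windows (`window` bp wide, stepping one bin), the
#' expected RNA count in each window is
#' `lambda = (rna_total / dna_total) * (dna + 0.5)`, a one-sided upper-tail
#' Poisson p-value is computed for the observed RNA count,
#' Benjamini-Hochberg corrected across windows, and windows with
#' `q < q_threshold` and observed/expected fold `>= min_fold` are merged
#' (overlapping or book-ended) into peaks.
#'
#' @param windows `GRanges` bin grid (constant bin width, sorted).
#' @param dna,rna numeric vectors of per-bin fragment counts for one
#'   replicate, parallel to `windows`.
#' @param q_threshold BH false-discovery threshold (default 0.05).
#' @param min_fold minimum observed/expected enrichment (default 2).
#' @param window sliding-window width in bp (default 500).
#' @param dna_total,rna_total library sizes; default the per-replicate sums.
#' @return `GRanges` of merged peak regions.
#' @export
callPeaksReplicate <- function(windows, dna, rna, q_threshold = 0.05,
                               min_fold = 2, window = 500L,
                               dna_total = sum(dna), rna_total = sum(rna)) {
  if (length(dna) != length(windows) || length(rna) != length(windows))
    stop("dna/rna counts and window grid have mismatched lengths")
  if (dna_total <= 0)
    stop("all-zero DNA library: cannot form expected counts")
  bw <- width(windows)[1]
  w <- max(1L, as.integer(round(window / bw)))
  chrom <- as.character(seqnames(windows))
  scale <- rna_total / dna_total
  sig <- vector("list", 0)
  # per-chromosome sliding sums, then a single global BH pass
  idx_list <- split(seq_along(windows), factor(chrom, unique(chrom)))
  win_stats <- lapply(idx_list, function(idx) {
    d <- .slide(dna[idx], w)
    r <- .slide(rna[idx], w)
    if (length(d) == 0L) return(NULL)
    lambda <- scale * (d + 0.5)
    p <- ppois(r - 1, lambda, lower.tail = FALSE)
    list(idx0 = idx[seq_along(d)], r = r, lambda = lambda, p = p)
  })
  win_stats <- Filter(Negate(is.null), win_stats)
  if (length(win_stats) == 0L) return(granges(windows)[0])
  pall <- unlist(lapply(win_stats, `[[`, "p"))
  qall <- p.adjust(pall, method = "BH")
  fold <- unlist(lapply(win_stats, function(s) s$r / s$lambda))
  keep <- qall < q_threshold & fold >= min_fold
  if (!any(keep)) return(granges(windows)[0])
  start_bin <- unlist(lapply(win_stats, `[[`, "idx0"))[keep]
  # a significant sliding window spans w consecutive bins
  sig_gr <- GRanges(seqnames(windows)[start_bin],
                    IRanges(start(windows)[start_bin],
                            start(windows)[start_bin] + w * bw - 1L),
                    seqinfo = seqinfo(windows))
  sl <- seqlengths(sig_gr)
  if (!all(is.na(sl)))
    sig_gr <- GenomicRanges::trim(sig_gr)
  reduce(sig_gr)
}

#' Call peaks for every replicate of a StarrExperiment
#'
#' @param se A [StarrExperiment-class] over a bin grid.
#' @param ... passed to [callPeaksReplicate()].
#' @return named list of peak `GRanges`, one per replicate.
#' @export
callPeaksAll <- function(se, ...) {
  dna <- dnaCounts(se); rna <- rnaCounts(se)
  w <- rowRanges(se)
  out <- lapply(colnames(dna), function(r)
    callPeaksReplicate(w, dna[, r], rna[, r], ...))
  names(out) <- colnames(dna)
  out
}

#' Build the cross-replicate consensus enhancer set
#'
#' Concatenates all per-replicate peaks, sorts and merges them (overlapping
#' or book-ended), and keeps each merged region iff it overlaps >= 1 bp of
#' peaks from at least `min_support` distinct replicates and its merged
#' length is at most `max_length` bp. Ids are assigned in coordinate order.
#'
#' @param per_replicate_peaks named list of peak `GRanges` (>= 2 replicates).
#' @param min_support minimum number of supporting replicates (default 2).
#' @param max_length maximum merged region length in bp (default 10000).
#' @return sorted, disjoint `GRanges` with metadata columns `id` and
#'   `support`.
#' @export
buildConsensus <- function(per_replicate_peaks, min_support = 2L,
                           max_length = 10000L) {
  if (length(per_replicate_peaks) == 0L)
    stop("no replicate peak sets supplied")
  if (is.null(names(per_replicate_peaks)))
    names(per_replicate_peaks) <- paste0("rep", seq_along(per_replicate_peaks))
  all_peaks <- unlist(GRangesList(lapply(per_replicate_peaks, granges)))
  if (length(all_peaks) == 0L) return(all_peaks)
  merged <- reduce(sort(all_peaks))
  support <- vapply(per_replicate_peaks, function(p)
    overlapsAny(merged, p), logical(length(merged)))
  if (length(merged) == 1L) support <- matrix(support, nrow = 1L)
  nsup <- rowSums(support)
  keep <- nsup >= min_support & width(merged) <= max_length
  out <- merged[keep]
  mcols(out)$id <- sprintf("cons%05d", seq_along(out))
  mcols(out)$support <- nsup[keep]
  out
}

#' Quantify enhancer activity per replicate
#'
#' For each consensus region and replicate, fragments (bins) overlapping the
#' region by >= 1 bp are summed for the DNA and RNA libraries and activity
#' is the library-size-normalized log2 ratio with a 0.5 pseudocount:
#' `log2(((rna + 0.5) / rna_total) / ((dna + 0.5) / dna_total))`.
#'
#' @param consensus consensus `GRanges` from [buildConsensus()].
#' @param se bin-level [StarrExperiment-class].
#' @return A [StarrExperiment-class] with rows = consensus regions and
#'   assays `dna`, `rna` (summed counts) and `activity`.
#' @export
quantifyActivity <- function(consensus, se) {
  if (length(consensus) == 0L) stop("empty consensus set")
  bins <- rowRanges(se)
  if (!all(overlapsAny(consensus, bins)))
    stop("consensus region(s) outside the count grid")
  hits <- findOverlaps(consensus, bins)
  dna_b <- dnaCounts(se); rna_b <- rnaCounts(se)
  idx <- factor(queryHits(hits), levels = seq_along(consensus))
  sum_by_region <- function(m) {
    out <- apply(m[subjectHits(hits), , drop = FALSE], 2,
                 function(v) tapply(v, idx, sum, default = 0))
    if (length(consensus) == 1L) out <- matrix(out, nrow = 1L,
                                               dimnames = list(NULL, colnames(m)))
    out[is.na(out)] <- 0
    out
  }
  dna <- sum_by_region(dna_b)
  rna <- sum_by_region(rna_b)
  dna_tot <- colSums(dna_b); rna_tot <- colSums(rna_b)
  activity <- log2(sweep(rna + 0.5, 2, rna_tot, "/") /
                     sweep(dna + 0.5, 2, dna_tot, "/"))
  out <- StarrExperiment(consensus, dna = dna, rna = rna,
                         design = colData(se), activity = activity)
  metadata(out)$library_sizes <- list(dna = dna_tot, rna = rna_tot)
  out
}

#' Per-population enhancer presence/absence matrix
#'
#' An enhancer is marked present in population `p` iff it overlaps >= 1 bp
#' of a peak in at least `min_replicates` replicates of `p`.
#'
#' @param consensus consensus `GRanges`.
#' @param per_replicate_peaks named list of peak `GRanges`; names are
#'   replicate ids appearing in `design`.
#' @param design replicate design data.frame (rownames = replicate ids,
#'   column `population`).
#' @param min_replicates supporting replicates required per population
#'   (default 1).
#' @return logical matrix, enhancers x populations, rownames = enhancer ids.
#' @export
populationPresence <- function(consensus, per_replicate_peaks, design,
                               min_replicates = 1L) {
  unknown <- setdiff(names(per_replicate_peaks), rownames(design))
  if (length(unknown))
    stop("replicate id(s) not in design: ", paste(unknown, collapse = ", "))
  pops <- unique(design$population)
  pres <- matrix(FALSE, length(consensus), length(pops),
                 dimnames = list(mcols(consensus)$id, pops))
  for (p in pops) {
    reps <- rownames(design)[design$population == p]
    reps <- intersect(reps, names(per_replicate_peaks))
    if (length(reps) == 0L) next
    hits <- vapply(reps, function(r)
      overlapsAny(consensus, per_replicate_peaks[[r]]),
      logical(length(consensus)))
    if (length(consensus) == 1L) hits <- matrix(hits, nrow = 1L)
    pres[, p] <- rowSums(hits) >= min_replicates
  }
  pres
}
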