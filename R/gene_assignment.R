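## Feature priority used when assigning enhancers to genes. Lower rank wins.
.FEATURE_RANKS <- c(tss_flanks = 1L, tss_upstream = 2L, promoter = 3L,
                    first_intron = 4L, intron = 5L, utr5 = 6L, utr3 = 7L,
                    exon = 8L, upstream = 9L, downstream = 10L,
                    intergenic = 11L)

#' Feature priority table
#'
#' The fixed priority order used to pick the representative feature for an
#' enhancer-gene pair: TSS flanks (within `tss_flank` bp of the TSS, either
#' side), then TSS-upstream (within 200 bp upstream of the TSS), promoter
#' (within 5 kb upstream of the gene), first intron, intron, 5' UTR,
#' 3' UTR, exon, upstream (within 10 kb upstream), downstream (within 10 kb
#' downstream), and intergenic.
#'
#' @return named integer vector of ranks.
#' @export
featurePriority <- function() .FEATURE_RANKS

## Canonical (longest) transcript structure per gene; validates exon bounds.
.geneModels <- function(annotation) {
  m <- mcols(annotation)
  genes <- annotation[m$type == "gene"]
  mrnas <- annotation[m$type == "mRNA"]
  models <- vector("list", length(genes))
  names(models) <- mcols(genes)$ID
  for (i in seq_along(genes)) {
    gid <- mcols(genes)$ID[i]
    tx <- mrnas[!is.na(mcols(mrnas)$Parent) & mcols(mrnas)$Parent == gid]
    tid <- if (length(tx)) mcols(tx)$ID[which.max(width(tx))] else NA
    sub <- annotation[!is.na(mcols(annotation)$Parent) &
                        mcols(annotation)$Parent %in% tid]
    exons <- sub[mcols(sub)$type == "exon"]
    if (length(exons) && (min(start(exons)) < start(genes)[i] ||
                          max(end(exons)) > end(genes)[i]))
      stop("malformed gene model: exon outside gene span for ", gid)
    exons <- sort(exons)
    strand_i <- as.character(strand(genes))[i]
    introns <- GRanges()
    if (length(exons) > 1L) {
      introns <- GRanges(seqnames(genes)[i],
                         IRanges(head(end(exons), -1L) + 1L,
                                 utils::tail(start(exons), -1L) - 1L))
      introns <- introns[width(introns) > 0]
    }
    first_intron <- if (length(introns) == 0L) GRanges() else
      if (strand_i == "-") introns[length(introns)] else introns[1L]
    other_introns <- if (length(introns) <= 1L) GRanges() else
      if (strand_i == "-") introns[-length(introns)] else introns[-1L]
    models[[i]] <- list(
      gene = genes[i], strand = strand_i,
      tss = if (strand_i == "-") end(genes)[i] else start(genes)[i],
      exons = exons,
      utr5 = sub[mcols(sub)$type == "five_prime_UTR"],
      utr3 = sub[mcols(sub)$type == "three_prime_UTR"],
      first_intron = first_intron, other_introns = other_introns
    )
  }
  models
}

.overlapsRange <- function(e, chrom, lo, hi) {
  if (hi < lo) return(FALSE)
  as.character(seqnames(e)) == chrom && start(e) <= hi && end(e) >= lo
}

## Best-priority feature of enhancer e for one gene model, or NULL when the
## gene is farther than max_distance (closest-edge semantics, inclusive).
.pairFeature <- function(e, gm, tss_flank, max_distance) {
  ch <- as.character(seqnames(gm$gene))
  if (as.character(seqnames(e)) != ch) return(NULL)
  gs <- start(gm$gene); ge <- end(gm$gene)
  es <- start(e); ee <- end(e)
  edge_dist <- if (ee < gs) gs - ee else if (es > ge) es - ge else 0L
  if (edge_dist > max_distance) return(NULL)
  minus <- gm$strand == "-"
  feats <- character(0)
  # TSS flanks: within tss_flank bp of the TSS, either side
  if (.overlapsRange(e, ch, gm$tss - tss_flank, gm$tss + tss_flank))
    feats <- c(feats, "tss_flanks")
  # within 200 bp strictly upstream of the TSS
  up200 <- if (minus) c(gm$tss + 1L, gm$tss + 200L) else
    c(gm$tss - 200L, gm$tss - 1L)
  if (.overlapsRange(e, ch, up200[1], up200[2]))
    feats <- c(feats, "tss_upstream")
  up5k <- if (minus) c(ge + 1L, ge + 5000L) else c(gs - 5000L, gs - 1L)
  if (.overlapsRange(e, ch, up5k[1], up5k[2])) feats <- c(feats, "promoter")
  if (length(gm$first_intron) && overlapsAny(e, gm$first_intron))
    feats <- c(feats, "first_intron")
  if (length(gm$other_introns) && overlapsAny(e, gm$other_introns))
    feats <- c(feats, "intron")
  if (length(gm$utr5) && overlapsAny(e, gm$utr5)) feats <- c(feats, "utr5")
  if (length(gm$utr3) && overlapsAny(e, gm$utr3)) feats <- c(feats, "utr3")
  if (length(gm$exons) && overlapsAny(e, gm$exons)) feats <- c(feats, "exon")
  up10k <- if (minus) c(ge + 1L, ge + max_distance) else
    c(gs - max_distance, gs - 1L)
  if (.overlapsRange(e, ch, up10k[1], up10k[2])) feats <- c(feats, "upstream")
  dn10k <- if (minus) c(gs - max_distance, gs - 1L) else
    c(ge + 1L, ge + max_distance)
  if (.overlapsRange(e, ch, dn10k[1], dn10k[2])) feats <- c(feats, "downstream")
  if (length(feats) == 0L) return(NULL)
  best <- feats[which.min(.FEATURE_RANKS[feats])]
  list(feature = best, rank = unname(.FEATURE_RANKS[[best]]))
}

#' Classify enhancer-gene feature relationships
#'
#' One call per (enhancer, gene) pair for every gene within `max_distance`
#' bp (closest edges, inclusive), reporting the highest-priority feature the
#' enhancer overlaps for that gene (see [featurePriority()]). Upstream and
#' downstream are strand-aware. Enhancers with no gene within range get a
#' single `intergenic` call with `gene = NA`.
#'
#' @param enhancers `GRanges` with an `id` metadata column (generated when
#'   absent).
#' @param annotation gene-model `GRanges` as from [simulateGenome()] or
#'   [readGff3Annotation()].
#' @param tss_flank TSS-flank half-width in bp (default 50; the alternative
#'   TSS +/- 200 bp definition is available by setting 200).
#' @param max_distance association cutoff in bp (default 10000).
#' @return data.frame with columns `enhancer`, `gene`, `feature`, `rank`.
#' @export
classifyFeatures <- function(enhancers, annotation, tss_flank = 50L,
                             max_distance = 10000L) {
  if (is.null(mcols(enhancers)$id))
    mcols(enhancers)$id <- sprintf("enh%04d", seq_along(enhancers))
  models <- .geneModels(annotation)
  rows <- list()
  gene_spans <- if (length(models))
    unlist(GRangesList(lapply(models, function(m) granges(m$gene))))
  else GRanges()
  # candidate pairs via an expanded overlap query, then exact edge logic
  for (i in seq_along(enhancers)) {
    e <- enhancers[i]
    found <- FALSE
    if (length(gene_spans)) {
      cand <- which(overlapsAny(gene_spans,
                                suppressWarnings(e + max_distance)))
      for (j in cand) {
        pf <- .pairFeature(e, models[[j]], tss_flank, max_distance)
        if (!is.null(pf)) {
          found <- TRUE
          rows[[length(rows) + 1L]] <- data.frame(
            enhancer = mcols(e)$id, gene = names(models)[j],
            feature = pf$feature, rank = pf$rank)
        }
      }
    }
    if (!found)
      rows[[length(rows) + 1L]] <- data.frame(
        enhancer = mcols(e)$id, gene = NA_character_,
        feature = "intergenic", rank = .FEATURE_RANKS[["intergenic"]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign enhancers to genes
#'
#' Strict mode keeps, per enhancer, all genes tied at the best (lowest)
#' priority rank; lenient mode keeps every gene within the distance cutoff.
#' Intergenic enhancers get no assignment in either mode.
#'
#' @param enhancers,annotation,tss_flank,max_distance as in
#'   [classifyFeatures()].
#' @param mode `"strict"` or `"lenient"`.
#' @param calls optional precomputed [classifyFeatures()] table.
#' @return data.frame with columns `enhancer`, `gene`, `feature`, `rank`,
#'   `mode`.
#' @export
assignGenes <- function(enhancers, annotation, mode = c("strict", "lenient"),
                        tss_flank = 50L, max_distance = 10000L,
                        calls = NULL) {
  mode <- match.arg(mode)
  if (is.null(calls))
    calls <- classifyFeatures(enhancers, annotation, tss_flank, max_distance)
  calls <- calls[!is.na(calls$gene), , drop = FALSE]
  if (mode == "strict" && nrow(calls)) {
    keep <- unlist(lapply(split(seq_len(nrow(calls)), calls$enhancer),
                          function(ix) ix[calls$rank[ix] == min(calls$rank[ix])]))
    calls <- calls[sort(keep), , drop = FALSE]
  }
  if (nrow(calls)) calls$mode <- mode
  rownames(calls) <- NULL
  calls
}

#' Per-gene enhancer specificity summary
#'
#' For each gene with at least one assigned enhancer: the maximum, over its
#' enhancers, of the number of populations where that enhancer is present
#' (`max_specificity`), and the number of assigned enhancers.
#'
#' @param presence logical enhancer x population matrix from
#'   [populationPresence()].
#' @param assignments assignment table with columns `enhancer`, `gene`.
#' @return data.frame with columns `gene`, `max_specificity`,
#'   `n_assigned_enhancers`.
#' @export
specificitySummary <- function(presence, assignments) {
  assignments <- assignments[!is.na(assignments$gene), , drop = FALSE]
  missing <- setdiff(assignments$enhancer, rownames(presence))
  if (length(missing))
    stop("enhancer(s) assigned but missing from presence matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  npop <- rowSums(presence)
  out <- do.call(rbind, lapply(split(assignments$enhancer, assignments$gene),
    function(enh) {
      enh <- unique(enh)
      data.frame(max_specificity = max(npop[enh]),
                 n_assigned_enhancers = length(enh))
    }))
  data.frame(gene = rownames(out), out, row.names = NULL)
}

#' Fraction of multi-enhancer genes by maximum specificity
#'
#' Support table for the association between population specificity and
#' enhancer redundancy: for each `max_specificity` level, the proportion of
#' genes with two or more assigned enhancers.
#'
#' @param summary output of [specificitySummary()].
#' @return data.frame with columns `max_specificity`, `n_genes`,
#'   `frac_multi_enhancer`.
#' @export
multiEnhancerTrend <- function(summary) {
  sp <- split(summary, summary$max_specificity)
  out <- do.call(rbind, lapply(sp, function(d)
    data.frame(max_specificity = d$max_specificity[1], n_genes = nrow(d),
               frac_multi_enhancer = mean(d$n_assigned_enhancers >= 2))))
  rownames(out) <- NULL
  out[order(out$max_specificity), ]
}

#' Genes with class-restricted enhancer coverage
#'
#' Classifies each gene by the populations its assigned-present enhancers
#' cover: `social_only` when every social population has at least one
#' assigned enhancer present and no solitary population does (and
#' symmetrically `solitary_only`); `mixed` when both classes are touched;
#' `none` otherwise. For the class-restricted genes the mechanism is
#' `conserved` when a single enhancer alone is present in all populations of
#' the class, else `compensatory`.
#'
#' @param presence logical enhancer x population matrix.
#' @param assignments assignment table (columns `enhancer`, `gene`).
#' @param design replicate design (columns `population`, `sociality`) or any
#'   data.frame mapping populations to sociality.
#' @return data.frame with columns `gene`, `convergence_class`, `mechanism`,
#'   `n_assigned_enhancers`, `populations_with_enhancer`.
#' @export
convergentTargets <- function(presence, assignments, design) {
  pop2soc <- unique(data.frame(population = as.character(design$population),
                               sociality = as.character(design$sociality)))
  soc_pops <- pop2soc$population[pop2soc$sociality == "social"]
  sol_pops <- pop2soc$population[pop2soc$sociality == "solitary"]
  assignments <- assignments[!is.na(assignments$gene), , drop = FALSE]
  out <- do.call(rbind, lapply(split(assignments$enhancer, assignments$gene),
    function(enh) {
      enh <- unique(intersect(enh, rownames(presence)))
      sub <- presence[enh, , drop = FALSE]
      covered <- colnames(sub)[colSums(sub) > 0]
      got_soc <- intersect(covered, soc_pops)
      got_sol <- intersect(covered, sol_pops)
      cls <- if (length(got_soc) == length(soc_pops) && length(got_sol) == 0L)
        "social_only"
      else if (length(got_sol) == length(sol_pops) && length(got_soc) == 0L)
        "solitary_only"
      else if (length(got_soc) > 0L && length(got_sol) > 0L) "mixed"
      else "none"
      mech <- "n/a"
      if (cls %in% c("social_only", "solitary_only")) {
        class_pops <- if (cls == "social_only") soc_pops else sol_pops
        single <- any(apply(sub[, class_pops, drop = FALSE], 1, all))
        mech <- if (single) "conserved" else "compensatory"
      }
      data.frame(convergence_class = cls, mechanism = mech,
                 n_assigned_enhancers = length(enh),
                 populations_with_enhancer = paste(covered, collapse = ","))
    }))
  data.frame(gene = rownames(out), out, row.names = NULL)
}
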