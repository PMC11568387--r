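#' @importFrom stats rnbinom rpois rnorm runif rbinom rbeta setNames
NULL

## Fixed fan-out of the master seed into per-stage child seeds so each stage
## is independently reproducible. Offsets are part of the contract.
.STAGE_OFFSETS <- c(genome = 11L, enhancers = 23L, activity = 31L,
                    counts = 41L, variants = 53L, cnee = 61L)

childSeed <- function(seed, stage) {
  if (!stage %in% names(.STAGE_OFFSETS))
    stop("unknown generator stage: ", stage)
  off <- .STAGE_OFFSETS[[stage]]
  as.integer((as.numeric(seed) * 1009 + off) %% (2^31 - 1))
}

.rnb <- function(n, mu, alpha) {
  # NB with variance mu + alpha*mu^2; alpha = 0 degenerates to Poisson
  if (alpha <= 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / alpha)
}

.simSeqinfo <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg@n_chromosomes))
  Seqinfo(chroms, rep(cfg@chrom_length, cfg@n_chromosomes))
}

## Non-overlapping placement of n intervals of given widths on [1, len],
## separated by at least `gap`, uniformly via a stick-breaking partition.
.placeNonOverlapping <- function(n, widths, len, gap = 0) {
  if (n == 0L) return(integer(0))
  occupied <- sum(widths) + gap * (n - 1L)
  free <- len - occupied
  if (free < 0) return(NULL)
  cuts <- sort(runif(n, 0, free))
  starts <- floor(cuts) + cumsum(c(0, widths[-n] + gap)) + 1
  as.integer(starts)
}

#' Simulate a genome annotation
#'
#' Places non-overlapping gene models (gene, mRNA, exons, UTRs) on a synthetic
#' genome. Each gene has a strand, a TSS at its 5' end, 1-4 exons, and
#' 5'/3' UTRs on its terminal exons. Deterministic given `cfg@seed`.
#'
#' @param cfg A [SimConfig-class].
#' @return A `GRanges` with `Seqinfo` carrying chromosome lengths and metadata
#'   columns `type` (gene/mRNA/exon/five_prime_UTR/three_prime_UTR), `ID` and
#'   `Parent`, suitable for GFF3 export via [writeGff3Annotation()].
#' @examples
#' ann <- simulateGenome(simConfig(n_genes = 5L, seed = 1L))
#' @export
simulateGenome <- function(cfg) {
  set.seed(childSeed(cfg@seed, "genome"))
  si <- .simSeqinfo(cfg)
  chroms <- seqlevels(si)
  per_chrom <- table(factor(rep(chroms, length.out = cfg@n_genes),
                            levels = chroms))
  recs <- list()
  gi <- 0L
  for (ch in chroms) {
    n <- as.integer(per_chrom[[ch]])
    if (n == 0L) next
    widths <- as.integer(round(runif(n, 2000, 8000)))
    starts <- .placeNonOverlapping(n, widths, cfg@chrom_length, gap = 1000)
    if (is.null(starts))
      stop("chromosome ", ch, " too short (", cfg@chrom_length,
           " bp) to fit ", n, " genes")
    for (k in seq_len(n)) {
      gi <- gi + 1L
      gid <- sprintf("gene%04d", gi)
      tid <- paste0(gid, ".t1")
      gstart <- starts[k]; gend <- starts[k] + widths[k] - 1L
      strand <- sample(c("+", "-"), 1L)
      n_exons <- sample(1:4, 1L)
      # split the gene span into alternating exon/intron blocks
      n_blocks <- 2L * n_exons - 1L
      bl <- as.integer(round(runif(n_blocks, 200, 1500)))
      bl <- pmax(50L, as.integer(round(bl / sum(bl) * widths[k])))
      bl[n_blocks] <- widths[k] - sum(bl[-n_blocks])
      stopifnot(bl[n_blocks] >= 1L)
      bstart <- gstart + cumsum(c(0L, bl[-n_blocks]))
      bend <- bstart + bl - 1L
      exon_idx <- seq(1L, n_blocks, by = 2L)
      ex_s <- bstart[exon_idx]; ex_e <- bend[exon_idx]
      utr5_len <- min(as.integer(round(runif(1, 50, 200))),
                      ex_e[1] - ex_s[1])
      utr3_len <- min(as.integer(round(runif(1, 50, 200))),
                      ex_e[n_exons] - ex_s[n_exons])
      # coordinate-wise left/right UTRs; 5'/3' follows strand
      left_utr <- c(ex_s[1], ex_s[1] + utr5_len)
      right_utr <- c(ex_e[n_exons] - utr3_len, ex_e[n_exons])
      if (strand == "+") {
        u5 <- left_utr; u3 <- right_utr
      } else {
        u5 <- right_utr; u3 <- left_utr
      }
      recs[[length(recs) + 1L]] <- data.frame(
        chrom = ch,
        start = c(gstart, gstart, ex_s, u5[1], u3[1]),
        end = c(gend, gend, ex_e, u5[2], u3[2]),
        strand = strand,
        type = c("gene", "mRNA", rep("exon", n_exons),
                 "five_prime_UTR", "three_prime_UTR"),
        ID = c(gid, tid, paste0(tid, ".e", seq_len(n_exons)),
               paste0(tid, ".u5"), paste0(tid, ".u3")),
        Parent = c(NA, gid, rep(tid, n_exons + 2L))
      )
    }
  }
  if (length(recs) == 0L) {
    gr <- GRanges(seqinfo = si)
    mcols(gr)$type <- character(0)
    mcols(gr)$ID <- character(0)
    mcols(gr)$Parent <- character(0)
    return(gr)
  }
  df <- do.call(rbind, recs)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                type = df$type, ID = df$ID, Parent = df$Parent,
                seqinfo = si)
  gr
}

.genes <- function(annotation) {
  annotation[mcols(annotation)$type == "gene"]
}

#' Per-truth expected linear activity by replicate
#'
#' Deterministic given the config seed: in populations where an enhancer is
#' active, each replicate (flask) gets
#' `base_activity * 2^N(0, rep_activity_sd)`, multiplied by `dae_effect` in
#' the favoured class for sociality-biased enhancers; inactive populations
#' get 1 (no enrichment). Flask-level jitter emulates transfection-to-
#' transfection variation and is the activity signal that causal SNP
#' frequencies track.
#'
#' @param truths enhancer truth `GRanges` from [simulateEnhancers()].
#' @param cfg A [SimConfig-class].
#' @param design replicate design (default [simDesign()]).
#' @return numeric matrix, truths x replicates.
#' @export
truthActivityByReplicate <- function(truths, cfg, design = simDesign(cfg)) {
  set.seed(childSeed(cfg@seed, "activity"))
  reps <- rownames(design)
  act <- matrix(1, length(truths), length(reps),
                dimnames = list(mcols(truths)$id, reps))
  if (length(truths) == 0L) return(act)
  jit <- matrix(rnorm(length(truths) * length(reps), 0, cfg@rep_activity_sd),
                length(truths), length(reps))
  for (i in seq_along(truths)) {
    active <- mcols(truths)$active_in[[i]]
    bias <- mcols(truths)$sociality_bias[i]
    for (r in seq_along(reps)) {
      pop <- design$population[r]
      if (pop %in% active) {
        a <- mcols(truths)$base_activity[i] * 2^jit[i, r]
        if (bias != "none" && design$sociality[r] == bias)
          a <- a * cfg@dae_effect
        act[i, r] <- max(1, a)
      }
    }
  }
  act
}

#' Simulate enhancer truth regions
#'
#' Plants non-overlapping enhancer regions (60% within gene bodies, 40%
#' intergenic by default), assigns each an activity class (`frac_conserved`
#' active in all populations, `frac_population_specific` in exactly one,
#' the rest in a random intermediate subset), a linear fold-enrichment in
#' `activity_range`, and a sociality bias for `frac_dae` of enhancers
#' (biased enhancers are made active in all populations so the shift is
#' measurable in both classes). `n_convergent_genes` genes additionally
#' receive class-restricted enhancer clusters: a single enhancer active in
#' all populations of one class ("conserved" mechanism) or one
#' population-specific enhancer per population of the class ("compensatory").
#'
#' @param cfg A [SimConfig-class].
#' @param annotation output of [simulateGenome()].
#' @param frac_genic fraction of enhancers placed inside gene spans.
#' @return `GRanges` with metadata columns `id`, `base_activity`,
#'   `active_in` (CharacterList), `sociality_bias`, `target_gene`,
#'   `planted_mechanism`, and `expected_class_diff` (expected social minus
#'   solitary mean log2 activity; non-zero marks enhancers that are
#'   class-differential in expectation, whether through a planted bias or a
#'   class-asymmetric activity pattern).
#' @export
simulateEnhancers <- function(cfg, annotation, frac_genic = 0.6) {
  set.seed(childSeed(cfg@seed, "enhancers"))
  si <- .simSeqinfo(cfg)
  pops <- names(cfg@populations)
  genes <- .genes(annotation)
  min_gap <- 2000L
  sl <- seqlengths(si)
  occ_ch <- character(0); occ_s <- integer(0); occ_e <- integer(0)

  is_free <- function(ch, s, e) {
    !any(occ_ch == ch & occ_s <= e + min_gap & occ_e >= s - min_gap)
  }
  claim <- function(ch, s, e) {
    occ_ch <<- c(occ_ch, ch); occ_s <<- c(occ_s, s); occ_e <<- c(occ_e, e)
    GRanges(ch, IRanges(s, e), seqinfo = si)
  }
  place_one <- function(target = NULL, width) {
    for (try in 1:200) {
      if (!is.null(target)) {
        ch <- as.character(seqnames(target))
        lo <- max(1L, start(target) - 9000L)
        hi <- min(sl[[ch]] - width, end(target) + 9000L - width)
        if (hi <= lo) next
        s <- as.integer(floor(runif(1, lo, hi)))
      } else {
        ch <- sample(seqlevels(si), 1L, prob = sl / sum(sl))
        s <- as.integer(floor(runif(1, 1, sl[[ch]] - width)))
      }
      e <- s + width - 1L
      if (is_free(ch, s, e)) return(claim(ch, s, e))
    }
    NULL
  }

  n <- cfg@n_enhancers
  widths <- as.integer(round(runif(n, 300, 1500)))
  genic <- runif(n) < frac_genic & length(genes) > 0
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- if (genic[i]) {
      # inside the span of a random gene when it fits
      g <- genes[sample(length(genes), 1L)]
      if (width(g) > widths[i] + 2L) {
        s <- as.integer(floor(runif(1, start(g), end(g) - widths[i])))
        e <- s + widths[i] - 1L
        if (is_free(as.character(seqnames(g)), s, e))
          claim(as.character(seqnames(g)), s, e)
        else place_one(NULL, widths[i])
      } else place_one(NULL, widths[i])
    } else place_one(NULL, widths[i])
    if (is.null(cand))
      stop("could not place enhancer ", i, "; genome too crowded")
    out[[i]] <- cand
  }

  u <- runif(n)
  n_pop <- length(pops)
  active_in <- lapply(seq_len(n), function(i) {
    if (u[i] < cfg@frac_conserved) pops
    else if (u[i] < cfg@frac_conserved + cfg@frac_population_specific)
      sample(pops, 1L)
    else sample(pops, sample(seq(2L, max(2L, n_pop - 1L)), 1L))
  })
  bias <- rep("none", n)
  is_dae <- runif(n) < cfg@frac_dae
  bias[is_dae] <- sample(c("social", "solitary"), sum(is_dae), replace = TRUE)
  active_in[is_dae] <- list(pops)  # biased enhancers measurable in both classes
  base_activity <- 2^runif(n, log2(cfg@activity_range[1]),
                           log2(cfg@activity_range[2]))
  mech <- rep(NA_character_, n)

  truths <- unlist(GRangesList(out))
  # convergent-gene clusters appended on top of the base set
  if (cfg@n_convergent_genes > 0L && length(genes) > 0L) {
    cls <- rep(c("social", "solitary"), length.out = cfg@n_convergent_genes)
    conserved <- rep(c(TRUE, FALSE), length.out = cfg@n_convergent_genes)
    gsel <- sample(length(genes), min(cfg@n_convergent_genes, length(genes)))
    for (k in seq_along(gsel)) {
      g <- genes[gsel[k]]
      class_pops <- pops[cfg@populations == cls[k]]
      if (conserved[k]) {
        w <- as.integer(round(runif(1, 300, 1200)))
        cand <- place_one(g, w)
        if (is.null(cand)) next
        truths <- c(truths, cand)
        active_in <- c(active_in, list(class_pops))
        bias <- c(bias, "none")
        base_activity <- c(base_activity,
                           2^runif(1, log2(cfg@activity_range[1]),
                                   log2(cfg@activity_range[2])))
        mech <- c(mech, paste0(cls[k], ":conserved:", mcols(g)$ID))
      } else {
        for (p in class_pops) {
          w <- as.integer(round(runif(1, 300, 1200)))
          cand <- place_one(g, w)
          if (is.null(cand)) next
          truths <- c(truths, cand)
          active_in <- c(active_in, list(p))
          bias <- c(bias, "none")
          base_activity <- c(base_activity,
                             2^runif(1, log2(cfg@activity_range[1]),
                                     log2(cfg@activity_range[2])))
          mech <- c(mech, paste0(cls[k], ":compensatory:", mcols(g)$ID))
        }
      }
    }
  }

  o <- order(as.integer(seqnames(truths)), start(truths))
  truths <- truths[o]
  mcols(truths)$id <- sprintf("enh%04d", seq_along(truths))
  mcols(truths)$base_activity <- base_activity[o]
  mcols(truths)$active_in <- IRanges::CharacterList(active_in[o])
  mcols(truths)$sociality_bias <- bias[o]
  mcols(truths)$planted_mechanism <- mech[o]
  # nearest gene within 10 kb, if any
  tg <- rep(NA_character_, length(truths))
  if (length(genes)) {
    hits <- GenomicRanges::distanceToNearest(truths, genes)
    ok <- mcols(hits)$distance <= 10000
    tg[queryHits(hits)[ok]] <- mcols(genes)$ID[subjectHits(hits)[ok]]
  }
  mcols(truths)$target_gene <- tg
  # expected social-minus-solitary mean log2 activity, from the truth
  # metadata alone: base activity in active populations (times dae_effect
  # where the bias matches the class), 1 elsewhere
  cls <- cfg@populations
  mcols(truths)$expected_class_diff <- vapply(seq_along(truths), function(i) {
    ai <- mcols(truths)$active_in[[i]]
    b <- mcols(truths)$sociality_bias[i]
    e <- vapply(names(cls), function(p) {
      if (!p %in% ai) 1
      else mcols(truths)$base_activity[i] *
        (if (b != "none" && cls[[p]] == b) cfg@dae_effect else 1)
    }, numeric(1))
    mean(log2(e[cls == "social"])) - mean(log2(e[cls == "solitary"]))
  }, numeric(1))
  truths
}

#' Build the default replicate design from a config
#'
#' One row per population x replicate; batch labels cross populations
#' (batch b1 holds replicate 1 of every population, etc.), mirroring a
#' flowcell-per-round sequencing layout, so batch is not confounded with
#' sociality.
#'
#' @param cfg A [SimConfig-class].
#' @return data.frame with rownames `<population>_r<k>` and columns
#'   `population`, `sociality`, `batch`.
#' @export
simDesign <- function(cfg) {
  pops <- names(cfg@populations)
  reps <- seq_len(cfg@replicates_per_population)
  df <- expand.grid(rep = reps, population = pops, stringsAsFactors = FALSE)
  df <- data.frame(
    population = df$population,
    sociality = unname(cfg@populations[df$population]),
    batch = paste0("b", df$rep),
    row.names = paste0(df$population, "_r", df$rep)
  )
  df
}

#' Simulate paired DNA/RNA fragment counts
#'
#' Negative-binomial fragment counts over a fixed bin grid. DNA means are
#' uniform at `depth / n_bins`; RNA means are DNA means multiplied by each
#' enhancer's per-replicate activity ([truthActivityByReplicate()]) inside
#' active truth regions and 1 elsewhere. Deterministic given the config seed.
#'
#' @param truths output of [simulateEnhancers()].
#' @param cfg A [SimConfig-class].
#' @param design replicate design (default [simDesign()]).
#' @return A [StarrExperiment-class] over the bin grid; the per-truth,
#'   per-replicate expected activity matrix is stored in
#'   `metadata(.)$activity_by_replicate`.
#' @export
simulateStarrCounts <- function(truths, cfg, design = simDesign(cfg)) {
  if (is.null(design) || nrow(design) == 0L)
    stop("empty replicate design")
  si <- .simSeqinfo(cfg)
  bins <- unlist(tileGenome(seqlengths(si), tilewidth = cfg@bin_size))
  act <- truthActivityByReplicate(truths, cfg, design)
  set.seed(childSeed(cfg@seed, "counts"))
  mu <- cfg@depth / length(bins)
  nrep <- nrow(design)
  dna <- matrix(0L, length(bins), nrep,
                dimnames = list(NULL, rownames(design)))
  rna <- dna
  hits <- if (length(truths)) findOverlaps(bins, truths) else NULL
  for (r in seq_len(nrep)) {
    mult <- rep(1, length(bins))
    if (!is.null(hits) && length(hits))
      mult[queryHits(hits)] <- pmax(mult[queryHits(hits)],
                                    act[subjectHits(hits), r])
    dna[, r] <- .rnb(length(bins), mu, cfg@nb_dispersion)
    rna[, r] <- .rnb(length(bins), mu * mult, cfg@nb_dispersion)
  }
  se <- StarrExperiment(bins, dna = dna, rna = rna, design = design)
  metadata(se)$activity_by_replicate <- act
  metadata(se)$bin_size <- cfg@bin_size
  se
}

.BASES <- c("A", "C", "G", "T")

#' Simulate variants, genotypes and outgroup alleles
#'
#' Places `n_snps_per_enhancer` biallelic SNPs inside each enhancer truth
#' region. Ancestral alt-allele frequencies are drawn in \[0.05, 0.95\];
#' per-population frequencies drift around them (Beta model). For causal
#' SNPs (`frac_causal_snps`), the per-replicate pooled alternate-allele
#' frequency follows `a + b * log2(activity)` of the containing enhancer in
#' that replicate (flask), plus noise, with `(a, b)` recorded. Diploid
#' genotypes are drawn per population at Hardy-Weinberg; group allele counts
#' are their sums. The outgroup allele equals the simulated ancestral allele
#' except with probability `outgroup_misid`. A `frac_selected` fraction of
#' SNPs receives an additional derived-allele frequency shift in the social
#' group (planted selection signal).
#'
#' @inheritParams simulateStarrCounts
#' @return list with `snps` (per-SNP table incl. per-replicate `freq_*` and
#'   per-population `pop_*` frequency columns and truth fields `causal`,
#'   `a`, `b`, `ancestral`, `selected`), `genotypes` (per-group allele
#'   counts + per-individual 0/1/2 matrix as attribute `"matrix"`), and
#'   `outgroup` (CHROM, POS, allele).
#' @export
simulateVariants <- function(truths, cfg, design = simDesign(cfg)) {
  if (length(truths) == 0L && cfg@frac_causal_snps > 0)
    stop("frac_causal_snps > 0 but there are no enhancers to host SNPs")
  act <- truthActivityByReplicate(truths, cfg, design)
  set.seed(childSeed(cfg@seed, "variants"))
  pops <- names(cfg@populations)
  social_pops <- pops[cfg@populations == "social"]
  k <- (1 - cfg@drift) / cfg@drift
  rows <- list()
  geno_counts <- list()
  geno_mat <- list()
  og <- list()
  si <- 0L
  for (i in seq_along(truths)) {
    npos <- min(cfg@n_snps_per_enhancer, width(truths)[i])
    if (npos == 0L) next
    pos <- sort(sample(start(truths)[i]:end(truths)[i], npos))
    for (p in pos) {
      si <- si + 1L
      ra <- sample(.BASES, 2L)
      ref <- ra[1]; alt <- ra[2]
      ancestral <- sample(c(ref, alt), 1L)
      p0 <- if (ancestral == ref) runif(1, 0.05, 0.5) else runif(1, 0.5, 0.95)
      p_pop <- setNames(rbeta(length(pops), p0 * k, (1 - p0) * k), pops)
      selected <- runif(1) < cfg@frac_selected
      if (selected) {
        dshift <- if (ancestral == ref) cfg@selection_shift else -cfg@selection_shift
        p_pop[social_pops] <- pmin(1, pmax(0, p_pop[social_pops] + dshift))
      }
      causal <- runif(1) < cfg@frac_causal_snps
      b <- if (causal) sample(c(-1, 1), 1L) * cfg@assoc_slope else 0
      a <- p0
      fr <- numeric(nrow(design))
      for (r in seq_len(nrow(design))) {
        pp <- design$population[r]
        base <- if (causal) a + b * log2(act[i, r]) else p_pop[[pp]]
        fr[r] <- min(1, max(0, base + rnorm(1, 0, cfg@freq_noise)))
      }
      gm <- vapply(pops, function(pp)
        rbinom(cfg@n_individuals, 2L, min(1, max(0, p_pop[[pp]]))),
        integer(cfg@n_individuals))
      out_allele <- if (runif(1) > cfg@outgroup_misid) ancestral else
        setdiff(c(ref, alt), ancestral)
      out_p_alt <- if (out_allele == alt) 0.98 else 0.02
      gout <- rbinom(cfg@n_individuals, 2L, out_p_alt)
      id <- sprintf("snp%05d", si)
      rows[[si]] <- data.frame(
        chrom = as.character(seqnames(truths))[i], pos = p, id = id,
        ref = ref, alt = alt, qual = round(runif(1, 20, 100), 1),
        enhancer = mcols(truths)$id[i], causal = causal, a = a, b = b,
        ancestral = ancestral, selected = selected,
        t(setNames(p_pop, paste0("pop_", pops))),
        t(setNames(fr, paste0("freq_", rownames(design)))),
        check.names = FALSE
      )
      geno_counts[[si]] <- data.frame(
        id = id,
        alt_social = sum(gm[, social_pops]),
        n_social = 2L * cfg@n_individuals * length(social_pops),
        alt_solitary = sum(gm[, setdiff(pops, social_pops)]),
        n_solitary = 2L * cfg@n_individuals *
          (length(pops) - length(social_pops)),
        alt_outgroup = sum(gout), n_outgroup = 2L * cfg@n_individuals
      )
      geno_mat[[si]] <- c(as.vector(gm), gout)
      og[[si]] <- data.frame(chrom = as.character(seqnames(truths))[i],
                             pos = p, allele = out_allele)
    }
  }
  if (si == 0L) {
    return(list(snps = data.frame(), genotypes = data.frame(),
                outgroup = data.frame()))
  }
  snps <- do.call(rbind, rows)
  rownames(snps) <- NULL
  genotypes <- do.call(rbind, geno_counts)
  gm <- do.call(rbind, geno_mat)
  colnames(gm) <- c(paste(rep(pops, each = cfg@n_individuals),
                          seq_len(cfg@n_individuals), sep = "."),
                    paste("outgroup", seq_len(cfg@n_individuals), sep = "."))
  attr(genotypes, "matrix") <- gm
  list(snps = snps, genotypes = genotypes, outgroup = do.call(rbind, og))
}

#' Simulate a conserved-element region set
#'
#' A synthetic stand-in for a cross-species conserved non-exonic element
#' (CNEE) catalogue: a configurable fraction of elements are jittered copies
#' of enhancer truth regions (true positional association), the rest are
#' placed uniformly at random.
#'
#' @param truths enhancer truth regions.
#' @param cfg A [SimConfig-class].
#' @param n number of elements.
#' @param frac_linked fraction overlapping truth regions by construction.
#' @return `GRanges` of elements.
#' @export
simulateCnees <- function(truths, cfg, n = 300L, frac_linked = 0.5) {
  set.seed(childSeed(cfg@seed, "cnee"))
  si <- .simSeqinfo(cfg)
  n_link <- if (length(truths)) round(n * frac_linked) else 0L
  out <- GRanges(seqinfo = si)
  if (n_link > 0L) {
    idx <- sample(length(truths), n_link, replace = TRUE)
    w <- as.integer(round(runif(n_link, 100, 400)))
    centers <- as.integer((start(truths)[idx] + end(truths)[idx]) / 2 +
                            round(rnorm(n_link, 0, 200)))
    s <- pmax(1L, centers - w %/% 2L)
    e <- pmin(rep(seqlengths(si)[as.character(seqnames(truths)[idx])],
                  length.out = n_link), s + w)
    out <- c(out, GRanges(seqnames(truths)[idx], IRanges(s, e), seqinfo = si))
  }
  n_rand <- n - n_link
  if (n_rand > 0L) {
    ch <- sample(seqlevels(si), n_rand, replace = TRUE,
                 prob = seqlengths(si) / sum(seqlengths(si)))
    w <- as.integer(round(runif(n_rand, 100, 400)))
    s <- as.integer(floor(runif(n_rand, 1, seqlengths(si)[ch] - w)))
    out <- c(out, GRanges(ch, IRanges(s, width = w), seqinfo = si))
  }
  out <- sort(out)
  mcols(out)$id <- sprintf("cnee%04d", seq_along(out))
  out
}

#' Simulate a full study
#'
#' Runs every generator stage with a single config: genome annotation,
#' enhancer truths, replicate design, paired DNA/RNA counts, variants with
#' genotypes and outgroup alleles, and a conserved-element set.
#'
#' @param cfg A [SimConfig-class].
#' @return list with elements `annotation`, `truths`, `design`, `counts`
#'   (a [StarrExperiment-class]), `variants`, `cnees`, `config`.
#' @examples
#' study <- simulateStudy(simConfig(n_genes = 10L, n_enhancers = 12L,
#'                                  chrom_length = 2e5, depth = 1e5))
#' @export
simulateStudy <- function(cfg) {
  annotation <- simulateGenome(cfg)
  truths <- simulateEnhancers(cfg, annotation)
  design <- simDesign(cfg)
  counts <- simulateStarrCounts(truths, cfg, design)
  variants <- simulateVariants(truths, cfg, design)
  cnees <- simulateCnees(truths, cfg)
  list(annotation = annotation, truths = truths, design = design,
       counts = counts, variants = variants, cnees = cnees, config = cfg)
}
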