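#' @importFrom stats lm pf binom.test chisq.test kruskal.test pchisq
NULL

#' Filter variant records
#'
#' Applies the variant-quality contract in fixed order: biallelic, then
#' QUAL, then missingness, then minor allele frequency. MAF is computed
#' from the mean of non-missing per-replicate alternate-allele frequencies;
#' the `maf_min` bound is inclusive.
#'
#' @param snps data.frame with columns `ref`, `alt`, `qual` and
#'   per-replicate `freq_*` columns (`NA` = missing).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param max_missing maximum fraction of missing replicate frequencies
#'   (default 0.25).
#' @param qual_min minimum phred-scaled site quality (default 30).
#' @return the surviving rows of `snps`.
#' @export
filterVariants <- function(snps, maf_min = 0.05, max_missing = 0.25,
                           qual_min = 30) {
  if (nrow(snps) == 0L) return(snps)
  fcols <- grep("^freq_", colnames(snps), value = TRUE)
  biallelic <- nchar(snps$ref) == 1L & nchar(snps$alt) == 1L &
    !grepl(",", snps$alt, fixed = TRUE)
  snps <- snps[biallelic, , drop = FALSE]
  snps <- snps[!is.na(snps$qual) & snps$qual >= qual_min, , drop = FALSE]
  fr <- as.matrix(snps[, fcols, drop = FALSE])
  miss <- rowMeans(is.na(fr))
  snps <- snps[miss <= max_missing, , drop = FALSE]
  fr <- as.matrix(snps[, fcols, drop = FALSE])
  p <- rowMeans(fr, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  snps[maf >= maf_min, , drop = FALSE]
}

#' Associate pooled allele frequencies with enhancer activity
#'
#' Each SNP is tested only against the enhancer containing it: ordinary
#' least squares of activity on alternate-allele frequency, two-sided
#' p-value on the slope, Benjamini-Hochberg correction applied once across
#' all tested pairs. When a replicate design is available (passed
#' explicitly, or taken from the `StarrExperiment`), replicate observations
#' are first averaged within populations, so the regression units are
#' populations; flasks from one population share the underlying pool and
#' treating them as independent would overstate the degrees of freedom.
#' SNPs with constant frequency or fewer than `min_obs` complete
#' observations are skipped; SNPs outside every enhancer are skipped with a
#' warning.
#'
#' @param snps data.frame with columns `chrom`, `pos`, `id` and `freq_*`
#'   columns named after replicates.
#' @param activity enhancer x replicate activity matrix (rownames =
#'   enhancer ids), or a [StarrExperiment-class] with an `activity` assay.
#' @param enhancers consensus `GRanges` with an `id` column (used to locate
#'   each SNP's containing enhancer).
#' @param design optional data.frame mapping replicate ids (row names) to a
#'   `population` column; defaults to the design stored in `activity` when
#'   that is a [StarrExperiment-class]. When `NULL`, replicates are treated
#'   as independent observations.
#' @param min_obs minimum complete observations per regression (default 4).
#' @return data.frame with columns `snp`, `enhancer`, `slope`, `intercept`,
#'   `r_squared`, `p_value`, `q_value`.
#' @export
associateActivity <- function(snps, activity, enhancers, design = NULL,
                              min_obs = 4L) {
  if (is(activity, "StarrExperiment")) {
    if (is.null(design)) design <- replicateDesign(activity)
    act <- activityMatrix(activity)
    rownames(act) <- mcols(rowRanges(activity))$id
  } else act <- activity
  fcols <- grep("^freq_", colnames(snps), value = TRUE)
  reps <- sub("^freq_", "", fcols)
  common <- intersect(reps, colnames(act))
  if (!is.null(design)) {
    common <- intersect(common, rownames(design))
    grp <- as.character(design[common, "population"])
  } else grp <- common
  if (length(unique(grp)) < min_obs)
    stop("fewer than ", min_obs, " observation units shared between ",
         "frequencies and activity")
  snp_gr <- GRanges(snps$chrom, IRanges(snps$pos, snps$pos))
  hits <- findOverlaps(snp_gr, enhancers, select = "first")
  outside <- is.na(hits)
  if (any(outside))
    warning(sum(outside), " SNP(s) outside every enhancer; skipped")
  rows <- list()
  for (i in which(!outside)) {
    eid <- mcols(enhancers)$id[hits[i]]
    if (!eid %in% rownames(act)) next
    f <- as.numeric(snps[i, paste0("freq_", common)])
    a <- as.numeric(act[eid, common])
    f <- as.numeric(tapply(f, grp, mean, na.rm = TRUE))
    a <- as.numeric(tapply(a, grp, mean, na.rm = TRUE))
    ok <- is.finite(f) & is.finite(a)
    if (sum(ok) < min_obs) next
    f <- f[ok]; a <- a[ok]
    if (max(f) - min(f) < .Machine$double.eps^0.5) next  # no variation
    n <- length(f)
    sxx <- sum((f - mean(f))^2)
    sxy <- sum((f - mean(f)) * (a - mean(a)))
    slope <- sxy / sxx
    intercept <- mean(a) - slope * mean(f)
    resid <- a - intercept - slope * f
    sst <- sum((a - mean(a))^2)
    r2 <- if (sst > 0) 1 - sum(resid^2) / sst else NA_real_
    df <- n - 2L
    s2 <- sum(resid^2) / df
    tstat <- if (s2 > 0) slope / sqrt(s2 / sxx) else sign(slope) * Inf
    p <- 2 * pt(-abs(tstat), df)
    rows[[length(rows) + 1L]] <- data.frame(
      snp = snps$id[i], enhancer = eid, slope = slope,
      intercept = intercept, r_squared = r2, p_value = p)
  }
  if (length(rows) == 0L)
    return(data.frame(snp = character(), enhancer = character(),
                      slope = numeric(), intercept = numeric(),
                      r_squared = numeric(), p_value = numeric(),
                      q_value = numeric()))
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Direction of effect of the derived allele
#'
#' Re-expresses each association slope with respect to the derived allele:
#' when the derived allele is the reference allele the slope sign flips.
#' `unresolved` when polarization is unresolved or the slope is exactly 0.
#'
#' @param assoc association table from [associateActivity()].
#' @param snps polarized SNP table ([polarize()]) with columns `id`,
#'   `derived_allele`.
#' @return `assoc` with an added `derived_direction` column
#'   (`increase`/`decrease`/`unresolved`).
#' @export
directionOfEffect <- function(assoc, snps) {
  der <- snps$derived_allele[match(assoc$snp, snps$id)]
  dir <- rep("unresolved", nrow(assoc))
  eff <- ifelse(der == "alt", assoc$slope,
                ifelse(der == "ref", -assoc$slope, NA_real_))
  dir[!is.na(eff) & eff > 0] <- "increase"
  dir[!is.na(eff) & eff < 0] <- "decrease"
  assoc$derived_direction <- dir
  assoc
}

#' Pearson chi-square statistic without continuity correction
#'
#' @param tab contingency table (matrix).
#' @return list with `statistic`, `df`, `p_value`.
#' @examples
#' pearsonChisq(rbind(c(8, 13), c(28, 24)))$statistic  # 1.485
#' @export
pearsonChisq <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has an empty row or column margin")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Battery of direction-of-effect contingency and rank tests
#'
#' Given per-site enhancer class (social-biased DAE, solitary-biased DAE,
#' non-DAE), derived-allele direction of effect and group PBS values, runs:
#' (i) a Pearson chi-square (no continuity correction) on the class x
#' direction table; (ii) per class, a two-sided exact binomial test of the
#' increase fraction against 0.5; (iii) pairwise two-sample proportion
#' tests between classes (chi-square form, no correction); and (iv) within
#' each class, Kruskal-Wallis tests of PBS by direction, separately for the
#' social and solitary PBS when supplied.
#'
#' @param sites data.frame with columns `class`, `derived_direction`
#'   (`increase`/`decrease`; other values dropped) and optionally
#'   `pbs_social`, `pbs_solitary`.
#' @return list with elements `table`, `chisq`, `binomial` (per class),
#'   `proportion_pairs`, `kruskal` (per class and PBS group).
#' @export
contingencyTests <- function(sites) {
  keep <- sites$derived_direction %in% c("increase", "decrease")
  sites <- sites[keep, , drop = FALSE]
  if (nrow(sites) == 0L) stop("no sites with a resolved direction of effect")
  tab <- table(factor(sites$class),
               factor(sites$derived_direction,
                      levels = c("increase", "decrease")))
  out <- list(table = tab)
  out$chisq <- if (nrow(tab) >= 2L) pearsonChisq(tab[rowSums(tab) > 0, ,
                                                     drop = FALSE]) else NULL
  out$binomial <- lapply(rownames(tab), function(cl) {
    n <- sum(tab[cl, ])
    if (n == 0L) return(NULL)
    bt <- binom.test(tab[cl, "increase"], n, p = 0.5)
    list(class = cl, n = n, increase = unname(tab[cl, "increase"]),
         frac_increase = unname(tab[cl, "increase"]) / n, p_value = bt$p.value)
  })
  names(out$binomial) <- rownames(tab)
  cls <- rownames(tab)[rowSums(tab) > 0]
  pairs <- if (length(cls) >= 2L) combn(cls, 2L, simplify = FALSE) else list()
  out$proportion_pairs <- lapply(pairs, function(pr) {
    t2 <- tab[pr, , drop = FALSE]
    ps <- pearsonChisq(t2)
    list(classes = pr, statistic = ps$statistic, p_value = ps$p_value)
  })
  kw <- list()
  for (col in intersect(c("pbs_social", "pbs_solitary"), colnames(sites))) {
    for (cl in rownames(tab)) {
      d <- sites[sites$class == cl & !is.na(sites[[col]]), , drop = FALSE]
      if (length(unique(d$derived_direction)) < 2L) next
      k <- kruskal.test(d[[col]], factor(d$derived_direction))
      kw[[paste(col, cl, sep = ":")]] <-
        list(pbs = col, class = cl, statistic = unname(k$statistic),
             p_value = k$p.value)
    }
  }
  out$kruskal <- kw
  out
}
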