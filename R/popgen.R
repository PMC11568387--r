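#' @importFrom stats quantile
NULL

#' Hudson's Fst estimator for one biallelic site
#'
#' `Fst = [ (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1) ] /
#'        [ p1(1-p2) + p2(1-p1) ]`
#' with allele frequencies `p1`, `p2` and sampled allele counts `n1`, `n2`.
#' Returns `NA` when the denominator is zero (both populations monomorphic
#' for the same allele). Vectorized over sites.
#'
#' @param p1,p2 allele frequencies in \[0, 1\].
#' @param n1,n2 total sampled allele counts (>= 2).
#' @return numeric Fst (can be negative; see [branchLength()] for clamping).
#' @examples
#' hudsonFst(1, 0, 100, 100)  # 1: fixed difference
#' @export
hudsonFst <- function(p1, n1, p2, n2) {
  if (any(c(p1, p2) < 0 | c(p1, p2) > 1, na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]")
  if (any(c(n1, n2) < 2, na.rm = TRUE))
    stop("allele counts must be >= 2")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Branch length from Fst
#'
#' `T = -ln(1 - Fst)` after clamping negative estimates to 0. `Fst = 1`
#' (a fixed difference) maps to the configurable cap `-ln(cap)`.
#'
#' @param fst numeric Fst values (finite; `NA` propagates).
#' @param cap residual probability used at `Fst >= 1` (default 1e-6, giving
#'   `T ~ 13.8`).
#' @return non-negative branch lengths.
#' @examples
#' branchLength(0.5)  # log(2)
#' @export
branchLength <- function(fst, cap = 1e-6) {
  if (any(!is.finite(fst) & !is.na(fst)))
    stop("non-finite Fst input")
  f <- pmax(fst, 0)
  f <- pmin(f, 1 - cap)
  -log(1 - f)
}

#' Population Branch Statistic
#'
#' The focal-population branch length on the three-population tree:
#' `PBS = (T_fs + T_fo - T_so) / 2`, where `T_xy` are pairwise
#' `-ln(1 - Fst)` branch lengths for focal/sister (`fs`), focal/outgroup
#' (`fo`) and sister/outgroup (`so`). May be negative; not clamped.
#'
#' @param t_fs,t_fo,t_so branch lengths (>= 0).
#' @return numeric PBS.
#' @examples
#' pbs(0.2, 0.3, 0.1)  # 0.2
#' @export
pbs <- function(t_fs, t_fo, t_so) (t_fs + t_fo - t_so) / 2

#' Polarize SNPs against an outgroup
#'
#' Sets the derived allele: the ancestral allele is the outgroup major
#' allele when the outgroup is at least `major_threshold` one allele (when
#' only a single outgroup allele is recorded it is taken as fixed); the
#' derived allele is the other one. Sites whose outgroup allele matches
#' neither `ref` nor `alt`, is missing, or is not sufficiently major are
#' flagged `unresolved`.
#'
#' @param snps data.frame with columns `ref`, `alt` and either `outgroup`
#'   (allele) or `outgroup_freq` columns; see Details.
#' @param outgroup character vector of outgroup alleles (recycled), or
#'   `NULL` to use `snps$outgroup`.
#' @param outgroup_major_freq optional numeric vector: frequency of the
#'   recorded outgroup allele among outgroup chromosomes (default 1).
#' @param major_threshold minimum outgroup major-allele frequency to call
#'   the ancestral state (default 0.9).
#' @return `snps` with columns `ancestral_call` and `derived_allele`
#'   (values `"ref"`, `"alt"` or `"unresolved"`).
#' @export
polarize <- function(snps, outgroup = NULL, outgroup_major_freq = NULL,
                     major_threshold = 0.9) {
  og <- if (is.null(outgroup)) snps$outgroup else outgroup
  if (is.null(og)) stop("no outgroup alleles supplied")
  og <- rep_len(as.character(og), nrow(snps))
  fr <- if (is.null(outgroup_major_freq)) rep(1, nrow(snps)) else
    rep_len(outgroup_major_freq, nrow(snps))
  derived <- rep("unresolved", nrow(snps))
  resolved <- !is.na(og) & fr >= major_threshold
  is_ref <- resolved & og == snps$ref
  is_alt <- resolved & og == snps$alt
  derived[is_ref] <- "alt"   # outgroup carries ref => ref ancestral
  derived[is_alt] <- "ref"
  snps$ancestral_call <- ifelse(derived == "alt", "ref",
                                ifelse(derived == "ref", "alt", "unresolved"))
  snps$derived_allele <- derived
  snps
}

#' Flag distribution outliers
#'
#' Values strictly above the given quantile (type-7 linear interpolation)
#' are flagged.
#'
#' @param values numeric vector (>= 20 non-missing values).
#' @param prob quantile (default 0.95).
#' @return logical vector parallel to `values` (`NA` stays `NA`).
#' @export
flagOutliers <- function(values, prob = 0.95) {
  ok <- !is.na(values)
  if (sum(ok) < 20L)
    stop("need >= 20 values to estimate the ", prob, " quantile")
  thr <- quantile(values[ok], prob, type = 7, names = FALSE)
  out <- values > thr
  out
}

#' Per-site PBS for social and solitary groups
#'
#' Computes pairwise Hudson Fst between the social group, the solitary
#' group and the outgroup from pooled allele counts, converts to branch
#' lengths (negative Fst clamped to 0) and returns both focal PBS values
#' plus 95th-percentile outlier flags per group. Sites monomorphic in all
#' three groups are dropped.
#'
#' @param counts data.frame with columns `id`, `alt_social`, `n_social`,
#'   `alt_solitary`, `n_solitary`, `alt_outgroup`, `n_outgroup` (as produced
#'   by [simulateVariants()]).
#' @param quantile_prob outlier quantile (default 0.95); set `NA` to skip
#'   flagging.
#' @return data.frame with per-site `fst_fs`, `fst_fo`, `fst_so`, `t_fs`,
#'   `t_fo`, `t_so`, `pbs_social`, `pbs_solitary`, `outlier_social`,
#'   `outlier_solitary`.
#' @export
computePbs <- function(counts, quantile_prob = 0.95) {
  p_soc <- counts$alt_social / counts$n_social
  p_sol <- counts$alt_solitary / counts$n_solitary
  p_out <- counts$alt_outgroup / counts$n_outgroup
  mono <- (p_soc %in% c(0, 1)) & (p_sol == p_soc) & (p_out == p_soc)
  keep <- !mono
  d <- counts[keep, , drop = FALSE]
  p_soc <- p_soc[keep]; p_sol <- p_sol[keep]; p_out <- p_out[keep]
  fst_fs <- hudsonFst(p_soc, d$n_social, p_sol, d$n_solitary)
  fst_fo <- hudsonFst(p_soc, d$n_social, p_out, d$n_outgroup)
  fst_so <- hudsonFst(p_sol, d$n_solitary, p_out, d$n_outgroup)
  t_fs <- branchLength(fst_fs)
  t_fo <- branchLength(fst_fo)
  t_so <- branchLength(fst_so)
  res <- data.frame(id = d$id, fst_fs = fst_fs, fst_fo = fst_fo,
                    fst_so = fst_so, t_fs = t_fs, t_fo = t_fo, t_so = t_so,
                    pbs_social = pbs(t_fs, t_fo, t_so),
                    pbs_solitary = pbs(t_fs, t_so, t_fo))
  if (!is.na(quantile_prob) && sum(!is.na(res$pbs_social)) >= 20L) {
    res$outlier_social <- flagOutliers(res$pbs_social, quantile_prob)
    res$outlier_solitary <- flagOutliers(res$pbs_solitary, quantile_prob)
  } else {
    res$outlier_social <- NA
    res$outlier_solitary <- NA
  }
  res
}
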