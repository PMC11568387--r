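#' @importFrom Biostrings DNAStringSet
NULL

#' Log-odds score matrix of a PWM
#'
#' Per-position probabilities are smoothed with the pseudocount
#' (`p' = (p + pc * bg) / (1 + pc)`, keeping columns normalized) and scored
#' as `log2(p' / bg)` bits. With pseudocount 0, zero-probability letters
#' score `-Inf` (an impossible match).
#'
#' @param pwm A [Pwm-class].
#' @return 4 x L numeric matrix of scores in bits (rows A, C, G, T).
#' @export
logoddsMatrix <- function(pwm) {
  bg <- pwm@background
  if (any(bg <= 0)) stop("background entries must be > 0")
  m <- (pwm@matrix + pwm@pseudocount * bg) / (1 + pwm@pseudocount)
  log2(m / bg)
}

## Integer-discretized scores (bin width in bits). -Inf stays -Inf.
.intScores <- function(pwm, bin) {
  lom <- logoddsMatrix(pwm)
  ints <- round(lom / bin)
  ints
}

## Exact null distribution of the per-offset score by dynamic programming
## over the discretized score grid. Returns function(t_int) -> P(S >= t_int)
## under the background model; probability mass on -Inf paths never reaches
## any finite threshold.
.scoreDP <- function(ints, background) {
  L <- ncol(ints)
  finite_cols <- lapply(seq_len(L), function(j) {
    fin <- is.finite(ints[, j])
    list(v = ints[fin, j], p = background[fin])
  })
  lo <- 0; hi <- 0
  probs <- 1
  offset <- 0  # probs[k] = P(sum == offset + k - 1)
  for (col in finite_cols) {
    if (length(col$v) == 0L) return(function(t) 0)
    new_lo <- offset + min(col$v)
    new_hi <- offset + length(probs) - 1 + max(col$v)
    new <- numeric(new_hi - new_lo + 1)
    for (k in seq_along(col$v)) {
      sh <- offset + col$v[k] - new_lo
      idx <- seq_along(probs) + sh
      new[idx] <- new[idx] + probs * col$p[k]
    }
    probs <- new
    offset <- new_lo
  }
  tail_from <- rev(cumsum(rev(probs)))
  function(t_int) {
    k <- t_int - offset + 1
    if (k <= 1) return(sum(probs))
    if (k > length(probs)) return(0)
    tail_from[k]
  }
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcomp <- function(seq) {
  paste(rev(.COMPLEMENT[strsplit(seq, "", fixed = TRUE)[[1]]]),
        collapse = "")
}

#' Scan a sequence with a PWM
#'
#' Best log-odds score over all offsets and both strands, with an exact
#' p-value: the probability, under the background model, that a single
#' position scores at least as high (dynamic programming over the
#' discretized score distribution; no correction for the number of offsets).
#' `N` bases score 0 (background).
#'
#' @param seq character DNA sequence (length >= motif length).
#' @param pwm A [Pwm-class].
#' @param bin score discretization width in bits (default 1e-3).
#' @return list with `score` (bits), `p_value`, `offset` (1-based on the
#'   given strand), `strand` (`"+"`/`"-"`).
#' @export
scanWindow <- function(seq, pwm, bin = 1e-3) {
  seq <- toupper(seq)
  L <- motifLength(pwm)
  if (nchar(seq) < L)
    stop("motif (", L, " bp) longer than sequence (", nchar(seq), " bp)")
  ints <- .intScores(pwm, bin)
  dimnames(ints) <- NULL
  score_strand <- function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    idx <- match(chars, c("A", "C", "G", "T"))   # NA for N
    n_off <- length(chars) - L + 1L
    best <- -Inf; best_off <- NA_integer_
    for (o in seq_len(n_off)) {
      tot <- 0
      for (j in seq_len(L)) {
        b <- idx[o + j - 1L]
        if (!is.na(b)) {
          v <- ints[b, j]
          if (!is.finite(v)) { tot <- -Inf; break }
          tot <- tot + v
        }
      }
      if (tot > best) { best <- tot; best_off <- o }
    }
    list(best = best, off = best_off)
  }
  fwd <- score_strand(seq)
  rev <- score_strand(.revcomp(seq))
  use_rev <- rev$best > fwd$best
  best <- if (use_rev) rev else fwd
  pfun <- .scoreDP(ints, pwm@background)
  p <- if (is.finite(best$best)) pfun(best$best) else 1
  list(score = if (is.finite(best$best)) best$best * bin else -Inf,
       p_value = p, offset = best$off,
       strand = if (use_rev) "-" else "+")
}

#' Allele effects on predicted TF binding
#'
#' Applies the two-allele decision rule to a pair of equal-length windows
#' centered on a SNP (differing at exactly one position): for each motif,
#' `gain`/`loss` when exactly one allele has a significant match
#' (`p < sig`); otherwise `modulated` when both best scores are positive
#' and their ratio exceeds `ratio_threshold`; else `none`. When the derived
#' allele is known, `direction` reports whether it increases or decreases
#' predicted binding.
#'
#' @param window_ref,window_alt character windows (typically 101 bp) for the
#'   reference and alternate allele.
#' @param pwms list of [Pwm-class] objects.
#' @param sig significance threshold on the match p-value (default 1e-4).
#' @param ratio_threshold score-ratio threshold (default 1.5), evaluated
#'   only when both scores are positive.
#' @param derived `"ref"`, `"alt"` or `NA`: which allele is derived.
#' @return data.frame with one row per motif: `motif`, `score_ref`,
#'   `score_alt`, `p_ref`, `p_alt`, `effect`
#'   (`gain`/`loss`/`modulated`/`none`), `direction`
#'   (`increase`/`decrease`/`NA` for the derived allele).
#' @export
alleleEffect <- function(window_ref, window_alt, pwms, sig = 1e-4,
                         ratio_threshold = 1.5, derived = NA) {
  if (nchar(window_ref) != nchar(window_alt))
    stop("allele windows differ in length")
  cr <- strsplit(toupper(window_ref), "", fixed = TRUE)[[1]]
  ca <- strsplit(toupper(window_alt), "", fixed = TRUE)[[1]]
  ndiff <- sum(cr != ca)
  if (ndiff != 1L)
    stop("allele windows must differ at exactly 1 position (found ",
         ndiff, ")")
  if (is.null(names(pwms)))
    names(pwms) <- vapply(pwms, function(p) p@id, character(1))
  rows <- lapply(pwms, function(pwm) {
    sr <- scanWindow(window_ref, pwm)
    sa <- scanWindow(window_alt, pwm)
    sig_r <- sr$p_value < sig
    sig_a <- sa$p_value < sig
    effect <- "none"
    if (xor(sig_r, sig_a)) {
      effect <- if (sig_a) "gain" else "loss"
    } else if (is.finite(sr$score) && is.finite(sa$score) &&
               sr$score > 0 && sa$score > 0) {
      if (max(sr$score, sa$score) / min(sr$score, sa$score) > ratio_threshold)
        effect <- "modulated"
    } else if (sig_r && sig_a) {
      # both significant but a score <= 0 cannot enter the ratio rule
      effect <- "none"
    }
    direction <- NA_character_
    if (effect != "none" && !is.na(derived) && derived %in% c("ref", "alt")) {
      d_score <- if (derived == "alt") sa$score else sr$score
      o_score <- if (derived == "alt") sr$score else sa$score
      direction <- if (d_score > o_score) "increase" else "decrease"
    }
    data.frame(motif = pwm@id, score_ref = sr$score, score_alt = sa$score,
               p_ref = sr$p_value, p_alt = sa$p_value, effect = effect,
               direction = direction)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Motif enrichment of a foreground sequence set
#'
#' Counts, per motif, the sequences with at least one significant match
#' (`p < sig`) in the foreground and in the background (foreground
#' sequences are removed from the background first), and tests enrichment
#' with an upper-tail hypergeometric p-value, BH-corrected across motifs.
#'
#' @param foreground,background character vectors of sequences.
#' @param pwms list of [Pwm-class] objects.
#' @param sig per-sequence match significance (default 1e-4).
#' @param q_threshold reporting threshold recorded in the output (default
#'   0.05).
#' @return data.frame per motif: `motif`, `fg_hits`, `bg_hits`, `fold`,
#'   `p_value`, `q_value`, `enriched`.
#' @export
motifEnrichment <- function(foreground, background, pwms, sig = 1e-4,
                            q_threshold = 0.05) {
  if (length(foreground) == 0L) stop("empty foreground set")
  background <- background[!background %in% foreground]
  hit <- function(seqs, pwm)
    vapply(seqs, function(s) scanWindow(s, pwm)$p_value < sig, logical(1))
  rows <- lapply(pwms, function(pwm) {
    fh <- sum(hit(foreground, pwm))
    bh <- sum(hit(background, pwm))
    n_fg <- length(foreground); n_bg <- length(background)
    K <- fh + bh; N <- n_fg + n_bg
    p <- if (K == 0L) 1 else phyper(fh - 1, K, N - K, n_fg,
                                    lower.tail = FALSE)
    fg_rate <- fh / n_fg
    bg_rate <- if (n_bg > 0) bh / n_bg else NA_real_
    fold <- if (!is.na(bg_rate) && bg_rate > 0) fg_rate / bg_rate
    else if (fg_rate > 0) Inf else 0
    data.frame(motif = pwm@id, fg_hits = fh, bg_hits = bh, fold = fold,
               p_value = p)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$enriched <- out$q_value < q_threshold
  rownames(out) <- NULL
  out
}

#' Read motifs in JASPAR PFM format
#'
#' Parses the four-row count format (`>id name` header, then
#' `A [ 1 2 ... ]` etc.).
#'
#' @param path file path.
#' @param background,pseudocount passed to [Pwm()].
#' @return named list of [Pwm-class] objects.
#' @export
readJasparPfm <- function(path, background = rep(0.25, 4),
                          pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  out <- list()
  for (s in starts) {
    hdr <- strsplit(sub("^>", "", lines[s]), "[ \t]+")[[1]]
    id <- hdr[1]
    rows <- lines[(s + 1):(s + 4)]
    mat <- t(vapply(rows, function(r) {
      nums <- regmatches(r, gregexpr("[0-9.eE+-]+", r))[[1]]
      as.numeric(nums)
    }, numeric(length(regmatches(rows[1],
                                 gregexpr("[0-9.eE+-]+", rows[1]))[[1]]))))
    out[[id]] <- Pwm(id, mat, background = background,
                     pseudocount = pseudocount)
  }
  out
}

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections; uses the
#' file's `Background letter frequencies` when present.
#'
#' @param path file path.
#' @param pseudocount passed to [Pwm()].
#' @return named list of [Pwm-class] objects.
#' @export
readMemeMotifs <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    pairs <- regmatches(lines[bg_i + 1],
                        gregexpr("[ACGT][ \t]+[0-9.eE+-]+",
                                 lines[bg_i + 1]))[[1]]
    if (length(pairs) == 4L) {
      toks <- strsplit(pairs, "[ \t]+")
      vals <- setNames(vapply(toks, function(x) as.numeric(x[2]), numeric(1)),
                       vapply(toks, `[`, character(1), 1))
      bg <- unname(vals[c("A", "C", "G", "T")])
    }
  }
  motif_i <- grep("^MOTIF", lines)
  out <- list()
  for (m in motif_i) {
    id <- strsplit(trimws(lines[m]), "[ \t]+")[[1]][2]
    lp <- grep("^letter-probability matrix", lines[m:length(lines)])[1] + m - 1
    w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[lp]))
    rows <- lines[(lp + 1):(lp + w)]
    mat <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "[ \t]+")[[1]]), numeric(4)))
    out[[id]] <- Pwm(id, t(mat), background = bg, pseudocount = pseudocount)
  }
  out
}

#' Simulate allele windows around motif-disrupting SNPs
#'
#' Generates SNP-centered window pairs on a random background; in a
#' `frac_disrupting` fraction the reference window carries the motif
#' consensus across the center and the alternate allele breaks it, in the
#' rest both windows are background. Emulates planted regulatory variants
#' for testing the allele-effect rule.
#'
#' @param pwm A [Pwm-class].
#' @param n number of SNP window pairs.
#' @param flank bases on each side of the SNP (window width `2*flank+1`,
#'   default 50 giving 101 bp).
#' @param frac_disrupting fraction with a planted, disrupted consensus.
#' @param seed RNG seed.
#' @return data.frame with `snp`, `window_ref`, `window_alt`, `disrupting`.
#' @export
simulateAlleleWindows <- function(pwm, n = 20L, flank = 50L,
                                  frac_disrupting = 0.5, seed = 1L) {
  set.seed(as.integer(seed))
  L <- motifLength(pwm)
  cons <- c("A", "C", "G", "T")[apply(pwm@matrix, 2, which.max)]
  width <- 2L * flank + 1L
  rows <- lapply(seq_len(n), function(i) {
    base <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
    disrupting <- runif(1) < frac_disrupting
    center <- flank + 1L
    ref <- base
    if (disrupting) {
      # plant the consensus so that a motif position sits on the SNP
      motif_pos <- sample(L, 1L)
      start <- center - motif_pos + 1L
      ref[start:(start + L - 1L)] <- cons
    }
    ref_c <- ref[center]
    alt_c <- sample(setdiff(c("A", "C", "G", "T"), ref_c), 1L)
    alt <- ref
    alt[center] <- alt_c
    data.frame(snp = sprintf("msnp%03d", i),
               window_ref = paste(ref, collapse = ""),
               window_alt = paste(alt, collapse = ""),
               disrupting = disrupting)
  })
  do.call(rbind, rows)
}
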