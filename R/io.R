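#' @importFrom utils read.delim write.table head tail
#' @importFrom rtracklayer import export
NULL

#' Read a BED file into GRanges
#'
#' Accepts 3-6 column BED (0-based, half-open on disk; 1-based closed in
#' the returned `GRanges`). Validates coordinates line by line and, when a
#' genome is given, checks chromosome names and bounds.
#'
#' @param path BED file path.
#' @param genome optional named numeric vector of chromosome lengths or
#'   `Seqinfo`.
#' @return `GRanges` with `id` (column 4) and `score` (column 5) when
#'   present.
#' @export
readBedRegions <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) return(GRanges())
  if (is(genome, "Seqinfo"))
    genome <- setNames(as.numeric(seqlengths(genome)), seqnames(genome))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  for (i in seq_along(parts)) {
    if (nf[i] < 3L)
      stop("BED parse error at line ", i, ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(parts[[i]][2]))
    e <- suppressWarnings(as.numeric(parts[[i]][3]))
    if (is.na(s) || is.na(e))
      stop("BED parse error at line ", i, ": non-numeric coordinates")
    if (s < 0)
      stop("BED parse error at line ", i, ": negative start")
    if (s >= e)
      stop("BED parse error at line ", i, ": start >= end")
    if (!is.null(genome)) {
      ch <- parts[[i]][1]
      if (!ch %in% names(genome))
        stop("BED parse error at line ", i, ": unknown chromosome '",
             ch, "'")
      if (e > genome[[ch]])
        stop("BED parse error at line ", i, ": end beyond chromosome ",
             "length")
    }
  }
  chrom <- vapply(parts, `[`, character(1), 1)
  s <- as.numeric(vapply(parts, `[`, character(1), 2))
  e <- as.numeric(vapply(parts, `[`, character(1), 3))
  strand <- rep("*", length(parts))
  has6 <- nf >= 6L
  strand[has6] <- vapply(parts[has6], `[`, character(1), 6)
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(chrom, IRanges(s + 1, e), strand = strand)
  if (!is.null(genome)) {
    si <- Seqinfo(names(genome), unname(genome))
    seqlevels(gr) <- seqlevels(si)
    seqinfo(gr) <- si
  }
  if (any(nf >= 4L))
    mcols(gr)$id <- ifelse(nf >= 4L,
                           vapply(parts, function(p)
                             if (length(p) >= 4L) p[4] else NA_character_,
                             character(1)), NA_character_)
  if (any(nf >= 5L))
    mcols(gr)$score <- suppressWarnings(
      as.numeric(vapply(parts, function(p)
        if (length(p) >= 5L) p[5] else NA_character_, character(1))))
  gr
}

#' Write regions as BED6
#'
#' Coordinates are converted to the BED convention (0-based, half-open);
#' the name column is the `id` metadata column and the score column is
#' `score` (clamped to \[0, 1000\]) when present.
#'
#' @param regions `GRanges`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeBedRegions <- function(regions, path) {
  name <- mcols(regions)$id
  if (is.null(name)) name <- sprintf("region%05d", seq_along(regions))
  score <- mcols(regions)$score
  if (is.null(score)) score <- 0
  score <- pmin(1000, pmax(0, round(score)))
  st <- as.character(strand(regions))
  st[st == "*"] <- "."
  df <- data.frame(as.character(seqnames(regions)), start(regions) - 1L,
                   end(regions), name, score, st)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a gene annotation as GFF3
#'
#' @param annotation annotation `GRanges` (as from [simulateGenome()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeGff3Annotation <- function(annotation, path) {
  export(annotation, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 gene annotation
#'
#' Reads via rtracklayer and normalizes to the internal annotation layout
#' (`type`, `ID`, `Parent` character columns), validating parent links.
#'
#' @param path GFF3 file path.
#' @return annotation `GRanges`.
#' @export
readGff3Annotation <- function(path) {
  gr <- import(path, format = "gff3")
  m <- mcols(gr)
  parent <- if ("Parent" %in% colnames(m)) {
    p <- as(m$Parent, "CharacterList")
    vapply(p, function(x) if (length(x)) x[[1]] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))
  ids <- if ("ID" %in% colnames(m)) as.character(m$ID) else
    rep(NA_character_, length(gr))
  type <- as.character(m$type)
  known <- c(ids[!is.na(ids)])
  orphan <- !is.na(parent) & !parent %in% known
  if (any(orphan))
    stop("orphan feature(s) with unknown Parent: ",
         paste(head(unique(parent[orphan]), 5), collapse = ", "))
  mcols(gr) <- DataFrame(type = type, ID = ids, Parent = parent)
  gr
}

#' Read a minimal VCF-style variant table
#'
#' Supports the plain-text dialect `CHROM POS ID REF ALT QUAL FILTER INFO`
#' (header line starting with `#CHROM`; `##` meta lines ignored) plus any
#' extra per-replicate frequency columns named `freq_*`. Multiallelic rows
#' (comma in ALT) are skipped or split per `multiallelic`.
#'
#' @param path file path.
#' @param multiallelic `"skip"` (drop, counted in attribute
#'   `"n_multiallelic"`) or `"split"` (one row per alternate allele).
#' @return data.frame with lower-case core columns (`chrom`, `pos`, `id`,
#'   `ref`, `alt`, `qual`) and any extra columns verbatim.
#' @export
readVcfMinimal <- function(path, multiallelic = c("skip", "split")) {
  multiallelic <- match.arg(multiallelic)
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM", lines)
  if (length(hdr_i) != 1L) stop("no #CHROM header line found")
  header <- strsplit(sub("^#", "", lines[hdr_i]), "\t", fixed = TRUE)[[1]]
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body) & !startsWith(body, "#")]
  if (length(body) == 0L) {
    out <- data.frame(matrix(nrow = 0, ncol = length(header)))
    colnames(out) <- header
    return(out)
  }
  df <- read.delim(text = paste(body, collapse = "\n"), header = FALSE,
                   sep = "\t", stringsAsFactors = FALSE)
  colnames(df) <- header[seq_len(ncol(df))]
  core <- c(chrom = "CHROM", pos = "POS", id = "ID", ref = "REF",
            alt = "ALT", qual = "QUAL")
  for (nm in names(core)) {
    if (!core[[nm]] %in% colnames(df))
      stop("missing required column ", core[[nm]])
    colnames(df)[colnames(df) == core[[nm]]] <- nm
  }
  multi <- grepl(",", df$alt, fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi && multiallelic == "skip") {
    df <- df[!multi, , drop = FALSE]
  } else if (n_multi) {
    rows <- lapply(seq_len(nrow(df)), function(i) {
      alts <- strsplit(df$alt[i], ",", fixed = TRUE)[[1]]
      out <- df[rep(i, length(alts)), , drop = FALSE]
      out$alt <- alts
      out
    })
    df <- do.call(rbind, rows)
  }
  df$pos <- as.integer(df$pos)
  df$qual <- suppressWarnings(as.numeric(df$qual))
  rownames(df) <- NULL
  attr(df, "n_multiallelic") <- n_multi
  df
}

#' Write a simulated study as a plain-text fixture directory
#'
#' Emits `annotation.gff3`, `truth.bed` (score = round(100 * base
#' activity)), `dna_counts.tsv`/`rna_counts.tsv` (window id, coordinates,
#' one column per replicate), `design.tsv`, `snps.tsv`, `genotypes.tsv` and
#' `outgroup.tsv`.
#'
#' @param study output of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
writeSimFixture <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGff3Annotation(study$annotation, file.path(dir, "annotation.gff3"))
  tr <- study$truths
  mcols(tr)$score <- round(100 * mcols(tr)$base_activity)
  writeBedRegions(tr, file.path(dir, "truth.bed"))
  w <- rowRanges(study$counts)
  base <- data.frame(window_id = sprintf("w%06d", seq_along(w)),
                     chrom = as.character(seqnames(w)),
                     start = start(w) - 1L, end = end(w))
  write.table(cbind(base, dnaCounts(study$counts)),
              file.path(dir, "dna_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cbind(base, rnaCounts(study$counts)),
              file.path(dir, "rna_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(replicate_id = rownames(study$design),
                         study$design),
              file.path(dir, "design.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (nrow(study$variants$snps)) {
    write.table(study$variants$snps, file.path(dir, "snps.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(study$variants$genotypes, file.path(dir, "genotypes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(study$variants$outgroup, file.path(dir, "outgroup.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
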