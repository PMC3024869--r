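# Gene annotation parsing, head-to-head pair detection, control pair sets and
# TSS-distance binning.

#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom S4Vectors mcols mcols<-
NULL

# Canonical internal gene table: gene_id, chrom, strand, tss, tes (1-based).
# Accepts a GRanges (with a gene_id metadata column) or an equivalent
# data.frame. TSS/TES are derived from strand for ranges input.
.geneTable <- function(genes) {
  if (is(genes, "GRanges")) {
    if (length(genes) == 0)
      return(data.frame(gene_id = character(0), chrom = character(0),
                        strand = character(0), tss = integer(0),
                        tes = integer(0)))
    if (is.null(mcols(genes)$gene_id))
      stop("GRanges annotation must carry a 'gene_id' metadata column")
    st <- as.character(strand(genes))
    df <- data.frame(
      gene_id = as.character(mcols(genes)$gene_id),
      chrom = as.character(seqnames(genes)),
      strand = st,
      tss = ifelse(st == "+", start(genes), end(genes)),
      tes = ifelse(st == "+", end(genes), start(genes)))
  } else {
    df <- as.data.frame(genes)
    need <- c("gene_id", "chrom", "strand", "tss", "tes")
    if (!all(need %in% names(df)))
      stop("annotation must have columns: ", paste(need, collapse = ", "))
    df <- df[need]
    df$gene_id <- as.character(df$gene_id)
    df$chrom <- as.character(df$chrom)
    df$strand <- as.character(df$strand)
  }
  .validateGeneTable(df)
  df
}

.validateGeneTable <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (anyDuplicated(df$gene_id)) {
    dup <- df$gene_id[duplicated(df$gene_id)][1]
    stop("duplicate gene id in annotation: ", dup)
  }
  bad <- (df$strand == "+" & df$tss >= df$tes) |
    (df$strand == "-" & df$tss <= df$tes)
  if (any(bad))
    stop("TSS/TES inconsistent with strand for gene(s): ",
         paste(utils::head(df$gene_id[bad], 5), collapse = ", "))
  invisible(df)
}

.asGRanges <- function(df) {
  if (nrow(df) == 0)
    return(GRanges())
  gr <- GRanges(seqnames = df$chrom,
                ranges = IRanges::IRanges(start = pmin(df$tss, df$tes),
                                          end = pmax(df$tss, df$tes)),
                strand = df$strand)
  mcols(gr)$gene_id <- df$gene_id
  gr
}

#' Read a gene annotation
#'
#' Reads gene records from GFF3 (feature type `gene`; 1-based coordinates via
#' \pkg{rtracklayer}) or from a five-column TSV (`gene_id`, `chrom`, `strand`,
#' `tss`, `tes`, 1-based). The TSS is the start coordinate for plus-strand
#' genes and the end coordinate for minus-strand genes.
#'
#' @param path file path.
#' @param dialect `"gff3"` or `"tsv"`.
#' @return a [GenomicRanges::GRanges] with a `gene_id` metadata column. An
#'   empty file yields an empty `GRanges` with a warning.
#' @export
readAnnotation <- function(path, dialect = c("gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "gff3") {
    gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                   error = function(e) stop("failed to parse GFF3 '", path,
                                            "': ", conditionMessage(e)))
    gr <- gr[!is.na(mcols(gr)$type) & as.character(mcols(gr)$type) == "gene"]
    if (length(gr) == 0) {
      warning("no gene features in annotation: ", path)
      return(GRanges())
    }
    ids <- as.character(mcols(gr)$ID)
    if (all(is.na(ids)) && !is.null(mcols(gr)$Name)) ids <- as.character(mcols(gr)$Name)
    if (anyNA(ids)) stop("gene feature without an ID attribute in ", path)
    df <- data.frame(gene_id = ids,
                     chrom = as.character(seqnames(gr)),
                     strand = as.character(strand(gr)),
                     tss = ifelse(as.character(strand(gr)) == "+", start(gr), end(gr)),
                     tes = ifelse(as.character(strand(gr)) == "+", end(gr), start(gr)))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) {
      warning("empty annotation file: ", path)
      return(GRanges())
    }
    has.header <- grepl("gene_id", lines[1], fixed = TRUE)
    df <- tryCatch(
      utils::read.delim(text = lines, header = has.header,
                        stringsAsFactors = FALSE),
      error = function(e) stop("failed to parse TSV '", path, "': ",
                               conditionMessage(e)))
    if (!has.header) {
      if (ncol(df) != 5) stop("annotation TSV must have 5 columns, found ", ncol(df))
      names(df) <- c("gene_id", "chrom", "strand", "tss", "tes")
    }
    bad <- which(!is.finite(suppressWarnings(as.numeric(df$tss))) |
                   !is.finite(suppressWarnings(as.numeric(df$tes))))
    if (length(bad) > 0)
      stop("malformed annotation line ", bad[1] + has.header, " in ", path)
    df$tss <- as.integer(df$tss)
    df$tes <- as.integer(df$tes)
  }
  .validateGeneTable(df)
  .asGRanges(df)
}

#' Detect head-to-head (divergent) gene pairs
#'
#' A head-to-head pair is a minus-strand gene M and a plus-strand gene P on
#' the same chromosome whose TSSs face each other with no other gene's TSS
#' strictly between them. The signed TSS distance is `P.tss - M.tss`;
#' distances <= 0 mark overlapping pairs.
#'
#' @param genes annotation as returned by [readAnnotation()] (GRanges) or an
#'   equivalent data.frame (`gene_id`, `chrom`, `strand`, `tss`, `tes`).
#' @param maxDistance maximum TSS distance in bp (default 1000, the classical
#'   upper bound for a bidirectional promoter).
#' @param maxOverlap maximum TSS overlap in bp for overlapping pairs. The
#'   default mirrors `maxDistance`, giving a symmetric window around zero;
#'   `Inf` keeps every adjacent arrangement with crossed TSSs, which also
#'   admits convergent pair geometries and is rarely what is wanted.
#' @return an [H2HPairs-class] object, sorted by chromosome then minus-gene TSS.
#' @export
detectH2HPairs <- function(genes, maxDistance = 1000, maxOverlap = maxDistance) {
  stopifnot(maxDistance > 0)
  gt <- .geneTable(genes)
  out <- list()
  for (chr in unique(gt$chrom)) {
    g <- gt[gt$chrom == chr, ]
    minus <- g[g$strand == "-", ]
    plus <- g[g$strand == "+", ]
    if (nrow(minus) == 0 || nrow(plus) == 0) next
    tss.sorted <- sort(g$tss)
    # candidate grid: D[i, j] = plus_j.tss - minus_i.tss
    D <- outer(-minus$tss, plus$tss, `+`)
    keep <- which(D <= maxDistance & D >= -maxOverlap, arr.ind = TRUE)
    if (nrow(keep) == 0) next
    m.tss <- minus$tss[keep[, 1]]
    p.tss <- plus$tss[keep[, 2]]
    lo <- pmin(m.tss, p.tss)
    hi <- pmax(m.tss, p.tss)
    # number of TSSs strictly inside (lo, hi); the pair's own TSSs sit on the
    # boundary and are never counted
    n.between <- pmax(0L, findInterval(hi - 1L, tss.sorted) -
                        findInterval(lo, tss.sorted))
    adj <- n.between == 0L
    if (!any(adj)) next
    out[[chr]] <- data.frame(
      minus_gene = minus$gene_id[keep[adj, 1]],
      plus_gene = plus$gene_id[keep[adj, 2]],
      chrom = chr,
      tss_distance = p.tss[adj] - m.tss[adj],
      minus_tss = m.tss[adj])
  }
  if (length(out) == 0)
    return(H2HPairs(data.frame(minus_gene = character(0),
                               plus_gene = character(0),
                               chrom = character(0),
                               tss_distance = integer(0))))
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$minus_tss, df$tss_distance, df$plus_gene,
                 method = "radix"), ]
  df$minus_tss <- NULL
  H2HPairs(df)
}

#' Same-strand adjacent control pairs
#'
#' For each focal gene, pairs it with its nearest same-strand neighbour (by
#' TSS order) on each side of the same chromosome, then deduplicates by
#' canonical key. This is the "adjacent" control used against head-to-head
#' pairs.
#'
#' @param genes annotation (GRanges or data.frame, see [detectH2HPairs()]).
#' @param focalGenes character vector of gene ids (must all be annotated).
#' @return a [PairSet-class] labelled `"adjacent-control"`.
#' @export
sameStrandAdjacentPairs <- function(genes, focalGenes) {
  gt <- .geneTable(genes)
  missing <- setdiff(focalGenes, gt$gene_id)
  if (length(missing) > 0)
    stop("focal gene(s) absent from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "))
  res <- list()
  for (key in unique(paste(gt$chrom, gt$strand))) {
    g <- gt[paste(gt$chrom, gt$strand) == key, ]
    g <- g[order(g$tss), ]
    n <- nrow(g)
    if (n < 2) next
    focal.idx <- which(g$gene_id %in% focalGenes)
    for (i in focal.idx) {
      if (i > 1) res[[length(res) + 1]] <- c(g$gene_id[i], g$gene_id[i - 1])
      if (i < n) res[[length(res) + 1]] <- c(g$gene_id[i], g$gene_id[i + 1])
    }
  }
  if (length(res) == 0)
    return(PairSet(matrix(character(0), ncol = 2), label = "adjacent-control"))
  m <- do.call(rbind, res)
  m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  m <- m[!duplicated(paste(m[, 1], m[, 2])), , drop = FALSE]
  PairSet(m, label = "adjacent-control")
}

#' Sample random control gene pairs
#'
#' Samples `nPerRep` gene pairs uniformly (no self-pairs) in each of `nReps`
#' replicates. Pairs may repeat; identical seeds give identical output.
#'
#' @param geneIds character vector of at least two gene ids.
#' @param nPerRep pairs per replicate.
#' @param nReps number of replicates.
#' @param seed integer random seed (mandatory).
#' @param label set label.
#' @return a [PairSet-class] with a replicate index.
#' @export
sampleRandomPairs <- function(geneIds, nPerRep, nReps = 1, seed,
                              label = "random-control") {
  geneIds <- unique(as.character(geneIds))
  if (length(geneIds) < 2) stop("need at least two gene ids to sample pairs")
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  n <- as.integer(nPerRep) * as.integer(nReps)
  a <- sample(geneIds, n, replace = TRUE)
  b <- sample(geneIds, n, replace = TRUE)
  for (iter in 1:100) {
    self <- a == b
    if (!any(self)) break
    b[self] <- sample(geneIds, sum(self), replace = TRUE)
  }
  stopifnot(!any(a == b))
  PairSet(cbind(a, b), label = label, rep = rep(seq_len(nReps), each = nPerRep))
}

#' Bin TSS distances
#'
#' Assigns non-overlapping pair distances to left-open right-closed bins
#' `(lo, hi]` built from consecutive edges; overlapping pairs (distance <= 0)
#' go to a separate `overlapping` category, and positive distances beyond the
#' last edge (or at/below the first positive edge) to `out-of-range`.
#' Percentages are computed against the total pair count, so counts always
#' conserve mass.
#'
#' @param pairs an [H2HPairs-class] object or a numeric vector of signed TSS
#'   distances.
#' @param edges strictly increasing numeric bin edges (at least two).
#' @return data.frame with columns `bin`, `count`, `percent`.
#' @export
binTssDistances <- function(pairs, edges) {
  if (length(edges) < 2) stop("need at least two bin edges")
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  d <- if (is(pairs, "H2HPairs")) pairs@pairs$tss_distance else as.numeric(pairs)
  total <- length(d)
  over <- d <= 0
  pos <- d[!over]
  bins <- cut(pos, breaks = edges, right = TRUE)
  counts <- c(overlapping = sum(over), table(bins),
              `out-of-range` = sum(is.na(bins)))
  df <- data.frame(bin = names(counts), count = as.integer(counts))
  df$percent <- if (total > 0) df$count / total * 100 else 0
  rownames(df) <- NULL
  df
}
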