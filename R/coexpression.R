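# Correlation, reciprocal correlation ranks, Mutual Rank / Relative Rank,
# multi-dataset significance ratios (SPR/SNR/SR) and inter-pair summaries.

# Accept a plain genes x samples matrix or a SummarizedExperiment (assay 1).
.exprMatrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) stop("expression matrix must have gene rownames")
    return(x)
  }
  if (is(x, "SummarizedExperiment") &&
      requireNamespace("SummarizedExperiment", quietly = TRUE)) {
    return(as.matrix(SummarizedExperiment::assay(x, 1)))
  }
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop("expression input must have gene rownames")
  x
}

#' Correlate two expression profiles
#'
#' Pearson or Spearman correlation over pairwise-complete samples, with a
#' two-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df (used for both methods;
#' the t approximation for Spearman is adequate for n >= 10). Perfect
#' correlation gives p = 0. Zero variance in either profile flags the
#' correlation as undefined rather than erroring.
#'
#' @param x,y numeric sample vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `p`, `n`, `method`, `undefined`.
#' @export
correlatePair <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete sample pairs, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, method = method,
                undefined = TRUE))
  r <- stats::cor(x, y, method = method)
  r <- max(-1, min(1, r))
  p <- if (1 - r^2 < .Machine$double.eps) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n, method = method, undefined = FALSE)
}

#' Reciprocal correlation rank matrix
#'
#' For every gene A, all other genes are sorted by descending correlation with
#' A; `Rank(A -> B)` is the 1-based position of B in A's list. Exact
#' correlation ties are broken by ascending gene id (byte order), which makes
#' the ranks integer and deterministic. Genes whose correlation with A is
#' undefined (zero variance) sort last.
#'
#' @param expr genes x samples matrix (rownames = gene ids) or
#'   SummarizedExperiment.
#' @param method `"pearson"` or `"spearman"`.
#' @return integer matrix R with `R[A, B] = Rank(A -> B)`; diagonal `NA`.
#' @export
correlationRanks <- function(expr, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- .exprMatrix(expr)
  ids <- rownames(m)
  ng <- nrow(m)
  if (ng < 3) stop("need at least 3 genes")
  C <- suppressWarnings(stats::cor(t(m), method = method))
  R <- matrix(NA_integer_, ng, ng, dimnames = list(ids, ids))
  for (i in seq_len(ng)) {
    x <- C[i, ]
    x[i] <- NA
    o <- order(-x, ids, method = "radix", na.last = TRUE)
    o <- o[o != i]
    R[i, o] <- seq_len(ng - 1L)
  }
  R
}

#' Mutual Rank and Relative Rank of a gene pair
#'
#' Mutual Rank is the geometric mean of the two reciprocal correlation ranks,
#' `MR = sqrt(Rank(A->B) * Rank(B->A))`; Relative Rank is their minimum,
#' `RR = min(Rank(A->B), Rank(B->A))`. Low values mean strong mutual
#' coexpression; `RR <= MR <= max(Rank(A->B), Rank(B->A))` always holds.
#'
#' @param pair character vector of two gene ids.
#' @param ranks rank matrix from [correlationRanks()].
#' @return list with `rank_ab`, `rank_ba`, `mr`, `rr`.
#' @export
mutualRank <- function(pair, ranks) {
  a <- pair[1]; b <- pair[2]
  for (g in c(a, b))
    if (!g %in% rownames(ranks))
      stop("gene '", g, "' not present in the rank matrix")
  rank.ab <- ranks[a, b]
  rank.ba <- ranks[b, a]
  list(rank_ab = rank.ab, rank_ba = rank.ba,
       mr = sqrt(as.numeric(rank.ab) * as.numeric(rank.ba)),
       rr = min(rank.ab, rank.ba))
}

#' Multi-dataset significance profile of a pair (SPR/SNR/SR)
#'
#' Across a collection of expression datasets, counts in how many a pair is
#' significantly positively (SP) or negatively (SN) correlated at `alpha`.
#' Dividing by the number of usable datasets gives the Significant Positive
#' Ratio, Significant Negative Ratio and Significant Ratio; by construction
#' `SPR + SNR = SR` exactly. Datasets where either gene is missing, has fewer
#' than 3 complete samples, or has zero variance are excluded from the
#' denominator.
#'
#' @param pair character vector of two gene ids.
#' @param datasets list of genes x samples matrices.
#' @param alpha two-sided significance threshold (default 0.05).
#' @param method correlation method.
#' @return list with `spr`, `snr`, `sr`, `n_datasets_used`.
#' @export
significanceProfile <- function(pair, datasets, alpha = 0.05,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  a <- pair[1]; b <- pair[2]
  used <- 0L; sp <- 0L; sn <- 0L
  for (m in datasets) {
    m <- .exprMatrix(m)
    if (!(a %in% rownames(m)) || !(b %in% rownames(m))) next
    keep <- is.finite(m[a, ]) & is.finite(m[b, ])
    if (sum(keep) < 3) next
    res <- correlatePair(m[a, ], m[b, ], method = method)
    if (res$undefined) next
    used <- used + 1L
    if (res$p < alpha && res$r > 0) sp <- sp + 1L
    if (res$p < alpha && res$r < 0) sn <- sn + 1L
  }
  if (used == 0L)
    stop("no usable dataset for pair ", a, " / ", b)
  list(spr = sp / used, snr = sn / used, sr = (sp + sn) / used,
       n_datasets_used = used)
}

#' Coexpression summary of a pair set in one dataset
#'
#' Per-pair correlation (with t-based p), Mutual Rank and Relative Rank, plus
#' set-level means and medians. Pairs with a gene absent from the dataset are
#' skipped with a logged count.
#'
#' @param pairs an [H2HPairs-class] or [PairSet-class] object.
#' @param expr genes x samples matrix.
#' @param method correlation method.
#' @param ranks optional precomputed [correlationRanks()] matrix for `expr`
#'   (recomputed when `NULL`).
#' @return list with `pairs` (per-pair data.frame), `summary` (mean/median of
#'   PCC, MR, RR), `n_used`, `n_skipped`.
#' @export
pairsetCoexpression <- function(pairs, expr,
                                method = c("pearson", "spearman"),
                                ranks = NULL) {
  method <- match.arg(method)
  m <- .exprMatrix(expr)
  pt <- pairTable(pairs)
  if (nrow(pt) == 0) stop("empty pair set")
  present <- pt$gene_a %in% rownames(m) & pt$gene_b %in% rownames(m)
  if (!all(present))
    .msg("skipped ", sum(!present), " pair(s) with genes absent from the dataset")
  if (!any(present)) stop("no pair has both genes in the dataset")
  pt <- pt[present, , drop = FALSE]
  if (is.null(ranks)) ranks <- correlationRanks(m, method = method)
  n <- ncol(m)
  r <- p <- numeric(nrow(pt))
  for (i in seq_len(nrow(pt))) {
    res <- correlatePair(m[pt$gene_a[i], ], m[pt$gene_b[i], ], method = method)
    r[i] <- res$r; p[i] <- res$p
  }
  rank.ab <- ranks[cbind(pt$gene_a, pt$gene_b)]
  rank.ba <- ranks[cbind(pt$gene_b, pt$gene_a)]
  per.pair <- data.frame(
    key = canonicalPairKey(pt$gene_a, pt$gene_b),
    gene_a = pt$gene_a, gene_b = pt$gene_b,
    r = r, p = p, rank_ab = rank.ab, rank_ba = rank.ba,
    mr = sqrt(as.numeric(rank.ab) * as.numeric(rank.ba)),
    rr = pmin(rank.ab, rank.ba))
  summ <- data.frame(
    metric = c("r", "mr", "rr"),
    mean = c(mean(per.pair$r, na.rm = TRUE), mean(per.pair$mr),
             mean(per.pair$rr)),
    median = c(stats::median(per.pair$r, na.rm = TRUE),
               stats::median(per.pair$mr), stats::median(per.pair$rr)))
  list(pairs = per.pair, summary = summ,
       n_used = nrow(per.pair), n_skipped = sum(!present))
}

#' Inter-pair coexpression among head-to-head genes
#'
#' Enumerates all unordered gene pairs within a set of head-to-head genes,
#' removes the actual head-to-head pairs, and summarizes correlation and
#' Mutual Rank over the remaining cross pairs. This measures coexpression
#' *among* divergently organized genes beyond their own partners.
#'
#' @param h2hGenes character vector of gene ids (>= 3 present in `expr`).
#' @param actualPairs an [H2HPairs-class] or [PairSet-class] of pairs to
#'   exclude (may be empty).
#' @param expr genes x samples matrix.
#' @param method correlation method.
#' @param ranks optional precomputed rank matrix for `expr`.
#' @return list with `summary` (mean/median of r and MR), `n_pairs`,
#'   `n_excluded`.
#' @export
interpairCoexpression <- function(h2hGenes, actualPairs, expr,
                                  method = c("pearson", "spearman"),
                                  ranks = NULL) {
  method <- match.arg(method)
  m <- .exprMatrix(expr)
  genes <- sort(unique(intersect(h2hGenes, rownames(m))))
  if (length(genes) < 3) stop("need at least 3 head-to-head genes in the dataset")
  C <- suppressWarnings(stats::cor(t(m[genes, , drop = FALSE]), method = method))
  if (is.null(ranks)) ranks <- correlationRanks(m, method = method)
  ut <- which(upper.tri(C), arr.ind = TRUE)
  ga <- genes[ut[, 1]]; gb <- genes[ut[, 2]]
  keys <- canonicalPairKey(ga, gb)
  excl <- keys %in% pairKeys(actualPairs)
  ga <- ga[!excl]; gb <- gb[!excl]
  r <- C[ut][!excl]
  mr <- sqrt(as.numeric(ranks[cbind(ga, gb)]) * as.numeric(ranks[cbind(gb, ga)]))
  summ <- data.frame(metric = c("r", "mr"),
                     mean = c(mean(r, na.rm = TRUE), mean(mr)),
                     median = c(stats::median(r, na.rm = TRUE),
                                stats::median(mr)))
  list(summary = summ, n_pairs = length(r), n_excluded = sum(excl))
}
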