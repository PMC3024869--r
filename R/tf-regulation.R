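# Transcription-factor association of pairs, TF-sharing similarity and
# classification, self-regulating pairs, and sharing-vs-coexpression tests.

#' Read a TF -> target association map
#'
#' Reads a two-column TSV (`tf_id`, `target_gene_id`) and returns the
#' gene-centric [TFMap-class].
#'
#' @param path TSV file path (optional header containing `tf`).
#' @return a [TFMap-class] object.
#' @export
readTFMap <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(TFMap(list()))
  has.header <- strsplit(lines[1], "\t")[[1]][1] %in% c("tf", "tf_id")
  df <- utils::read.delim(text = lines, header = has.header,
                          stringsAsFactors = FALSE)
  TFMap(split(as.character(df[[1]]), as.character(df[[2]])))
}

#' Pairs whose two genes are both TF-associated
#'
#' @param pairs an [H2HPairs-class] or [PairSet-class] object.
#' @param tfmap a [TFMap-class] object.
#' @return object of the same class as `pairs`, restricted to pairs where
#'   both genes have at least one associated TF.
#' @export
tfAssociatedPairs <- function(pairs, tfmap) {
  stopifnot(is(tfmap, "TFMap"))
  pt <- pairTable(pairs)
  assoc <- names(tfmap@targets)[lengths(tfmap@targets) > 0]
  keep <- pt$gene_a %in% assoc & pt$gene_b %in% assoc
  if (is(pairs, "H2HPairs")) return(H2HPairs(pairs@pairs[keep, , drop = FALSE]))
  PairSet(pairs@pairs[keep, , drop = FALSE], label = pairs@label,
          rep = if (length(pairs@rep)) pairs@rep[keep] else NULL)
}

#' TF-sharing similarity of one gene pair
#'
#' TF similarity is the fraction of shared TFs in the union of the two genes'
#' TF sets (Jaccard index). The sharing class is `no-share` (0 common TFs),
#' `one-share` (exactly 1) or `multi-share` (2 or more).
#'
#' @param geneA,geneB gene ids (both must be TF-associated; filter with
#'   [tfAssociatedPairs()] first).
#' @param tfmap a [TFMap-class] object.
#' @return list with `n_shared`, `n_union`, `tf_similarity`, `class`.
#' @export
tfSimilarity <- function(geneA, geneB, tfmap) {
  ta <- associatedTFs(tfmap, geneA)
  tb <- associatedTFs(tfmap, geneB)
  if (length(ta) == 0 || length(tb) == 0)
    stop("gene(s) without TF association: ",
         paste(c(geneA, geneB)[c(length(ta) == 0, length(tb) == 0)],
               collapse = ", "))
  ns <- length(intersect(ta, tb))
  nu <- length(union(ta, tb))
  list(n_shared = ns, n_union = nu, tf_similarity = ns / nu,
       class = if (ns == 0) "no-share" else if (ns == 1) "one-share" else "multi-share")
}

#' TF-sharing records for a pair set
#'
#' Vectorized [tfSimilarity()] over a set of TF-associated pairs.
#'
#' @param pairs an [H2HPairs-class] or [PairSet-class] of TF-associated pairs.
#' @param tfmap a [TFMap-class] object.
#' @return data.frame with columns `key`, `gene_a`, `gene_b`, `n_shared`,
#'   `n_union`, `tf_similarity`, `class` (factor no-share/one-share/multi-share).
#' @export
tfSharing <- function(pairs, tfmap) {
  pt <- pairTable(pairs)
  n <- nrow(pt)
  ns <- nu <- integer(n)
  for (i in seq_len(n)) {
    rec <- tfSimilarity(pt$gene_a[i], pt$gene_b[i], tfmap)
    ns[i] <- rec$n_shared; nu[i] <- rec$n_union
  }
  data.frame(
    key = canonicalPairKey(pt$gene_a, pt$gene_b),
    gene_a = pt$gene_a, gene_b = pt$gene_b,
    n_shared = ns, n_union = nu,
    tf_similarity = if (n) ns / nu else numeric(0),
    class = factor(ifelse(ns == 0, "no-share",
                          ifelse(ns == 1, "one-share", "multi-share")),
                   levels = c("no-share", "one-share", "multi-share")))
}

#' Compare TF-sharing proportions between a focal and a control set
#'
#' 2x2 Pearson chi-squared (no continuity correction by default) on
#' sharing/exclusive counts. The one-sided p (for the observed direction) is
#' reported alongside the two-sided chi-squared p.
#'
#' @param focal,control length-2 counts `c(n_sharing, n_exclusive)`.
#' @param correct apply the Yates continuity correction?
#' @return list with `prop_focal`, `prop_control`, `statistic`, `df`,
#'   `p.value` (two-sided), `p.one.sided`.
#' @export
sharingProportionTest <- function(focal, control, correct = FALSE) {
  stopifnot(length(focal) == 2, length(control) == 2)
  if (any(c(focal, control) < 0)) stop("counts must be non-negative")
  if (sum(focal) == 0 || sum(control) == 0)
    stop("both sets need a positive total")
  tab <- rbind(focal = focal, control = control)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  pf <- focal[1] / sum(focal)
  pc <- control[1] / sum(control)
  p2 <- unname(ht$p.value)
  list(prop_focal = pf, prop_control = pc,
       statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = p2,
       p.one.sided = if (pf >= pc) p2 / 2 else 1 - p2 / 2)
}

#' Pairs in which one gene is a TF regulating the other
#'
#' @param pairs an [H2HPairs-class] or [PairSet-class] object.
#' @param tfmap a [TFMap-class] object.
#' @return data.frame with columns `gene_a`, `gene_b`, `direction`
#'   (`"a->b"`, `"b->a"` or `"both"`), one row per self-regulating pair.
#' @export
selfRegulatingPairs <- function(pairs, tfmap) {
  pt <- pairTable(pairs)
  a.reg.b <- logical(nrow(pt))
  b.reg.a <- logical(nrow(pt))
  for (i in seq_len(nrow(pt))) {
    a.reg.b[i] <- pt$gene_a[i] %in% associatedTFs(tfmap, pt$gene_b[i])
    b.reg.a[i] <- pt$gene_b[i] %in% associatedTFs(tfmap, pt$gene_a[i])
  }
  keep <- a.reg.b | b.reg.a
  data.frame(gene_a = pt$gene_a[keep], gene_b = pt$gene_b[keep],
             direction = ifelse(a.reg.b[keep] & b.reg.a[keep], "both",
                                ifelse(a.reg.b[keep], "a->b", "b->a")))
}

#' TF sharing versus coexpression
#'
#' Per-sharing-class mean correlation, Welch t-tests between classes
#' (sharing vs no-share, multi-share vs one-share), and the Pearson
#' correlation between TF similarity and expression correlation over the
#' sharing pairs. A constant similarity vector flags the correlation as
#' undefined instead of failing.
#'
#' @param records data.frame from [tfSharing()].
#' @param pcc named numeric vector of per-pair correlation values, keyed by
#'   canonical pair key (must cover all records).
#' @param alpha significance threshold echoed into the result.
#' @return list with `class_means`, `tests` (data.frame), and
#'   `similarity_pcc_cor` (list r/p/n, possibly undefined).
#' @export
sharingVsCoexpression <- function(records, pcc, alpha = 0.05) {
  v <- pcc[records$key]
  if (anyNA(v)) stop("missing coexpression value for ",
                     sum(is.na(v)), " pair(s)")
  cls <- records$class
  class.means <- data.frame(
    class = levels(cls),
    n = as.integer(table(cls)),
    mean_pcc = as.numeric(tapply(v, cls, mean)))
  groups <- list(
    c("sharing", "no-share"),
    c("multi-share", "one-share"))
  tests <- list()
  for (g in groups) {
    va <- if (g[1] == "sharing") v[cls != "no-share"] else v[cls == g[1]]
    vb <- v[cls == g[2]]
    if (length(va) < 2 || length(vb) < 2)
      stop("degenerate group size for comparison ", g[1], " vs ", g[2],
           " (n = ", length(va), ", ", length(vb), ")")
    ht <- .safeWelch(va, vb)
    tests[[length(tests) + 1]] <- data.frame(
      comparison = paste(g, collapse = " vs "),
      mean_a = mean(va), mean_b = mean(vb),
      statistic = unname(ht$statistic), p.value = unname(ht$p.value))
  }
  sharing <- records$n_shared >= 1
  sim <- records$tf_similarity[sharing]
  vs <- v[sharing]
  simcor <- if (length(sim) >= 3 && stats::sd(sim) > 0 && stats::sd(vs) > 0) {
    res <- correlatePair(sim, vs, method = "pearson")
    list(r = res$r, p = res$p, n = res$n, undefined = FALSE)
  } else {
    list(r = NA_real_, p = NA_real_, n = length(sim), undefined = TRUE)
  }
  list(class_means = class.means, tests = do.call(rbind, tests),
       similarity_pcc_cor = simcor, alpha = alpha)
}
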