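# Information-content semantic similarity on an ontology DAG: OBO parsing,
# true-path propagation, term IC, minimum subsumer, Resnik/Lin similarity,
# gene- and pair-level similarity, and similarity-vs-coexpression summaries.

#' Read an OBO 1.2 subset into a GoDag
#'
#' Minimal parser for `[Term]` stanzas with `id`, `name`, `namespace` and
#' `is_a` tags (trailing `! comments` stripped). Obsolete terms and every
#' other tag are ignored; only `is_a` edges are honoured, keeping each
#' subsystem single-rooted.
#'
#' @param path OBO file path.
#' @return a [GoDag-class] object.
#' @export
readOBO <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- character(0); namespace <- character(0); parents <- list()
  cur <- NULL; cur.ns <- NA_character_; cur.parents <- character(0); obsolete <- FALSE
  flush <- function() {
    if (!is.null(cur) && !obsolete) {
      terms <<- c(terms, cur)
      namespace[cur] <<- cur.ns
      parents[[cur]] <<- cur.parents
    }
  }
  in.term <- FALSE
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      cur <- NULL; cur.ns <- NA_character_; cur.parents <- character(0)
      obsolete <- FALSE; in.term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in.term <- FALSE; next }
    if (!in.term || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur <- trimws(sub("^id:", "", ln))
    else if (grepl("^namespace:", ln)) cur.ns <- trimws(sub("^namespace:", "", ln))
    else if (grepl("^is_a:", ln)) cur.parents <- c(cur.parents, trimws(sub("^is_a:", "", ln)))
    else if (grepl("^is_obsolete:\\s*true", ln)) obsolete <- TRUE
  }
  flush()
  if (length(terms) == 0) stop("no [Term] stanzas in ", path)
  if (anyNA(namespace[terms])) {
    # single-namespace files may omit the tag; infer one shared namespace
    known <- unique(stats::na.omit(namespace[terms]))
    if (length(known) == 1) namespace[terms][is.na(namespace[terms])] <- known
    else stop("terms without a namespace in ", path)
  }
  GoDag(terms = terms, parents = parents, namespace = namespace[terms])
}

#' All ancestors of every term (including the term itself)
#'
#' @param dag a [GoDag-class] object.
#' @return named list: term id -> character vector of ancestor ids
#'   (self included).
#' @export
termAncestors <- function(dag) {
  stopifnot(is(dag, "GoDag"))
  anc <- vector("list", length(dag@terms))
  names(anc) <- dag@terms
  done <- stats::setNames(rep(FALSE, length(dag@terms)), dag@terms)
  # process in dependency order: parents before children
  pending <- dag@terms
  while (length(pending) > 0) {
    ready <- pending[vapply(dag@parents[pending],
                            function(p) all(done[p]), TRUE)]
    if (length(ready) == 0) stop("cycle detected in DAG")
    for (t in ready) {
      anc[[t]] <- unique(c(t, unlist(anc[dag@parents[[t]]], use.names = FALSE)))
      done[t] <- TRUE
    }
    pending <- setdiff(pending, ready)
  }
  anc
}

#' Propagate annotations by the true-path rule
#'
#' Closes a direct annotation set upward: a gene annotated to a term becomes
#' annotated to every ancestor of that term. Idempotent; the subsystem of
#' each propagated annotation is taken from the DAG.
#'
#' @param dag a [GoDag-class] object.
#' @param annots an [AnnotationSet-class] (direct or already propagated).
#' @return a propagated [AnnotationSet-class].
#' @export
propagateAnnotations <- function(dag, annots) {
  stopifnot(is(dag, "GoDag"), is(annots, "AnnotationSet"))
  a <- annotationTable(annots)
  unknown <- setdiff(unique(a$term_id), dag@terms)
  if (length(unknown) > 0)
    stop("annotation to unknown term(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  anc <- termAncestors(dag)
  ancn <- lengths(anc[a$term_id])
  out <- data.frame(
    gene_id = rep(a$gene_id, ancn),
    term_id = unlist(anc[a$term_id], use.names = FALSE))
  out$subsystem <- unname(dag@namespace[out$term_id])
  AnnotationSet(out, propagated = TRUE)
}

#' Term probabilities and information content
#'
#' With propagated annotations, `p(t)` is the number of genes annotated to
#' term `t` divided by the number of genes annotated to the root of `t`'s
#' subsystem (so `p(root) = 1`); information content is `IC(t) = -ln p(t)`,
#' in nats. Terms with zero propagated annotations receive no IC and are
#' excluded from similarity, with a logged count.
#'
#' @param dag a [GoDag-class] object.
#' @param annots a propagated [AnnotationSet-class].
#' @return data.frame with columns `term`, `subsystem`, `p`, `ic`.
#' @export
informationContent <- function(dag, annots) {
  stopifnot(is(dag, "GoDag"), is(annots, "AnnotationSet"))
  if (!isPropagated(annots))
    stop("annotations must be propagated first (see propagateAnnotations)")
  a <- annotationTable(annots)
  out <- list()
  for (ns in names(dag@roots)) {
    root <- dag@roots[[ns]]
    ans <- a[a$subsystem == ns, ]
    total <- length(unique(ans$gene_id[ans$term_id == root]))
    if (total == 0) stop("no annotated gene in subsystem ", ns)
    cnt <- tapply(ans$gene_id, ans$term_id, function(g) length(unique(g)))
    p <- as.numeric(cnt) / total
    out[[ns]] <- data.frame(term = names(cnt), subsystem = ns,
                            p = p, ic = -log(p))
  }
  ic <- do.call(rbind, out)
  rownames(ic) <- NULL
  n.zero <- length(dag@terms) - nrow(ic)
  if (n.zero > 0)
    .msg(n.zero, " term(s) without annotations excluded from IC")
  ic
}

.icVector <- function(ic) stats::setNames(ic$ic, ic$term)

#' Minimum subsumer and Resnik similarity of two terms
#'
#' The minimum subsumer is the common ancestor (terms themselves included)
#' with maximal information content; ties break by ascending term id. Its IC
#' is the Resnik similarity (in nats).
#'
#' @param dag a [GoDag-class] object.
#' @param ic IC table from [informationContent()].
#' @param t1,t2 term ids in the same subsystem.
#' @param ancestors optional precomputed [termAncestors()] list.
#' @return list with `term` (the subsumer) and `ic_ms` (Resnik similarity).
#' @export
minimumSubsumer <- function(dag, ic, t1, t2, ancestors = NULL) {
  for (t in c(t1, t2))
    if (!t %in% dag@terms) stop("term not in DAG: ", t)
  if (dag@namespace[[t1]] != dag@namespace[[t2]])
    stop("terms ", t1, " and ", t2, " are in different subsystems")
  if (is.null(ancestors)) ancestors <- termAncestors(dag)
  icv <- .icVector(ic)
  common <- intersect(ancestors[[t1]], ancestors[[t2]])
  common <- common[common %in% names(icv)]
  if (length(common) == 0)
    return(list(term = NA_character_, ic_ms = NA_real_))
  common <- sort(common, method = "radix")
  best <- common[which.max(icv[common])]
  list(term = best, ic_ms = unname(icv[best]))
}

#' Lin similarity of two terms
#'
#' The Resnik similarity normalized to [0, 1]:
#' `2 * IC(subsumer) / (IC(t1) + IC(t2))`, defined as 0 when both terms have
#' zero IC (root against root). Identical informative terms score 1; terms
#' whose only common ancestor is the root score 0.
#'
#' @inheritParams minimumSubsumer
#' @return numeric similarity in [0, 1].
#' @export
linSimilarity <- function(dag, ic, t1, t2, ancestors = NULL) {
  icv <- .icVector(ic)
  if (!t1 %in% names(icv) || !t2 %in% names(icv))
    return(NA_real_)
  ms <- minimumSubsumer(dag, ic, t1, t2, ancestors = ancestors)
  denom <- icv[[t1]] + icv[[t2]]
  if (denom == 0) return(0)
  unname(2 * ms$ic_ms / denom)
}

# All-pairs Lin similarity matrix for the IC-bearing terms of one subsystem.
.linMatrix <- function(dag, ic, subsystem, ancestors = NULL) {
  if (is.null(ancestors)) ancestors <- termAncestors(dag)
  sub <- ic[ic$subsystem == subsystem, ]
  terms <- sort(sub$term, method = "radix")
  icv <- stats::setNames(sub$ic, sub$term)[terms]
  k <- length(terms)
  A <- matrix(FALSE, k, k, dimnames = list(terms, terms))
  for (t in terms) {
    a <- intersect(ancestors[[t]], terms)
    A[t, a] <- TRUE
  }
  res <- matrix(NA_real_, k, k, dimnames = list(terms, terms))
  for (i in seq_len(k)) {
    for (j in i:k) {
      common <- which(A[i, ] & A[j, ])
      res[i, j] <- res[j, i] <- if (length(common)) max(icv[common]) else NA_real_
    }
  }
  denom <- outer(icv, icv, `+`)
  lin <- ifelse(denom == 0, 0, 2 * res / denom)
  list(terms = terms, resnik = res, lin = lin)
}

#' Gene-pair semantic similarity in one subsystem
#'
#' Combines term-level Lin similarities over all cross pairs of the two
#' genes' direct (pre-closure) annotations. `combine = "max"` (the default)
#' takes the best cross pair; `"bma"` is the best-match average; `"mean"`
#' averages all cross pairs. Undefined (`NA`) when either gene has no
#' IC-bearing direct annotation in the subsystem.
#'
#' @param dag a [GoDag-class] object.
#' @param ic IC table from [informationContent()].
#' @param annots the direct (unpropagated) [AnnotationSet-class].
#' @param g1,g2 gene ids.
#' @param subsystem subsystem label (e.g. `"BP"`).
#' @param combine `"max"`, `"bma"` or `"mean"`.
#' @param linmat optional precomputed `.linMatrix` result (internal reuse).
#' @return similarity in [0, 1], or `NA` if undefined.
#' @export
genePairSimilarity <- function(dag, ic, annots, g1, g2, subsystem,
                               combine = c("max", "bma", "mean"),
                               linmat = NULL) {
  combine <- match.arg(combine)
  a <- annotationTable(annots)
  if (is.null(linmat)) linmat <- .linMatrix(dag, ic, subsystem)
  t1 <- intersect(unique(a$term_id[a$gene_id == g1 & a$subsystem == subsystem]),
                  linmat$terms)
  t2 <- intersect(unique(a$term_id[a$gene_id == g2 & a$subsystem == subsystem]),
                  linmat$terms)
  if (length(t1) == 0 || length(t2) == 0) return(NA_real_)
  M <- linmat$lin[t1, t2, drop = FALSE]
  switch(combine,
         max = max(M),
         mean = mean(M),
         bma = mean(c(apply(M, 1, max), apply(M, 2, max))))
}

#' Representative similarity across subsystems
#'
#' The maximum of the defined per-subsystem similarities (a pair annotated in
#' any subsystem gets a representative value; all-undefined stays `NA`).
#'
#' @param values numeric vector of per-subsystem similarities (may contain
#'   `NA` for undefined subsystems).
#' @return numeric scalar or `NA`.
#' @export
representativeSimilarity <- function(values) {
  if (all(is.na(values))) return(NA_real_)
  max(values, na.rm = TRUE)
}

#' Per-pair functional similarity table
#'
#' Computes gene-pair Lin similarity in every subsystem of the DAG plus the
#' representative (maximum) similarity, for a whole pair set at once.
#'
#' @param dag a [GoDag-class] object.
#' @param ic IC table from [informationContent()].
#' @param annots the direct (unpropagated) [AnnotationSet-class].
#' @param pairs an [H2HPairs-class] or [PairSet-class] object, or a
#'   two-column matrix/data.frame of gene ids.
#' @param combine term-combination rule (see [genePairSimilarity()]).
#' @return data.frame with `key`, `gene_a`, `gene_b`, one `sim_<subsystem>`
#'   column per subsystem, and `sim_rep`. The combine rule is recorded in
#'   attribute `combine`.
#' @export
pairFunctionalSimilarity <- function(dag, ic, annots, pairs,
                                     combine = c("max", "bma", "mean")) {
  combine <- match.arg(combine)
  pt <- pairTable(pairs)
  a <- annotationTable(annots)
  subsystems <- names(dag@roots)
  ancestors <- termAncestors(dag)
  linmats <- lapply(subsystems, function(ns) .linMatrix(dag, ic, ns, ancestors))
  names(linmats) <- subsystems
  # direct IC-bearing terms per gene per subsystem
  gene.terms <- lapply(subsystems, function(ns) {
    ans <- a[a$subsystem == ns, ]
    ans <- ans[ans$term_id %in% linmats[[ns]]$terms, ]
    split(ans$term_id, ans$gene_id)
  })
  names(gene.terms) <- subsystems
  out <- data.frame(key = canonicalPairKey(pt$gene_a, pt$gene_b),
                    gene_a = pt$gene_a, gene_b = pt$gene_b)
  for (ns in subsystems) {
    lm <- linmats[[ns]]$lin
    gt <- gene.terms[[ns]]
    sim <- rep(NA_real_, nrow(pt))
    for (i in seq_len(nrow(pt))) {
      t1 <- gt[[pt$gene_a[i]]]
      t2 <- gt[[pt$gene_b[i]]]
      if (is.null(t1) || is.null(t2)) next
      M <- lm[unique(t1), unique(t2), drop = FALSE]
      sim[i] <- switch(combine,
                       max = max(M),
                       mean = mean(M),
                       bma = mean(c(apply(M, 1, max), apply(M, 2, max))))
    }
    out[[paste0("sim_", ns)]] <- sim
  }
  simcols <- as.matrix(out[paste0("sim_", subsystems)])
  out$sim_rep <- apply(simcols, 1, representativeSimilarity)
  attr(out, "combine") <- combine
  out
}

#' Mean functional similarity above coexpression thresholds
#'
#' For each threshold, the mean representative similarity over pairs whose
#' correlation exceeds it; empty subsets are flagged with `n = 0` and `NA`.
#'
#' @param funcsim numeric vector of representative similarities.
#' @param pcc numeric vector of per-pair correlations (same order).
#' @param thresholds ascending numeric thresholds.
#' @return data.frame with `threshold`, `n`, `mean_funcsim`.
#' @export
funcsimByCoexpressionThreshold <- function(funcsim, pcc, thresholds) {
  stopifnot(length(funcsim) == length(pcc))
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be sorted ascending")
  res <- lapply(thresholds, function(tau) {
    keep <- !is.na(pcc) & pcc > tau & !is.na(funcsim)
    data.frame(threshold = tau, n = sum(keep),
               mean_funcsim = if (any(keep)) mean(funcsim[keep]) else NA_real_)
  })
  do.call(rbind, res)
}

#' Null distribution of mean functional similarity from random pairs
#'
#' Samples `nPairs` random pairs of annotated genes, `nIter` times, and
#' returns the per-iteration mean representative similarity — the random
#' control against which an observed pair-set mean is judged.
#'
#' @param dag a [GoDag-class] object.
#' @param ic IC table from [informationContent()].
#' @param annots the direct [AnnotationSet-class].
#' @param nPairs pairs per iteration.
#' @param nIter iterations (the classical control uses 100).
#' @param seed integer random seed.
#' @param combine term-combination rule.
#' @return numeric vector of `nIter` null means.
#' @export
randomFuncsimControl <- function(dag, ic, annots, nPairs, nIter = 100, seed,
                                 combine = c("max", "bma", "mean")) {
  combine <- match.arg(combine)
  if (missing(seed)) stop("a seed is required")
  a <- annotationTable(annots)
  icv <- .icVector(ic)
  pool <- sort(unique(a$gene_id[a$term_id %in% names(icv)]), method = "radix")
  if (length(pool) < 3)
    stop("not enough annotated genes for a random control (", length(pool), ")")
  set.seed(seed)
  g1 <- sample(pool, nPairs * nIter, replace = TRUE)
  g2 <- sample(pool, nPairs * nIter, replace = TRUE)
  for (i in 1:100) {
    self <- g1 == g2
    if (!any(self)) break
    g2[self] <- sample(pool, sum(self), replace = TRUE)
  }
  sims <- pairFunctionalSimilarity(dag, ic, annots, cbind(g1, g2),
                                   combine = combine)
  iter <- rep(seq_len(nIter), each = nPairs)
  as.numeric(tapply(sims$sim_rep, iter, function(v) mean(v, na.rm = TRUE)))
}
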