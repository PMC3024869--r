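# Independent brute-force / closed-form oracles. These deliberately share no
# code with the package implementation: plain loops and textbook formulas.

# all divergent pairs by scanning every minus x plus combination
oracleH2H <- function(gt, maxDistance = 1000, maxOverlap = maxDistance) {
  res <- list()
  for (i in seq_len(nrow(gt))) {
    for (j in seq_len(nrow(gt))) {
      m <- gt[i, ]; p <- gt[j, ]
      if (m$strand != "-" || p$strand != "+") next
      if (m$chrom != p$chrom) next
      d <- p$tss - m$tss
      if (d > maxDistance || d < -maxOverlap) next
      lo <- min(m$tss, p$tss); hi <- max(m$tss, p$tss)
      others <- gt[gt$chrom == m$chrom, ]
      if (any(others$tss > lo & others$tss < hi)) next
      res[[length(res) + 1]] <- data.frame(
        minus_gene = m$gene_id, plus_gene = p$gene_id, tss_distance = d)
    }
  }
  if (length(res) == 0)
    return(data.frame(minus_gene = character(0), plus_gene = character(0),
                      tss_distance = integer(0)))
  do.call(rbind, res)
}

# nearest same-strand neighbour on each side, per focal gene
oracleAdjacent <- function(gt, focal) {
  keys <- character(0)
  for (f in focal) {
    fg <- gt[gt$gene_id == f, ]
    grp <- gt[gt$chrom == fg$chrom & gt$strand == fg$strand &
                gt$gene_id != f, ]
    left <- grp[grp$tss < fg$tss, ]
    right <- grp[grp$tss > fg$tss, ]
    nb <- character(0)
    if (nrow(left) > 0) nb <- c(nb, left$gene_id[which.max(left$tss)])
    if (nrow(right) > 0) nb <- c(nb, right$gene_id[which.min(right$tss)])
    for (g in nb)
      keys <- c(keys, paste(min(f, g), max(f, g), sep = "|"))
  }
  sort(unique(keys))
}

# Rank(A -> B) by explicit sort, ties by ascending gene id
oracleRanks <- function(mat, method = "pearson") {
  C <- suppressWarnings(cor(t(mat), method = method))
  ids <- rownames(mat)
  R <- matrix(NA_integer_, nrow(mat), nrow(mat), dimnames = list(ids, ids))
  for (a in ids) {
    others <- setdiff(ids, a)
    o <- others[order(-C[a, others], others)]
    for (k in seq_along(o)) R[a, o[k]] <- k
  }
  R
}

# all ancestors (self included) by recursive parent walk
oracleAncestors <- function(parents, term) {
  out <- term
  for (p in parents[[term]])
    out <- union(out, oracleAncestors(parents, p))
  sort(out)
}

# minimum subsumer by enumerating the ancestor intersection
oracleMinSubsumer <- function(parents, icv, t1, t2) {
  common <- intersect(oracleAncestors(parents, t1), oracleAncestors(parents, t2))
  common <- common[common %in% names(icv)]
  if (length(common) == 0) return(list(term = NA, ic = NA))
  common <- sort(common)
  best <- common[which.max(icv[common])]
  list(term = best, ic = unname(icv[best]))
}

oracleLin <- function(parents, icv, t1, t2) {
  ms <- oracleMinSubsumer(parents, icv, t1, t2)
  denom <- icv[[t1]] + icv[[t2]]
  if (denom == 0) return(0)
  2 * ms$ic / denom
}

# Cochran-Armitage trend chi-squared, textbook formula
oracleTrendChisq <- function(successes, totals, scores = seq_along(successes)) {
  N <- sum(totals)
  pbar <- sum(successes) / N
  num <- sum(successes * scores) - pbar * sum(totals * scores)
  den <- pbar * (1 - pbar) *
    (sum(totals * scores^2) - sum(totals * scores)^2 / N)
  num^2 / den
}

# 2x2 Pearson chi-squared, sum over (O - E)^2 / E
oracleChisq2x2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# power of the two-sided correlation test via the Fisher-z approximation
fisherZPower <- function(rho, n, alpha = 0.05) {
  z <- atanh(rho) * sqrt(n - 3)
  crit <- qnorm(1 - alpha / 2)
  pnorm(z - crit) + pnorm(-z - crit)
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of assignments
oracleWilcoxExact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  obs <- sum(r[seq_len(na)])
  all.sums <- apply(combn(n, na), 2, function(idx) sum(r[idx]))
  mu <- mean(all.sums)
  mean(abs(all.sums - mu) >= abs(obs - mu) - 1e-9)
}

# hypergeometric probability that two k-subsets of a pool overlap
oracleShareChance <- function(pool, k) {
  1 - choose(pool - k, k) / choose(pool, k)
}

# small random annotation table with both strands and several chromosomes
randomGeneTable <- function(n, seed, chroms = 2) {
  set.seed(seed)
  tss <- sample.int(200000, n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  len <- sample(200:2000, n, replace = TRUE)
  data.frame(
    gene_id = sprintf("r%03d", seq_len(n)),
    chrom = sample(paste0("chr", seq_len(chroms)), n, replace = TRUE),
    strand = strand,
    tss = tss,
    tes = ifelse(strand == "+", tss + len, tss - len))
}

# hand-built DAG: one BP subsystem, depth 3 tree with one shortcut edge
#        root
#       /    \
#      a      b
#     / \    / \
#    c   d  e   f    (+ shortcut: f is_a a)
#    |
#    g
toyDag <- function() {
  GoDag(
    terms = c("BP:root", "BP:a", "BP:b", "BP:c", "BP:d", "BP:e", "BP:f", "BP:g"),
    parents = list(
      `BP:a` = "BP:root", `BP:b` = "BP:root",
      `BP:c` = "BP:a", `BP:d` = "BP:a",
      `BP:e` = "BP:b", `BP:f` = c("BP:b", "BP:a"),
      `BP:g` = "BP:c"),
    namespace = setNames(rep("BP", 8),
                         c("BP:root", "BP:a", "BP:b", "BP:c", "BP:d", "BP:e",
                           "BP:f", "BP:g")))
}

# annotations on toyDag chosen so every IC is a simple closed-form count
toyAnnotations <- function() {
  AnnotationSet(data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6", "g7", "g8"),
    term_id = c("BP:g", "BP:c", "BP:d", "BP:e", "BP:f", "BP:f", "BP:b", "BP:root"),
    subsystem = "BP"))
}

# random leveled DAG for property tests: acyclic by construction
randomDag <- function(nTerms, seed, ns = "BP") {
  set.seed(seed)
  ids <- sprintf("%s:t%02d", ns, seq_len(nTerms))
  level <- c(0, sort(sample(1:4, nTerms - 1, replace = TRUE)))
  parents <- list()
  for (i in seq(2, nTerms)) {
    shallower <- ids[level < level[i]]
    k <- min(length(shallower), 1 + rbinom(1, 1, 0.3))
    parents[[ids[i]]] <- sample(shallower, k)
  }
  GoDag(terms = ids, parents = parents,
        namespace = setNames(rep(ns, nTerms), ids))
}

randomAnnotations <- function(dag, nGenes, seed, perGene = 2) {
  set.seed(seed)
  ns <- unname(dag@namespace[1])
  rows <- data.frame(
    gene_id = rep(sprintf("g%02d", seq_len(nGenes)), perGene),
    term_id = sample(dag@terms, nGenes * perGene, replace = TRUE),
    subsystem = ns)
  AnnotationSet(rows)
}
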