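# Orchestration of the full conservation-stratified analysis: group
# comparison statistics, the two-stage verdict logic, report tables and
# report serialization.

#' Two-group comparison
#'
#' Welch t-test or Wilcoxon rank-sum test, two-sided. The Wilcoxon test uses
#' exact enumeration for small tie-free groups (both n <= 20) and the normal
#' approximation with tie correction otherwise.
#'
#' @param a,b numeric value vectors.
#' @param test `"welch_t"` or `"wilcoxon"`.
#' @return list with `test`, `statistic`, `p.value`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b`.
#' @export
compareGroups <- function(a, b, test = c("welch_t", "wilcoxon")) {
  test <- match.arg(test)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0) stop("empty group in comparison")
  if (test == "welch_t") {
    if (length(a) < 2 || length(b) < 2)
      stop("welch_t needs at least 2 values per group")
    ht <- .safeWelch(a, b)
  } else {
    exact <- length(a) <= 20 && length(b) <= 20 && !anyDuplicated(c(a, b))
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact))
  }
  list(test = test, statistic = unname(ht$statistic),
       p.value = unname(ht$p.value),
       mean_a = mean(a), mean_b = mean(b),
       n_a = length(a), n_b = length(b))
}

# Two-stage verdict: stage 1 = feature differs from control in the expected
# direction; stage 2 = level means move monotonically in the expected
# direction across >= 3 adequately sized conservation levels.
.featureVerdict <- function(stage1_p, direction_ok, means, ns,
                            expected = c("increasing", "decreasing"),
                            alpha = 0.05, minLevelN = 10) {
  expected <- match.arg(expected)
  stage1 <- is.finite(stage1_p) && stage1_p < alpha && direction_ok
  usable <- which(is.finite(means) & ns >= minLevelN)
  if (length(usable) < 3)
    return(list(verdict = if (stage1) "postponed" else "negated",
                stage1 = stage1, monotone = NA, n_levels_used = length(usable)))
  dm <- diff(means[usable])
  mono.inc <- all(dm >= 0)
  mono.dec <- all(dm <= 0)
  mono.expected <- if (expected == "increasing") mono.inc else mono.dec
  mono.contrary <- if (expected == "increasing") {
    mono.dec && any(dm < 0)
  } else {
    mono.inc && any(dm > 0)
  }
  verdict <- if (stage1 && mono.expected) "inherent"
  else if (!stage1 || mono.contrary) "negated"
  else "postponed"
  list(verdict = verdict, stage1 = stage1, monotone = mono.expected,
       n_levels_used = length(usable))
}

# nested-set (cumulative) per-level statistic: f(values of pairs at level >= i)
.nestedStat <- function(values, levelIdx, nLevels, f) {
  vapply(seq_len(nLevels), function(i) {
    v <- values[levelIdx >= i]
    if (length(v) == 0) NA_real_ else f(v)
  }, 0)
}

.nestedN <- function(levelIdx, nLevels, good = TRUE) {
  vapply(seq_len(nLevels), function(i) sum(levelIdx >= i & good), 0L)
}

#' Run the full conservation-stratified analysis
#'
#' Executes the whole pipeline on a simulated (or equivalently structured)
#' input bundle: detects head-to-head pairs, assigns nested conservation
#' levels from ortholog maps and partner-species pair detection, bins TSS
#' distances and tests the short-distance conservation trend, summarizes
#' coexpression (PCC, Mutual Rank, Relative Rank, SPR/SNR/SR) against random
#' and same-strand-adjacent controls, analyses TF sharing, and computes
#' information-content functional similarity with a 100-iteration random
#' control. Each examined feature receives the two-stage verdict `inherent`
#' (differs from control and moves consistently with conservation), `negated`
#' (fails the control comparison or moves contrarily) or `postponed`
#' (control-significant but not consistent across levels).
#'
#' @param sim input bundle as returned by [simulateAll()]: `config`,
#'   `genome` (with `genes`, `species`, `orthologs`), `datasets`, `tfmap`,
#'   `dag`, `annotations`.
#' @param alpha significance threshold for every stage-wise test.
#' @param maxDistance maximum TSS distance for pair detection (bp).
#' @param minLevelN minimum per-level n for a level to enter the
#'   monotonicity check.
#' @param combine term-combination rule for functional similarity.
#' @param pccThresholds ascending correlation thresholds for the
#'   functional-similarity-by-coexpression table.
#' @param edges TSS-distance bin edges.
#' @param seed seed for the pipeline's own sampling (random control pairs);
#'   defaults to `config$seed + 7`.
#' @param outDir optional directory; when given, report tables are written
#'   as TSV plus a `report.json`.
#' @return a `StratifiedReport` list with elements `n_pairs`, `levels`,
#'   `tables`, `tests`, `verdicts`, `params`, `provenance`.
#' @export
runPipeline <- function(sim, alpha = 0.05, maxDistance = 1000,
                        minLevelN = 10, combine = c("max", "bma", "mean"),
                        pccThresholds = c(0.355, 0.5, 0.6),
                        edges = c(0, 100, 200, 400, 1000),
                        seed = NULL, outDir = NULL) {
  combine <- match.arg(combine)
  if (is.null(seed)) seed <- sim$config$seed + 7L
  cfg <- sim$config
  lv <- conservationLevels(cfg$species)
  nlv <- length(lv)

  # --- stage: pair detection -------------------------------------------------
  pairs <- detectH2HPairs(sim$genome$genes, maxDistance = maxDistance)
  if (length(pairs) == 0) stop("stage gene_models: no divergent pairs detected")
  pdf <- as.data.frame(pairs)
  h2h.genes <- unique(c(pdf$minus_gene, pdf$plus_gene))
  all.genes <- .geneTable(sim$genome$genes)$gene_id

  # --- stage: conservation ---------------------------------------------------
  species.pairs <- lapply(sim$genome$species, detectH2HPairs,
                          maxDistance = maxDistance)
  levels.f <- assignConservation(pairs, cfg$species, sim$genome$orthologs,
                                 species.pairs)
  lidx <- as.integer(levels.f)

  # --- stage: TSS distance ---------------------------------------------------
  tss.tab <- do.call(rbind, lapply(seq_len(nlv), function(i) {
    h <- binTssDistances(pdf$tss_distance[lidx >= i], edges)
    h$set <- lv[i]
    h
  }))
  in.bin <- pdf$tss_distance > 0 & pdf$tss_distance <= 100
  trend <- conservationTrendReport(levels.f, in.bin)

  # --- stage: coexpression (primary dataset) ---------------------------------
  if (length(sim$datasets) == 0) stop("stage coexpression: no expression dataset")
  ds1 <- sim$datasets[[1]]
  ranks <- correlationRanks(ds1)
  h2h.cx <- pairsetCoexpression(pairs, ds1, ranks = ranks)
  random.set <- sampleRandomPairs(all.genes, nPerRep = length(pairs),
                                  nReps = 2, seed = seed)
  random.cx <- pairsetCoexpression(random.set, ds1, ranks = ranks)
  adjacent.set <- sameStrandAdjacentPairs(sim$genome$genes, h2h.genes)
  adjacent.cx <- pairsetCoexpression(adjacent.set, ds1, ranks = ranks)
  t.pcc.rand <- compareGroups(h2h.cx$pairs$r, random.cx$pairs$r, "welch_t")
  t.pcc.adj <- compareGroups(h2h.cx$pairs$r, adjacent.cx$pairs$r, "welch_t")
  t.mr.rand <- compareGroups(h2h.cx$pairs$mr, random.cx$pairs$mr, "wilcoxon")
  interpair <- interpairCoexpression(h2h.genes, pairs, ds1, ranks = ranks)

  key.order <- match(h2h.cx$pairs$key, names(levels.f))
  cx.lidx <- lidx[key.order]
  coexpr.tab <- data.frame(
    set = lv,
    n = .nestedN(cx.lidx, nlv),
    mean_pcc = .nestedStat(h2h.cx$pairs$r, cx.lidx, nlv, mean),
    median_pcc = .nestedStat(h2h.cx$pairs$r, cx.lidx, nlv, stats::median),
    mean_mr = .nestedStat(h2h.cx$pairs$mr, cx.lidx, nlv, mean),
    median_mr = .nestedStat(h2h.cx$pairs$mr, cx.lidx, nlv, stats::median),
    mean_rr = .nestedStat(h2h.cx$pairs$rr, cx.lidx, nlv, mean),
    median_rr = .nestedStat(h2h.cx$pairs$rr, cx.lidx, nlv, stats::median))

  # --- stage: multi-dataset significance ratios ------------------------------
  keys <- pairKeys(pairs)
  prof <- t(vapply(seq_len(nrow(pdf)), function(i) {
    p <- significanceProfile(c(pdf$minus_gene[i], pdf$plus_gene[i]),
                             sim$datasets, alpha = alpha)
    c(p$spr, p$snr, p$sr)
  }, numeric(3)))
  colnames(prof) <- c("spr", "snr", "sr")
  rt <- pairTable(random.set)
  rand.n <- min(nrow(rt), length(pairs))
  rand.snr <- vapply(seq_len(rand.n), function(i) {
    significanceProfile(c(rt$gene_a[i], rt$gene_b[i]), sim$datasets,
                        alpha = alpha)$snr
  }, 0)
  sig.tab <- data.frame(
    set = lv,
    n = .nestedN(lidx, nlv),
    mean_spr = .nestedStat(prof[, "spr"], lidx, nlv, mean),
    mean_snr = .nestedStat(prof[, "snr"], lidx, nlv, mean),
    mean_sr = .nestedStat(prof[, "sr"], lidx, nlv, mean))
  t.snr.rand <- compareGroups(prof[, "snr"], rand.snr, "welch_t")

  # --- stage: TF sharing -----------------------------------------------------
  assoc <- tfAssociatedPairs(pairs, sim$tfmap)
  if (length(assoc) < 2) stop("stage tf_regulation: too few TF-associated pairs")
  records <- tfSharing(assoc, sim$tfmap)
  adj.assoc <- tfAssociatedPairs(adjacent.set, sim$tfmap)
  adj.records <- tfSharing(adj.assoc, sim$tfmap)
  share.test <- sharingProportionTest(
    c(sum(records$n_shared > 0), sum(records$n_shared == 0)),
    c(sum(adj.records$n_shared > 0), sum(adj.records$n_shared == 0)))
  assoc.lidx <- lidx[match(records$key, keys)]
  tf.tab <- data.frame(
    set = lv,
    n_associated = .nestedN(assoc.lidx, nlv),
    n_sharing = vapply(seq_len(nlv), function(i)
      sum(records$n_shared[assoc.lidx >= i] > 0), 0L))
  tf.tab$prop_sharing <- ifelse(tf.tab$n_associated > 0,
                                tf.tab$n_sharing / tf.tab$n_associated, NA)
  pcc.by.key <- stats::setNames(h2h.cx$pairs$r, h2h.cx$pairs$key)
  share.vs.cx <- tryCatch(
    sharingVsCoexpression(records, pcc.by.key, alpha = alpha),
    error = function(e) list(error = conditionMessage(e)))
  selfreg <- selfRegulatingPairs(pairs, sim$tfmap)

  # --- stage: functional similarity ------------------------------------------
  propagated <- propagateAnnotations(sim$dag, sim$annotations)
  ic <- informationContent(sim$dag, propagated)
  funcsim <- pairFunctionalSimilarity(sim$dag, ic, sim$annotations, pairs,
                                      combine = combine)
  fs.def <- !is.na(funcsim$sim_rep)
  n.annot <- sum(fs.def)
  if (n.annot < 3) stop("stage go_semantics: too few annotated pairs")
  null.means <- randomFuncsimControl(sim$dag, ic, sim$annotations,
                                     nPairs = n.annot, nIter = 100,
                                     seed = seed + 1L, combine = combine)
  pool <- sort(unique(annotationTable(sim$annotations)$gene_id))
  set.seed(seed + 2L)
  rnd.a <- sample(pool, n.annot, replace = TRUE)
  rnd.b <- sample(pool, n.annot, replace = TRUE)
  fix <- rnd.a == rnd.b
  rnd.b[fix] <- sample(pool, sum(fix), replace = TRUE)
  rnd.fs <- pairFunctionalSimilarity(sim$dag, ic, sim$annotations,
                                     cbind(rnd.a, rnd.b), combine = combine)
  t.fs.rand <- compareGroups(funcsim$sim_rep[fs.def],
                             rnd.fs$sim_rep[!is.na(rnd.fs$sim_rep)],
                             "wilcoxon")
  obs.mean <- mean(funcsim$sim_rep[fs.def])
  empirical.p <- mean(null.means >= obs.mean)
  subsystems <- names(sim$dag@roots)
  fs.tab <- data.frame(set = lv)
  for (ns in subsystems) {
    v <- funcsim[[paste0("sim_", ns)]]
    fs.tab[[paste0("mean_", ns)]] <- .nestedStat(v, lidx, nlv,
                                                 function(x) mean(x, na.rm = TRUE))
    fs.tab[[paste0("n_", ns)]] <- vapply(seq_len(nlv), function(i)
      sum(!is.na(v) & lidx >= i), 0L)
  }
  fs.tab$mean_rep <- .nestedStat(funcsim$sim_rep, lidx, nlv,
                                 function(x) mean(x, na.rm = TRUE))
  fs.tab$n_rep <- vapply(seq_len(nlv), function(i)
    sum(fs.def & lidx >= i), 0L)
  thr.tab <- do.call(rbind, lapply(seq_len(nlv), function(i) {
    keep <- lidx >= i
    res <- funcsimByCoexpressionThreshold(
      funcsim$sim_rep[keep],
      pcc.by.key[funcsim$key[keep]],
      pccThresholds)
    res$set <- lv[i]
    res
  }))
  # TSS distance vs coexpression (expected: no relationship)
  nono <- !pdf$overlapping
  dist.pcc <- if (sum(nono) >= 3)
    correlatePair(pdf$tss_distance[nono],
                  h2h.cx$pairs$r[match(keys, h2h.cx$pairs$key)][nono])
  else list(r = NA, p = NA, n = sum(nono), undefined = TRUE)

  # --- verdicts ----------------------------------------------------------------
  fs.level.n <- fs.tab$n_rep
  verdict.rows <- list(
    positive_coexpression = .featureVerdict(
      t.pcc.rand$p.value, t.pcc.rand$mean_a > t.pcc.rand$mean_b,
      coexpr.tab$mean_pcc, coexpr.tab$n, "increasing", alpha, minLevelN),
    negative_correlation = .featureVerdict(
      t.snr.rand$p.value, t.snr.rand$mean_a > t.snr.rand$mean_b,
      sig.tab$mean_snr, sig.tab$n, "increasing", alpha, minLevelN),
    tf_sharing = .featureVerdict(
      share.test$p.value, share.test$prop_focal > share.test$prop_control,
      tf.tab$prop_sharing, tf.tab$n_associated, "increasing", alpha, minLevelN),
    functional_similarity = .featureVerdict(
      t.fs.rand$p.value, t.fs.rand$mean_a > t.fs.rand$mean_b,
      fs.tab$mean_rep, fs.level.n, "increasing", alpha, minLevelN))
  verdicts <- data.frame(
    feature = names(verdict.rows),
    verdict = vapply(verdict.rows, `[[`, "", "verdict"),
    stage1_pass = vapply(verdict.rows, `[[`, TRUE, "stage1"),
    monotone = vapply(verdict.rows, function(v) isTRUE(v$monotone), TRUE),
    n_levels_used = vapply(verdict.rows, `[[`, 0L, "n_levels_used"))
  rownames(verdicts) <- NULL

  tests <- data.frame(
    name = c("pcc_h2h_vs_random", "pcc_h2h_vs_adjacent", "mr_h2h_vs_random",
             "snr_h2h_vs_random", "tf_sharing_h2h_vs_adjacent",
             "funcsim_h2h_vs_random", "tss_trend_nested", "tss_trend_disjoint",
             "funcsim_random_control_empirical", "tss_distance_vs_pcc"),
    test = c("welch_t", "welch_t", "wilcoxon", "welch_t", "chisq_2x2",
             "wilcoxon", "chisq_trend", "chisq_trend", "empirical_100_iter",
             "pearson_t"),
    statistic = c(t.pcc.rand$statistic, t.pcc.adj$statistic,
                  t.mr.rand$statistic, t.snr.rand$statistic,
                  share.test$statistic, t.fs.rand$statistic,
                  if (is.null(trend$nested)) NA else trend$nested$statistic,
                  if (is.null(trend$disjoint)) NA else trend$disjoint$statistic,
                  NA, dist.pcc$r),
    p.value = c(t.pcc.rand$p.value, t.pcc.adj$p.value, t.mr.rand$p.value,
                t.snr.rand$p.value, share.test$p.value, t.fs.rand$p.value,
                if (is.null(trend$nested)) NA else trend$nested$p.value,
                if (is.null(trend$disjoint)) NA else trend$disjoint$p.value,
                empirical.p, dist.pcc$p),
    n = c(t.pcc.rand$n_a + t.pcc.rand$n_b, t.pcc.adj$n_a + t.pcc.adj$n_b,
          t.mr.rand$n_a + t.mr.rand$n_b, t.snr.rand$n_a + t.snr.rand$n_b,
          length(assoc) + length(adj.assoc), t.fs.rand$n_a + t.fs.rand$n_b,
          length(pairs), length(pairs), 100L, dist.pcc$n))

  report <- list(
    n_pairs = length(pairs),
    levels = data.frame(set = lv, n = .nestedN(lidx, nlv)),
    tables = list(
      tss = tss.tab, trend = trend$table, coexpression = coexpr.tab,
      sigratio = sig.tab, tf = tf.tab, funcsim = fs.tab,
      thresholds = thr.tab),
    tests = tests,
    verdicts = verdicts,
    details = list(
      h2h_coexpression = h2h.cx, random_coexpression = random.cx,
      adjacent_coexpression = adjacent.cx, interpair = interpair,
      profiles = prof, sharing_records = records,
      sharing_vs_coexpression = share.vs.cx,
      self_regulating = selfreg, funcsim = funcsim,
      null_means = null.means, conservation = levels.f),
    params = list(alpha = alpha, maxDistance = maxDistance,
                  minLevelN = minLevelN, combine = combine,
                  pccThresholds = pccThresholds, edges = edges, seed = seed),
    provenance = c(
      tss = "binTssDistances", trend = "conservationTrendReport",
      coexpression = "pairsetCoexpression", sigratio = "significanceProfile",
      tf = "tfSharing", funcsim = "pairFunctionalSimilarity",
      thresholds = "funcsimByCoexpressionThreshold"))
  class(report) <- "StratifiedReport"
  if (!is.null(outDir)) writeReport(report, outDir)
  report
}

#' @export
print.StratifiedReport <- function(x, ...) {
  cat("Conservation-stratified head-to-head analysis\n")
  cat("  pairs:", x$n_pairs, "; nested sets:",
      paste(sprintf("%s=%d", x$levels$set, x$levels$n), collapse = ", "), "\n")
  cat("  verdicts:\n")
  for (i in seq_len(nrow(x$verdicts)))
    cat(sprintf("    %-24s %s\n", x$verdicts$feature[i], x$verdicts$verdict[i]))
  invisible(x)
}

#' Write a stratified report to disk
#'
#' Writes every report table as TSV plus a `report.json` with tests,
#' verdicts and parameters.
#'
#' @param report a `StratifiedReport` from [runPipeline()].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$tables))
    utils::write.table(report$tables[[nm]],
                       file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$tests, file.path(dir, "tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_pairs = report$n_pairs, levels = report$levels,
         tests = report$tests, verdicts = report$verdicts,
         params = report$params, provenance = as.list(report$provenance)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
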