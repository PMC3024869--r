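# Nested conservation assignment of head-to-head pairs from ortholog maps,
# and the chi-squared trend test across conservation strata.

#' Labels of the nested conservation sets
#'
#' The focal set is `"H"`; each partner species appends the upper-cased first
#' letter of its name, so the default order `mouse, chicken, fugu` yields
#' `H, HM, HMC, HMCF`.
#'
#' @param speciesOrder character vector of partner species from closest to
#'   most distant.
#' @return character vector of level labels, length `length(speciesOrder) + 1`.
#' @export
conservationLevels <- function(speciesOrder) {
  lv <- "H"
  for (s in speciesOrder) lv <- c(lv, paste0(lv[length(lv)], toupper(substr(s, 1, 1))))
  lv
}

#' Read a two-column ortholog map
#'
#' Reads a TSV of focal-species gene id and partner-species gene id. Many-to-
#' many entries (a focal gene with two partners, or a partner claimed by two
#' focal genes) are dropped entirely, with a logged count.
#'
#' @param path TSV file path (optional header containing `focal`).
#' @return named character vector: focal gene id -> partner gene id.
#' @export
readOrthologMap <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(stats::setNames(character(0), character(0)))
  has.header <- grepl("focal", lines[1], fixed = TRUE)
  df <- utils::read.delim(text = lines, header = has.header,
                          stringsAsFactors = FALSE)
  orthologMap(as.character(df[[1]]), as.character(df[[2]]))
}

#' Build a one-to-one ortholog map, dropping many-to-many entries
#'
#' @param focal,partner equal-length character vectors of gene ids.
#' @return named character vector: focal gene id -> partner gene id.
#' @export
orthologMap <- function(focal, partner) {
  stopifnot(length(focal) == length(partner))
  bad <- focal %in% focal[duplicated(focal)] |
    partner %in% partner[duplicated(partner)]
  if (any(bad))
    .msg("dropped ", sum(bad), " many-to-many ortholog entries")
  stats::setNames(partner[!bad], focal[!bad])
}

#' Assign nested conservation levels to head-to-head pairs
#'
#' A pair is conserved in partner species S when both genes have (one-to-one)
#' orthologs in S and those orthologs themselves form a head-to-head pair in
#' S. The conservation level is the deepest prefix of `speciesOrder` in which
#' the pair is conserved in every species of the prefix (sequentially
#' inclusive sets); conservation in a more distant species without the
#' intermediate one does not advance the level.
#'
#' @param pairs an [H2HPairs-class] or [PairSet-class] of focal-species pairs.
#' @param speciesOrder partner species from closest to most distant.
#' @param orthologMaps named list (per species) of named character vectors as
#'   returned by [orthologMap()].
#' @param speciesPairs named list (per species) of [H2HPairs-class] or
#'   [PairSet-class] objects of partner-species head-to-head pairs.
#' @return ordered factor of levels (see [conservationLevels()]), named by
#'   canonical pair key, one element per input pair.
#' @export
assignConservation <- function(pairs, speciesOrder, orthologMaps, speciesPairs) {
  for (s in speciesOrder) {
    if (is.null(orthologMaps[[s]])) stop("no ortholog map for species: ", s)
    if (is.null(speciesPairs[[s]])) stop("no pair set for species: ", s)
  }
  pt <- pairTable(pairs)
  keys <- canonicalPairKey(pt$gene_a, pt$gene_b)
  depth <- rep(0L, nrow(pt))
  alive <- rep(TRUE, nrow(pt))
  for (i in seq_along(speciesOrder)) {
    s <- speciesOrder[i]
    om <- orthologMaps[[s]]
    skeys <- pairKeys(speciesPairs[[s]])
    oa <- om[pt$gene_a]
    ob <- om[pt$gene_b]
    conserved <- !is.na(oa) & !is.na(ob) &
      canonicalPairKey(unname(oa), unname(ob)) %in% skeys
    alive <- alive & conserved
    depth[alive] <- i
  }
  lv <- conservationLevels(speciesOrder)
  stats::setNames(factor(lv[depth + 1L], levels = lv, ordered = TRUE), keys)
}

#' Chi-squared test for trend in proportions across ordered sets
#'
#' Cochran-Armitage-style trend test (1 df) on per-set success counts with
#' numeric scores (default `1..k`), as used to test whether the proportion of
#' pairs in a TSS-distance bin climbs with conservation level. With two sets
#' it reduces to the ordinary 2x2 chi-squared without continuity correction.
#'
#' @param successes,totals equal-length non-negative count vectors.
#' @param scores numeric scores per set (default `seq_along(successes)`).
#' @return list with `statistic`, `df` (always 1) and `p.value` (upper tail).
#' @export
proportionTrendTest <- function(successes, totals, scores = seq_along(successes)) {
  if (length(successes) != length(totals) || length(scores) != length(totals))
    stop("successes, totals and scores must have equal length")
  if (any(totals == 0)) stop("every set must have a positive total")
  if (any(successes < 0) || any(successes > totals))
    stop("need 0 <= successes <= totals")
  # the internal weighted-lm ANOVA warns on saturated fits; the trend
  # chi-squared itself is unaffected
  ht <- suppressWarnings(stats::prop.trend.test(successes, totals,
                                                score = scores))
  list(statistic = unname(ht$statistic), df = 1L,
       p.value = unname(ht$p.value))
}

#' Trend report across nested conservation sets
#'
#' Counts, per conservation level, how many pairs fall in a TSS-distance bin
#' and runs [proportionTrendTest()] both on the nested (cumulative) sets and
#' on their disjoint complements (deepest level kept as is); the nested sets
#' are not independent, so both numbers are reported and labelled.
#'
#' @param levels ordered factor of conservation levels per pair
#'   (from [assignConservation()]).
#' @param inBin logical per pair: does the pair fall in the focal bin?
#' @return list with a per-level `table` (nested counts) and the two test
#'   results `nested` and `disjoint`.
#' @export
conservationTrendReport <- function(levels, inBin) {
  stopifnot(length(levels) == length(inBin))
  lv <- levels(levels)
  idx <- as.integer(levels)
  nested.tot <- nested.suc <- integer(length(lv))
  disj.tot <- disj.suc <- integer(length(lv))
  for (i in seq_along(lv)) {
    nest <- idx >= i         # level i and deeper (nested set)
    disj <- idx == i         # exactly level i (disjoint complement)
    nested.tot[i] <- sum(nest); nested.suc[i] <- sum(inBin[nest])
    disj.tot[i] <- sum(disj); disj.suc[i] <- sum(inBin[disj])
  }
  tab <- data.frame(set = lv, count_in_bin = nested.suc, total = nested.tot,
                    proportion = ifelse(nested.tot > 0,
                                        nested.suc / nested.tot, NA))
  ok.n <- nested.tot > 0
  ok.d <- disj.tot > 0
  list(table = tab,
       nested = if (sum(ok.n) >= 2)
         proportionTrendTest(nested.suc[ok.n], nested.tot[ok.n],
                             scores = seq_along(lv)[ok.n])
       else NULL,
       disjoint = if (sum(ok.d) >= 2)
         proportionTrendTest(disj.suc[ok.d], disj.tot[ok.d],
                             scores = seq_along(lv)[ok.d])
       else NULL)
}
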