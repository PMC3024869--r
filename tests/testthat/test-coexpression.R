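# Correlation, rank lists, Mutual/Relative Rank, significance profiles,
# pair-set and inter-pair summaries.

test_that("correlatePair handles exact and hand-computed cases", {
  x <- 1:10
  perfect <- correlatePair(x, 2 * x + 1)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$p, 0)

  neg.p <- correlatePair(x, -x, method = "pearson")
  neg.s <- correlatePair(x, -x, method = "spearman")
  expect_equal(neg.p$r, -1)
  expect_equal(neg.s$r, -1)

  # independent arithmetic oracle: covariance / (sd_x * sd_y) by explicit sums
  a <- c(1, 2, 3, 4, 5); b <- c(2, 1, 4, 3, 5)
  n <- 5
  sxy <- sum((a - mean(a)) * (b - mean(b))) / (n - 1)
  r.oracle <- sxy / (sqrt(sum((a - mean(a))^2) / (n - 1)) *
                       sqrt(sum((b - mean(b))^2) / (n - 1)))
  got <- correlatePair(a, b)
  expect_equal(got$r, r.oracle, tolerance = 1e-12)
  t.oracle <- r.oracle * sqrt((n - 2) / (1 - r.oracle^2))
  expect_equal(got$p, 2 * pt(-abs(t.oracle), n - 2), tolerance = 1e-12)

  expect_error(correlatePair(1:2, 2:3), "at least 3")
  flat <- correlatePair(rep(1, 5), 1:5)
  expect_true(flat$undefined)
  expect_true(is.na(flat$r))
  # missing samples are dropped pairwise
  miss <- correlatePair(c(1, 2, NA, 4, 5), c(2, 4, 9, 8, 10))
  expect_equal(miss$n, 4)
})

test_that("rank lists sort by descending correlation with id tie-break", {
  set.seed(5)
  base <- rnorm(20)
  mat <- rbind(A = base + rnorm(20, sd = 0.1),
               B = base + rnorm(20, sd = 0.4),
               C = rnorm(20))
  R <- correlationRanks(mat)
  expect_equal(R["A", "B"], 1L)
  expect_equal(R["A", "C"], 2L)
  expect_true(is.na(R["A", "A"]))

  # exact tie: B and C identical profiles; id order puts B first in A's list
  tied <- rbind(A = c(1, 2, 3, 4, 5), B = c(5, 4, 3, 2, 1),
                C = c(5, 4, 3, 2, 1))
  Rt <- correlationRanks(tied)
  expect_equal(Rt["A", "B"], 1L)
  expect_equal(Rt["A", "C"], 2L)
})

test_that("rank lists match the brute-force sort oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    mat <- matrix(rnorm(8 * 15), nrow = 8,
                  dimnames = list(sprintf("g%02d", 1:8), NULL))
    for (method in c("pearson", "spearman"))
      expect_equal(correlationRanks(mat, method), oracleRanks(mat, method))
  }
})

test_that("mutual rank identities and symmetry hold", {
  ranks <- matrix(c(NA, 4, 9, NA), 2, 2,
                  dimnames = list(c("a", "b"), c("a", "b")))
  ranks["a", "b"] <- 4; ranks["b", "a"] <- 9
  mr <- mutualRank(c("a", "b"), ranks)
  expect_equal(mr$mr, 6)
  expect_equal(mr$rr, 4)

  ranks["a", "b"] <- 1; ranks["b", "a"] <- 1
  best <- mutualRank(c("a", "b"), ranks)
  expect_equal(best$mr, 1)
  expect_equal(best$rr, 1)

  expect_error(mutualRank(c("a", "zz"), ranks), "zz")

  set.seed(2)
  mat <- matrix(rnorm(10 * 12), nrow = 10,
                dimnames = list(sprintf("g%02d", 1:10), NULL))
  R <- correlationRanks(mat)
  ids <- rownames(mat)
  for (i in 1:9) {
    for (j in (i + 1):10) {
      ab <- mutualRank(c(ids[i], ids[j]), R)
      ba <- mutualRank(c(ids[j], ids[i]), R)
      expect_equal(ab$mr, ba$mr)
      expect_equal(ab$rr, ba$rr)
      expect_equal(ab$mr, sqrt(R[ids[i], ids[j]] * R[ids[j], ids[i]]))
      expect_lte(ab$rr, ab$mr)
      expect_lte(ab$mr, max(ab$rank_ab, ab$rank_ba))
    }
  }
})

test_that("significance profile counts match a direct per-dataset scan", {
  set.seed(8)
  mats <- lapply(1:12, function(k) {
    m <- matrix(rnorm(4 * 20), nrow = 4,
                dimnames = list(c("a", "b", "c", "d"), NULL))
    if (k <= 5) m["b", ] <- m["a", ] + rnorm(20, sd = 0.3)    # strong positive
    if (k %in% 6:7) m["b", ] <- -m["a", ] + rnorm(20, sd = 0.3) # strong negative
    m
  })
  prof <- significanceProfile(c("a", "b"), mats, alpha = 0.05)
  sp <- sn <- 0
  for (m in mats) {
    res <- correlatePair(m["a", ], m["b", ])
    if (res$p < 0.05 && res$r > 0) sp <- sp + 1
    if (res$p < 0.05 && res$r < 0) sn <- sn + 1
  }
  expect_equal(prof$spr, sp / 12)
  expect_equal(prof$snr, sn / 12)
  expect_identical(prof$spr + prof$snr, prof$sr)
  expect_equal(prof$n_datasets_used, 12)

  # datasets missing a gene drop out of the denominator
  mats[[1]] <- mats[[1]][c("a", "c", "d"), ]
  prof2 <- significanceProfile(c("a", "b"), mats)
  expect_equal(prof2$n_datasets_used, 11)
  expect_identical(prof2$spr + prof2$snr, prof2$sr)

  expect_error(significanceProfile(c("a", "zz"), mats), "usable")
})

test_that("pair-set summary separates planted pairs from random controls", {
  cfg <- simulationConfig(seed = 21, n_chromosomes = 2,
                          genes_per_chromosome = 150, n_h2h_pairs = 50,
                          n_datasets = 1, samples_per_dataset = 80,
                          rho_pair = 0.6, rho_inter = 0, rho_background = 0)
  sim <- simulateAll(cfg)
  pairs <- detectH2HPairs(sim$genome$genes)
  ds <- sim$datasets[[1]]
  ranks <- correlationRanks(ds)
  planted <- pairsetCoexpression(pairs, ds, ranks = ranks)
  rand <- pairsetCoexpression(
    sampleRandomPairs(rownames(ds), 100, seed = 3), ds, ranks = ranks)
  expect_gt(planted$summary$mean[planted$summary$metric == "r"],
            rand$summary$mean[rand$summary$metric == "r"])
  expect_lt(planted$summary$mean[planted$summary$metric == "mr"],
            rand$summary$mean[rand$summary$metric == "mr"])

  single <- PairSet(rbind(pairTable(pairs)[1, ]))
  one <- pairsetCoexpression(single, ds, ranks = ranks)
  expect_equal(one$summary$mean[one$summary$metric == "r"], one$pairs$r[1])

  expect_error(pairsetCoexpression(PairSet(matrix(character(0), ncol = 2)),
                                   ds, ranks = ranks), "empty")
  missing.set <- PairSet(rbind(c("nope1", "nope2")))
  expect_error(suppressMessages(
    pairsetCoexpression(missing.set, ds, ranks = ranks)), "no pair")
})

test_that("inter-pair analysis excludes the actual pairs and finds rho_inter", {
  set.seed(4)
  mat <- matrix(rnorm(4 * 30), nrow = 4,
                dimnames = list(c("a", "b", "c", "d"), NULL))
  actual <- PairSet(rbind(c("a", "b"), c("c", "d")))
  res <- interpairCoexpression(c("a", "b", "c", "d"), actual, mat)
  expect_equal(res$n_pairs, 4)   # C(4,2) - 2
  expect_equal(res$n_excluded, 2)
  none <- interpairCoexpression(c("a", "b", "c", "d"),
                                PairSet(matrix(character(0), ncol = 2)), mat)
  expect_equal(none$n_pairs, 6)

  cfg <- simulationConfig(seed = 31, n_chromosomes = 2,
                          genes_per_chromosome = 150, n_h2h_pairs = 60,
                          n_datasets = 1, samples_per_dataset = 100,
                          rho_pair = 0.6, rho_inter = 0.2, rho_background = 0)
  sim <- simulateAll(cfg)
  pairs <- detectH2HPairs(sim$genome$genes)
  ds <- sim$datasets[[1]]
  ranks <- correlationRanks(ds)
  h2h.genes <- unique(unlist(pairTable(pairs)))
  cross <- interpairCoexpression(h2h.genes, pairs, ds, ranks = ranks)
  rand <- pairsetCoexpression(
    sampleRandomPairs(rownames(ds), 300, seed = 5), ds, ranks = ranks)
  expect_gt(cross$summary$mean[cross$summary$metric == "r"],
            rand$summary$mean[rand$summary$metric == "r"])
})
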