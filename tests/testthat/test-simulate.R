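# Synthetic-data generator: config validation, genome round-trip, planted
# correlations, TF sharing and co-annotation effects, determinism.

test_that("configuration validation rejects impossible settings", {
  expect_error(simulationConfig(), "seed")
  expect_error(simulationConfig(seed = 1, rho_pair = 0.3, rho_inter = 0.5),
               "positive semi-definite")
  expect_error(simulationConfig(seed = 1, rho_background = 0.3,
                                rho_inter = 0.1),
               "positive semi-definite")
  expect_error(simulationConfig(seed = 1, n_h2h_pairs = 2000,
                                n_chromosomes = 2,
                                genes_per_chromosome = 100),
               "infeasible packing")
  expect_error(simulationConfig(seed = 1, tf_pool_size = 2, tfs_per_gene = 3),
               "tf_pool_size")
  expect_error(simulationConfig(seed = 1, p_share = 1.2), "\\[0, 1\\]")
  expect_error(simulationConfig(seed = 1, rho_pair = c(0.3, 0.4)),
               "per conservation level")
})

test_that("planted pairs are exactly the detectable divergent pairs", {
  cfg <- simulationConfig(seed = 17, n_chromosomes = 3,
                          genes_per_chromosome = 200, n_h2h_pairs = 60)
  g <- simulateGenome(cfg)
  det <- detectH2HPairs(g$genes)
  expect_setequal(pairKeys(det), g$truth$key)
  # distances agree with the truth table
  df <- as.data.frame(det)
  truth.d <- setNames(g$truth$tss_distance, g$truth$key)
  expect_equal(unname(truth.d[pairKeys(det)]), df$tss_distance)

  none <- simulateGenome(simulationConfig(seed = 2, n_h2h_pairs = 0,
                                          n_chromosomes = 2,
                                          genes_per_chromosome = 50))
  expect_length(detectH2HPairs(none$genes), 0)

  short <- simulateGenome(simulationConfig(
    seed = 3, n_h2h_pairs = 40, n_chromosomes = 2,
    genes_per_chromosome = 100,
    tss_distance_mixture = data.frame(lo = 0, hi = 100, weight = 1)))
  expect_true(all(short$truth$tss_distance > 0 &
                    short$truth$tss_distance <= 100))
})

test_that("conservation levels are nested and consistent with ortholog output", {
  cfg <- simulationConfig(seed = 23, n_chromosomes = 3,
                          genes_per_chromosome = 200, n_h2h_pairs = 80)
  g <- simulateGenome(cfg)
  pairs <- detectH2HPairs(g$genes)
  sp.pairs <- lapply(g$species, detectH2HPairs)
  lv <- assignConservation(pairs, cfg$species, g$orthologs, sp.pairs)
  truth.lv <- setNames(as.character(g$truth$level), g$truth$key)
  expect_equal(unname(truth.lv[names(lv)]), as.character(lv))
})

test_that("same seed gives identical simulations", {
  cfg <- simulationConfig(seed = 99, n_chromosomes = 2,
                          genes_per_chromosome = 80, n_h2h_pairs = 20,
                          n_datasets = 2, samples_per_dataset = 20)
  a <- simulateAll(cfg)
  b <- simulateAll(cfg)
  expect_identical(a$datasets, b$datasets)
  expect_identical(divergon:::.geneTable(a$genome$genes),
                   divergon:::.geneTable(b$genome$genes))
  expect_identical(a$truth, b$truth)
  expect_identical(a$tfmap@targets, b$tfmap@targets)
  expect_identical(annotationTable(a$annotations),
                   annotationTable(b$annotations))
})

test_that("planted expression correlations land near their targets", {
  cfg <- simulationConfig(seed = 41, n_chromosomes = 2,
                          genes_per_chromosome = 200, n_h2h_pairs = 100,
                          n_datasets = 1, samples_per_dataset = 150,
                          rho_pair = 0.6, rho_inter = 0, rho_background = 0)
  sim <- simulateAll(cfg)
  ds <- sim$datasets[[1]]
  r <- vapply(seq_len(nrow(sim$truth)), function(i)
    cor(ds[sim$truth$minus_gene[i], ], ds[sim$truth$plus_gene[i], ]), 0)
  se <- (1 - 0.6^2) / sqrt(150) / sqrt(100)
  expect_lt(abs(mean(r) - 0.6), 4 * se + 0.01)
})

test_that("forced TF sharing and chance sharing both behave", {
  cfg1 <- simulationConfig(seed = 61, n_chromosomes = 2,
                           genes_per_chromosome = 100, n_h2h_pairs = 40,
                           p_tf_assoc = 1, p_share = 1)
  sim1 <- simulateAll(cfg1)
  rec <- tfSharing(tfAssociatedPairs(detectH2HPairs(sim1$genome$genes),
                                     sim1$tfmap), sim1$tfmap)
  expect_equal(nrow(rec), 40)
  expect_true(all(rec$n_shared >= 1))

  cfg0 <- simulationConfig(seed = 62, n_chromosomes = 3,
                           genes_per_chromosome = 300, n_h2h_pairs = 400,
                           p_tf_assoc = 1, p_share = 0)
  sim0 <- simulateAll(cfg0)
  rec0 <- tfSharing(tfAssociatedPairs(detectH2HPairs(sim0$genome$genes),
                                      sim0$tfmap), sim0$tfmap)
  p.chance <- oracleShareChance(cfg0$tf_pool_size, cfg0$tfs_per_gene)
  se <- sqrt(p.chance * (1 - p.chance) / nrow(rec0))
  expect_lt(abs(mean(rec0$n_shared >= 1) - p.chance), 3 * se + 1e-6)
})

test_that("co-annotation forcing drives pair similarity to 1", {
  cfg <- simulationConfig(seed = 71, n_chromosomes = 2,
                          genes_per_chromosome = 100, n_h2h_pairs = 30,
                          p_coannotate = 1)
  sim <- simulateAll(cfg)
  prop <- propagateAnnotations(sim$dag, sim$annotations)
  ic <- suppressMessages(informationContent(sim$dag, prop))
  fs <- pairFunctionalSimilarity(sim$dag, ic, sim$annotations,
                                 detectH2HPairs(sim$genome$genes))
  expect_true(all(!is.na(fs$sim_rep)))
  expect_true(all(fs$sim_rep == 1))
  # and the DAG itself validates
  expect_true(validObject(sim$dag))
})

test_that("simulation bundles serialize to plain text and read back", {
  cfg <- simulationConfig(seed = 81, n_chromosomes = 2,
                          genes_per_chromosome = 60, n_h2h_pairs = 15,
                          n_datasets = 2, samples_per_dataset = 10)
  sim <- simulateAll(cfg)
  dir <- withr::local_tempdir()
  writeSimulation(sim, dir)
  ann <- readAnnotation(file.path(dir, "annotation.tsv"), "tsv")
  expect_equal(divergon:::.geneTable(ann)[order(divergon:::.geneTable(ann)$gene_id), ],
               divergon:::.geneTable(sim$genome$genes)[
                 order(divergon:::.geneTable(sim$genome$genes)$gene_id), ],
               ignore_attr = TRUE)
  mats <- readExpressionManifest(file.path(dir, "manifest.tsv"))
  expect_equal(names(mats), names(sim$datasets))
  expect_equal(mats$ds1, sim$datasets$ds1, tolerance = 1e-6)
  tfmap <- readTFMap(file.path(dir, "tf.tsv"))
  expect_identical(tfmap@targets[sort(names(tfmap@targets))],
                   sim$tfmap@targets[sort(names(sim$tfmap@targets))])
  dag <- readOBO(file.path(dir, "ontology.obo"))
  expect_setequal(dag@terms, sim$dag@terms)
  ann2 <- readGeneAnnotations(file.path(dir, "annotations.tsv"))
  expect_equal(nrow(annotationTable(ann2)),
               nrow(annotationTable(sim$annotations)))
  om <- readOrthologMap(file.path(dir, "orthologs_mouse.tsv"))
  expect_identical(om, sim$genome$orthologs$mouse)
})
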