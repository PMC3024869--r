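# Ontology parsing, propagation, information content, minimum subsumer,
# Resnik/Lin similarity, gene-pair similarity and the random control.

test_that("OBO subset parsing and writing round-trip a DAG", {
  dag <- toyDag()
  path <- withr::local_tempfile(fileext = ".obo")
  writeOBO(dag, path)
  back <- readOBO(path)
  expect_setequal(back@terms, dag@terms)
  expect_equal(back@parents[sort(names(back@parents))],
               dag@parents[sort(names(dag@parents))])
  expect_equal(back@roots, dag@roots)

  # hand-written stanza text with comments and an obsolete term
  txt <- c("format-version: 1.2", "",
           "[Term]", "id: X:1", "name: root", "namespace: XX", "",
           "[Term]", "id: X:2", "name: child", "namespace: XX",
           "is_a: X:1 ! root", "",
           "[Term]", "id: X:3", "name: gone", "namespace: XX",
           "is_a: X:1", "is_obsolete: true", "",
           "[Typedef]", "id: part_of")
  path2 <- withr::local_tempfile(fileext = ".obo")
  writeLines(txt, path2)
  dag2 <- readOBO(path2)
  expect_setequal(dag2@terms, c("X:1", "X:2"))
  expect_equal(dag2@parents[["X:2"]], "X:1")
})

test_that("true-path propagation closes upward and is idempotent", {
  dag <- toyDag()
  raw <- AnnotationSet(data.frame(gene_id = "g1", term_id = "BP:g",
                                  subsystem = "BP"))
  prop <- propagateAnnotations(dag, raw)
  expect_setequal(annotationTable(prop)$term_id,
                  c("BP:g", "BP:c", "BP:a", "BP:root"))
  again <- propagateAnnotations(dag, prop)
  expect_equal(annotationTable(again)[order(annotationTable(again)$term_id), ],
               annotationTable(prop)[order(annotationTable(prop)$term_id), ],
               ignore_attr = TRUE)

  bad <- AnnotationSet(data.frame(gene_id = "g1", term_id = "BP:nope",
                                  subsystem = "BP"))
  expect_error(propagateAnnotations(dag, bad), "BP:nope")
})

test_that("propagation matches the recursive ancestor-union oracle", {
  for (seed in 1:3) {
    dag <- randomDag(15, seed = seed)
    ann <- randomAnnotations(dag, nGenes = 10, seed = seed + 50)
    prop <- annotationTable(propagateAnnotations(dag, ann))
    raw <- annotationTable(ann)
    for (g in unique(raw$gene_id)) {
      want <- sort(unique(unlist(lapply(raw$term_id[raw$gene_id == g],
                                        function(t) oracleAncestors(dag@parents, t)))))
      expect_equal(sort(prop$term_id[prop$gene_id == g]), want)
    }
    # ancestor helper agrees with oracle on every term
    anc <- termAncestors(dag)
    for (t in dag@terms)
      expect_equal(sort(anc[[t]]), oracleAncestors(dag@parents, t))
  }
})

test_that("information content follows the annotation counts", {
  dag <- toyDag()
  prop <- propagateAnnotations(dag, toyAnnotations())
  ic <- suppressMessages(informationContent(dag, prop))
  icv <- setNames(ic$ic, ic$term)
  expect_equal(unname(icv["BP:root"]), 0)          # p(root) = 1
  # hand counts after closure: 8 genes at root; a covers g1,g2,g3,g5,g6 = 5
  expect_equal(unname(icv["BP:a"]), -log(5 / 8))
  expect_equal(unname(icv["BP:c"]), -log(2 / 8))
  expect_equal(unname(icv["BP:g"]), -log(1 / 8))
  expect_equal(unname(icv["BP:f"]), -log(2 / 8))
  # term annotating 5 of 10 genes would give IC = ln 2: check the formula shape
  expect_equal(unname(icv["BP:b"]), -log(4 / 8))
  expect_equal(unname(icv["BP:b"]), log(2))

  expect_error(informationContent(dag, toyAnnotations()), "propagated")
  # IC monotone along every edge
  for (t in dag@terms) {
    for (p in dag@parents[[t]]) {
      if (t %in% names(icv) && p %in% names(icv))
        expect_gte(icv[[t]], icv[[p]] - 1e-12)
    }
  }
})

test_that("minimum subsumer and Lin match identities and arithmetic", {
  dag <- toyDag()
  prop <- propagateAnnotations(dag, toyAnnotations())
  ic <- suppressMessages(informationContent(dag, prop))
  icv <- setNames(ic$ic, ic$term)

  self <- minimumSubsumer(dag, ic, "BP:c", "BP:c")
  expect_equal(self$term, "BP:c")
  expect_equal(self$ic_ms, unname(icv["BP:c"]))

  sib <- minimumSubsumer(dag, ic, "BP:c", "BP:d")
  expect_equal(sib$term, "BP:a")

  expect_equal(linSimilarity(dag, ic, "BP:c", "BP:c"), 1)
  # only the root subsumes the two main branches' exclusive leaves
  expect_equal(linSimilarity(dag, ic, "BP:d", "BP:e"), 0)
  expect_equal(linSimilarity(dag, ic, "BP:root", "BP:root"), 0)

  # arithmetic: IC(t1) = IC(t2) = ln 4, IC(ms) = ln 2 -> Lin = 0.5
  expect_equal(unname(icv["BP:c"]), log(4))
  expect_equal(linSimilarity(dag, ic, "BP:c", "BP:f"),
               2 * log(8 / 5) / (2 * log(4)))  # ms is BP:a here
  ms.cf <- minimumSubsumer(dag, ic, "BP:c", "BP:f")
  expect_equal(ms.cf$term, "BP:a")

  both <- GoDag(
    terms = c(dag@terms, "MF:r", "MF:x"),
    parents = c(dag@parents, list(`MF:x` = "MF:r")),
    namespace = c(dag@namespace, c(`MF:r` = "MF", `MF:x` = "MF")))
  expect_error(minimumSubsumer(both, ic, "BP:c", "MF:x"), "subsystem")
  expect_error(minimumSubsumer(dag, ic, "BP:c", "nope"), "not in DAG")
})

test_that("subsumer and Lin agree with brute force on random DAGs", {
  for (seed in 1:2) {
    dag <- randomDag(20, seed = seed + 10)
    ann <- randomAnnotations(dag, nGenes = 15, seed = seed + 60, perGene = 3)
    prop <- propagateAnnotations(dag, ann)
    ic <- suppressMessages(informationContent(dag, prop))
    icv <- setNames(ic$ic, ic$term)
    anc <- termAncestors(dag)
    terms <- ic$term
    for (t1 in terms) {
      for (t2 in terms) {
        got <- minimumSubsumer(dag, ic, t1, t2, ancestors = anc)
        want <- oracleMinSubsumer(dag@parents, icv, t1, t2)
        expect_equal(got$ic_ms, want$ic)
        lin.got <- linSimilarity(dag, ic, t1, t2, ancestors = anc)
        lin.want <- oracleLin(dag@parents, icv, t1, t2)
        expect_equal(lin.got, lin.want)
        expect_true(lin.got >= 0 && lin.got <= 1 + 1e-12)
        # Resnik bounded by the smaller IC
        expect_lte(got$ic_ms, min(icv[[t1]], icv[[t2]]) + 1e-12)
        # symmetry
        expect_equal(lin.got, linSimilarity(dag, ic, t2, t1, ancestors = anc))
      }
    }
  }
})

test_that("gene-pair similarity combines cross terms as requested", {
  dag <- toyDag()
  ann <- toyAnnotations()
  prop <- propagateAnnotations(dag, ann)
  ic <- suppressMessages(informationContent(dag, prop))
  # shared identical informative term -> 1 under max
  two <- AnnotationSet(data.frame(
    gene_id = c("x", "y", "y"), term_id = c("BP:c", "BP:c", "BP:e"),
    subsystem = "BP"))
  expect_equal(genePairSimilarity(dag, ic, two, "x", "y", "BP"), 1)
  # unannotated gene -> undefined
  expect_true(is.na(genePairSimilarity(dag, ic, two, "x", "zz", "BP")))

  # brute force over the 2 x 3 cross pairs, all combine rules
  g1.terms <- c("BP:c", "BP:d")
  g2.terms <- c("BP:e", "BP:f", "BP:g")
  multi <- AnnotationSet(data.frame(
    gene_id = c("u", "u", "v", "v", "v"),
    term_id = c(g1.terms, g2.terms), subsystem = "BP"))
  icv <- setNames(ic$ic, ic$term)
  M <- outer(g1.terms, g2.terms,
             Vectorize(function(a, b) oracleLin(dag@parents, icv, a, b)))
  expect_equal(genePairSimilarity(dag, ic, multi, "u", "v", "BP", "max"),
               max(M))
  expect_equal(genePairSimilarity(dag, ic, multi, "u", "v", "BP", "mean"),
               mean(M))
  expect_equal(genePairSimilarity(dag, ic, multi, "u", "v", "BP", "bma"),
               mean(c(apply(M, 1, max), apply(M, 2, max))))
})

test_that("representative similarity takes the defined maximum", {
  expect_equal(representativeSimilarity(c(BP = 0.3, MF = 0.7, CC = NA)), 0.7)
  expect_equal(representativeSimilarity(c(0.4, 0.4, 0.4)), 0.4)
  expect_equal(representativeSimilarity(c(NA, NA, 0.51)), 0.51)
  expect_true(is.na(representativeSimilarity(c(NA_real_, NA_real_))))
})

test_that("threshold table means climb when similarity tracks correlation", {
  set.seed(77)
  pcc <- runif(300, -0.5, 1)
  funcsim <- pmin(1, pmax(0, 0.2 + 0.5 * pcc + rnorm(300, sd = 0.05)))
  tab <- funcsimByCoexpressionThreshold(funcsim, pcc, c(0, 0.3, 0.6))
  expect_true(all(diff(tab$mean_funcsim) > 0))
  expect_equal(tab$n[1], sum(pcc > 0))

  overall <- funcsimByCoexpressionThreshold(funcsim, pcc, -1)
  expect_equal(overall$mean_funcsim, mean(funcsim))

  empty <- funcsimByCoexpressionThreshold(funcsim, pcc, c(1.5, 2))
  expect_equal(empty$n, c(0L, 0L))
  expect_true(all(is.na(empty$mean_funcsim)))

  expect_error(funcsimByCoexpressionThreshold(funcsim, pcc, c(0.5, 0.1)),
               "ascending")
})

test_that("random functional-similarity control is seeded and discriminates", {
  cfg <- simulationConfig(seed = 55, n_chromosomes = 2,
                          genes_per_chromosome = 100, n_h2h_pairs = 40,
                          n_datasets = 1, samples_per_dataset = 30,
                          p_coannotate = 0.9)
  sim <- simulateAll(cfg)
  prop <- propagateAnnotations(sim$dag, sim$annotations)
  ic <- suppressMessages(informationContent(sim$dag, prop))
  null1 <- randomFuncsimControl(sim$dag, ic, sim$annotations, nPairs = 30,
                                nIter = 100, seed = 9)
  null2 <- randomFuncsimControl(sim$dag, ic, sim$annotations, nPairs = 30,
                                nIter = 100, seed = 9)
  expect_length(null1, 100)
  expect_identical(null1, null2)

  planted <- pairFunctionalSimilarity(sim$dag, ic, sim$annotations,
                                      detectH2HPairs(sim$genome$genes))
  obs <- mean(planted$sim_rep, na.rm = TRUE)
  expect_gt(obs, quantile(null1, 0.95))

  expect_error(randomFuncsimControl(sim$dag, ic,
                                    AnnotationSet(data.frame(
                                      gene_id = "g", term_id = "BP:0001",
                                      subsystem = "BP")),
                                    nPairs = 5, nIter = 10, seed = 1),
               "not enough")
})
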