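# Seeded synthetic-data generator: genome annotations with planted divergent
# pairs and nested conservation, multi-dataset expression with planted
# correlation blocks, TF maps with controlled sharing, and a toy ontology
# with controlled co-annotation.

.perLevel <- function(x, nLevels, what) {
  if (length(x) == 1) return(rep(x, nLevels))
  if (length(x) != nLevels)
    stop(what, " must be a scalar or one value per conservation level (",
         nLevels, ")")
  x
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. Effect
#' sizes with one value per conservation level (`rho_pair`, `p_share`,
#' `p_coannotate`) may be given as scalars, which are recycled. The implied
#' correlation structure must satisfy
#' `0 <= rho_background <= rho_inter <= min(rho_pair) <= 1`, the positive
#' semi-definiteness condition of the nested factor construction used by
#' [simulateExpression()].
#'
#' @param seed integer random seed (mandatory).
#' @param n_chromosomes,genes_per_chromosome genome size (default 5 x 600 =
#'   3000 genes).
#' @param n_h2h_pairs number of planted divergent pairs (default 500).
#' @param tss_distance_mixture data.frame with columns `lo`, `hi`, `weight`:
#'   planted TSS distances are drawn uniformly from `(lo, hi]` with the given
#'   mixture weights (negative values plant overlapping pairs).
#' @param species partner species from closest to most distant.
#' @param conservation_probs named list (per species) of length-2 probability
#'   vectors `c(short, long)`: chain probability that a pair conserved so far
#'   stays conserved in this species, for pairs with TSS distance in (0, 100]
#'   (`short`) versus all others (`long`). Distance dependence plants the
#'   short-distance conservation trend.
#' @param n_datasets,samples_per_dataset expression collection size.
#' @param rho_pair within-pair correlation, per conservation level.
#' @param rho_inter correlation between head-to-head genes from different
#'   pairs.
#' @param rho_background correlation between background genes.
#' @param marginal `"normal"` or `"lognormal"` expression marginals.
#' @param tf_pool_size,tfs_per_gene,p_tf_assoc,p_share TF map: pool size, TFs
#'   drawn per associated gene, per-gene association probability, and the
#'   per-level probability that an associated planted pair is forced to share
#'   at least one TF.
#' @param dag_depth,branching,terms_per_gene,p_annotate,p_coannotate ontology:
#'   tree depth and branching per subsystem, direct terms per annotated gene,
#'   per-gene per-subsystem annotation probability, and the per-level
#'   probability that a planted pair is co-annotated to a shared deep term.
#' @return a validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed,
                             n_chromosomes = 5,
                             genes_per_chromosome = 600,
                             n_h2h_pairs = 500,
                             tss_distance_mixture = data.frame(
                               lo = c(-200, 0, 100, 200, 400),
                               hi = c(0, 100, 200, 400, 1000),
                               weight = c(0.10, 0.15, 0.20, 0.20, 0.35)),
                             species = c("mouse", "chicken", "fugu"),
                             conservation_probs = list(
                               mouse = c(short = 0.35, long = 0.10),
                               chicken = c(short = 0.50, long = 0.25),
                               fugu = c(short = 0.50, long = 0.25)),
                             n_datasets = 4,
                             samples_per_dataset = 100,
                             rho_pair = c(0.50, 0.60, 0.70, 0.80),
                             rho_inter = 0.20,
                             rho_background = 0,
                             marginal = c("normal", "lognormal"),
                             tf_pool_size = 300,
                             tfs_per_gene = 3,
                             p_tf_assoc = 0.8,
                             p_share = c(0.10, 0.35, 0.70, 0.90),
                             dag_depth = 4,
                             branching = 3,
                             terms_per_gene = 2,
                             p_annotate = 0.8,
                             p_coannotate = c(0.25, 0.55, 0.85, 0.95)) {
  if (missing(seed)) stop("a seed is required")
  marginal <- match.arg(marginal)
  nlv <- length(species) + 1L
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    n_h2h_pairs = as.integer(n_h2h_pairs),
    tss_distance_mixture = tss_distance_mixture,
    species = species,
    conservation_probs = conservation_probs,
    n_datasets = as.integer(n_datasets),
    samples_per_dataset = as.integer(samples_per_dataset),
    rho_pair = .perLevel(rho_pair, nlv, "rho_pair"),
    rho_inter = rho_inter,
    rho_background = rho_background,
    marginal = marginal,
    tf_pool_size = as.integer(tf_pool_size),
    tfs_per_gene = as.integer(tfs_per_gene),
    p_tf_assoc = p_tf_assoc,
    p_share = .perLevel(p_share, nlv, "p_share"),
    dag_depth = as.integer(dag_depth),
    branching = as.integer(branching),
    terms_per_gene = as.integer(terms_per_gene),
    p_annotate = p_annotate,
    p_coannotate = .perLevel(p_coannotate, nlv, "p_coannotate"))
  probs <- c(cfg$p_tf_assoc, cfg$p_share, cfg$p_annotate, cfg$p_coannotate,
             unlist(conservation_probs, use.names = FALSE))
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (!(cfg$rho_background >= 0 && cfg$rho_background <= cfg$rho_inter &&
        cfg$rho_inter <= min(cfg$rho_pair) && max(cfg$rho_pair) <= 1))
    stop("implied correlation structure is not positive semi-definite: need ",
         "0 <= rho_background <= rho_inter <= min(rho_pair) <= 1")
  if (2L * cfg$n_h2h_pairs > cfg$n_chromosomes * cfg$genes_per_chromosome)
    stop("infeasible packing: ", cfg$n_h2h_pairs, " pairs do not fit into ",
         cfg$n_chromosomes * cfg$genes_per_chromosome, " genes")
  if (cfg$tf_pool_size < cfg$tfs_per_gene)
    stop("tf_pool_size must be at least tfs_per_gene")
  if (cfg$dag_depth < 2) stop("dag_depth must be at least 2")
  if (abs(sum(tss_distance_mixture$weight)) < .Machine$double.eps)
    stop("tss_distance_mixture weights must not all be zero")
  for (s in species)
    if (is.null(conservation_probs[[s]]) || length(conservation_probs[[s]]) != 2)
      stop("conservation_probs must supply c(short, long) for species ", s)
  class(cfg) <- "SimulationConfig"
  cfg
}

# lay one chromosome's worth of units (pair or filler) onto coordinates
.layoutChromosome <- function(chrom, units) {
  cursor <- 10000L
  rows <- list()
  for (u in seq_along(units)) {
    gap <- sample(4000:8000, 1)
    if (units[[u]]$type == "pair") {
      p <- units[[u]]
      len1 <- sample(500:3000, 1); len2 <- sample(500:3000, 1)
      m.tes <- cursor
      m.tss <- cursor + len1
      p.tss <- m.tss + p$d
      p.tes <- p.tss + len2
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = c(p$minus, p$plus), chrom = chrom,
        strand = c("-", "+"),
        tss = c(m.tss, p.tss), tes = c(m.tes, p.tes))
      cursor <- max(m.tss, p.tes) + gap
    } else {
      g <- units[[u]]
      len <- sample(500:3000, 1)
      if (g$strand == "+") {
        tss <- cursor; tes <- cursor + len
      } else {
        tes <- cursor; tss <- cursor + len
      }
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = g$id, chrom = chrom, strand = g$strand,
        tss = tss, tes = tes)
      cursor <- cursor + len + gap
    }
  }
  do.call(rbind, rows)
}

#' Simulate a genome with planted head-to-head pairs and conservation
#'
#' Places `n_h2h_pairs` divergent pairs (TSS distances from the configured
#' mixture) and filler genes on `n_chromosomes` chromosomes, spaced so that
#' the planted pairs are exactly the divergent pairs within 1 kb. Each pair
#' draws a nested conservation level from the distance-dependent Bernoulli
#' chain; partner-species annotations and one-to-one ortholog maps are
#' emitted consistent with the drawn levels (conserved pairs appear as
#' divergent pairs in the partner species; a fraction of lost pairs keep
#' orthologs that are *not* head-to-head arranged, plus scattered filler
#' orthologs).
#'
#' @param config a [simulationConfig()].
#' @return list with `genes` (focal GRanges), `truth` (data.frame:
#'   `minus_gene`, `plus_gene`, `chrom`, `tss_distance`, `level`, `key`),
#'   `species` (list of partner GRanges), `orthologs` (list of named
#'   vectors), `levels` (level labels) and `config`.
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  lv <- conservationLevels(config$species)
  npairs <- config$n_h2h_pairs
  total.genes <- config$n_chromosomes * config$genes_per_chromosome
  nfiller <- total.genes - 2L * npairs

  mix <- config$tss_distance_mixture
  bin <- sample.int(nrow(mix), npairs, replace = TRUE, prob = mix$weight)
  d <- as.integer(mix$lo[bin] + floor(stats::runif(npairs) *
                                        (mix$hi[bin] - mix$lo[bin])) + 1L)
  short <- d > 0 & d <= 100

  # nested conservation chain, distance-dependent
  depth <- rep(0L, npairs)
  alive <- rep(TRUE, npairs)
  for (i in seq_along(config$species)) {
    pr <- config$conservation_probs[[config$species[i]]]
    p <- ifelse(short, pr[["short"]], pr[["long"]])
    alive <- alive & (stats::runif(npairs) < p)
    depth[alive] <- i
  }
  level <- factor(lv[depth + 1L], levels = lv, ordered = TRUE)

  minus.ids <- sprintf("g%05d", seq_len(npairs) * 2L - 1L)
  plus.ids <- sprintf("g%05d", seq_len(npairs) * 2L)
  filler.ids <- sprintf("f%05d", seq_len(nfiller))

  units <- c(
    lapply(seq_len(npairs), function(i)
      list(type = "pair", minus = minus.ids[i], plus = plus.ids[i], d = d[i])),
    lapply(seq_len(nfiller), function(i)
      list(type = "filler", id = filler.ids[i],
           strand = sample(c("+", "-"), 1))))
  units <- units[sample.int(length(units))]

  # chunk units into chromosomes by gene count
  chrom.of <- integer(length(units))
  cur.chrom <- 1L; cur.count <- 0L
  for (u in seq_along(units)) {
    sz <- if (units[[u]]$type == "pair") 2L else 1L
    if (cur.count + sz > config$genes_per_chromosome &&
        cur.chrom < config$n_chromosomes) {
      cur.chrom <- cur.chrom + 1L; cur.count <- 0L
    }
    chrom.of[u] <- cur.chrom
    cur.count <- cur.count + sz
  }
  ann <- do.call(rbind, lapply(seq_len(config$n_chromosomes), function(k)
    .layoutChromosome(paste0("chr", k), units[chrom.of == k])))

  pair.chrom <- character(npairs)
  for (u in seq_along(units)) {
    if (units[[u]]$type == "pair")
      pair.chrom[match(units[[u]]$minus, minus.ids)] <-
        paste0("chr", chrom.of[u])
  }
  truth <- data.frame(minus_gene = minus.ids, plus_gene = plus.ids,
                      chrom = pair.chrom,
                      tss_distance = d,
                      level = level,
                      key = canonicalPairKey(minus.ids, plus.ids))

  # partner species: conserved pairs stay divergent; some lost pairs keep
  # scattered (non-divergent) orthologs; some fillers get orthologs too
  species.ann <- list(); orthologs <- list()
  for (i in seq_along(config$species)) {
    s <- config$species[i]
    tag <- substr(s, 1, 1)
    units.s <- list()
    om.focal <- character(0); om.partner <- character(0)
    conserved <- depth >= i
    for (j in which(conserved)) {
      pm <- paste0(tag, "_", minus.ids[j]); pp <- paste0(tag, "_", plus.ids[j])
      units.s[[length(units.s) + 1]] <- list(type = "pair", minus = pm,
                                             plus = pp, d = d[j])
      om.focal <- c(om.focal, minus.ids[j], plus.ids[j])
      om.partner <- c(om.partner, pm, pp)
    }
    lost <- which(depth == i - 1L)
    keep.orth <- lost[stats::runif(length(lost)) < 0.3]
    for (j in keep.orth) {
      for (g in c(minus.ids[j], plus.ids[j])) {
        pg <- paste0(tag, "_", g)
        units.s[[length(units.s) + 1]] <- list(type = "filler", id = pg,
                                               strand = "+")
        om.focal <- c(om.focal, g); om.partner <- c(om.partner, pg)
      }
    }
    orth.filler <- filler.ids[stats::runif(nfiller) < 0.3]
    for (g in orth.filler) {
      pg <- paste0(tag, "_", g)
      units.s[[length(units.s) + 1]] <- list(type = "filler", id = pg,
                                             strand = "+")
      om.focal <- c(om.focal, g); om.partner <- c(om.partner, pg)
    }
    if (length(units.s) > 0) {
      units.s <- units.s[sample.int(length(units.s))]
      n.chrom.s <- config$n_chromosomes
      chrom.s <- rep(seq_len(n.chrom.s), length.out = length(units.s))
      ann.s <- do.call(rbind, lapply(seq_len(n.chrom.s), function(k) {
        us <- units.s[chrom.s == k]
        if (length(us) == 0) return(NULL)
        .layoutChromosome(paste0("chr", k), us)
      }))
    } else {
      ann.s <- data.frame(gene_id = character(0), chrom = character(0),
                          strand = character(0), tss = integer(0),
                          tes = integer(0))
    }
    species.ann[[s]] <- .asGRanges(ann.s)
    orthologs[[s]] <- orthologMap(om.focal, om.partner)
  }

  list(genes = .asGRanges(ann), truth = truth, species = species.ann,
       orthologs = orthologs, levels = lv, config = config)
}

#' Simulate expression datasets with planted correlation blocks
#'
#' Draws `n_datasets` independent genes x samples matrices from a nested
#' one-factor construction: all genes load on a global factor
#' (`rho_background`), head-to-head genes additionally on a shared factor
#' (`rho_inter`), and each planted pair on its own factor, topped up to the
#' pair's conservation-level `rho_pair`. Marginals are standard normal (a
#' log-normal option exists for realism); the analyses downstream are
#' correlation- and rank-based, so marginals are immaterial to them.
#'
#' @param config a [simulationConfig()].
#' @param genome output of [simulateGenome()] (for gene ids and the truth
#'   table).
#' @return named list of genes x samples matrices (`ds1`, `ds2`, ...).
#' @export
simulateExpression <- function(config, genome) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  gt <- .geneTable(genome$genes)
  genes <- gt$gene_id
  m <- length(genes)
  truth <- genome$truth
  npairs <- nrow(truth)

  pair.of <- integer(m); names(pair.of) <- genes
  pair.of[truth$minus_gene] <- seq_len(npairs)
  pair.of[truth$plus_gene] <- seq_len(npairs)
  in.pair <- pair.of > 0L

  g <- sqrt(config$rho_background)
  a <- sqrt(config$rho_inter - config$rho_background)
  rho.lv <- config$rho_pair[as.integer(truth$level)]
  b.gene <- numeric(m)
  b.gene[in.pair] <- sqrt(rho.lv - config$rho_inter)[pair.of[in.pair]]
  la <- ifelse(in.pair, a, 0)
  sigma <- sqrt(pmax(0, 1 - g^2 - la^2 - b.gene^2))

  n <- config$samples_per_dataset
  out <- vector("list", config$n_datasets)
  for (k in seq_len(config$n_datasets)) {
    F0 <- stats::rnorm(n)
    F1 <- stats::rnorm(n)
    Gp <- matrix(stats::rnorm(n * npairs), n, npairs)
    E <- matrix(stats::rnorm(n * m), n, m)
    X <- outer(F0, rep(g, m)) + outer(F1, la) +
      E * matrix(sigma, n, m, byrow = TRUE)
    if (npairs > 0)
      X <- X + Gp[, pmax(pair.of, 1L), drop = FALSE] *
        matrix(b.gene, n, m, byrow = TRUE)
    if (config$marginal == "lognormal") X <- exp(X)
    mat <- t(X)
    dimnames(mat) <- list(genes, sprintf("s%03d", seq_len(n)))
    out[[k]] <- mat
  }
  names(out) <- sprintf("ds%d", seq_len(config$n_datasets))
  out
}

#' Simulate a TF association map with controlled sharing
#'
#' Each gene is TF-associated with probability `p_tf_assoc` and draws
#' `tfs_per_gene` distinct TFs from the pool. For a planted pair whose two
#' genes are both associated, sharing of at least one TF is forced with the
#' pair's conservation-level `p_share` (one TF of the second gene is replaced
#' by one of the first gene's, when they do not already share).
#'
#' @param config a [simulationConfig()].
#' @param genome output of [simulateGenome()].
#' @return a [TFMap-class] object.
#' @export
simulateTFMap <- function(config, genome) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 2L)
  gt <- .geneTable(genome$genes)
  genes <- gt$gene_id
  pool <- sprintf("TF%04d", seq_len(config$tf_pool_size))
  assoc <- genes[stats::runif(length(genes)) < config$p_tf_assoc]
  targets <- lapply(assoc, function(g) sample(pool, config$tfs_per_gene))
  names(targets) <- assoc
  truth <- genome$truth
  p.share <- config$p_share[as.integer(truth$level)]
  force <- stats::runif(nrow(truth)) < p.share
  for (j in which(force)) {
    ga <- truth$minus_gene[j]; gb <- truth$plus_gene[j]
    ta <- targets[[ga]]; tb <- targets[[gb]]
    if (is.null(ta) || is.null(tb)) next
    if (length(intersect(ta, tb)) > 0) next
    # share one or two TFs (50/50), mirroring the observed mix of pairs with
    # one versus several common regulators
    k <- min(1L + stats::rbinom(1, 1, 0.5), length(ta), length(tb) - 1L)
    k <- max(k, 1L)
    tb[sample.int(length(tb), k)] <- sample(ta, k)
    targets[[gb]] <- tb
  }
  TFMap(targets)
}

# one rooted tree-plus-shortcut subsystem
.simulateSubsystemDag <- function(ns, depth, branching) {
  counts <- branching^(0:depth)
  total <- sum(counts)
  ids <- sprintf("%s:%04d", ns, seq_len(total))
  level <- rep(0:depth, counts)
  offset <- cumsum(c(0, counts))
  parents <- vector("list", total); names(parents) <- ids
  for (l in seq_len(depth)) {
    for (j in seq_len(counts[l + 1])) {
      child <- ids[offset[l + 1] + j]
      parent <- ids[offset[l] + ceiling(j / branching)]
      parents[[child]] <- parent
    }
  }
  # shortcut is_a edges to a random term one level up keep the DAG leveled
  deep <- which(level >= 2)
  extra <- deep[stats::runif(length(deep)) < 0.05]
  for (idx in extra) {
    l <- level[idx]
    cand <- ids[level == l - 1]
    cand <- setdiff(cand, parents[[ids[idx]]])
    if (length(cand) > 0)
      parents[[ids[idx]]] <- c(parents[[ids[idx]]], sample(cand, 1))
  }
  list(ids = ids, level = level, parents = parents)
}

#' Simulate an ontology DAG and gene annotations with planted co-annotation
#'
#' Builds one rooted tree-plus-shortcut DAG per subsystem (BP, MF, CC) and
#' annotates genes to deep terms. A planted pair is co-annotated to one
#' shared deep term (in a random subsystem) with its conservation-level
#' `p_coannotate`, which plants the functional-similarity effect.
#'
#' @param config a [simulationConfig()].
#' @param genome output of [simulateGenome()].
#' @return list with `dag` (a [GoDag-class]) and `annotations` (a direct,
#'   unpropagated [AnnotationSet-class]).
#' @export
simulateOntology <- function(config, genome) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 3L)
  gt <- .geneTable(genome$genes)
  genes <- gt$gene_id
  subsystems <- c("BP", "MF", "CC")
  built <- lapply(subsystems, .simulateSubsystemDag,
                  depth = config$dag_depth, branching = config$branching)
  names(built) <- subsystems
  terms <- unlist(lapply(built, `[[`, "ids"), use.names = FALSE)
  parents <- do.call(c, unname(lapply(built, `[[`, "parents")))
  namespace <- stats::setNames(rep(subsystems, vapply(built, function(b)
    length(b$ids), 0L)), terms)
  dag <- GoDag(terms = terms, parents = parents, namespace = namespace)

  deep.pool <- lapply(built, function(b) b$ids[b$level >= config$dag_depth - 1])
  rows <- list()
  for (ns in subsystems) {
    ann <- genes[stats::runif(length(genes)) < config$p_annotate]
    if (length(ann) == 0) next
    picks <- matrix(sample(deep.pool[[ns]],
                           length(ann) * config$terms_per_gene, replace = TRUE),
                    nrow = length(ann))
    rows[[ns]] <- data.frame(
      gene_id = rep(ann, config$terms_per_gene),
      term_id = as.character(picks),
      subsystem = ns)
  }
  truth <- genome$truth
  p.co <- config$p_coannotate[as.integer(truth$level)]
  co <- stats::runif(nrow(truth)) < p.co
  if (any(co)) {
    ns.pick <- sample(subsystems, sum(co), replace = TRUE)
    t.pick <- vapply(ns.pick, function(ns) sample(deep.pool[[ns]], 1), "")
    rows[["planted"]] <- data.frame(
      gene_id = c(truth$minus_gene[co], truth$plus_gene[co]),
      term_id = c(t.pick, t.pick),
      subsystem = c(ns.pick, ns.pick))
  }
  list(dag = dag, annotations = AnnotationSet(do.call(rbind, rows),
                                              propagated = FALSE))
}

#' Run the whole generator
#'
#' Convenience wrapper calling [simulateGenome()], [simulateExpression()],
#' [simulateTFMap()] and [simulateOntology()] with one config. Identical
#' seeds give identical output.
#'
#' @param config a [simulationConfig()].
#' @return list with `config`, `genome`, `truth`, `datasets`, `tfmap`,
#'   `dag`, `annotations`.
#' @export
simulateAll <- function(config) {
  genome <- simulateGenome(config)
  datasets <- simulateExpression(config, genome)
  tfmap <- simulateTFMap(config, genome)
  onto <- simulateOntology(config, genome)
  list(config = config, genome = genome, truth = genome$truth,
       datasets = datasets, tfmap = tfmap, dag = onto$dag,
       annotations = onto$annotations)
}
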