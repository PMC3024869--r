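#' @import methods
NULL

# ---- small shared helpers ----------------------------------------------------

#' Canonical key of an unordered gene pair
#'
#' Pairs are unordered for identity purposes; the canonical key is the two gene
#' ids sorted and joined by `|`.
#'
#' @param a,b character vectors of gene ids (recycled together).
#' @return character vector of keys.
#' @export
canonicalPairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

.msg <- function(...) message("divergon: ", ...)

# Welch t-test that treats two identical, zero-spread groups as the no-effect
# limit (statistic 0, p 1) instead of erroring on constant data.
.safeWelch <- function(a, b) {
  if (stats::sd(c(a, b)) == 0)
    return(list(statistic = 0, p.value = 1))
  ht <- stats::t.test(a, b)
  list(statistic = unname(ht$statistic), p.value = unname(ht$p.value))
}

# ---- H2HPairs ----------------------------------------------------------------

#' Head-to-head gene pairs
#'
#' Container for divergent (head-to-head) gene pairs. Each row records the
#' minus-strand member, the plus-strand member, the chromosome, the signed TSS
#' distance (plus-strand TSS minus minus-strand TSS, base pairs) and whether
#' the pair overlaps (TSS distance <= 0).
#'
#' @slot pairs data.frame with columns `minus_gene`, `plus_gene`, `chrom`,
#'   `tss_distance`, `overlapping`.
#' @export
setClass("H2HPairs", representation(pairs = "data.frame"))

setValidity("H2HPairs", function(object) {
  df <- object@pairs
  need <- c("minus_gene", "plus_gene", "chrom", "tss_distance", "overlapping")
  if (!all(need %in% names(df)))
    return(paste("missing columns:", paste(setdiff(need, names(df)), collapse = ", ")))
  if (nrow(df) == 0) return(TRUE)
  if (any(df$minus_gene == df$plus_gene)) return("self-pairs are not allowed")
  if (!identical(df$overlapping, df$tss_distance <= 0))
    return("overlapping flag inconsistent with tss_distance <= 0")
  keys <- canonicalPairKey(df$minus_gene, df$plus_gene)
  if (anyDuplicated(keys)) return("duplicate pair keys")
  TRUE
})

#' Construct an H2HPairs object
#'
#' @param pairs data.frame with columns `minus_gene`, `plus_gene`, `chrom`,
#'   `tss_distance` (`overlapping` is derived if absent).
#' @return an [H2HPairs-class] object.
#' @export
H2HPairs <- function(pairs) {
  if (is.null(pairs$overlapping)) pairs$overlapping <- pairs$tss_distance <= 0
  rownames(pairs) <- NULL
  new("H2HPairs", pairs = pairs)
}

#' @describeIn H2HPairs number of pairs
#' @param x an `H2HPairs` object.
#' @export
setMethod("length", "H2HPairs", function(x) nrow(x@pairs))

setMethod("show", "H2HPairs", function(object) {
  df <- object@pairs
  cat("H2HPairs with", nrow(df), "divergent gene pairs\n")
  if (nrow(df) > 0) {
    cat("  overlapping:", sum(df$overlapping),
        " non-overlapping:", sum(!df$overlapping), "\n")
    cat("  TSS distance range:", min(df$tss_distance), "..",
        max(df$tss_distance), "bp\n")
  }
})

#' Coerce head-to-head pairs to a data.frame
#' @param x an [H2HPairs-class] object.
#' @param ... unused.
#' @return the underlying pair data.frame.
#' @exportS3Method base::as.data.frame
as.data.frame.H2HPairs <- function(x, ...) x@pairs

#' Canonical keys of the pairs in a container
#'
#' @param x an [H2HPairs-class] or [PairSet-class] object.
#' @return character vector of canonical pair keys.
#' @export
setGeneric("pairKeys", function(x) standardGeneric("pairKeys"))

#' @rdname pairKeys
#' @export
setMethod("pairKeys", "H2HPairs", function(x)
  canonicalPairKey(x@pairs$minus_gene, x@pairs$plus_gene))

# ---- PairSet -----------------------------------------------------------------

#' Labelled set of unordered gene pairs
#'
#' Generic pair container used for control sets (same-strand adjacent pairs,
#' random pairs) and for projections of head-to-head pairs. Rows are stored in
#' canonical (sorted) order. Plain sets enforce unique canonical keys; sets
#' sampled in replicates carry a `rep` index and may repeat a pair across (or
#' within) replicates, as replicate sampling requires.
#'
#' @slot label character set label (e.g. `"h2h"`, `"adjacent-control"`).
#' @slot pairs two-column character matrix, rows in canonical order.
#' @slot rep integer replicate index per row (length 0 for plain sets).
#' @export
setClass("PairSet",
         representation(label = "character", pairs = "matrix", rep = "integer"))

setValidity("PairSet", function(object) {
  p <- object@pairs
  if (ncol(p) != 2) return("pairs must be a two-column matrix")
  if (nrow(p) == 0) return(TRUE)
  if (any(p[, 1] == p[, 2])) return("self-pairs are not allowed")
  if (any(p[, 1] > p[, 2])) return("pair rows must be in canonical (sorted) order")
  if (length(object@rep) == 0) {
    if (anyDuplicated(paste(p[, 1], p[, 2], sep = "|")))
      return("duplicate canonical pair keys in a plain PairSet")
  } else if (length(object@rep) != nrow(p)) {
    return("rep index length must match the number of pairs")
  }
  TRUE
})

#' Construct a PairSet
#'
#' @param pairs two-column character matrix or data.frame of gene-id pairs
#'   (any order; rows are canonicalized).
#' @param label set label.
#' @param rep optional integer replicate index per row; when supplied the
#'   unique-key requirement is waived (replicate sampling may repeat pairs).
#' @return a [PairSet-class] object.
#' @export
PairSet <- function(pairs, label = "pairs", rep = NULL) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) > 0) {
    mode(pairs) <- "character"
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  } else {
    pairs <- matrix(character(0), ncol = 2)
  }
  dimnames(pairs) <- list(NULL, c("gene_a", "gene_b"))
  new("PairSet", label = label, pairs = pairs,
      rep = if (is.null(rep)) integer(0) else as.integer(rep))
}

#' @describeIn PairSet number of pairs
#' @param x a `PairSet` object.
#' @export
setMethod("length", "PairSet", function(x) nrow(x@pairs))

setMethod("show", "PairSet", function(object) {
  cat("PairSet '", object@label, "' with ", nrow(object@pairs), " pairs",
      sep = "")
  if (length(object@rep) > 0)
    cat(" in", length(unique(object@rep)), "replicates")
  cat("\n")
})

#' @rdname pairKeys
#' @export
setMethod("pairKeys", "PairSet", function(x)
  if (nrow(x@pairs) == 0) character(0) else paste(x@pairs[, 1], x@pairs[, 2], sep = "|"))

#' Label of a pair set
#' @param x a [PairSet-class] object.
#' @return character label.
#' @export
setGeneric("setLabel", function(x) standardGeneric("setLabel"))

#' @rdname setLabel
#' @export
setMethod("setLabel", "PairSet", function(x) x@label)

#' Two-column data.frame of the gene pairs in a container
#'
#' @param x an [H2HPairs-class] or [PairSet-class] object, a two-column
#'   matrix/data.frame, or a character vector of canonical keys.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
pairTable <- function(x) {
  if (is(x, "H2HPairs"))
    return(data.frame(gene_a = x@pairs$minus_gene, gene_b = x@pairs$plus_gene))
  if (is(x, "PairSet"))
    return(as.data.frame(x@pairs))
  if (is.character(x) && is.null(dim(x))) {
    sp <- strsplit(x, "|", fixed = TRUE)
    return(data.frame(gene_a = vapply(sp, `[`, "", 1L),
                      gene_b = vapply(sp, `[`, "", 2L)))
  }
  x <- as.data.frame(x)
  stopifnot(ncol(x) >= 2)
  data.frame(gene_a = as.character(x[[1]]), gene_b = as.character(x[[2]]))
}

#' Coerce head-to-head pairs to a PairSet
#'
#' @param x an [H2HPairs-class] object.
#' @param label set label.
#' @return a [PairSet-class] object.
#' @export
asPairSet <- function(x, label = "h2h") {
  PairSet(as.matrix(pairTable(x)), label = label)
}

# ---- TFMap -------------------------------------------------------------------

#' Transcription-factor association map
#'
#' Bipartite map from genes to the transcription factors associated with
#' (predicted or verified to regulate) them.
#'
#' @slot targets named list: gene id -> character vector of TF ids.
#' @export
setClass("TFMap", representation(targets = "list"))

setValidity("TFMap", function(object) {
  tg <- object@targets
  if (length(tg) == 0) return(TRUE)
  if (is.null(names(tg)) || anyDuplicated(names(tg)))
    return("targets must be a uniquely named list keyed by gene id")
  if (any(vapply(tg, anyDuplicated, 0L) > 0))
    return("duplicate TFs within a gene's association set")
  TRUE
})

#' Construct a TFMap
#'
#' @param targets named list mapping gene ids to character vectors of TF ids
#'   (duplicates within a gene are removed).
#' @return a [TFMap-class] object.
#' @export
TFMap <- function(targets) {
  targets <- lapply(targets, function(v) sort(unique(as.character(v))))
  new("TFMap", targets = targets)
}

setMethod("show", "TFMap", function(object) {
  cat("TFMap:", length(object@targets), "TF-associated genes,",
      length(unique(unlist(object@targets, use.names = FALSE))), "TFs\n")
})

#' TFs associated with a gene
#'
#' @param x a [TFMap-class] object.
#' @param gene gene id.
#' @return character vector (empty if the gene is unassociated).
#' @export
setGeneric("associatedTFs", function(x, gene) standardGeneric("associatedTFs"))

#' @rdname associatedTFs
#' @export
setMethod("associatedTFs", "TFMap", function(x, gene) {
  v <- x@targets[[gene]]
  if (is.null(v)) character(0) else v
})

#' Inverse (TF -> targets) view of a TFMap
#'
#' @param x a [TFMap-class] object.
#' @return named list: TF id -> character vector of target gene ids.
#' @export
tfTargets <- function(x) {
  stopifnot(is(x, "TFMap"))
  if (length(x@targets) == 0) return(list())
  long <- data.frame(
    gene = rep(names(x@targets), lengths(x@targets)),
    tf = unlist(x@targets, use.names = FALSE))
  split(long$gene, long$tf)
}

# ---- GoDag -------------------------------------------------------------------

#' Ontology DAG (is_a edges, one root per subsystem)
#'
#' Directed acyclic graph of ontology terms. Only `is_a` edges are stored;
#' every non-root term must reach exactly one subsystem root (BP, MF or CC in
#' Gene Ontology usage, but any namespace labels are accepted).
#'
#' @slot terms character vector of term ids.
#' @slot parents named list: term id -> character vector of parent term ids.
#' @slot namespace named character: term id -> subsystem label.
#' @slot roots named character: subsystem label -> root term id.
#' @export
setClass("GoDag", representation(terms = "character", parents = "list",
                                 namespace = "character", roots = "character"))

setValidity("GoDag", function(object) {
  terms <- object@terms
  if (anyDuplicated(terms)) return("duplicate term ids")
  if (!setequal(names(object@parents), terms)) return("parents must be keyed by every term")
  if (!setequal(names(object@namespace), terms)) return("namespace must be keyed by every term")
  allp <- unlist(object@parents, use.names = FALSE)
  if (length(allp) && !all(allp %in% terms)) return("parent ids not in term set")
  for (t in terms) {
    for (p in object@parents[[t]]) {
      if (object@namespace[[p]] != object@namespace[[t]])
        return(sprintf("edge %s -> %s crosses subsystems", t, p))
    }
  }
  roots <- terms[lengths(object@parents[terms]) == 0]
  ns.root <- object@namespace[roots]
  if (anyDuplicated(ns.root)) return("more than one root in a subsystem")
  if (!setequal(unname(object@roots), roots)) return("roots slot inconsistent with parentless terms")
  if (!setequal(unique(unname(object@namespace)), names(object@roots)))
    return("every subsystem must have exactly one root")
  # acyclicity via Kahn-style peeling on child -> parent edges
  remaining <- setdiff(terms, roots)
  reached <- roots
  repeat {
    nxt <- remaining[vapply(object@parents[remaining],
                            function(p) all(p %in% reached), TRUE)]
    if (length(nxt) == 0) break
    reached <- c(reached, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  if (length(remaining) > 0)
    return(paste("cycle or unreachable terms:", paste(utils::head(remaining, 5), collapse = ", ")))
  TRUE
})

#' Construct a GoDag
#'
#' @param terms character vector of term ids.
#' @param parents named list: term id -> character vector of parent ids
#'   (`is_a`); missing entries are treated as parentless.
#' @param namespace named character: term id -> subsystem label.
#' @return a [GoDag-class] object.
#' @export
GoDag <- function(terms, parents, namespace) {
  parents <- parents[intersect(names(parents), terms)]
  missing <- setdiff(terms, names(parents))
  parents[missing] <- replicate(length(missing), character(0), simplify = FALSE)
  parents <- lapply(parents, as.character)
  namespace <- namespace[terms]
  roots <- terms[lengths(parents[terms]) == 0]
  rootmap <- stats::setNames(roots, namespace[roots])
  new("GoDag", terms = terms, parents = parents,
      namespace = stats::setNames(as.character(namespace), terms), roots = rootmap)
}

setMethod("show", "GoDag", function(object) {
  cat("GoDag:", length(object@terms), "terms in",
      length(object@roots), "subsystem(s) [",
      paste(names(object@roots), collapse = ", "), "]\n")
})

#' @describeIn GoDag number of terms
#' @param x a `GoDag` object.
#' @export
setMethod("length", "GoDag", function(x) length(x@terms))

# ---- AnnotationSet -----------------------------------------------------------

#' Gene-to-term annotation set
#'
#' Gene annotations against a [GoDag-class], partitioned by subsystem. After
#' propagation (true-path closure) a gene annotated to a term is annotated to
#' all of the term's ancestors.
#'
#' @slot annotations data.frame with columns `gene_id`, `term_id`, `subsystem`.
#' @slot propagated logical: has true-path closure been applied?
#' @export
setClass("AnnotationSet",
         representation(annotations = "data.frame", propagated = "logical"))

setValidity("AnnotationSet", function(object) {
  need <- c("gene_id", "term_id", "subsystem")
  if (!all(need %in% names(object@annotations)))
    return(paste("missing columns:", paste(setdiff(need, names(object@annotations)), collapse = ", ")))
  if (length(object@propagated) != 1) return("propagated must be a single logical")
  TRUE
})

#' Construct an AnnotationSet
#'
#' @param annotations data.frame with columns `gene_id`, `term_id`,
#'   `subsystem` (duplicate rows are removed).
#' @param propagated logical; `TRUE` only if `annotations` is already closed
#'   under the true-path rule.
#' @return an [AnnotationSet-class] object.
#' @export
AnnotationSet <- function(annotations, propagated = FALSE) {
  annotations <- unique(data.frame(
    gene_id = as.character(annotations$gene_id),
    term_id = as.character(annotations$term_id),
    subsystem = as.character(annotations$subsystem)))
  rownames(annotations) <- NULL
  new("AnnotationSet", annotations = annotations, propagated = propagated)
}

setMethod("show", "AnnotationSet", function(object) {
  a <- object@annotations
  cat("AnnotationSet:", length(unique(a$gene_id)), "genes,",
      length(unique(a$term_id)), "terms,",
      nrow(a), "annotations;",
      if (object@propagated) "propagated" else "direct (not propagated)", "\n")
})

#' Annotation table of an AnnotationSet
#' @param x an [AnnotationSet-class] object.
#' @return data.frame with columns `gene_id`, `term_id`, `subsystem`.
#' @export
annotationTable <- function(x) {
  stopifnot(is(x, "AnnotationSet"))
  x@annotations
}

#' Has an AnnotationSet been propagated?
#' @param x an [AnnotationSet-class] object.
#' @return logical.
#' @export
isPropagated <- function(x) {
  stopifnot(is(x, "AnnotationSet"))
  x@propagated
}
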