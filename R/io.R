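# Plain-text serialization of simulation bundles and readers for the
# tabular interchange formats (expression TSV + manifest, gene-term TSV).

#' Write a gene annotation as five-column TSV
#'
#' @param genes GRanges or data.frame annotation (see [detectH2HPairs()]).
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeAnnotationTsv <- function(genes, path) {
  gt <- .geneTable(genes)
  utils::write.table(gt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes x samples expression matrix from TSV
#'
#' First column is the gene id, remaining columns one sample each (header
#' row with sample ids).
#'
#' @param path TSV file.
#' @return numeric matrix with gene rownames.
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate gene rows in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  m
}

#' Write a genes x samples expression matrix as TSV
#'
#' @param mat numeric matrix with gene rownames.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeExpressionMatrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression dataset collection from a manifest
#'
#' The manifest is a two-column TSV (`dataset_id`, `path`); relative paths
#' are resolved against the manifest's directory.
#'
#' @param path manifest TSV.
#' @return named list of matrices.
#' @export
readExpressionManifest <- function(path) {
  mf <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  base <- dirname(path)
  out <- lapply(mf$path, function(p) {
    if (!file.exists(p)) p <- file.path(base, p)
    readExpressionMatrix(p)
  })
  names(out) <- mf$dataset_id
  out
}

#' Read gene-to-term annotations from a three-column TSV
#'
#' Columns: `gene_id`, `term_id`, `subsystem`.
#'
#' @param path TSV file.
#' @return a direct (unpropagated) [AnnotationSet-class].
#' @export
readGeneAnnotations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "term_id", "subsystem")
  if (!all(need %in% names(df)))
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  AnnotationSet(df, propagated = FALSE)
}

#' Write a GoDag as a minimal OBO 1.2 file
#'
#' @param dag a [GoDag-class] object.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeOBO <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in dag@terms) {
    p <- dag@parents[[t]]
    writeLines(c("[Term]",
                 paste0("id: ", t),
                 paste0("name: ", t),
                 paste0("namespace: ", dag@namespace[[t]]),
                 if (length(p) > 0) paste0("is_a: ", p),
                 ""), con)
  }
  invisible(path)
}

#' Write a full simulation bundle as plain-text files
#'
#' Writes the focal and partner-species annotations, ortholog maps,
#' expression matrices with a manifest, the TF map, the ontology (OBO), the
#' gene-term annotations and the planted-pair truth table.
#'
#' @param sim bundle from [simulateAll()].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeAnnotationTsv(sim$genome$genes, file.path(dir, "annotation.tsv"))
  for (s in names(sim$genome$species)) {
    writeAnnotationTsv(sim$genome$species[[s]],
                       file.path(dir, paste0("annotation_", s, ".tsv")))
    om <- sim$genome$orthologs[[s]]
    utils::write.table(data.frame(focal = names(om), partner = unname(om)),
                       file.path(dir, paste0("orthologs_", s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths <- character(0)
  for (k in names(sim$datasets)) {
    p <- paste0("expr_", k, ".tsv")
    writeExpressionMatrix(sim$datasets[[k]], file.path(dir, p))
    paths[k] <- p
  }
  utils::write.table(data.frame(dataset_id = names(paths),
                                path = unname(paths)),
                     file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tg <- tfTargets(sim$tfmap)
  utils::write.table(data.frame(
    tf_id = rep(names(tg), lengths(tg)),
    target_gene_id = unlist(tg, use.names = FALSE)),
    file.path(dir, "tf.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeOBO(sim$dag, file.path(dir, "ontology.obo"))
  utils::write.table(annotationTable(sim$annotations),
                     file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
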