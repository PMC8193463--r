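# Gold-standard construction: restrict the reference network to the
# benchmarked TFs and keep only edges whose binding site was actually
# occupied by its TF (>= 1 bp overlap between the TFBS and a ChIP-seq peak
# of the same TF).

#' Restrict a network to a set of regulators
#'
#' Keeps only edges whose regulator is listed; the node set is preserved.
#' Typically applied to a predicted network before comparison with a gold
#' standard built from a subset of TFs, so that false positives reflect
#' occupancy disagreement rather than regulator coverage.
#'
#' @param x a `grn`.
#' @param regulators character vector of regulator gene ids.
#' @return The restricted `grn`.
#' @export
restrict_to_regulators <- function(x, regulators) {
  stopifnot(is(x, "grn"))
  subset_edges(x, x$edges$regulator_id %in% regulators)
}

#' Build a gold-standard network from TF ChIP-seq occupancy
#'
#' Starting from a reference network, (1) edges arising from any regulator
#' without ChIP-seq data are removed, and (2) of the remaining TF-gene
#' edges, only those with at least one TFBS overlapping (>= 1 bp) a ChIP-seq
#' peak of the same TF are kept. Weights are reset to 0: gold standards are
#' unweighted.
#'
#' @param reference a reference `grn` with TFBS evidence.
#' @param peaks_by_tf named list, TF gene id -> [evidence_track()] of that
#'   TF's ChIP-seq peaks. Every key must be a TF node of the reference.
#' @return The gold-standard `grn` (an edge subset of the reference).
#' @export
build_gold_standard <- function(reference, peaks_by_tf) {
  stopifnot(is(reference, "grn"), is.list(peaks_by_tf))
  if (length(peaks_by_tf) &&
      (is.null(names(peaks_by_tf)) || any(!nzchar(names(peaks_by_tf))))) {
    stop("peaks_by_tf must be a named list keyed by TF gene id")
  }
  unknown <- setdiff(names(peaks_by_tf), reference$nodes$gene_id)
  if (length(unknown)) {
    stop(sprintf("ChIP peak track(s) for unknown TF id(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  x <- restrict_to_regulators(reference, names(peaks_by_tf))
  occupied_keys <- character(0)
  for (tf in names(peaks_by_tf)) {
    ev <- x$evidence[x$evidence$regulator_id == tf, , drop = FALSE]
    if (!nrow(ev)) next
    hit <- track_overlaps_any(peaks_by_tf[[tf]], ev)
    occupied_keys <- c(occupied_keys,
                       unique(paste(ev$regulator_id[hit], ev$target_id[hit],
                                    "tf_gene", sep = "\r")))
  }
  keep <- x$edges$edge_kind == "tf_gene" & edge_key(x$edges) %in% occupied_keys
  x <- subset_edges(x, keep)
  x$edges$weight <- rep(0, nrow(x$edges))
  x$provenance <- c(x$provenance,
                    sprintf("gold standard from ChIP occupancy of %d TF(s)",
                            length(peaks_by_tf)))
  x
}
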