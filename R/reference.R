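# Reference-network construction: a TF is assigned to the regulation of
# every gene whose TSS lies within d nucleotides downstream of one of the
# TF's binding sites, i.e. the TFBS overlaps the strand-aware upstream
# promoter window of the gene.

#' Strand-aware upstream promoter windows
#'
#' For a `+` strand gene the window is `[tss - d, tss)`; for a `-` strand
#' gene it is the mirrored `[tss + 1, tss + d + 1)` (0-based half-open, i.e.
#' the d bases immediately 5' of the TSS on the transcribed strand). Windows
#' are clipped at position 0 and not truncated by neighbouring genes.
#'
#' @param genes gene-model data frame.
#' @param d window size in nucleotides (> 0).
#' @return An interval data frame with one row per gene (empty clipped
#'   windows dropped) and a `gene_id` column.
#' @export
upstream_windows <- function(genes, d) {
  if (!is.numeric(d) || length(d) != 1 || is.na(d) || d <= 0) {
    stop("distance threshold d must be a single positive number")
  }
  validate_annotation(genes)
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0, genes$tss - d), genes$tss + 1)
  end <- ifelse(plus, genes$tss, genes$tss + d + 1)
  w <- data.frame(chrom = genes$chrom, start = start, end = end,
                  gene_id = genes$gene_id, strand = genes$strand,
                  tss = genes$tss, stringsAsFactors = FALSE)
  w[w$start < w$end, , drop = FALSE]
}

#' Assign TF binding sites to the genes they may regulate
#'
#' Emits one assignment per (TF, TFBS, gene) triple where the TFBS overlaps
#' the gene's upstream window by at least 1 bp (or is fully contained when
#' `contained = TRUE`). The recorded distance is the number of nucleotides
#' between the TFBS edge nearest the TSS and the TSS (0 when the TFBS
#' reaches or crosses the TSS). Exact-coordinate duplicate TFBSs within one
#' TF's track are deduplicated first.
#'
#' @param tfbs_by_tf named list, TF gene id -> [evidence_track()] of its
#'   binding sites.
#' @param genes gene-model data frame; every TF id must be present.
#' @param d distance threshold in nucleotides (> 0).
#' @param contained require full containment of the TFBS in the window
#'   instead of 1-bp overlap (default `FALSE`).
#' @return Assignment data frame: `regulator_id`, `target_id`, `chrom`,
#'   `start`, `end`, `name`, `distance`.
#' @export
assign_tfbs_to_genes <- function(tfbs_by_tf, genes, d, contained = FALSE) {
  validate_annotation(genes)
  if (is.null(names(tfbs_by_tf)) || any(!nzchar(names(tfbs_by_tf)))) {
    stop("tfbs_by_tf must be a named list keyed by TF gene id")
  }
  missing <- setdiff(names(tfbs_by_tf), genes$gene_id)
  if (length(missing)) {
    stop(sprintf("TF id(s) absent from annotation: %s",
                 paste(missing, collapse = ", ")))
  }
  windows <- upstream_windows(genes, d)
  wgr <- intervals_to_gr(windows)
  out <- vector("list", length(tfbs_by_tf))
  for (i in seq_along(tfbs_by_tf)) {
    tf <- names(tfbs_by_tf)[i]
    track <- tfbs_by_tf[[i]]
    stopifnot(is(track, "evidence_track"))
    iv <- track$intervals
    iv <- iv[!duplicated(iv[, c("chrom", "start", "end")]), , drop = FALSE]
    if (!nrow(iv)) next
    hits <- GenomicRanges::findOverlaps(
      intervals_to_gr(iv), wgr,
      type = if (contained) "within" else "any")
    if (!length(hits)) next
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    w <- windows[s, , drop = FALSE]
    dist <- ifelse(w$strand == "+",
                   pmax(0, w$tss - iv$end[q]),
                   pmax(0, iv$start[q] - w$tss - 1))
    out[[i]] <- data.frame(
      regulator_id = tf, target_id = w$gene_id,
      chrom = iv$chrom[q], start = iv$start[q], end = iv$end[q],
      name = iv$name[q], distance = dist, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_evidence()
  rownames(res) <- NULL
  res
}

#' Build the reference network from TFBS assignments
#'
#' One TF-gene edge per distinct (TF, target) pair, aggregating all its
#' assignments as evidence. Every annotated gene becomes a node (isolated
#' nodes retained); all edge weights are 0 (unfiltered reference edges).
#' Self-loops (a TF with a binding site upstream of its own TSS) are kept.
#'
#' @param assignments output of [assign_tfbs_to_genes()].
#' @param genes gene-model data frame.
#' @param d the threshold the assignments were made with (stored as network
#'   metadata).
#' @return A `grn`.
#' @export
build_reference_network <- function(assignments, genes, d = NA_real_) {
  validate_annotation(genes)
  if (nrow(assignments)) {
    unknown <- setdiff(unique(c(assignments$regulator_id, assignments$target_id)),
                       genes$gene_id)
    if (length(unknown)) {
      stop(sprintf("assignment references unknown gene(s): %s",
                   paste(unknown, collapse = ", ")))
    }
    pairs <- unique(assignments[, c("regulator_id", "target_id")])
    edges <- data.frame(regulator_id = pairs$regulator_id,
                        target_id = pairs$target_id,
                        edge_kind = "tf_gene", weight = 0,
                        stringsAsFactors = FALSE)
  } else {
    edges <- empty_edges()
  }
  grn(genes, edges, assignments, d = d,
      provenance = sprintf("reference network, d=%s", format(d)))
}

#' Merge experimentally determined miRNA-target edges into a network
#'
#' Adds one `mirna_gene` edge per distinct (miRNA, target) pair. miRNA ids
#' absent from the annotation are added as miRNA nodes with a warning;
#' unknown targets are skipped with a warning reporting the count. Existing
#' TF-gene edges are untouched.
#'
#' @param x a `grn`.
#' @param mirna_targets data frame with columns `mirna_id`, `target_id`.
#' @return The augmented `grn`.
#' @export
add_mirna_edges <- function(x, mirna_targets) {
  stopifnot(is(x, "grn"))
  mt <- unique(data.frame(mirna_id = as.character(mirna_targets$mirna_id),
                          target_id = as.character(mirna_targets$target_id),
                          stringsAsFactors = FALSE))
  known_target <- mt$target_id %in% x$nodes$gene_id
  if (any(!known_target)) {
    warning(sprintf("skipped %d miRNA-target pair(s) with unknown target gene",
                    sum(!known_target)))
    mt <- mt[known_target, , drop = FALSE]
  }
  new_mirnas <- setdiff(mt$mirna_id, x$nodes$gene_id)
  if (length(new_mirnas)) {
    warning(sprintf("added %d miRNA regulator(s) absent from annotation as miRNA nodes",
                    length(new_mirnas)))
    x$nodes <- rbind(x$nodes[, c("gene_id", "chrom", "strand", "tss", "gene_type")],
                     data.frame(gene_id = new_mirnas, chrom = NA_character_,
                                strand = "+", tss = 0, gene_type = "miRNA",
                                stringsAsFactors = FALSE))
  }
  if (nrow(mt)) {
    new_edges <- data.frame(regulator_id = mt$mirna_id, target_id = mt$target_id,
                            edge_kind = "mirna_gene", weight = 0,
                            stringsAsFactors = FALSE)
    combined <- rbind(x$edges[, c("regulator_id", "target_id", "edge_kind", "weight")],
                      new_edges)
    combined <- combined[!duplicated(edge_key(combined)), , drop = FALSE]
    rownames(combined) <- NULL
    x$edges <- combined
  }
  validate_grn(x)
}
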