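# The GRN container: a directed graph of gene models and regulatory edges.
# Edges carry an integer weight (0 = unfiltered reference edge) and, for
# TF-gene edges, the TFBS assignments supporting them.

empty_edges <- function() {
  data.frame(regulator_id = character(), target_id = character(),
             edge_kind = character(), weight = numeric(),
             stringsAsFactors = FALSE)
}

empty_evidence <- function() {
  data.frame(regulator_id = character(), target_id = character(),
             chrom = character(), start = numeric(), end = numeric(),
             name = character(), distance = numeric(),
             stringsAsFactors = FALSE)
}

edge_key <- function(edges) {
  paste(edges$regulator_id, edges$target_id, edges$edge_kind, sep = "\r")
}

#' Construct a gene regulatory network
#'
#' @param nodes gene-model data frame (see [read_gene_annotation()]).
#' @param edges data frame with columns `regulator_id`, `target_id`,
#'   `edge_kind` (`"tf_gene"` or `"mirna_gene"`) and optionally `weight`
#'   (default 0).
#' @param evidence TFBS assignment data frame supporting the tf_gene edges
#'   (columns `regulator_id`, `target_id`, `chrom`, `start`, `end`, `name`,
#'   `distance`).
#' @param d the TFBS-to-TSS distance threshold (nucleotides) the network was
#'   built with, or `NA`.
#' @param provenance character vector of free-text provenance labels.
#' @return An object of class `grn`.
#' @export
grn <- function(nodes, edges = empty_edges(), evidence = empty_evidence(),
                d = NA_real_, provenance = character()) {
  validate_annotation(nodes)
  if (!"weight" %in% names(edges)) edges$weight <- 0
  edges <- edges[, c("regulator_id", "target_id", "edge_kind", "weight"),
                 drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  rownames(evidence) <- NULL
  x <- structure(
    list(nodes = nodes, edges = edges, evidence = evidence,
         d = d, provenance = provenance),
    class = "grn"
  )
  validate_grn(x)
}

validate_grn <- function(x) {
  stopifnot(is(x, "grn"))
  e <- x$edges
  if (nrow(e)) {
    if (!all(e$edge_kind %in% c("tf_gene", "mirna_gene"))) {
      stop("edge_kind must be 'tf_gene' or 'mirna_gene'")
    }
    endpoints <- unique(c(e$regulator_id, e$target_id))
    missing <- setdiff(endpoints, x$nodes$gene_id)
    if (length(missing)) {
      stop(sprintf("edge endpoint(s) absent from node set: %s",
                   paste(utils::head(missing, 5), collapse = ", ")))
    }
    if (anyDuplicated(edge_key(e))) {
      stop("duplicate (regulator, target, kind) edges")
    }
  }
  if (nrow(x$evidence)) {
    ev_key <- paste(x$evidence$regulator_id, x$evidence$target_id, "tf_gene",
                    sep = "\r")
    orphan <- !ev_key %in% edge_key(e)
    if (any(orphan)) stop("TFBS evidence attached to no tf_gene edge")
  }
  invisible(x)
}

#' @export
print.grn <- function(x, ...) {
  nt <- sum(x$edges$edge_kind == "tf_gene")
  nm <- sum(x$edges$edge_kind == "mirna_gene")
  cat(sprintf("<grn> %d node(s); %d edge(s) (%d TF-gene, %d miRNA-gene)%s\n",
              nrow(x$nodes), nrow(x$edges), nt, nm,
              if (is.na(x$d)) "" else sprintf("; d = %g nt", x$d)))
  invisible(x)
}

# Subset a GRN to a logical/integer edge selection, dropping the evidence of
# discarded edges. Nodes are retained as metadata.
subset_edges <- function(x, keep) {
  e <- x$edges[keep, , drop = FALSE]
  ev <- x$evidence
  if (nrow(ev)) {
    ev_key <- paste(ev$regulator_id, ev$target_id, "tf_gene", sep = "\r")
    ev <- ev[ev_key %in% edge_key(e), , drop = FALSE]
  }
  rownames(e) <- NULL
  rownames(ev) <- NULL
  x$edges <- e
  x$evidence <- ev
  x
}

#' Summarize a network
#'
#' @param x a `grn`.
#' @return A one-row `data.frame`: node count, edge counts by kind, distinct
#'   regulator counts by type, and the number of nodes with at least one
#'   incident edge.
#' @export
network_summary <- function(x) {
  stopifnot(is(x, "grn"))
  e <- x$edges
  tf_e <- e[e$edge_kind == "tf_gene", , drop = FALSE]
  mir_e <- e[e$edge_kind == "mirna_gene", , drop = FALSE]
  data.frame(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(e),
    n_tf_edges = nrow(tf_e),
    n_mirna_edges = nrow(mir_e),
    n_tf_regulators = length(unique(tf_e$regulator_id)),
    n_mirna_regulators = length(unique(mir_e$regulator_id)),
    n_connected_nodes = length(unique(c(e$regulator_id, e$target_id)))
  )
}

#' Write a network as a weighted edge-list TSV
#'
#' Columns: regulator, target, kind, weight, n_tfbs, passed_filters. A
#' sibling `<stem>_evidence.tsv` holding the TFBS assignments is written when
#' the network carries evidence, so the network can be reloaded and
#' re-filtered. Header `#` lines record the distance threshold and
#' provenance; no timestamps, so identical runs produce identical files.
#'
#' @param x a `grn`.
#' @param path output TSV path.
#' @param evidence whether to write the evidence sidecar (default: yes when
#'   present).
#' @export
write_grn <- function(x, path, evidence = nrow(x$evidence) > 0) {
  stopifnot(is(x, "grn"))
  e <- x$edges
  ev_key <- paste(x$evidence$regulator_id, x$evidence$target_id, "tf_gene",
                  sep = "\r")
  n_tfbs <- as.integer(table(factor(ev_key, levels = edge_key(e)))[edge_key(e)])
  n_tfbs[is.na(n_tfbs)] <- 0L
  passed <- if ("passed_filters" %in% names(e)) e$passed_filters else ""
  header <- c(
    sprintf("# epigrn network v%s", as.character(utils::packageVersion("epigrn"))),
    sprintf("# d=%s", if (is.na(x$d)) "NA" else format(x$d, scientific = FALSE)),
    sprintf("# provenance=%s", paste(x$provenance, collapse = "; "))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  out <- data.frame(regulator = e$regulator_id, target = e$target_id,
                    kind = e$edge_kind, weight = e$weight, n_tfbs = n_tfbs,
                    passed_filters = passed, stringsAsFactors = FALSE)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (evidence && nrow(x$evidence)) {
    write.table(x$evidence, evidence_path(path), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

evidence_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_evidence.tsv")
}

#' Read a network written by [write_grn()]
#'
#' @param path edge-list TSV path.
#' @param nodes gene-model data frame providing the node set.
#' @return A `grn`. The evidence sidecar is loaded when present.
#' @export
read_grn <- function(path, nodes) {
  if (!file.exists(path)) stop(sprintf("network file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  header <- lines[grepl("^#", lines)]
  d <- NA_real_
  dm <- grep("^# d=", header, value = TRUE)
  if (length(dm)) d <- suppressWarnings(as.numeric(sub("^# d=", "", dm[1])))
  df <- read.delim(text = paste(lines[!grepl("^#", lines)], collapse = "\n"),
                   stringsAsFactors = FALSE)
  edges <- data.frame(regulator_id = as.character(df$regulator),
                      target_id = as.character(df$target),
                      edge_kind = as.character(df$kind),
                      weight = as.numeric(df$weight),
                      stringsAsFactors = FALSE)
  ev <- empty_evidence()
  evp <- evidence_path(path)
  if (file.exists(evp)) {
    ev <- read.delim(evp, stringsAsFactors = FALSE)
    ev$name <- as.character(ev$name)
  }
  g <- grn(nodes, edges, ev, d = d)
  if ("passed_filters" %in% names(df)) g$edges$passed_filters <- as.character(df$passed_filters)
  g
}

#' Export a network in SIF (simple interaction format)
#'
#' One line per edge: `regulator<TAB>kind<TAB>target`, directly importable
#' into Cytoscape.
#'
#' @param x a `grn`.
#' @param path output path.
#' @export
write_sif <- function(x, path) {
  stopifnot(is(x, "grn"))
  lines <- sprintf("%s\t%s\t%s", x$edges$regulator_id, x$edges$edge_kind,
                   x$edges$target_id)
  writeLines(lines, path)
  invisible(path)
}
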