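# Shared builders and independent oracles. Oracles deliberately avoid the
# code paths they check: overlap by linear scan, graphlet membership by
# exhaustive all-triples enumeration on an adjacency matrix, class identity
# by igraph isomorphism against explicit representative graphs.

make_genes <- function(n, d = 1500, strands = NULL) {
  spacing <- 4 * d
  if (is.null(strands)) strands <- rep(c("+", "+", "-"), length.out = n)
  data.frame(
    gene_id = sprintf("g%02d", seq_len(n)),
    chrom = "chr1",
    strand = strands,
    tss = as.numeric(2 * d + (seq_len(n) - 1) * spacing),
    gene_type = rep(c("TF", "coding", "coding", "noncoding"), length.out = n),
    stringsAsFactors = FALSE
  )
}

make_track <- function(starts, ends, chrom = "chr1", label = "t",
                       kind = "generic") {
  evidence_track(genomic_intervals(rep(chrom, length(starts)), starts, ends),
                 label = label, kind = kind)
}

# a one-TF / one-target GRN with explicit TFBS evidence, for filter tests
single_edge_grn <- function(tfbs_start, tfbs_end, tss = 10000, strand = "+",
                            d = 1500) {
  genes <- data.frame(
    gene_id = c("tfA", "g1"), chrom = "chr1", strand = c("+", strand),
    tss = c(500, tss), gene_type = c("TF", "coding"),
    stringsAsFactors = FALSE)
  ev <- data.frame(regulator_id = "tfA", target_id = "g1", chrom = "chr1",
                   start = tfbs_start, end = tfbs_end, name = NA_character_,
                   distance = 0, stringsAsFactors = FALSE)
  edges <- data.frame(regulator_id = "tfA", target_id = "g1",
                      edge_kind = "tf_gene", weight = 0,
                      stringsAsFactors = FALSE)
  grn(genes, edges, ev, d = d)
}

# linear-scan overlap oracle (0-based half-open)
overlap_scan <- function(intervals, chrom, start, end) {
  hit <- intervals$chrom == chrom & intervals$start < end & intervals$end > start
  intervals[hit, , drop = FALSE]
}

random_digraph_edges <- function(n_nodes, n_edges) {
  nodes <- sprintf("g%02d", seq_len(n_nodes))
  pairs <- expand.grid(regulator_id = nodes, target_id = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator_id != pairs$target_id, ]
  e <- pairs[sample(nrow(pairs), min(n_edges, nrow(pairs))), ]
  e$edge_kind <- "tf_gene"
  e$weight <- 0
  rownames(e) <- NULL
  e
}

# exhaustive all-triples graphlet membership: returns sorted "a,b,c" triple
# keys of weakly connected induced triples
graphlet_triples_bruteforce <- function(edges) {
  nodes <- sort(unique(c(edges$regulator_id, edges$target_id)))
  n <- length(nodes)
  if (n < 3) return(character(0))
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  adj[cbind(edges$regulator_id, edges$target_id)] <- TRUE
  diag(adj) <- FALSE
  und <- adj | t(adj)
  combs <- utils::combn(n, 3)
  keys <- character(0)
  for (j in seq_len(ncol(combs))) {
    trip <- combs[, j]
    npairs <- und[trip[1], trip[2]] + und[trip[1], trip[3]] + und[trip[2], trip[3]]
    if (npairs >= 2) keys <- c(keys, paste(nodes[trip], collapse = ","))
  }
  keys
}

# all permutations of 1..n as a list
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (i in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = i)
    }
  }
  out
}

# igraph representative of each triad class label (same arc lists the
# package documents, built independently here)
triad_rep_igraph <- function() {
  reps <- list(
    `021D` = c(1, 2, 1, 3), `021U` = c(2, 1, 3, 1), `021C` = c(1, 2, 2, 3),
    `111D` = c(1, 2, 2, 1, 3, 1), `111U` = c(1, 2, 2, 1, 1, 3),
    `030T` = c(1, 2, 1, 3, 2, 3), `030C` = c(1, 2, 2, 3, 3, 1),
    `201` = c(1, 2, 2, 1, 1, 3, 3, 1),
    `120D` = c(1, 2, 2, 1, 3, 1, 3, 2), `120U` = c(1, 2, 2, 1, 1, 3, 2, 3),
    `120C` = c(1, 2, 2, 1, 3, 1, 2, 3),
    `210` = c(1, 2, 2, 1, 1, 3, 3, 1, 2, 3),
    `300` = c(1, 2, 2, 1, 1, 3, 3, 1, 2, 3, 3, 2))
  lapply(reps, function(v) igraph::make_graph(v, n = 3, directed = TRUE))
}
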