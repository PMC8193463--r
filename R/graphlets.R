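# Directed 3-node graphlets (triads). A graphlet instance is an unordered
# node triple whose induced directed subgraph (self-loops ignored) is
# weakly connected, together with the isomorphism class of that subgraph.
# The 13 connected classes carry the standard triad-census MAN labels
# (021D, 021U, 021C, 111D, 111U, 030T, 030C, 201, 120D, 120U, 120C, 210,
# 300). Classing uses a canonical 6-bit arc code minimized over the six
# node permutations; the tables below are built once at install time.

# Arc-code bit layout for an ordered triple (n1, n2, n3):
#   1: n1->n2, 2: n2->n1, 4: n1->n3, 8: n3->n1, 16: n2->n3, 32: n3->n2
triad_code_from_matrix <- function(m) {
  sum(c(1, 2, 4, 8, 16, 32)[c(m[1, 2], m[2, 1], m[1, 3], m[3, 1], m[2, 3], m[3, 2])])
}

triad_matrix_from_code <- function(code) {
  bits <- as.logical(bitwAnd(code, c(1, 2, 4, 8, 16, 32)))
  m <- matrix(FALSE, 3, 3)
  m[1, 2] <- bits[1]; m[2, 1] <- bits[2]
  m[1, 3] <- bits[3]; m[3, 1] <- bits[4]
  m[2, 3] <- bits[5]; m[3, 2] <- bits[6]
  m
}

.triad_tables <- local({
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  canonical <- integer(64)
  connected <- logical(64)
  for (code in 0:63) {
    m <- triad_matrix_from_code(code)
    und <- m | t(m)
    connected[code + 1] <- sum(und[upper.tri(und)]) >= 2
    canonical[code + 1] <- min(vapply(perms, function(p)
      triad_code_from_matrix(m[p, p]), 0))
  }
  reps <- list(
    `021D` = rbind(c(1, 2), c(1, 3)),
    `021U` = rbind(c(2, 1), c(3, 1)),
    `021C` = rbind(c(1, 2), c(2, 3)),
    `111D` = rbind(c(1, 2), c(2, 1), c(3, 1)),
    `111U` = rbind(c(1, 2), c(2, 1), c(1, 3)),
    `030T` = rbind(c(1, 2), c(1, 3), c(2, 3)),
    `030C` = rbind(c(1, 2), c(2, 3), c(3, 1)),
    `201`  = rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1)),
    `120D` = rbind(c(1, 2), c(2, 1), c(3, 1), c(3, 2)),
    `120U` = rbind(c(1, 2), c(2, 1), c(1, 3), c(2, 3)),
    `120C` = rbind(c(1, 2), c(2, 1), c(3, 1), c(2, 3)),
    `210`  = rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3)),
    `300`  = rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
  )
  class_name <- setNames(rep(NA_character_, 64), 0:63)
  for (nm in names(reps)) {
    m <- matrix(FALSE, 3, 3)
    m[reps[[nm]]] <- TRUE
    class_name[[as.character(canonical[triad_code_from_matrix(m) + 1])]] <- nm
  }
  conn_canon <- sort(unique(as.integer(canonical[connected])))
  named_canon <- sort(as.integer(names(class_name)[!is.na(class_name)]))
  stopifnot(identical(conn_canon, named_canon), length(conn_canon) == 13L)
  list(canonical = canonical, connected = connected, class_name = class_name)
})

#' Classify a 3-node directed configuration
#'
#' @param code the 6-bit arc code of an ordered triple.
#' @return The triad class label, or `NA` if the configuration is not
#'   weakly connected.
#' @export
triad_class <- function(code) {
  stopifnot(all(code >= 0 & code <= 63))
  out <- rep(NA_character_, length(code))
  conn <- .triad_tables$connected[code + 1]
  out[conn] <- .triad_tables$class_name[
    as.character(.triad_tables$canonical[code + 1][conn])]
  out
}

# Simple directed edge list (character from/to, self-loops removed,
# duplicates across edge kinds collapsed) from a grn or edge data frame.
simple_arcs <- function(x) {
  e <- if (is(x, "grn")) x$edges else x
  if (!nrow(e)) {
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  a <- unique(data.frame(from = e$regulator_id, to = e$target_id,
                         stringsAsFactors = FALSE))
  a[a$from != a$to, , drop = FALSE]
}

#' Enumerate graphlet instances of a network
#'
#' Finds every unordered node triple whose induced directed subgraph
#' (ignoring self-loops) is weakly connected, with its triad class.
#' Enumeration is edge-anchored: triples are discovered by expanding each
#' arc with the neighbours of its endpoints, never by scanning all n^3
#' triples; every connected triple contains a node adjacent to the other
#' two, so this visits each instance at least once.
#'
#' @param x a `grn` or an edge data frame with `regulator_id`/`target_id`.
#' @return A `data.frame` with columns `n1`, `n2`, `n3` (sorted member
#'   ids), `class` and the canonical instance `key`.
#' @export
enumerate_graphlets <- function(x) {
  arcs <- simple_arcs(x)
  empty <- data.frame(n1 = character(), n2 = character(), n3 = character(),
                      class = character(), key = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(arcs)) return(empty)
  nodes <- sort(unique(c(arcs$from, arcs$to)))
  id <- seq_along(nodes)
  names(id) <- nodes
  fi <- id[arcs$from]
  ti <- id[arcs$to]
  n <- length(nodes)
  # arc presence hash: u * (n+1) + v
  arc_set <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_along(fi)) {
    assign(as.character(fi[k] * (n + 1) + ti[k]), TRUE, envir = arc_set)
  }
  has_arc <- function(u, v) {
    !is.null(arc_set[[as.character(u * (n + 1) + v)]])
  }
  nb <- vector("list", n)
  und <- unique(data.frame(a = pmin(fi, ti), b = pmax(fi, ti)))
  for (k in seq_len(nrow(und))) {
    nb[[und$a[k]]] <- c(nb[[und$a[k]]], und$b[k])
    nb[[und$b[k]]] <- c(nb[[und$b[k]]], und$a[k])
  }
  nb <- lapply(nb, unique)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  rows_n1 <- character(0); rows_n2 <- character(0); rows_n3 <- character(0)
  rows_class <- character(0)
  for (k in seq_len(nrow(und))) {
    u <- und$a[k]; v <- und$b[k]
    for (w in setdiff(union(nb[[u]], nb[[v]]), c(u, v))) {
      trip <- sort(c(u, v, w))
      tkey <- paste(trip, collapse = ",")
      if (!is.null(seen[[tkey]])) next
      assign(tkey, TRUE, envir = seen)
      a <- trip[1]; b <- trip[2]; cc <- trip[3]
      code <- sum(c(1, 2, 4, 8, 16, 32)[c(
        has_arc(a, b), has_arc(b, a), has_arc(a, cc),
        has_arc(cc, a), has_arc(b, cc), has_arc(cc, b))])
      cls <- triad_class(code)
      if (is.na(cls)) next
      rows_n1 <- c(rows_n1, nodes[a]); rows_n2 <- c(rows_n2, nodes[b])
      rows_n3 <- c(rows_n3, nodes[cc]); rows_class <- c(rows_class, cls)
    }
  }
  if (!length(rows_n1)) return(empty)
  out <- data.frame(n1 = rows_n1, n2 = rows_n2, n3 = rows_n3,
                    class = rows_class, stringsAsFactors = FALSE)
  out$key <- paste(out$n1, out$n2, out$n3, out$class, sep = "|")
  out[order(out$key), , drop = FALSE]
}

#' Compare two networks by graphlet presence/absence
#'
#' Graphlet instances (node triple + class) are treated as items of a
#' binary classification: TP = instances in both networks, FP = in `netA`
#' only, FN = in `netB` only. For predicted-vs-gold use, pass the predicted
#' network as `netA`; for time series, `netA` is the later network and
#' `netB` the earlier one. A triple whose induced class changes between the
#' networks is a different instance in each, so it counts as one FP plus
#' one FN.
#'
#' @param netA,netB `grn` objects (or edge data frames).
#' @return A one-row `data.frame` of counts and metrics.
#' @export
compare_graphlets <- function(netA, netB) {
  a <- enumerate_graphlets(netA)$key
  b <- enumerate_graphlets(netB)$key
  classification_metrics(length(intersect(a, b)),
                         length(setdiff(a, b)),
                         length(setdiff(b, a)))
}

#' Per-node local-topology comparison
#'
#' Restricting the graphlet comparison to instances containing one node
#' measures how much that node's local topology differs between the two
#' networks. Each instance contributes to exactly its three member nodes.
#' Nodes participating in no instance of either network are not reported
#' (their F1 is undefined, not 0).
#'
#' @param netA,netB `grn` objects.
#' @return A `data.frame` with one row per participating node: `gene_id`,
#'   `gene_type`, counts and metrics.
#' @export
node_local_f1 <- function(netA, netB) {
  a <- enumerate_graphlets(netA)
  b <- enumerate_graphlets(netB)
  tp_keys <- intersect(a$key, b$key)
  fp <- a[!a$key %in% tp_keys, , drop = FALSE]
  fn <- b[!b$key %in% tp_keys, , drop = FALSE]
  tp <- a[a$key %in% tp_keys, , drop = FALSE]
  count_members <- function(df) {
    members <- c(df$n1, df$n2, df$n3)
    table(members)
  }
  tpc <- count_members(tp); fpc <- count_members(fp); fnc <- count_members(fn)
  nodes <- sort(unique(c(names(tpc), names(fpc), names(fnc))))
  get <- function(tab, ids) {
    v <- as.numeric(tab[ids])
    v[is.na(v)] <- 0
    v
  }
  m <- classification_metrics(get(tpc, nodes), get(fpc, nodes), get(fnc, nodes))
  types <- rbind(netA$nodes[, c("gene_id", "gene_type")],
                 netB$nodes[, c("gene_id", "gene_type")])
  types <- types[!duplicated(types$gene_id), , drop = FALSE]
  gene_type <- types$gene_type[match(nodes, types$gene_id)]
  cbind(data.frame(gene_id = nodes, gene_type = gene_type,
                   stringsAsFactors = FALSE), m)
}

F1_BINS <- c("[0.0,0.5)", "[0.5,0.7)", "[0.7,0.9)", "[0.9,1.0]")

#' Bin per-node F1 values by gene type
#'
#' Nodes are counted into the four F1 intervals [0, 0.5), [0.5, 0.7),
#' [0.7, 0.9) and [0.9, 1.0] (the last closed at 1), overall and separately
#' for TFs, non-TF protein-coding genes and non-coding genes (miRNAs are
#' counted with the non-coding genes).
#'
#' @param report output of [node_local_f1()].
#' @return A `data.frame` with rows `all`, `TF`, `coding`, `noncoding` and
#'   one column per bin.
#' @export
bin_nodes_by_f1 <- function(report) {
  stopifnot(all(c("gene_type", "F1") %in% names(report)))
  bin <- cut(report$F1, breaks = c(0, 0.5, 0.7, 0.9, Inf),
             labels = F1_BINS, right = FALSE)
  grp <- ifelse(report$gene_type %in% "TF", "TF",
                ifelse(report$gene_type %in% "coding", "coding", "noncoding"))
  rows <- c("all", "TF", "coding", "noncoding")
  out <- matrix(0L, nrow = length(rows), ncol = length(F1_BINS),
                dimnames = list(rows, F1_BINS))
  tab_all <- table(bin)
  out["all", names(tab_all)] <- as.integer(tab_all)
  for (g in c("TF", "coding", "noncoding")) {
    tab <- table(bin[grp == g])
    out[g, names(tab)] <- as.integer(tab)
  }
  data.frame(type = rows, out, check.names = FALSE, row.names = NULL)
}
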