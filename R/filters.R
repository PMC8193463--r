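# The evidence-filter cascade. Each filter is a conjunctive veto on an
# edge's immutable evidence plus a +1 credit for surviving edges; the
# surviving edge SET is therefore invariant to filter order, and the final
# weight of an edge is the number of filter identifiers credited to it
# (each distinct active histone mark counts as its own identifier).

#' Default histone-mark effects
#'
#' The default active/repressive assignment for the thirteen histone
#' modifications the histone filter knows about. Active marks permit TF
#' binding and credit edge weight; repressive marks indicate inactive
#' chromatin and never credit.
#'
#' @return Named character vector, mark name -> `"active"` / `"repressive"`.
#' @export
default_mark_effects <- function() {
  c(H3K27me3 = "repressive",
    H3K36me2 = "active",
    H3K36me3 = "active",
    H3K4me1  = "active",
    H3K4me2  = "active",
    H3K4me3  = "active",
    H3K79me2 = "active",
    H3K9ac   = "active",
    H3K9me2  = "repressive",
    H3K9me3  = "repressive",
    H3S10ph  = "active",
    H4K16ac  = "active",
    H4K20me3 = "repressive")
}

resolve_mark_effects <- function(mark_names, effects) {
  bad <- !effects %in% c("active", "repressive")
  if (any(bad)) {
    stop(sprintf("mark effect(s) must be 'active' or 'repressive': %s",
                 paste(names(effects)[bad], collapse = ", ")))
  }
  unknown <- setdiff(mark_names, names(effects))
  if (length(unknown)) {
    stop(sprintf("histone mark(s) with no configured effect: %s",
                 paste(unknown, collapse = ", ")))
  }
  effects[mark_names]
}

# Shared bookkeeping: an outcome table for the current edges of a GRN.
new_outcomes <- function(x) {
  n <- nrow(x$edges)
  data.frame(regulator_id = x$edges$regulator_id,
             target_id = x$edges$target_id,
             edge_kind = x$edges$edge_kind,
             credits = rep("", n), removed_by = rep(NA_character_, n),
             stringsAsFactors = FALSE)
}

# Per-evidence-row edge index for TFBS-scoped filters.
evidence_edge_index <- function(x) {
  match(paste(x$evidence$regulator_id, x$evidence$target_id, "tf_gene", sep = "\r"),
        edge_key(x$edges))
}

apply_outcome <- function(x, outcomes, keep) {
  list(grn = subset_edges(x, keep), outcomes = outcomes)
}

#' DNA methylation filter
#'
#' A positive methylation signal over a TFBS is taken to block TF binding
#' there. A TFBS assignment is inactivated if it overlaps any methylation
#' interval; an edge is removed only if all of its assignments are
#' inactivated. Surviving TF-gene edges are credited `"methylation"`.
#' miRNA-gene edges pass untouched and uncredited. An empty track lets every
#' edge pass (with credit) and is reported via a message.
#'
#' @param x a `grn` with TFBS evidence.
#' @param meth an [evidence_track()] of methylation peaks.
#' @return `list(grn = filtered network, outcomes = per-edge outcome table)`.
#' @export
filter_methylation <- function(x, meth) {
  stopifnot(is(x, "grn"), is(meth, "evidence_track"))
  out <- new_outcomes(x)
  is_tf <- x$edges$edge_kind == "tf_gene"
  if (!nrow(meth$intervals)) {
    message("methylation track is empty: all edges pass the methylation filter")
  }
  methylated <- track_overlaps_any(meth, x$evidence)
  idx <- evidence_edge_index(x)
  # edge survives iff >= 1 of its TFBSs is unmethylated
  n_ev <- tabulate(idx, nbins = nrow(x$edges))
  n_alive <- tabulate(idx[!methylated], nbins = nrow(x$edges))
  keep <- !is_tf | (n_ev > 0 & n_alive > 0)
  out$credits[keep & is_tf] <- "methylation"
  out$removed_by[!keep] <- "methylation"
  apply_outcome(x, out, keep)
}

#' Chromatin accessibility filter
#'
#' A TF-gene edge is kept (and credited `"accessibility"`) if open chromatin
#' is observed near the target promoter: by default, if any accessibility
#' interval overlaps the target's upstream window of size `d` (the same
#' window used to build the reference network); with `scope = "tfbs"`, if it
#' overlaps at least one of the edge's own TFBSs. miRNA-gene edges pass
#' untouched and uncredited.
#'
#' @param x a `grn` built with threshold `d`.
#' @param dnase an [evidence_track()] of accessibility peaks (e.g.
#'   DNase-seq).
#' @param d distance threshold; must equal the network's construction
#'   threshold when that is recorded.
#' @param scope `"window"` (default) or `"tfbs"`.
#' @return `list(grn, outcomes)` as in [filter_methylation()].
#' @export
filter_accessibility <- function(x, dnase, d = x$d,
                                 scope = c("window", "tfbs")) {
  stopifnot(is(x, "grn"), is(dnase, "evidence_track"))
  scope <- match.arg(scope)
  if (!is.na(x$d) && !is.na(d) && d != x$d) {
    stop(sprintf("accessibility filter d (%g) differs from the network's construction threshold (%g)",
                 d, x$d))
  }
  if (is.na(d)) stop("no distance threshold available for the accessibility filter")
  out <- new_outcomes(x)
  is_tf <- x$edges$edge_kind == "tf_gene"
  if (!nrow(dnase$intervals)) {
    message("accessibility track is empty: all edges fail the accessibility filter")
  }
  if (scope == "window") {
    windows <- upstream_windows(x$nodes, d)
    open_window <- windows$gene_id[track_overlaps_any(dnase, windows)]
    accessible <- x$edges$target_id %in% open_window
  } else {
    idx <- evidence_edge_index(x)
    hit <- track_overlaps_any(dnase, x$evidence)
    accessible <- tabulate(idx[hit], nbins = nrow(x$edges)) > 0
  }
  keep <- !is_tf | accessible
  out$credits[keep & is_tf] <- "accessibility"
  out$removed_by[!keep] <- "accessibility"
  apply_outcome(x, out, keep)
}

#' Histone-mark filter
#'
#' For each TF-gene edge, the set of mark types whose peaks overlap at least
#' one of the edge's TFBSs is split into active marks A and repressive marks
#' Rp according to `effects`. Under the default `veto_if_no_active` policy
#' the edge is kept iff A is non-empty; under `always_veto` it is kept iff A
#' is non-empty and Rp is empty. Each distinct active mark type credits +1
#' (once per edge, regardless of peak count); repressive marks never credit.
#' miRNA-gene edges pass untouched and uncredited.
#'
#' @param x a `grn`.
#' @param marks named list, mark name -> [evidence_track()].
#' @param effects mark-effect map as in [default_mark_effects()].
#' @param policy `"veto_if_no_active"` (default) or `"always_veto"`.
#' @return `list(grn, outcomes)`; credited identifiers are the mark names.
#' @export
filter_histone <- function(x, marks, effects = default_mark_effects(),
                           policy = c("veto_if_no_active", "always_veto")) {
  stopifnot(is(x, "grn"), is.list(marks))
  policy <- match.arg(policy)
  if (length(marks) && (is.null(names(marks)) || any(!nzchar(names(marks))))) {
    stop("marks must be a named list keyed by histone mark name")
  }
  eff <- resolve_mark_effects(names(marks), effects)
  out <- new_outcomes(x)
  is_tf <- x$edges$edge_kind == "tf_gene"
  idx <- evidence_edge_index(x)
  n_edge <- nrow(x$edges)
  active_credit <- matrix(FALSE, nrow = n_edge,
                          ncol = length(marks),
                          dimnames = list(NULL, names(marks)))
  repressive_hit <- rep(FALSE, n_edge)
  for (m in names(marks)) {
    hit <- track_overlaps_any(marks[[m]], x$evidence)
    edge_hit <- tabulate(idx[hit], nbins = n_edge) > 0
    if (eff[[m]] == "active") {
      active_credit[, m] <- edge_hit
    } else {
      repressive_hit <- repressive_hit | edge_hit
    }
  }
  n_active <- if (length(marks)) rowSums(active_credit) else rep(0, n_edge)
  keep_tf <- if (policy == "veto_if_no_active") n_active >= 1 else
    n_active >= 1 & !repressive_hit
  keep <- !is_tf | keep_tf
  credited <- apply(active_credit, 1, function(row) paste(names(which(row)), collapse = ";"))
  if (!length(credited)) credited <- character(0)
  out$credits[is_tf & keep] <- credited[is_tf & keep]
  out$removed_by[!keep] <- "histone"
  apply_outcome(x, out, keep)
}

#' Regulator expression filter
#'
#' A TF-gene edge is kept (and credited `"expression"`) iff its regulator's
#' abundance is strictly greater than `threshold`. Regulators absent from
#' the table are treated as not expressed: a context-specific expression
#' table defines the context, and silence is no evidence of expression.
#' miRNA-gene edges are handled by [filter_mirna()] and pass untouched here.
#'
#' @param x a `grn`.
#' @param expr named numeric vector (see [read_abundance_table()]).
#' @param threshold minimum abundance to call a regulator expressed
#'   (strict inequality; default 0).
#' @return `list(grn, outcomes)`.
#' @export
filter_expression <- function(x, expr, threshold = 0) {
  stopifnot(is(x, "grn"), is.numeric(expr))
  out <- new_outcomes(x)
  is_tf <- x$edges$edge_kind == "tf_gene"
  ab <- expr[x$edges$regulator_id]
  expressed <- !is.na(ab) & ab > threshold
  keep <- !is_tf | expressed
  out$credits[is_tf & keep] <- "expression"
  out$removed_by[!keep] <- "expression"
  apply_outcome(x, out, keep)
}

#' miRNA abundance filter
#'
#' Identical contract to [filter_expression()] but restricted to miRNA-gene
#' edges, using the miRNA quantification table. Credits
#' `"mirna_expression"`.
#'
#' @inheritParams filter_expression
#' @param mirna_expr named numeric vector of miRNA abundances.
#' @return `list(grn, outcomes)`.
#' @export
filter_mirna <- function(x, mirna_expr, threshold = 0) {
  stopifnot(is(x, "grn"), is.numeric(mirna_expr))
  out <- new_outcomes(x)
  is_mir <- x$edges$edge_kind == "mirna_gene"
  ab <- mirna_expr[x$edges$regulator_id]
  expressed <- !is.na(ab) & ab > threshold
  keep <- !is_mir | expressed
  out$credits[is_mir & keep] <- "mirna_expression"
  out$removed_by[!keep] <- "mirna_expression"
  apply_outcome(x, out, keep)
}

#' Apply the full filter cascade
#'
#' Filters run in the fixed order methylation, accessibility, histone
#' marks, regulator expression, miRNA abundance. Filters whose data are not
#' supplied are skipped entirely (no veto, no credit) -- except expression,
#' the tool's minimum input, which is required. Each surviving edge's
#' weight is the total number of filter identifiers credited to it across
#' the applied filters.
#'
#' @param x a reference `grn`.
#' @param expression named numeric vector of gene abundances (required).
#' @param methylation,accessibility optional [evidence_track()]s.
#' @param histone optional named list of mark tracks.
#' @param mirna_expression optional named numeric vector of miRNA
#'   abundances.
#' @param mark_effects mark-effect map (default [default_mark_effects()]).
#' @param expression_threshold,mirna_threshold strict abundance cutoffs
#'   (default 0).
#' @param repressive_policy passed to [filter_histone()].
#' @param accessibility_scope passed to [filter_accessibility()].
#' @return `list(grn, report)`. The returned network's edges carry `weight`
#'   and a semicolon-joined `passed_filters` column; the report records the
#'   filters applied, per-filter removal counts and the weight histogram.
#' @export
apply_cascade <- function(x, expression,
                          methylation = NULL, accessibility = NULL,
                          histone = NULL, mirna_expression = NULL,
                          mark_effects = default_mark_effects(),
                          expression_threshold = 0, mirna_threshold = 0,
                          repressive_policy = "veto_if_no_active",
                          accessibility_scope = "window") {
  stopifnot(is(x, "grn"))
  if (missing(expression) || is.null(expression)) {
    stop("a gene expression quantification is the minimum required input")
  }
  steps <- list()
  if (!is.null(methylation)) {
    steps$methylation <- function(g) filter_methylation(g, methylation)
  }
  if (!is.null(accessibility)) {
    steps$accessibility <- function(g)
      filter_accessibility(g, accessibility, d = x$d, scope = accessibility_scope)
  }
  if (!is.null(histone) && length(histone)) {
    steps$histone <- function(g)
      filter_histone(g, histone, effects = mark_effects, policy = repressive_policy)
  }
  steps$expression <- function(g)
    filter_expression(g, expression, threshold = expression_threshold)
  if (!is.null(mirna_expression)) {
    steps$mirna <- function(g)
      filter_mirna(g, mirna_expression, threshold = mirna_threshold)
  }

  credits <- setNames(rep("", nrow(x$edges)), edge_key(x$edges))
  removed_by <- setNames(rep(NA_character_, nrow(x$edges)), edge_key(x$edges))
  removal_counts <- setNames(integer(length(steps)), names(steps))
  g <- x
  for (step in names(steps)) {
    res <- steps[[step]](g)
    oc <- res$outcomes
    key <- paste(oc$regulator_id, oc$target_id, oc$edge_kind, sep = "\r")
    got <- nzchar(oc$credits)
    credits[key[got]] <- ifelse(nzchar(credits[key[got]]),
                                paste(credits[key[got]], oc$credits[got], sep = ";"),
                                oc$credits[got])
    dropped <- !is.na(oc$removed_by)
    removed_by[key[dropped]] <- oc$removed_by[dropped]
    removal_counts[[step]] <- sum(dropped)
    g <- res$grn
  }
  n_credits <- vapply(strsplit(credits, ";", fixed = TRUE),
                      function(v) sum(nzchar(v)), 0L)
  key_surv <- edge_key(g$edges)
  g$edges$weight <- as.numeric(n_credits[key_surv])
  g$edges$passed_filters <- unname(credits[key_surv])
  g$provenance <- c(g$provenance,
                    sprintf("filter cascade: %s", paste(names(steps), collapse = " -> ")))
  report <- list(
    filters_applied = names(steps),
    removal_counts = removal_counts,
    n_input_edges = nrow(x$edges),
    n_output_edges = nrow(g$edges),
    weight_histogram = table(g$edges$weight),
    outcomes = data.frame(regulator_id = x$edges$regulator_id,
                          target_id = x$edges$target_id,
                          edge_kind = x$edges$edge_kind,
                          passed = unname(credits),
                          weight = unname(n_credits),
                          removed_by = unname(removed_by),
                          stringsAsFactors = FALSE)
  )
  list(grn = g, report = report)
}

#' Extract the subnetwork of edges at or above a weight
#'
#' @param x a weighted `grn`.
#' @param min_weight minimum edge weight (>= 0).
#' @return The `grn` restricted to edges with `weight >= min_weight`. Node
#'   metadata is retained; the edge-induced view drops isolated nodes
#'   implicitly.
#' @export
threshold_by_weight <- function(x, min_weight) {
  stopifnot(is(x, "grn"), min_weight >= 0)
  subset_edges(x, x$edges$weight >= min_weight)
}
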