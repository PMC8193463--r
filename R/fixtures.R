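# Synthetic toy genomes with planted ground truth. Gene promoter windows
# are non-overlapping by construction (except in the dedicated
# overlapping-promoters scenario), so each planted piece of evidence maps
# to exactly one edge and the expected outcome of every filter is known by
# construction, not by running the pipeline.

FIXTURE_SCENARIOS <- c("all_pass", "methylated_out", "mixed",
                       "overlapping_promoters")

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# One TFBS for TF k upstream of a gene; width 20, offset grows with k so
# TFBSs of different TFs never collide.
plant_tfbs <- function(gene, k, d) {
  offset <- 100 + 60 * k
  stopifnot(offset + 20 < d)
  if (gene$strand == "+") {
    end <- gene$tss - offset
    data.frame(chrom = gene$chrom, start = end - 20, end = end,
               stringsAsFactors = FALSE)
  } else {
    start <- gene$tss + 1 + offset
    data.frame(chrom = gene$chrom, start = start, end = start + 20,
               stringsAsFactors = FALSE)
  }
}

# An accessibility peak inside a gene's upstream window.
plant_open_window <- function(gene, d) {
  if (gene$strand == "+") {
    data.frame(chrom = gene$chrom, start = gene$tss - d + 5,
               end = gene$tss - d + 105, stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = gene$chrom, start = gene$tss + 5,
               end = gene$tss + 105, stringsAsFactors = FALSE)
  }
}

pad <- function(iv, by) {
  data.frame(chrom = iv$chrom, start = iv$start - by, end = iv$end + by,
             stringsAsFactors = FALSE)
}

#' Generate a deterministic synthetic fixture
#'
#' Builds a toy genome (gene annotation, per-TF TFBS tracks, methylation /
#' accessibility / histone-mark tracks, expression tables, miRNA targets
#' and per-TF ChIP-seq peaks) together with the exact expected reference
#' edge set, surviving edge set with weights, per-filter removal counts and
#' gold-standard edge set, all known by construction.
#'
#' Scenarios:
#' * `all_pass` -- every planted edge passes every filter (TF-gene weight 4
#'   = methylation + accessibility + one active mark + expression; miRNA
#'   edges weight 1).
#' * `methylated_out` -- as `all_pass`, but the only TFBS of every
#'   even-indexed target is methylated, removing those edges.
#' * `mixed` -- one TF edge per target, cycling through eight fates: full
#'   pass with one or two active marks, methylated, inaccessible promoter,
#'   repressive-mark-only, no marks, active+repressive mixed signal, and
#'   an unexpressed regulator; one expressed and one silent miRNA.
#' * `overlapping_promoters` -- two genes share upstream sequence; a single
#'   TFBS in the shared region yields two edges.
#'
#' @param scenario one of `r paste(FIXTURE_SCENARIOS, collapse = ", ")`.
#' @param n_genes total number of genes including regulators (default 16).
#' @param n_tfs,n_mirnas regulator counts (defaults 3 and 2).
#' @param d assignment distance threshold in nucleotides (default 1500).
#' @param chrom_length toy chromosome length; genes must fit (default
#'   sized to the gene layout).
#' @param seed integer seed; identical (spec, seed) pairs generate
#'   identical fixtures.
#' @return An object of class `grn_fixture`: the input data plus a `truth`
#'   list with `reference_edges`, `network_edges` (with weights),
#'   `removed_by` counts and `gold_edges`.
#' @export
generate_fixture <- function(scenario = c("all_pass", "methylated_out",
                                          "mixed", "overlapping_promoters"),
                             n_genes = 16, n_tfs = 3, n_mirnas = 2,
                             d = 1500, chrom_length = NULL, seed = 1) {
  scenario <- match.arg(scenario)
  if (n_tfs + n_mirnas > n_genes) stop("n_tfs + n_mirnas must not exceed n_genes")
  n_targets <- n_genes - n_tfs - n_mirnas
  if (n_targets < 8) stop("fixture needs at least 8 non-regulator genes")
  spacing <- 4 * d
  offset0 <- 2 * d
  need <- offset0 + n_genes * spacing + d
  if (is.null(chrom_length)) chrom_length <- need
  if (chrom_length < need) {
    stop(sprintf("chrom_length %d too small for %d genes (need >= %d)",
                 chrom_length, n_genes, need))
  }
  with_seed(seed, build_fixture(scenario, n_genes, n_tfs, n_mirnas, n_targets,
                                d, spacing, offset0, seed))
}

build_fixture <- function(scenario, n_genes, n_tfs, n_mirnas, n_targets,
                          d, spacing, offset0, seed) {
  chrom <- "chrS"
  ids <- c(sprintf("tf%d", seq_len(n_tfs)),
           sprintf("mir%d", seq_len(n_mirnas)),
           sprintf("gene%02d", seq_len(n_targets)))
  types <- c(rep("TF", n_tfs), rep("miRNA", n_mirnas),
             rep(c("coding", "coding", "coding", "noncoding"),
                 length.out = n_targets))
  strands <- rep(c("+", "+", "+", "-"), length.out = n_genes)
  tss <- offset0 + (seq_len(n_genes) - 1) * spacing
  genes <- data.frame(gene_id = ids, chrom = chrom, strand = strands,
                      tss = as.numeric(tss), gene_type = types,
                      stringsAsFactors = FALSE)
  if (scenario == "overlapping_promoters") {
    # last two targets share upstream sequence on the + strand
    i2 <- n_genes; i1 <- n_genes - 1
    genes$strand[c(i1, i2)] <- "+"
    genes$tss[i2] <- genes$tss[i1] + 200
  }
  validate_annotation(genes)
  gene_row <- function(id) genes[genes$gene_id == id, , drop = FALSE]
  tf_ids <- ids[seq_len(n_tfs)]
  mir_ids <- ids[n_tfs + seq_len(n_mirnas)]
  target_ids <- ids[(n_tfs + n_mirnas + 1):n_genes]

  # planted edge plan: one row per (tf, target, tfbs)
  plan <- switch(
    scenario,
    all_pass = ,
    methylated_out = {
      rows <- expand.grid(tf = tf_ids, target = target_ids,
                          stringsAsFactors = FALSE)
      rows$fate <- "pass1"
      if (scenario == "methylated_out") {
        even <- match(rows$target, target_ids) %% 2 == 0
        rows$fate[even] <- "methylated"
      }
      rows
    },
    mixed = {
      fates <- c("pass1", "pass2", "methylated", "inaccessible",
                 "repressive_only", "no_marks", "mixed_marks", "unexpressed")
      rows <- data.frame(target = target_ids,
                         fate = rep(fates, length.out = n_targets),
                         stringsAsFactors = FALSE)
      other_tfs <- tf_ids[-n_tfs]
      rows$tf <- rep(other_tfs, length.out = n_targets)
      rows$tf[rows$fate == "unexpressed"] <- tf_ids[n_tfs]
      rows[, c("tf", "target", "fate")]
    },
    overlapping_promoters = {
      data.frame(tf = tf_ids[1], target = c(target_ids[n_targets - 1],
                                            target_ids[n_targets]),
                 fate = "pass1", shared = TRUE, stringsAsFactors = FALSE)
    })

  meth_iv <- data.frame(chrom = chrom, start = 10, end = 60,
                        stringsAsFactors = FALSE)  # decoy away from genes
  dnase_iv <- NULL
  marks <- list(H3K4me3 = NULL, H3K9ac = NULL, H3K27me3 = NULL)
  tfbs <- setNames(vector("list", n_tfs), tf_ids)

  if (scenario == "overlapping_promoters") {
    g1 <- gene_row(plan$target[1])
    iv <- plant_tfbs(g1, 1, d)  # upstream of the earlier gene, inside both windows
    tfbs[[plan$tf[1]]] <- iv
    dnase_iv <- rbind(plant_open_window(g1, d),
                      plant_open_window(gene_row(plan$target[2]), d))
    marks$H3K4me3 <- pad(iv, 2)
    plan$tfbs_start <- iv$start
    plan$tfbs_end <- iv$end
  } else {
    plan$tfbs_start <- NA_real_
    plan$tfbs_end <- NA_real_
    for (r in seq_len(nrow(plan))) {
      g <- gene_row(plan$target[r])
      k <- match(plan$tf[r], tf_ids)
      iv <- plant_tfbs(g, k, d)
      plan$tfbs_start[r] <- iv$start
      plan$tfbs_end[r] <- iv$end
      tfbs[[plan$tf[r]]] <- rbind(tfbs[[plan$tf[r]]], iv)
      fate <- plan$fate[r]
      if (fate == "methylated") meth_iv <- rbind(meth_iv, pad(iv, 1))
      if (fate != "inaccessible") dnase_iv <- rbind(dnase_iv, plant_open_window(g, d))
      if (fate %in% c("pass1", "unexpressed")) marks$H3K4me3 <- rbind(marks$H3K4me3, pad(iv, 2))
      if (fate == "pass2") {
        marks$H3K4me3 <- rbind(marks$H3K4me3, pad(iv, 2))
        marks$H3K9ac <- rbind(marks$H3K9ac, pad(iv, 2))
      }
      if (fate == "methylated") marks$H3K4me3 <- rbind(marks$H3K4me3, pad(iv, 2))
      if (fate == "repressive_only") marks$H3K27me3 <- rbind(marks$H3K27me3, pad(iv, 2))
      if (fate == "mixed_marks") {
        marks$H3K4me3 <- rbind(marks$H3K4me3, pad(iv, 2))
        marks$H3K27me3 <- rbind(marks$H3K27me3, pad(iv, 2))
      }
    }
  }
  marks <- Filter(Negate(is.null), marks)
  as_track <- function(df, label, kind) {
    if (is.null(df)) df <- data.frame(chrom = character(), start = numeric(),
                                      end = numeric(), stringsAsFactors = FALSE)
    evidence_track(genomic_intervals(df$chrom, df$start, df$end), label, kind)
  }
  tfbs_by_tf <- lapply(tf_ids, function(tf) {
    as_track(tfbs[[tf]], paste0(tf, "_tfbs"), "tfbs")
  })
  names(tfbs_by_tf) <- tf_ids
  histone <- lapply(names(marks), function(m) as_track(marks[[m]], m, "histone_mark"))
  names(histone) <- names(marks)

  # expression: expressed regulators get a positive abundance drawn once
  unexpressed_tfs <- if (scenario == "mixed") tf_ids[n_tfs] else character(0)
  expr_tf <- setNames(round(stats::runif(n_tfs, 5, 50), 2), tf_ids)
  expr_tf[unexpressed_tfs] <- 0
  expression <- c(expr_tf,
                  setNames(round(stats::runif(n_targets, 0, 20), 2), target_ids))
  silent_mirnas <- if (scenario == "mixed") mir_ids[n_mirnas] else character(0)
  mirna_expression <- setNames(round(stats::runif(n_mirnas, 2, 30), 2), mir_ids)
  mirna_expression[silent_mirnas] <- 0
  mirna_targets <- data.frame(
    mirna_id = rep(mir_ids, each = 2),
    target_id = target_ids[(seq_len(2 * n_mirnas) - 1) %% n_targets + 1],
    stringsAsFactors = FALSE)

  # ChIP occupancy for the gold standard: peaks for all TFs but the last,
  # covering the TFBSs of their odd-indexed targets
  chip_tfs <- tf_ids[-n_tfs]
  if (scenario == "overlapping_promoters") chip_tfs <- tf_ids[1]
  chip_by_tf <- list()
  gold_rows <- NULL
  for (tf in chip_tfs) {
    sel <- plan$tf == tf & match(plan$target, target_ids) %% 2 == 1
    iv <- plan[sel, , drop = FALSE]
    peaks <- if (nrow(iv)) {
      pad(data.frame(chrom = chrom, start = iv$tfbs_start, end = iv$tfbs_end,
                     stringsAsFactors = FALSE), 3)
    } else NULL
    chip_by_tf[[tf]] <- as_track(peaks, paste0(tf, "_chip"), "chip_peak")
    if (nrow(iv)) {
      gold_rows <- rbind(gold_rows, unique(iv[, c("tf", "target")]))
    }
  }
  if (scenario == "overlapping_promoters") {
    # the single shared TFBS is occupied: both edges are gold
    gold_rows <- unique(plan[, c("tf", "target")])
  }

  # expected outcomes by construction
  surviving <- !plan$fate %in% c("methylated", "inaccessible",
                                 "repressive_only", "no_marks", "unexpressed")
  weight_of <- c(pass1 = 4, pass2 = 5, mixed_marks = 4)
  network_tf <- data.frame(
    regulator_id = plan$tf[surviving], target_id = plan$target[surviving],
    edge_kind = "tf_gene",
    weight = as.numeric(weight_of[plan$fate[surviving]]),
    stringsAsFactors = FALSE)
  mir_expressed <- mirna_expression[mirna_targets$mirna_id] > 0
  network_mir <- data.frame(
    regulator_id = mirna_targets$mirna_id[mir_expressed],
    target_id = mirna_targets$target_id[mir_expressed],
    edge_kind = "mirna_gene", weight = 1, stringsAsFactors = FALSE)
  reference_edges <- rbind(
    data.frame(regulator_id = plan$tf, target_id = plan$target,
               edge_kind = "tf_gene", stringsAsFactors = FALSE),
    data.frame(regulator_id = mirna_targets$mirna_id,
               target_id = mirna_targets$target_id,
               edge_kind = "mirna_gene", stringsAsFactors = FALSE))
  reference_edges <- unique(reference_edges)
  removed_by <- c(
    methylation = sum(plan$fate == "methylated"),
    accessibility = sum(plan$fate == "inaccessible"),
    histone = sum(plan$fate %in% c("repressive_only", "no_marks")),
    expression = sum(plan$fate == "unexpressed"),
    mirna = sum(!mir_expressed))
  truth <- list(
    reference_edges = reference_edges,
    network_edges = rbind(network_tf, network_mir),
    removed_by = removed_by,
    gold_edges = if (is.null(gold_rows)) {
      data.frame(regulator_id = character(), target_id = character(),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(regulator_id = gold_rows$tf, target_id = gold_rows$target,
                 stringsAsFactors = FALSE)
    },
    plan = plan)

  structure(
    list(scenario = scenario,
         genes = genes, d = d, seed = seed,
         tfbs_by_tf = tfbs_by_tf,
         methylation = as_track(meth_iv, "methylation", "methylation"),
         accessibility = as_track(dnase_iv, "accessibility", "accessibility"),
         histone = histone,
         expression = expression,
         mirna_expression = mirna_expression,
         mirna_targets = mirna_targets,
         chip_by_tf = chip_by_tf,
         truth = truth),
    class = "grn_fixture")
}

#' Run the standard pipeline on a fixture
#'
#' Convenience wrapper: TFBS assignment, reference construction, miRNA edge
#' merging and the full filter cascade, using the fixture's own tracks and
#' tables.
#'
#' @param fx a `grn_fixture`.
#' @param min_weight optional weight threshold applied to the filtered
#'   network.
#' @return `list(reference, filtered, report)`.
#' @export
fixture_pipeline <- function(fx, min_weight = NULL) {
  stopifnot(is(fx, "grn_fixture"))
  asg <- assign_tfbs_to_genes(fx$tfbs_by_tf, fx$genes, fx$d)
  ref <- build_reference_network(asg, fx$genes, d = fx$d)
  ref <- suppressWarnings(add_mirna_edges(ref, fx$mirna_targets))
  res <- apply_cascade(ref, expression = fx$expression,
                       methylation = fx$methylation,
                       accessibility = fx$accessibility,
                       histone = fx$histone,
                       mirna_expression = fx$mirna_expression)
  filtered <- res$grn
  if (!is.null(min_weight)) filtered <- threshold_by_weight(filtered, min_weight)
  list(reference = ref, filtered = filtered, report = res$report)
}

#' Write a fixture's files to a directory
#'
#' Emits all inputs in the formats the readers consume (annotation TSV,
#' per-TF TFBS BEDs, evidence BEDs, abundance TSVs, miRNA target TSV,
#' per-TF ChIP BEDs) plus ground-truth manifests
#' (`truth_reference_edges.tsv`, `truth_network_edges.tsv`).
#'
#' @param fx a `grn_fixture`.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of written paths.
#' @export
write_fixture <- function(fx, dir) {
  stopifnot(is(fx, "grn_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- list()
  p$annotation <- file.path(dir, "genes.tsv")
  write_gene_annotation(fx$genes, p$annotation)
  for (tf in names(fx$tfbs_by_tf)) {
    path <- file.path(dir, sprintf("tfbs_%s.bed", tf))
    write_bed(fx$tfbs_by_tf[[tf]], path)
    p$tfbs[[tf]] <- path
  }
  p$methylation <- file.path(dir, "methylation.bed")
  write_bed(fx$methylation, p$methylation)
  p$accessibility <- file.path(dir, "accessibility.bed")
  write_bed(fx$accessibility, p$accessibility)
  for (m in names(fx$histone)) {
    path <- file.path(dir, sprintf("histone_%s.bed", m))
    write_bed(fx$histone[[m]], path)
    p$histone[[m]] <- path
  }
  p$expression <- file.path(dir, "expression.tsv")
  write.table(data.frame(gene_id = names(fx$expression),
                         abundance = fx$expression),
              p$expression, sep = "\t", quote = FALSE, row.names = FALSE)
  p$mirna_expression <- file.path(dir, "mirna_expression.tsv")
  write.table(data.frame(gene_id = names(fx$mirna_expression),
                         abundance = fx$mirna_expression),
              p$mirna_expression, sep = "\t", quote = FALSE, row.names = FALSE)
  p$mirna_targets <- file.path(dir, "mirna_targets.tsv")
  write.table(fx$mirna_targets, p$mirna_targets, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  for (tf in names(fx$chip_by_tf)) {
    path <- file.path(dir, sprintf("chip_%s.bed", tf))
    write_bed(fx$chip_by_tf[[tf]], path)
    p$chip[[tf]] <- path
  }
  p$truth_reference <- file.path(dir, "truth_reference_edges.tsv")
  write.table(fx$truth$reference_edges, p$truth_reference, sep = "\t",
              quote = FALSE, row.names = FALSE)
  p$truth_network <- file.path(dir, "truth_network_edges.tsv")
  write.table(fx$truth$network_edges, p$truth_network, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(p)
}

#' Generate a time-series of rewired networks with exact edge bookkeeping
#'
#' Starting from a random regulator-to-target network, each subsequent time
#' point rewires a `churn_rate` fraction of edges (removals replaced by an
#' equal number of new edges never equal to a removed one), so the
#' edge-level TP/FP/FN between consecutive networks is known exactly from
#' the rewiring log.
#'
#' @param n_genes,n_regulators,n_edges network size (defaults 30, 6, 60).
#' @param n_timepoints number of networks (>= 2).
#' @param churn_rate fraction of edges rewired per step, in `[0, 1]`.
#' @param seed integer seed.
#' @return `list(networks, expected)` where `expected` has one row per
#'   consecutive pair with the exact TP/FP/FN (later network vs earlier).
#' @export
generate_timeseries_fixture <- function(n_genes = 30, n_regulators = 6,
                                        n_edges = 60, n_timepoints = 4,
                                        churn_rate = 0.2, seed = 1) {
  stopifnot(churn_rate >= 0, churn_rate <= 1, n_timepoints >= 2)
  with_seed(seed, {
    ids <- sprintf("g%02d", seq_len(n_genes))
    types <- c(rep("TF", n_regulators),
               rep(c("coding", "coding", "noncoding"),
                   length.out = n_genes - n_regulators))
    nodes <- data.frame(gene_id = ids, chrom = "chrT", strand = "+",
                        tss = as.numeric(seq_len(n_genes) * 1000),
                        gene_type = types, stringsAsFactors = FALSE)
    regs <- ids[seq_len(n_regulators)]
    all_pairs <- expand.grid(regulator_id = regs, target_id = ids,
                             stringsAsFactors = FALSE)
    all_pairs <- all_pairs[all_pairs$regulator_id != all_pairs$target_id, ]
    pair_key <- paste(all_pairs$regulator_id, all_pairs$target_id)
    if (n_edges > nrow(all_pairs)) stop("n_edges exceeds available pairs")
    current <- sample(nrow(all_pairs), n_edges)
    as_grn <- function(sel) {
      e <- all_pairs[sel, , drop = FALSE]
      e$edge_kind <- "tf_gene"
      e$weight <- 0
      grn(nodes, e)
    }
    networks <- list(as_grn(current))
    n_change <- round(churn_rate * n_edges)
    expected <- NULL
    for (t in seq_len(n_timepoints - 1)) {
      removed <- if (n_change) sample(current, n_change) else integer(0)
      kept <- setdiff(current, removed)
      pool <- setdiff(seq_len(nrow(all_pairs)), union(current, removed))
      added <- if (n_change) sample(pool, n_change) else integer(0)
      new <- c(kept, added)
      expected <- rbind(expected, data.frame(
        step = t, TP = length(kept), FP = length(added),
        FN = length(removed)))
      networks[[t + 1]] <- as_grn(new)
      current <- new
    }
    list(networks = networks, expected = expected,
         churn_rate = churn_rate, seed = seed)
  })
}
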