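# Helper: a two-TFBS edge (tfA -> g1) plus miRNA edge for pass-through checks
two_site_grn <- function(d = 1500) {
  genes <- data.frame(
    gene_id = c("tfA", "mir1", "g1"), chrom = "chr1",
    strand = "+", tss = c(500, 700, 10000),
    gene_type = c("TF", "miRNA", "coding"), stringsAsFactors = FALSE)
  ev <- data.frame(regulator_id = "tfA", target_id = "g1", chrom = "chr1",
                   start = c(9000, 8000), end = c(9010, 8010),
                   name = NA_character_, distance = c(990, 1990),
                   stringsAsFactors = FALSE)
  edges <- data.frame(
    regulator_id = c("tfA", "mir1"), target_id = c("g1", "g1"),
    edge_kind = c("tf_gene", "mirna_gene"), weight = 0,
    stringsAsFactors = FALSE)
  grn(genes, edges, ev, d = d)
}

tf_keys <- function(g) {
  e <- g$edges[g$edges$edge_kind == "tf_gene", ]
  sort(paste(e$regulator_id, e$target_id))
}

test_that("methylation removes an edge only when every TFBS is methylated", {
  g <- single_edge_grn(9000, 9010)
  res <- filter_methylation(g, make_track(9005, 9100, kind = "methylation"))
  expect_equal(nrow(res$grn$edges), 0)
  expect_equal(res$outcomes$removed_by[res$outcomes$edge_kind == "tf_gene"],
               "methylation")

  g2 <- two_site_grn()
  res2 <- filter_methylation(g2, make_track(9005, 9100, kind = "methylation"))
  expect_equal(tf_keys(res2$grn), "tfA g1")
  oc <- res2$outcomes[res2$outcomes$edge_kind == "tf_gene", ]
  expect_equal(oc$credits, "methylation")
  # miRNA edge untouched and uncredited
  expect_true("mirna_gene" %in% res2$grn$edges$edge_kind)
  expect_equal(res2$outcomes$credits[res2$outcomes$edge_kind == "mirna_gene"], "")
  # empty track: everything passes, with credit
  expect_message(res3 <- filter_methylation(g2, make_track(numeric(0), numeric(0))),
                 "empty")
  expect_equal(nrow(res3$grn$edges), 2)
})

test_that("accessibility keeps edges with open chromatin in the promoter window", {
  g <- single_edge_grn(9000, 9010, d = 1500)
  # peak 500 nt upstream of the TSS, inside the window
  res <- filter_accessibility(g, make_track(9450, 9500, kind = "accessibility"))
  expect_equal(nrow(res$grn$edges), 1)
  expect_equal(res$outcomes$credits[1], "accessibility")
  # nearest peak 3000 nt upstream: outside a 1.5 kb window
  far <- make_track(6900, 7000, kind = "accessibility")
  expect_equal(nrow(filter_accessibility(g, far)$grn$edges), 0)
  # but inside a 5 kb window
  g5 <- single_edge_grn(9000, 9010, d = 5000)
  expect_equal(nrow(filter_accessibility(g5, far)$grn$edges), 1)
  # threshold mismatch is an error
  expect_error(filter_accessibility(g, far, d = 2000), "differs")
})

test_that("histone filter credits distinct active mark types and vetoes repressive-only sites", {
  g <- single_edge_grn(9000, 9010)
  act2 <- list(H3K4me3 = make_track(8995, 9015), H3K9ac = make_track(9001, 9009))
  res <- filter_histone(g, act2)
  expect_equal(nrow(res$grn$edges), 1)
  expect_setequal(strsplit(res$outcomes$credits[1], ";")[[1]],
                  c("H3K4me3", "H3K9ac"))

  rep_only <- list(H3K27me3 = make_track(8995, 9015))
  expect_equal(nrow(filter_histone(g, rep_only)$grn$edges), 0)
  expect_equal(nrow(filter_histone(g, rep_only, policy = "always_veto")$grn$edges), 0)

  # three peaks of one mark credit once, not three times
  multi <- list(H3K4me3 = make_track(c(8990, 9000, 9005), c(9002, 9004, 9020)))
  res3 <- filter_histone(g, multi)
  expect_equal(res3$outcomes$credits[1], "H3K4me3")

  # mixed active + repressive: kept under the default policy (actives credit),
  # vetoed under always_veto
  mixed <- list(H3K4me3 = make_track(8995, 9015), H3K27me3 = make_track(8995, 9015))
  expect_equal(nrow(filter_histone(g, mixed)$grn$edges), 1)
  expect_equal(filter_histone(g, mixed)$outcomes$credits[1], "H3K4me3")
  expect_equal(nrow(filter_histone(g, mixed, policy = "always_veto")$grn$edges), 0)

  expect_error(filter_histone(g, list(H9Z = make_track(1, 2))), "H9Z")
})

test_that("expression gates regulator out-edges with a strict threshold", {
  g <- two_site_grn()
  res <- filter_expression(g, c(tfA = 5), threshold = 0)
  expect_equal(tf_keys(res$grn), "tfA g1")
  expect_equal(res$outcomes$credits[res$outcomes$edge_kind == "tf_gene"],
               "expression")
  # absent from the table means not expressed
  expect_equal(tf_keys(filter_expression(g, c(other = 5))$grn), character(0))
  # boundary: equal to the threshold is not expressed
  expect_equal(tf_keys(filter_expression(g, c(tfA = 5), threshold = 5)$grn),
               character(0))
  # miRNA edges are untouched by the gene-expression filter
  expect_true("mirna_gene" %in% filter_expression(g, c(other = 1))$grn$edges$edge_kind)
})

test_that("the miRNA filter mirrors expression semantics on mirna_gene edges", {
  g <- two_site_grn()
  res <- filter_mirna(g, c(mir1 = 3))
  expect_true("mirna_gene" %in% res$grn$edges$edge_kind)
  expect_equal(res$outcomes$credits[res$outcomes$edge_kind == "mirna_gene"],
               "mirna_expression")
  res0 <- filter_mirna(g, c(mir1 = 0))
  expect_false("mirna_gene" %in% res0$grn$edges$edge_kind)
  # TF edges untouched either way
  expect_equal(tf_keys(res0$grn), "tfA g1")
  # a network with no miRNA edges is unchanged
  g1 <- single_edge_grn(9000, 9010)
  expect_equal(nrow(filter_mirna(g1, c(mir1 = 0))$grn$edges), 1)
})

test_that("cascade weights count the filters each edge passed", {
  g <- single_edge_grn(9000, 9010)
  # expression only: weight 1
  r1 <- apply_cascade(g, expression = c(tfA = 10))
  expect_equal(r1$grn$edges$weight, 1)
  expect_equal(r1$grn$edges$passed_filters, "expression")
  # expression + one crediting mark: weight 2
  r2 <- apply_cascade(g, expression = c(tfA = 10),
                      histone = list(H3K4me3 = make_track(8995, 9015)))
  expect_equal(r2$grn$edges$weight, 2)
  # expression + 10 active mark types: weight 11
  marks10 <- setNames(
    lapply(1:10, function(i) make_track(8995, 9015)),
    c(names(which(default_mark_effects() == "active")), "H3K27ac"))
  effects <- c(default_mark_effects(), H3K27ac = "active")
  r11 <- apply_cascade(g, expression = c(tfA = 10), histone = marks10,
                       mark_effects = effects)
  expect_equal(r11$grn$edges$weight, 11)
})

test_that("the cascade applies only supplied filters and reports removals", {
  fx <- generate_fixture("mixed", seed = 2)
  pp <- fixture_pipeline(fx)
  expect_identical(pp$report$filters_applied,
                   c("methylation", "accessibility", "histone", "expression", "mirna"))
  expect_equal(as.integer(pp$report$removal_counts),
               as.integer(fx$truth$removed_by[names(pp$report$removal_counts)]))
  # no expression data is a contract violation: it is the minimum input
  ref <- pp$reference
  expect_error(apply_cascade(ref, expression = NULL), "minimum")
  # subset chain: every surviving edge existed in the reference
  expect_true(all(epigrn:::edge_key(pp$filtered$edges) %in%
                    epigrn:::edge_key(ref$edges)))
  # weight accounting against per-edge outcomes
  oc <- pp$report$outcomes
  surv <- oc[is.na(oc$removed_by), ]
  expect_equal(
    surv$weight,
    vapply(strsplit(surv$passed, ";", fixed = TRUE),
           function(v) sum(nzchar(v)), 0L))
})

test_that("surviving edge sets are invariant to filter order", {
  fx <- generate_fixture("mixed", seed = 8)
  pp <- fixture_pipeline(fx)
  ref <- pp$reference
  steps <- list(
    meth = function(g) filter_methylation(g, fx$methylation)$grn,
    acc = function(g) filter_accessibility(g, fx$accessibility, d = ref$d)$grn,
    hist = function(g) filter_histone(g, fx$histone)$grn,
    expr = function(g) filter_expression(g, fx$expression)$grn,
    mir = function(g) filter_mirna(g, fx$mirna_expression)$grn)
  perms <- combinat_perms(5)
  baseline <- sort(epigrn:::edge_key(pp$filtered$edges))
  for (p in perms) {
    g <- ref
    for (i in p) g <- suppressMessages(steps[[i]](g))
    expect_identical(sort(epigrn:::edge_key(g$edges)), baseline)
  }
})

test_that("extra supporting evidence never hurts and methylation never helps", {
  g <- single_edge_grn(9000, 9010)
  base_marks <- list(H3K4me3 = make_track(8995, 9015))
  run <- function(marks, meth = NULL) {
    apply_cascade(g, expression = c(tfA = 10), histone = marks,
                  methylation = meth)
  }
  w0 <- run(base_marks)$grn$edges$weight
  # adding an active-mark peak keeps the edge, weight does not decrease
  more <- c(base_marks, list(H3K9ac = make_track(8990, 9020)))
  w1 <- run(more)$grn$edges$weight
  expect_gte(w1, w0)
  # adding a methylation peak over the TFBS never increases a weight
  r_meth <- run(base_marks, meth = make_track(9001, 9009, kind = "methylation"))
  expect_equal(nrow(r_meth$grn$edges), 0)
  r_far <- run(base_marks, meth = make_track(100, 200, kind = "methylation"))
  expect_true(all(r_far$grn$edges$weight >= w0))
})

test_that("weight thresholding selects the expected subnetworks", {
  fx <- generate_fixture("mixed", seed = 4)
  pp <- fixture_pipeline(fx)
  net <- pp$filtered
  expect_identical(threshold_by_weight(net, 0)$edges, net$edges)
  w <- sort(unique(net$edges$weight))
  for (k in w) {
    sub <- threshold_by_weight(net, k)
    expect_true(all(sub$edges$weight >= k))
  }
  sizes <- vapply(0:6, function(k) nrow(threshold_by_weight(net, k)$edges), 0L)
  expect_true(all(diff(sizes) <= 0))
})
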