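genes_one <- data.frame(gene_id = c("tfA", "g"), chrom = "chr1",
                        strand = "+", tss = c(500, 10000),
                        gene_type = c("TF", "coding"),
                        stringsAsFactors = FALSE)

test_that("TFBS-to-gene assignment follows the strand-aware upstream window", {
  asg <- function(s, e, d, strand = "+", tss = 10000) {
    g <- genes_one
    g$strand[2] <- strand
    g$tss[2] <- tss
    assign_tfbs_to_genes(list(tfA = make_track(s, e)), g, d)
  }
  # TFBS 990 nt upstream of a + TSS, inside the 1.5 kb window
  a <- asg(9000, 9010, 1500)
  expect_equal(nrow(a), 1)
  expect_equal(a$target_id, "g")
  expect_equal(a$distance, 990)
  # downstream of the TSS: never assigned
  expect_equal(nrow(asg(10200, 10210, 1500)), 0)
  # beyond the threshold at 1.5 kb, captured at 5 kb (monotone in d)
  expect_equal(nrow(asg(7000, 7010, 1500)), 0)
  a5 <- asg(7000, 7010, 5000)
  expect_equal(nrow(a5), 1)
  expect_equal(a5$distance, 2990)
  # TFBS crossing the TSS boundary records distance 0
  expect_equal(asg(9995, 10005, 1500)$distance, 0)
  # minus strand mirrors: upstream means greater coordinates
  m <- asg(10991, 11011, 1500, strand = "-")
  expect_equal(nrow(m), 1)
  expect_equal(m$distance, 990)
  expect_equal(nrow(asg(9000, 9010, 1500, strand = "-")), 0)
  # errors
  expect_error(asg(9000, 9010, 0), "positive")
  expect_error(
    assign_tfbs_to_genes(list(ghost = make_track(1, 2)), genes_one, 1500),
    "ghost")
})

test_that("reference construction aggregates assignments per (TF, target) pair", {
  genes <- make_genes(6)
  asg <- data.frame(
    regulator_id = c("g01", "g01", "g01", "g01"),
    target_id = c("g02", "g02", "g02", "g03"),
    chrom = "chr1", start = c(100, 200, 300, 400),
    end = c(150, 250, 350, 450), name = NA_character_,
    distance = 0, stringsAsFactors = FALSE)
  ref <- build_reference_network(asg, genes, d = 1500)
  expect_equal(nrow(ref$edges), 2)
  expect_true(all(ref$edges$weight == 0))
  ev1 <- ref$evidence[ref$evidence$target_id == "g02", ]
  expect_equal(nrow(ev1), 3)
  # evidence conservation: nothing lost or invented
  expect_equal(nrow(ref$evidence), nrow(asg))
  # empty assignment set keeps all nodes, no edges
  ref0 <- build_reference_network(asg[0, ], genes, d = 1500)
  expect_equal(nrow(ref0$edges), 0)
  expect_equal(nrow(ref0$nodes), 6)
  expect_equal(network_summary(ref0)$n_connected_nodes, 0)
})

test_that("miRNA edges merge with dedup and unknown-target warnings", {
  genes <- make_genes(6)
  genes$gene_type[5] <- "miRNA"
  genes$gene_id[5] <- "mir1"
  ref <- build_reference_network(empty_ev <- data.frame(
    regulator_id = character(), target_id = character(), chrom = character(),
    start = numeric(), end = numeric(), name = character(),
    distance = numeric(), stringsAsFactors = FALSE), genes, d = 1500)
  out <- add_mirna_edges(ref, data.frame(mirna_id = c("mir1", "mir1"),
                                         target_id = c("g01", "g01")))
  expect_equal(nrow(out$edges), 1)
  expect_equal(out$edges$edge_kind, "mirna_gene")
  expect_warning(
    out2 <- add_mirna_edges(ref, data.frame(mirna_id = "mir1",
                                            target_id = "nope")),
    "unknown target")
  expect_equal(nrow(out2$edges), 0)
})

test_that("edge counts are additive over TF and miRNA contributions", {
  fx <- generate_fixture("all_pass", seed = 5)
  asg <- assign_tfbs_to_genes(fx$tfbs_by_tf, fx$genes, fx$d)
  ref <- build_reference_network(asg, fx$genes, d = fx$d)
  n_tf <- nrow(ref$edges)
  full <- add_mirna_edges(ref, fx$mirna_targets)
  m <- nrow(unique(fx$mirna_targets))
  expect_equal(nrow(full$edges), n_tf + m)
  s <- network_summary(full)
  expect_equal(s$n_tf_edges, n_tf)
  expect_equal(s$n_mirna_edges, m)
})

test_that("larger thresholds give nested edge sets and non-decreasing summaries", {
  set.seed(99)
  genes <- make_genes(12, d = 5000)
  n_sites <- 120
  span <- max(genes$tss) + 10000
  tracks <- list(
    g01 = make_track(starts <- sample(0:span, n_sites), starts + 15),
    g05 = make_track(starts2 <- sample(0:span, n_sites), starts2 + 15))
  genes$gene_type[c(1, 5)] <- "TF"
  nets <- lapply(c(1500, 2000, 5000), function(d) {
    build_reference_network(assign_tfbs_to_genes(tracks, genes, d), genes, d = d)
  })
  keys <- lapply(nets, function(n) epigrn:::edge_key(n$edges))
  expect_true(all(keys[[1]] %in% keys[[2]]))
  expect_true(all(keys[[2]] %in% keys[[3]]))
  sums <- do.call(rbind, lapply(nets, network_summary))
  for (col in names(sums)) {
    expect_true(all(diff(sums[[col]]) >= 0), label = sprintf("summary column %s", col))
  }
})

test_that("assignment results do not depend on input ordering", {
  set.seed(3)
  genes <- make_genes(8)
  genes$gene_type[1] <- "TF"
  starts <- sample(0:(max(genes$tss)), 60)
  tr1 <- make_track(starts, starts + 12)
  perm <- sample(60)
  tr2 <- evidence_track(tr1$intervals[perm, ], "perm")
  a1 <- assign_tfbs_to_genes(list(g01 = tr1), genes, 1500)
  a2 <- assign_tfbs_to_genes(list(g01 = tr2), genes, 1500)
  key <- function(a) sort(paste(a$target_id, a$start, a$end))
  expect_identical(key(a1), key(a2))
  r1 <- build_reference_network(a1, genes, 1500)
  r2 <- build_reference_network(a2, genes, 1500)
  expect_identical(sort(epigrn:::edge_key(r1$edges)),
                   sort(epigrn:::edge_key(r2$edges)))
})
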