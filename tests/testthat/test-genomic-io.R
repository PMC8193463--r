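test_that("BED lines map to intervals verbatim and bad lines are rejected", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2L\t100\t200\tpeak1",
               "chr2L\t300\t450\tpeak2\t7.5\t-",
               "chr3R\t0\t10"), path)
  tr <- read_bed(path)
  expect_equal(tr$intervals$chrom, c("chr2L", "chr2L", "chr3R"))
  expect_equal(tr$intervals$start, c(100, 300, 0))
  expect_equal(tr$intervals$end, c(200, 450, 10))
  expect_equal(tr$intervals$name, c("peak1", "peak2", NA))
  expect_equal(tr$intervals$score, c(NA, 7.5, NA))
  expect_equal(tr$intervals$strand, c("*", "-", "*"))

  writeLines(c("chr2L\t100\t200", "chr2L\t200\t100"), path)
  expect_error(read_bed(path), "line 2")
  writeLines("chr2L\tabc\t200", path)
  expect_error(read_bed(path), "non-integer")
  writeLines(character(0), path)
  expect_warning(tr <- read_bed(path), "no intervals")
  expect_equal(nrow(tr$intervals), 0)
})

test_that("indexed overlap queries agree with a linear scan", {
  set.seed(42)
  n <- 1000
  starts <- sample(0:99000, n, replace = TRUE)
  widths <- sample(1:500, n, replace = TRUE)
  chroms <- sample(c("chr1", "chr2"), n, replace = TRUE)
  iv <- genomic_intervals(chroms, starts, starts + widths)
  iv <- iv[sample(n), ]  # shuffled input order
  tr <- evidence_track(iv, "rand")
  for (q in seq_len(50)) {
    qs <- sample(0:99500, 1)
    qe <- qs + sample(1:800, 1)
    qc <- sample(c("chr1", "chr2"), 1)
    got <- track_query(tr, qc, qs, qe)
    want <- overlap_scan(tr$intervals, qc, qs, qe)
    expect_setequal(paste(got$chrom, got$start, got$end),
                    paste(want$chrom, want$start, want$end))
  }
})

test_that("BED coordinates round-trip byte-identically", {
  path <- withr::local_tempfile(fileext = ".bed")
  orig <- c("chr2L\t100\t200\tpeak1\t3.5\t+",
            "chr2L\t0\t987654321\t.\t.\t.",
            "chrX\t5\t6\tp\t0\t-")
  writeLines(orig, path)
  tr <- read_bed(path)
  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(tr, out)
  reread <- readLines(out)
  coord <- function(x) vapply(strsplit(x, "\t"), function(f)
    paste(f[1:3], collapse = "\t"), "")
  expect_identical(coord(reread), coord(orig))
  expect_identical(read_bed(out)$intervals, tr$intervals)
})

test_that("gene annotation dialects resolve TSS, strand and gene types", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstrand\ttss\tgene_type",
               "g1\tchr2L\t+\t10000\tTF",
               "g2\tchr2L\t-\t5000\tcoding"), tsv)
  genes <- read_gene_annotation(tsv)
  expect_equal(genes$gene_id, c("g1", "g2"))
  expect_equal(genes$tss, c(10000, 5000))
  expect_equal(genes$gene_type, c("TF", "coding"))

  # GTF: 1-based inclusive [5001, 6000] = 0-based [5000, 6000); minus-strand
  # TSS is the feature end, 0-based 5999
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr2L\tsrc\tgene\t5001\t6000\t.\t-\t.\t",
           'gene_id "gm"; gene_biotype "protein_coding";'),
    paste0("chr2L\tsrc\tgene\t9001\t9500\t.\t+\t.\t",
           'gene_id "gp"; gene_biotype "miRNA";')), gtf)
  ga <- read_gene_annotation(gtf)
  expect_equal(ga$tss[ga$gene_id == "gm"], 5999)
  expect_equal(ga$tss[ga$gene_id == "gp"], 9000)
  expect_equal(ga$gene_type[ga$gene_id == "gp"], "miRNA")
  ga2 <- read_gene_annotation(gtf, tf_ids = "gm")
  expect_equal(ga2$gene_type[ga2$gene_id == "gm"], "TF")

  writeLines(c("g1\tchr2L\t+\t100\tTF", "g1\tchr2L\t+\t200\tTF"), tsv)
  expect_error(read_gene_annotation(tsv), "duplicate")
  writeLines("g1\tchr2L\t?\t100\tTF", tsv)
  expect_error(read_gene_annotation(tsv), "strand")
})

test_that("annotations round-trip through write/read unchanged", {
  genes <- make_genes(20)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_annotation(genes, path)
  expect_identical(read_gene_annotation(path), genes)
})

test_that("abundance tables validate values and sum to the generated total", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tabundance", "g1\t5.0", "g2\t0.0"), path)
  ab <- read_abundance_table(path)
  expect_equal(ab[["g1"]], 5)
  expect_equal(ab[["g2"]], 0)

  writeLines("g1\t-3", path)
  expect_error(read_abundance_table(path), "negative")
  writeLines(c("g1\t3", "g1\t4"), path)
  expect_error(read_abundance_table(path), "g1")

  set.seed(11)
  vals <- round(runif(100, 0, 50), 3)
  df <- data.frame(id = sprintf("g%03d", 1:100), x = vals)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_equal(sum(read_abundance_table(path)), sum(vals))
})

test_that("networks round-trip through the edge-list TSV with evidence", {
  fx <- generate_fixture("mixed", seed = 3)
  pp <- fixture_pipeline(fx)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_grn(pp$filtered, path)
  back <- read_grn(path, fx$genes)
  expect_equal(back$d, pp$filtered$d)
  ord <- function(e) e[order(e$regulator_id, e$target_id, e$edge_kind), ]
  expect_equal(ord(back$edges)[, c("regulator_id", "target_id", "edge_kind", "weight")],
               ord(pp$filtered$edges)[, c("regulator_id", "target_id", "edge_kind", "weight")],
               ignore_attr = TRUE)
  expect_equal(nrow(back$evidence), nrow(pp$filtered$evidence))
  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(pp$filtered, sif)
  expect_equal(length(readLines(sif)), nrow(pp$filtered$edges))
})
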