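# Gene models: gene_id, chrom, strand (+/-), tss (0-based), gene_type in
# {TF, miRNA, coding, noncoding}. The TSS is the 5'-most transcribed
# position: feature start for + strand genes, feature end - 1 for - strand
# (internal 0-based coordinates).

GENE_TYPES <- c("TF", "miRNA", "coding", "noncoding")

validate_annotation <- function(genes) {
  required <- c("gene_id", "chrom", "strand", "tss", "gene_type")
  missing <- setdiff(required, names(genes))
  if (length(missing)) {
    stop(sprintf("gene annotation lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup)) {
    stop(sprintf("duplicate gene_id in annotation: %s",
                 paste(unique(dup), collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene annotation has strand values outside {+, -}")
  }
  if (any(genes$tss < 0)) stop("gene annotation has negative TSS positions")
  if (!all(genes$gene_type %in% GENE_TYPES)) {
    stop(sprintf("gene_type values must be one of: %s", paste(GENE_TYPES, collapse = ", ")))
  }
  invisible(genes)
}

#' Read a gene annotation
#'
#' Supports GTF, GFF3 and a simple tab-separated dialect with columns
#' `gene_id`, `chrom`, `strand`, `tss`, `gene_type`. For GTF/GFF3, `gene`
#' features are used and the TSS is the 5'-most transcribed position
#' (feature start for `+` strand, feature end for `-` strand, converted to
#' internal 0-based coordinates). Regulator types may be overlaid on
#' GTF/GFF3 biotypes with `tf_ids` / `mirna_ids`; genes whose type cannot be
#' resolved default to `"coding"` with a warning.
#'
#' @param path file path.
#' @param dialect one of `"tsv"`, `"gtf"`, `"gff3"` (default guessed from
#'   the file extension, falling back to `"tsv"`).
#' @param tf_ids,mirna_ids optional character vectors of gene ids to type as
#'   TF / miRNA regardless of annotated biotype.
#' @return A `data.frame` of gene models.
#' @export
read_gene_annotation <- function(path, dialect = NULL, tf_ids = NULL,
                                 mirna_ids = NULL) {
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  if (is.null(dialect)) {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, gtf = "gtf", gff = "gff3", gff3 = "gff3", "tsv")
  }
  dialect <- match.arg(dialect, c("tsv", "gtf", "gff3"))
  genes <- if (dialect == "tsv") {
    read_annotation_tsv(path)
  } else {
    read_annotation_gff(path, dialect)
  }
  if (!is.null(tf_ids)) genes$gene_type[genes$gene_id %in% tf_ids] <- "TF"
  if (!is.null(mirna_ids)) genes$gene_type[genes$gene_id %in% mirna_ids] <- "miRNA"
  unresolved <- is.na(genes$gene_type)
  if (any(unresolved)) {
    warning(sprintf("%d gene(s) with unresolved gene_type defaulted to 'coding'",
                    sum(unresolved)))
    genes$gene_type[unresolved] <- "coding"
  }
  rownames(genes) <- NULL
  validate_annotation(genes)
}

read_annotation_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- length(first) && is.na(suppressWarnings(
    as.numeric(strsplit(first, "\t", fixed = TRUE)[[1]][4])))
  df <- read.delim(path, header = has_header, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!has_header) names(df)[1:5] <- c("gene_id", "chrom", "strand", "tss", "gene_type")
  df$tss <- as.numeric(df$tss)
  df[, c("gene_id", "chrom", "strand", "tss", "gene_type")]
}

read_annotation_gff <- function(path, dialect) {
  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  md <- S4Vectors::mcols(gr)
  type_col <- if ("type" %in% names(md)) as.character(md$type) else rep("gene", length(gr))
  keep <- type_col == "gene"
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  ids <- if ("gene_id" %in% names(md)) as.character(md$gene_id) else
    if ("ID" %in% names(md)) as.character(md$ID) else
      stop("GTF/GFF3 gene features carry no gene_id/ID attribute")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("GTF/GFF3 gene features with unknown strand")
  # 1-based inclusive -> 0-based: TSS = start-1 on +, end-1 on -
  tss <- ifelse(strand == "+", GenomicRanges::start(gr) - 1L,
                GenomicRanges::end(gr) - 1L)
  biotype <- rep(NA_character_, length(gr))
  for (col in c("gene_biotype", "gene_type", "biotype")) {
    if (col %in% names(md)) {
      biotype <- as.character(md[[col]])
      break
    }
  }
  gene_type <- rep(NA_character_, length(gr))
  gene_type[!is.na(biotype) & biotype == "protein_coding"] <- "coding"
  gene_type[!is.na(biotype) & biotype == "miRNA"] <- "miRNA"
  gene_type[!is.na(biotype) &
              !biotype %in% c("protein_coding", "miRNA")] <- "noncoding"
  data.frame(gene_id = ids, chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = strand, tss = as.numeric(tss), gene_type = gene_type,
             stringsAsFactors = FALSE)
}

#' Write a gene annotation in the tab-separated dialect
#'
#' @param genes a gene-model data frame.
#' @param path output path.
#' @export
write_gene_annotation <- function(genes, path) {
  validate_annotation(genes)
  out <- genes[, c("gene_id", "chrom", "strand", "tss", "gene_type")]
  out$tss <- format(out$tss, trim = TRUE, scientific = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an abundance table
#'
#' Two or more tab-separated columns: gene id, then a non-negative numeric
#' abundance (counts, RPKM or FPKM, taken as provided). A header line is
#' auto-detected (non-numeric second field on line 1).
#'
#' @param path file path.
#' @return A named numeric vector, id -> abundance.
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("abundance table not found: %s", path))
  first <- readLines(path, n = 1L)
  has_header <- length(first) && is.na(suppressWarnings(
    as.numeric(strsplit(first, "\t", fixed = TRUE)[[1]][2])))
  df <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop(sprintf("abundance table '%s' needs >= 2 columns", path))
  ids <- as.character(df[[1]])
  vals <- suppressWarnings(as.numeric(df[[2]]))
  if (any(is.na(vals))) {
    stop(sprintf("abundance table '%s' has non-numeric abundances", path))
  }
  if (any(vals < 0)) {
    stop(sprintf("abundance table '%s' has negative abundance for: %s", path,
                 paste(ids[vals < 0], collapse = ", ")))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate gene_id in abundance table '%s': %s", path,
                 paste(unique(dup), collapse = ", ")))
  }
  setNames(vals, ids)
}

#' Read miRNA-target pairs
#'
#' Two-column tab-separated edge list: miRNA id, target gene id. A header
#' line is tolerated when its first field is `mirna_id` or `regulator`.
#'
#' @param path file path.
#' @return A `data.frame` with columns `mirna_id`, `target_id`.
#' @export
read_mirna_targets <- function(path) {
  if (!file.exists(path)) stop(sprintf("miRNA target file not found: %s", path))
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop(sprintf("miRNA target file '%s' needs 2 columns", path))
  if (nrow(df) && df[1, 1] %in% c("mirna_id", "regulator", "regulator_id")) {
    df <- df[-1, , drop = FALSE]
  }
  data.frame(mirna_id = df[[1]], target_id = df[[2]], stringsAsFactors = FALSE)
}
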