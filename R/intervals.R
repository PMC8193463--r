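#' @importFrom methods is
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table
NULL

# All coordinates inside the package are 0-based half-open (BED convention).
# GTF/GFF3 1-based inclusive inputs are converted on read and never stored.

#' Construct a table of genomic intervals
#'
#' Validates and normalizes a data frame of genomic spans. Coordinates are
#' 0-based half-open; empty intervals (`start >= end`) and negative starts are
#' rejected.
#'
#' @param chrom character vector of chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions.
#' @param name optional interval labels (default `NA`).
#' @param score optional numeric signal values (default `NA`).
#' @param strand optional strand, one of `"+"`, `"-"`, `"*"` (unstranded).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              score = NA_real_, strand = "*") {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

validate_intervals <- function(df, where = "interval set") {
  stopifnot(is.data.frame(df))
  required <- c("chrom", "start", "end")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s lacks column(s): %s", where, paste(missing, collapse = ", ")))
  }
  if (nrow(df)) {
    if (any(is.na(df$start)) || any(is.na(df$end))) {
      stop(sprintf("%s has missing coordinates", where))
    }
    if (any(df$start < 0)) {
      stop(sprintf("%s has negative start positions", where))
    }
    bad <- which(df$start >= df$end)
    if (length(bad)) {
      stop(sprintf("%s has empty or inverted intervals (start >= end) at row(s) %s",
                   where, paste(utils::head(bad, 5), collapse = ", ")))
    }
    if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", "*"))) {
      stop(sprintf("%s has strand values outside {+, -, *}", where))
    }
  }
  invisible(df)
}

# GRanges view of an interval table (1-based closed for IRanges machinery).
intervals_to_gr <- function(df) {
  if (!nrow(df)) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Create an evidence track
#'
#' An evidence track bundles a labelled, indexed collection of genomic
#' intervals of one assay type (methylation peaks, accessibility peaks, a
#' histone mark, or ChIP-seq peaks) and supports fast overlap queries.
#'
#' @param intervals a data frame as returned by [genomic_intervals()].
#' @param label track name.
#' @param kind one of `"methylation"`, `"accessibility"`, `"histone_mark"`,
#'   `"chip_peak"`, `"tfbs"`, `"generic"`.
#' @return An object of class `evidence_track`.
#' @export
evidence_track <- function(intervals, label = "track",
                           kind = c("generic", "methylation", "accessibility",
                                    "histone_mark", "chip_peak", "tfbs")) {
  kind <- match.arg(kind)
  if (!"name" %in% names(intervals)) intervals$name <- NA_character_
  if (!"score" %in% names(intervals)) intervals$score <- NA_real_
  if (!"strand" %in% names(intervals)) intervals$strand <- "*"
  intervals <- intervals[, c("chrom", "start", "end", "name", "score", "strand")]
  rownames(intervals) <- NULL
  validate_intervals(intervals, where = sprintf("track '%s'", label))
  structure(
    list(label = label, kind = kind, intervals = intervals,
         index = intervals_to_gr(intervals)),
    class = "evidence_track"
  )
}

#' @export
print.evidence_track <- function(x, ...) {
  cat(sprintf("<evidence_track '%s'> kind=%s, %d interval(s) on %d chromosome(s)\n",
              x$label, x$kind, nrow(x$intervals),
              length(unique(x$intervals$chrom))))
  invisible(x)
}

#' Query a track for overlapping intervals
#'
#' Returns the track intervals intersecting (by at least 1 bp) the half-open
#' query span.
#'
#' @param track an [evidence_track()].
#' @param chrom,start,end the query span (0-based half-open).
#' @return The subset of `track$intervals` overlapping the query.
#' @export
track_query <- function(track, chrom, start, end) {
  stopifnot(is(track, "evidence_track"), start < end)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  hits <- GenomicRanges::findOverlaps(q, track$index)
  track$intervals[S4Vectors::subjectHits(hits), , drop = FALSE]
}

# Vectorized any-overlap between a query interval table and a track.
# `type = "within"` requires the query to be fully contained in a track
# interval.
track_overlaps_any <- function(track, query_df, type = "any") {
  if (!nrow(query_df)) return(logical(0))
  if (!nrow(track$intervals)) return(rep(FALSE, nrow(query_df)))
  q <- intervals_to_gr(query_df)
  IRanges::overlapsAny(q, track$index, type = type)
}

#' Read a BED file as an evidence track
#'
#' Accepts BED3 to BED6. Coordinates are taken verbatim (BED is already
#' 0-based half-open); columns 4-6 populate name, score and strand when
#' present. `track` / `browser` / `#` lines are skipped. A well-formed empty
#' file yields an empty track with a warning; malformed coordinates raise an
#' error naming the offending line.
#'
#' @param path file path.
#' @param label track label (defaults to the file name).
#' @param kind passed to [evidence_track()].
#' @return An `evidence_track`.
#' @export
read_bed <- function(path, label = NULL, kind = "generic") {
  if (!file.exists(path)) stop(sprintf("BED file not found: %s", path))
  if (is.null(label)) label <- sub("\\.bed$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    warning(sprintf("BED file '%s' contains no intervals; empty track", path))
    return(evidence_track(genomic_intervals(character(), numeric(), numeric()),
                          label = label, kind = kind))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("BED parse error in '%s' at line %d: fewer than 3 fields",
                 path, lineno[which(nf < 3)[1]]))
  }
  getcol <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  chrom <- getcol(1)
  start <- suppressWarnings(as.numeric(getcol(2)))
  end <- suppressWarnings(as.numeric(getcol(3)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad)) {
    stop(sprintf("BED parse error in '%s' at line %d: non-integer coordinates",
                 path, lineno[bad[1]]))
  }
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    stop(sprintf("BED parse error in '%s' at line %d: invalid interval [%s, %s)",
                 path, lineno[bad[1]], getcol(2)[bad[1]], getcol(3)[bad[1]]))
  }
  name <- getcol(4)
  name[name %in% "."] <- NA_character_
  score <- suppressWarnings(as.numeric(getcol(5)))
  strand <- getcol(6)
  strand[is.na(strand) | strand == "."] <- "*"
  if (!all(strand %in% c("+", "-", "*"))) {
    stop(sprintf("BED parse error in '%s': strand column outside {+, -, .}", path))
  }
  evidence_track(
    data.frame(chrom = chrom, start = start, end = end, name = name,
               score = score, strand = strand, stringsAsFactors = FALSE),
    label = label, kind = kind
  )
}

#' Write intervals as BED6
#'
#' Coordinate columns round-trip byte-identically through [read_bed()].
#'
#' @param x an `evidence_track` or interval data frame.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  df <- if (is(x, "evidence_track")) x$intervals else x
  validate_intervals(df, where = "BED output")
  name <- if ("name" %in% names(df)) ifelse(is.na(df$name), ".", df$name) else rep(".", nrow(df))
  score <- if ("score" %in% names(df)) ifelse(is.na(df$score), ".", format(df$score, trim = TRUE, scientific = FALSE)) else rep(".", nrow(df))
  strand <- if ("strand" %in% names(df)) ifelse(df$strand == "*", ".", df$strand) else rep(".", nrow(df))
  out <- data.frame(
    chrom = df$chrom,
    start = format(df$start, trim = TRUE, scientific = FALSE),
    end = format(df$end, trim = TRUE, scientific = FALSE),
    name = name, score = score, strand = strand,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
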