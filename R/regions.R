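#' Construct a region set from BED-style coordinates
#'
#' Builds a [GenomicRanges::GRanges] from 0-based half-open coordinates, the
#' convention used by BED files and by all user-facing coordinates in this
#' package. Internally intervals are stored 1-based closed (the `GRanges`
#' convention); conversion happens only at this boundary and in
#' [read_bed()]/[write_bed()].
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based half-open, so a base-pair
#'   interval covering the first 100 bases of a chromosome is `start = 0`,
#'   `end = 100`. Requires `0 <= start < end`.
#' @param name,score optional per-interval label and numeric score.
#' @param strand optional strand (`"+"`, `"-"` or `"."`); defaults to `"*"`.
#' @param label optional free-text label for the whole set (condition,
#'   antibody, enhancer class); stored in `metadata()`.
#' @param seqlengths optional named vector of chromosome lengths.
#' @return A `GRanges` object.
#' @examples
#' region_set("chr1", c(0, 500), c(100, 900), label = "peaks")
#' @export
region_set <- function(chrom, start, end, name = NULL, score = NULL,
                       strand = NULL, label = NULL, seqlengths = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) == 1L && length(start) > 1L)
    chrom <- rep(chrom, length(start))
  if (any(is.na(start)) || any(is.na(end)))
    stop("start/end must be non-missing integers", call. = FALSE)
  if (any(start < 0)) stop("negative start coordinate", call. = FALSE)
  if (any(start >= end))
    stop("empty or inverted interval: start must be < end", call. = FALSE)
  if (is.null(strand)) strand <- "*"
  strand <- ifelse(strand == ".", "*", strand)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end),
    strand = strand,
    seqlengths = seqlengths
  )
  if (!is.null(name)) gr$name <- as.character(name)
  if (!is.null(score)) gr$score <- as.numeric(score)
  if (!is.null(label)) S4Vectors::metadata(gr)$label <- label
  gr
}

#' Region set label
#' @param x a `GRanges`.
#' @return The free-text label stored at construction, or `NA`.
#' @export
region_label <- function(x) {
  lbl <- S4Vectors::metadata(x)$label
  if (is.null(lbl)) NA_character_ else lbl
}

#' Convert a region set to a BED-style data frame
#'
#' @param x a `GRanges`.
#' @return data.frame with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), plus `name`, `score`, `strand` when present.
#' @export
as_bed_df <- function(x) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(x)),
    start = GenomicRanges::start(x) - 1,
    end = GenomicRanges::end(x),
    stringsAsFactors = FALSE
  )
  if (!is.null(x$name)) df$name <- x$name
  if (!is.null(x$score)) df$score <- x$score
  st <- as.character(GenomicRanges::strand(x))
  if (any(st != "*")) df$strand <- ifelse(st == "*", ".", st)
  df
}

#' Read a BED file into a region set
#'
#' Accepts BED3/BED6 (tab-separated, 0-based half-open). Malformed lines --
#' fewer than three columns, non-integer or negative coordinates, or
#' `start >= end` -- raise an error naming the offending line number.
#' `track`/`browser`/`#` header lines are skipped.
#'
#' @param path file path.
#' @param label optional set label (defaults to the file base name).
#' @return A `GRanges`; a write/read round trip preserves coordinates
#'   exactly.
#' @export
read_bed <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such BED file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ncols <- lengths(fields)
    if (any(ncols < 3L))
      stop("BED line ", lineno[which(ncols < 3L)[1L]],
           ": fewer than 3 tab-separated columns", call. = FALSE)
    chrom <- vapply(fields, `[[`, "", 1L)
    s_chr <- vapply(fields, `[[`, "", 2L)
    e_chr <- vapply(fields, `[[`, "", 3L)
    start <- suppressWarnings(as.numeric(s_chr))
    end <- suppressWarnings(as.numeric(e_chr))
    bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
    if (any(bad))
      stop("BED line ", lineno[which(bad)[1L]],
           ": non-integer coordinate", call. = FALSE)
    if (any(start < 0))
      stop("BED line ", lineno[which(start < 0)[1L]],
           ": negative coordinate", call. = FALSE)
    if (any(start >= end))
      stop("BED line ", lineno[which(start >= end)[1L]],
           ": start >= end (intervals are half-open and non-empty)",
           call. = FALSE)
    name <- ifelse(ncols >= 4L, vapply(fields, function(f)
      if (length(f) >= 4L) f[[4L]] else ".", ""), ".")
    score <- ifelse(ncols >= 5L, suppressWarnings(as.numeric(
      vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else "0", ""))), 0)
    strand <- ifelse(ncols >= 6L, vapply(fields, function(f)
      if (length(f) >= 6L) f[[6L]] else ".", ""), ".")
    gr <- region_set(chrom, start, end,
                     name = if (any(ncols >= 4L)) name else NULL,
                     score = if (any(ncols >= 5L)) score else NULL,
                     strand = strand)
  }
  S4Vectors::metadata(gr)$label <-
    if (is.null(label)) sub("\\.bed$", "", basename(path)) else label
  gr
}

#' Write a region set to a BED file
#'
#' Writes BED6 when name/score/strand metadata are present, BED3 otherwise;
#' coordinates are emitted 0-based half-open so that `read_bed(write_bed(x))`
#' is the identity on coordinates.
#'
#' @param x a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- as_bed_df(x)
  if (is.null(df$name) && (!is.null(df$score) || !is.null(df$strand)))
    df$name <- "."
  if (!is.null(df$name) && is.null(df$score)) df$score <- 0
  if (!is.null(df$score) && is.null(df$strand)) df$strand <- "."
  df <- df[, intersect(c("chrom", "start", "end", "name", "score", "strand"),
                       names(df)), drop = FALSE]
  old <- options(scipen = 100)
  on.exit(options(old))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chrom-sizes table
#'
#' Two-column TSV (`chrom`, `length`), the UCSC chrom.sizes convention.
#'
#' @param path file path.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          stringsAsFactors = FALSE)
  if (any(df$length <= 0)) stop("non-positive chromosome length", call. = FALSE)
  stats::setNames(as.integer(df$length), df$chrom)
}

#' Drop peaks on unplaced contigs
#'
#' Removes intervals whose chromosome name starts with the given prefix
#' (default `"chrUn"`), mirroring the routine removal of peaks on
#' unidentified assembly regions.
#'
#' @param x a `GRanges`.
#' @param prefix chromosome-name prefix to drop.
#' @return filtered `GRanges`.
#' @export
drop_unplaced <- function(x, prefix = "chrUn") {
  keep <- !startsWith(as.character(GenomicRanges::seqnames(x)), prefix)
  x[keep]
}
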