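#' Normalise a region set
#'
#' Sorts by (chrom, start, end) and collapses strictly overlapping intervals
#' so that no two intervals in the result share a base. Book-ended intervals
#' (touching but not overlapping, e.g. `[0,100)` and `[100,200)`) are kept
#' separate; use [merge_regions()] to join them.
#'
#' @param x a `GRanges`.
#' @return normalised `GRanges` (label preserved).
#' @export
normalise_regions <- function(x) {
  out <- GenomicRanges::reduce(GenomicRanges::sort(x, ignore.strand = TRUE),
                               min.gapwidth = 0L, ignore.strand = TRUE)
  S4Vectors::metadata(out)$label <- S4Vectors::metadata(x)$label
  out
}

#' Merge intervals within a gap tolerance
#'
#' Collapses intervals whose gap is at most `max_gap` base pairs. At the
#' default `max_gap = 0` book-ended intervals merge (`[0,100)` + `[100,200)`
#' becomes `[0,200)`), the common dialect of interval merging; the union of
#' covered bases is unchanged. Idempotent and insensitive to input order.
#'
#' @param x a `GRanges`.
#' @param max_gap non-negative gap (bp) across which intervals still merge.
#' @return merged, sorted `GRanges`.
#' @export
merge_regions <- function(x, max_gap = 0) {
  if (max_gap < 0) stop("max_gap must be >= 0", call. = FALSE)
  out <- GenomicRanges::reduce(GenomicRanges::sort(x, ignore.strand = TRUE),
                               min.gapwidth = max_gap + 1L,
                               ignore.strand = TRUE)
  S4Vectors::metadata(out)$label <- S4Vectors::metadata(x)$label
  out
}

#' Enumerate overlapping interval pairs between two sets
#'
#' Reports every pair `(i, j)` with `a[i]` overlapping `b[j]` by at least
#' `min_bp` bases and by at least `min_frac` of the reference-side interval
#' length. With `min_frac = 0` the relation is symmetric.
#'
#' @param a,b `GRanges` region sets.
#' @param min_bp minimum overlap in bases (default 1).
#' @param min_frac minimum overlap as a fraction of the reference interval's
#'   length, in `[0, 1]`.
#' @param frac_side which side the fraction is measured on: `"a"` (default),
#'   `"b"`, or `"both"` (reciprocal).
#' @return data.frame with columns `query` (index into `a`), `subject`
#'   (index into `b`), `chrom`, `overlap_bp`, `frac_a`, `frac_b`.
#' @export
overlap_pairs <- function(a, b, min_bp = 1, min_frac = 0,
                          frac_side = c("a", "b", "both")) {
  frac_side <- match.arg(frac_side)
  if (min_frac < 0 || min_frac > 1)
    stop("min_frac must be in [0, 1]", call. = FALSE)
  if (min_bp < 1) stop("min_bp must be >= 1", call. = FALSE)
  hits <- GenomicRanges::findOverlaps(a, b, minoverlap = min_bp,
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(a)[q], GenomicRanges::ranges(b)[s]))
  frac_a <- ov / GenomicRanges::width(a)[q]
  frac_b <- ov / GenomicRanges::width(b)[s]
  keep <- switch(frac_side,
                 a = frac_a >= min_frac,
                 b = frac_b >= min_frac,
                 both = frac_a >= min_frac & frac_b >= min_frac)
  data.frame(query = q[keep], subject = s[keep],
             chrom = as.character(GenomicRanges::seqnames(a))[q[keep]],
             overlap_bp = ov[keep],
             frac_a = frac_a[keep], frac_b = frac_b[keep],
             stringsAsFactors = FALSE)
}

#' Remove peaks overlapping a blacklist
#'
#' Drops any peak overlapping an artefact-prone (blacklisted) region by at
#' least one base; input order is preserved.
#'
#' @param peaks,blacklist `GRanges` sets.
#' @return filtered `GRanges`.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  if (length(blacklist) == 0L) return(peaks)
  hit <- IRanges::overlapsAny(peaks, blacklist, minoverlap = 1L,
                                    ignore.strand = TRUE)
  peaks[!hit]
}

#' Consensus peaks across two replicates
#'
#' A replicate-1 peak is retained iff some replicate-2 peak overlaps it by
#' at least `min_overlap_frac` of the replicate-1 peak's length (threshold
#' inclusive). This reference-side reading of "at least 50% overlap between
#' replicates" is the default; `reciprocal = TRUE` additionally requires the
#' fraction on the replicate-2 side.
#'
#' @param rep1,rep2 replicate peak sets (`GRanges`); `rep1` is the reference.
#' @param min_overlap_frac required overlap fraction in `(0, 1]`.
#' @param reciprocal require the fraction on both sides.
#' @return the retained `rep1` intervals.
#' @export
consensus_peaks <- function(rep1, rep2, min_overlap_frac = 0.5,
                            reciprocal = FALSE) {
  if (min_overlap_frac <= 0 || min_overlap_frac > 1)
    stop("min_overlap_frac must be in (0, 1]", call. = FALSE)
  prs <- overlap_pairs(rep1, rep2, min_bp = 1, min_frac = min_overlap_frac,
                       frac_side = if (reciprocal) "both" else "a")
  rep1[sort(unique(prs$query))]
}

#' Categorise two conditions' peaks into specific and shared groups
#'
#' A condition-1 peak overlapping (by at least one base) any condition-2 peak
#' is "shared", and vice versa; each shared region reported is the merged
#' union of a connected component of mutually overlapping peaks from both
#' conditions. Remaining peaks are condition-specific. Count conservation
#' holds per side: `n(cond1_only) + n(shared, cond1 side) = n(cond1)`.
#'
#' @param peaks_c1,peaks_c2 normalised peak sets (`GRanges`).
#' @param labels length-2 character, display names for the two conditions.
#' @return object of class `peak_categories`: a list with `cond1_only`,
#'   `cond2_only`, `shared` (merged regions) and a `counts` list holding
#'   `cond1_only`, `cond2_only`, `shared_regions`, `shared_cond1`,
#'   `shared_cond2`, `total_cond1`, `total_cond2`.
#' @export
categorize_by_condition <- function(peaks_c1, peaks_c2,
                                    labels = c("cond1", "cond2")) {
  hits <- GenomicRanges::findOverlaps(peaks_c1, peaks_c2, minoverlap = 1L,
                                      ignore.strand = TRUE)
  in1 <- unique(S4Vectors::queryHits(hits))
  in2 <- unique(S4Vectors::subjectHits(hits))
  only1 <- peaks_c1[setdiff(seq_along(peaks_c1), in1)]
  only2 <- peaks_c2[setdiff(seq_along(peaks_c2), in2)]
  shared_members <- c(GenomicRanges::granges(peaks_c1[in1]),
                      GenomicRanges::granges(peaks_c2[in2]))
  shared <- normalise_regions(shared_members)
  S4Vectors::metadata(only1)$label <- paste0(labels[1], "_only")
  S4Vectors::metadata(only2)$label <- paste0(labels[2], "_only")
  S4Vectors::metadata(shared)$label <- "shared"
  structure(list(
    cond1_only = only1,
    cond2_only = only2,
    shared = shared,
    labels = labels,
    counts = list(
      cond1_only = length(only1),
      cond2_only = length(only2),
      shared_regions = length(shared),
      shared_cond1 = length(in1),
      shared_cond2 = length(in2),
      total_cond1 = length(peaks_c1),
      total_cond2 = length(peaks_c2)
    )
  ), class = "peak_categories")
}

#' @export
print.peak_categories <- function(x, ...) {
  cts <- x$counts
  cat("Peak categories (", x$labels[1], " vs ", x$labels[2], ")\n", sep = "")
  cat(sprintf("  %s-only : %d of %d\n", x$labels[1], cts$cond1_only,
              cts$total_cond1))
  cat(sprintf("  %s-only : %d of %d\n", x$labels[2], cts$cond2_only,
              cts$total_cond2))
  cat(sprintf("  shared  : %d merged regions (%d %s-side, %d %s-side)\n",
              cts$shared_regions, cts$shared_cond1, x$labels[1],
              cts$shared_cond2, x$labels[2]))
  invisible(x)
}
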