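#' Build a background universe of regions
#'
#' Merges a list of region sets (for example all open-chromatin peaks plus
#' the enhancer catalogues) into a normalised, non-overlapping universe —
#' the urn of the hypergeometric overlap test. Provenance (set labels) is
#' recorded.
#'
#' @param sets list of `GRanges`.
#' @param max_gap gap tolerance passed to [merge_regions()] (default 0:
#'   book-ended regions merge).
#' @return object of class `background_universe`: list with `regions`
#'   (merged `GRanges`), `N` (region count) and `provenance`.
#' @export
build_background <- function(sets, max_gap = 0) {
  if (!is.list(sets)) sets <- list(sets)
  if (length(sets) == 0L || all(vapply(sets, length, 0L) == 0L))
    stop("cannot build a background from empty region sets", call. = FALSE)
  prov <- vapply(sets, region_label, "")
  merged <- merge_regions(
    do.call(c, unname(lapply(sets, GenomicRanges::granges))), max_gap = max_gap)
  structure(list(regions = merged, N = length(merged), provenance = prov),
            class = "background_universe")
}

#' @export
print.background_universe <- function(x, ...) {
  cat("Background universe: ", x$N, " merged regions (sources: ",
      paste(x$provenance, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Upper-tail hypergeometric probability
#'
#' Probability of observing `k` or more marked items when drawing `n` items
#' without replacement from an urn of `N` items of which `K` are marked,
#' i.e. `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Computed through the
#' numerically stable distribution function; exactly 1 at `k = 0`.
#'
#' @param N universe size.
#' @param K marked items in the universe.
#' @param n draw size.
#' @param k observed marked draws.
#' @return the upper-tail probability, in `(0, 1]`. Vectorised.
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (any(N < 0 | K < 0 | n < 0 | k < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(K > N | n > N))
    stop("K and n cannot exceed N", call. = FALSE)
  if (any(k > pmin(K, n)))
    stop("k cannot exceed min(K, n)", call. = FALSE)
  ifelse(k == 0, 1,
         stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE))
}

#' @keywords internal
new_overlap_enrichment <- function(label_a, label_b, N, K, n, k,
                                   frac_a_in_b, frac_b_in_a) {
  structure(list(set_a = label_a, set_b = label_b,
                 N = N, K = K, n = n, k = k,
                 p_value = hypergeom_upper_tail(N, K, n, k),
                 fraction_A_in_B = frac_a_in_b,
                 fraction_B_in_A = frac_b_in_a),
            class = "overlap_enrichment")
}

#' @export
print.overlap_enrichment <- function(x, ...) {
  cat(sprintf("Overlap enrichment: %s vs %s\n", x$set_a, x$set_b))
  cat(sprintf("  urn N=%d, K=%d, n=%d, k=%d; hypergeometric upper-tail p = %.3g\n",
              x$N, x$K, x$n, x$k, x$p_value))
  cat(sprintf("  %.1f%% of A in B; %.1f%% of B in A\n",
              100 * x$fraction_A_in_B, 100 * x$fraction_B_in_A))
  invisible(x)
}

#' Hypergeometric enrichment of the overlap between two region sets
#'
#' Counts are taken in universe-region space so the urn is well defined: a
#' universe region is "overlapped" by a set iff some interval of the set
#' covers at least `min_bp` of its bases. `K`, `n` and `k` are the numbers
#' of universe regions overlapped by A, by B, and by both, and the p-value
#' is the upper-tail hypergeometric probability of `k`. The reported
#' fractions are computed on raw peak counts (fraction of A peaks
#' overlapping B and vice versa) and do not depend on the universe.
#'
#' @param setA,setB `GRanges` region sets.
#' @param universe a `background_universe` (see [build_background()]).
#' @param min_bp minimum overlap in bases (default 1).
#' @return an `overlap_enrichment` object.
#' @export
region_overlap_enrichment <- function(setA, setB, universe, min_bp = 1) {
  stopifnot(inherits(universe, "background_universe"))
  if (universe$N == 0L) stop("empty background universe", call. = FALSE)
  u <- universe$regions
  inA <- IRanges::overlapsAny(u, setA, minoverlap = min_bp,
                                    ignore.strand = TRUE)
  inB <- IRanges::overlapsAny(u, setB, minoverlap = min_bp,
                                    ignore.strand = TRUE)
  fa <- if (length(setA)) mean(IRanges::overlapsAny(
    setA, setB, minoverlap = min_bp, ignore.strand = TRUE)) else NA_real_
  fb <- if (length(setB)) mean(IRanges::overlapsAny(
    setB, setA, minoverlap = min_bp, ignore.strand = TRUE)) else NA_real_
  new_overlap_enrichment(
    label_a = region_label(setA), label_b = region_label(setB),
    N = universe$N, K = sum(inA), n = sum(inB), k = sum(inA & inB),
    frac_a_in_b = fa, frac_b_in_a = fb)
}

#' Hypergeometric enrichment of a gene-set overlap
#'
#' Tests whether `query` and `target` share more genes than expected when
#' both are drawn from the stated gene universe (for instance all genes
#' associated with any accessible region).
#'
#' @param query,target character vectors of gene ids, both subsets of
#'   `universe`.
#' @param universe character vector, the gene background.
#' @param labels length-2 display labels for query and target.
#' @return an `overlap_enrichment` object with gene counts in the
#'   region-count slots.
#' @export
gene_set_enrichment <- function(query, target, universe,
                                labels = c("query", "target")) {
  query <- unique(as.character(query))
  target <- unique(as.character(target))
  universe <- unique(as.character(universe))
  if (!all(query %in% universe))
    stop("query genes must be a subset of the universe", call. = FALSE)
  if (!all(target %in% universe))
    stop("target genes must be a subset of the universe", call. = FALSE)
  k <- length(intersect(query, target))
  new_overlap_enrichment(
    label_a = labels[1], label_b = labels[2],
    N = length(universe), K = length(query), n = length(target), k = k,
    frac_a_in_b = if (length(query)) k / length(query) else NA_real_,
    frac_b_in_a = if (length(target)) k / length(target) else NA_real_)
}

#' Tabulate enrichment results
#'
#' @param results list of `overlap_enrichment` objects.
#' @return data.frame with columns `set_a`, `set_b`, `N`, `K`, `n`, `k`,
#'   `p_value`, `frac_a_in_b`, `frac_b_in_a`.
#' @export
enrichment_table <- function(results) {
  if (inherits(results, "overlap_enrichment")) results <- list(results)
  do.call(rbind, lapply(results, function(r)
    data.frame(set_a = r$set_a, set_b = r$set_b, N = r$N, K = r$K,
               n = r$n, k = r$k, p_value = r$p_value,
               frac_a_in_b = r$fraction_A_in_B,
               frac_b_in_a = r$fraction_B_in_A,
               stringsAsFactors = FALSE)))
}
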