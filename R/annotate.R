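#' Read a gene-model table
#'
#' TSV with header columns `gene_id`, `chrom`, `strand`, `tss` (0-based
#' position of the transcription start base).
#'
#' @param path file path.
#' @return validated gene-model data.frame.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_gene_table(df)
}

#' @keywords internal
validate_gene_table <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!all(need %in% names(genes)))
    stop("gene table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(genes) == 0L) stop("empty gene table", call. = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in gene table", call. = FALSE)
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'", call. = FALSE)
  if (any(genes$tss < 0)) stop("negative TSS position", call. = FALSE)
  genes
}

#' Write a gene-model table
#' @param genes gene-model data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes[, c("gene_id", "chrom", "strand", "tss")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign peaks to their nearest-TSS gene
#'
#' Every peak is assigned to the gene with the closest TSS on the same
#' chromosome. The distance is 0 when the peak spans the TSS, otherwise the
#' gap between the TSS and the nearest peak edge; the sign is taken along
#' the gene's strand (negative = peak upstream of the TSS). Exact-distance
#' ties go to the lexicographically smallest `gene_id`. Peaks on chromosomes
#' with no gene are reported with `gene_id = NA`.
#'
#' @param peaks `GRanges`.
#' @param genes gene-model data.frame (`gene_id`, `chrom`, `strand`, `tss`).
#' @param promoter_window numeric length-2, signed-distance window (bp)
#'   within which a peak is flagged as promoter-proximal; inclusive bounds,
#'   default `c(-3000, 3000)`.
#' @param max_distance optional cap (bp): peaks farther than this from every
#'   TSS are left unassigned. Default `Inf` (every peak gets a gene).
#' @return data.frame with one row per peak: `peak` (index), `chrom`,
#'   `start`, `end` (0-based half-open), `gene_id`, `distance` (signed bp),
#'   `is_promoter`.
#' @export
assign_peaks_to_genes <- function(peaks, genes,
                                  promoter_window = c(-3000, 3000),
                                  max_distance = Inf) {
  genes <- validate_gene_table(genes)
  if (length(promoter_window) != 2L || promoter_window[1] > promoter_window[2])
    stop("promoter_window must be c(lower, upper)", call. = FALSE)
  n <- length(peaks)
  out <- data.frame(
    peak = seq_len(n),
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1,
    end = GenomicRanges::end(peaks),
    gene_id = rep(NA_character_, n),
    distance = rep(NA_real_, n),
    is_promoter = rep(NA, n),
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(out)
  # among genes sharing an identical TSS position only the lexicographically
  # smallest id can ever win a tie, so deduplicate up front
  g <- genes[order(genes$chrom, genes$tss, genes$gene_id), ]
  g <- g[!duplicated(g[, c("chrom", "tss")]), ]
  for (chr in unique(out$chrom)) {
    gi <- g[g$chrom == chr, ]
    pi <- which(out$chrom == chr)
    if (nrow(gi) == 0L) next
    tss1 <- gi$tss + 1          # 1-based position of the TSS base
    s1 <- out$start[pi] + 1     # 1-based first base of peak
    e1 <- out$end[pi]           # 1-based last base of peak
    left <- findInterval(s1, tss1)          # last TSS <= peak start
    right_of_end <- findInterval(e1, tss1)  # last TSS <= peak end
    for (j in seq_along(pi)) {
      if (right_of_end[j] > 0 && tss1[right_of_end[j]] >= s1[j]) {
        # one or more TSSs inside the peak: distance 0, smallest id wins
        inside <- seq.int(max(left[j], 0L) + 1L, right_of_end[j])
        ids <- gi$gene_id[inside]
        k <- inside[order(ids)[1L]]
        d_gen <- 0
      } else {
        dl <- if (left[j] >= 1L) s1[j] - tss1[left[j]] else Inf
        dr <- if (left[j] < nrow(gi)) tss1[left[j] + 1L] - e1[j] else Inf
        if (dl < dr) {
          k <- left[j]; d_gen <- dl         # TSS left: peak downstream
        } else if (dr < dl) {
          k <- left[j] + 1L; d_gen <- -dr   # TSS right: peak upstream
        } else {                            # exact tie: smallest id
          cand <- c(left[j], left[j] + 1L)
          k <- cand[order(gi$gene_id[cand])[1L]]
          d_gen <- if (k == left[j]) dl else -dr
        }
      }
      # d_gen is genomic offset of the peak relative to the TSS
      # (positive = peak to the right); flip for minus-strand genes
      d_signed <- if (gi$strand[k] == "-") -d_gen else d_gen
      if (abs(d_signed) > max_distance) next
      out$gene_id[pi[j]] <- gi$gene_id[k]
      out$distance[pi[j]] <- d_signed
      out$is_promoter[pi[j]] <- d_signed >= promoter_window[1] &&
        d_signed <= promoter_window[2]
    }
  }
  out
}

#' Fraction of assigned peaks at promoters
#'
#' @param assignments output of [assign_peaks_to_genes()].
#' @return fraction in `[0, 1]` of assigned peaks whose signed TSS distance
#'   falls in the promoter window.
#' @export
classify_promoter_fraction <- function(assignments) {
  flags <- assignments$is_promoter[!is.na(assignments$gene_id)]
  if (length(flags) == 0L)
    stop("no assigned peaks to classify", call. = FALSE)
  mean(flags)
}

#' Construct a target-groups object
#'
#' @param cond1_specific,cond2_specific,shared character vectors of gene
#'   ids; must be pairwise disjoint.
#' @param labels display names for the two conditions.
#' @return object of class `target_groups`.
#' @export
target_groups <- function(cond1_specific, cond2_specific, shared,
                          labels = c("cond1", "cond2")) {
  gs <- list(cond1_specific = unique(as.character(cond1_specific)),
             cond2_specific = unique(as.character(cond2_specific)),
             shared = unique(as.character(shared)))
  for (i in 1:2) for (j in (i + 1):3)
    if (length(intersect(gs[[i]], gs[[j]])) > 0)
      stop("target groups must be pairwise disjoint", call. = FALSE)
  structure(c(gs, list(labels = labels)), class = "target_groups")
}

#' @export
print.target_groups <- function(x, ...) {
  cat("Target groups:\n")
  cat(sprintf("  %s-specific: %d genes\n", x$labels[1],
              length(x$cond1_specific)))
  cat(sprintf("  %s-specific: %d genes\n", x$labels[2],
              length(x$cond2_specific)))
  cat(sprintf("  shared     : %d genes\n", length(x$shared)))
  invisible(x)
}

#' Derive gene-level target groups from peak categories
#'
#' Assigns each peak category to nearest-TSS genes and classifies every
#' bound gene: hit via a shared peak, or (by default) via separate peaks in
#' both conditions, puts the gene in `shared`; a gene hit only through
#' condition-1-specific peaks is `cond1_specific`, and likewise for
#' condition 2. The three groups are disjoint by construction.
#'
#' @param categories a `peak_categories` object.
#' @param genes gene-model data.frame.
#' @param promoter_window,max_distance passed to [assign_peaks_to_genes()].
#' @param separate_as_shared if `TRUE` (default) a gene hit by a
#'   condition-1-only peak and a condition-2-only peak counts as shared; if
#'   `FALSE` such genes are assigned to no group and returned in the
#'   `ambiguous` attribute.
#' @return a `target_groups` object; attribute `assignments` carries the
#'   per-category peak-to-gene tables.
#' @export
derive_target_groups <- function(categories, genes,
                                 promoter_window = c(-3000, 3000),
                                 max_distance = Inf,
                                 separate_as_shared = TRUE) {
  stopifnot(inherits(categories, "peak_categories"))
  asg <- lapply(categories[c("cond1_only", "cond2_only", "shared")],
                assign_peaks_to_genes, genes = genes,
                promoter_window = promoter_window,
                max_distance = max_distance)
  hit <- lapply(asg, function(a) unique(a$gene_id[!is.na(a$gene_id)]))
  h1 <- hit$cond1_only; h2 <- hit$cond2_only; hs <- hit$shared
  both <- intersect(h1, h2)
  shared_genes <- if (separate_as_shared) union(hs, both) else hs
  excluded <- if (separate_as_shared) character(0) else setdiff(both, hs)
  tg <- target_groups(
    cond1_specific = setdiff(h1, union(shared_genes, union(h2, excluded))),
    cond2_specific = setdiff(h2, union(shared_genes, union(h1, excluded))),
    shared = shared_genes,
    labels = categories$labels
  )
  attr(tg, "assignments") <- asg
  attr(tg, "ambiguous") <- excluded
  tg
}
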