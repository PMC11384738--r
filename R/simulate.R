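#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults describe the study conditions the downstream statistics are
#' built for: two cellular states sharing one transcription factor, with
#' condition 2 placing about three quarters of its peaks on formative-state
#' (stateB-specific plus shared) enhancers, condition-1-specific targets
#' planted to go down (delta = -0.5), condition-2-specific targets up
#' (+0.5), shared targets flat, and per-gene log2FC noise of sd 0.5 — the
#' same scale as the DEG threshold.
#'
#' @param n_genes number of genes on the toy genome.
#' @param n_enhancers_per_class named counts for enhancer classes
#'   `stateA_specific`, `stateB_specific`, `shared`.
#' @param n_peaks_per_condition named counts `cond1`, `cond2`.
#' @param enhancer_composition per-condition probability vector over
#'   `stateA_specific`, `stateB_specific`, `shared`, `background`; each must
#'   sum to 1 (tolerance 1e-9).
#' @param peak_width,enhancer_width interval widths (bp).
#' @param replicate_jitter_sd sd (bp) of the Gaussian jitter applied to
#'   replicate peak edges.
#' @param tss_exclusion half-width (bp) of the TSS window enhancers must
#'   avoid (default 3000).
#' @param min_spacing minimum TSS spacing (bp).
#' @param effect_sizes named planted mean log2FC shifts for
#'   `cond1_specific`, `cond2_specific`, `shared` target groups.
#' @param noise_sd sd of per-gene log2FC noise (>= 0).
#' @param n_timepoints optional number of TPM timepoints to simulate
#'   (0 = none).
#' @param n_accessible number of accessible-chromatin regions generated for
#'   the background universe (see [generate_accessible_regions()]).
#' @param seed integer; identical config implies identical outputs.
#' @param chrom_names,chrom_lengths toy genome layout; default a single
#'   10 Mb chromosome.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 300,
                       n_enhancers_per_class = c(stateA_specific = 80,
                                                 stateB_specific = 100,
                                                 shared = 60),
                       n_peaks_per_condition = c(cond1 = 600, cond2 = 1200),
                       enhancer_composition = list(
                         cond1 = c(stateA_specific = 0.42,
                                   stateB_specific = 0.05,
                                   shared = 0.33, background = 0.20),
                         cond2 = c(stateA_specific = 0.04,
                                   stateB_specific = 0.50,
                                   shared = 0.24, background = 0.22)),
                       peak_width = 200, enhancer_width = 500,
                       replicate_jitter_sd = 20,
                       tss_exclusion = 3000, min_spacing = 20000,
                       effect_sizes = c(cond1_specific = -0.5,
                                        cond2_specific = 0.5,
                                        shared = 0),
                       noise_sd = 0.5, n_timepoints = 0,
                       n_accessible = 3000, seed = 1,
                       chrom_names = "chr1", chrom_lengths = 1e7) {
  cfg <- list(n_genes = n_genes, n_accessible = n_accessible,
              n_enhancers_per_class = n_enhancers_per_class,
              n_peaks_per_condition = n_peaks_per_condition,
              enhancer_composition = enhancer_composition,
              peak_width = peak_width, enhancer_width = enhancer_width,
              replicate_jitter_sd = replicate_jitter_sd,
              tss_exclusion = tss_exclusion, min_spacing = min_spacing,
              effect_sizes = effect_sizes, noise_sd = noise_sd,
              n_timepoints = n_timepoints, seed = as.integer(seed),
              chrom_names = chrom_names, chrom_lengths = chrom_lengths)
  validate_sim_config(cfg)
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  if (any(cfg$chrom_lengths <= 0))
    stop("chromosome lengths must be positive", call. = FALSE)
  if (anyDuplicated(cfg$chrom_names))
    stop("chromosome names must be unique", call. = FALSE)
  if (length(cfg$chrom_names) != length(cfg$chrom_lengths))
    stop("chrom_names and chrom_lengths differ in length", call. = FALSE)
  counts <- c(cfg$n_genes, cfg$n_enhancers_per_class,
              cfg$n_peaks_per_condition, cfg$n_timepoints,
              cfg$n_accessible)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  cls <- c("stateA_specific", "stateB_specific", "shared")
  if (!all(cls %in% names(cfg$n_enhancers_per_class)))
    stop("n_enhancers_per_class needs classes: ",
         paste(cls, collapse = ", "), call. = FALSE)
  for (cond in names(cfg$enhancer_composition)) {
    p <- cfg$enhancer_composition[[cond]]
    if (!all(c(cls, "background") %in% names(p)))
      stop("composition for ", cond, " needs stateA_specific, ",
           "stateB_specific, shared, background", call. = FALSE)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("composition for ", cond,
           " must be a probability vector summing to 1", call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$peak_width <= 0 || cfg$enhancer_width <= 0)
    stop("interval widths must be positive", call. = FALSE)
  if (cfg$replicate_jitter_sd < 0)
    stop("replicate_jitter_sd must be >= 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Generate a toy genome
#'
#' @param config a `sim_config`.
#' @return list of class `genome_spec` with `chrom_names` and
#'   `chrom_lengths` (named vector); default a single 10 Mb chromosome.
#' @export
generate_genome <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  structure(list(
    chrom_names = config$chrom_names,
    chrom_lengths = stats::setNames(config$chrom_lengths,
                                    config$chrom_names)),
    class = "genome_spec")
}

#' Generate gene models with a minimum TSS spacing
#'
#' TSS positions are drawn uniformly under a hard pairwise spacing
#' constraint (positions are drawn in a shrunken coordinate space and
#' spread back out, so all pairwise TSS distances are at least
#' `min_spacing` by construction). Genes are distributed over chromosomes
#' proportionally to length; ids are zero-padded and hence unique and
#' sortable; strands are random.
#'
#' @param genome a `genome_spec`.
#' @param n_genes gene count.
#' @param min_spacing minimum distance (bp) between any two TSSs on a
#'   chromosome.
#' @param seed integer seed.
#' @return gene-model data.frame (`gene_id`, `chrom`, `strand`, `tss`).
#' @export
generate_genes <- function(genome, n_genes, min_spacing = 20000, seed = 1) {
  lens <- genome$chrom_lengths
  if (n_genes == 0L)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), tss = numeric(0)))
  # apportion genes to chromosomes by length (largest remainder)
  share <- n_genes * lens / sum(lens)
  n_chr <- floor(share)
  rem <- n_genes - sum(n_chr)
  if (rem > 0) {
    o <- order(share - n_chr, decreasing = TRUE)
    n_chr[o[seq_len(rem)]] <- n_chr[o[seq_len(rem)]] + 1
  }
  for (i in seq_along(lens))
    if (n_chr[i] * min_spacing > lens[i])
      stop("cannot place ", n_chr[i], " genes with spacing ", min_spacing,
           " on a ", lens[i], " bp chromosome", call. = FALSE)
  withr::with_seed(seed, {
    rows <- lapply(seq_along(lens), function(i) {
      ni <- n_chr[i]
      if (ni == 0L) return(NULL)
      slack <- lens[i] - (ni - 1) * min_spacing - 1
      tss <- sort(stats::runif(ni, 0, slack)) +
        (seq_len(ni) - 1) * min_spacing
      data.frame(chrom = names(lens)[i],
                 strand = sample(c("+", "-"), ni, replace = TRUE),
                 tss = floor(tss), stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$gene_id <- sprintf("gene_%0*d", nchar(nrow(df)) + 1, seq_len(nrow(df)))
    df[, c("gene_id", "chrom", "strand", "tss")]
  })
}

#' @keywords internal
place_nonoverlapping <- function(genome, n, width, forbidden, seed_offset,
                                 seed, max_tries = 200) {
  lens <- genome$chrom_lengths
  withr::with_seed(seed + seed_offset, {
    placed <- GenomicRanges::GRanges()
    tries <- 0
    while (length(placed) < n) {
      tries <- tries + 1
      if (tries > max_tries)
        stop("could not place ", n, " non-overlapping regions after ",
             max_tries, " rounds; genome too crowded", call. = FALSE)
      need <- n - length(placed)
      chr <- sample(names(lens), need, replace = TRUE,
                    prob = lens / sum(lens))
      start0 <- floor(stats::runif(need, 0, lens[chr] - width))
      cand <- region_set(chr, start0, start0 + width)
      ok <- !IRanges::overlapsAny(cand, forbidden,
                                        ignore.strand = TRUE) &
        !IRanges::overlapsAny(cand, placed, ignore.strand = TRUE) &
        !duplicated(paste(chr, start0))
      # also reject candidates overlapping each other within this round
      cand <- cand[ok]
      if (length(cand) > 1L) {
        self <- GenomicRanges::countOverlaps(cand, cand,
                                             ignore.strand = TRUE) > 1
        cand <- cand[!self]
      }
      placed <- c(placed, cand)
    }
    GenomicRanges::sort(placed[seq_len(n)], ignore.strand = TRUE)
  })
}

#' Generate enhancer classes on the toy genome
#'
#' Places non-overlapping enhancers of three classes (`stateA_specific`,
#' `stateB_specific`, `shared`), none within `tss_exclusion` bp of any TSS,
#' by bounded rejection sampling.
#'
#' @param genome a `genome_spec`.
#' @param genes gene-model data.frame.
#' @param config a `sim_config` (uses `n_enhancers_per_class`,
#'   `enhancer_width`, `tss_exclusion`, `seed`).
#' @return named list of `GRanges`, one per class; classes never overlap
#'   one another.
#' @export
generate_enhancers <- function(genome, genes, config = sim_config()) {
  config <- validate_sim_config(config)
  lens <- genome$chrom_lengths
  w <- config$tss_exclusion
  tss_windows <- if (nrow(genes)) region_set(
    genes$chrom, pmax(genes$tss - w, 0),
    pmin(genes$tss + w + 1, lens[genes$chrom])) else GenomicRanges::GRanges()
  if (any(2 * w + 1 >= lens[unique(genes$chrom)]) && nrow(genes) > 0 &&
      sum(config$n_enhancers_per_class) > 0)
    stop("TSS exclusion window covers a whole chromosome", call. = FALSE)
  out <- list()
  forbidden <- tss_windows
  cls <- c("stateA_specific", "stateB_specific", "shared")
  for (i in seq_along(cls)) {
    n <- config$n_enhancers_per_class[[cls[i]]]
    gr <- place_nonoverlapping(genome, n, config$enhancer_width,
                               forbidden, seed_offset = 1000 + i,
                               seed = config$seed)
    S4Vectors::metadata(gr)$label <- cls[i]
    out[[cls[i]]] <- gr
    forbidden <- c(forbidden, gr)
  }
  out
}

#' Generate an accessible-chromatin region set
#'
#' Places regions uniformly on the genome, unconstrained by enhancers or
#' TSSs, emulating the bulk of detected open-chromatin (ATAC) regions that
#' form the background universe of the overlap tests together with the
#' enhancer catalogues.
#'
#' @param genome a `genome_spec`.
#' @param n region count.
#' @param width region width (bp).
#' @param seed integer seed.
#' @return a `GRanges` labelled `"accessible"`.
#' @export
generate_accessible_regions <- function(genome, n, width = 400, seed = 1) {
  lens <- genome$chrom_lengths
  withr::with_seed(seed + 211L, {
    chr <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
    s0 <- floor(stats::runif(n, 0, lens[chr] - width))
    gr <- region_set(chr, s0, s0 + width, label = "accessible")
    GenomicRanges::sort(gr, ignore.strand = TRUE)
  })
}

#' Generate condition peak sets with a planted enhancer composition
#'
#' Each peak samples an origin from the condition's composition vector:
#' enhancer-class origins centre the peak uniformly inside a uniformly
#' chosen enhancer of that class (guaranteeing overlap), and background
#' origins are rejection-resampled until they touch no enhancer of any
#' class, so the planted composition labels are exact. Replicates beyond
#' the first are jittered copies: both edges shifted by Gaussian noise of
#' sd `replicate_jitter_sd`, re-clipped to the genome with a 50 bp minimum
#' width.
#'
#' @param genome a `genome_spec`.
#' @param enhancers named list of class `GRanges` from
#'   [generate_enhancers()].
#' @param config a `sim_config`.
#' @param condition_label which condition's composition and count to use
#'   (`"cond1"` or `"cond2"`).
#' @param n_replicates number of replicate peak sets (default 2).
#' @return list of `GRanges`, one per replicate; replicate 1 carries the
#'   exact planted composition in its `origin` metadata column.
#' @export
generate_peaks <- function(genome, enhancers, config = sim_config(),
                           condition_label = "cond1", n_replicates = 2) {
  config <- validate_sim_config(config)
  comp <- config$enhancer_composition[[condition_label]]
  if (is.null(comp))
    stop("no composition for condition: ", condition_label, call. = FALSE)
  n <- config$n_peaks_per_condition[[condition_label]]
  cls <- c("stateA_specific", "stateB_specific", "shared")
  for (cl in cls)
    if (comp[[cl]] > 0 && length(enhancers[[cl]]) == 0L)
      stop("composition gives class ", cl,
           " nonzero probability but it has no enhancers", call. = FALSE)
  lens <- genome$chrom_lengths
  w <- config$peak_width
  all_enh <- do.call(c, unname(lapply(enhancers, GenomicRanges::granges)))
  withr::with_seed(config$seed + match(condition_label,
                                       names(config$n_peaks_per_condition)),
  {
    origin <- sample(names(comp), n, replace = TRUE, prob = comp)
    chrom <- character(n); start0 <- numeric(n)
    for (cl in cls) {
      idx <- which(origin == cl)
      if (length(idx) == 0L) next
      e <- enhancers[[cl]][sample.int(length(enhancers[[cl]]),
                                      length(idx), replace = TRUE)]
      centre <- GenomicRanges::start(e) - 1 +
        floor(stats::runif(length(idx)) * GenomicRanges::width(e))
      chrom[idx] <- as.character(GenomicRanges::seqnames(e))
      start0[idx] <- pmax(0, pmin(centre - floor(w / 2),
                                  lens[chrom[idx]] - w))
    }
    bg <- which(origin == "background")
    while (length(bg) > 0L) {
      chr <- sample(names(lens), length(bg), replace = TRUE,
                    prob = lens / sum(lens))
      s0 <- floor(stats::runif(length(bg), 0, lens[chr] - w))
      cand <- region_set(chr, s0, s0 + w)
      ok <- !IRanges::overlapsAny(cand, all_enh,
                                        ignore.strand = TRUE)
      chrom[bg[ok]] <- chr[ok]
      start0[bg[ok]] <- s0[ok]
      bg <- bg[!ok]
    }
    base <- region_set(chrom, start0, start0 + w,
                       name = sprintf("%s_peak_%04d", condition_label,
                                      seq_len(n)),
                       label = condition_label)
    base$origin <- origin
    base <- GenomicRanges::sort(base, ignore.strand = TRUE)
    reps <- list(base)
    if (n_replicates > 1) for (r in 2:n_replicates) {
      s1 <- GenomicRanges::start(base) - 1 +
        round(stats::rnorm(n, 0, config$replicate_jitter_sd))
      e1 <- GenomicRanges::end(base) +
        round(stats::rnorm(n, 0, config$replicate_jitter_sd))
      lo <- pmin(s1, e1); hi <- pmax(s1, e1)
      hi <- pmax(hi, lo + 50)  # minimum width clamp
      len <- lens[as.character(GenomicRanges::seqnames(base))]
      lo <- pmax(0, pmin(lo, len - 50))
      hi <- pmax(lo + 50, pmin(hi, len))
      rep_gr <- region_set(as.character(GenomicRanges::seqnames(base)),
                           lo, hi, name = base$name,
                           label = paste0(condition_label, "_rep", r))
      rep_gr$origin <- base$origin
      reps[[r]] <- GenomicRanges::sort(rep_gr, ignore.strand = TRUE)
    }
    reps
  })
}

#' Generate an expression table with planted group effects
#'
#' Per-gene log2FC is `delta(group) + Normal(0, noise_sd)` with `delta = 0`
#' for non-targets. Adjusted p-values come from a one-sample z-score of
#' the log2FC against `noise_sd` with Benjamini-Hochberg adjustment (with
#' `noise_sd = 0` the z-score degenerates: padj is 0 for nonzero log2FC
#' and 1 otherwise). Optional timepoint columns (`tpm_t0`, ...) follow a
#' linear trend of slope `delta` across the course on a log2 TPM scale.
#'
#' @param genes gene-model data.frame.
#' @param target_groups a `target_groups` object (gene ids must exist in
#'   `genes`).
#' @param config a `sim_config` (uses `effect_sizes`, `noise_sd`,
#'   `n_timepoints`, `seed`).
#' @return data.frame with `gene_id`, `group`, `log2fc`, `padj` and
#'   optional `tpm_t*` columns.
#' @export
generate_expression <- function(genes, target_groups,
                                config = sim_config()) {
  config <- validate_sim_config(config)
  stopifnot(inherits(target_groups, "target_groups"))
  ids <- genes$gene_id
  grp_genes <- target_groups[c("cond1_specific", "cond2_specific", "shared")]
  unknown <- setdiff(unlist(grp_genes), ids)
  if (length(unknown) > 0)
    stop("target groups contain unknown genes: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  group <- rep("none", length(ids))
  for (g in names(grp_genes)) group[ids %in% grp_genes[[g]]] <- g
  delta <- ifelse(group == "none", 0, config$effect_sizes[group])
  withr::with_seed(config$seed + 97L, {
    lfc <- delta + stats::rnorm(length(ids), 0, config$noise_sd)
    if (config$noise_sd > 0) {
      p <- 2 * stats::pnorm(-abs(lfc) / config$noise_sd)
      padj <- stats::p.adjust(p, method = "BH")
    } else {
      padj <- ifelse(lfc == 0, 1, 0)
    }
    out <- data.frame(gene_id = ids, group = group, log2fc = lfc,
                      padj = padj, stringsAsFactors = FALSE)
    if (config$n_timepoints > 0) {
      tt <- seq(0, 1, length.out = config$n_timepoints)
      base_l2 <- stats::rnorm(length(ids), 5, 1)
      for (j in seq_along(tt)) {
        noise <- stats::rnorm(length(ids), 0, config$noise_sd / 4)
        out[[paste0("tpm_t", j - 1)]] <-
          2^(base_l2 + delta * tt[j] + noise)
      }
    }
    out
  })
}
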