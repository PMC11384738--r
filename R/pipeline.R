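#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' the output preserves the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Pipeline configuration
#'
#' Assembles thresholds, bootstrap settings and either a simulation config
#' (synthetic mode) or input file paths (file mode) into one validated
#' object. In file mode the referenced files must exist.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param sim a `sim_config` (synthetic mode).
#' @param paths named list of input paths (file mode): `peaks_cond1`,
#'   `peaks_cond2` (BED), `genes` (TSV), `expression` (TSV); optional
#'   `enhancers_*` BEDs and `blacklist`.
#' @param alpha,min_abs_log2fc DEG thresholds (inclusive).
#' @param min_overlap_bp minimum overlap (bp) for all overlap counting.
#' @param consensus_frac fractional-overlap rule for replicate consensus
#'   peaks, in `(0, 1]`.
#' @param promoter_window signed-distance promoter window (bp).
#' @param bootstrap_B,bootstrap_seed draws and seed for the effect-size
#'   bootstrap; `bootstrap_seed = NULL` derives it from the global `seed`.
#' @param seed global seed, split deterministically into per-stage seeds.
#' @param outdir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            sim = sim_config(), paths = list(),
                            alpha = 0.05, min_abs_log2fc = 0.5,
                            min_overlap_bp = 1, consensus_frac = 0.5,
                            promoter_window = c(-3000, 3000),
                            bootstrap_B = 30000, bootstrap_seed = NULL,
                            seed = 1, outdir = tempfile("tfrewire_run_")) {
  mode <- match.arg(mode)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  if (consensus_frac <= 0 || consensus_frac > 1)
    stop("consensus_frac must be in (0, 1]", call. = FALSE)
  if (mode == "files") {
    need <- c("peaks_cond1", "peaks_cond2", "genes", "expression")
    for (f in need) {
      if (is.null(paths[[f]]))
        stop("file mode requires the path field: ", f, call. = FALSE)
      if (!file.exists(paths[[f]]))
        stop("input file for '", f, "' does not exist: ", paths[[f]],
             call. = FALSE)
    }
  }
  if (mode == "synthetic") {
    sim <- validate_sim_config(sim)
    sim$seed <- as.integer(seed)
  }
  structure(list(mode = mode, sim = sim, paths = paths, alpha = alpha,
                 min_abs_log2fc = min_abs_log2fc,
                 min_overlap_bp = min_overlap_bp,
                 consensus_frac = consensus_frac,
                 promoter_window = promoter_window,
                 bootstrap_B = bootstrap_B,
                 bootstrap_seed = bootstrap_seed,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipeline_config()]; a `sim:` block
#' mirrors [sim_config()]. Unknown keys are an error.
#'
#' @param path YAML file.
#' @param overrides named list of values overriding the file (CLI flags).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y[names(overrides)] <- overrides
  known <- c("mode", "sim", "paths", "alpha", "min_abs_log2fc",
             "min_overlap_bp", "consensus_frac", "promoter_window",
             "bootstrap_B", "bootstrap_seed", "seed", "outdir")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(y$sim)) {
    sim_args <- y$sim
    for (nm in c("n_enhancers_per_class", "n_peaks_per_condition",
                 "effect_sizes"))
      if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
    if (!is.null(sim_args$enhancer_composition))
      sim_args$enhancer_composition <-
        lapply(sim_args$enhancer_composition, unlist)
    y$sim <- do.call(sim_config, sim_args)
  }
  do.call(pipeline_config, y)
}

#' @keywords internal
write_tsv_exact <- function(df, path) {
  old <- options(scipen = 100, digits = 15)
  on.exit(options(old))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the integrative pipeline end to end
#'
#' Stages, in dependency order: simulate (or load) peak sets, enhancers and
#' expression; consensus peaks across replicates; categorise the two
#' conditions' peaks into specific and shared groups; assign peaks to
#' nearest-TSS genes and derive target groups; hypergeometric overlap
#' enrichment of each condition's peaks against each enhancer class (and
#' target groups against DEGs, gene space); size-matched bootstrap of each
#' target group's mean log2FC. All intermediate tables are written as
#' TSV/BED under `config$outdir`; identical config and seed give
#' byte-identical outputs.
#'
#' @param config a `pipeline_config`.
#' @param quiet suppress per-stage progress messages.
#' @return a `run_report` list: per-stage parameters, counts and output
#'   files, every number re-derivable from the written stage outputs.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[tfrewire] ", ...)
  t0 <- Sys.time()
  report <- list(version = as.character(utils::packageVersion("tfrewire")),
                 seed = config$seed, mode = config$mode,
                 outdir = config$outdir, stages = list())

  ## stage 1: inputs ---------------------------------------------------
  say("stage simulate/load")
  if (config$mode == "synthetic") {
    sim <- config$sim
    genome <- generate_genome(sim)
    genes <- generate_genes(genome, sim$n_genes, sim$min_spacing,
                            seed = sim$seed)
    enhancers <- generate_enhancers(genome, genes, sim)
    reps1 <- generate_peaks(genome, enhancers, sim, "cond1", 2)
    reps2 <- generate_peaks(genome, enhancers, sim, "cond2", 2)
    peaks1 <- consensus_peaks(reps1[[1]], reps1[[2]],
                              config$consensus_frac)
    peaks2 <- consensus_peaks(reps2[[1]], reps2[[2]],
                              config$consensus_frac)
    S4Vectors::metadata(peaks1)$label <- "cond1"
    S4Vectors::metadata(peaks2)$label <- "cond2"
    for (cl in names(enhancers))
      write_bed(enhancers[[cl]],
                file.path(config$outdir, paste0("enhancers_", cl, ".bed")))
    write_bed(reps1[[1]], file.path(config$outdir, "peaks_cond1_rep1.bed"))
    write_bed(reps1[[2]], file.path(config$outdir, "peaks_cond1_rep2.bed"))
    write_bed(reps2[[1]], file.path(config$outdir, "peaks_cond2_rep1.bed"))
    write_bed(reps2[[2]], file.path(config$outdir, "peaks_cond2_rep2.bed"))
    write_gene_table(genes, file.path(config$outdir, "genes.tsv"))
  } else {
    genes <- read_gene_table(config$paths$genes)
    peaks1 <- read_bed(config$paths$peaks_cond1, label = "cond1")
    peaks2 <- read_bed(config$paths$peaks_cond2, label = "cond2")
    if (!is.null(config$paths$blacklist)) {
      bl <- read_bed(config$paths$blacklist)
      peaks1 <- filter_blacklist(peaks1, bl)
      peaks2 <- filter_blacklist(peaks2, bl)
    }
    peaks1 <- drop_unplaced(peaks1)
    peaks2 <- drop_unplaced(peaks2)
    enh_paths <- config$paths[grepl("^enhancers_", names(config$paths))]
    enhancers <- lapply(enh_paths, read_bed)
    names(enhancers) <- sub("^enhancers_", "", names(enh_paths))
  }
  write_bed(peaks1, file.path(config$outdir, "peaks_cond1.bed"))
  write_bed(peaks2, file.path(config$outdir, "peaks_cond2.bed"))
  report$stages$inputs <- list(
    n_genes = nrow(genes), n_peaks_cond1 = length(peaks1),
    n_peaks_cond2 = length(peaks2),
    n_enhancers = vapply(enhancers, length, 0L))

  ## stage 2: categorise ----------------------------------------------
  say("stage categorize")
  cats <- categorize_by_condition(peaks1, peaks2)
  stopifnot(cats$counts$cond1_only + cats$counts$shared_cond1 ==
              cats$counts$total_cond1,
            cats$counts$cond2_only + cats$counts$shared_cond2 ==
              cats$counts$total_cond2)
  write_bed(cats$cond1_only, file.path(config$outdir, "peaks_cond1_only.bed"))
  write_bed(cats$cond2_only, file.path(config$outdir, "peaks_cond2_only.bed"))
  write_bed(cats$shared, file.path(config$outdir, "peaks_shared.bed"))
  report$stages$categorize <- cats$counts

  ## stage 3: annotate ------------------------------------------------
  say("stage annotate")
  tg <- derive_target_groups(cats, genes,
                             promoter_window = config$promoter_window)
  asg <- attr(tg, "assignments")
  for (nm in names(asg))
    write_tsv_exact(asg[[nm]],
                    file.path(config$outdir,
                              paste0("assignments_", nm, ".tsv")))
  grp_df <- data.frame(
    gene_id = c(tg$cond1_specific, tg$cond2_specific, tg$shared),
    group = rep(c("cond1_specific", "cond2_specific", "shared"),
                c(length(tg$cond1_specific), length(tg$cond2_specific),
                  length(tg$shared))), stringsAsFactors = FALSE)
  grp_df <- grp_df[order(grp_df$gene_id), ]
  write_tsv_exact(grp_df, file.path(config$outdir, "target_groups.tsv"))
  report$stages$annotate <- list(
    n_cond1_specific = length(tg$cond1_specific),
    n_cond2_specific = length(tg$cond2_specific),
    n_shared = length(tg$shared),
    promoter_fraction = tryCatch(
      classify_promoter_fraction(do.call(rbind, asg)),
      error = function(e) NA_real_))

  ## stage 4: expression ----------------------------------------------
  say("stage expression")
  if (config$mode == "synthetic") {
    expr <- generate_expression(genes, tg, config$sim)
  } else {
    expr <- read_expression(config$paths$expression)
  }
  write_tsv_exact(expr, file.path(config$outdir, "expression.tsv"))
  degs <- filter_degs(expr, alpha = config$alpha,
                      min_abs_log2fc = config$min_abs_log2fc)
  report$stages$expression <- list(n_genes = nrow(expr),
                                   n_degs = length(degs$all),
                                   n_up = length(degs$up),
                                   n_down = length(degs$down))

  ## stage 5: enrichment ----------------------------------------------
  say("stage enrich")
  enr <- list()
  if (length(enhancers) > 0) {
    # urn of the overlap test: all accessible regions plus the enhancer
    # catalogues (plus the peak sets themselves, which are accessible by
    # construction)
    uni_sets <- c(unname(enhancers), list(peaks1, peaks2))
    if (config$mode == "synthetic") {
      accessible <- generate_accessible_regions(
        genome, config$sim$n_accessible, seed = config$sim$seed)
      write_bed(accessible, file.path(config$outdir, "accessible.bed"))
      uni_sets <- c(uni_sets, list(accessible))
    } else if (!is.null(config$paths$accessible)) {
      uni_sets <- c(uni_sets, list(read_bed(config$paths$accessible)))
    }
    universe <- build_background(uni_sets)
    for (cl in names(enhancers)) {
      for (pk in list(peaks1, peaks2)) {
        enr[[length(enr) + 1L]] <- region_overlap_enrichment(
          pk, enhancers[[cl]], universe, min_bp = config$min_overlap_bp)
      }
    }
  }
  gene_universe <- expr$gene_id
  for (g in c("cond1_specific", "cond2_specific", "shared")) {
    gset <- intersect(tg[[g]], gene_universe)
    if (length(gset) && length(degs$all))
      enr[[length(enr) + 1L]] <- gene_set_enrichment(
        gset, degs$all, gene_universe, labels = c(g, "DEGs"))
  }
  enr_tab <- enrichment_table(enr)
  write_tsv_exact(enr_tab, file.path(config$outdir, "enrichment.tsv"))
  report$stages$enrich <- enr_tab

  ## stage 6: bootstrap -----------------------------------------------
  say("stage bootstrap")
  bseed <- if (is.null(config$bootstrap_seed)) config$seed + 7919L
           else config$bootstrap_seed
  boot <- compare_target_groups(tg, expr, B = config$bootstrap_B,
                                seed = bseed)
  write_tsv_exact(boot, file.path(config$outdir, "bootstrap.tsv"))
  report$stages$bootstrap <- boot

  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report$files <- sort(list.files(config$outdir))
  class(report) <- "run_report"
  say(sprintf("done in %.1f s; outputs in %s", report$elapsed_s,
              config$outdir))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("tfrewire run (", x$mode, " mode, seed ", x$seed, ")\n", sep = "")
  cat("  peaks: ", x$stages$categorize$cond1_only, " cond1-only, ",
      x$stages$categorize$cond2_only, " cond2-only, ",
      x$stages$categorize$shared_regions, " shared\n", sep = "")
  cat("  target groups: ", x$stages$annotate$n_cond1_specific, " / ",
      x$stages$annotate$n_cond2_specific, " / ",
      x$stages$annotate$n_shared, " genes\n", sep = "")
  cat("  DEGs: ", x$stages$expression$n_degs, " of ",
      x$stages$expression$n_genes, "\n", sep = "")
  cat("  enrichment rows: ", nrow(x$stages$enrich),
      "; bootstrap rows: ", nrow(x$stages$bootstrap), "\n", sep = "")
  cat("  outputs: ", x$outdir, "\n", sep = "")
  invisible(x)
}

#' Write a run report as JSON
#' @param report a `run_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
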