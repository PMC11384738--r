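#' Read an expression table
#'
#' TSV with header; requires `gene_id` plus either plain `log2fc`/`padj`
#' columns (single contrast) or suffixed `log2fc_<contrast>` /
#' `padj_<contrast>` columns (several contrasts). Optional `tpm_*` columns
#' carry a timepoint-resolved expression course.
#'
#' @param path file path.
#' @return data.frame keyed by unique `gene_id`.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(df))
    stop("expression table needs a gene_id column", call. = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in expression table", call. = FALSE)
  padj <- unlist(df[grepl("^padj", names(df))])
  if (length(padj) && any(padj < 0 | padj > 1, na.rm = TRUE))
    stop("padj values must lie in [0, 1]", call. = FALSE)
  df
}

#' Write an expression table
#' @param expr data.frame as returned by [read_expression()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @keywords internal
contrast_cols <- function(expr, contrast = NULL) {
  if (is.null(contrast)) {
    if (!all(c("log2fc", "padj") %in% names(expr)))
      stop("no plain log2fc/padj columns; name the contrast", call. = FALSE)
    c(log2fc = "log2fc", padj = "padj")
  } else {
    cols <- paste0(c("log2fc_", "padj_"), contrast)
    if (!all(cols %in% names(expr)))
      stop("contrast not found in expression table: ", contrast,
           call. = FALSE)
    c(log2fc = cols[1], padj = cols[2])
  }
}

#' Filter differentially expressed genes
#'
#' A gene is a DEG when `padj <= alpha` and `|log2fc| >= min_abs_log2fc`;
#' both thresholds are inclusive. Up- and downregulated subsets are split by
#' the sign of log2FC.
#'
#' @param expr expression table.
#' @param contrast contrast name for multi-contrast tables; `NULL` for the
#'   plain `log2fc`/`padj` columns.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param min_abs_log2fc minimum absolute log2 fold change (default 0.5).
#' @return list of gene-id vectors `all`, `up`, `down`.
#' @export
filter_degs <- function(expr, contrast = NULL, alpha = 0.05,
                        min_abs_log2fc = 0.5) {
  cols <- contrast_cols(expr, contrast)
  lfc <- expr[[cols["log2fc"]]]
  padj <- expr[[cols["padj"]]]
  pass <- !is.na(padj) & !is.na(lfc) &
    padj <= alpha & abs(lfc) >= min_abs_log2fc
  list(all = expr$gene_id[pass],
       up = expr$gene_id[pass & lfc > 0],
       down = expr$gene_id[pass & lfc < 0])
}

#' Wilcoxon rank-sum test between two groups
#'
#' Exact enumeration p-value for small tie-free samples
#' (`min(n, m) <= 8`); otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param values_a,values_b numeric vectors, both non-empty.
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`.
#' @return list with `statistic` (rank-sum W of group a), `p_value`,
#'   `exact` flag.
#' @export
rank_sum_test <- function(values_a, values_b,
                          alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- min(length(values_a), length(values_b)) <= 8 && !ties
  ht <- suppressWarnings(stats::wilcox.test(
    values_a, values_b, alternative = sub("_", ".", alternative),
    exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       exact = exact)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped (standard Wilcoxon convention). Exact
#' enumeration over sign patterns for `n <= 15` tie-free inputs; normal
#' approximation with corrections otherwise.
#'
#' @param paired_diffs numeric vector of paired differences; at least one
#'   must be nonzero.
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`.
#' @return list with `statistic` (V), `p_value`, `exact` flag, `n_used`.
#' @export
signed_rank_test <- function(paired_diffs,
                             alternative = c("two_sided", "greater",
                                             "less")) {
  alternative <- match.arg(alternative)
  d <- paired_diffs[paired_diffs != 0]
  if (length(d) == 0L)
    stop("all paired differences are zero", call. = FALSE)
  ties <- anyDuplicated(abs(d)) > 0
  exact <- length(d) <= 15 && !ties
  ht <- suppressWarnings(stats::wilcox.test(
    d, mu = 0, alternative = sub("_", ".", alternative),
    exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       exact = exact, n_used = length(d))
}

#' Summarise a gene group's expression trajectory
#'
#' Each gene's timepoint profile is z-normalised across timepoints (a
#' constant gene maps to an all-zero trajectory), then the group mean and
#' standard deviation are reported per timepoint.
#'
#' @param tpm numeric matrix or data.frame, genes in rows (rownames =
#'   gene ids), timepoints in columns; at least two timepoints.
#' @param gene_group character vector of gene ids (non-empty; all present
#'   in `tpm`).
#' @return data.frame with `timepoint`, `mean`, `sd`, `n_genes`.
#' @export
trajectory_summary <- function(tpm, gene_group) {
  tpm <- as.matrix(tpm)
  if (ncol(tpm) < 2L) stop("need at least two timepoints", call. = FALSE)
  gene_group <- unique(as.character(gene_group))
  if (length(gene_group) == 0L) stop("empty gene group", call. = FALSE)
  if (!all(gene_group %in% rownames(tpm)))
    stop("gene group contains ids absent from the matrix", call. = FALSE)
  m <- tpm[gene_group, , drop = FALSE]
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sdv == 0, 1, sdv)
  z[sdv == 0, ] <- 0
  data.frame(timepoint = colnames(tpm),
             mean = colMeans(z),
             sd = apply(z, 2, stats::sd),
             n_genes = nrow(z),
             row.names = NULL)
}

#' Spike-in-normalised relative CUT&RUN signal
#'
#' For each sample and target amplicon, the signal is divided by the
#' sample's genomic-background signal, then by its exogenous spike-in
#' signal, and finally expressed relative to the control sample:
#' `fold = rel(sample) / rel(control)` with
#' `rel = (target / background) / spike_in`. The control sample's own fold
#' change is exactly 1. When a sample carries several background or
#' spike-in rows their geometric mean is used (ratio-scale data).
#'
#' @param table data.frame with columns `sample_id`, `amplicon_id`, `role`
#'   (one of `target`, `genomic_background`, `spike_in`) and `signal`
#'   (positive, linear scale).
#' @param control_sample sample id used as the reference.
#' @param input `"linear"` (default) or `"ct"`; Ct values are converted to
#'   linear signal as `2^(-Ct)` before the ratios.
#' @return data.frame with `sample_id`, `amplicon_id`, `rel_signal`,
#'   `fold_vs_control`.
#' @export
cutrun_relative_signal <- function(table, control_sample,
                                   input = c("linear", "ct")) {
  input <- match.arg(input)
  need <- c("sample_id", "amplicon_id", "role", "signal")
  if (!all(need %in% names(table)))
    stop("signal table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(table$role %in% c("target", "genomic_background", "spike_in")))
    stop("unknown role in signal table", call. = FALSE)
  sig <- if (input == "ct") 2^(-table$signal) else table$signal
  if (any(!is.finite(sig) | sig <= 0))
    stop("signals must be positive", call. = FALSE)
  table$signal <- sig
  if (!control_sample %in% table$sample_id)
    stop("control sample not present: ", control_sample, call. = FALSE)
  gmean <- function(x) exp(mean(log(x)))
  samples <- unique(table$sample_id)
  norm <- lapply(samples, function(s) {
    rows <- table[table$sample_id == s, ]
    bg <- rows$signal[rows$role == "genomic_background"]
    sp <- rows$signal[rows$role == "spike_in"]
    if (length(bg) == 0L)
      stop("sample ", s, " lacks a genomic_background row", call. = FALSE)
    if (length(sp) == 0L)
      stop("sample ", s, " lacks a spike_in row", call. = FALSE)
    tg <- rows[rows$role == "target", ]
    data.frame(sample_id = s, amplicon_id = tg$amplicon_id,
               rel_signal = (tg$signal / gmean(bg)) / gmean(sp),
               stringsAsFactors = FALSE)
  })
  norm <- do.call(rbind, norm)
  ctrl <- norm[norm$sample_id == control_sample, ]
  idx <- match(norm$amplicon_id, ctrl$amplicon_id)
  if (anyNA(idx))
    stop("amplicon missing from the control sample", call. = FALSE)
  norm$fold_vs_control <- norm$rel_signal / ctrl$rel_signal[idx]
  norm$fold_vs_control[norm$sample_id == control_sample] <- 1
  norm
}
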