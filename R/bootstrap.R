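#' Size-matched bootstrap null for a gene group's mean log2 fold change
#'
#' Compares the observed mean log2FC of a target gene group against the
#' distribution of mean log2FC over `B` random gene groups of the same
#' size, each drawn without replacement from the pool of detected genes
#' (draws are independent of each other). The empirical p-value uses the
#' add-one (permutation-style) correction, `(1 + #extreme) / (B + 1)`, so
#' it is never exactly zero, and is one-sided in the direction of the
#' observed mean by default.
#'
#' @param target_genes character vector of gene ids, a subset of the pool.
#' @param expr expression table: data.frame with `gene_id` and `log2fc`
#'   columns (see [read_expression()]). Genes with missing log2FC are
#'   dropped from pool and target with a warning.
#' @param B number of bootstrap draws (default 30000).
#' @param seed integer seed; identical inputs and seed give identical draws.
#' @param pool optional character vector restricting the sampling pool;
#'   defaults to all detected genes (targets included).
#' @param exclude_targets drop the target genes from the pool before
#'   sampling (default `FALSE`).
#' @param alternative `"auto"` (one-sided in the direction of the observed
#'   mean; default), `"greater"`, `"less"`, or `"two_sided"` (on `|mean|`).
#' @param label group label carried into the result.
#' @return object of class `bootstrap_result`: list with `label`,
#'   `group_size`, `observed_mean`, `null_means` (length `B`), `B`,
#'   `p_empirical`, `direction`, `seed`.
#' @export
bootstrap_effect_size <- function(target_genes, expr, B = 30000, seed = 1,
                                  pool = NULL, exclude_targets = FALSE,
                                  alternative = c("auto", "greater", "less",
                                                  "two_sided"),
                                  label = "target") {
  alternative <- match.arg(alternative)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  target_genes <- unique(as.character(target_genes))
  if (length(target_genes) == 0L)
    stop("empty target gene set", call. = FALSE)
  lfc <- stats::setNames(expr$log2fc, expr$gene_id)
  if (anyNA(lfc)) {
    warning(sum(is.na(lfc)), " genes with missing log2FC excluded")
    lfc <- lfc[!is.na(lfc)]
  }
  if (is.null(pool)) pool <- names(lfc)
  pool <- unique(as.character(pool))
  if (!all(pool %in% names(lfc)))
    stop("pool contains genes absent from the expression table",
         call. = FALSE)
  if (!all(target_genes %in% pool))
    stop("target genes must be a subset of the sampling pool",
         call. = FALSE)
  obs <- mean(lfc[target_genes])
  if (exclude_targets) pool <- setdiff(pool, target_genes)
  v <- unname(lfc[pool])
  np <- length(v)
  k <- length(target_genes)
  if (np < k) stop("pool smaller than the target group", call. = FALSE)
  null_means <- withr::with_seed(seed,
    vapply(seq_len(B), function(i) mean(v[sample.int(np, k)]), numeric(1)))
  direction <- if (alternative == "auto") {
    if (obs >= 0) "greater" else "less"
  } else alternative
  n_extreme <- switch(direction,
                      greater = sum(null_means >= obs),
                      less = sum(null_means <= obs),
                      two_sided = sum(abs(null_means) >= abs(obs)))
  structure(list(label = label, group_size = k, observed_mean = obs,
                 null_means = null_means, B = B,
                 p_empirical = (1 + n_extreme) / (B + 1),
                 direction = direction, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "Bootstrap (%s): n = %d genes, observed mean log2FC = %.3f\n",
    x$label, x$group_size, x$observed_mean))
  cat(sprintf("  B = %d draws, one-sided (%s) empirical p = %.3g\n",
              x$B, x$direction, x$p_empirical))
  invisible(x)
}

#' Exact tail probability by exhaustive enumeration
#'
#' Enumerates every possible size-matched gene group (all combinations of
#' the pool of the target-group size) and returns the fraction of draws
#' whose mean log2FC is at least as extreme as the observed mean, in the
#' observed direction. The sampler's empirical p converges to this value as
#' the number of draws grows; it is the oracle mode for small pools.
#'
#' @inheritParams bootstrap_effect_size
#' @param max_combinations guard on `choose(|pool|, |target|)` (default 1e6).
#' @return list with `tail` (exact probability), `n_extreme`,
#'   `n_total = choose(|pool|, |target|)`, `observed_mean`, `direction`.
#' @export
bootstrap_exact <- function(target_genes, expr, pool = NULL,
                            alternative = c("auto", "greater", "less"),
                            max_combinations = 1e6) {
  alternative <- match.arg(alternative)
  target_genes <- unique(as.character(target_genes))
  if (length(target_genes) == 0L)
    stop("empty target gene set", call. = FALSE)
  lfc <- stats::setNames(expr$log2fc, expr$gene_id)
  lfc <- lfc[!is.na(lfc)]
  if (is.null(pool)) pool <- names(lfc)
  pool <- unique(as.character(pool))
  if (!all(target_genes %in% pool))
    stop("target genes must be a subset of the sampling pool",
         call. = FALSE)
  v <- unname(lfc[pool])
  np <- length(v)
  k <- length(target_genes)
  total <- choose(np, k)
  if (total > max_combinations)
    stop("choose(", np, ", ", k, ") exceeds the enumeration bound",
         call. = FALSE)
  obs <- mean(lfc[target_genes])
  means <- colMeans(matrix(v[utils::combn(np, k)], nrow = k))
  direction <- if (alternative == "auto") {
    if (obs >= 0) "greater" else "less"
  } else alternative
  n_extreme <- if (direction == "greater") sum(means >= obs)
               else sum(means <= obs)
  list(tail = n_extreme / total, n_extreme = n_extreme, n_total = total,
       observed_mean = obs, direction = direction)
}

#' Bootstrap several target groups against a shared pool
#'
#' Runs [bootstrap_effect_size()] for each group with the group's own
#' matched size, a shared sampling pool, and per-group seeds derived
#' deterministically from `seed`.
#'
#' @param groups named list of gene-id vectors (names are group labels;
#'   duplicates are an error). A `target_groups` object is accepted.
#' @inheritParams bootstrap_effect_size
#' @return data.frame (one row per group, ranked by `|observed_mean|`
#'   descending) with columns `label`, `size`, `observed_mean`,
#'   `p_empirical`, `direction`, `B`, `seed`, `rank`; full
#'   `bootstrap_result` objects in the `results` attribute.
#' @export
compare_target_groups <- function(groups, expr, B = 30000, seed = 1,
                                  pool = NULL, exclude_targets = FALSE,
                                  alternative = "auto") {
  if (inherits(groups, "target_groups")) {
    lab <- groups$labels
    groups <- list(groups$cond1_specific, groups$cond2_specific,
                   groups$shared)
    names(groups) <- c(paste0(lab[1], "_specific"),
                       paste0(lab[2], "_specific"), "shared")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named", call. = FALSE)
  if (anyDuplicated(names(groups)))
    stop("duplicate group labels", call. = FALSE)
  res <- lapply(seq_along(groups), function(i)
    bootstrap_effect_size(groups[[i]], expr, B = B, seed = seed + i,
                          pool = pool, exclude_targets = exclude_targets,
                          alternative = alternative,
                          label = names(groups)[i]))
  tab <- do.call(rbind, lapply(res, function(r)
    data.frame(label = r$label, size = r$group_size,
               observed_mean = r$observed_mean,
               p_empirical = r$p_empirical, direction = r$direction,
               B = r$B, seed = r$seed, stringsAsFactors = FALSE)))
  tab$rank <- rank(-abs(tab$observed_mean), ties.method = "first")
  attr(tab, "results") <- res
  tab
}
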