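# Brute-force oracles and fixture builders. Everything here is written
# independently of the package's interval/statistics code paths: oracles
# work on plain 0-based half-open data frames and enumerate exhaustively.

# random 0-based half-open intervals on a toy genome
rand_intervals <- function(n, glen = 10000, max_w = 400) {
  w <- sample.int(max_w, n, replace = TRUE)
  s <- vapply(w, function(wi) sample.int(glen - wi, 1) - 1L, 0L)
  data.frame(chrom = "chr1", start = s, end = s + w)
}

df_to_gr <- function(df, label = NULL) {
  region_set(df$chrom, df$start, df$end, label = label)
}

gr_to_df <- function(gr) {
  as_bed_df(gr)[, c("chrom", "start", "end")]
}

# per-base coverage oracle: which bases of [0, glen) are covered
oracle_coverage <- function(df, glen) {
  cov <- logical(glen)
  for (i in seq_len(nrow(df)))
    cov[(df$start[i] + 1):df$end[i]] <- TRUE
  cov
}

# O(n^2) all-pairs overlap oracle on one chromosome
oracle_pairs <- function(a, b, min_bp = 1, min_frac = 0, side = "a") {
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov < min_bp) next
    fa <- ov / (a$end[i] - a$start[i])
    fb <- ov / (b$end[j] - b$start[j])
    keep <- switch(side, a = fa >= min_frac, b = fb >= min_frac,
                   both = fa >= min_frac && fb >= min_frac)
    if (keep) out <- rbind(out, data.frame(query = i, subject = j,
                                           overlap_bp = ov))
  }
  out
}

# exact upper-tail hypergeometric by combinatorial enumeration; for N <= 30
# all binomial coefficients and their products stay below 2^53, so double
# arithmetic is exact
oracle_hyper_upper <- function(N, K, n, k) {
  if (k == 0) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# nearest-TSS oracle: all-pairs scan with the stated tie rule
oracle_nearest <- function(peak_start0, peak_end0, genes_chr) {
  s1 <- peak_start0 + 1; e1 <- peak_end0
  tss1 <- genes_chr$tss + 1
  # positive = peak genomically right of (downstream of, on +) the TSS
  d_gen <- ifelse(tss1 >= s1 & tss1 <= e1, 0,
                  ifelse(tss1 < s1, s1 - tss1, -(tss1 - e1)))
  best <- min(abs(d_gen))
  cand <- which(abs(d_gen) == best)
  win <- cand[order(genes_chr$gene_id[cand])[1]]
  d <- d_gen[win]
  if (genes_chr$strand[win] == "-") d <- -d
  list(gene_id = genes_chr$gene_id[win], distance = d)
}

# exact two-sided / one-sided rank-sum p by enumerating all C(n+m, n)
# assignments of ranks to group a (tie-free inputs only)
oracle_rank_sum_p <- function(a, b, alternative = "two_sided") {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n)])
  combs <- utils::combn(n + m, n)
  w_all <- colSums(matrix(seq_len(n + m)[combs], nrow = n))
  lower <- mean(w_all <= w_obs)
  upper <- mean(w_all >= w_obs)
  switch(alternative,
         greater = upper,
         less = lower,
         two_sided = min(1, 2 * min(lower, upper)))
}

# exact signed-rank p by enumerating all 2^n sign patterns
oracle_signed_rank_p <- function(d, alternative = "two_sided") {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  lower <- mean(v_all <= v_obs)
  upper <- mean(v_all >= v_obs)
  switch(alternative,
         greater = upper,
         less = lower,
         two_sided = min(1, 2 * min(lower, upper)))
}

# two-sample qPCR signal fixture for the CUT&RUN normalisation
cutrun_fixture <- function() {
  rbind(
    data.frame(sample_id = "ctrl", amplicon_id = c("e1", "e2", "bg", "spk"),
               role = c("target", "target", "genomic_background", "spike_in"),
               signal = c(4, 6, 2, 1)),
    data.frame(sample_id = "kd", amplicon_id = c("e1", "e2", "bg", "spk"),
               role = c("target", "target", "genomic_background", "spike_in"),
               signal = c(8, 6, 2, 2)))
}

# small expression table fixture
expr_table <- function(ids, lfc, padj = rep(0.5, length(ids))) {
  data.frame(gene_id = ids, log2fc = lfc, padj = padj,
             stringsAsFactors = FALSE)
}
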