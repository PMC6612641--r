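## Correlation-network node statistics (hub degree) on the age transcripts,
## with a seeded permutation null for edge FDR, and monozygotic-twin
## intraclass-correlation heritability contrasts between protein-coding and
## noncoding biotypes.

#' Permutation-thresholded Spearman co-expression network
#'
#' Computes all pairwise Spearman correlations between transcripts and
#' retains an edge iff its permutation-based BH q-value is at most
#' `fdr_max`. The null is built by permuting sample labels independently per
#' permutation (seeded); for tie-free data the permutation distribution of
#' Spearman's rho depends only on the sample count, so one pooled null of
#' `n_permutations` draws serves every pair. Permutation p-values are the
#' plug-in proportion `#(|null| >= |rho|) / n_permutations` (and may be
#' exactly zero when the observed correlation exceeds every null draw).
#'
#' @param expr transcripts x samples matrix, restricted to the transcripts
#'   of interest (>= 10 transcripts, >= 20 samples).
#' @param fdr_max BH q threshold on edges (default 0.01).
#' @param n_permutations permutation count (>= 100; default 10000).
#' @param seed integer seed for the permutation null.
#' @param biotype optional named character vector (transcript -> biotype)
#'   copied onto the node table.
#' @return list: `edges` (a, b, rho, p_value, q_value), `nodes`
#'   (`NetworkNodeStats`: transcript_id, degree, hub_rank, biotype).
#' @export
correlation_network <- function(expr, fdr_max = 0.01, n_permutations = 10000L,
                                seed = 1L, biotype = NULL) {
  if (nrow(expr) < 10) abort_input("network building needs >= 10 transcripts")
  if (ncol(expr) < 20) abort_input("network building needs >= 20 samples")
  if (n_permutations < 100)
    abort_input("n_permutations must be >= 100 (null too coarse)")

  n_s <- ncol(expr)
  ranks <- t(apply(expr, 1L, rank))
  rho_mat <- stats::cor(t(ranks))

  set.seed(derive_seed(seed, 17L))
  base <- seq_len(n_s)
  null_rho <- vapply(seq_len(n_permutations), function(b) {
    stats::cor(base, sample(base))
  }, numeric(1))
  null_abs <- sort(abs(null_rho))

  ut <- which(upper.tri(rho_mat), arr.ind = TRUE)
  rho <- rho_mat[ut]
  ## p = fraction of null |rho| >= observed |rho| (plug-in proportion)
  exceed <- n_permutations - findInterval(abs(rho) - 1e-12, null_abs)
  p <- exceed / n_permutations
  q <- bh_adjust(p)
  keep <- q <= fdr_max
  edges <- data.frame(a = rownames(expr)[ut[, 1]],
                      b = rownames(expr)[ut[, 2]],
                      rho = rho, p_value = p, q_value = q,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(edges) <- NULL

  degree <- setNames(integer(nrow(expr)), rownames(expr))
  if (nrow(edges) > 0) {
    tab <- table(c(edges$a, edges$b))
    degree[names(tab)] <- as.integer(tab)
  }
  nodes <- data.frame(transcript_id = names(degree),
                      degree = as.integer(degree),
                      hub_rank = rank(-degree, ties.method = "average"),
                      biotype = if (is.null(biotype)) NA_character_
                                else unname(biotype[names(degree)]),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  list(edges = edges, nodes = nodes)
}

#' Compare node degree between coding and noncoding transcripts
#'
#' Two-sided Wilcoxon rank-sum comparison of the degree distributions of
#' protein-coding vs noncoding nodes.
#'
#' @param nodes `NetworkNodeStats` data.frame with a `biotype` column.
#' @return list: p_value, statistic, median_degree_coding,
#'   median_degree_noncoding, n_coding, n_noncoding.
#' @export
compare_node_stats <- function(nodes) {
  coding <- nodes$degree[nodes$biotype == "protein_coding"]
  noncoding <- nodes$degree[!is.na(nodes$biotype) & nodes$biotype != "protein_coding"]
  if (length(coding) == 0 || length(noncoding) == 0)
    abort_input("both biotype groups must be nonempty")
  if (length(coding) == 1 && length(noncoding) == 1) {
    warning("single node per group; rank-sum test degenerate, p = 1")
    return(list(p_value = 1, statistic = NA_real_,
                median_degree_coding = coding, median_degree_noncoding = noncoding,
                n_coding = 1L, n_noncoding = 1L))
  }
  wt <- stats::wilcox.test(coding, noncoding, exact = FALSE)
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       median_degree_coding = stats::median(coding),
       median_degree_noncoding = stats::median(noncoding),
       n_coding = length(coding), n_noncoding = length(noncoding))
}

#' Per-gene one-way intraclass correlation over twin pairs
#'
#' ICC(1,1) with k = 2 members per pair: `(MSB - MSW) / (MSB + MSW)` from
#' the one-way ANOVA decomposition over pairs. Incomplete pairs are dropped
#' with a warning; genes are omitted when fewer than 3 complete pairs
#' remain.
#'
#' @param twin_expr genes x samples matrix.
#' @param pair_map data.frame with `sample_id` and `pair_id`.
#' @param biotype optional named character vector (gene -> biotype).
#' @return data.frame (`ICCResult`): gene_id, icc, biotype.
#' @export
icc_per_gene <- function(twin_expr, pair_map, biotype = NULL) {
  idx <- match(colnames(twin_expr), pair_map$sample_id)
  if (anyNA(idx)) abort_input("pair map must cover every twin sample")
  pid <- pair_map$pair_id[idx]
  sizes <- table(pid)
  complete <- names(sizes)[sizes == 2]
  if (length(complete) < length(sizes))
    warning("dropping ", length(sizes) - length(complete), " incomplete pair(s)")
  if (length(complete) < 3)
    abort_input("fewer than 3 complete twin pairs")
  keep <- pid %in% complete
  x <- twin_expr[, keep, drop = FALSE]
  pid <- pid[keep]
  ord <- order(pid)
  x <- x[, ord, drop = FALSE]
  n_pairs <- length(complete)

  m1 <- x[, seq(1, 2 * n_pairs, by = 2), drop = FALSE]
  m2 <- x[, seq(2, 2 * n_pairs, by = 2), drop = FALSE]
  pm <- (m1 + m2) / 2
  gm <- rowMeans(x)
  msb <- 2 * rowSums((pm - gm)^2) / (n_pairs - 1)
  msw <- rowSums((m1 - pm)^2 + (m2 - pm)^2) / n_pairs
  icc <- (msb - msw) / (msb + msw)
  data.frame(gene_id = rownames(x),
             icc = icc,
             biotype = if (is.null(biotype)) NA_character_
                       else unname(biotype[rownames(x)]),
             stringsAsFactors = FALSE)
}

#' Contrast heritability between noncoding and coding genes
#'
#' Mean ICC difference (noncoding minus coding; negative means noncoding
#' genes are less heritable), a seeded percentile bootstrap 95% CI, and a
#' two-sided Welch t-test p-value. Requires at least `min_genes` genes per
#' class.
#'
#' @param icc `ICCResult` data.frame with a `biotype` column.
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed for the bootstrap.
#' @param min_genes minimum genes per biotype class (default 20).
#' @return list: mean_difference, ci_lower, ci_upper, p_value,
#'   mean_icc_coding, mean_icc_noncoding, n_coding, n_noncoding.
#' @export
compare_heritability <- function(icc, n_boot = 10000L, seed = 1L,
                                 min_genes = 20L) {
  coding <- icc$icc[icc$biotype == "protein_coding"]
  noncoding <- icc$icc[!is.na(icc$biotype) & icc$biotype != "protein_coding"]
  if (length(coding) < min_genes || length(noncoding) < min_genes)
    abort_input("need >= ", min_genes, " genes per biotype class")
  diff_obs <- mean(noncoding) - mean(coding)
  set.seed(derive_seed(seed, 18L))
  boots <- vapply(seq_len(n_boot), function(b) {
    mean(sample(noncoding, replace = TRUE)) - mean(sample(coding, replace = TRUE))
  }, numeric(1))
  ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
  p <- if (isTRUE(all.equal(stats::var(coding), 0)) &&
           isTRUE(all.equal(stats::var(noncoding), 0)) &&
           isTRUE(all.equal(diff_obs, 0))) 1
       else stats::t.test(noncoding, coding)$p.value
  list(mean_difference = diff_obs, ci_lower = ci[1], ci_upper = ci[2],
       p_value = p,
       mean_icc_coding = mean(coding), mean_icc_noncoding = mean(noncoding),
       n_coding = length(coding), n_noncoding = length(noncoding))
}
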