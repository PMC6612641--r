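## Connectivity-map style screening. A bidirectional query signature
## (up-genes / down-genes) is matched against compound reference rankings
## with a Kolmogorov-Smirnov running-sum statistic, normalized so that a
## perfect construction attains the printed scale endpoints of -100/100
## exactly, plus hypergeometric compound-class enrichment among hits.

#' Normalized KS enrichment statistic of a gene set in a ranking
#'
#' With the t set members at ranking positions V(1) < ... < V(t) of n, the
#' raw running-sum statistic is `a = max_j(j/t - V(j)/n)` if it exceeds
#' `b = max_j(V(j)/n - (j-1)/t)`, else `-b`. The raw value is divided by its
#' maximum attainable magnitude for (t, n) — `(n - t)/n` for positive,
#' `(n - t + 1)/n` for negative — so perfect top placement returns exactly
#' +1 and perfect bottom placement exactly -1.
#'
#' @param gene_set character vector, a strict nonempty subset of `ranking`.
#' @param ranking character vector: a total order over the gene universe.
#' @return normalized enrichment statistic in \[-1, 1\].
#' @export
enrichment_statistic <- function(gene_set, ranking) {
  n <- length(ranking)
  v <- match(gene_set, ranking)
  if (anyNA(v)) abort_input("gene set contains genes absent from the ranking")
  t <- length(v)
  if (t == 0 || t >= n)
    abort_input("gene set must be a nonempty strict subset of the ranking")
  v <- sort(v)
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a > b) a / ((n - t) / n) else -b / ((n - t + 1) / n)
}

#' Bidirectional connectivity score of a query against one ranking
#'
#' `score = 100 * (es_up - es_down) / 2` when the two enrichment statistics
#' have opposite signs, else 0 (the classic connectivity-map convention: a
#' compound that moves both halves of the query the same way is a non-match).
#'
#' @param query list with disjoint nonempty `up_genes` and `down_genes`.
#' @param ranking character vector: total order over the gene universe.
#' @return list (`ConnectivityResult`): es_up, es_down, score in
#'   \[-100, 100\].
#' @export
connectivity_score <- function(query, ranking) {
  if (length(intersect(query$up_genes, query$down_genes)) > 0)
    abort_input("up and down gene sets must be disjoint")
  es_up <- enrichment_statistic(query$up_genes, ranking)
  es_down <- enrichment_statistic(query$down_genes, ranking)
  score <- if (es_up * es_down > 0) 0 else 100 * (es_up - es_down) / 2
  list(es_up = es_up, es_down = es_down, score = score)
}

#' Screen a compound library against a query signature
#'
#' Scores every compound, splits hits (`|score| >= hit_threshold`) by sign,
#' and tests each compound class for one-sided hypergeometric enrichment
#' among the positive hits and, separately, the negative hits, BH-adjusted
#' across classes.
#'
#' @param query list with `up_genes` and `down_genes`.
#' @param library list as returned by [generate_compound_library()]:
#'   `rankings` (named list of permutations of a shared universe) and a
#'   table with `compound_id` and a class column.
#' @param hit_threshold absolute score defining a hit (default 90).
#' @param class_field column of `library$truth` giving the compound class.
#' @return list: `scores` (compound_id, class, es_up, es_down, score, hit),
#'   `enrichment` (class, direction, hits_in_class, class_size, p_value,
#'   q_value).
#' @export
screen_library <- function(query, library, hit_threshold = 90,
                           class_field = "compound_class") {
  rankings <- library$rankings
  universe <- sort(rankings[[1]])
  bad <- names(rankings)[!vapply(rankings, function(r) {
    length(r) == length(universe) && identical(sort(r), universe)
  }, logical(1))]
  if (length(bad) > 0)
    abort_input("compounds with inconsistent universes: ",
                paste(bad, collapse = ", "))

  res <- lapply(rankings, connectivity_score, query = query)
  scores <- data.frame(
    compound_id = names(rankings),
    class = library$truth[[class_field]][match(names(rankings),
                                               library$truth$compound_id)],
    es_up = vapply(res, `[[`, numeric(1), "es_up"),
    es_down = vapply(res, `[[`, numeric(1), "es_down"),
    score = vapply(res, `[[`, numeric(1), "score"),
    stringsAsFactors = FALSE)
  scores$hit <- ifelse(scores$score >= hit_threshold, "positive",
                       ifelse(scores$score <= -hit_threshold, "negative", "none"))

  enr <- do.call(rbind, lapply(c("positive", "negative"), function(dir) {
    hits <- scores$compound_id[scores$hit == dir]
    do.call(rbind, lapply(unique(scores$class), function(cl) {
      members <- scores$compound_id[scores$class == cl]
      k <- length(intersect(hits, members))
      data.frame(class = cl, direction = dir,
                 hits_in_class = k, class_size = length(members),
                 n_hits = length(hits),
                 p_value = hypergeom_tail(k, length(members),
                                          nrow(scores), length(hits)),
                 stringsAsFactors = FALSE)
    }))
  }))
  enr$q_value <- stats::ave(enr$p_value, enr$direction, FUN = bh_adjust)
  rownames(scores) <- rownames(enr) <- NULL
  list(scores = scores, enrichment = enr)
}

#' One-sided hypergeometric enrichment p-value
#'
#' `P(X >= k)` for the overlap between a class of size `K` and `h` hits
#' drawn from a library of size `N`.
#'
#' @param k observed overlap.
#' @param K class size.
#' @param N library size.
#' @param h number of hits.
#' @return upper-tail probability.
#' @export
hypergeom_tail <- function(k, K, N, h) {
  stats::phyper(k - 1, K, N - K, h, lower.tail = FALSE)
}
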