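## Covariate-adjusted, windowed age-association scanning with BH FDR and
## cross-cohort consistency. The adjustment is residualize-then-rank-
## correlate: expression is residualized on the clinical covariates
## (aerobic capacity, insulin sensitivity) by least squares, then Spearman
## correlated with age inside an explicit age window.

#' Residualize expression on clinical covariates
#'
#' Per transcript, returns the residuals of the least-squares fit of
#' expression on an intercept plus the named covariates (age excluded), so
#' residuals have zero mean per transcript. Constant covariates are dropped
#' with a warning; a rank-deficient design is an error naming the collinear
#' columns.
#'
#' @param expr transcripts x samples log2 matrix.
#' @param metadata data.frame with one row per sample, aligned to the
#'   columns of `expr` via its `sample_id` column.
#' @param covariates character vector of metadata column names (may be empty,
#'   giving per-transcript mean centering).
#' @return residual matrix, same dimensions as `expr`.
#' @export
adjust_covariates <- function(expr, metadata,
                              covariates = c("vo2max", "insulin_sensitivity")) {
  ord <- match(colnames(expr), metadata$sample_id)
  if (anyNA(ord)) abort_input("metadata must cover every expression column")
  metadata <- metadata[ord, , drop = FALSE]
  if (anyNA(expr)) abort_input("expression matrix contains missing values")
  qrX <- covariate_design(metadata, covariates)
  t(qr.resid(qrX, t(expr)))
}

## QR of the intercept + covariates design, with validation. Shared by
## expression and age residualization so both sides use the same projection.
covariate_design <- function(metadata, covariates) {
  missing <- setdiff(covariates, colnames(metadata))
  if (length(missing) > 0)
    abort_input("covariates absent from metadata: ", paste(missing, collapse = ", "))
  keep <- covariates[vapply(covariates, function(v) {
    ok <- stats::sd(metadata[[v]]) > 0
    if (!ok) warning("dropping constant covariate: ", v)
    ok
  }, logical(1))]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(metadata[, keep, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    abort_input("rank-deficient covariate design; collinear columns: ",
                paste(bad, collapse = ", "))
  }
  qrX
}

#' Covariate-adjusted (partial Spearman) windowed age scan
#'
#' The full adjusted scan for one cohort: samples are restricted to the age
#' window, then both expression and age are residualized on the intercept +
#' covariate design estimated from the in-window samples, and the
#' residual-residual Spearman correlation is computed — a partial Spearman.
#' Residualizing the age side as well keeps null p-values calibrated and
#' avoids attenuating true age signals when covariates are confounded with
#' age (residualizing expression alone deflates both).
#'
#' @param expr transcripts x samples log2 matrix.
#' @param metadata data.frame with `sample_id`, `age` and the covariates.
#' @param window numeric `c(age_min, age_max)`.
#' @param covariates covariate column names (may be empty).
#' @param cohort_id label copied into the result.
#' @return `AgeAssociationResult` data.frame as from [age_scan()].
#' @export
covariate_adjusted_scan <- function(expr, metadata, window,
                                    covariates = c("vo2max", "insulin_sensitivity"),
                                    cohort_id = "cohort_1") {
  ord <- match(colnames(expr), metadata$sample_id)
  if (anyNA(ord)) abort_input("metadata must cover every expression column")
  metadata <- metadata[ord, , drop = FALSE]
  inw <- metadata$age >= window[1] & metadata$age <= window[2]
  if (sum(inw) < 10)
    abort_input("age window [", window[1], ", ", window[2], "] holds ",
                sum(inw), " samples; at least 10 are required")
  meta_w <- metadata[inw, , drop = FALSE]
  resid <- adjust_covariates(expr[, inw, drop = FALSE], meta_w, covariates)
  qrX <- suppressWarnings(covariate_design(meta_w, covariates))
  age_res <- as.numeric(qr.resid(qrX, meta_w$age))
  age_scan(resid, meta_w$age, window, cohort_id = cohort_id,
           correlate_with = age_res)
}

#' Windowed Spearman age-association scan
#'
#' Spearman rho (ties mid-ranked) and two-sided p per transcript using only
#' samples whose age lies inside the closed window, with BH q-values across
#' all scanned transcripts.
#'
#' @param residuals transcripts x samples matrix (typically from
#'   [adjust_covariates()]).
#' @param ages numeric vector aligned to the columns of `residuals`.
#' @param window numeric `c(age_min, age_max)`; at least 10 in-window
#'   samples are required.
#' @param cohort_id label copied into the result.
#' @param correlate_with optional numeric vector used in place of `ages` for
#'   the correlation itself (window membership is always judged on `ages`);
#'   used by [covariate_adjusted_scan()] to pass covariate-residualized ages.
#' @return data.frame (`AgeAssociationResult`): transcript_id, cohort_id,
#'   rho, p_value, q_value, n.
#' @export
age_scan <- function(residuals, ages, window, cohort_id = "cohort_1",
                     correlate_with = NULL) {
  stopifnot(length(ages) == ncol(residuals))
  inw <- ages >= window[1] & ages <= window[2]
  n <- sum(inw)
  if (n < 10)
    abort_input("age window [", window[1], ", ", window[2], "] holds ", n,
                " samples; at least 10 are required")
  target <- if (is.null(correlate_with)) ages else correlate_with
  stopifnot(length(target) == length(ages))
  rho <- row_spearman(residuals[, inw, drop = FALSE], target[inw])
  p <- spearman_p(rho, n)
  data.frame(transcript_id = rownames(residuals),
             cohort_id = cohort_id,
             rho = rho,
             p_value = p,
             q_value = bh_adjust(p),
             n = n,
             stringsAsFactors = FALSE)
}

#' Cross-cohort consistent age signature
#'
#' A transcript enters the signature iff its rho has the same sign in every
#' cohort where it was scanned, it was scanned in at least `min_cohorts`
#' cohorts (default: all), and the arithmetic mean of its per-cohort BH
#' q-values is at most `max_mean_q`.
#'
#' @param results list of per-cohort [age_scan()] data.frames (>= 2 cohorts).
#' @param max_mean_q signature threshold on the mean q-value.
#' @param min_cohorts minimum number of cohorts a transcript must be scanned
#'   in; defaults to all supplied cohorts.
#' @return data.frame (`AgeSignature`): transcript_id, direction, mean_rho,
#'   mean_q, n_cohorts_consistent.
#' @export
cross_cohort_signature <- function(results, max_mean_q = 0.03,
                                   min_cohorts = length(results)) {
  if (length(results) < 2) abort_input("at least 2 cohorts are required")
  all_res <- do.call(rbind, results)
  by_t <- split(all_res, all_res$transcript_id)
  rows <- lapply(by_t, function(d) {
    if (nrow(d) < min_cohorts) return(NULL)
    signs <- sign(d$rho)
    if (any(signs == 0) || length(unique(signs)) != 1) return(NULL)
    mq <- mean(d$q_value)
    if (mq > max_mean_q) return(NULL)
    data.frame(transcript_id = d$transcript_id[1],
               direction = as.integer(signs[1]),
               mean_rho = mean(d$rho),
               mean_q = mq,
               n_cohorts_consistent = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(transcript_id = character(0), direction = integer(0),
                      mean_rho = numeric(0), mean_q = numeric(0),
                      n_cohorts_consistent = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
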