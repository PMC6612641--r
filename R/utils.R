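`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
abort_config <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("ageswitch_config_error", "error", "condition")))
}

#' @keywords internal
abort_input <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("ageswitch_input_error", "error", "condition")))
}

#' Derive a per-stage sub-seed from a global seed
#'
#' Deterministic mixing keeps one user-facing seed while giving every
#' stochastic stage an independent stream. Kept below 2^31 so the result is
#' always a valid R integer seed.
#'
#' @param seed integer global seed.
#' @param offset integer stage index (>= 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) * 1009 + 97 * as.numeric(offset)) %% 2147483647)
}

#' Benjamini-Hochberg q-values
#'
#' Thin wrapper over [stats::p.adjust()] so the adjustment used across the
#' package is named once.
#'
#' @param p numeric vector of p-values.
#' @return numeric vector of BH q-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

## Spearman rho of each row of a matrix against one vector, with ties
## mid-ranked. Rows with zero rank variance get rho = 0.
row_spearman <- function(mat, y) {
  ry <- rank(y)
  rm <- t(apply(mat, 1L, rank))
  ry <- ry - mean(ry)
  rm <- rm - rowMeans(rm)
  denom <- sqrt(rowSums(rm^2) * sum(ry^2))
  rho <- as.numeric(rm %*% ry) / denom
  rho[!is.finite(rho)] <- 0
  rho
}

## Two-sided p for a Spearman rho via the t approximation (the standard
## large-sample treatment, as used by cor.test in the presence of ties).
spearman_p <- function(rho, n) {
  rho <- pmin(1 - 1e-15, pmax(-1 + 1e-15, rho))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  pmax(p, .Machine$double.xmin)
}

## Piecewise-linear age trajectory with a single knot: slope1 applies from
## `origin` up to the knot, slope2 beyond it. Continuous at the knot.
piecewise_age_term <- function(age, slope1, slope2, knot = 55, origin = 20) {
  slope1 * (pmin(age, knot) - origin) + slope2 * pmax(age - knot, 0)
}
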