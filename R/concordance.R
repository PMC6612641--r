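## Cross-tissue direction concordance of an age signature: the replication
## logic that asks what fraction of signature transcripts move in the same
## direction with age in a second tissue, against an exact binomial null of
## one half.

#' Direction concordance of an age signature in another tissue
#'
#' A shared transcript counts as consistent iff the sign of its rho in the
#' other tissue equals the signature direction and `|rho| >= min_abs_rho`
#' (default 0: sign-only agreement). Transcripts absent from the other
#' tissue's results are excluded from `n_tested`. The p-value is the exact
#' two-sided binomial test of `n_consistent` out of `n_tested` at 0.5.
#'
#' @param signature `AgeSignature` data.frame.
#' @param other_results `AgeAssociationResult` data.frame for the second
#'   tissue.
#' @param min_abs_rho magnitude filter applied in the second tissue.
#' @return list (`ConcordanceReport`): n_tested, n_consistent, fraction,
#'   p_value; `fraction` and `p_value` are NA (flagged) when the
#'   intersection is empty.
#' @export
direction_concordance <- function(signature, other_results, min_abs_rho = 0) {
  idx <- match(signature$transcript_id, other_results$transcript_id)
  rho <- other_results$rho[idx]
  tested <- !is.na(rho)
  n_tested <- sum(tested)
  if (n_tested == 0) {
    warning("no shared transcripts between signature and second tissue")
    return(list(n_tested = 0L, n_consistent = 0L,
                fraction = NA_real_, p_value = NA_real_))
  }
  consistent <- tested & sign(rho) == signature$direction & abs(rho) >= min_abs_rho
  n_consistent <- sum(consistent)
  list(n_tested = n_tested,
       n_consistent = n_consistent,
       fraction = n_consistent / n_tested,
       p_value = stats::binom.test(n_consistent, n_tested, p = 0.5)$p.value)
}
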