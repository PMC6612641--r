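## Group 1 / Group 2 switch classification of the age signature from the
## second age window, per-decade coefficient-of-variation stochasticity
## controls, and housekeeping-gene detection.

#' Classify signature transcripts into Group 1 / Group 2
#'
#' Operationalizes the trajectory "switch": a signature transcript is GROUP2
#' when its window-2 correlation with age is close to zero
#' (`|rho_w2| <= zero_band`), GROUP1 when the window-2 correlation keeps both
#' the magnitude (`|rho_w2| >= keep_min`) and the sign of the window-1
#' association, and UNCLASSIFIED otherwise (including transcripts missing
#' from the window-2 scan).
#'
#' @param signature `AgeSignature` data.frame from
#'   [cross_cohort_signature()].
#' @param window2_results `AgeAssociationResult` data.frame from the
#'   window-2 [age_scan()].
#' @param zero_band GROUP2 band on `|rho_w2|` (must be < `keep_min`).
#' @param keep_min GROUP1 minimum on `|rho_w2|`.
#' @return data.frame (`SwitchClassification`): transcript_id, rho_w1,
#'   rho_w2, group.
#' @export
classify_switch <- function(signature, window2_results,
                            zero_band = 0.1, keep_min = 0.2) {
  if (zero_band >= keep_min) abort_config("zero_band must be < keep_min")
  idx <- match(signature$transcript_id, window2_results$transcript_id)
  rho2 <- window2_results$rho[idx]
  group <- rep("UNCLASSIFIED", nrow(signature))
  has <- !is.na(rho2)
  group[has & abs(rho2) <= zero_band] <- "GROUP2"
  group[has & abs(rho2) >= keep_min &
          sign(rho2) == signature$direction] <- "GROUP1"
  data.frame(transcript_id = signature$transcript_id,
             rho_w1 = signature$mean_rho,
             rho_w2 = rho2,
             group = group,
             stringsAsFactors = FALSE)
}

decade_label <- function(age) sprintf("%ds", (age %/% 10) * 10)

#' Per-decade coefficient of variation and group contrast
#'
#' The CV is computed on the linear scale (`2^expression`) within left-closed
#' decade bins (\[20,30), \[30,40), ...); decades with fewer than
#' `min_samples` samples are omitted. When `groups` labels transcripts as
#' GROUP1/GROUP2, a per-decade two-sided rank-sum test compares the two
#' groups' CV values, BH-adjusted across decades.
#'
#' @param expr transcripts x samples log2 matrix.
#' @param ages numeric vector aligned to columns of `expr`.
#' @param groups optional named character vector (transcript_id -> group
#'   label) restricting the table and enabling the GROUP1 vs GROUP2 contrast.
#' @param min_samples minimum samples per reported decade (default 5).
#' @return list: `cv` (data.frame transcript_id, decade, cv, group) and
#'   `contrast` (data.frame decade, p_value, q_value, median_cv_group1,
#'   median_cv_group2; empty without both groups).
#' @export
decade_cv <- function(expr, ages, groups = NULL, min_samples = 5L) {
  stopifnot(length(ages) == ncol(expr))
  if (!is.null(groups)) {
    keep <- rownames(expr) %in% names(groups)
    expr <- expr[keep, , drop = FALSE]
  }
  dec <- decade_label(ages)
  counts <- table(dec)
  decades <- names(counts)[counts >= min_samples]
  if (length(decades) == 0) {
    warning("all decade bins hold fewer than ", min_samples, " samples")
    return(list(cv = data.frame(transcript_id = character(0), decade = character(0),
                                cv = numeric(0), group = character(0),
                                stringsAsFactors = FALSE),
                contrast = data.frame()))
  }
  lin <- 2^expr
  cv_tab <- do.call(rbind, lapply(sort(decades), function(d) {
    m <- lin[, dec == d, drop = FALSE]
    data.frame(transcript_id = rownames(expr),
               decade = d,
               cv = apply(m, 1L, stats::sd) / rowMeans(m),
               stringsAsFactors = FALSE)
  }))
  cv_tab$group <- if (is.null(groups)) NA_character_
                  else unname(groups[cv_tab$transcript_id])

  contrast <- data.frame()
  if (!is.null(groups) && all(c("GROUP1", "GROUP2") %in% groups)) {
    contrast <- do.call(rbind, lapply(sort(decades), function(d) {
      g1 <- cv_tab$cv[cv_tab$decade == d & cv_tab$group == "GROUP1"]
      g2 <- cv_tab$cv[cv_tab$decade == d & cv_tab$group == "GROUP2"]
      wt <- stats::wilcox.test(g1, g2, exact = FALSE)
      data.frame(decade = d, p_value = wt$p.value,
                 median_cv_group1 = stats::median(g1),
                 median_cv_group2 = stats::median(g2),
                 stringsAsFactors = FALSE)
    }))
    contrast$q_value <- bh_adjust(contrast$p_value)
  }
  list(cv = cv_tab, contrast = contrast)
}

#' Detect housekeeping transcripts across tissues
#'
#' A transcript is a housekeeping candidate iff its maximum decade CV is at
#' most `cv_max` in every supplied tissue; at least two tissues are required.
#'
#' @param cv_tables named list (one per tissue) of decade-CV data.frames as
#'   returned in `decade_cv()$cv`.
#' @param cv_max CV cap (linear scale, dimensionless).
#' @return character vector of housekeeping transcript ids.
#' @export
find_housekeeping <- function(cv_tables, cv_max = 0.05) {
  if (length(cv_tables) < 2)
    abort_input("housekeeping detection requires >= 2 tissues")
  per_tissue <- lapply(cv_tables, function(tab) {
    mx <- tapply(tab$cv, tab$transcript_id, max)
    names(mx)[mx <= cv_max]
  })
  Reduce(intersect, per_tissue)
}
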