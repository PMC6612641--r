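## Probe-level transcript quantification: exact 25-mer matching against the
## transcriptome, single-match filtering, per-sample GC-bin median
## adjustment, detection/variance filtering, and median-polish summarization
## into a transcript-by-sample log2 expression matrix. The pipeline order is
## fixed: match -> single-match filter -> GC adjust -> detection filter ->
## summarize, so multi-mapping probes can never influence a transcript
## signal.

#' Exact probe-to-transcript matching
#'
#' Counts, per probe, the number of distinct transcripts containing the probe
#' as an exact forward-strand substring (multiple hit positions within one
#' transcript count once). Probes containing ambiguous bases are flagged with
#' `match_count = 0` and a warning.
#'
#' @param probes named character vector of equal-length probe sequences
#'   (A/C/G/T).
#' @param sequences named character vector of transcript sequences.
#' @return data.frame (`ProbeMatchTable`): probe_id, sequence, gc_fraction,
#'   match_count, target_transcript (NA unless match_count == 1).
#' @export
match_probes <- function(probes, sequences) {
  if (is.null(names(probes))) names(probes) <- sprintf("probe_%d", seq_along(probes))
  widths <- nchar(probes)
  if (length(unique(widths)) != 1)
    abort_input("all probes must have equal length")
  clean <- grepl("^[ACGT]+$", probes)
  if (!all(clean))
    warning(sum(!clean), " probe(s) contain ambiguous bases; flagged match_count = 0")

  match_count <- integer(length(probes))
  target <- rep(NA_character_, length(probes))
  if (any(clean)) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(probes[clean]))
    subj <- Biostrings::DNAStringSet(sequences)
    hits <- Biostrings::vwhichPDict(pd, subj)  # per subject: probe indices hit
    cnt <- integer(sum(clean))
    tgt <- rep(NA_character_, sum(clean))
    for (j in seq_along(hits)) {
      h <- hits[[j]]
      cnt[h] <- cnt[h] + 1L
      tgt[h] <- ifelse(cnt[h] == 1L, names(sequences)[j], NA_character_)
    }
    match_count[clean] <- cnt
    target[clean] <- ifelse(cnt == 1L, tgt, NA_character_)
  }
  data.frame(probe_id = names(probes),
             sequence = unname(probes),
             gc_fraction = gc_fraction(probes),
             match_count = match_count,
             target_transcript = target,
             stringsAsFactors = FALSE)
}

#' Retain single-match probes
#'
#' @param match_table a `ProbeMatchTable` from [match_probes()].
#' @return character vector of retained probe ids (match_count == 1).
#' @export
filter_single_match <- function(match_table) {
  match_table$probe_id[match_table$match_count == 1L]
}

#' Per-sample GC-content adjustment
#'
#' Probes are grouped into equal-width GC-fraction bins; within each sample,
#' every bin's median intensity is shifted (additively, log2 scale) onto the
#' sample's global median. Bins holding fewer than `min_bin_size` probes are
#' merged into their nearest neighbour (never dropped). Output dimensions
#' equal input dimensions.
#'
#' @param intensity probes x samples log2 matrix (rownames are probe ids).
#' @param match_table `ProbeMatchTable` covering every probe row.
#' @param n_bins number of GC bins (>= 2).
#' @param min_bin_size bins smaller than this are merged (default 5).
#' @return the adjusted matrix, same dimensions and dimnames.
#' @export
gc_adjust <- function(intensity, match_table, n_bins = 10L, min_bin_size = 5L) {
  if (n_bins < 2) abort_config("n_bins must be >= 2")
  idx <- match(rownames(intensity), match_table$probe_id)
  if (anyNA(idx)) abort_input("every probe row must be present in the match table")
  gc <- match_table$gc_fraction[idx]

  rng <- range(gc)
  if (diff(rng) == 0) {
    bin <- rep(1L, length(gc))
  } else {
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    bin <- findInterval(gc, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  }
  ## merge undersized bins into the nearest occupied neighbour
  repeat {
    tab <- table(bin)
    small <- as.integer(names(tab))[tab < min_bin_size]
    if (length(small) == 0 || length(tab) == 1) break
    b <- small[1]
    others <- setdiff(as.integer(names(tab)), b)
    nearest <- others[which.min(abs(others - b))]
    bin[bin == b] <- nearest
  }

  adjusted <- intensity
  bins <- sort(unique(bin))
  for (s in seq_len(ncol(intensity))) {
    gm <- stats::median(intensity[, s])
    for (b in bins) {
      rows <- bin == b
      adjusted[rows, s] <- intensity[rows, s] + (gm - stats::median(intensity[rows, s]))
    }
  }
  adjusted
}

#' Detection and variance filtering
#'
#' A probe is retained iff its intensity exceeds the per-sample
#' `background_quantile` threshold in at least `min_sample_fraction` of
#' samples, and its across-sample SD is at least `min_sd`.
#'
#' @param adjusted probes x samples log2 matrix (>= 2 samples).
#' @param background_quantile per-sample background quantile.
#' @param min_sample_fraction minimum fraction of samples above background.
#' @param min_sd minimum across-sample SD, log2 units.
#' @return character vector of retained probe ids.
#' @export
detection_filter <- function(adjusted, background_quantile = 0.25,
                             min_sample_fraction = 0.5, min_sd = 0.05) {
  if (ncol(adjusted) < 2) abort_input("detection filtering needs >= 2 samples")
  thresholds <- apply(adjusted, 2L, stats::quantile, probs = background_quantile)
  above <- sweep(adjusted, 2L, thresholds, ">")
  sds <- apply(adjusted, 1L, stats::sd)
  keep <- rowMeans(above) >= min_sample_fraction & sds >= min_sd
  rownames(adjusted)[keep]
}

#' Build the probe-to-transcript summarization template
#'
#' Maps each transcript to the ordered list of its retained single-match
#' probes; each probe appears under at most one transcript.
#'
#' @param match_table `ProbeMatchTable`.
#' @param retained character vector of probe ids that passed all filters.
#' @return named list transcript_id -> character vector of probe ids.
#' @export
build_template <- function(match_table, retained) {
  keep <- match_table$match_count == 1L & match_table$probe_id %in% retained
  split(match_table$probe_id[keep], match_table$target_transcript[keep])
}

#' Tukey median polish of an additive row + column model
#'
#' Iteratively sweeps row then column medians, stopping after `max_iter`
#' iterations or when the maximum absolute change in the fit drops below
#' `tol`. At convergence the residual matrix has row and column medians of
#' (numerically) zero.
#'
#' @param x numeric matrix.
#' @param max_iter maximum sweeps (default 10).
#' @param tol convergence tolerance on the maximum absolute change.
#' @return list: overall, row, col, residuals, converged, iterations.
#' @export
median_polish <- function(x, max_iter = 10L, tol = 1e-6) {
  overall <- 0
  row_eff <- numeric(nrow(x))
  col_eff <- numeric(ncol(x))
  res <- x
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    delta <- 0
    rm <- apply(res, 1L, stats::median)
    res <- res - rm
    row_eff <- row_eff + rm
    delta <- max(delta, max(abs(rm)))
    mr <- stats::median(row_eff)
    row_eff <- row_eff - mr
    overall <- overall + mr

    cm <- apply(res, 2L, stats::median)
    res <- sweep(res, 2L, cm)
    col_eff <- col_eff + cm
    delta <- max(delta, max(abs(cm)))
    mc <- stats::median(col_eff)
    col_eff <- col_eff - mc
    overall <- overall + mc
    if (delta < tol) { converged <- TRUE; break }
  }
  list(overall = overall, row = row_eff, col = col_eff,
       residuals = res, converged = converged, iterations = it)
}

#' Summarize probes into transcript signals
#'
#' For transcripts with at least three retained probes the transcript signal
#' is the median-polish fit `overall + column (sample) effect`; transcripts
#' with one or two probes fall back to the per-sample probe median (noted in
#' the report). Transcripts listed in `all_transcripts` but absent from the
#' template are reported as dropped.
#'
#' @param adjusted probes x samples log2 matrix.
#' @param template named list transcript -> probe ids from [build_template()].
#' @param all_transcripts optional character vector used to report dropped
#'   transcripts.
#' @return list: `expression` (transcripts x samples), `dropped` (character),
#'   `median_fallback` (transcripts summarized by the probe median).
#' @export
summarize_transcripts <- function(adjusted, template, all_transcripts = NULL) {
  if (length(template) == 0) abort_input("empty summarization template")
  missing_probes <- setdiff(unlist(template), rownames(adjusted))
  if (length(missing_probes) > 0)
    abort_input("template probes absent from the intensity table: ",
                paste(utils::head(missing_probes, 5), collapse = ", "))

  n_s <- ncol(adjusted)
  expr <- matrix(NA_real_, length(template), n_s,
                 dimnames = list(names(template), colnames(adjusted)))
  fallback <- character(0)
  for (tid in names(template)) {
    m <- adjusted[template[[tid]], , drop = FALSE]
    if (nrow(m) >= 3) {
      mp <- median_polish(m)
      expr[tid, ] <- mp$overall + mp$col
    } else {
      expr[tid, ] <- apply(m, 2L, stats::median)
      fallback <- c(fallback, tid)
    }
  }
  dropped <- if (is.null(all_transcripts)) character(0)
             else setdiff(all_transcripts, names(template))
  list(expression = expr, dropped = dropped, median_fallback = fallback)
}

#' Run the full probe-quantification pipeline
#'
#' Fixed order: match -> single-match filter -> GC adjust -> detection
#' filter -> summarize. Multi-match probes are removed before any
#' intensity-level step, so their values cannot influence any transcript
#' signal.
#'
#' @param probes named character vector of probe sequences.
#' @param sequences named character vector of transcript sequences.
#' @param intensity probes x samples log2 matrix.
#' @param n_bins,background_quantile,min_sample_fraction,min_sd filter
#'   parameters (see the individual steps).
#' @return list: `expression`, `match_table`, `retained`, `dropped`,
#'   `median_fallback`, `filter_report`.
#' @export
quantify_probes <- function(probes, sequences, intensity,
                            n_bins = 10L, background_quantile = 0.25,
                            min_sample_fraction = 0.5, min_sd = 0.05) {
  match_table <- match_probes(probes, sequences)
  single <- filter_single_match(match_table)
  if (length(single) == 0) abort_input("no single-match probes")
  adjusted <- gc_adjust(intensity[single, , drop = FALSE], match_table, n_bins = n_bins)
  retained <- detection_filter(adjusted, background_quantile = background_quantile,
                               min_sample_fraction = min_sample_fraction,
                               min_sd = min_sd)
  if (length(retained) == 0) abort_input("all probes removed by the detection filter")
  template <- build_template(match_table, retained)
  summ <- summarize_transcripts(adjusted[retained, , drop = FALSE], template,
                                all_transcripts = names(sequences))
  list(expression = summ$expression,
       match_table = match_table,
       retained = retained,
       dropped = summ$dropped,
       median_fallback = summ$median_fallback,
       filter_report = list(n_probes = length(probes),
                            n_single_match = length(single),
                            n_detected = length(retained),
                            n_transcripts = nrow(summ$expression)))
}
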