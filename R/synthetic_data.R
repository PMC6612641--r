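## Synthetic-data generators.
##
## Every fixture the pipeline consumes can be generated here with full truth
## labels: transcriptomes with biotype annotation, probe-level intensity
## tables with GC bias and multi-mapping probes, multi-cohort age-structured
## expression with planted trajectory classes and covariate confounding,
## monozygotic-twin panels with biotype-specific heritability, and compound
## signature libraries with planted mimics/opposers. All generators are pure
## functions of their arguments including the seed.

BIOTYPES <- c("protein_coding", "lincRNA", "antisense", "pseudogene")

#' Plant per-transcript trajectory truth labels
#'
#' Assigns every transcript one of four trajectory classes. Age-related
#' transcripts carry a nonzero expression slope (log2 units per year) in the
#' first age window (20-55 y); `GROUP1` transcripts keep the same slope past
#' the knot at 55 y, `GROUP2` transcripts switch off (window-2 slope exactly
#' zero), `NULL_CLASS` transcripts are flat, and `HOUSEKEEPING` transcripts
#' are flat with a much lower noise SD (so their linear-scale coefficient of
#' variation stays below the housekeeping cap).
#'
#' Defaults mirror the stated world of the reference analysis: 300
#' age-related transcripts of which 75% are Group 2, slope magnitude
#' 0.015 log2/yr, two-thirds of age slopes negative, residual SD 0.25.
#'
#' @param n_transcripts total number of transcripts.
#' @param n_age_related number of GROUP1+GROUP2 transcripts.
#' @param group2_fraction fraction of the age-related set planted as GROUP2.
#' @param slope_per_year absolute window-1 slope, log2 units per year.
#' @param frac_negative fraction of age-related slopes that are negative.
#' @param n_housekeeping number of HOUSEKEEPING transcripts.
#' @param biotype_fractions named simplex over
#'   `protein_coding`, `lincRNA`, `antisense`, `pseudogene`.
#' @param noise_sd residual log2 SD for non-housekeeping transcripts.
#' @param housekeeping_noise_sd residual log2 SD for HOUSEKEEPING transcripts
#'   (0.02 maps to a linear-scale CV of about 1.4%).
#' @param seed integer seed.
#' @return data.frame with columns `transcript_id`, `gene_id`, `class_label`,
#'   `slope_window1`, `slope_window2`, `direction`, `biotype`, `noise_sd`.
#' @export
make_trajectory_truth <- function(n_transcripts,
                                  n_age_related = 300L,
                                  group2_fraction = 0.75,
                                  slope_per_year = 0.015,
                                  frac_negative = 2 / 3,
                                  n_housekeeping = 50L,
                                  biotype_fractions = c(protein_coding = 0.7,
                                                        lincRNA = 0.15,
                                                        antisense = 0.1,
                                                        pseudogene = 0.05),
                                  noise_sd = 0.25,
                                  housekeeping_noise_sd = 0.02,
                                  seed = 1L) {
  if (n_transcripts < n_age_related + n_housekeeping)
    abort_config("n_transcripts must cover the age-related and housekeeping sets")
  check_simplex(biotype_fractions)
  set.seed(derive_seed(seed, 11L))

  n_g2 <- round(group2_fraction * n_age_related)
  class_label <- c(rep("GROUP2", n_g2),
                   rep("GROUP1", n_age_related - n_g2),
                   rep("HOUSEKEEPING", n_housekeeping),
                   rep("NULL_CLASS", n_transcripts - n_age_related - n_housekeeping))
  class_label <- sample(class_label)

  direction <- integer(n_transcripts)
  is_age <- class_label %in% c("GROUP1", "GROUP2")
  direction[is_age] <- ifelse(stats::runif(sum(is_age)) < frac_negative, -1L, 1L)

  slope1 <- ifelse(is_age, direction * slope_per_year, 0)
  slope2 <- ifelse(class_label == "GROUP1", slope1, 0)

  data.frame(
    transcript_id = sprintf("ENST%08d", seq_len(n_transcripts)),
    gene_id = sprintf("ENSG%08d", seq_len(n_transcripts)),
    class_label = class_label,
    slope_window1 = slope1,
    slope_window2 = slope2,
    direction = direction,
    biotype = sample(BIOTYPES, n_transcripts, replace = TRUE,
                     prob = biotype_fractions[BIOTYPES]),
    noise_sd = ifelse(class_label == "HOUSEKEEPING", housekeeping_noise_sd, noise_sd),
    stringsAsFactors = FALSE
  )
}

check_simplex <- function(fractions) {
  if (is.null(names(fractions)) || !all(names(fractions) %in% BIOTYPES))
    abort_config("biotype fractions must be named with known biotypes: ",
                 paste(BIOTYPES, collapse = ", "))
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    abort_config("biotype fractions must be a simplex (non-negative, sum 1)")
  invisible(TRUE)
}

#' Describe a multi-cohort sampling design
#'
#' @param n_cohorts number of independent cohorts.
#' @param samples_per_cohort samples per cohort (>= 10).
#' @param age_range two-element numeric, years, within \[18, 90\].
#' @param covariate_effects named numeric: log2 expression change per SD of
#'   each covariate, applied to every transcript.
#' @param covariate_age_correlation named numeric: marginal correlation of
#'   each covariate with age (Gaussian copula confounding).
#' @param noise_sd residual log2 SD (> 0); per-transcript values in the truth
#'   table override it.
#' @param batch_shift_sd SD of per-cohort, per-transcript additive offsets.
#' @param seed integer seed.
#' @return a validated list of class `cohort_design`.
#' @export
cohort_design <- function(n_cohorts = 4L,
                          samples_per_cohort = 80L,
                          age_range = c(20, 55),
                          covariate_effects = c(vo2max = 0.05,
                                                insulin_sensitivity = 0.05),
                          covariate_age_correlation = c(vo2max = -0.4,
                                                        insulin_sensitivity = -0.3),
                          noise_sd = 0.25,
                          batch_shift_sd = 0.1,
                          seed = 1L) {
  if (samples_per_cohort < 10) abort_config("samples_per_cohort must be >= 10")
  if (length(age_range) != 2 || age_range[1] >= age_range[2] ||
      age_range[1] < 18 || age_range[2] > 90)
    abort_config("age_range must be increasing and within [18, 90]")
  if (noise_sd <= 0) abort_config("noise_sd must be > 0")
  if (!setequal(names(covariate_effects), names(covariate_age_correlation)))
    abort_config("covariate_effects and covariate_age_correlation must name the same covariates")
  if (any(abs(covariate_age_correlation) > 1))
    abort_config("covariate-age correlations must lie in [-1, 1]")
  structure(list(n_cohorts = as.integer(n_cohorts),
                 samples_per_cohort = as.integer(samples_per_cohort),
                 age_range = as.numeric(age_range),
                 covariate_effects = covariate_effects,
                 covariate_age_correlation = covariate_age_correlation,
                 noise_sd = noise_sd,
                 batch_shift_sd = batch_shift_sd,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Generate a synthetic transcriptome
#'
#' Random nucleotide sequences with per-transcript GC fraction drawn from
#' `gc_range`, plus an annotation table (transcript id, gene id, biotype).
#' When a truth table is supplied its ids and biotypes are reused so
#' downstream fixtures stay consistent.
#'
#' @param n_transcripts number of transcripts (ignored when `truth` given).
#' @param biotype_fractions simplex over biotypes (ignored when `truth` given).
#' @param length_range transcript length range, nt; minimum >= 100.
#' @param gc_range range the per-transcript GC fraction is drawn from.
#' @param seed integer seed.
#' @param truth optional trajectory-truth data.frame.
#' @return list with `sequences` (named character) and `annotation`
#'   (data.frame: transcript_id, gene_id, biotype).
#' @export
generate_transcriptome <- function(n_transcripts = NULL,
                                   biotype_fractions = c(protein_coding = 0.7,
                                                         lincRNA = 0.15,
                                                         antisense = 0.1,
                                                         pseudogene = 0.05),
                                   length_range = c(200L, 600L),
                                   gc_range = c(0.35, 0.65),
                                   seed = 1L,
                                   truth = NULL) {
  if (is.null(truth)) {
    if (is.null(n_transcripts) || n_transcripts < 1)
      abort_config("n_transcripts must be a positive count")
    check_simplex(biotype_fractions)
  } else {
    n_transcripts <- nrow(truth)
  }
  if (length_range[1] < 100) abort_config("minimum transcript length is 100 nt")
  if (gc_range[1] < 0 || gc_range[2] > 1 || gc_range[1] > gc_range[2])
    abort_config("gc_range must be an increasing range within [0, 1]")

  set.seed(derive_seed(seed, 12L))
  lens <- sample(seq(length_range[1], length_range[2]), n_transcripts, replace = TRUE)
  gcs <- stats::runif(n_transcripts, gc_range[1], gc_range[2])
  sequences <- vapply(seq_len(n_transcripts), function(i) {
    p <- c(A = (1 - gcs[i]) / 2, C = gcs[i] / 2, G = gcs[i] / 2, T = (1 - gcs[i]) / 2)
    paste(sample(names(p), lens[i], replace = TRUE, prob = p), collapse = "")
  }, character(1))

  if (is.null(truth)) {
    annotation <- data.frame(
      transcript_id = sprintf("ENST%08d", seq_len(n_transcripts)),
      gene_id = sprintf("ENSG%08d", seq_len(n_transcripts)),
      biotype = sample(BIOTYPES, n_transcripts, replace = TRUE,
                       prob = biotype_fractions[BIOTYPES]),
      stringsAsFactors = FALSE
    )
  } else {
    annotation <- truth[, c("transcript_id", "gene_id", "biotype")]
    rownames(annotation) <- NULL
  }
  names(sequences) <- annotation$transcript_id
  list(sequences = sequences, annotation = annotation)
}

#' Generate probe sequences and a probe-intensity table
#'
#' Draws `probes_per_transcript` 25-mer probes as true substrings of each
#' transcript, optionally plants multi-mapping probes (the probe sequence is
#' appended to a second transcript, guaranteeing a match count of at least
#' two) and "dead" probes pinned at background level. Observed log2 intensity
#' is `true abundance + gc_bias_amplitude * (GC - 0.5) * 2 + N(0, noise_sd)`,
#' where the per-sample true abundance is the transcript's baseline plus its
#' age trajectory plus between-sample biological variation (`abundance_sd`).
#' The realized abundance matrix is returned for recovery tests.
#'
#' @param transcriptome output of [generate_transcriptome()].
#' @param truth trajectory truth for the same transcripts.
#' @param design a [cohort_design()]; one cohort of
#'   `samples_per_cohort` samples is drawn and `noise_sd` sets the
#'   probe-level measurement noise.
#' @param probe_len probe length, nt (must not exceed the shortest transcript).
#' @param probes_per_transcript probes drawn per transcript.
#' @param multi_match_fraction fraction of probes planted into a second
#'   transcript, in \[0, 1).
#' @param gc_bias_amplitude log2 intensity bias per unit of (2 * GC - 1).
#' @param dead_probe_fraction fraction of transcripts that are unexpressed;
#'   all probes of such a transcript are pinned at background level (with
#'   live-probe measurement noise and GC-dependent nonspecific signal).
#' @param abundance_sd SD of between-sample biological variation, log2 units.
#' @param seed integer seed (defaults to the design's seed).
#' @return list: `probes` (named character), `probe_info` (probe_id,
#'   transcript_id, gc_fraction, multi_match, dead), `intensity` (probes x
#'   samples, log2), `abundance` (transcripts x samples truth), `sequences`
#'   (transcriptome after multi-match planting), `metadata` (sample_id, age).
#' @export
generate_probe_intensities <- function(transcriptome, truth, design,
                                       probe_len = 25L,
                                       probes_per_transcript = 8L,
                                       multi_match_fraction = 0,
                                       gc_bias_amplitude = 0,
                                       dead_probe_fraction = 0,
                                       abundance_sd = 0.5,
                                       seed = design$seed) {
  seqs <- transcriptome$sequences
  lens <- nchar(seqs)
  if (probe_len > min(lens))
    abort_config("probe_len exceeds the shortest transcript length")
  if (multi_match_fraction < 0 || multi_match_fraction >= 1)
    abort_config("multi_match_fraction must lie in [0, 1)")
  set.seed(derive_seed(seed, 13L))

  n_t <- length(seqs)
  ids <- names(seqs)
  src <- rep(ids, each = probes_per_transcript)
  starts <- unlist(lapply(lens, function(L) {
    sample.int(L - probe_len + 1L, probes_per_transcript,
               replace = (L - probe_len + 1L) < probes_per_transcript)
  }))
  probes <- substr(rep(unname(seqs), each = probes_per_transcript),
                   starts, starts + probe_len - 1L)
  probe_id <- sprintf("P_%s_%02d", src, sequence(rep(probes_per_transcript, n_t)))
  names(probes) <- probe_id
  n_p <- length(probes)

  multi <- rep(FALSE, n_p)
  n_multi <- floor(multi_match_fraction * n_p)
  if (n_multi > 0) {
    idx <- sample.int(n_p, n_multi)
    multi[idx] <- TRUE
    for (i in idx) {
      host <- sample(setdiff(ids, src[i]), 1L)
      seqs[host] <- paste0(seqs[host], probes[i])
    }
  }

  ## deadness is transcript-structured, as on real arrays: an unexpressed
  ## transcript pins all of its probes at background
  dead <- rep(FALSE, n_p)
  if (dead_probe_fraction > 0) {
    dead_tx <- sample(ids, floor(dead_probe_fraction * n_t))
    dead <- src %in% dead_tx
  }

  n_s <- design$samples_per_cohort
  ages <- stats::runif(n_s, design$age_range[1], design$age_range[2])
  baseline <- stats::rnorm(n_t, mean = 8, sd = 1.5)
  traj <- outer(seq_len(n_t), ages, function(i, a) {
    piecewise_age_term(a, truth$slope_window1[i], truth$slope_window2[i])
  })
  abundance <- baseline + traj +
    matrix(stats::rnorm(n_t * n_s, sd = abundance_sd), n_t, n_s)
  dimnames(abundance) <- list(ids, sprintf("S%03d", seq_len(n_s)))

  gc_frac <- gc_fraction(probes)
  intensity <- abundance[src, , drop = FALSE] +
    gc_bias_amplitude * (gc_frac - 0.5) * 2 +
    matrix(stats::rnorm(n_p * n_s, sd = design$noise_sd), n_p, n_s)
  if (any(dead)) {
    ## background probes behave like real unexpressed array probes: pinned
    ## at a common background level but with the same measurement noise and
    ## GC-dependent nonspecific signal as expressed probes; the truth
    ## abundance of an unexpressed transcript is that flat background
    bg <- min(abundance) - 3
    intensity[dead, ] <- bg + gc_bias_amplitude * (gc_frac[dead] - 0.5) * 2 +
      matrix(stats::rnorm(sum(dead) * n_s, sd = design$noise_sd), sum(dead), n_s)
    abundance[unique(src[dead]), ] <- bg
  }
  rownames(intensity) <- probe_id

  list(probes = probes,
       probe_info = data.frame(probe_id = probe_id, transcript_id = src,
                               gc_fraction = gc_frac, multi_match = multi,
                               dead = dead, stringsAsFactors = FALSE),
       intensity = intensity,
       abundance = abundance,
       sequences = seqs,
       metadata = data.frame(sample_id = colnames(abundance), age = ages,
                             stringsAsFactors = FALSE))
}

gc_fraction <- function(x) {
  (nchar(gsub("[^GCgc]", "", x))) / nchar(x)
}

#' Generate multi-cohort age-structured expression
#'
#' Sample ages are uniform over the design's age range; covariates follow a
#' Gaussian copula with the stated marginal correlation to age
#' (`cov = a * std_age + sqrt(1 - a^2) * N(0,1)`). Expression is
#' `baseline + piecewise age term (knot 55 y) + covariate terms +
#' per-cohort batch shift + N(0, noise_sd)`, all in log2 units.
#'
#' @param truth trajectory-truth data.frame from [make_trajectory_truth()].
#' @param design a [cohort_design()].
#' @param tissue tissue label written into the metadata.
#' @return list with `expression` (transcripts x samples, log2) and
#'   `metadata` (sample_id, cohort, age, covariates, tissue, pair_id).
#' @export
generate_cohorts <- function(truth, design, tissue = "muscle") {
  if (!inherits(design, "cohort_design")) abort_config("design must be a cohort_design")
  if (nrow(truth) == 0) abort_config("truth must be nonempty")
  set.seed(derive_seed(design$seed, 14L))

  n_t <- nrow(truth)
  covs <- names(design$covariate_effects)
  baseline <- stats::rnorm(n_t, mean = 8, sd = 1.5)

  expr_list <- vector("list", design$n_cohorts)
  meta_list <- vector("list", design$n_cohorts)
  for (ch in seq_len(design$n_cohorts)) {
    n_s <- design$samples_per_cohort
    age <- stats::runif(n_s, design$age_range[1], design$age_range[2])
    z_age <- as.numeric(scale(age))
    covariate <- sapply(covs, function(v) {
      a <- design$covariate_age_correlation[[v]]
      a * z_age + sqrt(1 - a^2) * stats::rnorm(n_s)
    })
    traj <- vapply(seq_len(n_s), function(s) {
      piecewise_age_term(age[s], truth$slope_window1, truth$slope_window2)
    }, numeric(n_t))
    ## housekeeping transcripts are by definition insensitive to physiology:
    ## covariate effects apply to every other trajectory class
    cov_sens <- as.numeric(truth$class_label != "HOUSEKEEPING")
    cov_term <- vapply(seq_len(n_s), function(s) {
      cov_sens * sum(design$covariate_effects * covariate[s, ])
    }, numeric(n_t))
    batch <- stats::rnorm(n_t, sd = design$batch_shift_sd)
    noise <- matrix(stats::rnorm(n_t * n_s), n_t, n_s) * truth$noise_sd
    expr <- baseline + traj + cov_term + batch + noise
    colnames(expr) <- sprintf("C%d_S%03d", ch, seq_len(n_s))
    rownames(expr) <- truth$transcript_id
    expr_list[[ch]] <- expr
    meta <- data.frame(sample_id = colnames(expr),
                       cohort = sprintf("cohort_%d", ch),
                       age = age, stringsAsFactors = FALSE)
    meta[covs] <- covariate
    meta$tissue <- tissue
    meta$pair_id <- NA_character_
    meta_list[[ch]] <- meta
  }
  list(expression = do.call(cbind, expr_list),
       metadata = do.call(rbind, meta_list))
}

#' Generate a monozygotic-twin expression panel
#'
#' Per gene, expression is `baseline + sqrt(h2) * pair effect +
#' sqrt(1 - h2) * individual effect` with unit total variance around the
#' baseline, so the one-way ICC recovers `h2`. The heritability fraction is
#' chosen by the gene's biotype class (protein-coding vs any noncoding).
#'
#' @param truth trajectory-truth data.frame (ids and biotypes are used).
#' @param n_pairs number of monozygotic pairs (default 17, the panel size the
#'   heritability contrast is designed around).
#' @param h2_coding heritability fraction for protein-coding genes, \[0, 1\].
#' @param h2_noncoding heritability fraction for noncoding genes, \[0, 1\].
#' @param seed integer seed.
#' @return list with `expression` (genes x samples) and `pair_map`
#'   (sample_id, pair_id).
#' @export
generate_twin_panel <- function(truth, n_pairs = 17L,
                                h2_coding = 0.8, h2_noncoding = 0.5,
                                seed = 1L) {
  if (h2_coding < 0 || h2_coding > 1 || h2_noncoding < 0 || h2_noncoding > 1)
    abort_config("heritability fractions must lie in [0, 1]")
  set.seed(derive_seed(seed, 15L))
  n_g <- nrow(truth)
  h2 <- ifelse(truth$biotype == "protein_coding", h2_coding, h2_noncoding)
  baseline <- stats::rnorm(n_g, 8, 1.5)
  pair_eff <- matrix(stats::rnorm(n_g * n_pairs), n_g, n_pairs)
  ind_eff <- matrix(stats::rnorm(n_g * 2 * n_pairs), n_g, 2 * n_pairs)
  shared <- pair_eff[, rep(seq_len(n_pairs), each = 2), drop = FALSE]
  expr <- baseline + sqrt(h2) * shared + sqrt(1 - h2) * ind_eff
  sample_id <- sprintf("TW%03d_%d", rep(seq_len(n_pairs), each = 2), rep(1:2, n_pairs))
  dimnames(expr) <- list(truth$transcript_id, sample_id)
  list(expression = expr,
       pair_map = data.frame(sample_id = sample_id,
                             pair_id = sprintf("pair_%03d", rep(seq_len(n_pairs), each = 2)),
                             stringsAsFactors = FALSE))
}

#' Generate a compound-signature library with planted hits
#'
#' Each compound is a total ranking (permutation) of the shared gene
#' universe. Planted mimics place the query's up-genes uniformly within the
#' top decile and its down-genes within the bottom decile; planted opposers
#' the reverse; neutral compounds are uniform random permutations.
#'
#' @param query_up,query_down disjoint gene sets, both subsets of `universe`.
#' @param universe character vector of gene ids (the shared scoring universe).
#' @param n_mimics,n_opposers,n_neutral compound counts per class.
#' @param seed integer seed.
#' @return list with `rankings` (named list of character permutations) and
#'   `truth` (compound_id, class_label, compound_class).
#' @export
generate_compound_library <- function(query_up, query_down, universe,
                                      n_mimics = 5L, n_opposers = 5L,
                                      n_neutral = 90L, seed = 1L) {
  if (length(intersect(query_up, query_down)) > 0)
    abort_input("query up/down gene sets must be disjoint")
  if (!all(c(query_up, query_down) %in% universe))
    abort_input("query gene sets must be subsets of the universe")
  n <- length(universe)
  k <- floor(n / 10)
  if (length(query_up) > k || length(query_down) > k)
    abort_config("query sets larger than a decile of the universe cannot be planted")
  set.seed(derive_seed(seed, 16L))

  plant <- function(top_set, bottom_set) {
    ranking <- character(n)
    pos_top <- sort(sample.int(k, length(top_set)))
    pos_bot <- sort(sample.int(k, length(bottom_set))) + (n - k)
    ranking[pos_top] <- sample(top_set)
    ranking[pos_bot] <- sample(bottom_set)
    rest <- setdiff(universe, c(top_set, bottom_set))
    ranking[ranking == ""] <- sample(rest)
    ranking
  }

  ids <- c(sprintf("mimic_%02d", seq_len(n_mimics)),
           sprintf("opposer_%02d", seq_len(n_opposers)),
           sprintf("neutral_%03d", seq_len(n_neutral)))
  class_label <- c(rep("planted_mimic", n_mimics),
                   rep("planted_opposer", n_opposers),
                   rep("neutral", n_neutral))
  compound_class <- c(rep("pathway_inhibitor", n_mimics),
                      rep("pathway_activator", n_opposers),
                      rep("neutral", n_neutral))
  rankings <- vector("list", length(ids))
  names(rankings) <- ids
  for (i in seq_along(ids)) {
    rankings[[i]] <- switch(class_label[i],
      planted_mimic = plant(query_up, query_down),
      planted_opposer = plant(query_down, query_up),
      neutral = sample(universe))
  }
  list(rankings = rankings,
       truth = data.frame(compound_id = ids, class_label = class_label,
                          compound_class = compound_class,
                          stringsAsFactors = FALSE))
}
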