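test_that("transcriptome generation respects fractions, determinism and errors", {
  tx <- generate_transcriptome(100, c(protein_coding = 0.5, lincRNA = 0.5,
                                      antisense = 0, pseudogene = 0), seed = 7)
  expect_length(tx$sequences, 100)
  expect_equal(nrow(tx$annotation), 100)
  n_coding <- sum(tx$annotation$biotype == "protein_coding")
  # binomial(100, 0.5) band at alpha ~ 1e-3
  expect_gte(n_coding, qbinom(5e-4, 100, 0.5))
  expect_lte(n_coding, qbinom(1 - 5e-4, 100, 0.5))

  tx_c <- generate_transcriptome(30, c(protein_coding = 1, lincRNA = 0,
                                       antisense = 0, pseudogene = 0), seed = 1)
  expect_true(all(tx_c$annotation$biotype == "protein_coding"))

  # same seed twice -> byte-identical FASTA and annotation
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(generate_transcriptome(40, seed = 3)$sequences, f1)
  write_fasta(generate_transcriptome(40, seed = 3)$sequences, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(generate_transcriptome(10, c(protein_coding = 0.6, lincRNA = 0.6,
                                            antisense = 0, pseudogene = 0)),
               class = "ageswitch_config_error")
  expect_error(generate_transcriptome(0), class = "ageswitch_config_error")
  expect_error(generate_transcriptome(10, length_range = c(50, 80)),
               class = "ageswitch_config_error")
})

test_that("trajectory truth conserves labels and encodes the switch", {
  truth <- make_trajectory_truth(400, n_age_related = 60, group2_fraction = 0.75,
                                 n_housekeeping = 20, seed = 2)
  expect_equal(nrow(truth), 400)
  expect_false(any(duplicated(truth$transcript_id)))
  expect_equal(sum(truth$class_label %in% c("GROUP1", "GROUP2")), 60)
  expect_equal(sum(truth$class_label == "GROUP2"), 45)
  # invariants per class
  g2 <- truth$class_label == "GROUP2"
  g1 <- truth$class_label == "GROUP1"
  expect_true(all(truth$slope_window2[g2] == 0 & truth$slope_window1[g2] != 0))
  expect_true(all(truth$slope_window1[g1] == truth$slope_window2[g1] &
                    truth$slope_window1[g1] != 0))
  flat <- truth$class_label %in% c("NULL_CLASS", "HOUSEKEEPING")
  expect_true(all(truth$slope_window1[flat] == 0 & truth$slope_window2[flat] == 0))
  expect_true(all(truth$noise_sd[truth$class_label == "HOUSEKEEPING"] < 0.05))
})

test_that("probe intensities: substrings, planted multi-matches, gc switch-off, determinism", {
  truth <- make_trajectory_truth(60, n_age_related = 20, n_housekeeping = 5, seed = 4)
  tx <- generate_transcriptome(truth = truth, seed = 4)
  des <- cohort_design(n_cohorts = 1, samples_per_cohort = 25, seed = 4)
  fix <- generate_probe_intensities(tx, truth, des, probes_per_transcript = 6,
                                    multi_match_fraction = 0.1,
                                    gc_bias_amplitude = 0)

  # every probe is a true substring of its source transcript
  src_ok <- mapply(function(p, t) grepl(p, fix$sequences[t], fixed = TRUE),
                   fix$probes, fix$probe_info$transcript_id)
  expect_true(all(src_ok))

  # planted multi-match probes match >= 2 transcripts under the matcher
  mt <- match_probes(fix$probes, fix$sequences)
  planted <- fix$probe_info$multi_match
  expect_true(all(mt$match_count[planted] >= 2))
  expect_equal(sum(planted), floor(0.1 * length(fix$probes)))

  # gc_bias_amplitude = 0 -> regression of intensity on GC has slope ~ 0
  resid_int <- rowMeans(fix$intensity) - rowMeans(fix$abundance)[fix$probe_info$transcript_id]
  fit <- summary(lm(resid_int ~ fix$probe_info$gc_fraction))
  expect_lt(abs(fit$coefficients[2, 1]), 2 * fit$coefficients[2, 2])

  # determinism
  fix2 <- generate_probe_intensities(tx, truth, des, probes_per_transcript = 6,
                                     multi_match_fraction = 0.1,
                                     gc_bias_amplitude = 0)
  expect_identical(fix$intensity, fix2$intensity)

  expect_error(generate_probe_intensities(tx, truth, des, probe_len = 10000),
               class = "ageswitch_config_error")
})

test_that("cohort generation: noise-free limit is exactly piecewise linear in age", {
  truth <- make_trajectory_truth(30, n_age_related = 20, group2_fraction = 0.5,
                                 n_housekeeping = 0, seed = 5,
                                 housekeeping_noise_sd = 1e-9)
  truth$noise_sd <- 1e-9
  des <- cohort_design(n_cohorts = 1, samples_per_cohort = 60,
                       age_range = c(20, 86),
                       covariate_effects = c(vo2max = 0, insulin_sensitivity = 0),
                       noise_sd = 1e-9, batch_shift_sd = 0, seed = 5)
  sim <- generate_cohorts(truth, des)
  age <- sim$metadata$age
  w1 <- age <= 55
  for (i in which(truth$slope_window1 != 0)) {
    # window-1 monotonicity is exact
    rho <- cor(sim$expression[i, w1], age[w1], method = "spearman")
    expect_equal(abs(rho), 1)
    # the fitted piecewise model is exact (residuals at noise level)
    x1 <- pmin(age, 55); x2 <- pmax(age - 55, 0)
    res <- residuals(lm(sim$expression[i, ] ~ x1 + x2))
    expect_lt(max(abs(res)), 1e-6)
  }
})

test_that("planted GROUP2 transcript gives strongly negative window-1 rho", {
  truth <- make_trajectory_truth(10, n_age_related = 1, group2_fraction = 1,
                                 slope_per_year = 0.02, n_housekeeping = 0,
                                 noise_sd = 0.2, seed = 6)
  i <- which(truth$class_label == "GROUP2")
  truth$slope_window1[i] <- -0.02
  truth$slope_window2[i] <- 0
  des <- cohort_design(n_cohorts = 1, samples_per_cohort = 100,
                       age_range = c(20, 55), noise_sd = 0.2, seed = 6)
  sim <- generate_cohorts(truth, des)
  rho <- cor(sim$expression[i, ], sim$metadata$age, method = "spearman")
  expect_lt(rho, -0.5)
})

test_that("all-null cohorts are calibrated at nominal alpha", {
  # ~5% nominally significant under the null, pooled over 50 replicates
  hits <- 0; total <- 0
  for (r in 1:50) {
    truth <- make_trajectory_truth(200, n_age_related = 0, n_housekeeping = 0,
                                   noise_sd = 0.2, seed = r)
    des <- cohort_design(n_cohorts = 1, samples_per_cohort = 60,
                         noise_sd = 0.2, seed = r)
    sim <- generate_cohorts(truth, des)
    sc <- covariate_adjusted_scan(sim$expression, sim$metadata, c(20, 55))
    hits <- hits + sum(sc$p_value < 0.05)
    total <- total + nrow(sc)
  }
  # pooled rate ~ 5%; band = 0.05 +/- 3 binomial SDs (plus approximation slack)
  rate <- hits / total
  slack <- 3 * sqrt(0.05 * 0.95 / total) + 0.005
  expect_gt(rate, 0.05 - slack)
  expect_lt(rate, 0.05 + slack)
})

test_that("twin panel: h2 endpoints behave and pair map is complete", {
  truth <- make_trajectory_truth(250, n_age_related = 100, n_housekeeping = 0,
                                 seed = 8)
  # h2 = 1: within-pair values identical, ICC exactly 1
  tp1 <- generate_twin_panel(truth, n_pairs = 10, h2_coding = 1,
                             h2_noncoding = 1, seed = 8)
  expect_true(all(table(tp1$pair_map$pair_id) == 2))
  odd <- seq(1, 20, 2)
  expect_equal(tp1$expression[, odd], tp1$expression[, odd + 1],
               ignore_attr = TRUE)
  icc1 <- icc_per_gene(tp1$expression, tp1$pair_map)
  expect_true(all(abs(icc1$icc - 1) < 1e-12))

  # h2 = 0: mean ICC near 0 (>= 200 genes, 50 pairs)
  tp0 <- generate_twin_panel(truth, n_pairs = 50, h2_coding = 0,
                             h2_noncoding = 0, seed = 9)
  icc0 <- icc_per_gene(tp0$expression, tp0$pair_map)
  expect_lt(abs(mean(icc0$icc)), 0.1)

  expect_error(generate_twin_panel(truth, h2_coding = 1.2),
               class = "ageswitch_config_error")
})

test_that("compound library: permutations, determinism, planted scores", {
  universe <- sprintf("g%03d", 1:300)
  up <- universe[5 + 1:20]; down <- universe[200 + 1:20]
  lib <- generate_compound_library(up, down, universe, n_mimics = 5,
                                   n_opposers = 5, n_neutral = 90, seed = 3)
  expect_length(lib$rankings, 100)
  expect_true(all(vapply(lib$rankings, function(r) setequal(r, universe), logical(1))))

  q <- list(up_genes = up, down_genes = down)
  scores <- vapply(lib$rankings, function(r) connectivity_score(q, r)$score,
                   numeric(1))
  expect_true(all(scores[lib$truth$class_label == "planted_mimic"] > 90))
  expect_true(all(scores[lib$truth$class_label == "planted_opposer"] < -90))

  lib2 <- generate_compound_library(up, down, universe, n_mimics = 5,
                                    n_opposers = 5, n_neutral = 90, seed = 3)
  expect_identical(lib$rankings, lib2$rankings)

  expect_error(generate_compound_library(up, c(up[1], down), universe),
               class = "ageswitch_input_error")
  expect_error(generate_compound_library(c(up, "not_in_universe"), down, universe),
               class = "ageswitch_input_error")
})

test_that("cohort_design validates its invariants", {
  expect_error(cohort_design(samples_per_cohort = 5), class = "ageswitch_config_error")
  expect_error(cohort_design(age_range = c(10, 55)), class = "ageswitch_config_error")
  expect_error(cohort_design(noise_sd = 0), class = "ageswitch_config_error")
})
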