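# Shared small probe fixture built in code (no stored data).
## Shared fixture. Sized so bin medians in the GC adjustment are estimated
## from ~300 probes each (their sampling error drives the residual GC
## correlation checked below).
probe_fixture <- local({
  truth <- make_trajectory_truth(500, n_age_related = 100, n_housekeeping = 20,
                                 seed = 21)
  tx <- generate_transcriptome(truth = truth, seed = 21)
  des <- cohort_design(n_cohorts = 1, samples_per_cohort = 24, noise_sd = 0.2,
                       seed = 21)
  fix <- generate_probe_intensities(tx, truth, des, probes_per_transcript = 8,
                                    multi_match_fraction = 0.1,
                                    gc_bias_amplitude = 0.8,
                                    dead_probe_fraction = 0.1)
  list(truth = truth, fix = fix)
})

test_that("match_probes agrees with a brute-force substring oracle", {
  fix <- probe_fixture$fix
  mt <- match_probes(fix$probes, fix$sequences)
  # oracle check on a sample of real probes plus absent random 25-mers
  set.seed(1)
  idx <- sample(nrow(mt), 25)
  for (i in idx) {
    expect_equal(mt$match_count[i], oracle_match_count(mt$sequence[i], fix$sequences))
  }
  absent <- replicate(5, paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = ""))
  mt_abs <- suppressWarnings(match_probes(absent, fix$sequences))
  for (i in seq_along(absent)) {
    expect_equal(mt_abs$match_count[i], oracle_match_count(absent[i], fix$sequences))
  }
  # gc_fraction is exact
  expect_equal(mt$gc_fraction, nchar(gsub("[AT]", "", mt$sequence)) / 25)
})

test_that("ambiguous-base probes are flagged, not fatal", {
  seqs <- c(t1 = paste(rep("ACGTA", 20), collapse = ""))
  probes <- c(p1 = substr(seqs[1], 1, 25),
              p2 = paste0("N", substr(seqs[1], 2, 25)))
  expect_warning(mt <- match_probes(probes, seqs), "ambiguous")
  expect_equal(mt$match_count, c(1L, 0L))
  expect_equal(mt$target_transcript, c("t1", NA))
})

test_that("single-match filter applies the rule", {
  tab <- data.frame(probe_id = c("a", "b", "c", "d"),
                    match_count = c(0L, 1L, 2L, 1L))
  expect_setequal(filter_single_match(tab), c("b", "d"))
  tab$match_count <- 1L
  expect_length(filter_single_match(tab), 4)
})

test_that("gc_adjust: degenerate bin, location equivariance, bias removal", {
  fix <- probe_fixture$fix
  mt <- match_probes(fix$probes, fix$sequences)
  single <- filter_single_match(mt)
  x <- fix$intensity[single, ]

  # all probes same GC -> output == input exactly
  mt_same <- mt
  mt_same$gc_fraction <- 0.5
  expect_equal(gc_adjust(x, mt_same), x)

  # adding c to one sample shifts that sample's output by exactly c
  adj <- gc_adjust(x, mt)
  x_shift <- x
  x_shift[, 3] <- x_shift[, 3] + 1.75
  adj_shift <- gc_adjust(x_shift, mt)
  expect_equal(adj_shift[, 3], adj[, 3] + 1.75)
  expect_equal(adj_shift[, -3], adj[, -3])

  # planted GC bias is removed: per-sample |rho(intensity, gc)| < 0.05
  # (live probes only; dead probes sit at background regardless of GC)
  live <- !fix$probe_info$dead[match(single, fix$probe_info$probe_id)]
  gc <- mt$gc_fraction[match(single, mt$probe_id)]
  rho_post <- apply(adj[live, ], 2, function(v) cor(v, gc[live], method = "spearman"))
  rho_pre <- apply(x[live, ], 2, function(v) cor(v, gc[live], method = "spearman"))
  expect_gt(mean(abs(rho_pre)), 0.1)  # the fixture really is biased
  expect_true(all(abs(rho_post) < 0.05))

  expect_error(gc_adjust(x, mt, n_bins = 1), class = "ageswitch_config_error")
})

test_that("detection filter removes constant, background and dead probes", {
  x <- rbind(const = rep(5, 10),
             good = 8 + c(0.3, -0.4, 0.2, -0.1, 0.5, -0.3, 0.2, -0.2, 0.4, -0.4),
             low = rep(c(0.1, 0.2), 5))
  colnames(x) <- sprintf("s%d", 1:10)
  kept <- detection_filter(x, background_quantile = 0.25, min_sample_fraction = 0.5,
                           min_sd = 0.05)
  expect_true("good" %in% kept)
  expect_false("const" %in% kept)   # SD = 0
  expect_false("low" %in% kept)     # never above background

  # planted dead probes on the synthetic fixture: >= 95% removed
  fix <- probe_fixture$fix
  mt <- match_probes(fix$probes, fix$sequences)
  single <- filter_single_match(mt)
  adj <- gc_adjust(fix$intensity[single, ], mt)
  kept2 <- detection_filter(adj)
  dead <- fix$probe_info$probe_id[fix$probe_info$dead]
  expect_gte(mean(!(intersect(dead, single) %in% kept2)), 0.95)
})

test_that("median polish: convergence invariant and exact additive recovery", {
  set.seed(42)
  x <- outer(rnorm(6), rep(1, 8)) + outer(rep(1, 6), rnorm(8)) + 5
  mp <- median_polish(x)
  expect_true(mp$converged)
  expect_lt(max(abs(apply(mp$residuals, 1, median))), 1e-6)
  expect_lt(max(abs(apply(mp$residuals, 2, median))), 1e-6)

  # probes = abundance + probe offsets, no noise -> recovery up to a constant
  abundance <- rnorm(10, 8, 1)
  offsets <- rnorm(5, 0, 0.5)
  probes <- outer(offsets, abundance, `+`)
  rownames(probes) <- sprintf("p%d", 1:5)
  colnames(probes) <- sprintf("s%d", 1:10)
  out <- summarize_transcripts(probes, list(tx = rownames(probes)))
  est <- out$expression["tx", ]
  expect_equal(est - mean(est), abundance - mean(abundance),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("summarization degenerate cases and dropped reporting", {
  x <- matrix(rnorm(12), 2, 6,
              dimnames = list(c("p1", "p2"), sprintf("s%d", 1:6)))
  # single-probe transcript -> identity
  out1 <- summarize_transcripts(x, list(t1 = "p1"))
  expect_equal(out1$expression["t1", ], x["p1", ], ignore_attr = TRUE)
  expect_equal(out1$median_fallback, "t1")
  # zero-probe transcript -> dropped report
  out2 <- summarize_transcripts(x, list(t1 = c("p1", "p2")),
                                all_transcripts = c("t1", "t2"))
  expect_equal(out2$dropped, "t2")
  expect_error(summarize_transcripts(x, list()), class = "ageswitch_input_error")
  expect_error(summarize_transcripts(x, list(t1 = "nope")),
               class = "ageswitch_input_error")
})

test_that("full pipeline recovers truth and quarantines multi-match probes", {
  fix <- probe_fixture$fix
  q <- quantify_probes(fix$probes, fix$sequences, fix$intensity)

  # per-transcript truth recovery on this small fixture
  shared <- rownames(q$expression)
  r <- vapply(shared, function(t) cor(q$expression[t, ], fix$abundance[t, ]),
              numeric(1))
  expect_gt(median(r), 0.95)

  # taint test: perturbing a multi-match probe leaves the output bit-identical
  mm <- fix$probe_info$probe_id[fix$probe_info$multi_match]
  pert <- fix$intensity
  pert[mm, ] <- pert[mm, ] + rnorm(length(mm) * ncol(pert), 0, 10)
  q2 <- quantify_probes(fix$probes, fix$sequences, pert)
  expect_identical(q$expression, q2$expression)

  # fixed pipeline order regression: quantify_probes == manual staging
  mt <- match_probes(fix$probes, fix$sequences)
  single <- filter_single_match(mt)
  adj <- gc_adjust(fix$intensity[single, ], mt)
  kept <- detection_filter(adj)
  summ <- summarize_transcripts(adj[kept, ], build_template(mt, kept),
                                all_transcripts = names(fix$sequences))
  expect_identical(q$expression, summ$expression)
})
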