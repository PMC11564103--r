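# Generators: determinism, conservation, planted ground truth.

test_that("plate simulation matches the closed-form expected score", {
  expect_equal(expected_pcy_score(
    c(glioblastoma = 0.4, immune = 0.3, other = 0.3),
    c(glioblastoma = 0.5)), 0.375)
  # no effect, no relative reduction
  expect_equal(expected_pcy_score(
    c(glioblastoma = 0.4, immune = 0.3, other = 0.3),
    c(glioblastoma = 1)), 0)

  cfg <- plate_sim_config(
    n_drugs = 1, wells_per_drug = 4, wells_dmso = 8,
    cells_per_well_mean = 3000,
    baseline_composition = c(glioblastoma = 0.4, immune = 0.3, other = 0.3),
    effect_map = tibble::tibble(drug_name = "drug01",
                                population = "glioblastoma", survival = 0.5),
    seed = 11)
  sim <- simulate_plate(cfg)
  truth <- sim$truth$expected_pcy[sim$truth$population == "glioblastoma"]
  expect_equal(truth, 0.375)
  est <- score_drug_responses(classify_populations(sim$cells))
  expect_lt(abs(est$pcy_score - 0.375), 0.05)
})

test_that("plate simulation is deterministic and conserves cells per well", {
  cfg <- plate_sim_config(n_drugs = 2, cells_per_well_mean = 100, seed = 5)
  a <- simulate_plate(cfg)
  b <- simulate_plate(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth, b$truth)
  # population labels partition each well's cells
  per_well <- dplyr::count(a$cells, well_id, population_true)
  totals <- dplyr::count(a$cells, well_id)
  expect_equal(
    dplyr::summarise(dplyr::group_by(per_well, well_id), n = sum(n))$n,
    totals$n)
  # marker gates consistent with the label
  cls <- classify_populations(a$cells)
  expect_true(all(cls$population == cls$population_true))
})

test_that("degenerate plate configurations error", {
  cfg <- plate_sim_config(
    n_drugs = 1,
    baseline_composition = c(glioblastoma = 1, immune = 0, other = 0),
    effect_map = tibble::tibble(drug_name = "drug01",
                                population = "glioblastoma", survival = 0))
  expect_error(simulate_plate(cfg), "empty wells expected")
  expect_error(plate_sim_config(baseline_composition = c(0.5, 0.4, 0.2)),
               "sum to 1")
  expect_error(
    plate_sim_config(effect_map = tibble::tibble(
      drug_name = "d", population = "immune", survival = 1.2)),
    "\\[0, 1\\]")
})

test_that("constellation simulation honours its label law and shape", {
  cfg <- network_sim_config(n_drugs = 40, n_eptg = 400, n_stg = 100,
                            n_planted_stg = 5, n_hits = 10, seed = 2)
  sim <- simulate_constellation(cfg)
  # byte-identical regeneration
  sim2 <- simulate_constellation(cfg)
  expect_identical(sim, sim2)
  # every drug annotated
  expect_setequal(unique(sim$bioactivity$compound_id),
                  sprintf("CPD%05d", 1:40))
  # scores within [0, 1]
  expect_true(all(sim$ppi$score >= 0 & sim$ppi$score <= 1))
  # saturating label law: connectivity >= 1 drugs are hits, others not
  expect_true(all(sim$labels$hit[sim$labels$connectivity >= 1] == 1))
  expect_true(all(sim$labels$hit[sim$labels$connectivity == 0] == 0))
  expect_length(sim$planted, 5)
  # designated drugs all carry planted connectivity
  des <- sim$labels[sim$labels$compound_id %in% sim$designated, ]
  expect_true(all(des$connectivity >= 1))
})

test_that("slope zero gives a pure Bernoulli(b) label marginal", {
  cfg <- network_sim_config(n_drugs = 400, n_eptg = 500, n_stg = 50,
                            n_planted_stg = 2, n_hits = 5,
                            label_slope = 0, label_intercept = 0, seed = 4)
  sim <- simulate_constellation(cfg)
  # sigmoid(0) = 0.5; empirical rate within 3 binomial SDs
  expect_lt(abs(mean(sim$labels$hit) - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("constellation config invariants are enforced", {
  expect_error(network_sim_config(n_planted_stg = 10, n_stg = 5), "<=")
  expect_error(network_sim_config(n_planted_stg = 0, label_slope = 2),
               "label_slope")
})

test_that("expression simulation plants expressing fractions exactly in law", {
  cfg <- expr_sim_config(n_genes = 50, n_cells_per_patient = 1000,
                         n_patients = 2, seed = 9)
  sim <- simulate_expression(cfg)
  expect_identical(sim$counts, simulate_expression(cfg)$counts)
  expect_true(all(sim$counts@x >= 8))  # expressed cells above the tau=3 cut
  fr <- expressing_fractions(sim$counts, sim$metadata, mode = "nonzero")
  pooled <- neural_specificity(fr)
  merged <- dplyr::inner_join(pooled, sim$gene_classes, by = "gene")
  # binomial sampling: estimated fractions near planted probabilities
  neur <- merged[merged$class == "neural_specific", ]
  expect_true(all(abs(neur$fraction_neural - neur$p_neural) < 0.04))
  expect_true(all(neur$fraction_immune == 0))
  silent <- merged[merged$class == "silent", ]
  expect_true(all(silent$fraction_neural == 0 & silent$fraction_immune == 0))
  # threshold and nonzero modes agree by construction
  fr_thr <- expressing_fractions(sim$counts, sim$metadata,
                                 mode = "threshold", tau = 3)
  expect_equal(fr$fraction, fr_thr$fraction)
})

test_that("expression config rejects degenerate inputs", {
  expect_error(expr_sim_config(n_genes = 0), "integer >= 1")
  expect_error(expr_sim_config(p_neural = 1.5), "\\[0, 1\\]")
})

test_that("trace simulation plants oscillators and drug steps", {
  cfg <- trace_sim_config(n_rois = 30, noise_sd = 0, oscillator_fraction = 1,
                          period_s = c(60, 60), amplitude = c(0.5, 0.5),
                          drug_step = 0, n_frames = 301, seed = 3)
  sim <- simulate_traces(cfg)
  expect_identical(sim$traces, simulate_traces(cfg)$traces)
  one <- sim$traces[sim$traces$roi_id == "roi0001", ]
  # noiseless sinusoid over 600 s with a 60 s period: 10 full cycles
  # (an edge peak may fall off the sampled window depending on phase)
  pk <- detect_peaks(one$time_s, one$intensity, min_prominence = 0.2)
  expect_true(nrow(pk) %in% 9:10)
  expect_equal(diff(pk$time_s), rep(60, nrow(pk) - 1), tolerance = 0.05)

  cfg0 <- trace_sim_config(n_rois = 10, oscillator_fraction = 0, seed = 8)
  expect_true(all(!simulate_traces(cfg0)$truth$oscillator))

  # drug step shifts the post-drug latent level
  cfgs <- trace_sim_config(n_rois = 5, oscillator_fraction = 0, noise_sd = 0,
                           drug_step = 0.5, seed = 1)
  sims <- simulate_traces(cfgs)
  tr <- sims$traces[sims$traces$roi_id == "roi0001", ]
  expect_equal(
    mean_drug_response(tr$time_s, tr$intensity, sims$drug_time_s, window_s = 100),
    0.5)
})

test_that("undersampled oscillation periods are rejected", {
  expect_error(trace_sim_config(period_s = c(3, 10), frame_interval_s = 2),
               "undersampled oscillation")
  expect_error(trace_sim_config(drug_frame = 400, n_frames = 300),
               "drug_frame")
})

test_that("dual-channel ratio recovers the latent signal", {
  cfg <- trace_sim_config(n_rois = 4, oscillator_fraction = 0,
                          drug_step = 0.5, noise_sd = 0.01,
                          dual_channel = TRUE, seed = 6)
  sim <- simulate_traces(cfg)
  prep <- fura2_preprocess(sim$traces, drug_time_s = sim$drug_time_s,
                           floor_quantile = 0.001)
  one <- prep$ratio[prep$ratio$roi_id == "roi0001", ]
  pre <- one$ratio[one$time_s < sim$drug_time_s]
  post <- one$ratio[one$time_s > sim$drug_time_s]
  # latent baseline 2, post-drug 2.5: the corrected ratio tracks both
  expect_lt(abs(median(pre, na.rm = TRUE) - 2), 0.05)
  expect_lt(abs(median(post, na.rm = TRUE) - 2.5), 0.05)
})
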