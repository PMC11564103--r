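# Marker gating, population fractions, PCY scores, replicate tests,
# hit calling.

test_that("population definitions match the marker panel", {
  cells <- tibble::tibble(
    cell_id = as.character(1:5), plate_id = "p", well_id = "w",
    drug_name = "DMSO", concentration_um = 0, replicate = 1,
    nestin = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    s100b = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    cd45 = c(FALSE, TRUE, FALSE, TRUE, FALSE))
  cls <- classify_populations(cells)
  # Nestin+ S100B- CD45- -> glioblastoma; CD45+ alone -> immune;
  # triple-negative -> other; Nestin+CD45+ -> unassigned
  expect_equal(cls$population,
               c("glioblastoma", "immune", "other", "unassigned", "glioblastoma"))
  # unassigned cells stay in the denominator
  fr <- population_fractions(cls)
  expect_equal(unique(fr$n_total), 5L)
  expect_equal(sum(fr$fraction), 4 / 5)
})

test_that("strict classification flags overlapping definitions", {
  cells <- tibble::tibble(nestin = TRUE, s100b = FALSE, cd45 = FALSE)
  defs <- population_defs(list(a = ~nestin, b = ~ !cd45))
  expect_error(classify_populations(cells, defs, strict = TRUE), "overlapping")
  expect_equal(classify_populations(cells, defs)$population, "a")
})

test_that("gating modes behave as specified", {
  # pre-gated input passes through
  cells <- tibble::tibble(plate_id = "p", nestin = TRUE, s100b = FALSE,
                          cd45 = FALSE)
  expect_identical(gate_cells(cells), cells)

  # fixed threshold
  raw <- tibble::tibble(plate_id = "p",
                        intensity_nestin = c(400, 600),
                        intensity_s100b = c(1, 2), intensity_cd45 = c(1, 2))
  gated <- gate_cells(raw, method = "fixed",
                      thresholds = c(nestin = 500, s100b = 10, cd45 = 10))
  expect_equal(gated$nestin, c(FALSE, TRUE))

  # bimodal mixture: threshold between the modes, positive fraction ~ 1/2
  set.seed(1)
  n <- 1200
  ints <- c(rnorm(n / 2, log10(100), 0.08), rnorm(n / 2, log10(1000), 0.08))
  raw2 <- tibble::tibble(plate_id = "p", intensity_nestin = 10^ints,
                         intensity_s100b = 10^ints, intensity_cd45 = 10^ints)
  g2 <- gate_cells(raw2, method = "gmm")
  expect_lt(abs(mean(g2$nestin) - 0.5), 0.02)
  thr <- attr(g2, "thresholds")$threshold[1]
  expect_gt(thr, 150)
  expect_lt(thr, 700)

  # degenerate channel errors with its name
  raw3 <- tibble::tibble(plate_id = "p", intensity_nestin = rep(5, 600),
                         intensity_s100b = rexp(600), intensity_cd45 = rexp(600))
  expect_error(gate_cells(raw3, method = "gmm"), "nestin")
})

test_that("PCY score reproduces its defining arithmetic", {
  expect_equal(compute_pcy_score(0, 0.4), 1)       # strongest on-target
  expect_equal(compute_pcy_score(0.4, 0.4), 0)     # no effect
  expect_equal(compute_pcy_score(0.2, 0.4), 0.5)
  expect_equal(compute_pcy_score(0.6, 0.3), -1)    # off-target toxicity
  expect_warning(out <- compute_pcy_score(0.1, 0), "TP_DMSO")
  expect_true(is.na(out))
  expect_error(compute_pcy_score(-0.1, 0.4), "non-negative")
  # monotonicity: score strictly decreasing in TP_DRUG
  scores <- compute_pcy_score(seq(0, 1, 0.1), 0.4)
  expect_true(all(diff(scores) < 0))
})

test_that("pipeline scores equal brute-force recomputation on random tables", {
  for (seed in 1:25) {
    cells <- classify_populations(random_well_table(seed))
    got <- score_drug_responses(cells, adjust = "holm")
    want <- oracle_pcy(cells)
    expect_equal(got$pcy_score[match(want$drug_name, got$drug_name)],
                 want$pcy_score, tolerance = 1e-12)
  }
})

test_that("PCY scores are invariant to rescaling well sizes", {
  cells <- classify_populations(random_well_table(7))
  big <- dplyr::bind_rows(lapply(1:3, function(i) {
    out <- cells
    out$cell_id <- paste0(out$cell_id, "_", i)
    out
  }))
  expect_equal(score_drug_responses(cells)$pcy_score,
               score_drug_responses(big)$pcy_score, tolerance = 1e-12)
})

test_that("apoptosis exclusion barely moves scores when flags are independent", {
  cfg <- plate_sim_config(
    n_drugs = 8, cells_per_well_mean = 800,
    effect_map = tibble::tibble(drug_name = sprintf("drug%02d", 1:8),
                                population = "glioblastoma",
                                survival = seq(0.2, 0.9, 0.1)),
    seed = 21)
  cells <- classify_populations(simulate_plate(cfg, apoptotic_rate = 0.1)$cells)
  with_all <- score_drug_responses(cells)$pcy_score
  without <- score_drug_responses(cells, exclude_apoptotic = TRUE)$pcy_score
  expect_gt(cor(with_all, without), 0.99)
})

test_that("replicate t-test matches a permutation oracle and its symmetries", {
  drug <- c(0.10, 0.11, 0.12, 0.09)
  dmso <- c(0.40, 0.38, 0.41, 0.39)
  p <- test_drug_response(drug, dmso, tails = "one")
  expect_lt(p, 0.001)
  expect_lt(oracle_permutation_p(drug, dmso), 0.05)  # 1/70 split extreme
  # identical groups: one-tailed ~0.5, two-tailed ~1
  same <- c(0.2, 0.25, 0.22, 0.21)
  expect_equal(test_drug_response(same, same, tails = "one"), 0.5)
  expect_equal(test_drug_response(same, same, tails = "two"), 1)
  # swapping groups flips the one-tailed p
  a <- c(0.1, 0.12, 0.14, 0.2)
  b <- c(0.15, 0.18, 0.22, 0.3)
  expect_equal(test_drug_response(a, b, "one") + test_drug_response(b, a, "one"),
               1, tolerance = 1e-10)
  expect_warning(out <- test_drug_response(0.1, dmso), "fewer than 2")
  expect_true(is.na(out))
})

test_that("multiple-testing adjustment follows the size-20 convention", {
  expect_equal(adjust_pvalues(0.04), 0.04)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), method = "bh"),
               c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(c(0.01, 0.04), method = "holm"),
               c(0.02, 0.04))
  # auto switches from Holm to BH at family size 20
  p19 <- seq(0.001, 0.019, length.out = 19)
  p20 <- seq(0.001, 0.020, length.out = 20)
  expect_equal(adjust_pvalues(p19), p.adjust(p19, "holm"))
  expect_equal(adjust_pvalues(p20), p.adjust(p20, "BH"))
  expect_error(adjust_pvalues(c(0.1, Inf)), "finite")
})

test_that("hit calls apply the score and q thresholds", {
  resp <- tibble::tibble(pcy_score = c(0.2, 0.2, -0.1, 0.3),
                         q_value = c(0.01, 0.2, 0.01, NA))
  out <- call_hits(resp, "sample")
  expect_equal(out$on_target_hit, c(TRUE, FALSE, FALSE, FALSE))
  cohort <- tibble::tibble(
    drug_name = rep(c("a", "b"), each = 3),
    patient_id = rep(1:3, 2),
    pcy_score = c(0.05, 0.02, 0.023, 0.05, 0.02, 0.017))
  ch <- call_hits(cohort, "cohort")
  # mean 0.031 -> hit; 0.029 -> not
  expect_equal(ch$cohort_hit, c(TRUE, FALSE))
})

test_that("viability score is the relative reduction of well totals", {
  expect_equal(viability_score(500, 1000), 0.5)
  expect_equal(viability_score(c(10, 10), c(10, 10)), 0)
  expect_equal(viability_score(c(4, 6), c(10, 10)), 0.5)
  expect_warning(out <- viability_score(5, 0), "undefined")
  expect_true(is.na(out))
})
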