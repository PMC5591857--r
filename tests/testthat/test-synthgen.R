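test_that("config validation names the offending field", {
  expect_error(cohort_config(n_birds = c(5)), "n_birds")
  expect_error(cohort_config(n_birds = c(a = 0)), "n_birds")
  expect_error(cohort_config(trials_per_song = 6), "trials_per_song")
  expect_error(cohort_config(novel_slope_pct = 1), "novel_slope_pct")
  expect_error(cohort_config(novel_slope_pct = -15), "novel_slope_pct")
  expect_error(cohort_config(noise_cv = -0.1), "noise_cv")
  expect_error(cohort_config(fi_true = -1), "fi_true")
  expect_error(
    cohort_config(fi_true = tibble::tibble(group = "nope", hemisphere = "left",
                                           region = "NCM", fi = 1.2)),
    "fi_true"
  )
})

test_that("same config and seed give bit-identical cohorts", {
  cfg <- tiny_config(noise_cv = 0.2)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("adding birds does not perturb existing birds' data", {
  small <- cohort_config(n_birds = c(hdac3i = 2), seed = 7,
                         electrodes_per_hemisphere_nonncm = 0)
  large <- cohort_config(n_birds = c(hdac3i = 4), seed = 7,
                         electrodes_per_hemisphere_nonncm = 0)
  t_small <- generate_cohort(small)$trials
  t_large <- generate_cohort(large)$trials
  shared <- dplyr::semi_join(t_large, dplyr::distinct(t_small["bird"]),
                             by = "bird")
  expect_equal(as.data.frame(shared), as.data.frame(t_small))
})

test_that("null effect with zero noise yields identical slopes and FI = 1", {
  cfg <- tiny_config(noise_cv = 0, fi_true = 1)
  ch <- generate_cohort(cfg)
  rates <- fit_ssa_rates(ch$trials)
  expect_equal(rates$rate, rep(cfg$novel_slope_pct, nrow(rates)))
  fi <- compute_fi(rates)
  expect_equal(fi$fi, rep(1, nrow(fi)))
})

test_that("configured cell FI halves the familiar slope exactly", {
  cfg <- cohort_config(
    n_birds = c(hdac3i = 2, vehicle = 1), noise_cv = 0, seed = 5,
    fi_true = tibble::tibble(group = "hdac3i", hemisphere = "left",
                             region = "NCM", fi = 2)
  )
  ch <- generate_cohort(cfg)
  gt <- ch$ground_truth$series_slope
  drug_left <- gt[gt$group == "hdac3i" & gt$hemisphere == "left" &
                    gt$region == "NCM", ]
  fam <- drug_left$slope_abs[drug_left$stim_class == "F"]
  nov <- drug_left$slope_abs[drug_left$stim_class == "N"]
  expect_equal(mean(fam) * 2, mean(nov))
  # downstream: all left-NCM drug FI exactly 2, all other cells exactly 1
  pooled <- pool_fi(compute_fi(fit_ssa_rates(ch$trials)))
  expect_equal(pooled$median_fi[pooled$group == "hdac3i" &
                                  pooled$hemisphere == "left" &
                                  pooled$region == "NCM"], 2)
  expect_equal(max(abs(pooled$median_fi[!(pooled$group == "hdac3i" &
                                            pooled$hemisphere == "left" &
                                            pooled$region == "NCM")] - 1)),
               0, tolerance = 1e-12)
})

test_that("zero-noise OLS slopes equal ground-truth slopes to numerical precision", {
  cfg <- tiny_config(noise_cv = 0,
                     fi_true = tibble::tibble(group = "hdac3i",
                                              hemisphere = "left",
                                              region = "NCM", fi = 1.19))
  ch <- generate_cohort(cfg)
  rates <- fit_ssa_rates(ch$trials)
  keys <- c("bird", "group", "hemisphere", "region", "site", "set",
            "stimulus", "stim_class")
  m <- dplyr::inner_join(rates, ch$ground_truth$series_slope, by = keys)
  expect_equal(nrow(m), nrow(rates))
  expect_equal(m$rate, m$rate_pct, tolerance = 1e-12)
  expect_equal(100 * m$slope_abs / m$mean_magnitude, m$rate_pct,
               tolerance = 1e-12)
})

test_that("trial noise has the configured coefficient of variation", {
  cfg <- cohort_config(n_birds = c(hdac3i = 6), noise_cv = 0.15, seed = 21,
                       electrodes_per_hemisphere_nonncm = 0)
  ch <- generate_cohort(cfg)
  noiseless <- generate_cohort(cohort_config(
    n_birds = c(hdac3i = 6), noise_cv = 0, seed = 21,
    electrodes_per_hemisphere_nonncm = 0
  ))
  ratio <- ch$trials$magnitude / noiseless$trials$magnitude
  expect_equal(mean(ratio), 1, tolerance = 0.01)
  expect_equal(stats::sd(ratio) / mean(ratio), 0.15, tolerance = 0.02)
})

test_that("qPCR generator encodes fold changes in CT space", {
  fc <- tibble::tibble(group = "hdac3i", hemisphere = "left", region = "NCM",
                       gene = "zenk", fold = 2)
  ct <- generate_qpcr(fold_changes = fc, noise_sd = 0, seed = 1)
  rel <- delta_delta_ct(ct)
  hit <- rel$group == "hdac3i" & rel$hemisphere == "left" &
    rel$region == "NCM" & rel$gene == "zenk"
  expect_equal(rel$rel_expression[hit], rep(200, sum(hit)))
  expect_equal(rel$rel_expression[!hit], rep(100, sum(!hit)))
  # fold 1 everywhere, zero noise: 100% in every cell
  rel0 <- delta_delta_ct(generate_qpcr(noise_sd = 0, seed = 1))
  expect_equal(rel0$rel_expression, rep(100, nrow(rel0)))
  # determinism under noise
  expect_identical(generate_qpcr(noise_sd = 0.4, seed = 9),
                   generate_qpcr(noise_sd = 0.4, seed = 9))
  expect_error(generate_qpcr(fold_changes = dplyr::mutate(fc, fold = -1)),
               "fold_changes")
})
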