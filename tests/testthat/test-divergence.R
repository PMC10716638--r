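test_that("pointwise t statistics match hand arithmetic and conventions", {
  P <- rbind(c(0.6, 0.5, 0.6, 0.5),
             c(0.7, 0.5, 0.6, 0.5),
             c(0.8, 0.5, 0.6, NA),
             c(0.5, 0.5, 0.6, NA))
  colnames(P) <- c(0, 50, 100, 150)
  res <- pointwise_tests(P)

  # x = {0.6, 0.7, 0.8, 0.5}: t = 0.15 / (s/sqrt(4)), df = 3
  x <- c(0.6, 0.7, 0.8, 0.5)
  expect_equal(res$t[1], (mean(x) - 0.5) / (sd(x) / 2), tolerance = 1e-10)
  expect_equal(res$p[1], 2 * pt(-res$t[1], df = 3), tolerance = 1e-10)
  expect_equal(res$t[1], 2.3238, tolerance = 1e-4)
  expect_equal(res$p[1], 0.1027, tolerance = 1e-3)
  expect_equal(res$n[1], 4L)

  # all values exactly at the null
  expect_equal(res$t[2], 0)
  expect_equal(res$p[2], 1)

  # constant non-null values: zero variance convention
  expect_equal(res$t[3], Inf)
  expect_equal(res$p[3], 0)

  # two defined values remain testable
  expect_equal(res$n[4], 2L)
})

test_that("untestable bins are flagged and an empty analysis errors", {
  P <- rbind(c(0.6, NA), c(0.7, 0.4))
  colnames(P) <- c(0, 50)
  res <- pointwise_tests(P)
  expect_true(is.na(res$t[2]))
  expect_equal(res$n[2], 1L)

  P_bad <- rbind(c(0.6, NA), c(NA, 0.4))
  colnames(P_bad) <- c(0, 50)
  expect_error(pointwise_tests(P_bad), "two or more")
})

test_that("onset detection follows the run-length rule", {
  bins <- seq(0, 1450, by = 50)
  crit <- onset_criterion()

  p <- rep(0.5, 30)
  p[bins >= 450] <- 0.01
  expect_equal(detect_onset(setNames(p, bins), crit), 450)

  expect_true(is.na(detect_onset(setNames(rep(0.5, 30), bins), crit)))

  # a 9-bin run, a gap, then a 12-bin run: the 12-run's first bin wins
  p <- rep(0.5, 30)
  p[3:11] <- 0.01          # 9 bins, too short
  p[14:25] <- 0.01         # 12 bins
  expect_equal(detect_onset(setNames(p, bins), crit), bins[14])

  # NA p-values break runs like non-significant bins
  p <- rep(0.5, 30)
  p[3:30] <- 0.01
  p[12] <- NA              # splits into runs of 9 and 18
  expect_equal(detect_onset(setNames(p, bins), crit), bins[13])

  expect_error(onset_criterion(run_length = 10, window = c(0, 400)),
               "fewer than run_length")
  expect_error(detect_onset(setNames(rep(0.01, 5), bins[1:5]),
                            onset_criterion(window = c(0, 1500))),
               "fewer than run_length")
})

test_that("significance is strict inequality at alpha", {
  bins <- seq(0, 1450, by = 50)
  p <- rep(0.05, 30)
  expect_true(is.na(detect_onset(setNames(p, bins), onset_criterion())))
  p <- rep(0.04999, 30)
  expect_equal(detect_onset(setNames(p, bins), onset_criterion()), 0)
})

test_that("onset detection agrees with brute force on random patterns", {
  crit <- onset_criterion(run_length = 3, window = c(0, 600), bin_ms = 50)
  bins <- seq(0, 550, by = 50)
  set.seed(77)
  for (i in 1:200) {
    sig <- runif(12) < 0.4
    p <- ifelse(sig, 0.01, 0.5)
    got <- detect_onset(setNames(p, bins), crit)
    want_idx <- brute_onset_index(sig, 3)
    want <- if (is.na(want_idx)) NA_real_ else bins[want_idx]
    expect_identical(got, want)
  }
})

test_that("the bootstrap is reproducible and stays on the bin lattice", {
  exp <- tiny_experiment(seed = 17)
  sel <- select_trials(exp$table, "all_gendered")
  boot <- bootstrap_config(n_boot = 60, seed = 123)
  r1 <- bootstrap_divergence(sel, "targets_vs_distractors", boot = boot)
  r2 <- bootstrap_divergence(sel, "targets_vs_distractors", boot = boot)
  expect_identical(r1$boot_onsets, r2$boot_onsets)
  expect_identical(r1$mean_divergence_ms, r2$mean_divergence_ms)

  lattice <- seq(0, 1450, by = 50)
  detected <- r1$boot_onsets[!is.na(r1$boot_onsets)]
  expect_true(all(detected %in% lattice))
  if (length(detected)) {
    expect_true(r1$ci_low_ms %in% lattice)
    expect_true(r1$ci_high_ms %in% lattice)
    expect_true(r1$ci_low_ms <= r1$mean_divergence_ms)
    expect_true(r1$mean_divergence_ms <= r1$ci_high_ms)
    expect_true(r1$mean_divergence_ms >= 0 && r1$mean_divergence_ms < 1500)
  }
})

test_that("a stronger preference never delays detection (fixed seeds)", {
  onset_at <- function(pref, seed) {
    cfg <- sim_config(asymptote_pref = pref)
    tab <- simulate_gaze(build_design(cfg, seed = seed), cfg,
                         seed = seed + 1L)$table
    sel <- select_trials(tab, "all_gendered")
    detect_onset(pointwise_tests(proportion_curves(sel,
      "targets_vs_distractors")), onset_criterion())
  }
  for (seed in c(101, 202)) {
    weak <- onset_at(0.65, seed)
    strong <- onset_at(0.9, seed)
    expect_false(is.na(strong))
    if (!is.na(weak)) expect_lte(strong, weak)
  }
})

test_that("the strict-literal per-bin resampling mode runs", {
  exp <- tiny_experiment(seed = 19)
  sel <- select_trials(exp$table, "all_gendered")
  res <- bootstrap_divergence(sel, "targets_vs_distractors",
                              boot = bootstrap_config(n_boot = 10, seed = 5,
                                                      literal_bins = TRUE))
  expect_s3_class(res, "divergence_result")
  detected <- res$boot_onsets[!is.na(res$boot_onsets)]
  expect_true(all(detected %in% seq(0, 1450, by = 50)))
})

test_that("run_contrast exposes the five study analyses by name", {
  exp <- tiny_experiment(seed = 23)
  plan <- list(
    list("compatible_vs_incompatible", "all_gendered"),
    list("compatible_vs_incompatible", "gender_match"),
    list("compatible_vs_incompatible", "gender_mismatch"),
    list("targets_vs_distractors", "all_gendered"),
    list("targets_vs_distractors", "neutral")
  )
  for (p in plan) {
    res <- run_contrast(exp$table, p[[1]], p[[2]],
                        boot = bootstrap_config(n_boot = 8, seed = 3))
    expect_s3_class(res, "divergence_result")
    expect_equal(res$subset, p[[2]])
    expect_equal(res$contrast, p[[1]])
  }
})

test_that("an egocentric generator makes the compatible contrast diverge", {
  cfg <- sim_config(egocentric_effect = 0.2)
  tab <- simulate_gaze(build_design(cfg, seed = 71), cfg, seed = 72)$table
  res <- run_contrast(tab, "compatible_vs_incompatible", "all_gendered",
                      boot = bootstrap_config(n_boot = 40, seed = 7))
  expect_false(is.na(res$onset_ms))
  expect_gt(res$detection_rate, 0.9)
  expect_lt(abs(res$mean_divergence_ms - 500), 200)
})

test_that("stage failures carry the stage name", {
  exp <- tiny_experiment(seed = 29)
  gendered_only <- exp$table[exp$table$item_type == "gendered", ]
  expect_error(run_contrast(gendered_only, "targets_vs_distractors",
                            "neutral"),
               "select_trials")
  expect_error(run_contrast(exp$table, "compatible_vs_incompatible",
                            "neutral"),
               "bootstrap_divergence")
})
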