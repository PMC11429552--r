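test_that("colored noise is unit-variance, zero-mean and deterministic", {
  x <- colored_noise(4096, 1, seed = 5)
  expect_lt(abs(var(x) - 1), 1e-6)
  expect_lt(abs(mean(x)), 1e-12)
  expect_identical(x, colored_noise(4096, 1, seed = 5))
  expect_false(identical(x, colored_noise(4096, 1, seed = 6)))
  expect_error(colored_noise(32, 1), ">= 64")
  expect_error(colored_noise(1024, 2.5), "exponent")
})

test_that("white-noise Hurst estimates land in the unbiased band and grow with the spectral slope", {
  h0 <- h05 <- h15 <- numeric(50)
  for (s in 1:50) {
    h0[s] <- hurst_rs_oracle(colored_noise(4096, 0, seed = s))
    h05[s] <- hurst_rs_oracle(colored_noise(2048, 0.5, seed = s))
    h15[s] <- hurst_rs_oracle(colored_noise(2048, 1.5, seed = s))
  }
  expect_gt(mean(h0), 0.4)
  expect_lt(mean(h0), 0.6)
  expect_gt(mean(h15), mean(h05))
})

test_that("generated epoch sets have the requested size, balance and determinism", {
  cfg <- generator_config(n_participants = 3, trials_per_class = 10, seed = 4)
  run <- generate_epochs(cfg)
  expect_equal(n_epochs(run$epochs), 60)
  tab <- table(run$epochs$labels)
  expect_equal(unname(tab["haptic"]), unname(tab["non_haptic"]))
  for (p in 1:3) {
    sub <- run$epochs$labels[run$epochs$participant_ids == p]
    expect_equal(sum(sub == "haptic"), 10)
  }
  expect_true(all(is.finite(run$epochs$data)))
  run2 <- generate_epochs(cfg)
  expect_identical(run$epochs$data, run2$epochs$data)
})

test_that("malformed planted effects are rejected with the offending token", {
  expect_error(planted_effect("XX_13-21Hz_Hurst", "non_haptic_higher",
                              "slope_tilt"), "XX")
  expect_error(planted_effect("Cz_13-22Hz_Hurst", "non_haptic_higher",
                              "slope_tilt"), "13-22Hz")
  expect_error(planted_effect("Cz_13-21Hz_Wavelet", "non_haptic_higher",
                              "slope_tilt"), "Wavelet")
  expect_error(planted_effect("Cz_13-21Hz_Hurst", intended_d = -1), "intended_d")
})

test_that("without planted effects the feature p-values are approximately uniform", {
  cfg <- generator_config(n_participants = 5, trials_per_class = 30, seed = 12)
  run <- generate_epochs(cfg)
  tab <- extract_feature_table(band_decompose(run$epochs))
  y <- tab$label
  ps <- vapply(feature_columns(tab), function(f) {
    mwu_test(tab[[f]][y == "haptic"], tab[[f]][y == "non_haptic"])$p.value
  }, numeric(1))
  frac <- mean(ps < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.09)
})

test_that("verify_manifest recovers the planted directions on a small strong run", {
  cfg <- generator_config(n_participants = 6, trials_per_class = 25,
                          preset = "strong", seed = 8)
  run <- generate_epochs(cfg)
  man <- verify_manifest(run$epochs, run$manifest)
  expect_true(all(is.finite(man$realized_d)))
  for (i in seq_along(man$effects)) {
    e <- man$effects[[i]]
    if (e$direction == "non_haptic_higher") {
      expect_gt(man$realized_d[i], 0)
    } else {
      expect_lt(man$realized_d[i], 0)
    }
  }
  # every planted effect should be substantial at 300 epochs
  expect_true(all(abs(man$realized_d) > 0.5))
})

test_that("a single strong band-gain effect dominates all 360 features", {
  eff <- list(planted_effect("Cz_21-30Hz_Activity", "non_haptic_higher",
                             "band_gain", intended_d = 2.4, magnitude = 0.45))
  cfg <- generator_config(n_participants = 15, trials_per_class = 20,
                          effects = eff, seed = 13)
  run <- generate_epochs(cfg)
  tab <- extract_feature_table(band_decompose(run$epochs))
  ds <- vapply(feature_columns(tab), function(f) abs(table_cohens_d(tab, f)),
               numeric(1))
  expect_identical(names(which.max(ds)), "Cz_21-30Hz_Activity")
})

test_that("planting effects leaves untouched channels at chance (effect locality)", {
  tab <- strong_table()
  touched <- c("Pz", "Fz", "Cz", "P4", "C3")
  quiet <- setdiff(analysis_channels(), touched)
  cols <- grep(paste0("^(", paste(quiet, collapse = "|"), ")_"),
               feature_columns(tab), value = TRUE)
  expect_length(cols, 160)
  ds <- vapply(cols, function(f) abs(table_cohens_d(tab, f)), numeric(1))
  expect_lt(max(ds), 0.15)
})
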