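test_that("Hjorth parameters match their definitions and degrade gracefully", {
  hp <- hjorth_params(c(0, 1, 2, 3))
  expect_equal(hp$activity, 1.25)
  const <- hjorth_params(rep(2, 100))
  expect_equal(c(const$activity, const$mobility, const$complexity), c(0, 0, 0))
  expect_true(const$degenerate)
  # discrete sinusoid: mobility tends to the per-sample angular frequency
  fs <- 1024
  s <- sin(2 * pi * 10 * seq_len(8192) / fs)
  expect_lt(abs(hjorth_params(s)$mobility - 2 * pi * 10 / fs) /
              (2 * pi * 10 / fs), 0.02)
})

test_that("permutation entropy spans [0, log 3!] with the documented conventions", {
  expect_equal(permutation_entropy(1:200), 0)
  set.seed(2)
  expect_lt(abs(permutation_entropy(rnorm(4096)) - log(6)), 0.05)
  for (s in 1:20) {
    x <- rnorm(128)
    expect_lte(permutation_entropy(x), log(6) + 1e-12)
  }
  expect_error(permutation_entropy(rnorm(100), order = 1), "order")
})

test_that("Higuchi fractal dimension separates smooth lines from noise and stays in [1,2]", {
  line <- seq(0, 1, length.out = 2048)
  expect_lte(as.numeric(higuchi_fd(line)), 1.05)
  set.seed(3)
  expect_gte(as.numeric(higuchi_fd(rnorm(4096))), 1.85)
  for (s in 1:20) {
    v <- as.numeric(higuchi_fd(colored_noise(512, runif(1, 0, 2), seed = s)))
    expect_gte(v, 1); expect_lte(v, 2)
  }
  expect_error(higuchi_fd(rnorm(2048), kmax = 1), "kmax")
  expect_error(higuchi_fd(rnorm(50)), "length")
})

test_that("rescaled-range Hurst behaves for white noise, random walks, and stays in [0,1]", {
  h_white <- h_walk <- numeric(50)
  for (s in 1:50) {
    w <- with(list(), {set.seed(s); rnorm(2048)})
    h_white[s] <- as.numeric(hurst_exponent(w))
    h_walk[s] <- as.numeric(hurst_exponent(cumsum(w)))
  }
  expect_gte(mean(h_white), 0.45)
  expect_lte(mean(h_white), 0.62)
  expect_true(all(h_walk > h_white))
  expect_true(all(h_white >= 0 & h_white <= 1))
  const <- hurst_exponent(rep(1, 256))
  expect_equal(as.numeric(const), 0.5)
  expect_true(attr(const, "degenerate"))
})

test_that("band power matches the flat one-sided density for white noise and concentrates for sines", {
  fs <- 1024
  expect_equal(band_power(rep(0, 2048), fs, "low_beta"), 0)
  lev <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    lev[s] <- band_power(rnorm(4096), fs, list(lo = 1, hi = 511))
  }
  expect_lt(abs(mean(lev) - 2 / fs) / (2 / fs), 0.15)
  tt <- seq_len(4096) / fs
  s17 <- sin(2 * pi * 17 * tt)
  expect_gt(band_power(s17, fs, "low_beta"),
            100 * band_power(s17, fs, "high_beta"))
})

test_that("spectral entropy is low for narrowband, high for broadband, zero when degenerate", {
  fs <- 1024
  tt <- seq_len(2048) / fs
  expect_lte(as.numeric(spectral_entropy(sin(2 * pi * 17 * tt), fs, "low_beta")), 0.5)
  set.seed(4)
  expect_gte(as.numeric(spectral_entropy(rnorm(8192), fs, "low_beta")), 0.9)
  z <- spectral_entropy(rep(0, 2048), fs, "low_beta")
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
})

test_that("skewness and kurtosis follow the population g1/g2 conventions", {
  m <- signal_moments(c(-1, 0, 1, -1, 0, 1))
  expect_equal(m$skewness, 0)
  set.seed(5)
  g <- rnorm(1e5)
  mg <- signal_moments(g)
  expect_lt(abs(mg$kurtosis), 0.1)
  expect_gt(signal_moments(c(0, 0, 0, 10))$skewness, 0)
  # agreement with an established implementation (population moments)
  x <- rexp(500)
  expect_equal(signal_moments(x)$skewness, e1071::skewness(x, type = 1),
               tolerance = 1e-12)
  expect_equal(signal_moments(x)$kurtosis, e1071::kurtosis(x, type = 1),
               tolerance = 1e-12)
})

test_that("the feature table has the full named grid and is row-stable", {
  ep <- make_small_epochs(8, n = 1024, seed = 6)
  bands <- band_decompose(ep)
  tab <- extract_feature_table(bands)
  expect_s3_class(tab, "feature_table")
  expect_length(feature_columns(tab), 360)
  expect_true(all(vapply(tab[feature_columns(tab)], function(c)
    all(is.finite(c)), logical(1))))
  # single channel x single band -> 10 columns
  one <- lapply(bands["low_beta"], function(b) select_channels(b, "Cz"))
  tab1 <- extract_feature_table(one)
  expect_length(feature_columns(tab1), 10)
  # permuting epochs permutes rows identically
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  permuted <- lapply(bands, function(b) {
    eeg_epochs(b$data[perm, , , drop = FALSE], b$fs, b$channel_names,
               b$labels[perm], b$participant_ids[perm])
  })
  tab_p <- extract_feature_table(permuted)
  expect_equal(as.matrix(tab_p[feature_columns(tab_p)]),
               as.matrix(tab[feature_columns(tab)])[perm, ],
               ignore_attr = TRUE)
})

test_that("feature values scale as dimensional analysis dictates", {
  set.seed(7)
  x <- colored_noise(2048, 1)
  c0 <- 3.7
  expect_equal(hjorth_params(c0 * x)$activity, c0^2 * hjorth_params(x)$activity,
               tolerance = 1e-10)
  expect_equal(hjorth_params(c0 * x)$mobility, hjorth_params(x)$mobility,
               tolerance = 1e-8)
  expect_equal(hjorth_params(c0 * x)$complexity, hjorth_params(x)$complexity,
               tolerance = 1e-8)
  expect_equal(permutation_entropy(c0 * x), permutation_entropy(x),
               tolerance = 1e-8)
  expect_equal(as.numeric(spectral_entropy(c0 * x, 1024, "low_beta")),
               as.numeric(spectral_entropy(x, 1024, "low_beta")),
               tolerance = 1e-8)
  expect_equal(signal_moments(c0 * x)$skewness, signal_moments(x)$skewness,
               tolerance = 1e-8)
  expect_equal(signal_moments(c0 * x)$kurtosis, signal_moments(x)$kurtosis,
               tolerance = 1e-8)
})

test_that("feature names round-trip across the full 9 x 4 x 10 grid", {
  for (ch in analysis_channels()) {
    for (bl in band_definitions()$label) {
      for (ft in feature_names()) {
        name <- format_feature_name(ch, bl, ft)
        parsed <- parse_feature_name(name, channels = analysis_channels())
        expect_identical(parsed$channel, ch)
        expect_identical(parsed$band_label, bl)
        expect_identical(parsed$feature, ft)
      }
    }
  }
  expect_error(parse_feature_name("Cz_13-21Hz_NotAFeature"), "NotAFeature")
  expect_error(format_feature_name("C_z", "13-21Hz", "Hurst"), "underscore")
})

test_that("the DFA alternative tracks the R/S estimate for canonical noise classes", {
  h_w <- h_p <- numeric(20)
  for (s in 1:20) {
    h_w[s] <- as.numeric(hurst_exponent(colored_noise(2048, 0, seed = s),
                                        method = "dfa"))
    h_p[s] <- as.numeric(hurst_exponent(colored_noise(2048, 1.5, seed = s),
                                        method = "dfa"))
  }
  expect_gt(mean(h_w), 0.35)
  expect_lt(mean(h_w), 0.65)
  expect_gt(mean(h_p), mean(h_w))
  const <- hurst_exponent(rep(3, 256), method = "dfa")
  expect_equal(as.numeric(const), 0.5)
  expect_true(attr(const, "degenerate"))
})
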