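#' A planted class effect
#'
#' Describes one class difference the synthetic generator plants: which
#' feature it targets (\code{Channel_Band_Feature}), which class has the
#' higher mean, by which mechanism it is produced, and the intended effect
#' size (Cohen's d).
#'
#' Mechanisms:
#' \describe{
#'   \item{band_gain}{multiplicative gain on the in-band spectral component of
#'     the higher class; drives Activity and PSD. \code{magnitude} is the
#'     fractional amplitude gain g (power gain \code{(1+g)^2}).}
#'   \item{burst_amplitude}{sparse Gaussian-windowed band-limited bursts added
#'     to the higher class; drives kurtosis. \code{magnitude} is the burst
#'     amplitude in units of the background in-band RMS.}
#'   \item{slope_tilt}{power-preserving within-band shape change of the
#'     signal, driving the Hurst / spectral-entropy feature family. For
#'     Spectral_Ent targets: a Gaussian concentration (strength
#'     \code{magnitude}) of the \emph{lower} class's in-band spectrum, which
#'     narrows its effective bandwidth and lowers its entropy (and, mildly,
#'     its Hurst exponent). For Hurst (and other) targets: slow-envelope
#'     amplitude modulation (depth \code{magnitude}) of the \emph{higher}
#'     class's in-band component, which lengthens the band-limited signal's
#'     temporal persistence and raises its rescaled-range Hurst exponent
#'     while leaving expected band power unchanged. A pure within-band
#'     spectral tilt cannot reach per-feature effect sizes near d = 1.5 for
#'     R/S Hurst on 2 s band-limited epochs, which is why the Hurst knob
#'     acts on the temporal envelope instead.}
#' }
#'
#' @param feature_name Target feature, e.g. \code{"Pz_13-21Hz_Hurst"}. Must
#'   parse against the 9-channel x 4-band x 10-feature grid.
#' @param direction \code{"non_haptic_higher"} or \code{"haptic_higher"}.
#' @param mechanism \code{"band_gain"}, \code{"burst_amplitude"} or
#'   \code{"slope_tilt"}.
#' @param intended_d Target Cohen's d (> 0).
#' @param magnitude Mechanism parameter; when NULL it is derived from
#'   \code{intended_d} via mechanism-specific calibration constants.
#' @return An object of class \code{planted_effect}.
#' @export
planted_effect <- function(feature_name,
                           direction = c("non_haptic_higher", "haptic_higher"),
                           mechanism = c("band_gain", "burst_amplitude", "slope_tilt"),
                           intended_d = 1,
                           magnitude = NULL) {
  direction <- match.arg(direction)
  mechanism <- match.arg(mechanism)
  parsed <- parse_feature_name(feature_name, channels = analysis_channels())
  if (!parsed$band_label %in% band_definitions()$label)
    stopf("unknown band token '%s' in '%s'", parsed$band_label, feature_name)
  if (!is.numeric(intended_d) || intended_d <= 0)
    stopf("`intended_d` must be > 0")
  if (is.null(magnitude))
    magnitude <- default_magnitude_scale(mechanism, parsed$feature, intended_d)
  structure(
    list(feature_name = feature_name, channel = parsed$channel,
         band_label = parsed$band_label, feature = parsed$feature,
         direction = direction, mechanism = mechanism,
         magnitude = magnitude, intended_d = intended_d),
    class = "planted_effect"
  )
}

# Empirical magnitude -> realized-d response curves per mechanism, measured
# on the default generator settings (beta = 1, 2 s epochs at 1024 Hz, 600
# epochs, single effect); see the methods vignette. Inverted by
# interpolation to derive a default magnitude from an intended d.
calibration_curves <- function() {
  list(
    band_gain = list(mag = c(0, 0.05, 0.1, 0.15, 0.2, 0.3, 0.45),
                     d = c(0, 0.33, 0.66, 0.97, 1.25, 1.77, 2.4)),
    burst_amplitude = list(mag = c(0, 6, 8, 10, 12),
                           d = c(0, 0.85, 1.53, 2.26, 3.05)),
    tilt_entropy = list(mag = c(0, 0.5, 1, 2, 3, 4, 6),
                        d = c(0, 0.75, 1.48, 2.78, 3.79, 4.62, 5.97)),
    tilt_hurst = list(mag = c(0, 0.3, 0.5, 0.7, 0.9, 1.2, 1.6),
                      d = c(0, 0.26, 0.63, 1.02, 1.38, 1.84, 2.25))
  )
}

default_magnitude_scale <- function(mechanism, feature, intended_d) {
  key <- switch(mechanism,
                band_gain = "band_gain",
                burst_amplitude = "burst_amplitude",
                slope_tilt = if (identical(feature, "Spectral_Ent"))
                  "tilt_entropy" else "tilt_hurst")
  cv <- calibration_curves()[[key]]
  as.numeric(stats::approx(cv$d, cv$mag, xout = min(intended_d, max(cv$d)),
                           rule = 2)$y)
}

#' Planted effects of the moderate/strong presets
#'
#' The ten class effects the presets plant: low-beta Hurst at Pz, Fz, Cz and
#' P4; high-beta kurtosis, PSD and activity at Cz; and low-beta spectral
#' entropy at C3, Cz and Pz. All are higher in the non-haptic class except C3
#' low-beta spectral entropy, which is higher in the haptic class. The strong
#' preset targets d = 1.5 per feature, the moderate preset d = 0.6.
#'
#' Effects whose mechanisms overlap at one channel/band cell are calibrated
#' jointly so every planted feature realizes close to its intended d: the
#' two Cz high-beta band-gain effects split one gain (and leave room for the
#' power the kurtosis bursts add), and at Cz/Pz low beta the
#' envelope-modulation and concentration knobs are reduced to compensate for
#' each other's cross effect on Hurst and spectral entropy.
#'
#' @param preset \code{"strong"} or \code{"moderate"}.
#' @return List of \code{\link{planted_effect}} objects.
#' @export
preset_effects <- function(preset = c("strong", "moderate")) {
  preset <- match.arg(preset)
  d <- if (preset == "strong") 1.5 else 0.6
  nh <- "non_haptic_higher"
  mag <- function(mech, feat, dd) default_magnitude_scale(mech, feat, dd)
  # joint-calibration deductions (see methods vignette): at shared cells the
  # companion knob contributes part of the effect, so each knob targets the
  # remainder of the intended d
  a_solo <- mag("slope_tilt", "Hurst", d * 0.92)
  a_shared <- mag("slope_tilt", "Hurst", d * 0.76)
  k_solo <- mag("slope_tilt", "Spectral_Ent", d)
  k_shared <- mag("slope_tilt", "Spectral_Ent", d * 1.2)
  # the two stacked band gains jointly top up the part of the power effect
  # that the kurtosis bursts at the same cell do not already provide
  g_joint <- mag("band_gain", "PSD", d * 0.12)
  g_half <- sqrt(1 + g_joint) - 1
  list(
    planted_effect("Pz_13-21Hz_Hurst", nh, "slope_tilt", intended_d = d,
                   magnitude = a_shared),
    planted_effect("Fz_13-21Hz_Hurst", nh, "slope_tilt", intended_d = d,
                   magnitude = a_solo),
    planted_effect("Cz_13-21Hz_Hurst", nh, "slope_tilt", intended_d = d,
                   magnitude = a_shared),
    planted_effect("P4_13-21Hz_Hurst", nh, "slope_tilt", intended_d = d,
                   magnitude = a_solo),
    planted_effect("Cz_21-30Hz_Kurtosis", nh, "burst_amplitude", intended_d = d,
                   magnitude = mag("burst_amplitude", "Kurtosis", d * 1.1)),
    planted_effect("Cz_21-30Hz_PSD", nh, "band_gain", intended_d = d,
                   magnitude = g_half),
    planted_effect("Cz_21-30Hz_Activity", nh, "band_gain", intended_d = d,
                   magnitude = g_half),
    planted_effect("C3_13-21Hz_Spectral_Ent", "haptic_higher", "slope_tilt",
                   intended_d = d, magnitude = k_solo),
    planted_effect("Cz_13-21Hz_Spectral_Ent", nh, "slope_tilt", intended_d = d,
                   magnitude = k_shared),
    planted_effect("Pz_13-21Hz_Spectral_Ent", nh, "slope_tilt", intended_d = d,
                   magnitude = k_shared)
  )
}

#' Synthetic EEG generator configuration
#'
#' @param n_participants Number of simulated participants (>= 1).
#' @param trials_per_class Trials per class per participant (>= 1).
#' @param fs Sampling rate in Hz (> 60).
#' @param epoch_duration Epoch length in seconds; \code{epoch_duration * fs}
#'   must be an integer >= 256. The default of 2 s is a stand-in: the
#'   latency window of the emulated paradigm is not pinned down, and 2 s is
#'   long enough for stable Hurst/Higuchi estimation at 13 Hz and above.
#' @param channels Channel names; must include the nine analysis channels.
#' @param background_exponent Spectral slope beta of the 1/f^beta background.
#' @param effects List of \code{\link{planted_effect}}; overridden by
#'   \code{preset} when that is non-NULL.
#' @param preset NULL (use \code{effects} as given), \code{"moderate"} or
#'   \code{"strong"} (use \code{\link{preset_effects}}).
#' @param participant_gain Half-range of the per-participant, per-channel
#'   random amplitude offsets (default 0.1, i.e. +/-10%); 0 disables them.
#' @param seed Integer RNG seed.
#' @return An object of class \code{generator_config}.
#' @export
generator_config <- function(n_participants = 15, trials_per_class = 100,
                             fs = 1024, epoch_duration = 2,
                             channels = analysis_channels(),
                             background_exponent = 1,
                             effects = list(), preset = NULL,
                             participant_gain = 0.1, seed = 1) {
  if (!is_count(n_participants)) stopf("`n_participants` must be an integer >= 1")
  if (!is_count(trials_per_class)) stopf("`trials_per_class` must be an integer >= 1")
  if (!is.numeric(fs) || fs <= 60)
    stopf("`fs` must exceed 60 Hz (twice the highest band edge)")
  n <- epoch_duration * fs
  if (abs(n - round(n)) > 1e-9 || round(n) < 256)
    stopf("epoch_duration * fs must be an integer >= 256")
  channels <- as.character(channels)
  miss <- setdiff(analysis_channels(), channels)
  if (length(miss) > 0)
    stopf("channels must include all analysis channels; missing: %s",
          paste(miss, collapse = ", "))
  if (!is.numeric(background_exponent) || background_exponent < 0 ||
      background_exponent > 2)
    stopf("`background_exponent` must lie in [0, 2]")
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("moderate", "strong"))
    effects <- preset_effects(preset)
  }
  if (!all(vapply(effects, inherits, logical(1), "planted_effect")))
    stopf("`effects` must be a list of planted_effect objects")
  for (e in effects) {
    if (!e$channel %in% channels)
      stopf("effect channel '%s' not among config channels", e$channel)
  }
  structure(
    list(n_participants = as.integer(n_participants),
         trials_per_class = as.integer(trials_per_class),
         fs = fs, epoch_duration = epoch_duration,
         n_samples = as.integer(round(n)),
         channels = channels,
         background_exponent = background_exponent,
         effects = effects, preset = preset,
         participant_gain = participant_gain,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' 1/f^beta colored noise
#'
#' Spectrally shaped white Gaussian noise: the FFT of a white draw is
#' multiplied by \code{f^(-beta/2)} (DC zeroed) and inverted, then the result
#' is centered and scaled to exactly unit sample variance. Deterministic
#' under a fixed seed.
#'
#' @param n_samples Length (>= 64).
#' @param exponent Spectral slope beta in [0, 2].
#' @param seed Integer seed (NULL uses the current RNG stream).
#' @return Numeric vector, zero mean, unit sample variance.
#' @export
colored_noise <- function(n_samples, exponent, seed = NULL) {
  if (!is_count(n_samples) || n_samples < 64)
    stopf("`n_samples` must be an integer >= 64")
  if (!is.numeric(exponent) || exponent < 0 || exponent > 2)
    stopf("`exponent` must lie in [0, 2]")
  w <- with_seed(seed, rnorm(n_samples))
  g <- spectral_gain(n_samples, exponent)
  x <- Re(stats::fft(stats::fft(w) * g, inverse = TRUE)) / n_samples
  x <- x - mean(x)
  x / sqrt(var(x))
}

# even-symmetric 1/f^(beta/2) amplitude gain over FFT bins (DC zeroed),
# normalized to unit expected variance
spectral_gain <- function(n, beta) {
  k <- 0:(n - 1)
  f <- pmin(k, n - k)
  g <- c(0, f[-1]^(-beta / 2))
  g / sqrt(mean(g^2))
}

# rows of an n-point FFT whose (folded) frequency lies in [lo, hi] Hz
band_rows <- function(n, fs, lo, hi) {
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  which(f >= lo & f <= hi)
}

#' Generate labeled synthetic EEG epochs
#'
#' Synthesizes \code{n_participants * 2 * trials_per_class} epochs of
#' 1/f^beta background noise (per-channel independent, spectrally shaped
#' white Gaussian noise with the random phases of the white draw), applies
#' each planted effect to its named channel, band and class, and adds small
#' per-participant channel gain offsets. Class labels are balanced within
#' every participant. Output is bit-identical for identical config + seed.
#'
#' @param config A \code{\link{generator_config}}.
#' @return List with \code{epochs} (an \code{\link{eeg_epochs}}) and
#'   \code{manifest} (a ground-truth manifest; see
#'   \code{\link{verify_manifest}}).
#' @export
generate_epochs <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_samples
  fs <- config$fs
  npart <- config$n_participants
  tpc <- config$trials_per_class
  per_part <- 2L * tpc
  ntot <- npart * per_part
  nch <- length(config$channels)
  amp_base <- 10

  labels <- rep(rep(c("haptic", "non_haptic"), each = tpc), npart)
  participant_ids <- rep(seq_len(npart), each = per_part)
  h_cols <- which(labels == "haptic")
  nh_cols <- which(labels == "non_haptic")

  bg <- spectral_gain(n, config$background_exponent)
  defs <- band_definitions()

  with_seed(config$seed, {
    pg <- matrix(runif(npart * nch, 1 - config$participant_gain,
                       1 + config$participant_gain), npart, nch)
    data <- array(0, dim = c(ntot, nch, n))
    for (ci in seq_len(nch)) {
      ch <- config$channels[ci]
      gains <- list(haptic = bg, non_haptic = bg)
      bursts <- list()
      ams <- list()
      for (e in config$effects) {
        if (e$channel != ch) next
        bd <- band_def(e$band_label)
        rows <- band_rows(n, fs, bd$lo, bd$hi)
        higher <- if (e$direction == "non_haptic_higher") "non_haptic" else "haptic"
        lower <- setdiff(c("haptic", "non_haptic"), higher)
        if (e$mechanism == "band_gain") {
          gains[[higher]][rows] <- gains[[higher]][rows] * (1 + e$magnitude)
        } else if (e$mechanism == "slope_tilt") {
          if (e$feature == "Spectral_Ent") {
            # concentrate the lower class's in-band spectrum; power-preserving
            kk <- 0:(n - 1)
            f <- pmin(kk, n - kk)[rows] * fs / n
            fmid <- (bd$lo + bd$hi) / 2
            m <- exp(-e$magnitude * ((f - fmid) / ((bd$hi - bd$lo) / 2))^2)
            old <- gains[[lower]][rows]
            scale <- sqrt(sum(old^2) / sum((m * old)^2))
            gains[[lower]][rows] <- m * old * scale
          } else {
            # slow-envelope AM of the higher class's in-band component
            ams[[length(ams) + 1L]] <-
              list(cols = if (higher == "haptic") h_cols else nh_cols,
                   rows = rows, alpha = e$magnitude)
          }
        } else if (e$mechanism == "burst_amplitude") {
          bursts[[length(bursts) + 1L]] <-
            list(cols = if (higher == "haptic") h_cols else nh_cols,
                 lo = bd$lo, hi = bd$hi,
                 amp = e$magnitude * sqrt(mean((bg^2)[rows]) * length(rows) / n))
        }
      }
      W <- matrix(rnorm(n * ntot), n, ntot)
      X <- stats::mvfft(W)
      X[, h_cols] <- X[, h_cols] * gains$haptic
      X[, nh_cols] <- X[, nh_cols] * gains$non_haptic
      x <- Re(stats::mvfft(X, inverse = TRUE)) / n
      for (am in ams) {
        mask <- numeric(n)
        mask[am$rows] <- 1
        inband <- Re(stats::mvfft(X[, am$cols, drop = FALSE] * mask,
                                  inverse = TRUE)) / n
        env_rows <- band_rows(n, fs, 0.25, 2)
        E <- stats::mvfft(matrix(rnorm(n * length(am$cols)), n,
                                 length(am$cols)))
        emask <- numeric(n)
        emask[env_rows] <- 1
        env <- Re(stats::mvfft(E * emask, inverse = TRUE)) / n
        esd <- sqrt(colMeans(env^2) - colMeans(env)^2)
        env <- sweep(env, 2L, ifelse(esd > 0, esd, 1), "/")
        # lognormal envelope, unit expected power
        x[, am$cols] <- x[, am$cols] - inband +
          inband * exp(am$alpha * env) / exp(am$alpha^2 / 2)
      }
      for (bu in bursts) {
        tgrid <- (seq_len(n) - 1) / fs
        env_sd <- 0.025
        nb <- 1L
        for (col in bu$cols) {
          centers <- runif(nb, 3 * env_sd, n / fs - 3 * env_sd)
          fcs <- runif(nb, bu$lo, bu$hi)
          phis <- runif(nb, 0, 2 * pi)
          add <- numeric(n)
          for (b in seq_len(nb)) {
            env <- exp(-((tgrid - centers[b])^2) / (2 * env_sd^2))
            add <- add + env * sin(2 * pi * fcs[b] * tgrid + phis[b])
          }
          x[, col] <- x[, col] + bu$amp * add
        }
      }
      colgain <- amp_base * pg[participant_ids, ci]
      x <- sweep(x, 2L, colgain, "*")
      data[, ci, ] <- t(x)
    }
    epochs <- eeg_epochs(data, fs, config$channels, labels, participant_ids)
    manifest <- structure(
      list(effects = config$effects,
           realized_d = structure(rep(NA_real_, length(config$effects)),
                                  names = vapply(config$effects,
                                                 `[[`, "", "feature_name")),
           seed = config$seed,
           preset = config$preset,
           n_epochs = ntot),
      class = "ground_truth_manifest")
    list(epochs = epochs, manifest = manifest)
  })
}

#' @export
print.ground_truth_manifest <- function(x, ...) {
  cat(sprintf("<ground_truth_manifest> %d planted effect(s), seed %d\n",
              length(x$effects), x$seed))
  for (i in seq_along(x$effects)) {
    e <- x$effects[[i]]
    cat(sprintf("  %-28s %-18s %-16s d*=%.2f realized=%s\n",
                e$feature_name, e$direction, e$mechanism, e$intended_d,
                ifelse(is.na(x$realized_d[i]), "NA",
                       sprintf("%+.2f", x$realized_d[i]))))
  }
  invisible(x)
}

#' Verify realized effect sizes of a manifest
#'
#' Extracts each planted effect's named feature from the epochs (band-pass
#' filtering the named channel, computing the named feature per epoch) and
#' fills in the realized Cohen's d. The sign convention is fixed:
#' \code{realized_d = (mean non-haptic - mean haptic) / pooled sd}, so a
#' positive value is consistent with \code{non_haptic_higher}.
#'
#' @param epochs The \code{eeg_epochs} generated from the manifest's config.
#' @param manifest The matching ground-truth manifest.
#' @return The manifest with \code{realized_d} filled in.
#' @export
verify_manifest <- function(epochs, manifest) {
  stopifnot(inherits(epochs, "eeg_epochs"),
            inherits(manifest, "ground_truth_manifest"))
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(manifest$effects)) {
    e <- manifest$effects[[i]]
    vals <- tryCatch(
      feature_values(epochs, e$channel, e$band_label, e$feature, cache),
      error = function(err) stopf("feature extraction failed for '%s': %s",
                                  e$feature_name, conditionMessage(err)))
    d <- cohens_d(vals[epochs$labels == "non_haptic"],
                  vals[epochs$labels == "haptic"])
    manifest$realized_d[i] <- d
  }
  manifest
}

# per-epoch values of one named feature at one channel/band, with caching
# of the filtered channel and its kernel outputs
feature_values <- function(epochs, channel, band_label, feature,
                           cache = new.env(parent = emptyenv())) {
  key <- paste(channel, band_label, sep = "|")
  if (!exists(key, cache)) {
    bd <- band_def(band_label)
    chi <- match(channel, epochs$channel_names)
    if (is.na(chi)) stopf("channel '%s' not present", channel)
    sig <- zero_phase_bandpass(t(epochs$data[, chi, ]), epochs$fs, bd$lo, bd$hi)
    fm <- cpp_feature_matrix(sig, 10L, 3L, 1L)
    sp <- spectral_features_matrix(sig, epochs$fs, bd$lo, bd$hi)
    assign(key, list(fm = fm, sp = sp), cache)
  }
  v <- get(key, cache)
  switch(feature,
         Activity = v$fm[1L, ],
         Mobility = v$fm[2L, ],
         Complexity = v$fm[3L, ],
         PSD = v$sp$psd,
         Perm_Ent = v$fm[4L, ],
         Spectral_Ent = v$sp$spectral_ent,
         Higuchi = pmin(pmax(ifelse(is.na(v$fm[5L, ]), 1, v$fm[5L, ]), 1), 2),
         Hurst = pmin(pmax(ifelse(is.na(v$fm[6L, ]), 0.5, v$fm[6L, ]), 0), 1),
         Skewness = v$fm[7L, ],
         Kurtosis = v$fm[8L, ],
         stopf("unknown feature '%s'", feature))
}
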