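#' Canonical base feature names
#'
#' The ten per-channel, per-band features: Hjorth activity (variance),
#' mobility and complexity; Welch band power (PSD); permutation and spectral
#' entropy; Higuchi fractal dimension; rescaled-range Hurst exponent;
#' skewness and excess kurtosis.
#'
#' @return Character vector of length 10.
#' @export
feature_names <- function() {
  c("Activity", "Mobility", "Complexity", "PSD", "Perm_Ent",
    "Spectral_Ent", "Higuchi", "Hurst", "Skewness", "Kurtosis")
}

#' Compose a feature column name
#'
#' Names follow the pattern \code{Channel_Band_Feature}, e.g.
#' \code{"Pz_13-21Hz_Hurst"}.
#'
#' @param channel Channel name (no underscores).
#' @param band_label Band label such as "13-21Hz".
#' @param feature One of \code{\link{feature_names}}.
#' @return Character scalar (vectorized over its arguments).
#' @export
format_feature_name <- function(channel, band_label, feature) {
  if (any(grepl("_", channel, fixed = TRUE)))
    stopf("channel names must not contain underscores")
  paste(channel, band_label, feature, sep = "_")
}

#' Parse a feature column name
#'
#' Inverse of \code{\link{format_feature_name}}. Validates the feature token
#' against the canonical set; when \code{channels} is supplied the channel
#' token is validated too.
#'
#' @param name Feature column name.
#' @param channels Optional vector of admissible channel names.
#' @return List with \code{channel}, \code{band_label}, \code{feature}.
#' @export
parse_feature_name <- function(name, channels = NULL) {
  parts <- strsplit(name, "_", fixed = TRUE)[[1L]]
  if (length(parts) < 3L)
    stopf("cannot parse feature name '%s' (expected Channel_Band_Feature)", name)
  channel <- parts[1L]
  band_label <- parts[2L]
  feature <- paste(parts[-(1:2)], collapse = "_")
  if (!feature %in% feature_names())
    stopf("unknown feature token '%s' in '%s'", feature, name)
  if (!grepl("Hz$", band_label))
    stopf("unknown band token '%s' in '%s'", band_label, name)
  if (!is.null(channels) && !channel %in% channels)
    stopf("unknown channel token '%s' in '%s'", channel, name)
  list(channel = channel, band_label = band_label, feature = feature)
}

#' Hjorth parameters
#'
#' Activity is the population variance; mobility is
#' \code{sqrt(var(diff(x)) / var(x))}; complexity is the mobility of the
#' first difference divided by the mobility of the signal. A constant signal
#' returns \code{(0, 0, 0)} with \code{degenerate = TRUE}.
#'
#' @param x Numeric signal, length >= 3.
#' @return List with \code{activity}, \code{mobility}, \code{complexity},
#'   \code{degenerate}.
#' @export
hjorth_params <- function(x) {
  if (length(x) < 3L) stopf("signal must have length >= 3")
  if (!all(is.finite(x))) stopf("signal contains non-finite samples")
  v <- cpp_hjorth(as.numeric(x))
  list(activity = v[1L], mobility = v[2L], complexity = v[3L],
       degenerate = v[1L] <= 0)
}

#' Permutation entropy
#'
#' Shannon entropy (natural log) of the distribution of ordinal patterns of
#' the given order and delay; ties are broken by index order. For the default
#' order 3 the value lies in \code{[0, log(3!)]} = [0, 1.7918] nats.
#'
#' @param x Numeric signal.
#' @param order Pattern order (>= 2, <= 6).
#' @param delay Pattern delay (>= 1).
#' @return Entropy in nats.
#' @export
permutation_entropy <- function(x, order = 3, delay = 1) {
  if (!is_count(order) || order < 2 || order > 6)
    stopf("`order` must be an integer in [2, 6]")
  if (!is_count(delay)) stopf("`delay` must be a positive integer")
  if (length(x) < order * delay + 1)
    stopf("signal too short for order %d, delay %d", order, delay)
  cpp_perm_entropy(as.numeric(x), as.integer(order), as.integer(delay))
}

#' Higuchi fractal dimension
#'
#' Least-squares slope of log mean curve length against log(1/k) over
#' k = 1..kmax, clamped to the theoretical range [1, 2]. When clamping (or a
#' flat signal) fires, the \code{"degenerate"} attribute is TRUE.
#'
#' @param x Numeric signal, length >= 10 * kmax.
#' @param kmax Maximum down-sampling factor (>= 2).
#' @return Fractal dimension in [1, 2], with attribute \code{degenerate}.
#' @export
higuchi_fd <- function(x, kmax = 10) {
  if (!is_count(kmax) || kmax < 2) stopf("`kmax` must be an integer >= 2")
  if (length(x) < 10 * kmax)
    stopf("signal must have length >= 10 * kmax = %d", 10 * kmax)
  raw <- cpp_higuchi_raw(as.numeric(x), as.integer(kmax))
  degen <- is.na(raw) || raw < 1 || raw > 2
  out <- if (is.na(raw)) 1 else min(max(raw, 1), 2)
  attr(out, "degenerate") <- degen
  out
}

#' Hurst exponent (rescaled-range, or DFA as an alternative)
#'
#' Default \code{method = "rs"}: slope of log mean R/S against log window
#' size over a dyadic window ladder. \code{method = "dfa"}: detrended
#' fluctuation analysis, the slope of log RMS residual fluctuation of the
#' linearly detrended integrated signal against log window size. Both are
#' clamped to [0, 1]; a constant signal returns 0.5 with
#' \code{degenerate = TRUE}. The feature table always uses "rs".
#'
#' @param x Numeric signal, length >= 32.
#' @param method \code{"rs"} (default) or \code{"dfa"}.
#' @return Hurst estimate in [0, 1], with attribute \code{degenerate}.
#' @export
hurst_exponent <- function(x, method = c("rs", "dfa")) {
  method <- match.arg(method)
  if (length(x) < 32L) stopf("signal must have length >= 32")
  raw <- if (method == "rs") cpp_hurst_raw(as.numeric(x)) else dfa_raw(x)
  degen <- is.na(raw) || raw < 0 || raw > 1
  out <- if (is.na(raw)) 0.5 else min(max(raw, 0), 1)
  attr(out, "degenerate") <- degen
  out
}

# DFA-1: log-log slope of RMS residual of per-window linear detrends of the
# integrated signal, over a dyadic window ladder
dfa_raw <- function(x) {
  n <- length(x)
  if (pop_sd(x) == 0) return(NA_real_)
  y <- cumsum(x - mean(x))
  wmin <- if (n >= 64) 16L else 8L
  ws <- c(); fs_ <- c()
  w <- wmin
  t1 <- seq_len(n)
  while (w <= n %/% 4 || (w == wmin && w <= n %/% 2)) {
    nb <- n %/% w
    res2 <- 0
    tt <- seq_len(w)
    sxx <- sum((tt - mean(tt))^2)
    for (b in seq_len(nb)) {
      seg <- y[((b - 1) * w + 1):(b * w)]
      beta <- sum((tt - mean(tt)) * (seg - mean(seg))) / sxx
      fit <- mean(seg) + beta * (tt - mean(tt))
      res2 <- res2 + sum((seg - fit)^2)
    }
    ws <- c(ws, w)
    fs_ <- c(fs_, sqrt(res2 / (nb * w)))
    w <- w * 2L
  }
  if (length(ws) < 2 || any(fs_ <= 0)) return(NA_real_)
  lw <- log(ws); lf <- log(fs_)
  sum((lw - mean(lw)) * (lf - mean(lf))) / sum((lw - mean(lw))^2)
}

#' Skewness and excess kurtosis
#'
#' Fisher-Pearson skewness g1 and excess kurtosis g2, computed from
#' population moments (a Gaussian signal has kurtosis 0). Zero-variance
#' signals return (0, 0) with \code{degenerate = TRUE}.
#'
#' @param x Numeric signal, length >= 4.
#' @return List with \code{skewness}, \code{kurtosis}, \code{degenerate}.
#' @export
signal_moments <- function(x) {
  if (length(x) < 4L) stopf("signal must have length >= 4")
  v <- cpp_moments(as.numeric(x))
  list(skewness = v[1L], kurtosis = v[2L],
       degenerate = pop_sd(x) == 0)
}

# Welch power spectral density of the columns of `mat` (time x signals).
# Hann-windowed segments of `nperseg` samples with 50% overlap; one-sided
# density scaling so that flat unit-variance white noise has level 2/fs.
welch_psd <- function(mat, fs, nperseg = NULL) {
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1L)
  n <- nrow(mat)
  if (is.null(nperseg)) nperseg <- min(n, as.integer(fs))
  nperseg <- as.integer(nperseg)
  if (n < nperseg) stopf("signal length %d below Welch segment %d", n, nperseg)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nperseg - 1L)) / nperseg))
  wss <- sum(w^2)
  nfreq <- nperseg %/% 2L + 1L
  acc <- matrix(0, nfreq, ncol(mat))
  for (s in starts) {
    seg <- mat[s:(s + nperseg - 1L), , drop = FALSE] * w
    X <- stats::mvfft(seg)
    P <- Mod(X[1:nfreq, , drop = FALSE])^2
    acc <- acc + P
  }
  acc <- acc / length(starts)
  scale <- 2 / (fs * wss)
  dens <- acc * scale
  dens[1L, ] <- dens[1L, ] / 2
  if (nperseg %% 2L == 0L) dens[nfreq, ] <- dens[nfreq, ] / 2
  list(freq = (0:(nfreq - 1L)) * fs / nperseg, psd = dens)
}

#' Welch band power
#'
#' Mean Welch power spectral density over the frequency bins inside
#' \code{[lo, hi]}. Welch uses 1 s Hann segments with 50% overlap.
#'
#' @param x Numeric signal (length >= 256).
#' @param fs Sampling rate in Hz.
#' @param band Band name, label or \code{list(lo=, hi=)}.
#' @return Non-negative scalar band power density.
#' @export
band_power <- function(x, fs, band) {
  bd <- band_def(band)
  if (length(x) < 256L) stopf("signal must have length >= 256 for Welch PSD")
  if (bd$hi >= fs / 2) stopf("band edge %g Hz at or above Nyquist", bd$hi)
  ws <- welch_psd(as.numeric(x), fs)
  sel <- ws$freq >= bd$lo & ws$freq <= bd$hi
  if (!any(sel)) stopf("no Welch bins inside [%g, %g] Hz", bd$lo, bd$hi)
  mean(ws$psd[sel, 1L])
}

#' Spectral entropy of a band
#'
#' Shannon entropy of the Welch PSD normalized to a probability distribution
#' over the in-band bins, divided by log(number of bins); lies in [0, 1].
#' All-zero in-band power returns 0 with \code{degenerate = TRUE}.
#'
#' @inheritParams band_power
#' @return Normalized entropy in [0, 1], with attribute \code{degenerate}.
#' @export
spectral_entropy <- function(x, fs, band) {
  bd <- band_def(band)
  if (length(x) < 256L) stopf("signal must have length >= 256 for Welch PSD")
  ws <- welch_psd(as.numeric(x), fs)
  sel <- ws$freq >= bd$lo & ws$freq <= bd$hi
  if (sum(sel) < 2L) stopf("need at least 2 Welch bins inside the band")
  p <- ws$psd[sel, 1L]
  tot <- sum(p)
  if (tot <= 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  p <- p / tot
  nz <- p > 0
  H <- -sum(p[nz] * log(p[nz])) / log(sum(sel))
  attr(H, "degenerate") <- FALSE
  H
}

# vectorized spectral features for a time x epochs matrix
spectral_features_matrix <- function(mat, fs, lo, hi) {
  ws <- welch_psd(mat, fs)
  sel <- ws$freq >= lo & ws$freq <= hi
  dens <- ws$psd[sel, , drop = FALSE]
  psd <- colMeans(dens)
  tot <- colSums(dens)
  nb <- nrow(dens)
  p <- sweep(dens, 2L, ifelse(tot > 0, tot, 1), "/")
  plogp <- p * log(p)
  plogp[!is.finite(plogp)] <- 0
  se <- -colSums(plogp) / log(nb)
  se[tot <= 0] <- 0
  list(psd = psd, spectral_ent = se)
}

#' Extract the full feature table
#'
#' Computes the ten base features for every (epoch, channel, band) of a band
#' decomposition, yielding \code{channels x bands x 10} named columns (360 for
#' the canonical 9-channel, 4-band setup) plus \code{label} and
#' \code{participant} columns.
#'
#' Higuchi and Hurst estimates falling outside their theoretical ranges are
#' clamped ([1,2] and [0,1]); clamp counts are recorded in the
#' \code{"clamp_counts"} attribute and reported via \code{message()} when
#' \code{verbose = TRUE}.
#'
#' @param band_epochs Named list of band-filtered \code{eeg_epochs} (as from
#'   \code{\link{band_decompose}}); all entries must share epoch count,
#'   labels, channels and sampling rate.
#' @param kmax Higuchi kmax.
#' @param pe_order,pe_delay Permutation entropy order and delay.
#' @param verbose Report clamp counts.
#' @return A \code{feature_table} (data.frame) with one row per epoch.
#' @export
extract_feature_table <- function(band_epochs, kmax = 10, pe_order = 3,
                                  pe_delay = 1, verbose = FALSE) {
  if (!is.list(band_epochs) || is.null(names(band_epochs)) ||
      !all(vapply(band_epochs, inherits, logical(1), "eeg_epochs")))
    stopf("`band_epochs` must be a named list of eeg_epochs")
  ref <- band_epochs[[1L]]
  for (b in band_epochs) {
    if (n_epochs(b) != n_epochs(ref) || !identical(b$labels, ref$labels) ||
        !identical(b$channel_names, ref$channel_names) || b$fs != ref$fs)
      stopf("band epoch sets disagree on epochs, labels, channels or fs")
  }
  bands <- lapply(names(band_epochs), band_def)
  names(bands) <- names(band_epochs)
  ne <- n_epochs(ref)
  feats <- feature_names()
  cols <- list()
  clamp_hi <- 0L; clamp_hu <- 0L
  for (ch in ref$channel_names) {
    chi <- match(ch, ref$channel_names)
    for (bn in names(band_epochs)) {
      bd <- bands[[bn]]
      sig <- t(band_epochs[[bn]]$data[, chi, ])   # time x epochs
      fm <- cpp_feature_matrix(sig, as.integer(kmax), as.integer(pe_order),
                               as.integer(pe_delay))
      sp <- spectral_features_matrix(sig, ref$fs, bd$lo, bd$hi)
      hig <- fm[5L, ]
      clamp_hi <- clamp_hi + sum(is.na(hig) | hig < 1 | hig > 2)
      hig <- pmin(pmax(ifelse(is.na(hig), 1, hig), 1), 2)
      hur <- fm[6L, ]
      clamp_hu <- clamp_hu + sum(is.na(hur) | hur < 0 | hur > 1)
      hur <- pmin(pmax(ifelse(is.na(hur), 0.5, hur), 0), 1)
      vals <- cbind(fm[1L, ], fm[2L, ], fm[3L, ], sp$psd, fm[4L, ],
                    sp$spectral_ent, hig, hur, fm[7L, ], fm[8L, ])
      colnames(vals) <- format_feature_name(ch, bd$label, feats)
      cols[[length(cols) + 1L]] <- vals
    }
  }
  tab <- as.data.frame(do.call(cbind, cols))
  tab$label <- ref$labels
  tab$participant <- ref$participant_ids
  class(tab) <- c("feature_table", "data.frame")
  attr(tab, "clamp_counts") <- c(higuchi = clamp_hi, hurst = clamp_hu)
  if (verbose && (clamp_hi + clamp_hu) > 0L)
    message(sprintf("clamped %d Higuchi and %d Hurst estimates of %d",
                    clamp_hi, clamp_hu, ne * length(cols)))
  tab
}

#' Feature column names of a feature table
#' @param table A \code{feature_table}.
#' @return Character vector excluding the label/participant columns.
#' @export
feature_columns <- function(table) {
  setdiff(colnames(table), c("label", "participant"))
}
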