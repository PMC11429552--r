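#' Canonical analysis bands
#'
#' The four frequency bands used throughout: low alpha (8-9.5 Hz), high alpha
#' (10-13 Hz), low beta (13-21 Hz) and high beta (21-30 Hz).
#'
#' @return A data.frame with columns \code{name}, \code{lo}, \code{hi},
#'   \code{label} (the label used inside feature names, e.g. "13-21Hz").
#' @export
band_definitions <- function() {
  data.frame(
    name  = c("low_alpha", "high_alpha", "low_beta", "high_beta"),
    lo    = c(8, 10, 13, 21),
    hi    = c(9.5, 13, 21, 30),
    label = c("8-9.5Hz", "10-13Hz", "13-21Hz", "21-30Hz"),
    stringsAsFactors = FALSE
  )
}

#' Look up or build a band definition
#'
#' @param band Either a canonical band name ("low_beta"), a band label
#'   ("13-21Hz"), or a list/vector with elements \code{lo} and \code{hi}.
#' @return A list with \code{name}, \code{lo}, \code{hi}, \code{label} and
#'   \code{canonical} (TRUE when it is one of the four canonical bands).
#' @export
band_def <- function(band) {
  defs <- band_definitions()
  if (is.character(band) && length(band) == 1L) {
    i <- match(band, defs$name)
    if (is.na(i)) i <- match(band, defs$label)
    if (is.na(i))
      stopf("unknown band '%s'; canonical bands: %s", band,
            paste(defs$name, collapse = ", "))
    return(list(name = defs$name[i], lo = defs$lo[i], hi = defs$hi[i],
                label = defs$label[i], canonical = TRUE))
  }
  if ((is.list(band) || is.numeric(band)) && !is.null(band[["lo"]]) && !is.null(band[["hi"]])) {
    lo <- as.numeric(band[["lo"]]); hi <- as.numeric(band[["hi"]])
    if (!(lo > 0 && hi > lo)) stopf("band edges must satisfy 0 < lo < hi")
    i <- which(defs$lo == lo & defs$hi == hi)
    if (length(i) == 1L)
      return(list(name = defs$name[i], lo = lo, hi = hi,
                  label = defs$label[i], canonical = TRUE))
    return(list(name = sprintf("band_%g_%g", lo, hi), lo = lo, hi = hi,
                label = sprintf("%g-%gHz", lo, hi), canonical = FALSE))
  }
  stopf("`band` must be a band name/label or a list with lo and hi")
}

# Squared-magnitude response of a digital Butterworth band-pass at the
# supplied frequencies (Hz). Forward-backward filtering has exactly this
# (zero-phase) frequency response.
butter_mag2 <- function(freqs, fs, lo, hi, order = 4) {
  ba <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  w <- 2 * pi * freqs / fs
  z <- exp(-1i * w)
  num <- Reduce(function(acc, coef) acc * z + coef, ba$b, accumulate = FALSE,
                init = 0 * z)
  den <- Reduce(function(acc, coef) acc * z + coef, ba$a, accumulate = FALSE,
                init = 0 * z)
  Mod(num / den)^2
}

# Zero-phase band-pass of the columns of `mat` (time x signals): odd-reflect
# pad, apply the squared Butterworth magnitude response in the frequency
# domain, strip the pad. Chunked over columns to bound memory.
zero_phase_bandpass <- function(mat, fs, lo, hi, order = 4, chunk = 512L) {
  n <- nrow(mat)
  pad <- min(n - 1L, as.integer(ceiling(3 * fs / lo)))
  npad <- n + 2L * pad
  nfft <- stats::nextn(npad, c(2L, 3L, 5L))
  k <- 0:(nfft - 1L)
  freqs <- pmin(k, nfft - k) * fs / nfft
  h2 <- butter_mag2(freqs, fs, lo, hi, order)
  out <- matrix(0, n, ncol(mat))
  idx_front <- (pad + 1L):2L
  idx_back <- (n - 1L):(n - pad)
  for (start in seq(1L, ncol(mat), by = chunk)) {
    cols <- start:min(start + chunk - 1L, ncol(mat))
    x <- mat[, cols, drop = FALSE]
    padded <- matrix(0, nfft, length(cols))
    padded[1:pad, ] <- 2 * rep(x[1L, ], each = pad) - x[idx_front, , drop = FALSE]
    padded[(pad + 1L):(pad + n), ] <- x
    padded[(pad + n + 1L):npad, ] <-
      2 * rep(x[n, ], each = pad) - x[idx_back, , drop = FALSE]
    X <- stats::mvfft(padded)
    y <- Re(stats::mvfft(X * h2, inverse = TRUE)) / nfft
    out[, cols] <- y[(pad + 1L):(pad + n), , drop = FALSE]
  }
  out
}

#' Decimate an epoch set
#'
#' Optional speed convenience: zero-phase low-pass at 80% of the new
#' Nyquist, then keep every \code{fs / fs_new}-th sample. Off the default
#' path — all analyses run at the native rate unless explicitly decimated.
#' The highest analysis band (30 Hz) is untouched at the default 256 Hz
#' target.
#'
#' @param epochs An \code{eeg_epochs} object.
#' @param fs_new Target sampling rate; must divide \code{fs}.
#' @return A decimated \code{eeg_epochs}.
#' @export
decimate_epochs <- function(epochs, fs_new = 256) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  fac <- epochs$fs / fs_new
  if (abs(fac - round(fac)) > 1e-9 || fac < 1)
    stopf("fs_new must divide fs (%g / %g)", epochs$fs, fs_new)
  fac <- as.integer(round(fac))
  if (fac == 1L) return(epochs)
  d <- dim(epochs$data)
  keep <- seq(1L, d[3L], by = fac)
  out <- array(0, dim = c(d[1L], d[2L], length(keep)))
  for (ch in seq_len(d[2L])) {
    sig <- t(epochs$data[, ch, ])
    # anti-alias: zero-phase band-pass with a near-zero low edge
    low <- zero_phase_bandpass(sig, epochs$fs, 0.5 / (d[3L] / epochs$fs),
                               0.8 * fs_new / 2)
    out[, ch, ] <- t(low[keep, , drop = FALSE])
  }
  eeg_epochs(out, fs_new, epochs$channel_names, epochs$labels,
             epochs$participant_ids)
}

#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward (zero phase,
#' effective 8th order) to every channel of every epoch. The response is
#' realized as the filter's squared magnitude in the frequency domain on
#' odd-reflect-padded epochs, which is the forward-backward response up to
#' boundary treatment and vectorizes across epochs.
#'
#' @param x An \code{eeg_epochs} object, or a numeric vector (then \code{fs}
#'   is required).
#' @param band A band name, label, or \code{list(lo=, hi=)}; see
#'   \code{\link{band_def}}.
#' @param fs Sampling rate, only for vector input.
#' @param order Butterworth order of the one-way prototype (default 4).
#' @return Filtered object of the same shape as the input.
#' @export
bandpass <- function(x, band, fs = NULL, order = 4) {
  bd <- band_def(band)
  if (inherits(x, "eeg_epochs")) fs <- x$fs
  if (is.null(fs)) stopf("`fs` is required for vector input")
  if (bd$hi >= fs / 2)
    stopf("band edge %g Hz is at or above Nyquist (%g Hz)", bd$hi, fs / 2)
  if (is.numeric(x) && is.null(dim(x))) {
    return(drop(zero_phase_bandpass(matrix(x, ncol = 1), fs, bd$lo, bd$hi, order)))
  }
  stopifnot(inherits(x, "eeg_epochs"))
  d <- dim(x$data)
  out <- x$data
  for (ch in seq_len(d[2L])) {
    sig <- t(x$data[, ch, ])            # time x epochs
    out[, ch, ] <- t(zero_phase_bandpass(sig, fs, bd$lo, bd$hi, order))
  }
  eeg_epochs(out, x$fs, x$channel_names, x$labels, x$participant_ids)
}

#' Decompose epochs into the four analysis bands
#'
#' Produces one band-pass-filtered copy of the epoch set per canonical band
#' (or per row of a custom band table).
#'
#' @param epochs An \code{eeg_epochs} object.
#' @param bands A band table as returned by \code{\link{band_definitions}}.
#' @param order Butterworth order passed to \code{\link{bandpass}}.
#' @return Named list (band name -> filtered \code{eeg_epochs}).
#' @export
band_decompose <- function(epochs, bands = band_definitions(), order = 4) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  fs <- epochs$fs
  if (any(bands$hi >= fs / 2))
    stopf("band edge at or above Nyquist (%g Hz)", fs / 2)
  d <- dim(epochs$data)
  n <- d[3L]
  # one shared forward FFT per channel; per-band multiply + inverse
  pad <- min(n - 1L, as.integer(ceiling(3 * fs / min(bands$lo))))
  npad <- n + 2L * pad
  nfft <- stats::nextn(npad, c(2L, 3L, 5L))
  k <- 0:(nfft - 1L)
  freqs <- pmin(k, nfft - k) * fs / nfft
  h2 <- lapply(seq_len(nrow(bands)), function(i) {
    butter_mag2(freqs, fs, bands$lo[i], bands$hi[i], order)
  })
  arrays <- lapply(seq_len(nrow(bands)), function(i) array(0, dim = d))
  idx_front <- (pad + 1L):2L
  idx_back <- (n - 1L):(n - pad)
  chunk <- 512L
  for (ch in seq_len(d[2L])) {
    mat <- t(epochs$data[, ch, ])       # time x epochs
    for (start in seq(1L, ncol(mat), by = chunk)) {
      cols <- start:min(start + chunk - 1L, ncol(mat))
      x <- mat[, cols, drop = FALSE]
      padded <- matrix(0, nfft, length(cols))
      padded[1:pad, ] <- 2 * rep(x[1L, ], each = pad) - x[idx_front, , drop = FALSE]
      padded[(pad + 1L):(pad + n), ] <- x
      padded[(pad + n + 1L):npad, ] <-
        2 * rep(x[n, ], each = pad) - x[idx_back, , drop = FALSE]
      X <- stats::mvfft(padded)
      for (i in seq_len(nrow(bands))) {
        y <- Re(stats::mvfft(X * h2[[i]], inverse = TRUE)) / nfft
        arrays[[i]][cols, ch, ] <- t(y[(pad + 1L):(pad + n), , drop = FALSE])
      }
    }
  }
  out <- lapply(arrays, function(a) {
    eeg_epochs(a, fs, epochs$channel_names, epochs$labels,
               epochs$participant_ids)
  })
  names(out) <- bands$name
  out
}
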