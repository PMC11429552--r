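#' Labeled multichannel EEG epochs
#'
#' Container for a cube of EEG samples (epoch x channel x time) together with
#' the sampling rate, channel names, per-epoch class labels
#' (\code{"haptic"} / \code{"non_haptic"}) and participant ids.
#'
#' @param data Numeric 3-D array, dimensions epoch x channel x time. All
#'   samples must be finite.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one unique name per channel.
#' @param labels Per-epoch class, coercible to a factor with levels
#'   \code{"haptic"}, \code{"non_haptic"}.
#' @param participant_ids Integer vector, one id per epoch.
#' @return An object of class \code{eeg_epochs}.
#' @export
eeg_epochs <- function(data, fs, channel_names, labels, participant_ids = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a 3-D array (epoch x channel x time)")
  if (!all(is.finite(data)))
    stopf("epoch data contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stopf("`fs` must be a positive sampling rate in Hz")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(data)[2L])
    stopf("%d channel names supplied for %d channels", length(channel_names), dim(data)[2L])
  if (anyDuplicated(channel_names))
    stopf("channel names must be unique")
  labels <- factor(as.character(labels), levels = c("haptic", "non_haptic"))
  if (length(labels) != dim(data)[1L] || anyNA(labels))
    stopf("`labels` must give 'haptic' or 'non_haptic' for each of %d epochs", dim(data)[1L])
  if (is.null(participant_ids)) participant_ids <- rep(1L, dim(data)[1L])
  participant_ids <- as.integer(participant_ids)
  if (length(participant_ids) != dim(data)[1L])
    stopf("`participant_ids` must have one entry per epoch")
  dimnames(data) <- list(NULL, channel_names, NULL)
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         labels = labels, participant_ids = participant_ids),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  cat(sprintf("  channels: %s\n", paste(x$channel_names, collapse = ", ")))
  tab <- table(x$labels)
  cat(sprintf("  labels: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  participants: %d\n", length(unique(x$participant_ids))))
  invisible(x)
}

#' Number of epochs
#' @param epochs An \code{eeg_epochs} object.
#' @return Integer epoch count.
#' @export
n_epochs <- function(epochs) dim(epochs$data)[1L]

#' Restrict an epoch set to named channels
#'
#' Returns the epochs restricted to `names`, in the requested order; labels
#' and participant ids are untouched.
#'
#' @param epochs An \code{eeg_epochs} object.
#' @param names Channel names to keep (order is respected).
#' @return An \code{eeg_epochs} object with the requested channels.
#' @export
select_channels <- function(epochs, names = analysis_channels()) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  names <- as.character(names)
  missing <- setdiff(names, epochs$channel_names)
  if (length(missing) > 0)
    stopf("unknown channel(s): %s. Available: %s",
          paste(missing, collapse = ", "),
          paste(epochs$channel_names, collapse = ", "))
  idx <- match(names, epochs$channel_names)
  eeg_epochs(epochs$data[, idx, , drop = FALSE], epochs$fs, names,
             epochs$labels, epochs$participant_ids)
}
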