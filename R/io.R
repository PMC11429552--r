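#' Write / read a feature table as CSV
#'
#' Plain CSV with one header row (feature names plus \code{label} and
#' \code{participant}); the read path restores the \code{feature_table}
#' class and label factor.
#'
#' @param table A \code{feature_table}.
#' @param path File path.
#' @return \code{write_feature_table}: the path, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @return \code{read_feature_table}: a \code{feature_table}.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  tab$label <- factor(tab$label, levels = c("haptic", "non_haptic"))
  tab$participant <- as.integer(tab$participant)
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Serialize a selection result
#'
#' JSON with method, alpha, ordered feature names and their scores or
#' p-values; \code{read_selection} restores the object.
#'
#' @param sel A \code{selection_result}.
#' @param path File path (.json).
#' @return The path / the restored \code{selection_result}.
#' @export
write_selection <- function(sel, path) {
  stopifnot(inherits(sel, "selection_result"))
  payload <- list(method = sel$method, alpha = sel$alpha,
                  features = sel$features)
  if (!is.null(sel$retained_p)) payload$p_values <- unname(sel$retained_p)
  if (!is.null(sel$scores)) payload$scores <- unname(sel$scores)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection
#' @param sep Field separator for the CSV variant.
#' @export
write_selection_csv <- function(sel, path, sep = ",") {
  stopifnot(inherits(sel, "selection_result"))
  value <- if (!is.null(sel$retained_p)) unname(sel$retained_p)
           else unname(sel$scores)
  df <- data.frame(feature = sel$features, value = value)
  names(df)[2] <- if (!is.null(sel$retained_p)) "p_value" else "score"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(method = p$method, features = p$features,
              alpha = if (is.null(p$alpha)) NA_real_ else p$alpha)
  if (!is.null(p$p_values)) {
    out$retained_p <- p$p_values
    out$p_values <- p$p_values
  }
  if (!is.null(p$scores)) out$scores <- p$scores
  structure(out, class = "selection_result")
}

#' Write an accuracy report
#'
#' CSV with rows = models and columns = subset sizes (the Tables 3-4 layout),
#' and optionally a JSON sidecar with per-cell best hyperparameters.
#'
#' @param report An \code{accuracy_report}.
#' @param path CSV path.
#' @param json_path Optional JSON path for metadata.
#' @return The CSV path, invisibly.
#' @export
write_accuracy_report <- function(report, path, json_path = NULL) {
  stopifnot(inherits(report, "accuracy_report"))
  utils::write.csv(as.data.frame(report$accuracy), path, row.names = TRUE)
  if (!is.null(json_path)) {
    meta <- list(method = report$method, seed = report$seed,
                 sizes = report$sizes,
                 best_params = apply(report$best_params, c(1, 2),
                                     function(p) p))
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  invisible(path)
}

#' Write / read a ground-truth manifest as JSON
#'
#' @param manifest A ground-truth manifest.
#' @param path File path (.json).
#' @return The path / the restored manifest.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "ground_truth_manifest"))
  payload <- list(
    seed = manifest$seed,
    preset = manifest$preset,
    n_epochs = manifest$n_epochs,
    effects = lapply(seq_along(manifest$effects), function(i) {
      e <- manifest$effects[[i]]
      list(feature_name = e$feature_name, direction = e$direction,
           mechanism = e$mechanism, magnitude = e$magnitude,
           intended_d = e$intended_d,
           realized_d = manifest$realized_d[i])
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  effects <- lapply(p$effects, function(e) {
    planted_effect(e$feature_name, e$direction, e$mechanism,
                   intended_d = e$intended_d, magnitude = e$magnitude)
  })
  realized <- vapply(p$effects, function(e) {
    if (is.null(e$realized_d) || is.na(e$realized_d)) NA_real_
    else as.numeric(e$realized_d)
  }, numeric(1))
  names(realized) <- vapply(effects, `[[`, "", "feature_name")
  structure(list(effects = effects, realized_d = realized,
                 seed = p$seed, preset = p$preset, n_epochs = p$n_epochs),
            class = "ground_truth_manifest")
}

#' Save / load an epoch set
#'
#' Binary little-endian doubles for the sample cube plus a JSON sidecar
#' (dimensions, sampling rate, channel names, labels, participant ids).
#'
#' @param epochs An \code{eeg_epochs}.
#' @param path Data file path; the sidecar is \code{paste0(path, ".json")}.
#' @return The path / the restored \code{eeg_epochs}.
#' @export
save_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(epochs$data), con, size = 8, endian = "little")
  side <- list(dim = dim(epochs$data), fs = epochs$fs,
               channel_names = epochs$channel_names,
               labels = as.character(epochs$labels),
               participant_ids = epochs$participant_ids)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(side$dim)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, what = "double", n = prod(d), size = 8,
                  endian = "little")
  eeg_epochs(array(vals, dim = d), side$fs, side$channel_names,
             side$labels, side$participant_ids)
}

#' Read a generator configuration from YAML
#'
#' The YAML keys mirror the arguments of \code{\link{generator_config}};
#' \code{effects} entries are lists with \code{feature_name},
#' \code{direction}, \code{mechanism} and \code{intended_d} (and optionally
#' \code{magnitude}).
#'
#' @param path YAML file path.
#' @return A \code{generator_config}.
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$effects)) {
    y$effects <- lapply(y$effects, function(e) do.call(planted_effect, e))
  }
  do.call(generator_config, y)
}
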