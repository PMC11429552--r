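#' Per-channel class-mean maps of one feature
#'
#' For one base feature in one band, computes the mean feature value per
#' channel within each class, then min-max normalizes the 2 x 9 class/channel
#' means jointly to [0, 1] (the convention used for topographic displays).
#' Raw means are retained alongside. A zero range (constant feature) yields
#' all-zero normalized values with \code{degenerate = TRUE}.
#'
#' @param table A \code{feature_table} containing all nine analysis channels
#'   for the requested feature/band.
#' @param base_feature One of \code{\link{feature_names}}.
#' @param band Band name or label.
#' @param channels Channels to map (default the nine analysis channels).
#' @return Object of class \code{topo_map} with \code{raw} and
#'   \code{normalized} (class x channel matrices).
#' @export
class_mean_maps <- function(table, base_feature, band,
                            channels = analysis_channels()) {
  if (!base_feature %in% feature_names())
    stopf("unknown base feature '%s'", base_feature)
  bd <- band_def(band)
  cols <- format_feature_name(channels, bd$label, base_feature)
  missing <- setdiff(cols, colnames(table))
  if (length(missing) > 0)
    stopf("missing feature column(s): %s", paste(missing, collapse = ", "))
  y <- factor(table$label)
  classes <- c("haptic", "non_haptic")
  raw <- t(vapply(classes, function(cl) {
    colMeans(as.matrix(table[y == cl, cols, drop = FALSE]))
  }, numeric(length(cols))))
  dimnames(raw) <- list(classes, channels)
  rng <- range(raw)
  degenerate <- diff(rng) == 0
  normalized <- if (degenerate) raw * 0 else (raw - rng[1L]) / diff(rng)
  structure(list(feature = base_feature, band = bd$label,
                 channels = channels, raw = raw, normalized = normalized,
                 degenerate = degenerate),
            class = "topo_map")
}

#' @export
print.topo_map <- function(x, ...) {
  cat(sprintf("<topo_map> %s, %s%s\n", x$feature, x$band,
              if (x$degenerate) " (degenerate: zero range)" else ""))
  print(round(x$normalized, 3))
  invisible(x)
}

# approximate 2-D 10-20 positions (unit head circle) for the analysis grid
channel_positions <- function() {
  data.frame(
    channel = analysis_channels(),
    x = c(-0.45, 0, 0.45, -0.55, 0, 0.55, -0.45, 0, 0.45),
    y = c(0.5, 0.55, 0.5, 0, 0, 0, -0.5, -0.55, -0.5),
    stringsAsFactors = FALSE
  )
}

#' Plot a topographic map pair
#'
#' Renders the normalized class means of a \code{\link{class_mean_maps}}
#' result as two scalp maps (haptic, non-haptic) using inverse-distance
#' interpolation on approximate 10-20 positions. Cosmetic convenience; the
#' numeric map is the contractual output.
#'
#' @param x A \code{topo_map}.
#' @param resolution Grid resolution per axis.
#' @param ... Unused.
#' @return Invisibly, \code{x}.
#' @export
plot.topo_map <- function(x, resolution = 61, ...) {
  pos <- channel_positions()
  pos <- pos[match(x$channels, pos$channel), ]
  grid <- seq(-1, 1, length.out = resolution)
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  for (cl in rownames(x$normalized)) {
    vals <- x$normalized[cl, ]
    z <- outer(grid, grid, Vectorize(function(gx, gy) {
      if (gx^2 + gy^2 > 1) return(NA_real_)
      d2 <- (pos$x - gx)^2 + (pos$y - gy)^2
      if (any(d2 < 1e-12)) return(vals[which.min(d2)])
      w <- 1 / d2
      sum(w * vals) / sum(w)
    }))
    graphics::image(grid, grid, z, zlim = c(0, 1), col = pal, axes = FALSE,
                    asp = 1, xlab = "", ylab = "",
                    main = sprintf("%s %s (%s)", x$feature, x$band, cl))
    graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE)
    graphics::points(pos$x, pos$y, pch = 21, bg = "white")
    graphics::text(pos$x, pos$y, pos$channel, pos = 3, cex = 0.7)
  }
  invisible(x)
}
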