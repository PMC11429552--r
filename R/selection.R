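#' One-way ANOVA F statistic per feature column
#'
#' Relevance of each column against the class label: between-class mean
#' square over within-class mean square (two classes, df 1 and n - 2).
#' Constant columns yield 0.
#'
#' @param x Numeric matrix (rows = samples).
#' @param y Two-level factor.
#' @return Numeric vector of F statistics.
#' @export
f_statistic <- function(x, y) {
  x <- as.matrix(x)
  y <- factor(y)
  lev <- levels(droplevels(y))
  if (length(lev) != 2L) stopf("exactly two classes are required")
  n <- nrow(x)
  i1 <- y == lev[1L]
  n1 <- sum(i1); n2 <- n - n1
  m1 <- colMeans(x[i1, , drop = FALSE])
  m2 <- colMeans(x[!i1, , drop = FALSE])
  m <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  ssw <- colSums(sweep(x[i1, , drop = FALSE], 2L, m1)^2) +
    colSums(sweep(x[!i1, , drop = FALSE], 2L, m2)^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[!is.finite(f)] <- 0
  f
}

#' Rank features by maximum relevance, minimum redundancy
#'
#' Greedy forward selection. The first pick maximizes the one-way ANOVA F
#' statistic against the class label; every subsequent pick maximizes the
#' quotient of its F statistic to the mean absolute Pearson correlation with
#' the already-selected features. Ties are broken by column order; constant
#' columns score 0 and rank last.
#'
#' The reported \code{score} is the running minimum of the greedy quotient,
#' rescaled so the maximum is 100 (the raw quotient is kept in
#' \code{raw_quotient}): the greedy quotient itself is not monotone in rank,
#' while the reported relevance is conventionally non-increasing.
#'
#' @param table A \code{feature_table} (or data.frame with a \code{label}
#'   column).
#' @param k Number of features to rank (default: all).
#' @return A \code{ranked_features} data.frame with columns \code{rank},
#'   \code{feature}, \code{score}, \code{raw_quotient}, \code{f_stat}.
#' @export
mrmr_rank <- function(table, k = NULL) {
  feats <- feature_columns(table)
  if (is.null(k)) k <- length(feats)
  if (!is_count(k)) stopf("`k` must be a positive integer")
  k <- min(k, length(feats))
  x <- as.matrix(table[, feats, drop = FALSE])
  y <- factor(table$label)
  if (nlevels(droplevels(y)) != 2L) stopf("exactly two classes are required")
  n <- nrow(x)
  f <- f_statistic(x, y)
  sds <- sqrt(colSums(sweep(x, 2L, colMeans(x))^2) / (n - 1))
  const <- sds == 0
  xz <- sweep(x, 2L, colMeans(x))
  xz <- sweep(xz, 2L, ifelse(const, 1, sds), "/")

  p <- length(feats)
  selected <- integer(0)
  raw <- numeric(0)
  sumabs <- rep(0, p)
  remaining <- rep(TRUE, p)
  for (step in seq_len(k)) {
    if (step == 1L) {
      quot <- f
    } else {
      red <- sumabs / length(selected)
      quot <- f / pmax(red, 1e-12)
    }
    quot[const] <- 0
    quot[!remaining] <- -Inf
    pick <- which.max(quot)
    selected <- c(selected, pick)
    raw <- c(raw, max(quot[pick], 0))
    remaining[pick] <- FALSE
    if (step < k) {
      cors <- abs(as.numeric(crossprod(xz, xz[, pick])) / (n - 1))
      cors[const | !is.finite(cors)] <- 0
      sumabs <- sumabs + cors
    }
  }
  score <- cummin(raw)
  if (score[1L] > 0) score <- 100 * score / score[1L]
  out <- data.frame(rank = seq_along(selected),
                    feature = feats[selected],
                    score = score,
                    raw_quotient = raw,
                    f_stat = f[selected],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_features", "data.frame")
  out
}

#' Two-sided Mann-Whitney U test p-value
#'
#' For class sizes up to 8 on both sides, the exact permutation distribution
#' of U is enumerated (ties handled via midranks). Larger samples use the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric vectors for the two groups.
#' @return List with \code{p.value}, \code{U} (statistic of group \code{x}),
#'   \code{exact}.
#' @export
mwu_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stopf("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (max(n1, n2) <= 8L) {
    n <- n1 + n2
    combs <- utils::combn(n, n1)
    Us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    return(list(p.value = p, U = U, exact = TRUE))
  }
  n <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(p.value = 1, U = U, exact = FALSE))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  list(p.value = min(1, 2 * pnorm(-z)), U = U, exact = FALSE)
}

#' Filter candidate features by Mann-Whitney U tests
#'
#' Runs a two-sided Mann-Whitney U test per candidate feature (haptic vs
#' non-haptic), retains those with p below \code{alpha}, and orders them by
#' ascending p-value. No multiple-testing correction is applied by default;
#' set \code{adjust = "BH"} for Benjamini-Hochberg-adjusted filtering.
#'
#' @param table A \code{feature_table}.
#' @param candidates Feature names to test (must exist in \code{table}).
#' @param alpha Significance threshold (default 0.05).
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return A \code{selection_result} (method \code{"mrmr_mwu"}) with the
#'   retained features sorted by ascending p; the \code{p_values} element
#'   covers all candidates.
#' @export
mwu_filter <- function(table, candidates, alpha = 0.05,
                       adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (length(candidates) == 0L) stopf("`candidates` must be non-empty")
  missing <- setdiff(candidates, colnames(table))
  if (length(missing) > 0)
    stopf("candidate feature(s) not in table: %s", paste(missing, collapse = ", "))
  y <- factor(table$label)
  i1 <- y == "haptic"
  p <- vapply(candidates, function(f) {
    mwu_test(table[[f]][i1], table[[f]][!i1])$p.value
  }, numeric(1))
  pf <- if (adjust == "BH") stats::p.adjust(p, method = "BH") else p
  keep <- which(pf < alpha)
  keep <- keep[order(p[keep])]
  structure(
    list(method = "mrmr_mwu",
         features = candidates[keep],
         p_values = p,
         retained_p = p[keep],
         alpha = alpha,
         adjust = adjust),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method = %s, %d feature(s)\n",
              x$method, length(x$features)))
  if (x$method == "mrmr_mwu") {
    for (i in seq_along(x$features))
      cat(sprintf("  %2d. %-30s p = %.3g\n", i, x$features[i], x$retained_p[i]))
  } else {
    for (i in seq_along(x$features))
      cat(sprintf("  %2d. %-30s score = %.2f\n", i, x$features[i], x$scores[i]))
  }
  invisible(x)
}

#' Select features by MRMR or MRMR + Mann-Whitney
#'
#' \code{method = "mrmr"}: the top \code{k} of \code{\link{mrmr_rank}}.
#' \code{method = "mrmr_mwu"}: the MRMR top-\code{pool} (default 20) filtered
#' by \code{\link{mwu_filter}} at \code{alpha}, reordered by ascending p and
#' truncated to \code{k}. If fewer than \code{k} candidates survive the
#' filter, all survivors are returned with a warning.
#'
#' @param table A \code{feature_table}.
#' @param method \code{"mrmr"} or \code{"mrmr_mwu"}.
#' @param k Number of features to return.
#' @param pool MRMR candidate pool size for the hybrid method.
#' @param alpha Mann-Whitney significance threshold.
#' @return A \code{selection_result}.
#' @export
select_features <- function(table, method = c("mrmr", "mrmr_mwu"), k = 10,
                            pool = 20, alpha = 0.05) {
  method <- match.arg(method)
  if (!is_count(k)) stopf("`k` must be a positive integer")
  if (method == "mrmr") {
    rk <- mrmr_rank(table, k)
    return(structure(
      list(method = "mrmr", features = rk$feature, scores = rk$score,
           alpha = NA_real_),
      class = "selection_result"))
  }
  rk <- mrmr_rank(table, min(pool, length(feature_columns(table))))
  sel <- mwu_filter(table, rk$feature, alpha = alpha)
  if (length(sel$features) < k) {
    warnf("only %d of %d requested features survive the Mann-Whitney filter",
          length(sel$features), k)
    return(sel)
  }
  sel$features <- sel$features[seq_len(k)]
  sel$retained_p <- sel$retained_p[seq_len(k)]
  sel
}
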