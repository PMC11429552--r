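#' Classifier specification
#'
#' @param model_id One of "SGD", "SVC", "DT", "GNB", "KNN", "RF", "MLP".
#' @param grid Named list of hyperparameter values (each entry a vector of
#'   candidate values); NULL uses the model's default grid.
#' @return An object of class \code{model_spec}.
#' @export
model_spec <- function(model_id, grid = NULL) {
  ids <- c("SGD", "SVC", "DT", "GNB", "KNN", "RF", "MLP")
  if (!model_id %in% ids)
    stopf("model_id must be one of %s", paste(ids, collapse = ", "))
  if (is.null(grid)) grid <- default_grids()[[model_id]]
  if (!is.list(grid) || length(grid) == 0L || is.null(names(grid)))
    stopf("`grid` must be a non-empty named list")
  known <- names(default_grids()[[model_id]])
  bad <- setdiff(names(grid), known)
  if (length(bad) > 0)
    stopf("invalid grid entr%s for %s: %s (known: %s)",
          if (length(bad) > 1) "ies" else "y", model_id,
          paste(bad, collapse = ", "), paste(known, collapse = ", "))
  structure(list(model_id = model_id, grid = grid), class = "model_spec")
}

default_grids <- function() {
  list(
    SGD = list(loss = c("hinge", "log"), alpha = c(1e-4, 1e-3, 1e-2)),
    SVC = list(kernel = c("rbf", "linear"), C = c(0.1, 1, 10),
               gamma = c("scale", "0.01", "0.1")),
    DT  = list(max_depth = c(5, 10, NA), min_samples_leaf = c(1, 5)),
    GNB = list(var_smoothing = c(1e-9, 1e-7)),
    KNN = list(k = c(3, 5, 9, 15), metric = c("euclidean", "manhattan")),
    RF  = list(num_trees = c(100, 300), max_depth = c(NA, 10)),
    MLP = list(hidden = c(50, 100, 25), alpha = c(1e-4, 1e-3), max_iter = 500)
  )
}

#' Default specifications of the seven-classifier battery
#'
#' Stochastic gradient descent linear classifier (SGD), support vector
#' classifier (SVC), decision tree (DT), Gaussian Naive Bayes (GNB),
#' k-nearest neighbours (KNN), random forest (RF) and a single-hidden-layer
#' multilayer perceptron (MLP), each with a small default hyperparameter
#' grid.
#'
#' @return Named list of \code{\link{model_spec}} objects.
#' @export
default_model_specs <- function() {
  ids <- c("SGD", "SVC", "DT", "GNB", "KNN", "RF", "MLP")
  out <- lapply(ids, model_spec)
  names(out) <- ids
  out
}

expand_grid_rows <- function(grid) {
  df <- expand.grid(grid, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

# drop grid rows that are duplicates for the model (linear SVC ignores gamma)
prune_grid <- function(model_id, rows) {
  if (model_id != "SVC") return(rows)
  seen <- character(0)
  keep <- list()
  for (r in rows) {
    key <- if (identical(r$kernel, "linear")) paste("linear", r$C)
           else paste("rbf", r$C, r$gamma)
    if (key %in% seen) next
    seen <- c(seen, key)
    keep[[length(keep) + 1L]] <- r
  }
  keep
}

#' Random 80/20 shuffle split
#'
#' Uniformly random permutation of the rows under the seed; the first
#' \code{round(train_frac * n)} go to training.
#'
#' @param table A \code{feature_table} (or anything with rows); alternatively
#'   an integer row count.
#' @param train_frac Training fraction in (0, 1).
#' @param seed Integer seed.
#' @param stratified Draw the training rows per class instead of from the
#'   pooled rows (off by default, matching a plain shuffle; requires a
#'   table with a \code{label} column).
#' @return Object of class \code{split_indices} with \code{train},
#'   \code{test}, \code{seed} and per-class counts in \code{class_counts}.
#' @export
shuffle_split <- function(table, train_frac = 0.8, seed = 1,
                          stratified = FALSE) {
  n <- if (is.numeric(table) && length(table) == 1L) as.integer(table)
       else nrow(table)
  if (is.null(n) || n < 10L) stopf("need at least 10 rows to split")
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1)
    stopf("`train_frac` must lie strictly between 0 and 1")
  if (stratified) {
    if (is.numeric(table) || is.null(table$label))
      stopf("stratified splitting needs a table with a `label` column")
    perm <- with_seed(seed, {
      tr <- unlist(lapply(split(seq_len(n), table$label), function(rows) {
        sample(rows, round(train_frac * length(rows)))
      }), use.names = FALSE)
      c(tr, sample(setdiff(seq_len(n), tr)))
    })
    ntrain <- sum(vapply(split(seq_len(n), droplevels(factor(table$label))),
                         function(rows) round(train_frac * length(rows)),
                         numeric(1)))
  } else {
    perm <- with_seed(seed, sample.int(n))
    ntrain <- round(train_frac * n)
  }
  cc <- NULL
  if (!is.numeric(table) && !is.null(table$label)) {
    cc <- list(train = table(table$label[perm[seq_len(ntrain)]]),
               test = table(table$label[perm[-seq_len(ntrain)]]))
  }
  structure(list(train = perm[seq_len(ntrain)], test = perm[-seq_len(ntrain)],
                 seed = seed, class_counts = cc),
            class = "split_indices")
}

#' Leave-one-participant-out split
#'
#' Holds out every epoch of one participant as the test set. Pooled shuffle
#' splits share participants between train and test, which can inflate
#' accuracy; this split is the conservative alternative for multi-subject
#' tables.
#'
#' @param table A \code{feature_table} with a \code{participant} column.
#' @param holdout The participant id to hold out.
#' @return A \code{split_indices} object.
#' @export
participant_split <- function(table, holdout) {
  if (is.null(table$participant)) stopf("table has no `participant` column")
  test <- which(table$participant == holdout)
  if (length(test) == 0L)
    stopf("participant '%s' not present (ids: %s)", holdout,
          paste(sort(unique(table$participant)), collapse = ", "))
  train <- setdiff(seq_len(nrow(table)), test)
  cc <- NULL
  if (!is.null(table$label))
    cc <- list(train = table(table$label[train]),
               test = table(table$label[test]))
  structure(list(train = train, test = test, seed = NA_integer_,
                 class_counts = cc),
            class = "split_indices")
}

# ---- model backends ----------------------------------------------------
# x: standardized numeric matrix; y: factor with 2 levels

fit_sgd <- function(x, y, loss, alpha, seed, n_epochs = 10) {
  lev <- levels(y)
  yy <- ifelse(y == lev[2L], 1, -1)
  n <- nrow(x); d <- ncol(x)
  w <- rep(0, d); b <- 0
  t <- 0
  with_seed(seed, {
    for (ep in seq_len(n_epochs)) {
      ord <- sample.int(n)
      for (i in ord) {
        t <- t + 1
        eta <- 1 / (alpha * (t + 1 / alpha))
        f <- sum(w * x[i, ]) + b
        if (loss == "hinge") {
          grad_on <- yy[i] * f < 1
          w <- (1 - eta * alpha) * w + if (grad_on) eta * yy[i] * x[i, ] else 0
          if (grad_on) b <- b + eta * yy[i]
        } else {
          s <- 1 / (1 + exp(yy[i] * f))
          w <- (1 - eta * alpha) * w + eta * yy[i] * s * x[i, ]
          b <- b + eta * yy[i] * s
        }
      }
    }
  })
  list(w = w, b = b, levels = lev)
}

predict_sgd <- function(fit, x) {
  f <- as.numeric(x %*% fit$w) + fit$b
  factor(ifelse(f >= 0, fit$levels[2L], fit$levels[1L]), levels = fit$levels)
}

fit_gnb <- function(x, y, var_smoothing) {
  lev <- levels(y)
  eps <- var_smoothing * max(apply(x, 2L, var))
  stats_by <- lapply(lev, function(l) {
    xi <- x[y == l, , drop = FALSE]
    list(mu = colMeans(xi),
         v = apply(xi, 2L, var) * (nrow(xi) - 1) / nrow(xi) + eps,
         prior = nrow(xi) / nrow(x))
  })
  names(stats_by) <- lev
  list(stats = stats_by, levels = lev)
}

predict_gnb <- function(fit, x) {
  ll <- vapply(fit$levels, function(l) {
    s <- fit$stats[[l]]
    rowSums(sweep(sweep(x, 2L, s$mu)^2, 2L, -2 * s$v, "/")) -
      sum(0.5 * log(2 * pi * s$v)) + log(s$prior)
  }, numeric(nrow(x)))
  ll <- matrix(ll, ncol = length(fit$levels))
  factor(fit$levels[max.col(ll, ties.method = "first")], levels = fit$levels)
}

.fit_model <- function(model_id, x, y, params, seed) {
  switch(model_id,
    SGD = list(kind = "SGD",
               fit = fit_sgd(x, y, params$loss, params$alpha, seed)),
    SVC = {
      gamma <- if (identical(params$gamma, "scale")) {
        v <- mean(apply(x, 2L, var)); 1 / (ncol(x) * max(v, 1e-12))
      } else as.numeric(params$gamma)
      kern <- if (identical(params$kernel, "rbf")) "radial" else "linear"
      list(kind = "SVC",
           fit = e1071::svm(x, y, kernel = kern, cost = params$C,
                            gamma = gamma, scale = FALSE))
    },
    DT = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      md <- if (is.na(params$max_depth)) 30L else as.integer(params$max_depth)
      list(kind = "DT",
           fit = rpart::rpart(.y ~ ., data = df, method = "class",
                              control = rpart::rpart.control(
                                maxdepth = md,
                                minbucket = as.integer(params$min_samples_leaf),
                                cp = 0, xval = 0)))
    },
    GNB = list(kind = "GNB", fit = fit_gnb(x, y, params$var_smoothing)),
    KNN = list(kind = "KNN",
               fit = list(x = x, y = y, k = as.integer(params$k),
                          metric = match(params$metric,
                                         c("euclidean", "manhattan")) - 1L,
                          levels = levels(y))),
    RF = {
      md <- if (is.na(params$max_depth)) 0L else as.integer(params$max_depth)
      df <- data.frame(.y = y, x, check.names = FALSE)
      list(kind = "RF",
           fit = ranger::ranger(.y ~ ., data = df,
                                num.trees = as.integer(params$num_trees),
                                max.depth = md, seed = seed,
                                num.threads = 1L))
    },
    MLP = {
      fit <- with_seed(seed,
        nnet::nnet(x, stats::model.matrix(~ y - 1)[, 2L, drop = FALSE],
                   size = as.integer(params$hidden),
                   decay = params$alpha, maxit = as.integer(params$max_iter),
                   entropy = TRUE, MaxNWts = 50000, trace = FALSE))
      list(kind = "MLP", fit = fit, levels = levels(y))
    },
    stopf("unknown model id '%s'", model_id))
}

.predict_model <- function(model, x) {
  switch(model$kind,
    SGD = predict_sgd(model$fit, x),
    SVC = predict(model$fit, x),
    DT = predict(model$fit, newdata = data.frame(x, check.names = FALSE),
                 type = "class"),
    GNB = predict_gnb(model$fit, x),
    KNN = {
      pr <- cpp_knn_predict(model$fit$x, x,
                            as.integer(model$fit$y) - 1L,
                            model$fit$k, model$fit$metric,
                            length(model$fit$levels))
      factor(model$fit$levels[pr + 1L], levels = model$fit$levels)
    },
    RF = predict(model$fit, data = data.frame(x, check.names = FALSE))$predictions,
    MLP = {
      p <- predict(model$fit, x)
      factor(ifelse(p[, 1L] >= 0.5, model$levels[2L], model$levels[1L]),
             levels = model$levels)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# z-score scaler fit on training rows only
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(center = mu, scale = sdv)
}

apply_scaler <- function(scaler, x) {
  sweep(sweep(as.matrix(x), 2L, scaler$center), 2L, scaler$scale, "/")
}

#' Grid search + refit on a training partition
#'
#' Exhaustive search over the model's hyperparameter grid by mean k-fold
#' cross-validated accuracy on the training rows only. Features are z-scored
#' with statistics fit on each fold's training part during CV, and on the
#' full training partition for the final refit; the stored scaler is applied
#' to any data passed to \code{predict}. Deterministic under \code{seed} for
#' seedable models.
#'
#' @param spec A \code{\link{model_spec}}.
#' @param x Training feature matrix / data.frame (raw, unstandardized).
#' @param y Training labels (two classes present).
#' @param cv_folds Number of CV folds (default 5).
#' @param seed Integer seed (fold assignment and model randomness).
#' @return Object of class \code{grid_fit} with \code{best_params},
#'   \code{cv_accuracy}, the refit model and the training scaler.
#' @export
grid_train <- function(spec, x, y, cv_folds = 5, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  # backends with formula interfaces reject names like "Cz_21-30Hz_PSD"
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- droplevels(factor(y))
  if (nlevels(y) < 2L) stopf("training data must contain at least 2 classes")
  rows <- prune_grid(spec$model_id, expand_grid_rows(spec$grid))
  n <- nrow(x)
  folds <- with_seed(seed, sample(rep(seq_len(cv_folds), length.out = n)))
  cv_acc <- numeric(length(rows))
  for (ri in seq_along(rows)) {
    acc <- numeric(cv_folds)
    for (fi in seq_len(cv_folds)) {
      tr <- folds != fi
      scaler <- fit_scaler(x[tr, , drop = FALSE])
      xtr <- apply_scaler(scaler, x[tr, , drop = FALSE])
      xte <- apply_scaler(scaler, x[!tr, , drop = FALSE])
      fit <- .fit_model(spec$model_id, xtr, y[tr], rows[[ri]],
                        seed = seed + fi)
      pred <- .predict_model(fit, xte)
      acc[fi] <- mean(pred == y[!tr])
    }
    cv_acc[ri] <- mean(acc)
  }
  best <- which.max(cv_acc)
  scaler <- fit_scaler(x)
  fit <- .fit_model(spec$model_id, apply_scaler(scaler, x), y, rows[[best]],
                    seed = seed)
  structure(list(model_id = spec$model_id,
                 best_params = rows[[best]],
                 cv_accuracy = cv_acc[best],
                 cv_grid = cv_acc,
                 fit = fit, scaler = scaler, levels = levels(y)),
            class = "grid_fit")
}

#' @export
predict.grid_fit <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  x <- apply_scaler(object$scaler, x)
  .predict_model(object$fit, x)
}

#' @export
print.grid_fit <- function(x, ...) {
  cat(sprintf("<grid_fit> %s, CV accuracy %.1f%%\n",
              x$model_id, 100 * x$cv_accuracy))
  cat("  best:", paste(names(x$best_params),
                       vapply(x$best_params, format, ""), sep = "=",
                       collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate the classifier battery over nested feature subsets
#'
#' For each subset size s and each model: restrict the feature table to the
#' top-s selected features (a size equal to or above the total feature count
#' means "all features"), grid-train on the 80% training partition of one
#' shared shuffle split, and report held-out test accuracy in percent.
#'
#' @param table A \code{feature_table}.
#' @param selection A \code{selection_result} giving the feature ordering.
#' @param sizes Integer vector of subset sizes (e.g. \code{c(5, 10, 15, 20,
#'   360)}). Sizes above the number of selected features (but below the
#'   total) are truncated with a warning.
#' @param models List of \code{\link{model_spec}}s (default: all seven).
#' @param seed Integer seed (split, folds, model randomness).
#' @param train_frac Training fraction (default 0.8).
#' @param cv_folds CV folds inside the grid search.
#' @param split Optional \code{split_indices} to use instead of the seeded
#'   shuffle split (e.g. a \code{\link{participant_split}}).
#' @return An \code{accuracy_report}: accuracy matrix (models x sizes, in %)
#'   plus metadata with per-cell best hyperparameters.
#' @export
evaluate_battery <- function(table, selection, sizes = c(5, 10, 15, 20),
                             models = default_model_specs(), seed = 1,
                             train_frac = 0.8, cv_folds = 5, split = NULL) {
  stopifnot(inherits(selection, "selection_result"))
  feats <- feature_columns(table)
  if (is.null(split))
    split <- shuffle_split(table, train_frac = train_frac, seed = seed)
  stopifnot(inherits(split, "split_indices"))
  y <- factor(table$label)
  acc <- matrix(NA_real_, length(models), length(sizes),
                dimnames = list(vapply(models, `[[`, "", "model_id"),
                                ifelse(sizes >= length(feats), "all", sizes)))
  best <- vector("list", length(models) * length(sizes))
  dim(best) <- c(length(models), length(sizes))
  for (si in seq_along(sizes)) {
    s <- sizes[si]
    if (s >= length(feats)) {
      cols <- feats
    } else {
      if (s > length(selection$features)) {
        warnf("size %d exceeds the %d selected features; truncating",
              s, length(selection$features))
        s <- length(selection$features)
      }
      cols <- selection$features[seq_len(s)]
    }
    xs <- as.matrix(table[, cols, drop = FALSE])
    for (mi in seq_along(models)) {
      fit <- grid_train(models[[mi]], xs[split$train, , drop = FALSE],
                        y[split$train], cv_folds = cv_folds, seed = seed)
      pred <- predict(fit, xs[split$test, , drop = FALSE])
      acc[mi, si] <- 100 * mean(pred == y[split$test])
      best[[mi, si]] <- fit$best_params
    }
  }
  structure(list(accuracy = acc,
                 sizes = sizes,
                 method = selection$method,
                 seed = seed,
                 best_params = best,
                 split = split),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> selection = %s, seed = %d (test accuracy %%)\n",
              x$method, x$seed))
  print(round(x$accuracy, 1))
  invisible(x)
}
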