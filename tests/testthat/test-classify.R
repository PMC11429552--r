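test_that("the shuffle split is a seeded 80/20 partition", {
  sp <- shuffle_split(3000, seed = 1)
  expect_equal(length(sp$train), 2400)
  expect_equal(length(sp$test), 600)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:3000)
  expect_identical(shuffle_split(3000, seed = 1)$train, sp$train)
  expect_false(identical(shuffle_split(3000, seed = 2)$train, sp$train))
  expect_error(shuffle_split(5), "at least 10")
  expect_error(shuffle_split(100, train_frac = 1.2), "train_frac")
})

test_that("model specs validate their ids and grid entries", {
  expect_error(model_spec("XGB"), "model_id")
  expect_error(model_spec("KNN", list(neighbours = 3)), "neighbours")
  expect_length(default_model_specs(), 7)
  expect_named(default_model_specs(),
               c("SGD", "SVC", "DT", "GNB", "KNN", "RF", "MLP"))
})

test_that("a perfectly separating feature yields perfect KNN cross-validation", {
  set.seed(1)
  n <- 200
  y <- factor(rep(c("haptic", "non_haptic"), each = n / 2))
  x <- cbind(sep = ifelse(y == "haptic", -3, 3) + rnorm(n, sd = 0.1),
             noise = rnorm(n))
  fit <- grid_train(model_spec("KNN"), x, y, seed = 3)
  expect_equal(fit$cv_accuracy, 1)
  expect_true(all(predict(fit, x) == y))
})

test_that("randomly permuted labels stay at chance through the grid search", {
  set.seed(2)
  n <- 600
  y <- factor(sample(rep(c("haptic", "non_haptic"), each = n / 2)))
  x <- matrix(rnorm(n * 5), n, 5)
  for (id in c("GNB", "KNN")) {
    fit <- grid_train(model_spec(id), x, y, seed = 4)
    expect_gte(fit$cv_accuracy, 0.45)
    expect_lte(fit$cv_accuracy, 0.55)
  }
})

test_that("a one-point grid returns that combination", {
  set.seed(3)
  y <- factor(rep(c("haptic", "non_haptic"), each = 30))
  x <- matrix(rnorm(60 * 3), 60, 3)
  fit <- grid_train(model_spec("KNN", list(k = 9, metric = "manhattan")),
                    x, y, seed = 1)
  expect_equal(fit$best_params$k, 9)
  expect_equal(fit$best_params$metric, "manhattan")
})

test_that("standardization statistics come from the training rows only", {
  set.seed(4)
  y <- factor(rep(c("haptic", "non_haptic"), each = 50))
  x <- matrix(rnorm(100 * 4, mean = 5, sd = 2), 100, 4)
  fit <- grid_train(model_spec("GNB"), x, y, seed = 2)
  expect_equal(unname(fit$scaler$center), unname(colMeans(x)))
  expect_equal(unname(fit$scaler$scale), unname(apply(x, 2, sd)))
  # independently re-applying the scaler reproduces the predictions
  xs <- sweep(sweep(x, 2, colMeans(x)), 2, apply(x, 2, sd), "/")
  colnames(xs) <- paste0("V", 1:4)
  manual <- hapticEEG:::.predict_model(fit$fit, xs)
  expect_identical(as.character(manual), as.character(predict(fit, x)))
})

test_that("the battery reports one accuracy cell per model and size", {
  set.seed(5)
  n <- 120
  y <- rep(c("haptic", "non_haptic"), each = n / 2)
  cols <- c(lapply(1:4, function(i) rnorm(n) + (y == "haptic") * 1.5),
            lapply(5:12, function(i) rnorm(n)))
  names(cols) <- sprintf("f%02d", 1:12)
  tab <- make_toy_table(cols, y)
  sel <- select_features(tab, "mrmr", k = 8)
  expect_warning(
    rep5 <- evaluate_battery(tab, sel, sizes = c(2, 4, 6, 8, 12),
                             models = tiny_model_specs(), seed = 6,
                             cv_folds = 3),
    NA)
  expect_equal(dim(rep5$accuracy), c(7, 5))
  expect_equal(colnames(rep5$accuracy)[5], "all")
  expect_true(all(rep5$accuracy >= 0 & rep5$accuracy <= 100))
  # deterministic backends reproduce the report under the same seed
  det <- tiny_model_specs()[c("DT", "GNB", "KNN", "SVC")]
  r1 <- evaluate_battery(tab, sel, sizes = c(4, 8), models = det, seed = 7,
                         cv_folds = 3)
  r2 <- evaluate_battery(tab, sel, sizes = c(4, 8), models = det, seed = 7,
                         cv_folds = 3)
  expect_identical(r1$accuracy, r2$accuracy)
  # sizes above the selected set are truncated with a warning
  expect_warning(
    evaluate_battery(tab, sel, sizes = 10, models = det["KNN"], seed = 8,
                     cv_folds = 3),
    "truncat")
})

test_that("more selected features do not lose information on average (moderate effects)", {
  wins <- 0L
  for (s in 1:5) {
    cfg <- generator_config(n_participants = 5, trials_per_class = 20,
                            preset = "moderate", seed = 100 + s)
    run <- generate_epochs(cfg)
    tab <- extract_feature_table(band_decompose(run$epochs))
    sel <- select_features(tab, "mrmr", k = 10)
    det <- tiny_model_specs()[c("GNB", "KNN", "DT")]
    rep5 <- evaluate_battery(tab, sel, sizes = c(5, 10), models = det,
                             seed = s, cv_folds = 3)
    if (mean(rep5$accuracy[, 2]) >= mean(rep5$accuracy[, 1])) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("stratified and leave-one-participant-out splits partition as documented", {
  set.seed(9)
  y <- rep(c("haptic", "non_haptic"), times = c(60, 40))
  tab <- make_toy_table(list(a = rnorm(100)), y,
                        participant = rep(1:4, each = 25))
  sp <- shuffle_split(tab, seed = 1, stratified = TRUE)
  expect_equal(as.numeric(sp$class_counts$train), c(48, 32))
  expect_setequal(c(sp$train, sp$test), 1:100)
  expect_error(shuffle_split(100, stratified = TRUE), "label")
  lo <- participant_split(tab, 3)
  expect_setequal(lo$test, 51:75)
  expect_length(intersect(lo$train, lo$test), 0)
  expect_error(participant_split(tab, 9), "not present")
  # battery accepts an externally supplied split
  tab2 <- make_toy_table(list(a = rnorm(100) + (y == "haptic") * 5,
                              b = rnorm(100)), y,
                         participant = rep(1:4, each = 25))
  sel <- select_features(tab2, "mrmr", k = 1)
  rep_lo <- evaluate_battery(tab2, sel, sizes = 1,
                             models = tiny_model_specs()["KNN"],
                             seed = 2, cv_folds = 3, split = lo)
  expect_gt(rep_lo$accuracy[1, 1], 90)
})
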