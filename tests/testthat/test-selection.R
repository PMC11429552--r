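test_that("the F statistic agrees with one-way ANOVA", {
  set.seed(1)
  y <- rep(c("haptic", "non_haptic"), each = 20)
  x <- matrix(rnorm(40 * 5), 40, 5)
  x[, 2] <- x[, 2] + (y == "haptic") * 1.5
  f <- f_statistic(x, y)
  for (j in 1:5) expect_equal(f[j], f_oracle(x[, j], y), tolerance = 1e-10)
  xc <- cbind(x, 7)  # constant column
  expect_equal(unname(f_statistic(xc, y)[6]), 0)
})

test_that("the MRMR quotient penalizes redundant copies (toy brute-force check)", {
  set.seed(2)
  n <- 400
  y <- rep(c("haptic", "non_haptic"), each = n / 2)
  f1 <- (y == "haptic") + rnorm(n, sd = 1.2)   # strongest single feature
  f2 <- f1                                     # exact copy: maximal redundancy
  f3 <- 0.5 * (y == "haptic") + rnorm(n, sd = 1.2)  # weaker, non-redundant
  tab <- make_toy_table(list(f1 = f1, f2 = f2, f3 = f3), y)
  rk <- mrmr_rank(tab)
  expect_identical(rk$feature[1], "f1")
  # brute-force quotients at step 2: the copy is divided by |r| = 1, the
  # weaker feature only by its small incidental correlation with f1
  fstat <- f_statistic(as.matrix(tab[, c("f1", "f2", "f3")]), y)
  q2 <- fstat[2] / abs(cor(f2, f1))
  q3 <- fstat[3] / abs(cor(f3, f1))
  expect_lt(q2, q3)
  expect_identical(rk$feature[2], "f3")
})

test_that("MRMR scores are rescaled to 100, non-increasing, and the ranking is total", {
  set.seed(3)
  y <- rep(c("haptic", "non_haptic"), each = 30)
  cols <- list(a = rnorm(60) + (y == "haptic"), b = rnorm(60), c = rnorm(60),
               d = rep(1, 60))
  tab <- make_toy_table(cols, y)
  rk <- mrmr_rank(tab)
  expect_equal(rk$score[1], 100)
  expect_true(all(diff(rk$score) <= 1e-12))
  expect_identical(rk$feature[4], "d")   # constant ranks last
  expect_equal(unname(rk$score[4]), 0)
  expect_identical(mrmr_rank(tab), rk)   # deterministic
  one <- make_toy_table(list(a = rnorm(60) + (y == "haptic")), y)
  rk1 <- mrmr_rank(one)
  expect_equal(rk1$score, 100)
  # full ranking is a permutation of all columns
  expect_setequal(mrmr_rank(tab, k = 4)$feature, c("a", "b", "c", "d"))
  expect_error(mrmr_rank(make_toy_table(cols, rep("haptic", 60))), "two classes")
  expect_error(mrmr_rank(tab, k = 0), "k")
})

test_that("Mann-Whitney p-values match exact enumeration for small groups (ties included)", {
  set.seed(4)
  cases <- list(
    list(x = c(1.2, 3.4, 0.1, 2.2), y = c(4.5, 6.1, 5.0)),
    list(x = rnorm(6), y = rnorm(8) + 1),
    list(x = c(1, 2, 2, 3), y = c(2, 3, 3, 4)),        # heavy ties
    list(x = c(5, 5, 5), y = c(5, 5, 5, 5)),           # all tied
    list(x = rnorm(8), y = rnorm(8))
  )
  for (cs in cases) {
    got <- mwu_test(cs$x, cs$y)
    expect_true(got$exact)
    expect_equal(got$p.value, mwu_oracle_exact(cs$x, cs$y), tolerance = 1e-12)
  }
  # tie-free exact agrees with the reference implementation
  x <- c(0.3, 1.7, 2.9, 4.1, 0.9); y <- c(2.2, 3.3, 5.5, 6.6)
  expect_equal(mwu_test(x, y)$p.value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
  # large-sample approximation close to the reference implementation
  set.seed(5)
  xl <- rnorm(60); yl <- rnorm(70) + 0.4
  expect_equal(mwu_test(xl, yl)$p.value,
               stats::wilcox.test(xl, yl, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-6)
})

test_that("the Mann-Whitney filter retains shifted features, drops identical ones, orders by p", {
  set.seed(6)
  n <- 300
  y <- rep(c("haptic", "non_haptic"), each = n / 2)
  same <- rnorm(n / 2)
  sep <- c(rnorm(n / 2), rnorm(n / 2) + 50)   # fully separated classes
  weak <- rnorm(n) + 0.4 * (y == "non_haptic")
  tab <- make_toy_table(list(same = c(same, same), sep = sep, weak = weak,
                             noise = rnorm(n)), y)
  sel <- mwu_filter(tab, c("same", "sep", "weak", "noise"))
  expect_s3_class(sel, "selection_result")
  expect_false("same" %in% sel$features)
  expect_identical(sel$features[1], "sep")
  expect_lt(sel$retained_p[1], 1e-40)
  expect_true(all(diff(sel$retained_p) >= 0))
  expect_gt(sel$p_values["same"], 0.9)
  expect_error(mwu_filter(tab, character(0)), "non-empty")
  expect_error(mwu_filter(tab, "absent"), "absent")
})

test_that("fully separated large classes give the extreme U and a vanishing p", {
  x <- seq_len(1500)
  y <- seq_len(1500) + 2000
  got <- mwu_test(y, x)       # first group larger everywhere
  expect_equal(got$U, 1500 * 1500)
  expect_lt(got$p.value, 1e-100)
})

test_that("select_features implements both proposals and warns when survivors run short", {
  set.seed(7)
  n <- 200
  y <- rep(c("haptic", "non_haptic"), each = n / 2)
  cols <- c(lapply(1:3, function(i) rnorm(n) + (y == "haptic") * (4 - i)),
            lapply(4:25, function(i) rnorm(n)))
  names(cols) <- sprintf("f%02d", 1:25)
  tab <- make_toy_table(cols, y)
  sel <- select_features(tab, "mrmr", k = 20)
  expect_length(sel$features, 20)
  expect_identical(select_features(tab, "mrmr", k = 25)$features |> sort(),
                   sort(names(cols)))
  hyb <- select_features(tab, "mrmr_mwu", k = 3)
  expect_length(hyb$features, 3)
  expect_true(all(hyb$retained_p < 0.05))
  # null table: typically far fewer than 10 survivors -> warning path
  null_cols <- lapply(1:25, function(i) rnorm(n))
  names(null_cols) <- sprintf("n%02d", 1:25)
  ntab <- make_toy_table(null_cols, y)
  expect_warning(res <- select_features(ntab, "mrmr_mwu", k = 10), "survive")
  expect_lt(length(res$features), 10)
})
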