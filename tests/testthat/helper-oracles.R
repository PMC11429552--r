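# Independent brute-force oracles, written as literal translations of the
# definitions; deliberately naive and separate from the package kernels.

pe_oracle <- function(x, order = 3, delay = 1) {
  nwin <- length(x) - (order - 1) * delay
  pats <- character(nwin)
  for (t in seq_len(nwin)) {
    w <- x[t + (0:(order - 1)) * delay]
    pats[t] <- paste(order(w) - 1, collapse = "")  # ties: first index wins
  }
  p <- table(pats) / nwin
  -sum(p * log(p))
}

higuchi_oracle <- function(x, kmax = 10) {
  n <- length(x)
  Lk <- numeric(0); ks <- numeric(0)
  for (k in 1:kmax) {
    Ls <- numeric(0)
    for (m in 1:k) {
      nm <- floor((n - m) / k)
      if (nm < 1) next
      s <- 0
      for (i in 1:nm) s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      Ls <- c(Ls, s * (n - 1) / (nm * k) / k)
    }
    if (length(Ls) == 0 || mean(Ls) <= 0) next
    Lk <- c(Lk, mean(Ls)); ks <- c(ks, k)
  }
  unname(coef(lm(log(Lk) ~ log(1 / ks)))[2])
}

hurst_rs_oracle <- function(x) {
  n <- length(x)
  wmin <- if (n >= 64) 16 else 8
  ws <- c(); rs <- c()
  w <- wmin
  while (w <= n / 2) {
    vals <- c()
    for (b in seq_len(n %/% w)) {
      seg <- x[((b - 1) * w + 1):(b * w)]
      s <- sqrt(mean((seg - mean(seg))^2))
      if (s <= 0) next
      y <- cumsum(seg - mean(seg))
      vals <- c(vals, (max(y) - min(y)) / s)
    }
    if (length(vals) > 0) { ws <- c(ws, w); rs <- c(rs, mean(vals)) }
    w <- w * 2
  }
  unname(coef(lm(log(rs) ~ log(ws)))[2])
}

f_oracle <- function(x, g) {
  fit <- stats::lm(x ~ factor(g))
  unname(stats::anova(fit)[["F value"]][1])
}

# exact two-sided Mann-Whitney p by enumeration; U via pairwise counting
# (different computational route than the package's rank-sum formula)
mwu_oracle_exact <- function(x, y) {
  u_pair <- function(a, b) {
    s <- 0
    for (ai in a) for (bi in b) s <- s + (ai > bi) + 0.5 * (ai == bi)
    s
  }
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  mu <- n1 * (n - n1) / 2
  uobs <- u_pair(x, y)
  sets <- utils::combn(n, n1)
  us <- apply(sets, 2, function(idx) u_pair(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(uobs - mu) - 1e-9)
}

# quick labelled feature-table stand-in (no signal processing involved)
make_toy_table <- function(cols, labels, participant = NULL) {
  tab <- as.data.frame(cols, check.names = FALSE)
  tab$label <- factor(labels, levels = c("haptic", "non_haptic"))
  tab$participant <- if (is.null(participant)) 1L else participant
  class(tab) <- c("feature_table", "data.frame")
  tab
}

make_small_epochs <- function(n_epochs = 10, channels = analysis_channels(),
                              n = 512, fs = 1024, seed = 1) {
  set.seed(seed)
  data <- array(rnorm(n_epochs * length(channels) * n),
                dim = c(n_epochs, length(channels), n))
  eeg_epochs(data, fs, channels,
             rep(c("haptic", "non_haptic"), length.out = n_epochs),
             rep(1L, n_epochs))
}

table_cohens_d <- function(tab, feature) {
  y <- tab$label
  cohens_d(tab[[feature]][y == "non_haptic"], tab[[feature]][y == "haptic"])
}
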