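# Independent oracles used across test files.  These are deliberately
# naive (brute-force enumeration, textbook closed forms) and share no
# code with the implementation.

# mean-over-pairs ring difference for one moiety X, enumerating all Y < X
oracle_ring_diff_moiety <- function(eps, rings, X) {
  vals <- c()
  for (j in seq_along(rings)) {
    if (!is.na(eps[j]) && rings[j] < X) {
      i <- which(rings == X)
      vals <- c(vals, (eps[i] - eps[j]) / (X - rings[j]))
    }
  }
  mean(vals)
}

# pooled mean over every pairwise (X, Y) combination with X > Y
oracle_mean_ring_diff <- function(eps, rings) {
  vals <- c()
  for (i in seq_along(rings)) {
    for (j in seq_along(rings)) {
      if (!is.na(eps[i]) && !is.na(eps[j]) && rings[i] > rings[j]) {
        vals <- c(vals, (eps[i] - eps[j]) / (rings[i] - rings[j]))
      }
    }
  }
  mean(vals)
}

# textbook Bartlett K-squared
oracle_bartlett <- function(groups) {
  k <- length(groups)
  ni <- lengths(groups)
  N <- sum(ni)
  vi <- vapply(groups, var, 1)
  sp2 <- sum((ni - 1) * vi) / (N - k)
  num <- (N - k) * log(sp2) - sum((ni - 1) * log(vi))
  den <- 1 + (sum(1 / (ni - 1)) - 1 / (N - k)) / (3 * (k - 1))
  num / den
}

# closed-form simple OLS
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  yhat <- a + b * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = b, intercept = a, r_squared = r2)
}

# inverse-variance weighted mean, written longhand
oracle_weighted_mean <- function(v, s) {
  w <- 1 / s^2
  sum(w * v) / sum(w)
}

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# small synthetic peak batch with known truth, reusing only exported API
make_noiseless_config <- function(...) {
  synthetic_config(noise_base_sigma = 0, noise_amplitude_coeff = 0,
                   growth_noise_sd = 0, ...)
}
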