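# shared fixtures, all generated in code

`%||%` <- function(a, b) if (is.null(a)) b else a

# profile with every stochastic term switched off
quiet_profile <- function(...) {
  subject_profile(acc_noise_sd = 0, gyro_noise_sd = 0, timing_jitter_sd = 0,
                  rom_cycle_cv = 0, tremor_amp = 0, ...)
}

# flat rest posture (sensor z up): included angles (y, z) = (0, 90) deg
flat_rest <- function() matrix(rep(c(0, 90), each = 6), 6, 2)

# small labeled segment set (default-noise profile)
make_segments <- function(n_per_exercise = 3, seed = 11L, profile = NULL) {
  if (is.null(profile)) profile <- subject_profile(seed = seed)
  segment_cycles(generate_dataset(n_per_exercise, profile))
}

# linearly separable 2-feature toy set: classes on a line, two points each
separable_features <- function(n_per_class = 2, jitter = 0.02, seed = 5L) {
  set.seed(seed)
  y <- rep(1:6, each = n_per_class)
  X <- cbind(f1 = y + rnorm(length(y), 0, jitter),
             f2 = -y + rnorm(length(y), 0, jitter))
  list(X = X, y = y)
}

# brute-force time-domain statistics, straight from the definitions
brute_time_features <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  sigma <- sqrt(sum((x - mu)^2) / n)
  q <- as.numeric(quantile(x, c(0.25, 0.75)))
  c(sum = sum(x), abs_sum = sum(abs(x)), sqr_sum = sum(x^2), avg = mu,
    abs_avg = sum(abs(x)) / n, median = median(x), quart = q[2] - q[1],
    min = min(x), max = max(x), range = max(x) - min(x),
    abs_dev_avg = sum(abs(x - mu)) / n, std_dev = sigma, var = sigma^2,
    skrew = sum(((x - mu) / sigma)^3) / n,
    kurt = sum(((x - mu) / sigma)^4) / n)
}

# pairwise-comparison (Mann-Whitney) AUC oracle
brute_auc <- function(scores, y_true, positive_class) {
  sp <- scores[y_true == positive_class]
  sn <- scores[y_true != positive_class]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# brute-force subtractive-clustering density
brute_density <- function(X, r_a) {
  n <- nrow(X)
  vapply(seq_len(n), function(i) {
    sum(vapply(seq_len(n), function(j) {
      exp(-sum((X[i, ] - X[j, ])^2) / (r_a / 2)^2)
    }, 0))
  }, 0)
}
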