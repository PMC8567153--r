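# Independent numerical oracles used across the suite.

# trapezoidal integration of a rate series (deg/s) sampled at fs -> angle (deg)
trapz_integrate <- function(rate, fs) {
  n <- length(rate)
  c(0, cumsum((rate[-1] + rate[-n]) / 2)) / fs
}

# naive O(n^2) DFT amplitude/phase at bin k (0-based), one-sided normalisation;
# independent of stats::fft
dft_bin <- function(x, k) {
  n <- length(x)
  x <- x - mean(x)
  co <- sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))
  scale <- if (k == 0 || (n %% 2 == 0 && k == n / 2)) 1 / n else 2 / n
  list(amplitude = abs(co) * scale, phase = Arg(co))
}

# brute-force mean over the same m windows of 100 samples used by the
# static-drift estimator
window_mean_oracle <- function(x, n0, m, r) {
  vals <- unlist(lapply(seq_len(m) - 1L, function(j) {
    start <- n0 + j * r + 1L
    x[start:(start + 99L)]
  }))
  mean(vals)
}

# rank-statistic AUC (Mann-Whitney), independent of the threshold sweep
auc_rank_oracle <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# a small labelled dataset with gaussian class-shifted features
make_gaussian_dataset <- function(n1, n0, p = 5, shift = 0, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n1 * p, mean = shift), n1, p),
             matrix(rnorm(n0 * p), n0, p))
  labeled_dataset(X, c(rep(1L, n1), rep(0L, n0)))
}

# quick noise-free labelled trial for feature tests
make_test_trial <- function(duration = 10, peak = 70, speed = 35, seed = 1,
                            noise = noise_free(), label = 1L) {
  pr <- generate_stop_sign_profile(duration, peak, speed)
  synthesize_recording(pr, noise, seed = seed, label = label)
}
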