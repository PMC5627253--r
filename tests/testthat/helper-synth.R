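# Shared fixtures, built once per test run. Everything is generated in code;
# nothing is read from disk.

# a clean noiseless record with constant planted ST level
clean_record <- make_ecg_record(
  beat_template_params(st_level = 0.1, st_slope = 0), n_beats = 40, seed = 7)

# per-beat jitter so planted levels/slopes vary
jitter_record <- make_ecg_record(
  beat_template_params(st_level = 0.05, st_slope = 0.002,
                       st_jitter_sd = 0.02), n_beats = 200, seed = 11)

# small cohort reused by model tests (kept small so fits stay fast)
small_cohort <- make_cohort(cohort_spec(300, seed = 42))
small_cw <- cohort_windows(small_cohort)

# independent brute-force Gram-Schmidt (classical, with reorthogonalization)
# used as the projection oracle
oracle_gram_schmidt <- function(n) {
  k <- 0:(n - 1)
  x <- (k - (n - 1) / 2) / ((n - 1) / 2)
  V <- outer(x, 0:(n - 1), `^`)
  Q <- V
  for (j in seq_len(n)) {
    v <- Q[, j]
    if (j > 1) {
      for (pass in 1:2) {
        for (i in seq_len(j - 1)) v <- v - sum(Q[, i] * v) * Q[, i]
      }
    }
    Q[, j] <- v / sqrt(sum(v * v))
  }
  sweep(Q, 2, sign(diag(crossprod(V, Q))), `*`)
}

# brute-force AUC over all event/non-event pairs (ties count one half)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

expect_error_class <- function(expr, class) {
  expect_error(expr, class = class)
}
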