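# Shared fixtures and independent oracles for the test suite.

fs_hz <- 50
n_30s <- 1500

make_tone <- function(freq, n = n_30s, fs = fs_hz, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * seq_len(n) / fs + phase)
}

rms <- function(x) sqrt(mean(x^2))

# accelerometer-only two-device block set used for fast end-to-end runs
acc_blocks <- function(exercises = c(1, 3), hand = "right") {
  expand.grid(device = c("phone", "myo"), sensor = "accelerometer",
              hand = hand, exercise = exercises,
              stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

# Brute-force metric oracle: direct summation, written independently of
# compute_metrics().
oracle_metrics <- function(y, p, grid = 1) {
  n <- length(y)
  mse <- sum((y - p)^2) / n
  mae <- sum(abs(y - p)) / n
  r2 <- 1 - sum((y - p)^2) / sum((y - mean(y))^2)
  r <- sum((y - mean(y)) * (p - mean(p))) /
    sqrt(sum((y - mean(y))^2) * sum((p - mean(p))^2))
  cls <- round(y / grid) * grid
  ks <- sort(unique(cls))
  mae_k <- vapply(ks, function(k) mean(abs(y[cls == k] - p[cls == k])),
                  numeric(1))
  mse_k <- vapply(ks, function(k) mean((y[cls == k] - p[cls == k])^2),
                  numeric(1))
  list(mse = mse, mae = mae, r2 = r2, r = r,
       bmae = sum(mae_k) / length(ks), bmse = sum(mse_k) / length(ks))
}

# small cohort + feature table shared across reporting/model tests,
# built once per session
.fixture_env <- new.env(parent = emptyenv())

tiny_feature_table <- function() {
  if (is.null(.fixture_env$ft)) {
    cfg <- synthetic_config(n_patients = 8, blocks = acc_blocks(),
                            seed = 303)
    coh <- generate_cohort(cfg)
    .fixture_env$cohort <- coh
    .fixture_env$ft <- assemble_feature_table(coh)
  }
  .fixture_env$ft
}

tiny_cohort <- function() {
  invisible(tiny_feature_table())
  .fixture_env$cohort
}
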