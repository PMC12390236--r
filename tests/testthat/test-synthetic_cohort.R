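# Synthetic cohort generator: determinism, label validity, severity-monotone
# signal encodings, class-weight fidelity.

no_block_config <- function(n = 10, seed = 1, ...) {
  synthetic_config(n_patients = n, seed = seed,
                   blocks = data.frame(device = character(0),
                                       sensor = character(0),
                                       hand = character(0),
                                       exercise = integer(0)), ...)
}

test_that("patient and cohort generation are deterministic under a fixed seed", {
  cfg <- synthetic_config(n_patients = 3, blocks = acc_blocks(1), seed = 1)
  expect_identical(generate_patient(cfg, 1), generate_patient(cfg, 1))
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  # serialized datasets are byte-identical
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  unlink(c(d1, d2), recursive = TRUE)
  write_cohort(c1, d1); write_cohort(c2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  # and a written cohort round-trips
  back <- read_cohort(d1)
  exam1 <- names(c1$recordings)[1]
  bk <- names(c1$recordings[[exam1]])[1]
  expect_equal(back$recordings[[exam1]][[bk]]$x,
               c1$recordings[[exam1]][[bk]]$x, tolerance = 1e-12)
})

test_that("degenerate severity weights pin the latent trait", {
  w <- default_severity_weights()
  w$tremor <- c(1, 0, 0, 0, 0)
  cfg <- no_block_config(n = 30, seed = 2, severity_weights = w)
  traits <- vapply(1:30, function(i)
    generate_patient(cfg, i)$trait_severities[["tremor"]], numeric(1))
  expect_true(all(traits == 0))
})

test_that("invalid severity weights are rejected", {
  w <- default_severity_weights()
  w$tremor <- c(0.5, 0.5, 0.5, 0, 0)
  expect_error(synthetic_config(severity_weights = w), "summing to 1")
})

test_that("labels are valid: integer symptoms in 0..4, states on a 0.5 grid in [-4,4]", {
  coh <- generate_cohort(no_block_config(n = 80, seed = 3))
  ex <- coh$examinations
  for (s in c("tremor", "bradykinesia", "stiffness", "dyskinesia")) {
    expect_true(all(ex[[s]] %in% 0:4))
  }
  for (s in c("trs_clinician", "trs_patient")) {
    expect_true(all(ex[[s]] >= -4 & ex[[s]] <= 4))
    expect_true(all(abs(ex[[s]] * 2 - round(ex[[s]] * 2)) < 1e-12))
  }
})

test_that("treatment-response state hits its poles without observer noise", {
  zero <- list(tremor = 0, bradykinesia = 0, stiffness = 0, dyskinesia = 0)
  expect_equal(unname(derive_trs_label(zero, noise_sd = 0)), c(0, 0))
  park <- list(tremor = 4, bradykinesia = 4, stiffness = 4, dyskinesia = 0)
  expect_equal(unname(derive_trs_label(park, noise_sd = 0)), c(-4, -4))
  dysk <- list(tremor = 0, bradykinesia = 0, stiffness = 0, dyskinesia = 4)
  expect_equal(unname(derive_trs_label(dysk, noise_sd = 0)), c(4, 4))
})

test_that("latent trait class frequencies match configured weights (binomial check)", {
  cfg <- no_block_config(n = 500, seed = 4)
  traits <- t(vapply(1:500, function(i)
    generate_patient(cfg, i)$trait_severities, numeric(4)))
  for (s in colnames(traits)) {
    w <- cfg$severity_weights[[s]]
    for (k in 0:4) {
      phat <- mean(traits[, s] == k)
      se <- sqrt(w[k + 1] * (1 - w[k + 1]) / 500)
      expect_lt(abs(phat - w[k + 1]), 3 * se + 1e-9)
    }
  }
})

test_that("examination labels follow the trait-plus-jitter distribution (chi-square)", {
  cfg <- no_block_config(n = 400, seed = 5)
  coh <- generate_cohort(cfg)
  # oracle: exact convolution of trait weights with the +/-1 jitter kernel,
  # clipped to 0..4
  jitter_p <- c(0.15, 0.70, 0.15)
  expected_dist <- function(w) {
    out <- numeric(5)
    for (t in 0:4) for (j in -1:1) {
      k <- min(max(t + j, 0), 4)
      out[k + 1] <- out[k + 1] + w[t + 1] * jitter_p[j + 2]
    }
    out
  }
  for (s in c("tremor", "dyskinesia")) {
    exp_p <- expected_dist(cfg$severity_weights[[s]])
    obs <- tabulate(coh$examinations[[s]] + 1, 5)
    gof <- suppressWarnings(stats::chisq.test(obs, p = exp_p))
    expect_gt(gof$p.value, 0.001)
  }
  # dyskinesia severity 4 stays sparse as configured
  expect_lt(mean(coh$examinations$dyskinesia == 4), 0.05)
})

test_that("zero labels with zero noise give DC-only rest recordings", {
  cfg <- synthetic_config(noise_sd = 0, seed = 6)
  prof <- generate_patient(cfg, 1)
  zero <- list(tremor = 0, bradykinesia = 0, stiffness = 0, dyskinesia = 0)
  rec <- simulate_exercise_signal(prof, zero, "phone", "accelerometer",
                                  "right", 1, seed = 11, config = cfg)
  for (ch in c("x", "y", "z")) {
    expect_lt(diff(range(rec[[ch]])), 1e-9)
  }
  # gravity is present on the accelerometer: total DC magnitude ~ 9.81
  expect_equal(sqrt(rec$x[1]^2 + rec$y[1]^2 + rec$z[1]^2), 9.81,
               tolerance = 1e-6)
  gyro <- simulate_exercise_signal(prof, zero, "phone", "gyroscope",
                                   "right", 1, seed = 11, config = cfg)
  expect_lt(max(abs(gyro$x)), 1e-9)
})

test_that("severity encodings are monotone in the configured directions", {
  cfg <- synthetic_config(seed = 7)
  prof <- generate_patient(cfg, 1)
  lab <- function(tr = 0, br = 0, st = 0, dy = 0)
    list(tremor = tr, bradykinesia = br, stiffness = st, dyskinesia = dy)
  n_seeds <- 20
  strict_tr <- 0; strict_fv <- 0; strict_st <- 0
  for (s in seq_len(n_seeds)) {
    bp <- vapply(0:4, function(tr) {
      rec <- simulate_exercise_signal(prof, lab(tr = tr), "phone",
                                      "accelerometer", "right", 1,
                                      seed = 100 + s, config = cfg)
      pdsense:::bandpower(rec$x - mean(rec$x), 50, 3, 9)
    }, numeric(1))
    expect_true(all(diff(bp) > -1e-12))
    strict_tr <- strict_tr + all(diff(bp) > 0)

    fdom <- vapply(0:4, function(br) {
      rec <- simulate_exercise_signal(prof, lab(br = br), "phone",
                                      "accelerometer", "right", 3,
                                      seed = 200 + s, config = cfg)
      # total movement PSD: sum of per-axis spectra (rotation-invariant)
      sp <- estimate_psd(rec$x - mean(rec$x), 50)
      tot <- sp$psd + estimate_psd(rec$y - mean(rec$y), 50)$psd +
        estimate_psd(rec$z - mean(rec$z), 50)$psd
      sel <- sp$f >= 0.3 & sp$f <= 3
      sp$f[sel][which.max(tot[sel])]
    }, numeric(1))
    expect_true(all(diff(fdom) <= 1e-12))
    strict_fv <- strict_fv + any(diff(fdom) < 0)

    vv <- vapply(0:4, function(st) {
      rec <- simulate_exercise_signal(prof, lab(br = 1, st = st), "phone",
                                      "accelerometer", "right", 3,
                                      seed = 300 + s, config = cfg)
      var(rec$x - mean(rec$x)) + var(rec$y - mean(rec$y)) +
        var(rec$z - mean(rec$z))
    }, numeric(1))
    expect_true(all(diff(vv) < 1e-12))
    strict_st <- strict_st + all(diff(vv) < 0)
  }
  expect_gt(strict_tr, n_seeds / 2)
  expect_gt(strict_fv, n_seeds / 2)
  expect_gt(strict_st, n_seeds / 2)
})

test_that("tremor and stiffness leave the specified signatures in single recordings", {
  cfg <- synthetic_config(seed = 8)
  prof <- generate_patient(cfg, 1)
  lab0 <- list(tremor = 0, bradykinesia = 0, stiffness = 0, dyskinesia = 0)
  lab4 <- list(tremor = 4, bradykinesia = 0, stiffness = 0, dyskinesia = 0)
  r0 <- simulate_exercise_signal(prof, lab0, "phone", "accelerometer",
                                 "right", 1, seed = 5, config = cfg)
  r4 <- simulate_exercise_signal(prof, lab4, "phone", "accelerometer",
                                 "right", 1, seed = 5, config = cfg)
  expect_gt(pdsense:::bandpower(r4$x - mean(r4$x), 50, 3, 9),
            pdsense:::bandpower(r0$x - mean(r0$x), 50, 3, 9))

  s0 <- simulate_exercise_signal(prof, lab0, "phone", "accelerometer",
                                 "right", 3, seed = 5, config = cfg)
  s4 <- simulate_exercise_signal(prof,
                                 list(tremor = 0, bradykinesia = 0,
                                      stiffness = 4, dyskinesia = 0),
                                 "phone", "accelerometer", "right", 3,
                                 seed = 5, config = cfg)
  expect_lt(var(s4$x - mean(s4$x)), var(s0$x - mean(s0$x)))
})

test_that("every block is present when nothing is dropped, and missingness removes blocks", {
  cfg <- synthetic_config(n_patients = 2, seed = 9,
                          missing_block_probability = 0)
  coh <- generate_cohort(cfg)
  expect_true(all(vapply(coh$recordings, length, integer(1)) == 24))
  cfg2 <- synthetic_config(n_patients = 4, seed = 9,
                           missing_block_probability = 0.5)
  coh2 <- generate_cohort(cfg2)
  expect_lt(mean(vapply(coh2$recordings, length, integer(1))), 24)
  # empty cohort is a valid edge case
  empty <- generate_cohort(synthetic_config(n_patients = 0, seed = 1))
  expect_equal(length(empty$recordings), 0)
})
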