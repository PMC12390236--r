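# Feature bank: per processed channel (X, Y, Z, M) a recording yields
#   12 time-domain features        (x4 channels = 48)
#    8 frequency-domain x 4 bands  (= 128)
#    5 STFT window statistics x 4 bands (= 80)
#    5 stats of windowed range + 5 of windowed entropy (= 40)
#    mean/sd of DWT detail levels D1-D3 (= 24)
# plus 3 axis-pair Pearson correlations -> 323 features per recording.

# Adjusted Fisher-Pearson skewness: n/((n-1)(n-2)) * sum(((x-mean)/s)^3);
# defined as 0 for zero-variance input or n < 3.
skewness_adj <- function(x) {
  n <- length(x)
  if (n < 3) return(0)
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(0)
  n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3)
}

# Excess kurtosis: n * sum((x-mean)^4) / (sum((x-mean)^2))^2 - 3; 0 when
# degenerate.
kurtosis_excess <- function(x) {
  n <- length(x)
  if (n < 4) return(0)
  d <- x - mean(x)
  ss <- sum(d^2)
  if (ss == 0) return(0)
  n * sum(d^4) / ss^2 - 3
}

#' Approximate entropy of a sequence
#'
#' Embedding dimension `m = 2`, tolerance `r = 0.2 * sd(x)` by convention;
#' 0 for constant input.
#'
#' @param x numeric sequence.
#' @param m embedding dimension.
#' @param r tolerance; defaults to `0.2 * sd(x)`.
#' @return nonnegative scalar.
#' @export
approx_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  if (!is.finite(r) || r <= 0) return(0)
  .entropies_cpp(as.numeric(x), as.integer(m), r)[1]
}

#' Sample entropy of a sequence
#'
#' @inheritParams approx_entropy
#' @return nonnegative scalar; 0 for constant input or when no template
#'   pairs match.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  if (!is.finite(r) || r <= 0) return(0)
  .entropies_cpp(as.numeric(x), as.integer(m), r)[2]
}

TIME_FEATURE_NAMES <- c("mean", "sd", "median", "skewness", "kurtosis",
                        "max", "min", "iqr", "apen", "sampen", "power",
                        "abs_mean_diff")

#' Time-domain features of one channel
#'
#' Mean, standard deviation, median, adjusted skewness, excess kurtosis,
#' max, min, interquartile range, approximate entropy, sample entropy,
#' power (mean of squares) and the absolute difference between the means of
#' the first and second signal halves (split at `floor(n/2)`).
#'
#' @param x numeric sequence, length >= 4.
#' @param entropies if `FALSE`, the two entropy features are skipped
#'   (10 features instead of 12).
#' @return named numeric vector.
#' @export
time_domain_features <- function(x, entropies = TRUE) {
  n <- length(x)
  if (n < 4) stop("need at least 4 samples for time-domain features")
  h <- n %/% 2
  s <- sd(x)
  ent <- if (!entropies) NULL else if (!is.finite(s) || s == 0) {
    c(apen = 0, sampen = 0)
  } else {
    setNames(.entropies_cpp(as.numeric(x), 2L, 0.2 * s), c("apen", "sampen"))
  }
  c(mean = mean(x), sd = s, median = median(x),
    skewness = skewness_adj(x), kurtosis = kurtosis_excess(x),
    max = max(x), min = min(x), iqr = IQR(x),
    ent,
    power = mean(x^2),
    abs_mean_diff = abs(mean(x[seq_len(h)]) - mean(x[(h + 1):n])))
}

FREQ_FEATURE_NAMES <- c("max_power", "max_power_freq", "spec_power", "wmp",
                        "spec_kurtosis", "spec_skewness", "spec_iqr",
                        "spec_centroid")

# Eight spectral features on one (f, psd) band slice. Degenerate (all-zero
# power) spectra yield zeros so feature tables stay finite.
freq_features_one <- function(f, p) {
  if (length(p) == 0 || sum(p) == 0) {
    return(setNames(rep(0, 8), FREQ_FEATURE_NAMES))
  }
  c(max_power = max(p),
    max_power_freq = f[which.max(p)],
    spec_power = mean(p),
    # weighted mean power normalized by the sum of frequencies
    wmp = if (sum(f) > 0) sum(p * f) / sum(f) else 0,
    spec_kurtosis = kurtosis_excess(p),
    spec_skewness = skewness_adj(p),
    spec_iqr = IQR(p),
    spec_centroid = sum(f * p) / sum(p))
}

#' Frequency-domain features per band
#'
#' Eight features (max power, its frequency, mean spectral power, weighted
#' mean power, spectral kurtosis, skewness, interquartile range of PSD
#' values, spectral centroid) computed on the PSD bins falling inside each
#' of the 0-25, 0-3, 3-9 and 9-14 Hz bands.
#'
#' @param spectrum list with `f` and `psd` as from [estimate_psd()].
#' @param bands named list of Hz intervals.
#' @return named numeric vector of `8 * length(bands)` features.
#' @export
frequency_domain_features <- function(spectrum, bands = FEATURE_BANDS) {
  out <- numeric(0)
  for (bn in names(bands)) {
    sel <- spectrum$f >= bands[[bn]][1] & spectrum$f <= bands[[bn]][2]
    v <- freq_features_one(spectrum$f[sel], spectrum$psd[sel])
    names(v) <- paste0(FREQ_FEATURE_NAMES, "_", bn)
    out <- c(out, v)
  }
  out
}

# mean, sd, skewness, min, max of a vector; sd 0 for length < 2, skewness 0
# for fewer than 3 values; all 0 for empty input.
vec_stats5 <- function(v) {
  if (length(v) == 0) return(c(mean = 0, sd = 0, skew = 0, min = 0, max = 0))
  c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
    skew = skewness_adj(v), min = min(v), max = max(v))
}

#' Short-time Fourier transform window features
#'
#' 4 s windows with 2 s hop (partial trailing windows dropped; 14 windows
#' for a 30 s signal at 50 Hz). Each window's mean PSD is computed within
#' each band, and the per-window vector is summarized by its mean, standard
#' deviation, skewness, min and max.
#'
#' @inheritParams highpass_gravity_removal
#' @param bands named list of Hz intervals.
#' @param window_sec window length in seconds.
#' @param hop_sec hop between window starts in seconds.
#' @return named numeric vector of `5 * length(bands)` features.
#' @export
stft_window_features <- function(x, fs = 50, bands = FEATURE_BANDS,
                                 window_sec = 4, hop_sec = 2) {
  n <- round(window_sec * fs)
  if (length(x) < n) stop("signal shorter than one STFT window")
  frames <- frame_signal(x, n, round(hop_sec * fs))
  sp <- segment_psd(frames, fs)
  out <- numeric(0)
  for (bn in names(bands)) {
    sel <- sp$f >= bands[[bn]][1] & sp$f <= bands[[bn]][2]
    per_window <- colMeans(sp$psd[sel, , drop = FALSE])
    v <- vec_stats5(per_window)
    names(v) <- paste0("stft_", names(v), "_", bn)
    out <- c(out, v)
  }
  out
}

# Shannon entropy (nats) of a 16-bin amplitude histogram; 0 for a constant
# window.
window_entropy <- function(v, nbins = 16) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(0)
  cuts <- seq(rng[1], rng[2], length.out = nbins + 1)
  cnt <- tabulate(findInterval(v, cuts, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins)
  p <- cnt[cnt > 0] / length(v)
  -sum(p * log(p))
}

#' Windowed value-range and entropy features
#'
#' The signal is segmented into non-overlapping 4 s windows; per window the
#' value range and the Shannon entropy of a 16-bin amplitude histogram are
#' computed, and each per-window vector is summarized by mean, standard
#' deviation, skewness, min and max.
#'
#' @inheritParams highpass_gravity_removal
#' @param window_sec window length in seconds.
#' @return named numeric vector of 10 features.
#' @export
windowed_range_entropy_features <- function(x, fs = 50, window_sec = 4) {
  n <- round(window_sec * fs)
  if (length(x) < n) stop("signal shorter than one window")
  frames <- frame_signal(x, n, n)
  rng <- apply(frames, 2, function(v) diff(range(v)))
  ent <- apply(frames, 2, window_entropy)
  r <- vec_stats5(rng); names(r) <- paste0("win_range_", names(r))
  e <- vec_stats5(ent); names(e) <- paste0("win_entropy_", names(e))
  c(r, e)
}

# Daubechies order-10 (20-tap) decomposition filters; standard published
# orthonormal coefficients.
DB10_DEC_LO <- c(
  -1.3264202894521244e-05, 9.358867032006959e-05, -1.1646685512928545e-04,
  -6.858566949597116e-04, 1.992405295185056e-03, 1.395351747052901e-03,
  -1.0733175483330575e-02, 3.6065535669561697e-03, 3.3212674059341e-02,
  -2.9457536821875813e-02, -7.139414716639708e-02, 9.305736460357235e-02,
  1.2736934033579325e-01, -1.9594627437737705e-01, -2.4984642432731538e-01,
  2.811723436605775e-01, 6.884590394536035e-01, 5.272011889317256e-01,
  1.881768000776915e-01, 2.6670057900555554e-02)
DB10_DEC_HI <- rev(DB10_DEC_LO) * rep_len(c(-1, 1), 20)

# One analysis step with symmetric padding; returns approximation and
# detail coefficients of length floor((n + 19) / 2).
dwt_step_db10 <- function(x) {
  n <- length(x); fl <- length(DB10_DEC_LO); p <- fl - 1
  if (n < fl) stop("signal shorter than the wavelet filter support")
  xp <- c(x[p:1], x, x[n:(n - p + 1)])
  conv1 <- function(h) {
    full <- convolve(xp, rev(h), type = "open")
    valid <- full[fl:(fl + n + p - 1)]
    valid[seq(2, length(valid), by = 2)]
  }
  list(a = conv1(DB10_DEC_LO), d = conv1(DB10_DEC_HI))
}

#' Three-level discrete wavelet transform features
#'
#' Daubechies order-10 wavelet, symmetric boundary padding; the mean and
#' standard deviation of the detail (high-frequency) coefficients at levels
#' 1-3. At a 50 Hz sampling rate the levels roughly cover 12.5-25,
#' 6.25-12.5 and 3.125-6.25 Hz.
#'
#' @param x numeric sequence (longer than the 20-tap filter support).
#' @return named numeric vector of 6 features.
#' @export
dwt_features <- function(x) {
  out <- numeric(0)
  a <- x
  for (lev in 1:3) {
    st <- dwt_step_db10(a)
    out <- c(out, setNames(c(mean(st$d), sd(st$d)),
                           paste0("dwt_d", lev, c("_mean", "_sd"))))
    a <- st$a
  }
  out
}

#' Pearson correlations between axis pairs
#'
#' @param x,y,z equal-length axis sequences.
#' @return named vector `corr_XY`, `corr_XZ`, `corr_YZ` in `[-1, 1]`;
#'   0 where a channel is constant.
#' @export
axis_correlations <- function(x, y, z) {
  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(0)
    cor(a, b)
  }
  c(corr_XY = safe_cor(x, y), corr_XZ = safe_cor(x, z),
    corr_YZ = safe_cor(y, z))
}

#' Full sensor feature vector for one recording
#'
#' Applies [preprocess_recording()] and computes all feature blocks on each
#' of the four channels plus the axis correlations: 323 named features
#' (319 with `time_entropy = "magnitude_only"`).
#'
#' @param rec a recording list (see [simulate_exercise_signal()]).
#' @param time_entropy `"all"` computes approximate/sample entropy on every
#'   channel; `"magnitude_only"` restricts them to the magnitude channel.
#' @return named numeric vector.
#' @export
extract_recording_features <- function(rec, time_entropy = c("all", "magnitude_only")) {
  time_entropy <- match.arg(time_entropy)
  fs <- rec$sampling_rate
  chans <- preprocess_recording(rec)
  out <- numeric(0)
  for (cn in names(chans)) {
    x <- chans[[cn]]
    ent <- time_entropy == "all" || cn == "M"
    v <- c(time_domain_features(x, entropies = ent),
           frequency_domain_features(estimate_psd(x, fs)),
           stft_window_features(x, fs),
           windowed_range_entropy_features(x, fs),
           dwt_features(x))
    names(v) <- paste0(cn, "/", names(v))
    out <- c(out, v)
  }
  c(out, axis_correlations(chans$X, chans$Y, chans$Z))
}

# "Phone-ACC-#1"-style block label used in feature names and reports
block_label <- function(device, sensor, exercise) {
  sprintf("%s-%s-#%d",
          ifelse(device == "phone", "Phone", "MYO"),
          ifelse(sensor == "accelerometer", "ACC", "GYRO"),
          as.integer(exercise))
}
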