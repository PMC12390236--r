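# Signal conditioning: Butterworth filtering, magnitude signal, frequency
# band decomposition and Welch spectral estimation. All filters are 4th-order
# Butterworth applied forward-backward (zero phase).

# Forward-backward filtering with odd-reflection padding at both ends (and
# mean removal restored afterwards for low-pass filters) so that boundary
# transients decay inside the padding, not inside the data.
butter_filtfilt <- function(x, w, type) {
  bf <- signal::butter(4, w, type = type)
  n <- length(x)
  mu <- mean(x)
  xc <- x - mu
  pad <- min(n - 1, 500)
  xp <- c(2 * xc[1] - xc[(pad + 1):2], xc, 2 * xc[n] - xc[(n - 1):(n - pad)])
  y <- as.numeric(signal::filtfilt(bf, xp))[(pad + 1):(pad + n)]
  if (type == "low") y + mu else y
}

#' Remove the gravitational component with a 0.1 Hz high-pass filter
#'
#' @param x numeric channel sequence.
#' @param fs sampling rate in Hz (50 for both devices).
#' @return filtered sequence of the same length.
#' @export
highpass_gravity_removal <- function(x, fs = 50) {
  if (length(x) < 50) stop("signal too short for the 0.1 Hz high-pass filter")
  butter_filtfilt(x, 0.1 / (fs / 2), "high")
}

#' Suppress high-frequency noise with a 20 Hz low-pass filter
#'
#' Motor features of interest stay well below 20 Hz; the passband
#' (<= 15 Hz) is preserved within a few percent.
#'
#' @inheritParams highpass_gravity_removal
#' @return filtered sequence of the same length.
#' @export
lowpass_denoise <- function(x, fs = 50) {
  if (length(x) < 50) stop("signal too short for the 20 Hz low-pass filter")
  butter_filtfilt(x, 20 / (fs / 2), "low")
}

#' Magnitude signal
#'
#' Per-sample Euclidean norm of the three axes,
#' \eqn{M_i = \sqrt{x_i^2 + y_i^2 + z_i^2}}; invariant under rotation of the
#' device axes, which matters because the sensors are not always worn in the
#' same orientation.
#'
#' @param x,y,z equal-length numeric axis sequences.
#' @return nonnegative numeric sequence.
#' @export
magnitude <- function(x, y, z) {
  if (length(x) != length(y) || length(y) != length(z))
    stop("axis channels must have equal length")
  sqrt(x^2 + y^2 + z^2)
}

#' Decompose a signal into the 0-3, 3-9 and 9-14 Hz bands
#'
#' The 0-3 Hz band is realized as a 3 Hz low-pass, the others as
#' band-passes; each output has the input's length. The bands separate slow
#' voluntary movement and dyskinesia (0-3 Hz), the physiological tremor
#' range (3-9 Hz), and higher-frequency content (9-14 Hz).
#'
#' @inheritParams highpass_gravity_removal
#' @return named list of three numeric sequences
#'   (`"0-3Hz"`, `"3-9Hz"`, `"9-14Hz"`).
#' @export
band_decompose <- function(x, fs = 50) {
  if (length(x) < 50) stop("signal too short for band decomposition")
  nyq <- fs / 2
  list(
    "0-3Hz"  = butter_filtfilt(x, 3 / nyq, "low"),
    "3-9Hz"  = butter_filtfilt(x, c(3, 9) / nyq, "pass"),
    "9-14Hz" = butter_filtfilt(x, c(9, 14) / nyq, "pass")
  )
}

# Frame a signal into windows of `n` samples advancing by `hop`; partial
# trailing windows are dropped. Returns a matrix n x n_windows.
frame_signal <- function(x, n, hop) {
  nw <- if (length(x) < n) 0 else floor((length(x) - n) / hop) + 1
  if (nw == 0) return(matrix(numeric(0), nrow = n, ncol = 0))
  idx <- outer(seq_len(n), (seq_len(nw) - 1) * hop, "+")
  matrix(x[idx], nrow = n)
}

# One-sided PSD of each column (Hann window, per-segment mean removal,
# density scaling: sum(psd) * df = variance contribution).
segment_psd <- function(frames, fs) {
  n <- nrow(frames)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n) # Hann
  frames <- sweep(frames, 2, colMeans(frames)) * w
  nf <- n %/% 2 + 1
  X <- stats::mvfft(frames)[seq_len(nf), , drop = FALSE]
  p <- (Mod(X)^2) / (fs * sum(w^2))
  scale <- rep(2, nf); scale[1] <- 1
  if (n %% 2 == 0) scale[nf] <- 1
  list(f = seq(0, nf - 1) * fs / n, psd = p * scale)
}

#' Welch power spectral density estimate
#'
#' 4 s Hann segments with 50% overlap, per-segment mean removal, averaged
#' one-sided periodograms with density scaling so that the integrated PSD
#' approximates the signal variance.
#'
#' @inheritParams highpass_gravity_removal
#' @param window_sec segment length in seconds.
#' @return list with `f` (Hz grid up to the Nyquist frequency) and `psd`
#'   (nonnegative power density values).
#' @export
estimate_psd <- function(x, fs = 50, window_sec = 4) {
  n <- round(window_sec * fs)
  if (length(x) < n) n <- length(x)
  frames <- frame_signal(x, n, max(1, n %/% 2))
  sp <- segment_psd(frames, fs)
  list(f = sp$f, psd = rowMeans(sp$psd))
}

#' Preprocess one tri-axial recording into its four feature channels
#'
#' Accelerometer channels pass the 0.1 Hz gravity high-pass then the 20 Hz
#' low-pass; gyroscope channels (no gravity component) only the low-pass.
#' The magnitude channel is computed from the filtered axes.
#'
#' @param rec a recording list with `x`, `y`, `z`, `sensor`,
#'   `sampling_rate`.
#' @return named list of channels `X`, `Y`, `Z`, `M`.
#' @export
preprocess_recording <- function(rec) {
  fs <- rec$sampling_rate
  chans <- list(X = rec$x, Y = rec$y, Z = rec$z)
  if (identical(rec$sensor, "accelerometer"))
    chans <- lapply(chans, highpass_gravity_removal, fs = fs)
  chans <- lapply(chans, lowpass_denoise, fs = fs)
  chans$M <- magnitude(chans$X, chans$Y, chans$Z)
  chans
}

# Bandpower via the Welch estimate (used by tests and the generator checks)
bandpower <- function(x, fs, lo, hi) {
  sp <- estimate_psd(x, fs)
  sel <- sp$f >= lo & sp$f <= hi
  df <- sp$f[2] - sp$f[1]
  sum(sp$psd[sel]) * df
}
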