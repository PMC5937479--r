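#' Names of the 18 per-frame descriptors, in canonical column order
#'
#' Five spectrogram-analysis features, six linear-prediction (formant)
#' features and seven harmonicity-analysis features.
#'
#' @return Character vector of length 18.
#' @export
mpeg7_feature_names <- function() {
  c("total_power", "relevant_power", "power_centroid",
    "spectral_dispersion", "spectrum_flatness",
    "formant_freq_1", "formant_freq_2", "formant_freq_3",
    "formant_bw_1", "formant_bw_2", "formant_bw_3",
    "pitch", "harmonic_centroid", "harmonic_spectral_deviation",
    "harmonic_spectral_spread", "harmonic_spectral_variation",
    "harmonicity_ratio", "upper_limit_of_harmonicity")
}

#' Feature extraction configuration
#'
#' @param relevant_band Frequency band (Hz) integrated by the
#'   `relevant_power` feature. Default 500--5000 Hz, the band holding most
#'   anuran call energy.
#' @param lpc_order Linear-prediction order for formant estimation.
#' @param f0_range Pitch search range in Hz.
#' @param power_floor_db Floor applied to dB power features so silence stays
#'   finite.
#' @param voicing_threshold Minimum normalized-autocorrelation peak for a
#'   frame to count as voiced; unvoiced frames report pitch 0 and zeroed
#'   harmonic features (the harmonicity ratio itself is always reported).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(relevant_band = c(500, 5000), lpc_order = 12,
                           f0_range = c(50, 4000), power_floor_db = -120,
                           voicing_threshold = 0.4) {
  stopifnot(length(relevant_band) == 2, relevant_band[1] < relevant_band[2],
            lpc_order >= 2, length(f0_range) == 2, f0_range[1] < f0_range[2])
  structure(list(relevant_band = relevant_band, lpc_order = lpc_order,
                 f0_range = f0_range, power_floor_db = power_floor_db,
                 voicing_threshold = voicing_threshold),
            class = "feature_config")
}

.hamming <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

.next_pow2 <- function(n) 2^ceiling(log2(n))

# Batch featurization of a frame matrix (frames in rows). Spectra and
# autocorrelations are computed for all frames at once with mvfft; only the
# LPC recursion, root finding and harmonic-peak search loop per frame.
.featurize_frames <- function(frames, sample_rate, config) {
  s <- nrow(frames); len <- ncol(frames)
  floor_db <- config$power_floor_db
  floor_lin <- 10^(floor_db / 10)

  msq <- rowMeans(frames^2)
  silent <- msq < floor_lin
  total_power <- ifelse(silent, floor_db, 10 * log10(pmax(msq, floor_lin)))

  w <- .hamming(len)
  xc <- frames - rowMeans(frames)           # per-frame DC removal
  fw <- t(xc) * w                           # len x s, windowed

  nfft <- .next_pow2(len)                   # spectrum resolution
  nfft2 <- .next_pow2(2 * len)              # linear (non-circular) autocorr
  k <- nfft / 2 + 1
  freqs <- (0:(k - 1)) * sample_rate / nfft

  pad <- function(m, n) rbind(m, matrix(0, n - nrow(m), ncol(m)))
  spec <- stats::mvfft(pad(fw, nfft))
  p <- Mod(spec[seq_len(k), , drop = FALSE])^2      # k x s power spectrum
  amp <- sqrt(p)

  pf <- Mod(stats::mvfft(pad(fw, nfft2)))^2
  ac <- Re(stats::mvfft(pf, inverse = TRUE)) / nfft2  # rows = lags 0..len-1
  ac <- ac[seq_len(len), , drop = FALSE]
  acw <- Re(stats::fft(Mod(stats::fft(c(w, numeric(nfft2 - len))))^2,
                       inverse = TRUE)) / nfft2
  acw <- acw[seq_len(len)] / acw[1]          # window autocorrelation (lag norm)

  ptot <- colSums(p)
  band <- config$relevant_band
  in_band <- freqs >= band[1] & freqs <= band[2]
  pband <- colSums(p[in_band, , drop = FALSE])
  relevant_power <- ifelse(silent | ptot <= 0, floor_db,
                           pmax(total_power + 10 * log10(pmax(pband, 1e-300) / ptot),
                                floor_db))

  centroid <- ifelse(silent | ptot <= 0, 0, colSums(p * freqs) / ptot)
  # power-weighted spread about the centroid
  disp <- numeric(s)
  nz <- which(!silent & ptot > 0)
  if (length(nz)) {
    d2 <- (matrix(freqs, k, length(nz)) -
             matrix(centroid[nz], k, length(nz), byrow = TRUE))^2
    disp[nz] <- sqrt(colSums(p[, nz, drop = FALSE] * d2) / ptot[nz])
  }

  # flatness over non-DC bins: geometric / arithmetic mean of the spectrum
  pnd <- p[-1, , drop = FALSE]
  am <- colMeans(pnd)
  gm <- exp(colMeans(log(pmax(pnd, 1e-300))))
  flat <- ifelse(silent | am <= 0, 1, pmin(gm / am, 1))

  # ---- LPC formants + harmonic features (per-frame loop) ----
  order <- min(config$lpc_order, len - 1)
  nyq <- sample_rate / 2
  f0r <- config$f0_range
  lag_min <- max(2L, floor(sample_rate / f0r[2]))
  lag_max <- min(len - 1L, ceiling(sample_rate / f0r[1]))
  usable <- if (lag_max >= lag_min) {
    lg <- lag_min:lag_max
    lg[acw[lg + 1] > 0.05]
  } else integer(0)

  out <- matrix(0, s, 18, dimnames = list(NULL, mpeg7_feature_names()))
  out[, "total_power"] <- total_power
  out[, "relevant_power"] <- relevant_power
  out[, "power_centroid"] <- centroid
  out[, "spectral_dispersion"] <- disp
  out[, "spectrum_flatness"] <- flat

  prev_harm <- NULL
  for (i in seq_len(s)) {
    if (!silent[i]) {
      out[i, 6:11] <- .lpc_formants_from_ac(ac[, i], order, sample_rate)
      # normalized autocorrelation, compensated for the analysis window taper
      if (length(usable) && ac[1, i] > 0) {
        rn <- (ac[usable + 1, i] / ac[1, i]) / acw[usable + 1]
        # a periodic signal peaks at every period multiple; take the local
        # maximum at the shortest lag among near-maximal peaks (octave guard)
        m <- length(rn)
        is_peak <- rn >= c(rn[1], rn[-m]) & rn >= c(rn[-1], rn[m])
        peaks <- which(is_peak & rn >= 0.95 * max(rn))
        if (length(peaks) == 0) peaks <- which.max(rn)
        j <- peaks[1]
        hr <- min(max(max(rn), 0), 1)
        out[i, "harmonicity_ratio"] <- hr
        if (rn[j] >= config$voicing_threshold) {
          lag <- usable[j]
          # parabolic refinement of the peak lag
          if (j > 1 && j < m && usable[j + 1] - usable[j - 1] == 2) {
            denom <- rn[j - 1] - 2 * rn[j] + rn[j + 1]
            if (denom < 0) lag <- lag + 0.5 * (rn[j - 1] - rn[j + 1]) / denom
          }
          f0 <- sample_rate / lag
          hf <- .harmonic_peak_features(amp[, i], freqs, f0, nyq, prev_harm)
          out[i, "pitch"] <- f0
          out[i, "harmonic_centroid"] <- hf$hc
          out[i, "harmonic_spectral_deviation"] <- hf$hsd
          out[i, "harmonic_spectral_spread"] <- hf$hss
          out[i, "harmonic_spectral_variation"] <- hf$hsv
          out[i, "upper_limit_of_harmonicity"] <- hf$ulh
          prev_harm <- hf$amps
        } else prev_harm <- NULL
      } else prev_harm <- NULL
    } else prev_harm <- NULL
    if (silent[i]) out[i, "spectrum_flatness"] <- 1
  }
  out[1, "harmonic_spectral_variation"] <- 0   # no predecessor frame
  out[!is.finite(out)] <- 0
  out
}

# Levinson-Durbin on autocorrelation lags 0..p; returns predictor
# coefficients a_1..a_p of A(z) = 1 - sum a_k z^-k, or NULL if degenerate.
.levinson <- function(r, p) {
  if (r[1] <= 0) return(NULL)
  a <- numeric(p)
  e <- r[1]
  for (m in seq_len(p)) {
    acc <- r[m + 1]
    if (m > 1) acc <- acc - sum(a[seq_len(m - 1)] * r[m:2])
    kref <- acc / e
    a_new <- a
    a_new[m] <- kref
    if (m > 1) a_new[seq_len(m - 1)] <- a[seq_len(m - 1)] - kref * a[(m - 1):1]
    a <- a_new
    e <- e * (1 - kref^2)
    if (e <= 0) break
  }
  a
}

.lpc_formants_from_ac <- function(ac, order, sample_rate,
                                  max_formant_bw = 500) {
  a <- .levinson(ac, order)
  if (is.null(a)) return(numeric(6))
  # roots of z^p - a1 z^(p-1) - ... - ap
  roots <- polyroot(c(-rev(a), 1))
  roots <- roots[Im(roots) > 1e-9]
  if (length(roots) == 0) return(numeric(6))
  f <- Arg(roots) / (2 * pi) * sample_rate
  bw <- -(sample_rate / pi) * log(pmin(Mod(roots), 1 - 1e-12))
  # only sharp resonances qualify as formants; broad poles model the
  # overall spectral tilt, not a resonance
  keep <- bw <= max_formant_bw & f > 50 & f < sample_rate / 2 - 50
  f <- f[keep]; bw <- bw[keep]
  if (length(f) == 0) return(numeric(6))
  o <- order(f)
  f <- f[o]; bw <- bw[o]
  res <- numeric(6)
  n <- min(3, length(f))
  res[seq_len(n)] <- f[seq_len(n)]
  res[3 + seq_len(n)] <- bw[seq_len(n)]
  res
}

# Harmonic-peak analysis: locate the spectral peak near each multiple of f0
# and derive the MPEG-7-style harmonic descriptors from the peak amplitude
# series.
.harmonic_peak_features <- function(amp, freqs, f0, nyq, prev_amps) {
  h_max <- min(30L, floor((nyq - freqs[2]) / f0))
  if (h_max < 1)
    return(list(hc = 0, hsd = 0, hss = 0, hsv = 0, ulh = 0, amps = NULL))
  df <- freqs[2] - freqs[1]
  a_h <- numeric(h_max); f_h <- numeric(h_max); snr_h <- numeric(h_max)
  for (h in seq_len(h_max)) {
    lo <- max(2L, floor((h * f0 - f0 / 3) / df) + 1L)
    hi <- min(length(freqs), ceiling((h * f0 + f0 / 3) / df) + 1L)
    win <- amp[lo:hi]
    j <- which.max(win)
    a_h[h] <- win[j]
    f_h[h] <- freqs[lo + j - 1]
    med <- stats::median(win)
    snr_h[h] <- if (med > 0) win[j] / med else Inf
  }
  # only locally prominent peaks (>= ~6 dB above their local floor) count
  # as harmonics for the centroid and spread; otherwise the noise floor
  # drags both upward as the SNR drops
  w_h <- a_h * (snr_h >= 2)
  if (sum(w_h) == 0) w_h <- a_h
  tot <- sum(w_h)
  hc <- if (tot > 0) sum(f_h * w_h) / tot else 0
  # deviation of log-amplitudes from a 3-point smoothed spectral envelope
  la <- log10(pmax(a_h, 1e-30))
  if (h_max >= 3) {
    se <- la
    se[2:(h_max - 1)] <- (la[1:(h_max - 2)] + la[2:(h_max - 1)] + la[3:h_max]) / 3
    se[1] <- (la[1] + la[2]) / 2
    se[h_max] <- (la[h_max - 1] + la[h_max]) / 2
    hsd <- mean(abs(la - se))
  } else hsd <- 0
  a2 <- sum(w_h^2)
  hss <- if (hc > 0 && a2 > 0) sqrt(sum(w_h^2 * (f_h - hc)^2) / a2) / hc else 0
  hsv <- 0
  if (!is.null(prev_amps)) {
    m <- min(length(prev_amps), h_max)
    num <- sum(prev_amps[seq_len(m)] * a_h[seq_len(m)])
    den <- sqrt(sum(prev_amps[seq_len(m)]^2) * sum(a_h[seq_len(m)]^2))
    if (den > 0) hsv <- min(max(1 - num / den, 0), 1)
  }
  # highest harmonic that still stands clear (>= ~6 dB) of its local floor
  strong <- which(snr_h >= 2)
  ulh <- if (length(strong)) min(f_h[max(strong)], nyq) else 0
  list(hc = hc, hsd = hsd, hss = hss, hsv = hsv, ulh = ulh, amps = a_h)
}

#' Spectrogram-analysis features of a single frame
#'
#' @param frame Numeric sample vector.
#' @param sample_rate Sampling rate in Hz.
#' @param band Band (Hz) for `relevant_power`.
#' @param config A [feature_config()]; `band` overrides its band.
#' @return Named numeric vector: `total_power`, `relevant_power` (dB, floored),
#'   `power_centroid`, `spectral_dispersion` (Hz), `spectrum_flatness` (0-1).
#' @export
spectral_features <- function(frame, sample_rate, band = NULL,
                              config = feature_config()) {
  stopifnot(length(frame) > 0)
  if (!is.null(band)) config$relevant_band <- band
  x <- .featurize_frames(matrix(frame, nrow = 1), sample_rate, config)
  x[1, 1:5]
}

#' LPC formant frequencies and bandwidths of a single frame
#'
#' Formants are the angles of the first three complex linear-prediction
#' polynomial root pairs with positive imaginary part, sorted ascending in
#' frequency; bandwidths follow from the root moduli
#' (`bw = -(sample_rate/pi) * log|r|`). Fewer than three qualifying roots
#' yield trailing zeros.
#'
#' @param frame Numeric sample vector.
#' @param sample_rate Sampling rate in Hz.
#' @param lpc_order LPC order (autocorrelation method, Levinson-Durbin).
#' @return Named vector `(formant_freq_1..3, formant_bw_1..3)`.
#' @export
lpc_formants <- function(frame, sample_rate, lpc_order = 12) {
  stopifnot(length(frame) > 0)
  cfg <- feature_config(lpc_order = lpc_order)
  x <- .featurize_frames(matrix(frame, nrow = 1), sample_rate, cfg)
  x[1, 6:11]
}

#' Harmonicity-analysis features of a single frame
#'
#' Pitch is located as the peak of the window-compensated normalized
#' autocorrelation inside `f0_range`; harmonic descriptors are computed from
#' the harmonic-peak amplitude series. The harmonic spectral variation
#' compares against `prev_frame` (0 when absent).
#'
#' @param frame Numeric sample vector.
#' @param sample_rate Sampling rate in Hz.
#' @param f0_range Pitch search range (Hz).
#' @param prev_frame Optional preceding frame (for the variation feature).
#' @param config A [feature_config()].
#' @return Named vector `(pitch, harmonic_centroid, harmonic_spectral_deviation,
#'   harmonic_spectral_spread, harmonic_spectral_variation, harmonicity_ratio,
#'   upper_limit_of_harmonicity)`.
#' @export
harmonic_features <- function(frame, sample_rate, f0_range = c(50, 4000),
                              prev_frame = NULL, config = feature_config()) {
  stopifnot(length(frame) > 0)
  config$f0_range <- f0_range
  m <- if (is.null(prev_frame)) matrix(frame, nrow = 1) else
    rbind(prev_frame, frame)
  x <- .featurize_frames(m, sample_rate, config)
  x[nrow(x), c(12:16, 17, 18)]
}

#' Extract the 18-descriptor feature matrix of a frame series
#'
#' @param frames A `frame_series` from [frame_signal()].
#' @param config A [feature_config()].
#' @return An object of class `frame_feature_matrix`: list with `X`
#'   (`n_frames` x 18 matrix, columns in [mpeg7_feature_names()] order),
#'   `feature_names`, `source_id`, `sample_rate` and `frame_s` (frame hop in
#'   seconds).
#' @export
extract_features <- function(frames, config = feature_config()) {
  stopifnot(inherits(frames, "frame_series"))
  x <- .featurize_frames(frames$frames, frames$sample_rate, config)
  structure(list(X = x,
                 feature_names = mpeg7_feature_names(),
                 source_id = frames$source_id,
                 sample_rate = frames$sample_rate,
                 frame_s = floor(frames$hop_ms * frames$sample_rate / 1000) /
                   frames$sample_rate),
            class = "frame_feature_matrix")
}

#' @export
print.frame_feature_matrix <- function(x, ...) {
  cat(sprintf("<frame_feature_matrix '%s': %d frames x %d features>\n",
              x$source_id, nrow(x$X), ncol(x$X)))
  invisible(x)
}
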