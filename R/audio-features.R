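# Handcrafted audio feature bank: FFT magnitude statistics (11 values),
# MFCC aggregation (128 values) and spectral centroid/bandwidth/contrast
# aggregation (224 values), concatenated to the 363-dimensional f_audio
# vector (352 in the MFCC+spectral configuration).

LOG_FLOOR <- 1e-10

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))

# Frame a waveform into columns (frame_length x n_frames), hop samples apart,
# zero-padding the tail so at least one frame always exists.
frame_signal <- function(x, frame_length, hop) {
  n <- length(x)
  if (n < frame_length) x <- c(x, numeric(frame_length - n))
  n <- length(x)
  n_frames <- 1L + (n - frame_length) %/% hop
  idx <- outer(seq_len(frame_length), (seq_len(n_frames) - 1L) * hop, `+`)
  matrix(x[idx], frame_length, n_frames)
}

# One-sided STFT magnitude: (frame_length/2 + 1) x n_frames.
stft_mag <- function(x, frame_length = 2048L, hop = 512L,
                     window = hann_window(frame_length)) {
  fr <- frame_signal(x, frame_length, hop) * window
  sp <- stats::mvfft(fr)
  Mod(sp[seq_len(frame_length %/% 2L + 1L), , drop = FALSE])
}

stft_bin_freqs <- function(frame_length, sample_rate)
  (seq_len(frame_length %/% 2L + 1L) - 1L) * sample_rate / frame_length

# ---- preprocessing ----------------------------------------------------------

#' Preprocess an audio clip
#'
#' Optional DC-offset removal, peak normalization to `[-1, 1]`, and
#' single-ended noise reduction by spectral subtraction: a broadband noise
#' floor is estimated per frame as the median STFT magnitude across frequency
#' bins (robust to the sparse harmonic peaks of vocal signals), subtracted
#' from every bin (floored at 5% of the original magnitude), and the signal
#' resynthesized by weighted overlap-add. All steps are
#' deterministic. An all-zero clip with normalization requested is returned
#' unchanged with attribute `warning = "all-zero clip"`.
#'
#' @param clip a [audio_clip()].
#' @param dc_remove subtract the mean.
#' @param normalize rescale so the peak magnitude is 1.
#' @param denoise apply spectral subtraction.
#' @param frame_length,hop STFT parameters for the denoiser.
#' @return The processed [audio_clip()].
#' @export
preprocess_audio <- function(clip, dc_remove = TRUE, normalize = TRUE,
                             denoise = FALSE, frame_length = 1024L,
                             hop = 256L) {
  stopifnot(inherits(clip, "painsense_clip"))
  x <- clip$samples
  warn <- NULL
  if (dc_remove) x <- x - mean(x)
  if (denoise && any(x != 0)) {
    w <- hann_window(frame_length)
    # reflection-pad so overlap-add has full window coverage at the edges
    pad <- min(frame_length, length(x))
    n_orig <- length(x)
    x <- c(rev(x[seq_len(pad)]), x, rev(x[seq(n_orig - pad + 1L, n_orig)]))
    fr <- frame_signal(x, frame_length, hop) * w
    sp <- stats::mvfft(fr)
    mag <- Mod(sp); ph <- Arg(sp)
    # broadband noise-floor estimate: per-frame median magnitude across bins
    # (robust to the sparse harmonic peaks of vocal signals)
    floor_est <- apply(mag, 2, stats::median)
    mag2 <- pmax(mag - rep(floor_est, each = nrow(mag)), 0.05 * mag)
    rec <- Re(stats::mvfft(mag2 * exp(1i * ph), inverse = TRUE)) / frame_length
    rec <- rec * w                       # synthesis window
    n_frames <- ncol(rec)
    out_len <- frame_length + (n_frames - 1L) * hop
    acc <- numeric(out_len); wsum <- numeric(out_len)
    for (f in seq_len(n_frames)) {
      at <- (f - 1L) * hop + seq_len(frame_length)
      acc[at] <- acc[at] + rec[, f]
      wsum[at] <- wsum[at] + w^2
    }
    x <- (acc / pmax(wsum, 1e-8))[pad + seq_len(n_orig)]
  }
  if (normalize) {
    pk <- max(abs(x))
    if (pk == 0) warn <- "all-zero clip" else x <- x / pk
  }
  out <- audio_clip(x, clip$sample_rate, clip$label)
  attr(out, "warning") <- warn
  out
}

#' Resample a clip by bandlimited-free linear interpolation
#'
#' Utility used to bring clips to a common analysis rate (default 16 kHz)
#' before feature extraction.
#'
#' @param clip a [audio_clip()].
#' @param sample_rate target rate in Hz.
#' @return The resampled [audio_clip()].
#' @export
resample_clip <- function(clip, sample_rate = 16000L) {
  if (clip$sample_rate == sample_rate) return(clip)
  n_out <- max(1L, round(length(clip$samples) * sample_rate /
                           clip$sample_rate))
  t_out <- (seq_len(n_out) - 1) / sample_rate
  t_in <- (seq_along(clip$samples) - 1) / clip$sample_rate
  audio_clip(stats::approx(t_in, clip$samples, xout = pmin(t_out, max(t_in)),
                           rule = 2)$y,
             sample_rate, clip$label)
}

# ---- statistical block (f1, d1 = 11) ----------------------------------------

moment_skewness <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

moment_kurtosis <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^4) / s2^2
}

#' Statistical FFT-magnitude features (f1)
#'
#' Eleven descriptive statistics of the one-sided FFT magnitude spectrum of
#' the whole clip, in this fixed order: mean, median, standard deviation,
#' first quartile, third quartile, kurtosis (Pearson, m4/m2^2), skewness,
#' minimum, maximum, energy (sum of squared magnitudes) and RMS energy
#' (root mean squared magnitude).
#'
#' @param clip a [audio_clip()] of length >= 2.
#' @return Named numeric vector of length 11.
#' @export
statistical_features <- function(clip) {
  stopifnot(inherits(clip, "painsense_clip"))
  x <- clip$samples
  if (length(x) < 2L) stop("data error: clip shorter than 2 samples")
  mag <- Mod(stats::fft(x))[seq_len(length(x) %/% 2L + 1L)]
  q <- stats::quantile(mag, c(0.25, 0.75), names = FALSE)
  c(mean = mean(mag), median = stats::median(mag), sd = stats::sd(mag),
    q1 = q[1], q3 = q[2], kurtosis = moment_kurtosis(mag),
    skewness = moment_skewness(mag), min = min(mag), max = max(mag),
    energy = sum(mag^2), rms_energy = sqrt(mean(mag^2)))
}

# ---- MFCC block (f2, d2 = 128) ----------------------------------------------

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_mels, frame_length, sample_rate,
                           fmin = 0, fmax = sample_rate / 2) {
  n_bins <- frame_length %/% 2L + 1L
  freqs <- stft_bin_freqs(frame_length, sample_rate)
  pts <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax),
                       length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- pts[m]; ce <- pts[m + 1L]; hi <- pts[m + 2L]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

dct_matrix <- function(n_out, n_in) {
  # orthonormal DCT-II
  M <- sqrt(2 / n_in) * cos(pi / n_in * outer(seq_len(n_out) - 1,
                                              seq_len(n_in) - 0.5))
  M[1, ] <- M[1, ] / sqrt(2)
  M
}

agg_stats10 <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  s <- if (length(v) > 1L) stats::sd(v) else 0
  c(mean(v), s, q[2], min(v), max(v), q[1], q[3],
    moment_skewness(v), moment_kurtosis(v), sqrt(mean(v^2)))
}

#' MFCC features (f2)
#'
#' Frames the clip (Hann window), takes the magnitude spectrum, maps it
#' through a mel filter bank, applies a log with floor `1e-10` and an
#' orthonormal DCT-II, and retains DCT coefficients 2-13 (12 per frame).
#' Each coefficient's track over time is aggregated with ten statistics
#' (mean, sd, median, min, max, Q1, Q3, skewness, kurtosis, RMS), giving
#' 120 values; eight statistics of the first ("c0", log-energy) coefficient
#' track (mean, sd, median, min, max, Q1, Q3, range) complete the 128.
#'
#' @param clip a [audio_clip()].
#' @param frame_length,hop analysis frame and hop in samples.
#' @param n_mels number of mel filters.
#' @param keep 1-based indices of retained DCT coefficients.
#' @return Named numeric vector, length 128 at the defaults.
#' @export
mfcc_features <- function(clip, frame_length = 2048L, hop = 512L,
                          n_mels = 40L, keep = 2:13) {
  stopifnot(inherits(clip, "painsense_clip"))
  if (length(clip$samples) < 1L) stop("data error: empty clip")
  mag <- stft_mag(clip$samples, frame_length, hop)
  fb <- mel_filterbank(n_mels, frame_length, clip$sample_rate)
  melspec <- fb %*% (mag^2)                   # n_mels x n_frames
  logmel <- log(pmax(melspec, LOG_FLOOR))
  D <- dct_matrix(max(c(1L, keep)), n_mels)
  cep <- D %*% logmel                          # coefficients x frames
  kept <- cep[keep, , drop = FALSE]
  out <- as.vector(apply(kept, 1, agg_stats10))
  names(out) <- as.vector(outer(
    c("mean", "sd", "median", "min", "max", "q1", "q3", "skew", "kurt", "rms"),
    paste0("mfcc", keep), function(s, c) paste(c, s, sep = "_")))
  c0 <- cep[1L, ]
  q <- stats::quantile(c0, c(0.25, 0.5, 0.75), names = FALSE)
  c0s <- c(mean(c0), if (length(c0) > 1L) stats::sd(c0) else 0, q[2],
           min(c0), max(c0), q[1], q[3], max(c0) - min(c0))
  names(c0s) <- paste0("c0_", c("mean", "sd", "median", "min", "max",
                                "q1", "q3", "range"))
  c(out, c0s)
}

# ---- spectral block (f3, d3 = 224) ------------------------------------------

agg_stats14 <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  s <- if (length(v) > 1L) stats::sd(v) else 0
  dv <- if (length(v) > 1L) diff(v) else 0
  c(mean(v), s, q[2], min(v), max(v), q[1], q[3], q[3] - q[1],
    max(v) - min(v), moment_skewness(v), moment_kurtosis(v),
    sqrt(mean(v^2)), mean(abs(dv)), if (length(dv) > 1L) stats::sd(dv) else 0)
}

STAT14_NAMES <- c("mean", "sd", "median", "min", "max", "q1", "q3", "iqr",
                  "range", "skew", "kurt", "rms", "madiff", "sddiff")

#' Spectral features (f3)
#'
#' From the squared-magnitude STFT, computes four per-frame descriptor
#' families: spectral centroid (power-weighted mean frequency), spectral
#' bandwidth (power-weighted standard deviation around the centroid), and a
#' 7-band spectral contrast (log peak-minus-valley of the band power, bands
#' below 200 Hz and six octaves upward) together with the 7 per-band valley
#' levels. The 16 tracks are each aggregated with 14 statistics (mean, sd,
#' median, min, max, Q1, Q3, IQR, range, skewness, kurtosis, RMS, mean
#' absolute first difference, sd of first difference) for 224 values.
#'
#' @param clip a [audio_clip()].
#' @param frame_length,hop STFT parameters.
#' @param fmin_contrast lowest contrast band edge in Hz.
#' @param quantile_frac fraction of band bins averaged for peak/valley.
#' @return Named numeric vector, length 224 at the defaults.
#' @export
spectral_features <- function(clip, frame_length = 2048L, hop = 512L,
                              fmin_contrast = 200, quantile_frac = 0.2) {
  stopifnot(inherits(clip, "painsense_clip"))
  if (length(clip$samples) < 1L) stop("data error: empty clip")
  mag <- stft_mag(clip$samples, frame_length, hop)
  p <- mag^2
  freqs <- stft_bin_freqs(frame_length, clip$sample_rate)
  tot <- colSums(p)
  tot[tot == 0] <- LOG_FLOOR
  centroid <- colSums(freqs * p) / tot
  bandwidth <- sqrt(colSums(p * (outer(freqs, centroid, `-`))^2) / tot)
  # contrast bands: [0, fmin), then octaves up to Nyquist
  sr <- clip$sample_rate
  edges <- c(0, fmin_contrast * 2^(0:5), sr / 2)
  edges <- pmin(edges, sr / 2)
  n_bands <- length(edges) - 1L          # 7 at defaults
  peaks <- valleys <- matrix(0, n_bands, ncol(p))
  for (b in seq_len(n_bands)) {
    in_band <- freqs >= edges[b] & (if (b == n_bands) freqs <= edges[b + 1L]
                                    else freqs < edges[b + 1L])
    sub <- p[in_band, , drop = FALSE]
    k <- max(1L, round(quantile_frac * nrow(sub)))
    sorted <- apply(sub, 2, sort)
    if (is.null(dim(sorted))) sorted <- matrix(sorted, nrow = 1L)
    valleys[b, ] <- log(pmax(colMeans(sorted[seq_len(k), , drop = FALSE]),
                             LOG_FLOOR))
    peaks[b, ] <- log(pmax(
      colMeans(sorted[nrow(sorted) - seq_len(k) + 1L, , drop = FALSE]),
      LOG_FLOOR))
  }
  tracks <- rbind(centroid = centroid, bandwidth = bandwidth,
                  peaks - valleys, valleys)
  rownames(tracks) <- c("centroid", "bandwidth",
                        paste0("contrast", seq_len(n_bands)),
                        paste0("valley", seq_len(n_bands)))
  out <- as.vector(apply(tracks, 1, agg_stats14))
  names(out) <- as.vector(outer(STAT14_NAMES, rownames(tracks),
                                function(s, tr) paste(tr, s, sep = "_")))
  out
}

# ---- concatenation ----------------------------------------------------------

#' Concatenated audio feature vector (f_audio)
#'
#' Extracts and concatenates the selected feature blocks in the fixed order
#' statistical (11), MFCC (128), spectral (224): `d = 363` with all three,
#' `d = 352` in the MFCC+spectral configuration used by the fused audio
#' classifier.
#'
#' @param clip a [audio_clip()].
#' @param blocks subset of `c("statistical", "mfcc", "spectral")`, kept in
#'   the canonical order.
#' @param ... passed to the block extractors.
#' @return Numeric feature vector with attribute `block_dims` (named block
#'   dimensions summing to its length).
#' @export
extract_all <- function(clip, blocks = c("statistical", "mfcc", "spectral"),
                        ...) {
  stopifnot(inherits(clip, "painsense_clip"))
  if (length(clip$samples) < 2L) stop("data error: empty clip")
  blocks <- match.arg(blocks, several.ok = TRUE)
  blocks <- intersect(c("statistical", "mfcc", "spectral"), blocks)
  parts <- list()
  if ("statistical" %in% blocks) parts$statistical <- statistical_features(clip)
  if ("mfcc" %in% blocks) parts$mfcc <- mfcc_features(clip, ...)
  if ("spectral" %in% blocks) parts$spectral <- spectral_features(clip, ...)
  out <- unlist(parts)
  if (any(!is.finite(out))) stop("feature vector contains non-finite values")
  attr(out, "block_dims") <- vapply(parts, length, integer(1))
  out
}

#' Feature matrix for a set of clips
#'
#' @param clips list of [audio_clip()] objects.
#' @param blocks,... passed to [extract_all()].
#' @param sample_rate common analysis rate; clips are resampled to it first.
#' @return `n x d` matrix (rows = clips) with attribute `block_dims`.
#' @export
audio_feature_matrix <- function(clips,
                                 blocks = c("statistical", "mfcc", "spectral"),
                                 sample_rate = 16000L, ...) {
  rows <- lapply(clips, function(cl)
    extract_all(resample_clip(cl, sample_rate), blocks = blocks, ...))
  X <- do.call(rbind, rows)
  attr(X, "block_dims") <- attr(rows[[1L]], "block_dims")
  X
}
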