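# Seeded generator of paired L-class face-image + vocalization samples whose
# pain-related signal (brow furrow, mouth aperture; vocal pitch, loudness,
# roughness) is monotone in the class index, with pose / illumination / noise
# nuisance variation. Stands in for the licensed clinical datasets so that
# every pipeline stage is testable offline.

#' Synthetic benchmark configuration
#'
#' @param L class count, 2-5 pain intensity levels.
#' @param n_per_class samples per class.
#' @param image_size face image side length in pixels.
#' @param sample_rate audio rate in Hz; `duration` clip length in seconds.
#' @param difficulty separation scale in (0, 1]: 1 gives maximally distinct
#'   class-conditional distributions, values near 0 collapse them to chance.
#' @param pose_shift maximum face translation in pixels (uniform).
#' @param illum_range multiplicative illumination gain range.
#' @param noise_sd pixel noise standard deviation (intensity units).
#' @param snr_db audio signal-to-noise ratio of the additive noise floor.
#' @param seed master RNG seed.
#' @return A `painsense_synth_config` list.
#' @export
synth_config <- function(L = 3L, n_per_class = 50L, image_size = 32L,
                         sample_rate = 16000L, duration = 1.0,
                         difficulty = 0.8, pose_shift = 2L,
                         illum_range = c(0.85, 1.15), noise_sd = 0.03,
                         snr_db = 15, seed = 1L) {
  L <- as.integer(L)
  if (!L %in% 2:5) stop("L must be one of 2, 3, 4, 5")
  stopifnot(n_per_class >= 1, image_size >= 16, sample_rate > 0,
            duration > 0, difficulty > 0, difficulty <= 1,
            pose_shift >= 0, noise_sd >= 0,
            length(illum_range) == 2L, illum_range[1] <= illum_range[2])
  structure(list(L = L, n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size),
                 sample_rate = as.integer(sample_rate), duration = duration,
                 difficulty = difficulty, pose_shift = pose_shift,
                 illum_range = illum_range, noise_sd = noise_sd,
                 snr_db = snr_db, seed = as.integer(seed)),
            class = "painsense_synth_config")
}

# Draw one face template. All geometry is relative to the image size so the
# generator works at any resolution. class_frac in [0, 1] scales the pain
# expression: brow furrow (inner brow ends pulled down and together) and
# mouth aperture both increase with it.
draw_face <- function(size, class_frac, difficulty, pose, illum, noise_sd) {
  s <- size
  img <- array(0.15, c(s, s, 3))
  cx <- s / 2 + pose[1]; cy <- s / 2 + pose[2]
  xs <- matrix(seq_len(s), s, s, byrow = TRUE)   # column coordinate
  ys <- matrix(seq_len(s), s, s)                 # row coordinate
  rx <- 0.38 * s; ry <- 0.45 * s
  head <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
  for (ch in 1:3) img[, , ch][head] <- c(0.85, 0.72, 0.62)[ch]
  eff <- class_frac * difficulty
  # eyes
  ey <- cy - 0.12 * s; ex <- 0.14 * s
  for (sgn in c(-1, 1)) {
    eye <- ((xs - (cx + sgn * ex)) / (0.06 * s))^2 +
      ((ys - ey) / (0.035 * s))^2 <= 1
    for (ch in 1:3) img[, , ch][eye] <- 0.08
  }
  # brows: furrow depth (inner end drawn down) grows with class
  furrow <- 0.10 * s * eff
  by0 <- cy - 0.22 * s
  for (sgn in c(-1, 1)) {
    x_in <- cx + sgn * 0.05 * s; x_out <- cx + sgn * 0.22 * s
    for (t in seq(0, 1, length.out = ceiling(0.2 * s) * 4L)) {
      bx <- x_in + t * (x_out - x_in)
      by <- by0 + (1 - t) * furrow
      sel <- abs(xs - bx) <= max(1, 0.015 * s) &
        abs(ys - by) <= max(1, 0.02 * s)
      for (ch in 1:3) img[, , ch][sel] <- 0.12
    }
  }
  # mouth: aperture height grows with class
  my <- cy + 0.22 * s
  mh <- 0.02 * s + 0.10 * s * eff
  mouth <- ((xs - cx) / (0.16 * s))^2 + ((ys - my) / mh)^2 <= 1
  for (ch in 1:3) img[, , ch][mouth] <- c(0.35, 0.08, 0.10)[ch]
  img <- img * illum
  if (noise_sd > 0) img <- img + array(stats::rnorm(length(img), 0, noise_sd),
                                       dim(img))
  pmin(pmax(img, 0), 1)
}

#' Generate synthetic face images
#'
#' Parametric face templates (elliptic head, eyes, brows, mouth) whose brow
#' furrow and mouth aperture increase monotonically with the pain class,
#' under pose / illumination / pixel-noise nuisance variation. Ground-truth
#' face boxes are returned for the detector-free normalization path.
#'
#' @param cfg a [synth_config()].
#' @return list: `images` (list of `size x size x 3` arrays in `[0, 1]`),
#'   `labels` (integer `0 .. L-1`), `boxes` (data frame `x, y, w, h`).
#' @export
gen_faces <- function(cfg) {
  stopifnot(inherits(cfg, "painsense_synth_config"))
  set.seed(cfg$seed)
  n <- cfg$L * cfg$n_per_class
  labels <- rep(0:(cfg$L - 1L), each = cfg$n_per_class)
  s <- cfg$image_size
  images <- vector("list", n)
  boxes <- data.frame(x = integer(n), y = integer(n), w = integer(n),
                      h = integer(n))
  for (i in seq_len(n)) {
    pose <- if (cfg$pose_shift > 0)
      stats::runif(2, -cfg$pose_shift, cfg$pose_shift) else c(0, 0)
    illum <- stats::runif(1, cfg$illum_range[1], cfg$illum_range[2])
    class_frac <- if (cfg$L > 1L) labels[i] / (cfg$L - 1L) else 0
    images[[i]] <- draw_face(s, class_frac, cfg$difficulty, pose, illum,
                             cfg$noise_sd)
    cx <- s / 2 + pose[1]; cy <- s / 2 + pose[2]
    x0 <- max(1L, round(cx - 0.40 * s)); y0 <- max(1L, round(cy - 0.47 * s))
    x1 <- min(s, round(cx + 0.40 * s)); y1 <- min(s, round(cy + 0.47 * s))
    boxes[i, ] <- c(x0, y0, x1 - x0 + 1L, y1 - y0 + 1L)
  }
  list(images = images, labels = labels, boxes = boxes)
}

# One harmonic vocalization: fundamental frequency, loudness and roughness
# all increase with class_frac * difficulty.
synth_voc <- function(n, sr, class_frac, difficulty, snr_db) {
  eff <- class_frac * difficulty
  t <- (seq_len(n) - 1) / sr
  f0 <- 130 * (1 + 1.2 * eff) * stats::runif(1, 0.97, 1.03)
  n_harm <- 8L
  x <- numeric(n)
  for (h in seq_len(n_harm))
    x <- x + (1 / h) * sin(2 * pi * h * f0 * t + stats::runif(1, 0, 2 * pi))
  env <- sin(pi * pmin(pmax(t / max(t), 0), 1))^0.5    # attack-decay envelope
  x <- x * env
  # roughness: amplitude-modulated noise burst grows with class
  rough <- 0.6 * eff
  if (rough > 0) {
    am <- 1 + 0.8 * sin(2 * pi * stats::runif(1, 28, 45) * t)
    x <- x + rough * am * env * stats::rnorm(n)
  }
  # loudness target: RMS monotone in class
  target_rms <- 0.08 + 0.25 * eff
  x <- x * target_rms / max(sqrt(mean(x^2)), 1e-12)
  # additive noise floor at the configured SNR
  noise_rms <- target_rms / 10^(snr_db / 20)
  x <- x + stats::rnorm(n, 0, noise_rms)
  pmin(pmax(x, -1), 1)
}

#' Generate synthetic vocalization clips
#'
#' Harmonic vocalization-like signals whose fundamental frequency, RMS
#' loudness and roughness (amplitude-modulated noise) increase monotonically
#' with the pain class, plus an additive noise floor at the configured SNR.
#'
#' @param cfg a [synth_config()].
#' @return list: `clips` (list of [audio_clip()]), `labels` (integer).
#' @export
gen_audio <- function(cfg) {
  stopifnot(inherits(cfg, "painsense_synth_config"))
  set.seed(cfg$seed + 10007L)
  n <- cfg$L * cfg$n_per_class
  labels <- rep(0:(cfg$L - 1L), each = cfg$n_per_class)
  n_samp <- round(cfg$sample_rate * cfg$duration)
  clips <- vector("list", n)
  for (i in seq_len(n)) {
    class_frac <- if (cfg$L > 1L) labels[i] / (cfg$L - 1L) else 0
    clips[[i]] <- audio_clip(
      synth_voc(n_samp, cfg$sample_rate, class_frac, cfg$difficulty,
                cfg$snr_db),
      cfg$sample_rate, labels[i])
  }
  list(clips = clips, labels = labels)
}

#' Generate paired image + audio samples
#'
#' Produces one face image and one vocalization clip per sample sharing a
#' pain class label, with a pairing manifest — the unit of multimodal fusion.
#'
#' @param cfg a [synth_config()].
#' @return list: `faces` (as [gen_faces()]), `audio` (as [gen_audio()]),
#'   `pairs` (data frame `image_id`, `audio_id`, `label`).
#' @export
gen_paired <- function(cfg) {
  faces <- gen_faces(cfg)
  audio <- gen_audio(cfg)
  stopifnot(identical(faces$labels, audio$labels))
  n <- length(faces$labels)
  pairs <- data.frame(image_id = paste0("img", seq_len(n)),
                      audio_id = paste0("aud", seq_len(n)),
                      label = faces$labels)
  list(faces = faces, audio = audio, pairs = pairs)
}

#' Materialize a synthetic benchmark directory
#'
#' Writes the exact on-disk layout the pipelines read: `images/*.png` with
#' `images.csv` (`path,label,x,y,w,h`), `audio/*.wav` with `audio.csv`
#' (`path,label`), and `pairs.csv` (`image_id,audio_id,label`), plus a JSON
#' snapshot of the generator configuration.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(cfg, dir) {
  data <- gen_paired(cfg)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "audio"), recursive = TRUE, showWarnings = FALSE)
  n <- length(data$faces$labels)
  img_paths <- file.path("images", sprintf("img%04d.png", seq_len(n)))
  aud_paths <- file.path("audio", sprintf("aud%04d.wav", seq_len(n)))
  for (i in seq_len(n)) {
    png::writePNG(data$faces$images[[i]], file.path(dir, img_paths[i]))
    wav_write(data$audio$clips[[i]], file.path(dir, aud_paths[i]))
  }
  utils::write.csv(cbind(data.frame(path = img_paths,
                                    label = data$faces$labels),
                         data$faces$boxes),
                   file.path(dir, "images.csv"), row.names = FALSE)
  utils::write.csv(data.frame(path = aud_paths, label = data$audio$labels),
                   file.path(dir, "audio.csv"), row.names = FALSE)
  utils::write.csv(data$pairs, file.path(dir, "pairs.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
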