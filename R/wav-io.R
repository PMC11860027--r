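# Minimal RIFF/WAVE PCM 16-bit mono reader/writer.

#' Audio clip container
#'
#' @param samples numeric waveform with amplitudes in `[-1, 1]`.
#' @param sample_rate sampling rate in Hz.
#' @param label optional pain class label.
#' @return A `painsense_clip` list.
#' @export
audio_clip <- function(samples, sample_rate, label = NA_integer_) {
  stopifnot(is.numeric(samples), length(samples) >= 1L, sample_rate > 0)
  if (any(!is.finite(samples))) stop("waveform contains non-finite samples")
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.integer(sample_rate),
                 label = label),
            class = "painsense_clip")
}

#' @export
print.painsense_clip <- function(x, ...) {
  cat(sprintf("audio clip: %d samples @ %d Hz (%.3f s), label %s\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, format(x$label)))
  invisible(x)
}

#' Write / read mono PCM 16-bit WAV files
#'
#' `wav_write` quantizes the waveform to signed 16-bit PCM (values clipped to
#' `[-1, 1]`); `wav_read` returns amplitudes scaled back to `[-1, 1)`.
#'
#' @param clip a [audio_clip()].
#' @param path file path.
#' @return `wav_read`: an [audio_clip()]; `wav_write`: `path`, invisibly.
#' @export
wav_write <- function(clip, path) {
  stopifnot(inherits(clip, "painsense_clip"))
  x <- pmin(pmax(clip$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(clip$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(clip$sample_rate * 2L), con, size = 4,
           endian = "little")                              # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname wav_write
#' @export
wav_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  sample_rate <- NULL; n_channels <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      n_channels <- fmt[2]
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, raw(), n = size - 16L))
    } else if (id == "data") {
      if (is.null(bits)) stop("malformed WAV: data before fmt")
      if (bits != 16L) stop("only 16-bit PCM supported, got ", bits, "-bit")
      samples <- readBin(con, integer(), n = size %/% 2L, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, raw(), n = size))
    }
  }
  if (is.null(samples)) stop("malformed WAV: no data chunk")
  if (n_channels != 1L) stop("only mono WAV supported, got ", n_channels,
                             " channels")
  audio_clip(samples / 32768, sample_rate)
}
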