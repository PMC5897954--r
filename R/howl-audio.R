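# Synthetic howl generation, broadcast rendering and template
# cross-correlation TOA extraction.

#' Manual spectrogram-read jitter (seconds)
#'
#' Standard deviation of the Gaussian jitter that emulates repeated manual
#' onset reads off a spectrogram with a 1024-sample Hann window at 90%
#' overlap and 16 kHz sampling (hop of 102.4 samples, i.e. 6.4 ms).
#' Pass it as `jitter_sd` to [extract_toa()] to emulate manual reading;
#' extraction is exact (jitter off) by default.
#' @export
howl_read_jitter_sd <- 102.4 / 16000

#' Specify a synthetic howl
#'
#' A howl-like test tone: a fundamental sweeping `f0_start` to `f0_end`
#' over `duration` seconds plus `n_harmonics` harmonics. The defaults are a
#' 7 s, 300--1000 Hz sweep with four harmonics sampled at 16 kHz, the
#' synthetic howl used in low-density wolf-array field trials.
#'
#' @param duration Tone length in seconds.
#' @param f0_start,f0_end Fundamental frequency at start/end, Hz.
#' @param n_harmonics Number of harmonics above the fundamental.
#' @param harmonic_weights Relative amplitudes for harmonics 2..(n+1);
#'   default `1/k` for harmonic `k`.
#' @param sample_rate Sampling rate, Hz.
#' @param sweep `"linear"` (default) or `"log"` frequency trajectory;
#'   `"chord"` mixes the band edges as simultaneous steady tones instead.
#' @return A list of class `howl_spec`.
#' @examples
#' spec <- howl_spec()
#' w <- generate_howl(spec)
#' length(w$samples) # 112000
#' @export
howl_spec <- function(duration = 7, f0_start = 300, f0_end = 1000,
                      n_harmonics = 4, harmonic_weights = NULL,
                      sample_rate = 16000, sweep = c("linear", "log", "chord")) {
  sweep <- match.arg(sweep)
  if (duration <= 0) abort("duration must be > 0")
  if (f0_start <= 0 || f0_end < f0_start) abort("need 0 < f0_start <= f0_end")
  if (n_harmonics < 0) abort("n_harmonics must be >= 0")
  f_max <- f0_end * (n_harmonics + 1)
  if (sample_rate < 2 * f_max) {
    abort(sprintf(
      "sample_rate %g Hz violates Nyquist for harmonic %d at %g Hz",
      sample_rate, n_harmonics + 1, f_max
    ))
  }
  if (is.null(harmonic_weights)) {
    harmonic_weights <- if (n_harmonics > 0) 1 / (2:(n_harmonics + 1)) else numeric(0)
  }
  if (length(harmonic_weights) != n_harmonics) {
    abort("harmonic_weights must have length n_harmonics")
  }
  structure(
    list(
      duration = duration, f0_start = f0_start, f0_end = f0_end,
      n_harmonics = n_harmonics, harmonic_weights = harmonic_weights,
      sample_rate = sample_rate, sweep = sweep
    ),
    class = "howl_spec"
  )
}

#' Generate the synthetic howl waveform
#'
#' Synthesises the tone described by a [howl_spec()]: the instantaneous
#' fundamental moves from `f0_start` to `f0_end` across the duration
#' (phase obtained by integrating the frequency trajectory) and harmonics
#' `k * f0` are added with the spec's weights. The result is peak-normalised.
#'
#' @param spec A [howl_spec()].
#' @return A list of class `waveform` with `samples` (in \[-1, 1\]) and
#'   `sample_rate`.
#' @export
generate_howl <- function(spec) {
  stopifnot(inherits(spec, "howl_spec"))
  fs <- spec$sample_rate
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1) / fs
  weights <- c(1, spec$harmonic_weights)
  if (spec$sweep == "chord") {
    # steady tones at the band edges, harmonics on each
    phase0 <- cbind(spec$f0_start * t, spec$f0_end * t)
    x <- rowSums(vapply(seq_along(weights), function(k) {
      weights[k] * rowSums(sin(2 * pi * k * phase0)) / 2
    }, numeric(n)))
  } else {
    # integral of f0(t) gives the phase argument
    phase0 <- if (spec$sweep == "linear") {
      spec$f0_start * t + (spec$f0_end - spec$f0_start) * t^2 / (2 * spec$duration)
    } else {
      r <- spec$f0_end / spec$f0_start
      if (r == 1) spec$f0_start * t
      else spec$f0_start * spec$duration * (r^(t / spec$duration) - 1) / log(r)
    }
    x <- rowSums(vapply(seq_along(weights), function(k) {
      weights[k] * sin(2 * pi * k * phase0)
    }, numeric(n)))
  }
  x <- x / max(abs(x))
  structure(list(samples = x, sample_rate = fs), class = "waveform")
}

#' Render a broadcast into a simulated recording
#'
#' Places an attenuated copy of the template at `onset` seconds (nearest
#' sample) in a longer buffer and adds white Gaussian noise scaled so the
#' signal-to-noise ratio over the template window equals `noise_snr_db`.
#'
#' @param template A `waveform` (see [generate_howl()]).
#' @param onset Start time of the template in the recording, seconds.
#' @param attenuation_db Amplitude attenuation in dB (0 = unattenuated).
#' @param noise_snr_db Target SNR over the template window, dB; `Inf`
#'   renders a noise-free recording.
#' @param total_length Recording length, seconds.
#' @param seed RNG seed for the noise draw.
#' @param channel_id Label carried through to the output.
#' @return A list of class `recording` with `samples`, `sample_rate`,
#'   `channel_id`, `true_onset` (kept for testing) and `snr_db`.
#' @export
render_broadcast <- function(template, onset, attenuation_db = 0,
                             noise_snr_db = Inf, total_length, seed = 1L,
                             channel_id = "A") {
  stopifnot(inherits(template, "waveform"))
  fs <- template$sample_rate
  n_total <- round(total_length * fs)
  n_tpl <- length(template$samples)
  if (onset < 0 || onset + n_tpl / fs > total_length) {
    abort(sprintf("onset %.3f s puts the template outside the %.3f s recording", onset, total_length))
  }
  i0 <- round(onset * fs) + 1L
  gain <- 10^(-attenuation_db / 20)
  x <- numeric(n_total)
  x[i0:(i0 + n_tpl - 1L)] <- gain * template$samples
  if (is.finite(noise_snr_db)) {
    sig_pow <- mean((gain * template$samples)^2)
    noise_sd <- sqrt(sig_pow / 10^(noise_snr_db / 10))
    set.seed(as.integer(seed))
    x <- x + rnorm(n_total, sd = noise_sd)
  }
  structure(
    list(
      samples = x, sample_rate = fs, channel_id = channel_id,
      true_onset = (i0 - 1L) / fs, snr_db = noise_snr_db
    ),
    class = "recording"
  )
}

# linear cross-correlation of recording with template via FFT;
# returns correlation at lags 0..(n_rec - n_tpl)
xcorr_lags <- function(rec, tpl) {
  n <- length(rec) + length(tpl) - 1L
  nfft <- 2^ceiling(log2(n))
  R <- fft(c(rec, numeric(nfft - length(rec))))
  S <- fft(c(tpl, numeric(nfft - length(tpl))))
  cc <- Re(fft(R * Conj(S), inverse = TRUE)) / nfft
  cc[seq_len(length(rec) - length(tpl) + 1L)]
}

#' Extract a time of arrival by template cross-correlation
#'
#' Matched-filter onset detection: the recording is cross-correlated with
#' the template and the correlation peak gives the onset. The peak must
#' exceed `k_sig` times the median absolute correlation to count as a
#' detection; otherwise the extraction reports failure (an `NA` row, not an
#' error). The measurement is repeated `n_repeats` times, each repeat
#' perturbed by Gaussian jitter of sd `jitter_sd` seconds (emulating
#' repeated manual spectrogram reads; see [howl_read_jitter_sd]), and the
#' mean is returned.
#'
#' @param recording A `recording` (see [render_broadcast()]).
#' @param template The `waveform` to search for.
#' @param n_repeats Number of repeated reads to average (>= 1).
#' @param jitter_sd Per-repeat Gaussian read jitter, seconds (0 = exact).
#' @param k_sig Peak-significance factor: peak >= k_sig * median |corr|.
#' @param seed RNG seed for the jitter draws.
#' @return A one-row tibble with `toa_s`, `snr_db` and `detected`
#'   (`toa_s`/`snr_db` are `NA` when no significant peak is found).
#' @export
extract_toa <- function(recording, template, n_repeats = 3, jitter_sd = 0,
                        k_sig = 8, seed = 1L) {
  stopifnot(inherits(recording, "recording"), inherits(template, "waveform"))
  if (recording$sample_rate != template$sample_rate) {
    abort("recording and template sample rates differ")
  }
  if (n_repeats < 1) abort("n_repeats must be >= 1")
  fs <- recording$sample_rate
  cc <- xcorr_lags(recording$samples, template$samples)
  peak_i <- which.max(cc)
  peak <- cc[peak_i]
  floor_med <- median(abs(cc))
  if (!is.finite(peak) || floor_med == 0 && peak == 0 ||
      peak < k_sig * floor_med) {
    return(tibble(toa_s = NA_real_, snr_db = NA_real_, detected = 0L))
  }
  onset <- (peak_i - 1L) / fs
  if (jitter_sd > 0 && n_repeats >= 1) {
    set.seed(as.integer(seed))
    onset <- mean(onset + rnorm(n_repeats, sd = jitter_sd))
  }
  # SNR over the detected window vs the rest of the recording
  idx <- peak_i:min(peak_i + length(template$samples) - 1L, length(recording$samples))
  sig_pow <- mean(recording$samples[idx]^2)
  noise_pow <- if (length(recording$samples) > length(idx)) {
    mean(recording$samples[-idx]^2)
  } else {
    NA_real_
  }
  snr <- if (is.na(noise_pow) || noise_pow == 0) Inf
  else 10 * log10(max(sig_pow - noise_pow, .Machine$double.eps) / noise_pow)
  tibble(toa_s = onset, snr_db = snr, detected = 1L)
}

#' Write / read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE I/O for the package's simulated recordings: mono,
#' 16-bit little-endian PCM. Samples are clipped to \[-1, 1\] and quantised
#' to 16 bits on write.
#'
#' @param wave A `waveform` or `recording` (anything with `samples` and
#'   `sample_rate`).
#' @param path File path.
#' @return `write_wav()` returns `path` invisibly; `read_wav()` returns a
#'   `waveform`.
#' @export
write_wav <- function(wave, path) {
  x <- pmin(pmax(wave$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  fs <- as.integer(wave$sample_rate)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # PCM
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) abort("not a RIFF file")
  readBin(con, integer(), size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) abort("not a WAVE file")
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) abort("no data chunk found")
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) abort("only mono PCM WAV supported")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, "raw", n = sz - 8L)
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = sz / 2L, size = 2,
                     endian = "little", signed = TRUE)
      break
    } else {
      readBin(con, "raw", n = sz)
    }
  }
  if (is.null(fs)) abort("fmt chunk missing")
  structure(list(samples = pcm / 32767, sample_rate = fs), class = "waveform")
}
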