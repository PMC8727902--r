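#' Signal-to-noise ratio of two aligned waveforms
#'
#' SNR on whole-utterance RMS: `20 * log10(rms(speech) / rms(noise))`.
#'
#' @param speech,noise [waveform()]s of equal length and sample rate;
#'   `noise` must not be silent.
#' @return SNR in decibels.
#' @examples
#' s <- waveform(rnorm(8000, sd = 0.1), 8000)
#' n <- waveform(rnorm(8000, sd = 0.1), 8000)
#' compute_snr(s, n)  # ~0 dB
#' @export
compute_snr <- function(speech, noise) {
  stopifnot(is_waveform(speech), is_waveform(noise))
  if (length(speech$samples) != length(noise$samples))
    stop("speech and noise must have equal length")
  if (speech$sample_rate != noise$sample_rate)
    stop("speech and noise must share a sample rate")
  rn <- rms(noise)
  if (rn == 0) stop("noise is silent; SNR undefined")
  20 * log10(rms(speech) / rn)
}

#' Mix speech with babble at an exact target SNR
#'
#' Crops the babble to the speech length from a uniformly random offset
#' (seeded, recorded in the result), rescales the cropped noise so the
#' re-measured SNR equals `target_snr_db` exactly, and sums. If the sum
#' would exceed full scale, speech, noise and mix are scaled down together,
#' which leaves the SNR untouched. The sentinel `"clean"` skips mixing and
#' returns the speech unchanged.
#'
#' The returned object keeps the scaled components (`speech`, `noise`) and
#' provenance (`speaker_id`, `sentence_id`, `group`, `hints_available`) so a
#' simulated recognizer and the downstream analysis can condition on them.
#'
#' @param speech A non-silent [waveform()].
#' @param babble A [combine_talkers()] result (or a bare [waveform()]) at
#'   least as long as the speech.
#' @param target_snr_db Target SNR in dB, or `"clean"`.
#' @param speaker_id,sentence_id,group Provenance labels.
#' @param hints_available Whether phrase hints accompany this recording.
#' @param seed Integer seed for the crop offset.
#' @return An object of class `mixed_recording`.
#' @export
mix_at_snr <- function(speech, babble, target_snr_db,
                       speaker_id = NA_character_, sentence_id = NA_character_,
                       group = NA_character_, hints_available = FALSE,
                       seed = 1L) {
  stopifnot(is_waveform(speech))
  clean <- identical(target_snr_db, "clean") ||
    (is.numeric(target_snr_db) && is.infinite(target_snr_db))
  if (!clean && (!is.numeric(target_snr_db) || !is.finite(target_snr_db)))
    stop("'target_snr_db' must be a finite number or \"clean\"")

  if (clean) {
    return(structure(list(audio = speech, speech = speech, noise = NULL,
                          target_snr_db = "clean", speaker_id = speaker_id,
                          sentence_id = sentence_id, group = group,
                          hints_available = hints_available,
                          crop_offset = NA_integer_, peak_scale = 1),
                     class = "mixed_recording"))
  }

  noise_wave <- if (inherits(babble, "babble_noise")) babble$audio else babble
  stopifnot(is_waveform(noise_wave))
  if (noise_wave$sample_rate != speech$sample_rate)
    stop("speech and babble must share a sample rate")
  n_s <- length(speech$samples); n_b <- length(noise_wave$samples)
  if (n_b < n_s) stop("babble is shorter than the speech")
  if (rms(speech) == 0) stop("silent speech: SNR target is unreachable")

  offset <- withr::with_seed(seed,
    if (n_b == n_s) 0L else sample.int(n_b - n_s + 1L, 1L) - 1L)
  noise <- noise_wave$samples[(offset + 1L):(offset + n_s)]
  rn <- sqrt(mean(noise^2))
  if (rn == 0) stop("cropped babble segment is silent")

  scale <- rms(speech) / (rn * 10^(target_snr_db / 20))
  noise <- noise * scale
  mix <- speech$samples + noise
  peak_scale <- 1
  peak <- max(abs(mix))
  if (peak > 1) {           # joint rescale preserves the component SNR
    peak_scale <- 1 / peak
    mix <- mix * peak_scale
    noise <- noise * peak_scale
  }
  speech_out <- waveform(speech$samples * peak_scale, speech$sample_rate)
  structure(list(audio = waveform(mix, speech$sample_rate),
                 speech = speech_out,
                 noise = waveform(noise, speech$sample_rate),
                 target_snr_db = target_snr_db,
                 speaker_id = speaker_id, sentence_id = sentence_id,
                 group = group, hints_available = hints_available,
                 crop_offset = offset, peak_scale = peak_scale),
            class = "mixed_recording")
}

#' @export
print.mixed_recording <- function(x, ...) {
  snr <- if (identical(x$target_snr_db, "clean")) "clean"
         else sprintf("%g dB", x$target_snr_db)
  cat(sprintf("<mixed_recording: %s, speaker %s, sentence %s, %.2f s @ %g Hz>\n",
              snr, x$speaker_id, x$sentence_id, duration(x$audio),
              x$audio$sample_rate))
  invisible(x)
}
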