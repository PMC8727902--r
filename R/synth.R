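#' Bundled high-frequency English vocabulary
#'
#' A list of roughly 500 high-frequency English content words shipped with
#' the package, used to build sentence corpora and as the substitution /
#' insertion pool of the simulated recognizer.
#'
#' @return Character vector of unique lowercase words.
#' @export
default_vocab <- function() {
  path <- system.file("extdata", "high_freq_words.txt", package = "asrnoise")
  unique(readLines(path, warn = FALSE))
}

#' Generate a sentence corpus
#'
#' Sentences of 5-9 words (by default) drawn from a high-frequency
#' vocabulary, with no word repeated within a sentence; 50 sentences by
#' default, mirroring a typical read-speech stimulus set.
#'
#' @param n Number of sentences.
#' @param min_len,max_len Sentence length bounds in words; lengths are
#'   uniform on `[min_len, max_len]`.
#' @param vocab Word pool (>= `max_len` words).
#' @param seed Integer seed; the corpus is deterministic given the seed.
#' @return An object of class `sentence_corpus`: list with `sentences`
#'   (list of character vectors) and `ids`.
#' @export
generate_corpus <- function(n = 50, min_len = 5, max_len = 9,
                            vocab = default_vocab(), seed = 1L) {
  if (n < 1) stop("'n' must be at least 1")
  if (!(min_len <= max_len)) stop("need min_len <= max_len")
  if (length(vocab) < max_len)
    stop("vocabulary too small: need at least ", max_len, " words")
  sentences <- withr::with_seed(seed, {
    lens <- min_len + sample.int(max_len - min_len + 1L, n, replace = TRUE) - 1L
    lapply(lens, function(L) sample(vocab, L, replace = FALSE))
  })
  structure(list(sentences = sentences,
                 ids = sprintf("s%03d", seq_len(n))),
            class = "sentence_corpus")
}

#' @export
print.sentence_corpus <- function(x, ...) {
  lens <- vapply(x$sentences, length, integer(1))
  cat(sprintf("<sentence_corpus: %d sentences, %d-%d words>\n",
              length(x$sentences), min(lens), max(lens)))
  invisible(x)
}

#' Generate a speaker cohort
#'
#' Emulates a small clinical cohort: `n_pd` speakers with Parkinson's
#' disease and `n_hc` healthy controls. PD speakers receive a dysarthria
#' severity (mild or moderate) and a positive intelligibility handicap in
#' logit units (mild: 0.3-0.7, moderate: 0.7-1.2) that feeds the simulated
#' recognizer's error model; control handicaps are 0. Ages and sexes are
#' sampled to match the marginals of a typical PD pilot cohort (PD around
#' age 71, controls around 63); sex counts are configurable.
#'
#' @param n_pd,n_hc Group sizes.
#' @param seed Integer seed.
#' @param pd_n_male,hc_n_male Number of male speakers per group (defaults:
#'   3 of 5 in each).
#' @return Data frame with columns `speaker_id`, `group`, `sex`, `age`,
#'   `severity`, `intelligibility_offset`.
#' @export
generate_cohort <- function(n_pd = 5, n_hc = 5, seed = 1L,
                            pd_n_male = min(3, n_pd),
                            hc_n_male = min(3, n_hc)) {
  if (n_pd < 0 || n_hc < 0 || n_pd + n_hc < 1) stop("empty cohort")
  if (pd_n_male > n_pd || hc_n_male > n_hc) stop("male count exceeds group size")
  withr::with_seed(seed, {
    mk_sex <- function(n, n_male)
      sample(c(rep("male", n_male), rep("female", n - n_male)))
    sev <- if (n_pd > 0)
      sample(c(rep("mild", ceiling(0.6 * n_pd)),
               rep("moderate", n_pd - ceiling(0.6 * n_pd)))) else character(0)
    off <- vapply(sev, function(s)
      if (s == "mild") stats::runif(1, 0.3, 0.7) else stats::runif(1, 0.7, 1.2),
      numeric(1))
    data.frame(
      speaker_id = sprintf("P%02d", seq_len(n_pd + n_hc)),
      group = c(rep("PD", n_pd), rep("HC", n_hc)),
      sex = c(mk_sex(n_pd, pd_n_male), mk_sex(n_hc, hc_n_male)),
      age = round(c(pmin(pmax(stats::rnorm(n_pd, 71, 13), 45), 85),
                    pmin(pmax(stats::rnorm(n_hc, 63, 13), 40), 80))),
      severity = c(sev, rep(NA_character_, n_hc)),
      intelligibility_offset = c(unname(off), rep(0, n_hc)),
      stringsAsFactors = FALSE)
  })
}

#' Assign reading sentences to speakers
#'
#' Each speaker receives `per_speaker` distinct sentences, sampled without
#' replacement per speaker (different speakers may share sentences),
#' emulating an app that shows every participant a short randomized list.
#'
#' @param cohort A [generate_cohort()] data frame.
#' @param corpus A [generate_corpus()] object.
#' @param per_speaker Sentences per speaker.
#' @param seed Integer seed.
#' @return Data frame with columns `speaker_id`, `sentence_id`,
#'   `utterance_id`.
#' @export
assign_sentences <- function(cohort, corpus, per_speaker = 5, seed = 1L) {
  stopifnot(is.data.frame(cohort), inherits(corpus, "sentence_corpus"))
  n_sent <- length(corpus$sentences)
  if (n_sent < per_speaker)
    stop("corpus too small: ", n_sent, " sentences for ", per_speaker,
         " per speaker")
  withr::with_seed(seed, {
    picks <- lapply(seq_len(nrow(cohort)),
                    function(i) sample(corpus$ids, per_speaker))
    data.frame(
      speaker_id = rep(cohort$speaker_id, each = per_speaker),
      sentence_id = unlist(picks),
      utterance_id = sprintf("u%03d", seq_len(nrow(cohort) * per_speaker)),
      stringsAsFactors = FALSE)
  })
}

# one voiced syllable: harmonic stack with a hann amplitude envelope
.syllable <- function(n, f0, sample_rate, amp = 0.3) {
  t <- (seq_len(n) - 1) / sample_rate
  env <- .hann(n)
  x <- numeric(n)
  for (h in 1:4) x <- x + (0.8^h) * sin(2 * pi * h * f0 * t)
  amp * env * x / 2
}

#' Synthesize a speech-like utterance waveform
#'
#' An acoustic stand-in for a recorded sentence: one amplitude-modulated
#' harmonic burst group per word (plus a short fricative-like noise onset),
#' at a word rate of about 3 words per second, so duration grows with word
#' count. The waveform carries the audio pipeline (resampling, mixing); it
#' is not intelligible speech — the simulated recognizer reads provenance,
#' not acoustics.
#'
#' @param sentence Character vector of words (non-empty).
#' @param speaker Optional one-row slice of a [generate_cohort()] data
#'   frame; sets the fundamental-frequency range by sex.
#' @param sample_rate Output sample rate, Hz.
#' @param seed Integer seed; the waveform is bit-reproducible.
#' @return A [waveform()].
#' @export
synthesize_utterance <- function(sentence, speaker = NULL,
                                 sample_rate = 48000, seed = 1L) {
  sentence <- as.character(sentence)
  if (length(sentence) == 0L) stop("empty sentence")
  f0_base <- if (!is.null(speaker) && identical(speaker$sex, "male")) 115
             else if (!is.null(speaker) && identical(speaker$sex, "female")) 210
             else 150
  withr::with_seed(seed, {
    parts <- lapply(seq_along(sentence), function(i) {
      f0 <- f0_base * stats::runif(1, 0.92, 1.08)
      n_voiced <- round(stats::runif(1, 0.18, 0.26) * sample_rate)
      n_noise <- round(0.04 * sample_rate)
      n_gap <- round(0.06 * sample_rate)
      c(0.08 * .hann(n_noise) * stats::rnorm(n_noise),
        .syllable(n_voiced, f0, sample_rate),
        stats::rnorm(n_gap, sd = 1e-4))
    })
    waveform(unlist(parts), sample_rate)
  })
}

#' Generate a single-talker babble source clip
#'
#' A continuous speech-like clip (default 30 s) for babble construction:
#' runs of syllables separated by pauses, a minority of which exceed 500 ms
#' so that silence trimming has work to do. Fundamental frequency is drawn
#' from a sex-dependent range (males lower: 90-140 Hz vs 170-240 Hz).
#' Pauses carry a -60 dB noise floor, well under the -40 dB silence
#' threshold.
#'
#' @param duration_s Clip length in seconds (>= 1).
#' @param sex `"male"` or `"female"`.
#' @param sample_rate Sample rate, Hz.
#' @param seed Integer seed.
#' @param talker_id Label for the clip.
#' @return A [talker_clip()].
#' @export
generate_talker_clip <- function(duration_s = 30, sex = c("male", "female"),
                                 sample_rate = 48000, seed = 1L,
                                 talker_id = paste0("t", seed)) {
  sex <- match.arg(sex)
  if (duration_s < 1) stop("clip must be at least 1 s")
  n_total <- round(duration_s * sample_rate)
  f0_range <- if (sex == "male") c(90, 140) else c(170, 240)
  audio <- withr::with_seed(seed, {
    x <- stats::rnorm(n_total, sd = 3e-4)   # -60 dB floor under 0.3 peak
    pos <- 1L
    long_pause_done <- FALSE
    while (pos < n_total) {
      n_syl <- sample(4:10, 1)
      for (k in seq_len(n_syl)) {
        f0 <- stats::runif(1, f0_range[1], f0_range[2])
        nv <- round(stats::runif(1, 0.12, 0.22) * sample_rate)
        if (pos + nv > n_total) break
        x[pos:(pos + nv - 1L)] <- x[pos:(pos + nv - 1L)] +
          .syllable(nv, f0, sample_rate)
        pos <- pos + nv + round(0.03 * sample_rate)
      }
      pause <- if (stats::runif(1) < 0.15) stats::runif(1, 0.6, 0.9)
               else stats::runif(1, 0.15, 0.45)
      if (pause > 0.5) long_pause_done <- TRUE
      pos <- pos + round(pause * sample_rate)
    }
    if (!long_pause_done) {           # guarantee one prolonged pause
      mid <- n_total %/% 2L
      nq <- min(round(0.7 * sample_rate), n_total - mid + 1L)
      x[mid:(mid + nq - 1L)] <- stats::rnorm(nq, sd = 3e-4)
    }
    x
  })
  talker_clip(waveform(audio, sample_rate), talker_id, sex)
}
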