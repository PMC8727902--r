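# Babble construction: silence trimming, spectral equalization, combining.

sr <- 8000
speech_seg <- function(dur_s = 0.8) {
  0.5 * sin(2 * pi * 300 * (0:(round(dur_s * sr) - 1)) / sr)
}
quiet_seg <- function(dur_ms, seed = 1) {
  withr::with_seed(seed, rnorm(round(dur_ms / 1000 * sr), sd = 1e-5))
}

test_that("a 600 ms internal silence is shortened to 500 ms", {
  w <- waveform(c(speech_seg(), quiet_seg(600), speech_seg()), sr)
  y <- trim_silences(w)
  expect_equal(duration(w) - duration(y), 0.1, tolerance = 1e-6)
})

test_that("a 400 ms silence is left alone", {
  w <- waveform(c(speech_seg(), quiet_seg(400), speech_seg()), sr)
  expect_equal(trim_silences(w)$samples, w$samples)
})

test_that("multiple gaps are each capped by the frame-level detector", {
  # 900/300/510 ms gaps on the 10 ms frame grid -> trimmed by 400/0/10 ms
  w <- waveform(c(speech_seg(), quiet_seg(900, 1), speech_seg(),
                  quiet_seg(300, 2), speech_seg(), quiet_seg(510, 3),
                  speech_seg()), sr)
  y <- trim_silences(w)
  expect_equal(duration(w) - duration(y), 0.410, tolerance = 1e-6)
})

test_that("trim_silences is idempotent and errors on silent input", {
  withr::with_seed(5, {
    for (k in 1:4) {
      cl <- generate_talker_clip(8, sample(c("male", "female"), 1), sr,
                                 seed = k)
      once <- trim_silences(cl$audio)
      expect_equal(trim_silences(once)$samples, once$samples)
      expect_lte(duration(once), duration(cl$audio))
    }
  })
  expect_error(trim_silences(waveform(numeric(100) , sr)), "silent")
  expect_error(trim_silences(waveform(numeric(0), sr)), "empty")
})

test_that("equalization flattens tonal and coloured spectra", {
  tone <- make_tone(1000, 2, sr)
  eq <- equalize_spectrum(tone)
  expect_gt(spectral_flatness(eq), spectral_flatness(tone))
  expect_equal(rms(eq), rms(tone), tolerance = 1e-9)
  expect_equal(length(eq$samples), length(tone$samples))

  pink <- make_pink(2, sr, seed = 8)
  eqp <- equalize_spectrum(pink)
  expect_gt(spectral_flatness(eqp), spectral_flatness(pink))
  # band-level oracle on the output spectrum: mean band power within 3 dB
  lv <- band_levels_db(eqp)
  expect_lt(max(lv) - min(lv), 3)
})

test_that("equalization leaves white noise essentially unchanged in shape", {
  w <- withr::with_seed(9, waveform(0.2 * rnorm(2 * sr), sr))
  eq <- equalize_spectrum(w)
  expect_equal(rms(eq), rms(w), tolerance = 1e-9)
  expect_equal(spectral_flatness(eq), spectral_flatness(w), tolerance = 0.1)
  lv_in <- band_levels_db(w); lv_out <- band_levels_db(eq)
  expect_lt(max(abs(lv_in - lv_out)), 2)
})

test_that("equalization rejects inputs shorter than a window", {
  expect_error(equalize_spectrum(waveform(rnorm(100), sr)), "window")
  expect_error(equalize_spectrum(make_tone(100, 1, sr), window_ms = 20,
                                 hop_ms = 30), "window_ms > hop_ms")
})

test_that("combine_talkers records a balanced 10-talker composition", {
  withr::with_seed(2, {
    clips <- lapply(1:10, function(i)
      generate_talker_clip(3, if (i %% 2) "male" else "female", sr, seed = i))
    bab <- combine_talkers(clips)
    expect_equal(bab$n_talkers, 10)
    expect_equal(bab$n_male, 5)
    expect_equal(bab$n_female, 5)
    expect_equal(rms(bab$audio), 0.1, tolerance = 0.01 * 0.1)
    expect_equal(length(bab$audio$samples),
                 min(vapply(clips, function(cl) length(cl$audio$samples),
                            integer(1))))
  })
})

test_that("two identical opposite-sex clips combine to a rescaled copy", {
  w <- make_tone(220, 2, sr, amp = 0.3)
  clips <- list(talker_clip(w, "a", "male"), talker_clip(w, "b", "female"))
  bab <- combine_talkers(clips, target_rms = 0.05)
  expect_equal(rms(bab$audio), 0.05, tolerance = 1e-9)
  expect_equal(bab$audio$samples,
               w$samples * (0.05 / rms(w)), tolerance = 1e-9)
})

test_that("combining independent noise hits the target RMS within 1%", {
  withr::with_seed(13, {
    clips <- lapply(1:6, function(i)
      talker_clip(waveform(0.1 * rnorm(2 * sr), sr), paste0("n", i),
                  if (i %% 2) "male" else "female"))
    expect_equal(rms(combine_talkers(clips, 0.1)$audio), 0.1,
                 tolerance = 0.001)
  })
})

test_that("combine_talkers enforces its preconditions", {
  w <- make_tone(220, 2, sr, amp = 0.3)
  m <- talker_clip(w, "m", "male"); f <- talker_clip(w, "f", "female")
  expect_error(combine_talkers(list(m)), "at least 2")
  expect_error(combine_talkers(list(m, m)), "unbalanced")
  f2 <- talker_clip(make_tone(220, 2, 16000, amp = 0.3), "f2", "female")
  expect_error(combine_talkers(list(m, f2)), "sample rates")
  expect_error(talker_clip(waveform(rnorm(100), sr), "x", "male"),
               "at least 1 s")
})
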