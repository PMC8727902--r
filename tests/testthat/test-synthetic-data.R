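# Synthetic study materials: corpus, cohort, assignments, waveforms.

test_that("the default corpus has 50 sentences of 5-9 distinct words", {
  co <- generate_corpus(seed = 5)
  lens <- vapply(co$sentences, length, integer(1))
  expect_length(co$sentences, 50)
  expect_true(all(lens >= 5 & lens <= 9))
  expect_true(all(vapply(co$sentences, anyDuplicated, integer(1)) == 0))
  expect_identical(generate_corpus(seed = 5)$sentences, co$sentences)
  expect_false(identical(generate_corpus(seed = 6)$sentences, co$sentences))
})

test_that("corpus respects forced lengths and vocabulary bounds", {
  one <- generate_corpus(n = 1, min_len = 5, max_len = 5, seed = 1)
  expect_length(one$sentences, 1)
  expect_length(one$sentences[[1]], 5)
  expect_error(generate_corpus(vocab = letters[1:4]), "too small")
})

test_that("the default cohort is 5 PD + 5 HC with PD-only handicaps", {
  ch <- generate_cohort(seed = 3)
  expect_equal(nrow(ch), 10)
  expect_equal(sum(ch$group == "PD"), 5)
  expect_equal(sum(ch$group == "HC"), 5)
  expect_true(all(ch$intelligibility_offset[ch$group == "HC"] == 0))
  expect_true(all(ch$intelligibility_offset[ch$group == "PD"] > 0))
  expect_true(all(is.na(ch$severity[ch$group == "HC"])))
  expect_true(all(ch$severity[ch$group == "PD"] %in% c("mild", "moderate")))
  expect_identical(generate_cohort(seed = 3), ch)
})

test_that("moderate severity implies a larger handicap than mild", {
  for (s in 1:5) {
    ch <- generate_cohort(seed = s)
    mild <- ch$intelligibility_offset[ch$severity %in% "mild"]
    mod <- ch$intelligibility_offset[ch$severity %in% "moderate"]
    if (length(mild) && length(mod)) expect_gt(min(mod), max(mild))
  }
})

test_that("a control-only cohort has all-zero offsets", {
  ch <- generate_cohort(n_pd = 0, n_hc = 4, seed = 1)
  expect_true(all(ch$intelligibility_offset == 0))
  expect_true(all(ch$group == "HC"))
})

test_that("sentence assignment is per-speaker distinct and deterministic", {
  co <- generate_corpus(seed = 2)
  ch <- generate_cohort(seed = 2)
  plan <- assign_sentences(ch, co, seed = 4)
  expect_equal(nrow(plan), 50)          # 10 speakers x 5 sentences
  by_spk <- split(plan$sentence_id, plan$speaker_id)
  expect_true(all(vapply(by_spk, function(x) !anyDuplicated(x), logical(1))))
  expect_identical(assign_sentences(ch, co, seed = 4), plan)
  expect_error(assign_sentences(ch, generate_corpus(n = 3, seed = 1),
                                per_speaker = 5), "too small")
})

test_that("every speaker can read the whole corpus if asked", {
  co <- generate_corpus(n = 6, seed = 1)
  ch <- generate_cohort(n_pd = 1, n_hc = 1, seed = 1)
  plan <- assign_sentences(ch, co, per_speaker = 6, seed = 1)
  expect_true(all(vapply(split(plan$sentence_id, plan$speaker_id),
                         function(x) setequal(x, co$ids), logical(1))))
})

test_that("utterance duration tracks word count at ~3 words/s", {
  s6 <- c("make", "the", "most", "of", "your", "time")
  w <- synthesize_utterance(s6, sample_rate = 16000, seed = 9)
  expect_equal(duration(w), 2, tolerance = 0.2)
  expect_gt(rms(w), 0)
  expect_identical(synthesize_utterance(s6, sample_rate = 16000, seed = 9)$samples,
                   w$samples)
  w9 <- synthesize_utterance(letters[1:9], sample_rate = 16000, seed = 9)
  expect_gt(duration(w9), duration(w))
  expect_error(synthesize_utterance(character(0)), "empty")
})

test_that("talker clips run 30 s by default and contain a prolonged pause", {
  cl <- generate_talker_clip(sex = "male", sample_rate = 8000, seed = 21)
  expect_equal(duration(cl$audio), 30, tolerance = 0.01)
  expect_equal(cl$sex, "male")
  trimmed <- trim_silences(cl$audio)
  expect_lt(duration(trimmed), duration(cl$audio))  # a >500 ms pause existed
})

test_that("male clips sit lower in pitch than female clips", {
  m <- generate_talker_clip(6, "male", 8000, seed = 31)
  f <- generate_talker_clip(6, "female", 8000, seed = 31)
  expect_lt(estimate_f0(m$audio), estimate_f0(f$audio))
  expect_lt(estimate_f0(m$audio), 160)
  expect_gt(estimate_f0(f$audio), 150)
})

test_that("clip generation is deterministic and validates duration", {
  a <- generate_talker_clip(3, "female", 8000, seed = 8)
  b <- generate_talker_clip(3, "female", 8000, seed = 8)
  expect_identical(a$audio$samples, b$audio$samples)
  expect_error(generate_talker_clip(0.5, "male"), "at least 1 s")
})
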