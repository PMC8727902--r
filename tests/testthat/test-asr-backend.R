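# Simulated recognizer: logistic error model, hint rescue, determinism.

quiet_rec <- function(rate = 48000, group = "HC") {
  mix_at_snr(make_tone(200, 0.5, rate), NULL, "clean", group = group)
}
noisy_rec <- function(snr, rate = 48000, group = "HC") {
  s <- make_tone(200, 0.5, rate)
  b <- withr::with_seed(1, waveform(0.1 * rnorm(2 * rate), rate))
  mix_at_snr(s, b, snr, group = group, seed = 2)
}

test_that("word_error_probability matches the logistic closed form", {
  p0 <- asr_params(base_logit = 0, snr_slope = 0, group_offset_pd = 0,
                   lowrate_offset = 0)
  expect_equal(word_error_probability(p0, 0), 0.5)
  expect_equal(word_error_probability(p0, 17), 0.5)   # slope 0: flat

  p1 <- asr_params(base_logit = 0, snr_slope = -0.2, group_offset_pd = 0,
                   lowrate_offset = 0)
  expect_equal(word_error_probability(p1, 10), plogis(-2))
  expect_equal(word_error_probability(p1, "clean"), plogis(-0.2 * 30))
})

test_that("error probability is monotone in SNR and ordered by group", {
  p <- asr_params()
  probs <- vapply(c(0, 5, 10, 15, 20, 30),
                  function(s) word_error_probability(p, s), numeric(1))
  expect_true(all(diff(probs) < 0))
  for (s in c(0, 10, 20))
    expect_gt(word_error_probability(p, s, "PD"),
              word_error_probability(p, s, "HC"))
  expect_gt(word_error_probability(p, 10, rate = 8000),
            word_error_probability(p, 10, rate = 48000))
})

test_that("hints never increase the effective error probability", {
  p <- asr_params(hint_factor = 0.4)
  for (s in c(0, 5, 10))
    expect_lt(word_error_probability(p, s, hints = TRUE),
              word_error_probability(p, s, hints = FALSE))
  p_nohelp <- asr_params(hint_factor = 1)
  expect_equal(word_error_probability(p_nohelp, 5, hints = TRUE),
               word_error_probability(p_nohelp, 5, hints = FALSE))
})

test_that("asr_params validates its fields", {
  expect_error(asr_params(hint_factor = 0), "hint_factor")
  expect_error(asr_params(hint_factor = 1.2), "hint_factor")
  expect_error(asr_params(sub_del_ins_split = c(0.5, 0.5, 0.5)), "summing")
  expect_error(asr_params(base_logit = NA), "finite")
})

test_that("an error-free backend returns the truth exactly", {
  p <- asr_params(base_logit = -50, snr_slope = 0, group_offset_pd = 0,
                  lowrate_offset = 0)
  truth <- c("make", "the", "most", "of", "your", "time")
  res <- transcribe(quiet_rec(), truth, p, seed = 3)
  expect_identical(res$hypothesis, truth)
})

test_that("an all-deletion backend at p = 1 returns an empty hypothesis", {
  p <- asr_params(base_logit = 50, snr_slope = 0, group_offset_pd = 0,
                  lowrate_offset = 0, sub_del_ins_split = c(0, 1, 0))
  res <- transcribe(quiet_rec(), c("one", "two", "three"), p, seed = 4)
  expect_length(res$hypothesis, 0)
})

test_that("a fixed seed gives a bit-identical hypothesis", {
  p <- asr_params()
  truth <- c("make", "the", "most", "of", "your", "time")
  rec <- noisy_rec(0)
  r1 <- transcribe(rec, truth, p, seed = 77)
  r2 <- transcribe(rec, truth, p, seed = 77)
  r3 <- transcribe(rec, truth, p, seed = 78)
  expect_identical(r1$hypothesis, r2$hypothesis)
  expect_false(identical(r1$hypothesis, r3$hypothesis))
})

test_that("substitution-only corruption at p = 0.2 scores near 80%", {
  p <- asr_params(base_logit = qlogis(0.2), snr_slope = 0,
                  group_offset_pd = 0, lowrate_offset = 0,
                  sub_del_ins_split = c(1, 0, 0))
  vocab <- default_vocab()
  rec <- quiet_rec()
  withr::with_seed(10, {
    accs <- vapply(1:300, function(i) {
      truth <- sample(vocab, 6)
      res <- transcribe(rec, truth, p, seed = i)
      accuracy(res$hypothesis, truth)$value
    }, numeric(1))
  })
  expect_equal(mean(accs), 80, tolerance = 2.5 / 80)  # ~2.5 points MC slack
})

test_that("hints rescue substitutions of hinted words only", {
  p <- asr_params(base_logit = 3, snr_slope = 0, group_offset_pd = 0,
                  lowrate_offset = 0, hint_factor = 0.01,
                  sub_del_ins_split = c(1, 0, 0))
  truth <- c("make", "the", "most", "of", "your", "time")
  rec <- quiet_rec()
  # with near-total rescue the hinted transcript is almost always perfect
  n_ok <- sum(vapply(1:50, function(i)
    identical(transcribe(rec, truth, p, hints = TRUE, seed = i)$hypothesis,
              truth), logical(1)))
  expect_gt(n_ok, 40)
  # without hints, p ~ 0.95 substitution: essentially never perfect
  n_ok0 <- sum(vapply(1:50, function(i)
    identical(transcribe(rec, truth, p, seed = i)$hypothesis, truth),
    logical(1)))
  expect_lt(n_ok0, 3)
  # a hint list not covering the truth gives no rescue
  res <- transcribe(rec, truth, p, hints = c("zebra"), seed = 1)
  resn <- transcribe(rec, truth, p, hints = NULL, seed = 1)
  expect_identical(res$hypothesis, resn$hypothesis)
})

test_that("transcribe rejects empty truth and bad params", {
  expect_error(transcribe(quiet_rec(), character(0), asr_params()), "empty")
})
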