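#' Parameters of the simulated recognizer's error model
#'
#' The simulated backend generates transcription errors from recording
#' provenance rather than acoustics. A per-word error probability is a
#' logistic function of SNR with additive logit offsets, and errors are
#' partitioned into substitutions, deletions and insertions:
#'
#' \deqn{p = \mathrm{logistic}(b + m \cdot \mathrm{SNR} + o_{PD} + o_{8k} + o_{spk})}
#'
#' Phrase hints rescue a fraction of would-be substitutions: with hints the
#' substitution probability is multiplied by `hint_factor` (deletions and
#' insertions are unaffected — hints help avoid word confusions, not
#' dropouts).
#'
#' Defaults are chosen so the model reproduces the qualitative pattern of
#' cloud-recognizer behaviour on dysarthric and healthy speech: accuracy
#' near ceiling in quiet, a decline beginning around 10 dB SNR that reaches
#' roughly a 40-point drop at 0 dB, markedly worse recognition of 8 kHz
#' audio, a constant logit handicap for parkinsonian speech whose
#' probability-scale effect only emerges at low SNR, and a substantial
#' hinting benefit.
#'
#' @param base_logit Intercept: logit of the per-word error probability at
#'   0 dB SNR for a healthy speaker at 48 kHz.
#' @param snr_slope Change in logit per dB of SNR (negative: fewer errors as
#'   SNR rises).
#' @param group_offset_pd Added logit for speakers with Parkinson's disease.
#' @param lowrate_offset Added logit when the audio sample rate is below
#'   16 kHz.
#' @param hint_factor Multiplier in (0, 1\] on the substitution probability
#'   when phrase hints cover the word.
#' @param sub_del_ins_split Three non-negative weights summing to 1 that
#'   partition errors into substitutions, deletions and insertions.
#' @param clean_snr_db Effective SNR assigned to the noise-free condition.
#' @return An object of class `asr_params`.
#' @export
asr_params <- function(base_logit = -0.4, snr_slope = -0.25,
                       group_offset_pd = 1.0, lowrate_offset = 5.5,
                       hint_factor = 0.5,
                       sub_del_ins_split = c(sub = 0.7, del = 0.2, ins = 0.1),
                       clean_snr_db = 30) {
  if (!(hint_factor > 0 && hint_factor <= 1))
    stop("'hint_factor' must lie in (0, 1]")
  if (length(sub_del_ins_split) != 3L || any(sub_del_ins_split < 0) ||
      abs(sum(sub_del_ins_split) - 1) > 1e-8)
    stop("'sub_del_ins_split' must be 3 non-negative weights summing to 1")
  for (nm in c("base_logit", "snr_slope", "group_offset_pd",
               "lowrate_offset", "clean_snr_db")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v)) stop("'", nm, "' must be a finite scalar")
  }
  names(sub_del_ins_split) <- c("sub", "del", "ins")
  structure(list(base_logit = base_logit, snr_slope = snr_slope,
                 group_offset_pd = group_offset_pd,
                 lowrate_offset = lowrate_offset, hint_factor = hint_factor,
                 sub_del_ins_split = sub_del_ins_split,
                 clean_snr_db = clean_snr_db),
            class = "asr_params")
}

#' @export
print.asr_params <- function(x, ...) {
  cat("<asr_params>\n")
  cat(sprintf("  logit(p_err) = %g %+g*SNR %+g*[PD] %+g*[<16 kHz]\n",
              x$base_logit, x$snr_slope, x$group_offset_pd, x$lowrate_offset))
  cat(sprintf("  split sub/del/ins = %g/%g/%g, hint factor %g, clean = %g dB\n",
              x$sub_del_ins_split[1], x$sub_del_ins_split[2],
              x$sub_del_ins_split[3], x$hint_factor, x$clean_snr_db))
  invisible(x)
}

#' Per-word error probability of the simulated recognizer
#'
#' Evaluates the logistic error model at a given condition. With
#' `hints = TRUE` the returned value is the effective probability that a
#' truth word ends up wrong after hint rescue, i.e.
#' `p * (1 - w_sub * (1 - hint_factor))`.
#'
#' @param params An [asr_params()] object.
#' @param snr_db SNR in dB, or `"clean"` (mapped to `params$clean_snr_db`).
#' @param group `"PD"` or `"HC"`.
#' @param rate Audio sample rate in Hz; rates below 16 kHz incur
#'   `lowrate_offset`.
#' @param hints Whether phrase hints cover the words.
#' @param speaker_offset Additional per-speaker logit (speaker
#'   intelligibility handicap).
#' @return Probability in \[0, 1\].
#' @examples
#' p <- asr_params(base_logit = 0, snr_slope = -0.2, group_offset_pd = 0)
#' word_error_probability(p, snr_db = 10)  # logistic(-2)
#' @export
word_error_probability <- function(params, snr_db, group = c("HC", "PD"),
                                   rate = 48000, hints = FALSE,
                                   speaker_offset = 0) {
  stopifnot(inherits(params, "asr_params"))
  group <- match.arg(group)
  snr <- if (identical(snr_db, "clean")) params$clean_snr_db else snr_db
  if (!is.numeric(snr) || !is.finite(snr)) stop("invalid 'snr_db'")
  lgt <- params$base_logit + params$snr_slope * snr +
    (group == "PD") * params$group_offset_pd +
    (rate < 16000) * params$lowrate_offset + speaker_offset
  p <- stats::plogis(lgt)
  if (isTRUE(hints))
    p <- p * (1 - params$sub_del_ins_split["sub"] * (1 - params$hint_factor))
  unname(p)
}

#' Simulated transcription of a mixed recording
#'
#' The simulated backend implementing the recognizer contract
#' (audio + optional phrase hints -> hypothesis transcript). It reads the
#' recording's provenance (SNR, speaker group, sample rate), computes the
#' per-word error probability from `params`, and corrupts the ground-truth
#' transcript: each truth word is independently kept, substituted with a
#' vocabulary word (uniform, excluding the truth word), or deleted
#' according to the error split; insertions are drawn once per inter-word
#' gap. If `hints` is supplied, substitution of a hinted word happens with
#' probability scaled by `hint_factor`. The output is bit-identical for a
#' fixed seed.
#'
#' An adapter slot for a real cloud recognizer exists in the contract but
#' no network backend ships with the package.
#'
#' @param rec A [mix_at_snr()] result.
#' @param truth Ground-truth transcript: character vector of tokens (a raw
#'   string is normalized first).
#' @param params An [asr_params()] object.
#' @param hints `NULL` (no hinting), `TRUE` (hint every word), or a
#'   character vector of hinted words.
#' @param seed Integer seed; fixes the hypothesis exactly.
#' @param vocab Vocabulary for substitutions and insertions.
#' @param speaker_offset Per-speaker logit handicap (0 for healthy
#'   controls).
#' @return An object of class `asr_result` with elements `hypothesis`
#'   (character vector), `backend_id`, `hints_used`.
#' @export
transcribe <- function(rec, truth, params, hints = NULL, seed = 1L,
                       vocab = default_vocab(), speaker_offset = 0) {
  stopifnot(inherits(rec, "mixed_recording"), inherits(params, "asr_params"))
  if (is.character(truth) && length(truth) == 1L && grepl("\\s", truth))
    truth <- normalize_text(truth)
  truth <- as.character(truth)
  if (length(truth) == 0L) stop("empty ground-truth transcript")

  rate <- rec$audio$sample_rate
  group <- if (identical(rec$group, "PD")) "PD" else "HC"
  p <- word_error_probability(params, rec$target_snr_db, group, rate,
                              hints = FALSE, speaker_offset = speaker_offset)
  w <- params$sub_del_ins_split
  hinted <- if (is.null(hints)) rep(FALSE, length(truth))
            else if (isTRUE(hints)) rep(TRUE, length(truth))
            else truth %in% hints

  p_sub <- p * w["sub"] * ifelse(hinted, params$hint_factor, 1)
  p_del <- rep(p * w["del"], length(truth))
  p_ins <- p * w["ins"]

  hyp <- withr::with_seed(seed, {
    u <- stats::runif(length(truth))
    fate <- ifelse(u < p_sub, "sub",
                   ifelse(u < p_sub + p_del, "del", "keep"))
    words <- character(0)
    for (i in seq_along(truth)) {
      if (stats::runif(1) < p_ins)                       # gap before word i
        words <- c(words, sample(vocab, 1L))
      words <- c(words, switch(fate[i],
        keep = truth[i],
        del  = character(0),
        sub  = {
          pool <- setdiff(vocab, truth[i])
          if (length(pool) == 0L) truth[i] else sample(pool, 1L)
        }))
    }
    if (stats::runif(1) < p_ins) words <- c(words, sample(vocab, 1L))
    words
  })
  structure(list(hypothesis = hyp, backend_id = "simulated",
                 hints_used = !is.null(hints)),
            class = "asr_result")
}

#' @export
print.asr_result <- function(x, ...) {
  cat(sprintf("<asr_result [%s]%s: \"%s\">\n", x$backend_id,
              if (x$hints_used) " +hints" else "",
              paste(x$hypothesis, collapse = " ")))
  invisible(x)
}
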