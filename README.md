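# asrnoise

Reproducible speech-recognition intelligibility experiments in
multi-talker babble noise, with a simulated ASR backend.

## What this is for

Clinical speech researchers measure how well automatic speech recognition
(ASR) decodes read sentences in background noise — in particular for
speakers with dysarthria secondary to Parkinson's disease (PD), whose
intelligibility suffers most in noisy, multi-talker settings. The standard
protocol: record sentences, build an N-talker babble masker from
single-talker clips, mix speech and babble at controlled signal-to-noise
ratios (SNRs), transcribe with and without *phrase hints* (a word list that
biases the recognizer), score word accuracy against ground truth, and
compare groups with Kruskal–Wallis tests.

`asrnoise` implements every stage of that protocol as testable R code. A
synthetic-data module generates the study materials (sentence corpus,
PD/control cohort, speech-like waveforms, talker clips), and the
recognizer is a *simulated* backend with a controllable logistic error
model — worse at low SNR, worse at 8 kHz, worse for PD speech, helped by
hints — so the full experiment runs end to end with no cloud service and
no human recordings.

## The core metric

A hypothesis `S` is scored against the ground truth `T` as

```
f(S, T) = 100/L * |largest order-preserving set of equal-word pairs|,
L = max(|S|, |T|)
```

i.e. the word-level longest common subsequence normalized by the padded
common length: words that appear in both transcripts but out of order
score nothing, and extra hypothesis words dilute the score. Per-word error
probability in the simulated backend is
`logistic(b + m*SNR + o_PD + o_8k + o_speaker)`, with errors split into
substitutions / deletions / insertions and hints multiplying the
substitution probability by a factor in (0, 1].

## Worked example

```r
library(asrnoise)

cfg <- experiment_config(seed = 7, n_sentences = 10, per_speaker = 2,
                         clip_duration_s = 6, noise_rate = 16000,
                         sample_rates = c(16000, 8000),
                         snr_grid_db = c(Inf, 10, 0))
ex <- run_experiment(cfg)
accuracy_by_snr(ex)
#>   snr_db hints_mode      mean  n
#> 3  clean     corpus 100.00000 20
#> 2     10     corpus  88.13492 20
#> 1      0     corpus  62.12897 20
#> 6  clean       none 100.00000 20
#> 5     10       none  81.85913 20
#> 4      0       none  39.47222 20
```

Accuracy is at ceiling in quiet, declines by 10 dB SNR, and collapses at
0 dB; hinting (`corpus` mode) recovers ~23 points at 0 dB. The contrasts
show the characteristic group structure — PD vs control separates only in
the hardest condition, and narrow-band (8 kHz) audio is significantly
worse in quiet:

```r
subset(ex$contrasts, significant)
#>            family     condition h_statistic df      p_value significant
#>      downsampling 8000 vs 16000   23.893742  1 1.018022e-06        TRUE
#>    group_no_hints         snr 0    9.422449  1 2.143451e-03        TRUE
#>     hints_vs_none         snr 0    6.087823  1 1.361167e-02        TRUE
#>  group_with_hints         snr 0    4.194095  1 4.056499e-02        TRUE
```

`run_experiment(cfg, out_dir = "out")` additionally writes `results.csv`
(long format: one row per utterance × condition), `summary.json` and a
Markdown report; two runs of one config are byte-identical. Individual
stages are exported too: `generate_talker_clip()`, `trim_silences()`,
`equalize_spectrum()`, `combine_talkers()`, `mix_at_snr()`,
`transcribe()`, `accuracy()`, `kruskal_wallis()`, plus WAV I/O
(`read_wav()`/`write_wav()`, 16-bit PCM mono) and band-limited
`resample()`. A thin command-line wrapper lives at
`inst/scripts/run_experiment.R`.

See `vignettes/intelligibility-in-noise.Rmd` for the model, parameter
defaults and design choices.

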