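# Independent oracles used by the unit and acceptance tests. These stay
# deliberately separate from the package's implementation paths.

# --- scoring oracle: exhaustive monotone-alignment enumeration ------------
# All subsequences of the shorter transcript, tried largest-first against
# the longer one; the best order-preserving match size falls out without
# any dynamic programming.

.subset_cache <- new.env(parent = emptyenv())

subsets_by_size <- function(n) {
  key <- as.character(n)
  if (!is.null(.subset_cache[[key]])) return(.subset_cache[[key]])
  out <- list()
  for (k in seq(n, 1)) {
    cm <- utils::combn(n, k)
    out <- c(out, lapply(seq_len(ncol(cm)), function(j) cm[, j]))
  }
  .subset_cache[[key]] <- out
  out
}

is_subsequence <- function(a, b) {
  i <- 1L
  for (x in b) {
    if (i <= length(a) && a[i] == x) i <- i + 1L
  }
  i > length(a)
}

brute_force_accuracy <- function(s, t) {
  L <- max(length(s), length(t))
  if (L == 0L) return(list(value = 100, matched = 0L))
  a <- if (length(s) <= length(t)) s else t   # enumerate the shorter
  b <- if (length(s) <= length(t)) t else s
  best <- 0L
  if (length(a) > 0L) {
    for (idx in subsets_by_size(length(a))) {
      if (is_subsequence(a[idx], b)) { best <- length(idx); break }
    }
  }
  list(value = 100 * best / L, matched = best)
}

# --- Kruskal-Wallis hand formula (no ties) --------------------------------
kw_hand <- function(groups) {
  x <- unlist(groups)
  r <- rank(x)
  N <- length(x)
  idx <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  rbar <- tapply(r, idx, mean)
  n <- tapply(r, idx, length)
  12 / (N * (N + 1)) * sum(n * rbar^2) - 3 * (N + 1)
}

# --- pitch estimate: median autocorrelation peak over energetic frames ----
estimate_f0 <- function(w, fmin = 70, fmax = 300) {
  sr <- w$sample_rate
  flen <- round(0.04 * sr)
  starts <- seq(1, length(w$samples) - flen, by = flen)
  lag_min <- floor(sr / fmax); lag_max <- ceiling(sr / fmin)
  f0s <- c()
  peak <- max(abs(w$samples))
  for (s in starts) {
    seg <- w$samples[s:(s + flen - 1)]
    if (sqrt(mean(seg^2)) < 0.1 * peak) next
    ac <- stats::acf(seg, lag.max = lag_max, plot = FALSE)$acf[-1]
    lag <- which.max(ac[lag_min:lag_max]) + lag_min - 1
    f0s <- c(f0s, sr / lag)
  }
  stats::median(f0s)
}

# --- small signal builders ------------------------------------------------
make_tone <- function(freq, dur_s, sr, amp = 0.5) {
  waveform(amp * sin(2 * pi * freq * (0:(round(dur_s * sr) - 1)) / sr), sr)
}

make_pink <- function(dur_s, sr, seed = 1) {
  # 1/f magnitude shaping of white noise in the frequency domain
  withr::with_seed(seed, {
    n <- round(dur_s * sr)
    X <- stats::fft(stats::rnorm(n))
    f <- c(1, seq_len(n - 1))
    f <- pmin(f, n - f + 1)            # symmetric shaping
    x <- Re(stats::fft(X / sqrt(f), inverse = TRUE)) / n
    waveform(0.3 * x / max(abs(x)), sr)
  })
}

# mean band power (dB) over equal-width bands, from the output spectrum
band_levels_db <- function(w, n_bands = 8, f_lo = 150, f_hi = 3500) {
  n <- length(w$samples)
  psd <- Mod(stats::fft(w$samples))^2
  freq <- (0:(n - 1)) * w$sample_rate / n
  edges <- seq(f_lo, f_hi, length.out = n_bands + 1)
  vapply(seq_len(n_bands), function(b) {
    sel <- freq >= edges[b] & freq < edges[b + 1]
    10 * log10(mean(psd[sel]))
  }, numeric(1))
}

# random transcripts over a small alphabet so matches actually occur
random_transcript <- function(max_len = 8, alphabet = letters[1:5]) {
  n <- sample(0:max_len, 1)
  if (n == 0) character(0) else sample(alphabet, n, replace = TRUE)
}

# compact experiment config reused across pipeline tests
small_config <- function(seed = 11, ...) {
  experiment_config(seed = seed, n_sentences = 10, per_speaker = 2,
                    clip_duration_s = 6, noise_rate = 16000,
                    sample_rates = c(16000, 8000),
                    snr_grid_db = c(Inf, 10, 0), ...)
}
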