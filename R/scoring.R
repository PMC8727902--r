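#' Normalize raw text into a word-token transcript
#'
#' Lowercases, strips punctuation, and splits on whitespace. Recognizer
#' output is typically cased and punctuated; scoring works on bare word
#' tokens.
#'
#' @param raw A character string (or vector of strings, concatenated in
#'   order).
#' @return Character vector of lowercase tokens; empty input gives
#'   `character(0)`.
#' @examples
#' normalize_text("Make the most of your time")
#' @export
normalize_text <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  s <- tolower(paste(raw, collapse = " "))
  s <- gsub("[^a-z0-9 ]+", "", s)
  toks <- strsplit(trimws(gsub("\\s+", " ", s)), " ", fixed = TRUE)[[1]]
  toks[nzchar(toks)]
}

# word-level longest common subsequence length, O(|s| * |t|)
.lcs_length <- function(s, t) {
  ns <- length(s); nt <- length(t)
  if (ns == 0L || nt == 0L) return(0L)
  prev <- integer(nt + 1L)
  for (i in seq_len(ns)) {
    cur <- integer(nt + 1L)
    match_i <- s[i] == t
    for (j in seq_len(nt)) {
      cur[j + 1L] <- if (match_i[j]) prev[j] + 1L
                     else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[nt + 1L]
}

#' Word-matching accuracy under the best order-preserving alignment
#'
#' Scores a hypothesis transcript `s` against a ground-truth transcript
#' `t` as the percentage of words matched by the largest order-preserving
#' set of equal-word pairs (the word-level longest common subsequence),
#' normalized by the padded common length `L = max(|s|, |t|)` — the shorter
#' transcript is conceptually padded with blanks that can never match.
#' Words present in both transcripts but out of order therefore contribute
#' at most once, and extra hypothesis words dilute the score through `L`.
#'
#' Two empty transcripts score 100 (vacuously perfect).
#'
#' @param s Hypothesis transcript: character vector of tokens (raw strings
#'   are normalized via [normalize_text()]).
#' @param t Ground-truth transcript, same forms accepted.
#' @return An object of class `accuracy_score` with fields `value`
#'   (percentage in \[0, 100\]), `matched` (aligned equal words) and
#'   `length` (the padded common length `L`).
#' @examples
#' accuracy(c("make", "most", "of", "time"),
#'          c("make", "the", "most", "of", "your", "time"))  # 66.67
#' accuracy(c("time", "your"), c("your", "time"))            # 50
#' @export
accuracy <- function(s, t) {
  needs_norm <- function(x) is.character(x) && length(x) == 1L &&
    grepl("[[:space:][:punct:][:upper:]]", x)
  if (needs_norm(s)) s <- normalize_text(s)
  if (needs_norm(t)) t <- normalize_text(t)
  s <- as.character(s); t <- as.character(t)
  L <- max(length(s), length(t))
  if (L == 0L)
    return(structure(list(value = 100, matched = 0L, length = 0L),
                     class = "accuracy_score"))
  m <- .lcs_length(s, t)
  structure(list(value = 100 * m / L, matched = m, length = L),
            class = "accuracy_score")
}

#' @export
print.accuracy_score <- function(x, ...) {
  cat(sprintf("accuracy: %.2f%% (%d/%d words matched)\n",
              x$value, x$matched, x$length))
  invisible(x)
}

#' Score many hypothesis/reference pairs
#'
#' Convenience wrapper: normalizes and scores parallel vectors of raw
#' hypothesis and reference strings.
#'
#' @param hyp,ref Character vectors of equal length.
#' @return Numeric vector of accuracy percentages.
#' @export
score_transcripts <- function(hyp, ref) {
  if (length(hyp) != length(ref)) stop("'hyp' and 'ref' lengths differ")
  vapply(seq_along(hyp), function(i)
    accuracy(normalize_text(hyp[i]), normalize_text(ref[i]))$value,
    numeric(1))
}
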