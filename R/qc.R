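# Sequence-complexity reports over denoised output: windowed DUST score and
# trinucleotide block entropy, both on a 0-100 scale. High DUST / low
# entropy flags low-complexity (repeat-dominated) sequence.

.tri_counts <- function(win) {
  l <- nchar(win) - 2L
  if (l < 1L) stop("window too short for trinucleotides")
  words <- substring(win, 1:l, 3:(l + 2L))
  table(words)
}

.windows_of <- function(seq, window) {
  n <- nchar(seq)
  if (n <= window) return(data.frame(start = 0L, end = n))
  starts <- seq(0L, n - 1L, by = window)
  data.frame(start = starts, end = pmin(starts + window, n))
}

#' Windowed DUST low-complexity score
#'
#' Counts overlapping trinucleotide words in consecutive windows (default
#' 64 bases, last window truncated; sequences shorter than one window give a
#' single truncated window) and scores each window by
#' `100 * sum_i n_i (n_i - 1) / (l (l - 1))`, where `n_i` is the occurrence
#' count of word `i` among the `l = window - 2` words. A window that repeats
#' a single word scores 100; a window of all-distinct words scores 0. The
#' unscaled sum is reported too.
#'
#' @param seq DNA string.
#' @param window window width in bases (>= 3); default 64.
#' @return data frame with columns `start` (0-based), `end` (half-open),
#'   `score` (0-100) and `raw` (unscaled sum).
#' @export
dust_score <- function(seq, window = 64L) {
  stopifnot(window >= 3L)
  w <- .windows_of(seq, window)
  res <- lapply(seq_len(nrow(w)), function(r) {
    win <- substring(seq, w$start[r] + 1L, w$end[r])
    n_i <- as.numeric(.tri_counts(win))
    l <- sum(n_i)
    raw <- sum(n_i * (n_i - 1))
    score <- if (l > 1) 100 * raw / (l * (l - 1)) else 0
    c(score = score, raw = raw)
  })
  cbind(w, do.call(rbind, res))
}

#' Windowed trinucleotide block entropy
#'
#' Shannon diversity of the trinucleotide words in each window, with the
#' logarithm taken base `4^3` (the word-alphabet size) and scaled by 100:
#' `-100 * sum_i (n_i / l) log_64(n_i / l)`. A single repeated word gives 0;
#' more diverse windows score higher (a window of `l` distinct words scores
#' `100 * log_64(l)`).
#'
#' @inheritParams dust_score
#' @return data frame with columns `start`, `end`, `entropy` (0-100 scale).
#' @export
block_entropy <- function(seq, window = 64L) {
  stopifnot(window >= 3L)
  w <- .windows_of(seq, window)
  ent <- vapply(seq_len(nrow(w)), function(r) {
    win <- substring(seq, w$start[r] + 1L, w$end[r])
    n_i <- as.numeric(.tri_counts(win))
    p <- n_i / sum(n_i)
    100 * -sum(p * log(p, base = 64))
  }, 0)
  cbind(w, entropy = ent)
}

#' Complexity report for a read set
#'
#' @param reads a [read_set()].
#' @param window window width; default 64.
#' @return data frame keyed by read id and 0-based window start, with DUST
#'   score and block entropy per window.
#' @export
complexity_report <- function(reads, window = 64L) {
  stopifnot(inherits(reads, "data.frame"))
  out <- lapply(seq_len(nrow(reads)), function(r) {
    d <- dust_score(reads$bases[r], window)
    e <- block_entropy(reads$bases[r], window)
    data.frame(id = reads$id[r], start = d$start, end = d$end,
               dust = d$score, entropy = e$entropy,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
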