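# Two-pass sliding-window denoising over double-sided contexts.
#
# Pass 1 aggregates, over ALL reads of a run, the statistics vector m: for
# every double-sided context (k symbols left, k symbols right) the counts of
# the center symbol. Pass 2 replaces each eligible interior symbol z_i by
#
#   argmin_xhat  m^T Pi^{-1} (lambda_xhat . pi_{z_i})
#
# where pi_z is column z of the channel, lambda_xhat column xhat of the loss,
# and "." the elementwise product. The same machinery serves the 4-letter
# base alphabet and the 10-letter homopolymer-length alphabet.

#' Construct a read set
#'
#' A light container for reads: parallel vectors of ids, base strings over
#' `{A,C,G,T,N}`, and optional Phred quality strings (Sanger, Phred+33) of
#' matching length.
#'
#' @param id character vector of read identifiers.
#' @param bases character vector of base strings.
#' @param quals optional character vector of Phred+33 quality strings, or
#'   `NULL` when qualities are absent (FASTA input).
#' @return a data frame of class `read_set` with columns `id`, `bases` and
#'   `quals` (`NA` when absent).
#' @export
read_set <- function(id, bases, quals = NULL) {
  id <- as.character(id)
  bases <- toupper(as.character(bases))
  stopifnot(length(id) == length(bases))
  if (length(bases) && any(grepl("[^ACGTN]", bases)))
    stop("bases must be over {A,C,G,T,N}")
  if (is.null(quals)) {
    quals <- rep(NA_character_, length(id))
  } else {
    quals <- as.character(quals)
    stopifnot(length(quals) == length(id))
    bad <- which(!is.na(quals) & nchar(quals) != nchar(bases))
    if (length(bad))
      stop("quality length differs from sequence length for record '",
           id[bad[1L]], "'")
  }
  structure(data.frame(id = id, bases = bases, quals = quals,
                       stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set with", nrow(x), "reads",
      if (all(is.na(x$quals))) "(no qualities)" else "(with qualities)", "\n")
  if (nrow(x)) {
    show <- utils::head(x, 3L)
    for (i in seq_len(nrow(show)))
      cat(sprintf("  %s  %s%s\n", show$id[i],
                  substr(show$bases[i], 1, 40),
                  if (nchar(show$bases[i]) > 40) "..." else ""))
    if (nrow(x) > 3L) cat("  ...\n")
  }
  invisible(x)
}

#' Phred+33 helpers
#'
#' @param q character vector of Phred+33 quality strings.
#' @return `phred_to_int` gives a list of integer vectors; `int_to_phred`
#'   the inverse.
#' @keywords internal
phred_to_int <- function(q) {
  lapply(q, function(s) {
    if (is.na(s)) return(integer(0))
    utf8ToInt(s) - 33L
  })
}

int_to_phred <- function(qs) {
  vapply(qs, function(v) intToUtf8(v + 33L), "")
}

# Enumerate interior window components for one alphabet-agnostic symbol
# vector; used by both counting and denoising passes. Returns NULL when the
# sequence is shorter than the window.
.windows_chr <- function(s, k) {
  n <- nchar(s)
  if (n < 2L * k + 1L) return(NULL)
  i <- (k + 1L):(n - k)
  list(i = i,
       left = substring(s, i - k, i - 1L),
       center = substring(s, i, i),
       right = substring(s, i + 1L, i + k),
       window = substring(s, i - k, i + k))
}

#' Aggregate double-sided context counts over a read set
#'
#' First pass of the denoiser: every interior position `i`
#' (`k+1 <= i <= n-k`, 1-based) whose full `2k+1` window is free of `N`
#' increments the count of its center symbol under the context formed by the
#' `k` symbols on each side. Counts are pooled across all reads — deep
#' amplicon coverage is what makes the per-context statistics informative.
#' Reads shorter than `2k+1` contribute nothing.
#'
#' @param reads a [read_set()] (or anything with a `bases` character column).
#' @param k context half-width, a positive integer.
#' @return an object of class `context_counts`: list with `k`, `alphabet`,
#'   and `counts`, a matrix with one row per observed context (rownames
#'   `"LEFT|RIGHT"`) and one column per alphabet symbol.
#' @export
collect_context_counts <- function(reads, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  bases <- if (is.data.frame(reads)) reads$bases else as.character(reads)
  if (length(bases) == 0L) stop("reads must be nonempty")
  .collect_counts(bases, k, DNA_BASES)
}

.collect_counts <- function(seqs, k, alphabet) {
  ctx <- character(0)
  cen <- character(0)
  for (s in seqs) {
    w <- .windows_chr(s, k)
    if (is.null(w)) next
    keep <- !grepl("N", w$window, fixed = TRUE)
    if (!any(keep)) next
    ctx <- c(ctx, paste(w$left[keep], w$right[keep], sep = "|"))
    cen <- c(cen, w$center[keep])
  }
  if (length(ctx) == 0L) {
    counts <- matrix(0L, 0L, length(alphabet),
                     dimnames = list(NULL, alphabet))
  } else {
    tab <- table(factor(ctx), factor(cen, levels = alphabet))
    counts <- matrix(as.integer(tab), nrow(tab), length(alphabet),
                     dimnames = list(rownames(tab), alphabet))
  }
  structure(list(k = k, alphabet = alphabet, counts = counts),
            class = "context_counts")
}

#' @export
print.context_counts <- function(x, ...) {
  cat("context_counts: k =", x$k, "|", nrow(x$counts), "contexts,",
      sum(x$counts), "counted positions over alphabet {",
      paste(x$alphabet, collapse = ","), "}\n")
  invisible(x)
}

#' Denoise a single symbol from its context statistics
#'
#' The per-position decision rule: given the aggregated count vector `m_vec`
#' of center symbols seen under this double-sided context, the observed
#' center symbol `z`, the channel `Pi` and the loss `Lambda`, return
#' `argmin_xhat m^T Pi^{-1} (lambda_xhat . pi_z)`. The product
#' `pi_z . Pi^{-T} m` estimates the count vector of the underlying clean
#' symbol, so the rule minimizes expected loss against a channel-inverted
#' estimate rather than doing majority voting on `m` directly. Negative
#' entries arising from the inversion are used as-is. Ties break toward the
#' first symbol in alphabet order (A < C < G < T).
#'
#' @param m_vec nonnegative count 4-vector ordered (A, C, G, T).
#' @param z observed center base, one of `"A","C","G","T"`.
#' @param Pi a [confusion_matrix()].
#' @param Lambda 4x4 loss matrix; default [hamming_loss()].
#' @return the reconstructed base, a length-1 character.
#' @export
denoise_symbol <- function(m_vec, z, Pi, Lambda = hamming_loss(4L)) {
  stopifnot(length(m_vec) == 4L, all(m_vec >= 0))
  zi <- match(z, DNA_BASES)
  if (is.na(zi)) stop("z must be one of A, C, G, T")
  Lambda <- .check_loss(Lambda, 4L)
  idx <- .dude_rule_single(as.numeric(m_vec), zi, unclass(Pi), Lambda)
  DNA_BASES[idx]
}

# scalar rule shared by both alphabets; returns 1-based index into alphabet
.dude_rule_single <- function(m, zi, Pi, Lambda) {
  Pi_inv <- solve(Pi)
  scores <- vapply(seq_len(ncol(Pi)), function(xh) {
    sum(m * (Pi_inv %*% (Lambda[, xh] * Pi[, zi])))
  }, 0)
  .argmin_tol(scores)
}

# first index within tolerance of the minimum: mathematical ties (equal
# counts under a symmetric channel) must break toward the first symbol
# regardless of floating-point summation order
.argmin_tol <- function(scores, tol = 1e-9) {
  lo <- min(scores)
  which(scores <= lo + tol * (1 + abs(lo)))[1L]
}

# Precompute, for a counts matrix M (contexts x alphabet), the decision table
# D (contexts x alphabet): D[c, z] = argmin_xhat M[c,]^T Pi^{-1}
# (Lambda[,xhat] * Pi[,z]). Per-position work in pass 2 is then a table
# lookup, keeping the whole run linear in the number of bases.
.decision_table <- function(counts, Pi, Lambda) {
  A <- ncol(Pi)
  Pi_inv <- solve(Pi)
  dec <- matrix(NA_integer_, nrow(counts), A)
  for (z in seq_len(A)) {
    W <- Pi_inv %*% (Lambda * Pi[, z])   # col xhat = Pi^{-1}(lambda_xhat.pi_z)
    S <- counts %*% W                    # contexts x xhat scores
    lo <- do.call(pmin, as.data.frame(S))
    thr <- lo + 1e-9 * (1 + abs(lo))
    dec[, z] <- max.col(1 * (S <= thr), ties.method = "first")
  }
  rownames(dec) <- rownames(counts)
  dec
}

#' Denoise substitution errors across a read set
#'
#' The full two-pass procedure: aggregate context counts over all reads
#' (unless `counts` is supplied), then rewrite each read position-by-position
#' with [denoise_symbol()]'s rule. Read ids, lengths, order and qualities are
#' preserved. Positions copied verbatim: the `k` boundary positions at each
#' end, positions whose `2k+1` window contains an `N`, and — when
#' `quality_threshold` is given — positions whose Phred score exceeds the
#' threshold (high-confidence calls are left alone; only low-quality bases
#' are revisited). With no threshold every eligible interior position is
#' denoised. Forward and reverse reads should be passed in separate calls.
#'
#' @inheritParams denoise_symbol
#' @param reads a [read_set()].
#' @param k context half-width; default 5.
#' @param quality_threshold optional numeric; positions with Phred quality
#'   strictly greater than this are not modified.
#' @param counts optional precomputed [collect_context_counts()] over the
#'   same reads (both passes must see identical data).
#' @return a [read_set()] of the same shape with corrected bases, plus an
#'   attribute `denoise_stats` (positions denoised / gated / boundary).
#' @export
denoise_reads <- function(reads, Pi, Lambda = hamming_loss(4L), k = 5L,
                          quality_threshold = NULL, counts = NULL) {
  stopifnot(inherits(reads, "data.frame"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  Pi <- confusion_matrix(Pi)
  Lambda <- .check_loss(Lambda, 4L)
  if (is.null(counts)) counts <- collect_context_counts(reads, k)
  stopifnot(inherits(counts, "context_counts"), counts$k == k)

  dec <- .decision_table(counts$counts, unclass(Pi), Lambda)
  ctx_index <- stats::setNames(seq_len(nrow(dec)), rownames(dec))
  quals <- if (!is.null(quality_threshold)) phred_to_int(reads$quals)

  out <- reads$bases
  n_denoised <- 0L; n_gated <- 0L; n_changed <- 0L
  for (r in seq_along(out)) {
    w <- .windows_chr(out[r], k)
    if (is.null(w)) next
    eligible <- !grepl("N", w$window, fixed = TRUE)
    if (!is.null(quality_threshold) && length(quals[[r]])) {
      q_ok <- quals[[r]][w$i] <= quality_threshold
      n_gated <- n_gated + sum(eligible & !q_ok)
      eligible <- eligible & q_ok
    }
    if (!any(eligible)) next
    ci <- ctx_index[paste(w$left[eligible], w$right[eligible], sep = "|")]
    if (anyNA(ci)) {           # context unseen in pass 1: leave untouched
      eligible[eligible] <- !is.na(ci)
      ci <- ci[!is.na(ci)]
      if (!length(ci)) next
    }
    zi <- match(w$center[eligible], counts$alphabet)
    xhat <- counts$alphabet[dec[cbind(ci, zi)]]
    n_denoised <- n_denoised + length(xhat)
    changed <- xhat != w$center[eligible]
    if (any(changed)) {
      n_changed <- n_changed + sum(changed)
      s <- strsplit(out[r], "", fixed = TRUE)[[1L]]
      s[w$i[eligible][changed]] <- xhat[changed]
      out[r] <- paste(s, collapse = "")
    }
  }
  res <- read_set(reads$id, out,
                  if (all(is.na(reads$quals))) NULL else reads$quals)
  attr(res, "denoise_stats") <- list(
    reads_in = nrow(reads), reads_out = nrow(res),
    positions_denoised = n_denoised, positions_gated = n_gated,
    positions_changed = n_changed)
  res
}
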