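# Evaluation statistics: per-base error rate, aligned-base gain, adjusted
# error rate and its relative gain, and the measure of concordance (MoC)
# between clusterings. A small deterministic global aligner (affine gaps,
# scores mirroring common short-read mapping defaults) serves as the oracle
# for counting aligned/mismatched bases on toy and synthetic data.

#' Global alignment statistics between two sequences
#'
#' Optimal global alignment under match +1, mismatch -4, gap open -6, gap
#' extension -1 (affine; a gap of length L costs 6 + L). Returns the counts
#' the error-rate metrics consume: `aligned_bases` = matched + mismatched
#' columns, `mismatched_bases` = substitutions + inserted + deleted bases.
#'
#' @param a,b nonempty DNA strings (`a` the reference, `b` the read).
#' @return a list with `aligned_bases`, `mismatched_bases`, `matches`,
#'   `substitutions`, `insertions`, `deletions`, `score` and the aligned
#'   strings `aligned_a`, `aligned_b`.
#' @export
global_align <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -4,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(b), Biostrings::DNAString(a),
    type = "global", substitutionMatrix = mat,
    gapOpening = 6, gapExtension = 1)
  pa <- as.character(Biostrings::alignedSubject(al))   # reference
  pb <- as.character(Biostrings::alignedPattern(al))   # read
  ca <- strsplit(pa, "", fixed = TRUE)[[1L]]
  cb <- strsplit(pb, "", fixed = TRUE)[[1L]]
  gap_a <- ca == "-"
  gap_b <- cb == "-"
  matches <- sum(!gap_a & !gap_b & ca == cb)
  subs <- sum(!gap_a & !gap_b & ca != cb)
  ins <- sum(gap_a)      # base present in read, absent in reference
  del <- sum(gap_b)
  list(aligned_bases = matches + subs,
       mismatched_bases = subs + ins + del,
       matches = matches, substitutions = subs,
       insertions = ins, deletions = del,
       score = Biostrings::score(al),
       aligned_a = pa, aligned_b = pb)
}

#' Alignment statistics of a read set against stored truth
#'
#' For synthetic data the truth sequence travels with each read, so counting
#' needs no aligner when lengths match (column-wise comparison); otherwise
#' [global_align()] is used. Totals are pooled over all reads.
#'
#' @param reads a [read_set()].
#' @param truth data frame with columns `id` and `true_bases` (e.g. the
#'   `truth` attribute from the simulator).
#' @return a list with pooled `aligned_bases` and `mismatched_bases`.
#' @export
alignment_stats <- function(reads, truth) {
  stopifnot(inherits(reads, "data.frame"))
  tb <- truth$true_bases[match(reads$id, truth$id)]
  if (anyNA(tb)) stop("truth is missing reads: ",
                      reads$id[which(is.na(tb))[1L]])
  aligned <- 0; mism <- 0
  for (r in seq_len(nrow(reads))) {
    x <- tb[r]; y <- reads$bases[r]
    if (nchar(x) == nchar(y)) {
      aligned <- aligned + nchar(x)
      mism <- mism + sum(strsplit(x, "", fixed = TRUE)[[1L]] !=
                           strsplit(y, "", fixed = TRUE)[[1L]])
    } else {
      st <- global_align(x, y)
      aligned <- aligned + st$aligned_bases
      mism <- mism + st$mismatched_bases
    }
  }
  list(aligned_bases = aligned, mismatched_bases = mism)
}

#' Per-base error rate
#'
#' `mismatched / aligned`: erroneous bases (substitutions, insertions,
#' deletions) over mapped bases (matches + mismatches). Because indels count
#' in the numerator but not the denominator the ratio can exceed 1 in
#' pathological cases; such rates are flagged with a warning and returned
#' as computed.
#'
#' @param stats a list with `aligned_bases` and `mismatched_bases`.
#' @return the error rate.
#' @export
error_rate <- function(stats) {
  if (stats$aligned_bases == 0) stop("no aligned bases")
  e <- stats$mismatched_bases / stats$aligned_bases
  if (e > 1) warning("error rate exceeds 1 (indel-dominated alignment)")
  e
}

#' Relative gain of aligned bases
#'
#' `(aligned_tool - aligned_raw) / aligned_raw`: how many more bases align
#' after denoising than before, relative to raw.
#'
#' @param aligned_tool,aligned_raw aligned-base counts after/before
#'   denoising.
#' @export
aligned_gain <- function(aligned_tool, aligned_raw) {
  if (aligned_raw == 0) stop("no aligned bases in raw data")
  (aligned_tool - aligned_raw) / aligned_raw
}

#' Adjusted error rate
#'
#' `(1 + g) * e_tool - g * e_raw`: a weighted blend that penalizes a
#' denoiser whose apparent error rate drops only because fewer bases align.
#'
#' @param e_tool,e_raw error rates after/before denoising.
#' @param g relative aligned-base gain from [aligned_gain()].
#' @export
adjusted_error_rate <- function(e_tool, e_raw, g) {
  (1 + g) * e_tool - g * e_raw
}

#' Relative gain of the adjusted error rate over raw
#'
#' `(e_raw - e_hat) / e_raw`: 0 when denoising changes nothing, 1 when it
#' removes every error.
#'
#' @param e_raw raw error rate.
#' @param e_hat adjusted error rate of the tool.
#' @export
adjusted_gain <- function(e_raw, e_hat) {
  if (e_raw == 0) stop("raw error rate is 0")
  (e_raw - e_hat) / e_raw
}

#' Measure of concordance between two clusterings
#'
#' For partitions `P` (I clusters) and `Q` (J clusters) of the same objects,
#' with `f_ij` the overlap between cluster `P_i` and `Q_j` and `p_i`, `q_j`
#' the cluster sizes:
#' `MoC = (sum_ij f_ij^2 / (p_i q_j) - 1) / (sqrt(I J) - 1)`.
#' 1 means identical partitions, 0 no concordance. The degenerate case
#' `I = J = 1` (both partitions trivial, hence identical) is defined as 1.
#'
#' @param P,Q [cluster_assignment()]s (or data frames with `id`, `cluster`)
#'   over the same set of ids.
#' @return the concordance, in `[0, 1]`.
#' @export
moc <- function(P, Q) {
  if (!setequal(P$id, Q$id) || nrow(P) != nrow(Q))
    stop("clusterings must cover the same read ids")
  qc <- Q$cluster[match(P$id, Q$id)]
  f <- table(P$cluster, qc)
  I <- nrow(f); J <- ncol(f)
  if (I == 1L && J == 1L) return(1)
  p <- rowSums(f); q <- colSums(f)
  s <- sum(f^2 / outer(p, q))
  (s - 1) / (sqrt(I * J) - 1)
}

#' Summarize denoising performance against raw data
#'
#' Pools alignment statistics for raw and denoised reads against the stored
#' truth and reports the full metric set.
#'
#' @param raw,denoised [read_set()]s of the same reads before/after
#'   denoising.
#' @param truth truth table (`id`, `true_bases`).
#' @return a data frame with one row per quantity (`error_rate_raw`,
#'   `error_rate_tool`, `aligned_gain`, `adjusted_error_rate`,
#'   `adjusted_gain`).
#' @export
evaluate_denoising <- function(raw, denoised, truth) {
  s_raw <- alignment_stats(raw, truth)
  s_tool <- alignment_stats(denoised, truth)
  e_raw <- error_rate(s_raw)
  e_tool <- error_rate(s_tool)
  g <- aligned_gain(s_tool$aligned_bases, s_raw$aligned_bases)
  e_hat <- adjusted_error_rate(e_tool, e_raw, g)
  data.frame(
    metric = c("error_rate_raw", "error_rate_tool", "aligned_gain",
               "adjusted_error_rate", "adjusted_gain"),
    value = c(e_raw, e_tool, g, e_hat, adjusted_gain(e_raw, e_hat)),
    stringsAsFactors = FALSE)
}
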