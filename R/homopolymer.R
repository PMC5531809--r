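# Homopolymer indel correction on flowgrams.
#
# Pyrosequencing flows bases in a fixed cycle (default T, A, C, G); each flow
# reports a light intensity roughly proportional to the homopolymer run
# length of that base. Standard base calling rounds intensities to integers,
# and rounding mistakes become insertions/deletions. Here the intensities are
# quantized to {0..9}, the quantizer + intensity densities induce a virtual
# 10x10 channel Gamma, and the same two-pass context rule used for
# substitutions is applied over the integer alphabet before the corrected
# sequence is rebuilt from the flow cycle.

#' Construct a flowgram set
#'
#' @param id character vector of read identifiers.
#' @param intensities list of nonnegative numeric vectors, one per read.
#' @param flow_order the cyclic base order of the instrument; default
#'   `c("T","A","C","G")`, so flow `i` interrogates
#'   `flow_order[(i - 1) %% 4 + 1]`.
#' @return an object of class `flowgram_set`.
#' @export
flowgram_set <- function(id, intensities, flow_order = c("T", "A", "C", "G")) {
  id <- as.character(id)
  stopifnot(is.list(intensities), length(id) == length(intensities))
  flow_order <- toupper(as.character(flow_order))
  if (!identical(sort(flow_order), sort(DNA_BASES)))
    stop("flow_order must be a permutation of A, C, G, T")
  for (j in seq_along(intensities)) {
    f <- intensities[[j]]
    if (!is.numeric(f) || anyNA(f) || any(f < 0))
      stop("negative or missing intensity in flowgram '", id[j], "'")
  }
  structure(list(id = id, intensities = lapply(intensities, as.numeric),
                 flow_order = flow_order),
            class = "flowgram_set")
}

#' @export
print.flowgram_set <- function(x, ...) {
  cat("flowgram_set with", length(x$id), "flowgrams, flow order",
      paste(x$flow_order, collapse = ""), "\n")
  invisible(x)
}

#' @export
length.flowgram_set <- function(x) length(x$id)

.flow_base <- function(i, flow_order) flow_order[(i - 1L) %% 4L + 1L]

#' Round flow intensities to homopolymer lengths
#'
#' The scalar quantizer `Q(f) = argmin_{i in 0..9} |i - f|`: ordinary
#' rounding saturated at the alphabet bound, so every intensity at or above
#' 9.5 maps to 9. Half-integer ties round up, matching round-half-up base
#' callers.
#'
#' @param f numeric vector of nonnegative intensities.
#' @param max_length alphabet bound (default 9).
#' @return integer vector in `0..max_length`.
#' @examples
#' quantize_flow(c(0.03, 1.03, 0.09, 0.12, 1.89, 0.09, 0.09, 1.01))
#' @export
quantize_flow <- function(f, max_length = 9L) {
  if (any(f < 0)) stop("flow intensities must be nonnegative")
  pmin(as.integer(floor(f + 0.5)), as.integer(max_length))
}

#' Aggregate context counts over quantized flowgrams
#'
#' First pass of the homopolymer denoiser: the same counting contract as
#' [collect_context_counts()], but over the 10-symbol integer alphabet of
#' quantized run lengths, pooled across all flowgrams of a run.
#'
#' @param qflows list of integer vectors in `0..9` (quantized flowgrams).
#' @param k context half-width, a positive integer (default 2).
#' @return a `context_counts` object over alphabet `"0".."9"`.
#' @export
collect_flow_counts <- function(qflows, k = 2L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  stopifnot(is.list(qflows))
  seqs <- vapply(qflows, function(v) paste(v, collapse = ""), "")
  .collect_counts(seqs, k, as.character(FLOW_LENGTHS))
}

#' Denoise one quantized flowgram against aggregated statistics
#'
#' Second pass for a single flowgram: boundary positions (`i <= k` or
#' `i >= n-k+1`) keep their quantized value; each interior position is
#' replaced by `argmin_xhat m^T Gamma^{-1} (lambda_xhat . gamma_z)` over the
#' ten candidate lengths, with ties broken toward the smaller length
#' (conservative: fewer inserted bases).
#'
#' @param qflow integer vector in `0..9`.
#' @param counts `context_counts` from [collect_flow_counts()] over the same
#'   flow set.
#' @param Gamma a [virtual_dmc()].
#' @param Lambda 10x10 loss matrix; default [hamming_loss()].
#' @param k context half-width (must match `counts$k`).
#' @return integer vector of corrected lengths, same length as `qflow`.
#' @export
denoise_flowgram <- function(qflow, counts, Gamma, Lambda = hamming_loss(10L),
                             k = 2L) {
  Gamma <- virtual_dmc(Gamma)
  Lambda <- .check_loss(Lambda, nrow(Gamma))
  stopifnot(inherits(counts, "context_counts"), counts$k == k)
  dec <- .decision_table(counts$counts, unclass(Gamma), Lambda)
  .denoise_qflow(qflow, dec, counts, k)
}

.denoise_qflow <- function(qflow, dec, counts, k) {
  n <- length(qflow)
  out <- as.integer(qflow)
  if (n < 2L * k + 1L) return(out)
  s <- paste(qflow, collapse = "")
  w <- .windows_chr(s, k)
  ci <- match(paste(w$left, w$right, sep = "|"), rownames(dec))
  zi <- match(w$center, counts$alphabet)
  ok <- !is.na(ci)
  out[w$i[ok]] <- FLOW_LENGTHS[dec[cbind(ci[ok], zi[ok])]]
  out
}

#' Rebuild a DNA sequence from corrected homopolymer lengths
#'
#' Emits, for each flow `i`, the flowed base repeated `lengths[i]` times
#' (zeros contribute nothing). The output length is `sum(lengths)` and need
#' not equal the flow count.
#'
#' @param lengths integer vector of run lengths in `0..9`.
#' @param flow_order cyclic base order; default `c("T","A","C","G")`.
#' @return a DNA string.
#' @examples
#' reconstruct_sequence(c(0, 1, 0, 0, 2, 0, 0, 1))  # "ATTG"
#' @export
reconstruct_sequence <- function(lengths, flow_order = c("T", "A", "C", "G")) {
  if (length(lengths) == 0L) return("")
  stopifnot(all(lengths >= 0), all(lengths <= 9))
  bases <- .flow_base(seq_along(lengths), flow_order)
  paste(strrep(bases, as.integer(lengths)), collapse = "")
}

#' Correct homopolymer errors across a flowgram set
#'
#' The end-to-end pipeline: derive the virtual channel from the intensity
#' model ([build_virtual_dmc()]), quantize every flowgram
#' ([quantize_flow()]), pool context counts over the whole set
#' ([collect_flow_counts()]), denoise each flowgram against the pooled
#' statistics, and rebuild the corrected DNA sequence from the flow cycle.
#' One output record per input flowgram, order preserved.
#'
#' @param flows a [flowgram_set()].
#' @param model a [flow_density_model()] describing `P(f | N)` for the
#'   instrument; alternatively supply a precomputed `Gamma`.
#' @param k context half-width; default 2 (the 10-letter alphabet makes
#'   larger contexts expensive and sparse).
#' @param Gamma optional precomputed [virtual_dmc()]; overrides `model`.
#' @param Lambda 10x10 loss matrix; default [hamming_loss()].
#' @return a [read_set()] (no qualities) of corrected sequences, with the
#'   corrected length vectors in attribute `corrected_lengths`.
#' @export
denoise_flowgram_set <- function(flows, model = flow_density_model(),
                                 k = 2L, Gamma = NULL,
                                 Lambda = hamming_loss(10L)) {
  stopifnot(inherits(flows, "flowgram_set"))
  if (is.null(Gamma)) Gamma <- build_virtual_dmc(model)
  Gamma <- virtual_dmc(Gamma)
  Lambda <- .check_loss(Lambda, nrow(Gamma))
  k <- as.integer(k)
  qflows <- lapply(flows$intensities, quantize_flow)
  counts <- collect_flow_counts(qflows, k)
  dec <- .decision_table(counts$counts, unclass(Gamma), Lambda)
  corrected <- lapply(qflows, .denoise_qflow, dec = dec, counts = counts,
                      k = k)
  seqs <- vapply(corrected, reconstruct_sequence, "",
                 flow_order = flows$flow_order)
  out <- read_set(flows$id, seqs)
  attr(out, "corrected_lengths") <- corrected
  out
}

#' Naive flowgram base calling
#'
#' The uncorrected baseline: quantize each intensity and rebuild the
#' sequence directly, with no context statistics.
#'
#' @param flows a [flowgram_set()].
#' @return a [read_set()] of naively called sequences.
#' @export
naive_base_call <- function(flows) {
  stopifnot(inherits(flows, "flowgram_set"))
  seqs <- vapply(flows$intensities, function(f)
    reconstruct_sequence(quantize_flow(f), flows$flow_order), "")
  read_set(flows$id, seqs)
}
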