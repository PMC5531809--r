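# Ground-truthed synthetic data: reference amplicons, community mixtures,
# memoryless substitution corruption (optionally with a linear position
# error ramp), and flowgrams drawn from an intensity model. Every corrupted
# record keeps its truth alongside, so evaluation never needs an aligner.

#' Generate random reference amplicons
#'
#' i.i.d.-uniform DNA strings; reproducible under `set.seed()`.
#'
#' @param n_refs number of references.
#' @param ref_length length of each reference, in bases.
#' @return a [read_set()] with ids `ref1, ref2, ...`.
#' @export
generate_references <- function(n_refs, ref_length) {
  n_refs <- as.integer(n_refs)
  if (n_refs == 0L) return(read_set(character(0), character(0)))
  seqs <- vapply(seq_len(n_refs), function(i)
    paste(sample(DNA_BASES, ref_length, replace = TRUE), collapse = ""), "")
  read_set(paste0("ref", seq_len(n_refs)), seqs)
}

#' Log-series community weights
#'
#' Default uneven mixing proportions spanning two orders of magnitude
#' between the most and least abundant member, the kind of skew seen in
#' mock microbial communities.
#'
#' @param n number of community members.
#' @return numeric weights summing to 1, decreasing.
#' @export
uneven_proportions <- function(n) {
  if (n == 1L) return(1)
  w <- 10^(-seq(0, 2, length.out = n))
  w / sum(w)
}

#' Sample reads from a reference community
#'
#' Draws each read's source reference according to `proportions` and takes
#' the forward substring of length `read_length`. Amplicon reads are
#' primer-anchored — every read of an amplicon starts at the same (primer)
#' position — so the default start offset is 1 for all reads; set
#' `offsets = "uniform"` for shotgun-style random starts. The returned set
#' records the truth (source reference, offset, true sequence) as a `truth`
#' attribute.
#'
#' @param refs a [read_set()] of references.
#' @param n_reads number of reads to sample.
#' @param read_length read length (must not exceed the reference length).
#' @param proportions mixing weights over references; default even.
#' @param offsets `"primer"` (all reads start at position 1, the amplicon
#'   convention) or `"uniform"` (random start positions).
#' @return a [read_set()] with attribute `truth`, a data frame with columns
#'   `id`, `ref`, `offset` (1-based) and `true_bases`.
#' @export
sample_reads <- function(refs, n_reads, read_length,
                         proportions = NULL,
                         offsets = c("primer", "uniform")) {
  stopifnot(inherits(refs, "data.frame"), nrow(refs) >= 1L)
  offsets <- match.arg(offsets)
  if (is.null(proportions)) proportions <- rep(1 / nrow(refs), nrow(refs))
  stopifnot(length(proportions) == nrow(refs),
            abs(sum(proportions) - 1) < 1e-8)
  ref_len <- nchar(refs$bases)
  if (any(read_length > ref_len)) stop("read_length exceeds reference length")
  src <- sample.int(nrow(refs), n_reads, replace = TRUE, prob = proportions)
  off <- if (offsets == "primer") rep(1L, n_reads) else
    1L + floor(stats::runif(n_reads) * (ref_len[src] - read_length + 1L))
  seqs <- substring(refs$bases[src], off, off + read_length - 1L)
  out <- read_set(sprintf("read%d", seq_len(n_reads)), seqs)
  attr(out, "truth") <- data.frame(
    id = out$id, ref = refs$id[src], offset = as.integer(off),
    true_bases = seqs, stringsAsFactors = FALSE)
  out
}

#' Corrupt reads through a memoryless substitution channel
#'
#' Each base is replaced independently by a draw from its row of `Pi`.
#' Alternatively, with `error_start`/`error_end` given, a position-dependent
#' ramp emulates Illumina-style degradation: at relative position `p` in a
#' read the channel is `(1 - a_p) I + a_p E`, where `a_p` interpolates
#' linearly from `error_start` (first base) to `error_end` (last base) and
#' `E` spreads errors uniformly over the three other bases.
#'
#' @param reads a [read_set()].
#' @param Pi a [confusion_matrix()]; ignored when a ramp is given.
#' @param error_start,error_end optional per-base error probabilities at the
#'   first/last read position (linear interpolation between them).
#' @return a [read_set()] of corrupted reads; the input's `truth` attribute,
#'   if any, is carried over (with `true_bases` from the input bases).
#' @export
corrupt_dmc <- function(reads, Pi = NULL, error_start = NULL,
                        error_end = NULL) {
  stopifnot(inherits(reads, "data.frame"))
  ramp <- !is.null(error_start) || !is.null(error_end)
  if (ramp) stopifnot(!is.null(error_start), !is.null(error_end),
                      error_start >= 0, error_end >= 0,
                      error_start <= 1, error_end <= 1)
  if (!ramp) Pi <- confusion_matrix(Pi)
  lens <- nchar(reads$bases)
  chars <- strsplit(reads$bases, "", fixed = TRUE)
  x <- unlist(chars, use.names = FALSE)
  xi <- match(x, DNA_BASES)          # NA for N: passed through untouched
  z <- x
  ok <- !is.na(xi)
  if (any(ok)) {
    if (ramp) {
      pos <- unlist(lapply(lens, function(n)
        if (n == 1L) 0.5 else (seq_len(n) - 1) / (n - 1)), use.names = FALSE)
      alpha <- error_start + (error_end - error_start) * pos[ok]
      err <- stats::runif(sum(ok)) < alpha
      zi <- xi[ok]
      if (any(err)) {
        shift <- sample.int(3L, sum(err), replace = TRUE)
        zi[err] <- ((zi[err] - 1L + shift) %% 4L) + 1L
      }
    } else {
      cum <- t(apply(unclass(Pi), 1L, cumsum))
      u <- stats::runif(sum(ok))
      zi <- max.col(cum[xi[ok], , drop = FALSE] >= u, ties.method = "first")
    }
    z[ok] <- DNA_BASES[zi]
  }
  seqs <- vapply(split(z, rep.int(seq_along(lens), lens)),
                 paste, "", collapse = "")
  out <- read_set(reads$id, unname(seqs),
                  if (all(is.na(reads$quals))) NULL else reads$quals)
  truth <- attr(reads, "truth")
  if (is.null(truth))
    truth <- data.frame(id = reads$id, ref = NA_character_,
                        offset = NA_integer_, true_bases = reads$bases,
                        stringsAsFactors = FALSE)
  attr(out, "truth") <- truth
  out
}

#' Generate flowgrams from true sequences
#'
#' Computes each read's true homopolymer run lengths against the cyclic flow
#' order (runs longer than 9 are rejected — outside the channel alphabet),
#' then draws every flow intensity from `P(f | N)` of the supplied model:
#' truncated-normal around `N` for incorporated flows and the model's
#' zero-length density for empty flows.
#'
#' @param reads a [read_set()] over `{A,C,G,T}`.
#' @param model a [flow_density_model()].
#' @param flow_order cyclic base order; default `c("T","A","C","G")`.
#' @return a [flowgram_set()] with attribute `true_lengths`, the list of
#'   noise-free run-length vectors.
#' @export
generate_flowgrams <- function(reads, model = flow_density_model(),
                               flow_order = c("T", "A", "C", "G")) {
  stopifnot(inherits(reads, "data.frame"),
            inherits(model, "flow_density_model"))
  true_lengths <- lapply(seq_len(nrow(reads)), function(r) {
    tryCatch(flow_lengths(reads$bases[r], flow_order, model$max_length),
             error = function(e)
               stop("read '", reads$id[r], "': ", conditionMessage(e),
                    call. = FALSE))
  })
  intens <- lapply(true_lengths, function(N) .draw_intensities(N, model))
  out <- flowgram_set(reads$id, intens, flow_order)
  attr(out, "true_lengths") <- true_lengths
  out
}

#' True flow run lengths of a sequence
#'
#' The inverse of [reconstruct_sequence()]: walk the sequence's homopolymer
#' runs against the cyclic flow order, emitting zero for every flow whose
#' base is not next in the sequence.
#'
#' @param seq DNA string over `{A,C,G,T}`.
#' @param flow_order cyclic base order.
#' @param max_length longest representable run (error beyond it).
#' @return integer vector of run lengths, one per flow.
#' @export
flow_lengths <- function(seq, flow_order = c("T", "A", "C", "G"),
                         max_length = 9L) {
  if (grepl("[^ACGT]", seq)) stop("sequence must be over {A,C,G,T}")
  runs <- rle(strsplit(seq, "", fixed = TRUE)[[1L]])
  if (any(runs$lengths > max_length))
    stop("homopolymer run longer than ", max_length)
  lens <- integer(0)
  pos <- 1L
  for (j in seq_along(runs$values)) {
    while (.flow_base(pos, flow_order) != runs$values[j]) {
      lens[pos] <- 0L
      pos <- pos + 1L
    }
    lens[pos] <- runs$lengths[j]
    pos <- pos + 1L
  }
  lens
}

.draw_intensities <- function(N, model) {
  f <- numeric(length(N))
  zero <- N == 0L
  if (model$family == "truncated_normal") {
    if (any(zero)) f[zero] <- stats::rexp(sum(zero), rate = model$zero_rate)
    if (any(!zero)) {
      mu <- N[!zero]
      s <- model$sigma0 + model$sigma1 * mu
      # inverse-CDF draw from the normal truncated to [0, Inf)
      lo <- stats::pnorm(0, mu, s)
      u <- lo + stats::runif(length(mu)) * (1 - lo)
      f[!zero] <- stats::qnorm(u, mu, s)
    }
  } else {
    # generic rejection sampling against the model density
    for (i in seq_along(N)) f[i] <- .reject_draw(model, N[i])
  }
  pmax(f, 0)
}

.reject_draw <- function(model, n) {
  # envelope: uniform over [0, max_length + 3] scaled to the density peak
  grid <- seq(0, model$max_length + 3, by = 0.01)
  dmax <- max(model$density(n, grid)) * 1.1
  repeat {
    x <- stats::runif(1, 0, model$max_length + 3)
    if (stats::runif(1, 0, dmax) <= model$density(n, x)) return(x)
  }
}

#' Simulate a ground-truthed amplicon dataset
#'
#' Convenience wrapper tying the pieces together: generate references, sample
#' a community of reads, and corrupt them through the chosen channel.
#'
#' @param n_refs,ref_length,n_reads,read_length community dimensions.
#' @param Pi substitution channel; default symmetric 1% error.
#' @param proportions mixing weights (default even); see
#'   [uneven_proportions()] for the skewed default.
#' @param error_start,error_end optional ramp endpoints (override `Pi`).
#' @param seed optional integer seed for full reproducibility.
#' @return a list with `refs`, `clean` (sampled reads + `truth` attribute)
#'   and `noisy` (corrupted reads + `truth` attribute).
#' @export
simulate_amplicon_data <- function(n_refs = 5L, ref_length = 250L,
                                   n_reads = 2000L, read_length = 100L,
                                   Pi = symmetric_confusion(0.01),
                                   proportions = NULL,
                                   error_start = NULL, error_end = NULL,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  refs <- generate_references(n_refs, ref_length)
  clean <- sample_reads(refs, n_reads, read_length, proportions)
  noisy <- corrupt_dmc(clean, Pi, error_start, error_end)
  list(refs = refs, clean = clean, noisy = noisy)
}

#' Write a simulated dataset's truth table
#'
#' TSV with columns `id`, `ref`, `offset`, `true_bases` so downstream
#' evaluation can proceed without re-alignment.
#'
#' @param reads a [read_set()] carrying a `truth` attribute.
#' @param path output path.
#' @export
write_truth_tsv <- function(reads, path) {
  truth <- attr(reads, "truth")
  if (is.null(truth)) stop("reads carry no truth attribute")
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
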