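#' DNA alphabet used throughout the package
#'
#' The fixed symbol order `A < C < G < T` used to index confusion-matrix
#' rows/columns, context-count vectors and argmin tie-breaks.
#' @keywords internal
DNA_BASES <- c("A", "C", "G", "T")

#' Homopolymer-length alphabet
#'
#' Quantized flowgram intensities live on `{0, ..., 9}`; runs longer than 9
#' are outside the model.
#' @keywords internal
FLOW_LENGTHS <- 0:9

.rcond_est <- function(m) {
  k <- tryCatch(kappa(m, exact = TRUE), error = function(e) Inf)
  if (!is.finite(k) || k <= 0) return(0)
  1 / k
}

#' Construct and validate a confusion matrix
#'
#' A confusion matrix (the discrete memoryless channel, DMC) holds the
#' conditional probabilities `P(noisy z | clean x)` over `{A,C,G,T}`: rows are
#' the clean symbol, columns the noisy symbol, and every row sums to 1. The
#' denoising rule inverts this matrix, so near-singular matrices are rejected.
#'
#' @param probs numeric 4x4 matrix of conditional probabilities, rows indexed
#'   by the clean base and columns by the noisy base, in the fixed order
#'   A, C, G, T.
#' @return the validated matrix with dimnames set to the base alphabet, of
#'   class `confusion_matrix`.
#' @examples
#' confusion_matrix(diag(4))
#' confusion_matrix(symmetric_confusion(0.01))
#' @export
confusion_matrix <- function(probs) {
  probs <- as.matrix(probs)
  if (!all(dim(probs) == c(4L, 4L)))
    stop("confusion matrix must be 4x4")
  .validate_stochastic(probs, tol = 1e-9, what = "confusion matrix")
  dimnames(probs) <- list(clean = DNA_BASES, noisy = DNA_BASES)
  structure(probs, class = c("confusion_matrix", "matrix", "array"))
}

.validate_stochastic <- function(m, tol, what) {
  if (any(m < -tol) || any(m > 1 + tol))
    stop(what, ": entries must lie in [0, 1]")
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol))
    stop(what, ": rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  if (.rcond_est(m) < 1e-10)
    stop(what, " not invertible")
  invisible(m)
}

#' Symmetric substitution channel
#'
#' Convenience constructor for the equal-error DMC in which each base is
#' miscalled with total probability `p`, spread uniformly over the three
#' other bases.
#'
#' @param p total per-base substitution probability, in `[0, 0.75)`.
#' @return a [confusion_matrix()].
#' @export
symmetric_confusion <- function(p) {
  stopifnot(p >= 0, p < 0.75)
  m <- matrix(p / 3, 4, 4)
  diag(m) <- 1 - p
  confusion_matrix(m)
}

#' Hamming loss matrix
#'
#' Zero on the diagonal, one off it: every miscall costs the same. This is the
#' loss under which the denoising rule reduces to picking the most plausible
#' clean symbol. Used for both the 4-letter substitution alphabet and the
#' 10-letter homopolymer-length alphabet.
#'
#' @param n alphabet size (4 for bases, 10 for homopolymer lengths).
#' @return an `n` x `n` 0/1 matrix.
#' @export
hamming_loss <- function(n = 4L) {
  m <- matrix(1, n, n)
  diag(m) <- 0
  m
}

.check_loss <- function(Lambda, n) {
  Lambda <- as.matrix(Lambda)
  if (!all(dim(Lambda) == c(n, n))) stop("loss matrix must be ", n, "x", n)
  if (any(Lambda < 0)) stop("loss matrix entries must be nonnegative")
  if (any(diag(Lambda) != 0)) stop("loss matrix diagonal must be 0")
  Lambda
}

#' Estimate a confusion matrix from aligned read/reference pairs
#'
#' Counts substitution columns in gap-free alignments of reads against their
#' references and normalizes per clean base: `probs[x, z] = n(x -> z) / n(x)`.
#' Columns containing `N` or a gap character (`-`) in either sequence are
#' skipped. Clean bases that never occur get an identity row (absent
#' evidence, the channel is assumed not to alter that base).
#'
#' @param pairs a list of length-2 character vectors (or a 2-column character
#'   matrix / data.frame) giving `(reference, read)` strings of equal length.
#' @return a [confusion_matrix()].
#' @examples
#' estimate_confusion(list(c("ACGT", "ACGT")))
#' @export
estimate_confusion <- function(pairs) {
  if (is.data.frame(pairs) || is.matrix(pairs))
    pairs <- lapply(seq_len(nrow(pairs)), function(i) as.character(pairs[i, 1:2]))
  if (length(pairs) == 0L) stop("no alignable columns")
  refs  <- toupper(vapply(pairs, `[`, "", 1L))
  reads <- toupper(vapply(pairs, `[`, "", 2L))
  if (any(nchar(refs) != nchar(reads)))
    stop("reference and read must have equal length in every pair")
  x <- unlist(strsplit(refs, "", fixed = TRUE), use.names = FALSE)
  z <- unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE)
  keep <- x %in% DNA_BASES & z %in% DNA_BASES
  if (!any(keep)) stop("no alignable columns")
  tab <- table(factor(x[keep], DNA_BASES), factor(z[keep], DNA_BASES))
  counts <- matrix(as.numeric(tab), 4, 4)
  n <- rowSums(counts)
  probs <- diag(4)
  for (i in which(n > 0)) probs[i, ] <- counts[i, ] / n[i]
  if (.rcond_est(probs) < 1e-10) stop("confusion matrix not invertible")
  confusion_matrix(probs)
}

#' Parametric conditional flowgram-intensity model
#'
#' The homopolymer channel is described by densities `P(f | N)`: the
#' distribution of the observed light intensity `f` given the true run length
#' `N` of the flowed base, for `N` in `0..9`. The default family is a normal
#' with mean `N` truncated to `[0, Inf)` whose spread grows linearly with the
#' run length, `sd(N) = sigma0 + sigma1 * N`, and an exponential for `N = 0`
#' (no incorporation, small residual signal). Any family can be plugged in by
#' supplying `density` directly.
#'
#' @param sigma0,sigma1 intercept and slope of the per-length standard
#'   deviation, in intensity units.
#' @param zero_rate rate of the exponential intensity density at `N = 0`.
#' @param density optional function `(N, f) -> density value`, vectorized in
#'   `f`, overriding the built-in family.
#' @param max_length largest representable run length (alphabet bound).
#' @return an object of class `flow_density_model`.
#' @export
flow_density_model <- function(sigma0 = 0.05, sigma1 = 0.03, zero_rate = 10,
                               density = NULL, max_length = 9L) {
  if (is.null(density)) {
    stopifnot(sigma0 > 0, sigma1 >= 0, zero_rate > 0)
    density <- function(N, f) {
      if (N == 0) return(stats::dexp(f, rate = zero_rate))
      s <- sigma0 + sigma1 * N
      out <- stats::dnorm(f, mean = N, sd = s) /
        stats::pnorm(0, mean = N, sd = s, lower.tail = FALSE)
      out[f < 0] <- 0
      out
    }
    family <- "truncated_normal"
  } else {
    family <- "custom"
  }
  structure(
    list(family = family, sigma0 = sigma0, sigma1 = sigma1,
         zero_rate = zero_rate, density = density,
         max_length = as.integer(max_length)),
    class = "flow_density_model")
}

#' @export
print.flow_density_model <- function(x, ...) {
  cat("Flowgram intensity model P(f | N), N in 0..", x$max_length, "\n",
      sep = "")
  if (x$family == "truncated_normal")
    cat(sprintf("  family: truncated normal, sd(N) = %g + %g N; N=0: Exp(%g)\n",
                x$sigma0, x$sigma1, x$zero_rate))
  else cat("  family: custom density\n")
  invisible(x)
}

#' Derive the virtual channel between run lengths and quantized intensities
#'
#' Rounding a noisy intensity to the nearest integer induces a discrete
#' memoryless channel between the true homopolymer length `i` and the
#' quantized length `j`: `Gamma(i, j)` is the mass of `P(f | i)` on the
#' quantizer cell of `j` — `[j - 0.5, j + 0.5)` for interior `j`,
#' `[0, 0.5)` for `j = 0`, and `[8.5, Inf)` for the saturated top symbol
#' `j = 9` (the quantizer maps every intensity at or above 8.5 to 9, so the
#' top bin is closed at infinity and rows remain stochastic).
#'
#' @param model a [flow_density_model()].
#' @param abs_tol absolute quadrature tolerance per cell.
#' @return a 10x10 row-stochastic matrix of class `virtual_dmc`.
#' @export
build_virtual_dmc <- function(model, abs_tol = 1e-8) {
  stopifnot(inherits(model, "flow_density_model"))
  nmax <- model$max_length
  nsym <- nmax + 1L
  G <- matrix(0, nsym, nsym)
  # piecewise adaptive quadrature with knots at the half-integer cell edges
  # AND the integers inside each cell: the densities peak at integer means,
  # and a peak at a panel endpoint is never missed by the adaptive rule,
  # while one in the middle of a wide panel can be when it is very narrow
  piece_int <- function(dens, lo, hi) {
    if (is.finite(hi)) {
      knots <- seq(lo, hi, by = 0.5)
    } else {
      knots <- seq(lo, nmax + 3, by = 0.5)
    }
    v <- sum(vapply(seq_len(length(knots) - 1L), function(p)
      stats::integrate(dens, knots[p], knots[p + 1L], abs.tol = abs_tol,
                       stop.on.error = FALSE)$value, 0))
    if (!is.finite(hi))
      v <- v + stats::integrate(dens, nmax + 3, Inf, abs.tol = abs_tol,
                                stop.on.error = FALSE)$value
    v
  }
  for (i in 0:nmax) {
    dens <- function(f) model$density(i, f)
    for (j in 0:nmax) {
      lo <- if (j == 0) 0 else j - 0.5
      hi <- if (j == nmax) Inf else j + 0.5
      G[i + 1L, j + 1L] <- piece_int(dens, lo, hi)
    }
    # the bins tile [0, Inf), so their sum is the numerical check that the
    # density is normalized
    total <- sum(G[i + 1L, ])
    if (!is.finite(total) || abs(total - 1) > 1e-6)
      stop("density for N = ", i, " does not integrate to 1 (got ",
           format(total), ")")
    # renormalize away residual quadrature error so rows are exactly stochastic
    G[i + 1L, ] <- pmax(G[i + 1L, ], 0)
    G[i + 1L, ] <- G[i + 1L, ] / total
  }
  virtual_dmc(G)
}

#' Construct and validate a virtual DMC over homopolymer lengths
#'
#' @param probs 10x10 row-stochastic matrix `Gamma(i, j)` over true length
#'   `i` and quantized length `j`, both in `0..9`.
#' @return the validated matrix, of class `virtual_dmc`.
#' @export
virtual_dmc <- function(probs) {
  probs <- as.matrix(probs)
  if (nrow(probs) != ncol(probs)) stop("virtual DMC must be square")
  .validate_stochastic(probs, tol = 1e-6, what = "virtual DMC")
  lab <- as.character(seq_len(nrow(probs)) - 1L)
  dimnames(probs) <- list(true = lab, quantized = lab)
  structure(probs, class = c("virtual_dmc", "matrix", "array"))
}

#' Diagnose a channel matrix
#'
#' Reports row-sum deviations and a reciprocal-condition estimate for a
#' square channel matrix, flagging matrices whose rows deviate from 1 by more
#' than `1e-6` or whose reciprocal condition estimate falls below `1e-10`
#' (treated as singular: the denoising rule needs the inverse).
#'
#' @param m square numeric matrix (confusion matrix or virtual DMC).
#' @return a list with `row_sum_dev` (per-row deviation from 1), `rcond`
#'   (reciprocal condition estimate), `singular` and `ok` flags.
#' @export
validate_channel <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("channel matrix must be square")
  dev <- abs(rowSums(m) - 1)
  rc <- .rcond_est(m)
  singular <- rc < 1e-10
  list(row_sum_dev = dev, rcond = rc, singular = singular,
       ok = !singular && all(dev <= 1e-6))
}

#' Read or write a confusion matrix as TSV
#'
#' The on-disk dialect is a 5x5 tab-separated table: the first row and column
#' carry the base labels `A C G T`, cells are conditional probabilities.
#' Values are written with 12 significant digits so a write/read round trip
#' reproduces the matrix to that precision.
#'
#' @param path file path (a `.gz` suffix is handled transparently).
#' @return `read_confusion_tsv` returns a [confusion_matrix()];
#'   `write_confusion_tsv` returns `path` invisibly.
#' @export
read_confusion_tsv <- function(path) {
  lines <- .read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) != 5L) stop("confusion matrix TSV must have 5 rows")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header[-1L], DNA_BASES))
    stop("confusion matrix TSV header must be A C G T")
  probs <- matrix(NA_real_, 4, 4)
  for (i in 1:4) {
    cells <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
    if (length(cells) != 5L || cells[1L] != DNA_BASES[i])
      stop("malformed confusion matrix row ", i + 1L)
    probs[i, ] <- as.numeric(cells[-1L])
  }
  if (anyNA(probs)) stop("non-numeric cell in confusion matrix TSV")
  confusion_matrix(probs)
}

#' @rdname read_confusion_tsv
#' @param m a [confusion_matrix()] (or plain 4x4 row-stochastic matrix).
#' @export
write_confusion_tsv <- function(m, path) {
  m <- confusion_matrix(m)
  con <- .open_text_out(path)
  on.exit(close(con))
  writeLines(paste(c("", DNA_BASES), collapse = "\t"), con)
  for (i in 1:4)
    writeLines(paste(c(DNA_BASES[i], sprintf("%.12g", m[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read or write a flow-density-model configuration
#'
#' A flat `key<TAB>value` text file naming the density family and its
#' parameters, so that the channel used for homopolymer correction is always
#' explicit and serializable.
#'
#' @param path file path.
#' @return `read_density_config` returns a [flow_density_model()];
#'   `write_density_config` returns `path` invisibly.
#' @export
read_density_config <- function(path) {
  lines <- .read_text_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad)) stop("malformed config line ", bad[1L])
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  if (!identical(unname(vals["family"]), "truncated_normal"))
    stop("unsupported density family: ", vals["family"])
  num <- function(key, default) {
    if (key %in% names(vals)) as.numeric(vals[[key]]) else default
  }
  flow_density_model(sigma0 = num("sigma0", 0.05),
                     sigma1 = num("sigma1", 0.03),
                     zero_rate = num("zero_rate", 10),
                     max_length = as.integer(num("max_length", 9)))
}

#' @rdname read_density_config
#' @param model a [flow_density_model()] of the built-in family.
#' @export
write_density_config <- function(model, path) {
  stopifnot(inherits(model, "flow_density_model"))
  if (model$family != "truncated_normal")
    stop("only the built-in family can be serialized")
  con <- .open_text_out(path)
  on.exit(close(con))
  writeLines(c(
    "family\ttruncated_normal",
    sprintf("sigma0\t%.12g", model$sigma0),
    sprintf("sigma1\t%.12g", model$sigma1),
    sprintf("zero_rate\t%.12g", model$zero_rate),
    sprintf("max_length\t%d", model$max_length)), con)
  invisible(path)
}
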