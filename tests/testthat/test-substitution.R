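test_that("context counting enumerates interior windows", {
  cc <- collect_context_counts(read_set("r1", "AAAAA"), k = 2)
  expect_equal(rownames(cc$counts), "AA|AA")
  expect_equal(cc$counts["AA|AA", ], c(A = 1L, C = 0L, G = 0L, T = 0L))

  cc <- collect_context_counts(read_set("r1", "ACGTA"), k = 1)
  expect_equal(sum(cc$counts), 3L)
  expect_equal(cc$counts["A|G", "C"], 1L)
  expect_equal(cc$counts["C|T", "G"], 1L)
  expect_equal(cc$counts["G|A", "T"], 1L)
})

test_that("windows touching N and short reads contribute nothing", {
  cc <- collect_context_counts(read_set("r1", "AANAA"), k = 1)
  expect_equal(sum(cc$counts), 0L)
  cc <- collect_context_counts(read_set(c("a", "b"), c("ACGT", "ACGTACGT")),
                               k = 2)
  expect_equal(sum(cc$counts), 4L)  # only the length-8 read has interiors
  expect_error(collect_context_counts(read_set("r", "ACGT"), k = 0),
               "positive")
})

test_that("counting total matches the window-count invariant", {
  set.seed(5)
  reads <- generate_references(20, 60)
  for (k in c(1, 3, 5)) {
    cc <- collect_context_counts(reads, k)
    expect_equal(sum(cc$counts), sum(pmax(0, nchar(reads$bases) - 2 * k)))
  }
})

test_that("single-symbol rule matches the brute-force minimizer", {
  Pi <- matrix(0.1 / 3, 4, 4); diag(Pi) <- 0.9
  Pi <- confusion_matrix(Pi)
  # identity channel never edits
  expect_equal(denoise_symbol(c(5, 2, 9, 0), "C", confusion_matrix(diag(4))),
               "C")
  # one observed C among 11 is consistent with a true C: kept
  expect_equal(denoise_symbol(c(10, 1, 0, 0), "C", Pi), "C")
  expect_equal(oracle_rule_direct(c(10, 1, 0, 0), 2L, unclass(Pi),
                                  hamming_loss(4)), 2L)
  # channel-inverted estimate favors A once the majority is large enough
  expect_equal(denoise_symbol(c(30, 1, 0, 0), "C", Pi), "A")
  expect_equal(oracle_rule_direct(c(30, 1, 0, 0), 2L, unclass(Pi),
                                  hamming_loss(4)), 1L)
})

test_that("direct and rearranged forms of the rule agree", {
  set.seed(11)
  Lambda <- hamming_loss(4)
  for (i in 1:2000) {
    Pi <- random_channel(4)
    m <- rpois(4, lambda = sample(c(1, 5, 50), 1))
    z <- sample(1:4, 1)
    a <- oracle_rule_direct(m, z, Pi, Lambda)
    b <- oracle_rule_rearranged(m, z, Pi, Lambda)
    expect_identical(a, b)
    expect_identical(denoise_symbol(m, c("A", "C", "G", "T")[z],
                                    confusion_matrix(Pi)),
                     c("A", "C", "G", "T")[a])
  }
})

test_that("identity channel leaves reads byte-identical", {
  set.seed(3)
  reads <- read_set(
    c("a", "b", "c"),
    c("ACGTACGTACGTAAA", "TTTTNGGGGACGTAC", "ACG"),
    c("IIIIIIIIIIIIIII", "!!!!!IIIII#####", "III"))
  out <- denoise_reads(reads, confusion_matrix(diag(4)), k = 2)
  expect_identical(out$bases, reads$bases)
  expect_identical(out$id, reads$id)
  expect_identical(out$quals, reads$quals)
})

test_that("a minority substitution is corrected against the consensus", {
  clean <- strrep("ACGTACGTAC", 3)
  mut <- clean
  substr(mut, 15, 15) <- "G"   # interior A -> G
  reads <- read_set(sprintf("r%d", 1:1001),
                    c(rep(clean, 1000), mut))
  Pi <- symmetric_confusion(0.01)
  out <- denoise_reads(reads, Pi, k = 2)
  expect_identical(out$bases, rep(clean, 1001))
})

test_that("reads shorter than the window pass through unchanged", {
  reads <- read_set("tiny", "ACGTACGTA")  # length 9 < 2k+1 for k = 5
  out <- denoise_reads(reads, symmetric_confusion(0.02), k = 5)
  expect_identical(out$bases, reads$bases)
})

test_that("quality gating copies confident positions verbatim", {
  clean <- strrep("ACGTACGTAC", 2)
  mut <- clean
  substr(mut, 9, 9) <- "C"
  hi <- strrep("I", 20)        # Phred 40 everywhere: all gated
  reads <- read_set(sprintf("r%d", 1:21), c(rep(clean, 20), mut),
                    rep(hi, 21))
  Pi <- symmetric_confusion(0.1)
  gated <- denoise_reads(reads, Pi, k = 2, quality_threshold = 20)
  expect_identical(gated$bases[21], mut)      # error kept: gated out
  open <- denoise_reads(reads, Pi, k = 2, quality_threshold = 50)
  expect_identical(open$bases[21], clean)     # threshold above Q40: denoised
})

test_that("denoising preserves read count, order, length and qualities", {
  set.seed(9)
  sim <- simulate_amplicon_data(n_refs = 2, ref_length = 60, n_reads = 80,
                                read_length = 40, seed = 17)
  out <- denoise_reads(sim$noisy, symmetric_confusion(0.01), k = 3)
  expect_identical(out$id, sim$noisy$id)
  expect_identical(nchar(out$bases), nchar(sim$noisy$bases))
  st <- attr(out, "denoise_stats")
  expect_identical(st$reads_in, st$reads_out)
})

test_that("denoising reduces the error rate at deep coverage", {
  sim <- simulate_amplicon_data(n_refs = 2, ref_length = 80, n_reads = 400,
                                read_length = 60,
                                Pi = symmetric_confusion(0.01), seed = 29)
  Pi <- symmetric_confusion(0.01)
  out <- denoise_reads(sim$noisy, Pi, k = 5)
  truth <- attr(sim$noisy, "truth")
  e_raw <- error_rate(alignment_stats(sim$noisy, truth))
  e_out <- error_rate(alignment_stats(out, truth))
  expect_lt(e_out, e_raw)

  # a second pass over its own output must not be worse than one pass
  out2 <- denoise_reads(out, Pi, k = 5)
  e_out2 <- error_rate(alignment_stats(out2, truth))
  expect_lte(e_out2, e_raw)
})

test_that("vectorized denoising agrees with the per-symbol rule", {
  set.seed(13)
  sim <- simulate_amplicon_data(n_refs = 1, ref_length = 40, n_reads = 30,
                                read_length = 30,
                                Pi = symmetric_confusion(0.05), seed = 31)
  k <- 2
  Pi <- symmetric_confusion(0.05)
  counts <- collect_context_counts(sim$noisy, k)
  out <- denoise_reads(sim$noisy, Pi, k = k, counts = counts)
  for (r in 1:5) {
    s <- strsplit(sim$noisy$bases[r], "")[[1]]
    o <- strsplit(out$bases[r], "")[[1]]
    n <- length(s)
    for (i in (k + 1):(n - k)) {
      key <- paste0(paste(s[(i - k):(i - 1)], collapse = ""), "|",
                    paste(s[(i + 1):(i + k)], collapse = ""))
      m <- counts$counts[key, ]
      expect_identical(o[i], denoise_symbol(m, s[i], Pi))
    }
  }
})
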