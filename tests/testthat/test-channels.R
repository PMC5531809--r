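test_that("estimate_confusion counts substitution columns directly", {
  # noiseless alignment -> identity channel
  expect_equal(unclass(estimate_confusion(list(c("AAAA", "AAAA")))),
               diag(4), ignore_attr = TRUE)

  # 90 A->A and 10 A->C columns, everything else noiseless
  pairs <- list(c(strrep("A", 90), strrep("A", 90)),
                c(strrep("A", 10), strrep("C", 10)),
                c("CGT", "CGT"))
  pi_hat <- estimate_confusion(pairs)
  expect_equal(pi_hat["A", ], c(A = 0.9, C = 0.1, G = 0, T = 0))
  expect_equal(unclass(pi_hat)[2:4, ], diag(4)[2:4, ], ignore_attr = TRUE)

  # one T->A among 100 T columns
  pairs <- c(list(c("ACGT", "ACGA")),
             rep(list(c("ACGT", "ACGT")), 99))
  pi_hat <- estimate_confusion(pairs)
  expect_equal(pi_hat["T", "A"], 0.01)
  expect_equal(pi_hat["T", "T"], 0.99)
  expect_equal(unclass(pi_hat)[1:3, ], diag(4)[1:3, ], ignore_attr = TRUE)
})

test_that("estimate_confusion skips N/gap columns and rejects empty input", {
  pi_hat <- estimate_confusion(list(c("ANG-", "ACGT"), c("ACGT", "ACGT")))
  expect_equal(unclass(pi_hat), diag(4), ignore_attr = TRUE)
  expect_error(estimate_confusion(list()), "no alignable columns")
  expect_error(estimate_confusion(list(c("NNNN", "ACGT"))),
               "no alignable columns")
})

test_that("estimate_confusion recovers the generating channel", {
  set.seed(71)
  p <- 0.02
  Pi <- symmetric_confusion(p)
  refs <- generate_references(1, 2000)
  reads <- sample_reads(refs, 150, 2000)
  noisy <- corrupt_dmc(reads, Pi)
  pairs <- Map(c, attr(noisy, "truth")$true_bases, noisy$bases)
  pi_hat <- estimate_confusion(pairs)
  n_per_row <- 150 * 2000 / 4
  for (x in 1:4) for (z in 1:4) {
    se <- sqrt(Pi[x, z] * (1 - Pi[x, z]) / n_per_row)
    expect_lt(abs(pi_hat[x, z] - Pi[x, z]), 3 * se + 1e-12)
  }
})

test_that("virtual DMC integrates the density over quantizer cells", {
  # near-degenerate density concentrated at f = N: channel is the identity
  sharp <- flow_density_model(sigma0 = 1e-3, sigma1 = 0, zero_rate = 1e3)
  G <- build_virtual_dmc(sharp)
  expect_equal(unclass(G), diag(10), tolerance = 1e-9, ignore_attr = TRUE)

  # sd 0.1: essentially all mass of N=1 inside [0.5, 1.5]
  G <- build_virtual_dmc(flow_density_model(sigma0 = 0.1, sigma1 = 0))
  expect_lt(abs(G["1", "1"] - (pnorm(5) - pnorm(-5))), 1e-6)
  expect_lt(G["1", "0"] + G["1", "2"], 1e-6)

  # sd 0.5 at N = 2: cell mass from an independent closed-form computation
  G <- build_virtual_dmc(flow_density_model(sigma0 = 0.5, sigma1 = 0))
  trunc_mass <- function(lo, hi, mu, s)
    (pnorm(hi, mu, s) - pnorm(lo, mu, s)) / (1 - pnorm(0, mu, s))
  expect_equal(G["2", "2"], trunc_mass(1.5, 2.5, 2, 0.5), tolerance = 1e-7)
  expect_equal(G["3", "9"], trunc_mass(8.5, Inf, 3, 0.5), tolerance = 1e-7)
})

test_that("virtual DMC rows are stochastic for any valid model", {
  for (s0 in c(0.05, 0.15, 0.4)) {
    G <- build_virtual_dmc(flow_density_model(sigma0 = s0, sigma1 = 0.03))
    expect_equal(rowSums(G), rep(1, 10), ignore_attr = TRUE)
    expect_true(all(G >= 0 & G <= 1))
  }
})

test_that("sharpening the density drives the virtual DMC toward identity", {
  # sharpen every conditional density, including the zero-length one
  dev <- vapply(c(0.4, 0.25, 0.12, 0.05), function(s0) {
    G <- build_virtual_dmc(flow_density_model(sigma0 = s0, sigma1 = 0,
                                              zero_rate = 2 / s0))
    max(abs(unclass(G) - diag(10)))
  }, 0)
  expect_true(all(diff(dev) < 0))
})

test_that("validate_channel flags singular and off-stochastic matrices", {
  d <- validate_channel(diag(4))
  expect_true(d$ok)
  expect_false(d$singular)
  expect_equal(d$row_sum_dev, rep(0, 4), ignore_attr = TRUE)

  dup <- rbind(c(0.7, 0.3, 0, 0), c(0.7, 0.3, 0, 0), diag(4)[3:4, ])
  expect_true(validate_channel(dup)$singular)
  expect_true(validate_channel(matrix(0.25, 4, 4))$singular)
  expect_true(validate_channel(symmetric_confusion(0.05))$ok)
})

test_that("confusion matrix constructor enforces invariants", {
  expect_error(confusion_matrix(matrix(0.25, 4, 4)), "not invertible")
  bad <- diag(4); bad[1, 1] <- 0.5
  expect_error(confusion_matrix(bad), "sum to 1")
  bad <- diag(4); bad[1, ] <- c(1.5, -0.5, 0, 0)
  expect_error(confusion_matrix(bad), "\\[0, 1\\]")
})

test_that("confusion TSV round trips to 12 significant digits", {
  Pi <- symmetric_confusion(1 / 3 * 0.1)
  Pi[1, ] <- c(0.912345678901, 0.05, 0.02, 1 - 0.912345678901 - 0.07)
  Pi <- confusion_matrix(unclass(Pi) / rowSums(unclass(Pi)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_confusion_tsv(Pi, path)
  back <- read_confusion_tsv(path)
  expect_equal(signif(unclass(back), 12), signif(unclass(Pi), 12))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("x\ty", "1\t2"), bad)
  expect_error(read_confusion_tsv(bad), "5 rows|header")
})

test_that("density model config round trips", {
  m <- flow_density_model(sigma0 = 0.12, sigma1 = 0.07, zero_rate = 8)
  path <- withr::local_tempfile(fileext = ".conf")
  write_density_config(m, path)
  back <- read_density_config(path)
  expect_equal(back$sigma0, 0.12)
  expect_equal(back$sigma1, 0.07)
  expect_equal(back$zero_rate, 8)
  expect_equal(back$density(2, 1.7), m$density(2, 1.7))
})
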