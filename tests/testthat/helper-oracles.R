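# Independent oracles: brute-force implementations kept deliberately naive
# and separate from the package's vectorized code paths.

# Denoising rule, literal form: argmin over xhat of m^T Pi^{-1} (lambda . pi_z)
oracle_rule_direct <- function(m, z_idx, Pi, Lambda) {
  Pi_inv <- solve(Pi)
  A <- ncol(Pi)
  best <- 1L
  best_score <- Inf
  for (xh in seq_len(A)) {
    v <- Lambda[, xh] * Pi[, z_idx]
    score <- drop(t(m) %*% Pi_inv %*% v)
    if (score < best_score - 1e-12) {
      best <- xh
      best_score <- score
    }
  }
  best
}

# Rearranged form: argmin over xhat of lambda_xhat^T (pi_z . Pi^{-T} m)
oracle_rule_rearranged <- function(m, z_idx, Pi, Lambda) {
  est <- Pi[, z_idx] * drop(t(solve(Pi)) %*% m)
  A <- ncol(Pi)
  scores <- vapply(seq_len(A), function(xh) sum(Lambda[, xh] * est), 0)
  which.min(scores)
}

# random diagonally-dominant row-stochastic matrix (always invertible)
random_channel <- function(n = 4L, max_err = 0.3) {
  m <- matrix(stats::runif(n * n), n, n)
  diag(m) <- 0
  m <- m / rowSums(m) * stats::runif(n, 0, max_err)
  diag(m) <- 1 - rowSums(m)
  m
}

# direct-formula concordance between two label vectors sharing names
oracle_moc <- function(pa, qa) {
  qa <- qa[names(pa)]
  pl <- unique(pa); ql <- unique(qa)
  I <- length(pl); J <- length(ql)
  if (I == 1L && J == 1L) return(1)
  s <- 0
  for (i in seq_len(I)) for (j in seq_len(J)) {
    fij <- sum(pa == pl[i] & qa == ql[j])
    s <- s + fij^2 / (sum(pa == pl[i]) * sum(qa == ql[j]))
  }
  (s - 1) / (sqrt(I * J) - 1)
}

random_partition <- function(ids, max_clusters = 5L) {
  stats::setNames(sample(paste0("c", seq_len(max_clusters)),
                         length(ids), replace = TRUE), ids)
}

mean_edit_distance <- function(a, b) {
  mean(mapply(function(x, y) utils::adist(x, y), a, b))
}

# exhaustive trinucleotide statistics for the complexity oracles
oracle_tri_stats <- function(win) {
  l <- nchar(win) - 2L
  words <- vapply(seq_len(l), function(i) substr(win, i, i + 2L), "")
  table(words)
}
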