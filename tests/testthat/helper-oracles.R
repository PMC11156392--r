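# Brute-force oracle: direct product-form evaluation of the sequence law
# over all 2^N sequences, independent of the package's log-space /
# transfer-matrix code paths. Rows ordered by integer index.
bruteDistribution <- function(N, p, gamma) {
  grid <- as.matrix(expand.grid(rep(list(0:1), N)))
  w <- apply(grid, 1L, function(sig) {
    s <- 1 - 2 * sig
    prod(ifelse(sig == 0, p, 1 - p)) * exp(gamma * sum(s[-1L] * s[-N]))
  })
  idx <- drop(grid %*% 2^(0:(N - 1)))
  o <- order(idx)
  list(index = idx[o], weight = w[o], Z = sum(w), prob = w[o] / sum(w))
}

# Brute-force minimum alternation distance for index m at length N.
bruteMinDistance <- function(m, N) {
  sig <- as.integer(m %/% 2^(0:(N - 1)) %% 2)
  refw <- as.integer(seq_len(N) %% 2 == 0)
  d <- sum(sig != refw)
  min(d, N - d)
}

# Shared parameter grid for property-style checks.
paramGrid <- expand.grid(p = c(0.3, 0.5, 0.62),
                         gamma = c(-0.7, -0.2027, 0, 0.35),
                         N = c(2L, 5L, 11L, 14L))

tvDistance <- function(a, b) sum(abs(a - b)) / 2

# Empirical index frequencies of a SimulationResult as a full 2^N vector.
fullEmpirical <- function(res, N) {
  emp <- numeric(2^N)
  f <- empiricalFrequencies(res)
  emp[f$index + 1] <- f$frequency
  emp
}
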