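#' Model parameters for fibril stacking
#'
#' Construct the parameter bundle of the nearest-neighbour stacking model.
#' `p` is the probability that a wildtype molecule is selected at each
#' attachment (proportional to the wt:v concentration ratio). The coupling
#' `gamma` rescales the attachment likelihood by `exp(gamma)` when the new
#' molecule matches the end molecule's type and `exp(-gamma)` when it
#' differs, so `gamma < 0` favours alternation. Instead of `gamma` you may
#' give the binding `odds` ratio, related by `odds = exp(-2 * gamma)`.
#'
#' @param N chain length (number of molecules), at least 2.
#' @param p wildtype selection probability, in (0, 1).
#' @param gamma nearest-neighbour coupling; ignored when `odds` is given.
#' @param odds optional odds ratio (> 0) from which `gamma` is derived.
#' @param temperature kelvin; used only by the thermodynamic conversions.
#'   Defaults to physiological 310.15 K.
#'
#' @return a [ModelParams-class] object.
#' @examples
#' mp <- modelParams(N = 12, p = 0.5, odds = 1.5)
#' coupling(mp)   # -0.2027...
#' oddsRatio(mp)  # 1.5
#' @export
modelParams <- function(N = 12, p = 0.5, gamma = 0, odds = NULL,
                        temperature = 310.15) {
  if (!is.null(odds)) gamma <- oddsToGamma(odds)
  new("ModelParams", N = as.integer(N), p = as.numeric(p),
      gamma = as.numeric(gamma), temperature = as.numeric(temperature))
}

#' @rdname modelParams
#' @aliases chainLength wtProb coupling oddsRatio tempKelvin
#' @export
setMethod("chainLength", "ModelParams", function(object) object@N)

#' @rdname modelParams
#' @export
setMethod("wtProb", "ModelParams", function(object) object@p)

#' @rdname modelParams
#' @export
setMethod("coupling", "ModelParams", function(object) object@gamma)

#' @rdname modelParams
#' @export
setMethod("oddsRatio", "ModelParams",
          function(object) gammaToOdds(object@gamma))

#' @rdname modelParams
#' @export
setMethod("tempKelvin", "ModelParams", function(object) object@temperature)

setMethod("show", "ModelParams", function(object) {
  cat(sprintf(
    "ModelParams: N = %d, p(wt) = %g, gamma = %g (odds ratio %g), T = %g K\n",
    object@N, object@p, object@gamma, gammaToOdds(object@gamma),
    object@temperature))
})

#' Largest chain length enumerated exhaustively
#'
#' Operations that tabulate all `2^N` sequences (enumeration of the
#' distribution, spectra) are limited to `N <= 22`; beyond that only the
#' transfer-matrix, dynamic-programming and sampling paths apply.
#'
#' @return the cap (22).
#' @export
enumerationCap <- function() 22L

checkCap <- function(N) {
  if (N > enumerationCap())
    stop(sprintf(
      "N = %d exceeds the enumeration cap (%d); use the transfer-matrix or DP path",
      N, enumerationCap()), call. = FALSE)
  invisible(N)
}

# Resolve homogeneous params + optional per-site overrides into vectors:
# ps[i] = wildtype selection probability at position i (length N),
# gs[j] = coupling on the bond between positions j and j+1 (length N-1).
siteVectors <- function(params, sitePs = numeric(0), siteGammas = numeric(0)) {
  n <- params@N
  list(ps = if (length(sitePs)) sitePs else rep(params@p, n),
       gs = if (length(siteGammas)) siteGammas else rep(params@gamma, n - 1L))
}

# Log unnormalised weight of each row of a 0/1 matrix (rows = sequences).
logWeightMatrix <- function(bits, ps, gs) {
  n <- ncol(bits)
  s <- 1 - 2 * bits  # +1 wildtype, -1 variant
  lw <- bits %*% log(1 - ps) + (1 - bits) %*% log(ps)
  lw + (s[, -n, drop = FALSE] * s[, -1L, drop = FALSE]) %*% gs
}

#' Unnormalised Gibbs weight of a sequence
#'
#' The probability model assigns each type sequence a weight proportional to
#' a Bernoulli selection term per molecule times `exp(gamma * s_i * s_(i-1))`
#' per adjacent pair, where `s = +1` for wildtype and `-1` for variant.
#' This returns that product without the normalising constant; divide by
#' [partitionFunction()] (or use [sequenceProbability()]) to normalise.
#' Computed in log space internally.
#'
#' @param seq a [FibrilSequence-class] whose length equals `chainLength(params)`.
#' @param params a [ModelParams-class].
#' @return a non-negative number.
#' @examples
#' mp <- modelParams(N = 12, p = 0.5, gamma = 0)
#' sequenceWeight(fibrilSequence("vwvwvwvwvwvw"), mp) # 0.5^12
#' @export
sequenceWeight <- function(seq, params) {
  stopifnot(is(seq, "FibrilSequence"), is(params, "ModelParams"))
  if (length(seq@types) != params@N)
    stop(sprintf("sequence length %d does not match N = %d",
                 length(seq@types), params@N))
  sv <- siteVectors(params)
  exp(drop(logWeightMatrix(rbind(seq@types), sv$ps, sv$gs)))
}

# Transfer-matrix log partition constant; state = type at current position.
# Works for any N and for position-dependent fields; rescales each step.
logPartitionTM <- function(ps, gs) {
  v <- c(ps[1L], 1 - ps[1L])          # (weight of sigma_1 = 0, = 1)
  acc <- 0
  for (j in seq_along(gs)) {
    a <- c(ps[j + 1L], 1 - ps[j + 1L])
    eg <- exp(gs[j]); emg <- exp(-gs[j])
    v <- c(a[1L] * (v[1L] * eg + v[2L] * emg),   # new sigma = 0
           a[2L] * (v[1L] * emg + v[2L] * eg))   # new sigma = 1
    m <- max(v)
    acc <- acc + log(m)
    v <- v / m
  }
  acc + log(sum(v))
}

#' Partition constant of the sequence model
#'
#' The sum of unnormalised weights over all `2^N` sequences — the reciprocal
#' of the model's proportionality constant. Two routes are provided:
#' `"transfer_matrix"` (the default; cost linear in `N`, no cap) and
#' `"enumeration"` (explicit sum over all `2^N` sequences, `N` capped at
#' [enumerationCap()]). The two agree to relative 1e-12. At `p = 0.5` the
#' closed form is `Z = 2 * (2 * cosh(gamma))^(N - 1) / 2^N`.
#'
#' @param params a [ModelParams-class].
#' @param method `"transfer_matrix"` or `"enumeration"`.
#' @return a positive number.
#' @examples
#' partitionFunction(modelParams(N = 12, p = 0.5, gamma = 0)) # 1
#' @export
partitionFunction <- function(params,
                              method = c("transfer_matrix", "enumeration")) {
  stopifnot(is(params, "ModelParams"))
  method <- match.arg(method)
  sv <- siteVectors(params)
  if (method == "enumeration") {
    checkCap(params@N)
    lw <- logWeightMatrix(allSequenceBits(params@N), sv$ps, sv$gs)
    m <- max(lw)
    exp(m + log(sum(exp(lw - m))))
  } else {
    exp(logPartitionTM(sv$ps, sv$gs))
  }
}

#' Probability of a specific type sequence
#'
#' The normalised Gibbs probability: [sequenceWeight()] divided by the
#' partition constant (computed by transfer matrix, so any `N` works).
#'
#' @inheritParams sequenceWeight
#' @return a probability in `[0, 1]`.
#' @examples
#' mp <- modelParams(N = 12, p = 0.5, odds = 1.5)
#' sequenceProbability(fibrilSequence("vwvwvwvwvwvw"), mp) # ~0.0018
#' @export
sequenceProbability <- function(seq, params) {
  sv <- siteVectors(params)
  lw <- log(sequenceWeight(seq, params))
  exp(lw - logPartitionTM(sv$ps, sv$gs))
}

#' Enumerate the exact sequence distribution
#'
#' Tabulates the normalised probability of every length-`N` sequence,
#' ordered by integer index (see [sequenceToIndex()]). Requires
#' `N <= enumerationCap()`.
#'
#' @param params a [ModelParams-class].
#' @return a [SequenceDistribution-class].
#' @examples
#' d <- enumerateDistribution(modelParams(N = 4, p = 0.5, odds = 1.5))
#' sum(probabilities(d)) # 1
#' @export
enumerateDistribution <- function(params) {
  stopifnot(is(params, "ModelParams"))
  checkCap(params@N)
  sv <- siteVectors(params)
  lw <- drop(logWeightMatrix(allSequenceBits(params@N), sv$ps, sv$gs))
  m <- max(lw)
  w <- exp(lw - m)
  Z <- sum(w)
  new("SequenceDistribution", params = params, prob = w / Z,
      Z = Z * exp(m))
}

#' @rdname enumerateDistribution
#' @param object a [SequenceDistribution-class].
#' @aliases probabilities partitionConstant
#' @export
setMethod("probabilities", "SequenceDistribution",
          function(object) object@prob)

#' @rdname enumerateDistribution
#' @export
setMethod("partitionConstant", "SequenceDistribution",
          function(object) object@Z)

setMethod("show", "SequenceDistribution", function(object) {
  n <- object@params@N
  top <- order(object@prob, decreasing = TRUE)[seq_len(min(2L, 2^n))]
  cat(sprintf("SequenceDistribution over %d sequences (N = %d)\n", 2^n, n))
  cat(sprintf("  Z = %.6g; modal sequences: %s\n", object@Z,
              paste(vapply(top - 1, function(m)
                as.character(indexToSequence(m, n)), ""), collapse = ", ")))
})

# Backward transfer-matrix messages f[, i] proportional to the summed weight
# of all completions from a molecule of each type at position i. Columns are
# normalised (only ratios matter downstream).
backwardMessages <- function(ps, gs) {
  n <- length(ps)
  f <- matrix(1, nrow = 2L, ncol = n)
  for (i in (n - 1L):1L) {
    a <- c(ps[i + 1L], 1 - ps[i + 1L])
    eg <- exp(gs[i]); emg <- exp(-gs[i])
    f[1L, i] <- a[1L] * eg * f[1L, i + 1L] + a[2L] * emg * f[2L, i + 1L]
    f[2L, i] <- a[1L] * emg * f[1L, i + 1L] + a[2L] * eg * f[2L, i + 1L]
    f[, i] <- f[, i] / sum(f[, i])
  }
  f
}

# Vectorised exact Gibbs sampling: count x N matrix of 0/1 indicators.
# Draw order is position-major (all first molecules, then all second, ...),
# so results are reproducible bit-for-bit for a given (seed, count).
sampleGibbsMatrix <- function(count, ps, gs) {
  n <- length(ps)
  f <- backwardMessages(ps, gs)
  out <- matrix(0L, nrow = count, ncol = n)
  w0 <- ps[1L] * f[1L, 1L]
  w1 <- (1 - ps[1L]) * f[2L, 1L]
  out[, 1L] <- as.integer(stats::runif(count) < w1 / (w0 + w1))
  for (i in 2:n) {
    s_prev <- 1 - 2 * out[, i - 1L]
    w0 <- ps[i] * exp(gs[i - 1L] * s_prev) * f[1L, i]
    w1 <- (1 - ps[i]) * exp(-gs[i - 1L] * s_prev) * f[2L, i]
    out[, i] <- as.integer(stats::runif(count) < w1 / (w0 + w1))
  }
  out
}

#' Exact sampling from the sequence distribution
#'
#' Draws i.i.d. sequences from the globally-normalised Gibbs law by backward
#' transfer-matrix conditionals: sample position 1 from its exact marginal,
#' then each next position from its exact conditional given the previous one.
#' No enumeration is involved, so any `N` works. Reproducible under a fixed
#' seed.
#'
#' @param params a [ModelParams-class].
#' @param count number of sequences to draw (>= 1).
#' @param seed integer seed.
#' @return a list of `count` [FibrilSequence-class] objects.
#' @examples
#' draws <- exactSampler(modelParams(N = 6, p = 0.5, odds = 4), 5, seed = 1)
#' @export
exactSampler <- function(params, count, seed) {
  stopifnot(is(params, "ModelParams"), count >= 1)
  sv <- siteVectors(params)
  set.seed(as.integer(seed))
  bits <- sampleGibbsMatrix(as.integer(count), sv$ps, sv$gs)
  lapply(seq_len(nrow(bits)), function(i)
    new("FibrilSequence", types = bits[i, ]))
}
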