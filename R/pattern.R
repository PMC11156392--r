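#' Distance of a sequence from perfect alternation
#'
#' Every length-`N` chain has exactly two perfectly alternating references:
#' one starting with wildtype (w,v,w,v,...) and one starting with variant.
#' This reports the Hamming distance to each and the minimum; the distances
#' always sum to `N`, so the minimum is at most `floor(N / 2)`. When `N` is
#' even and both distances equal `N / 2` the sequence is tied between the
#' references and both tags are reported.
#'
#' @param seq a [FibrilSequence-class].
#' @return a list: `distance` (the minimum), `nearest` (`"w"`, `"v"`, or
#'   both), `d_w` and `d_v` (distances to each reference).
#' @examples
#' minAlternationDistance(fibrilSequence("vwvwvwvwvwvw"))$distance # 0
#' minAlternationDistance(fibrilSequence("wwwwwwwwwwww"))$nearest  # both tied
#' @export
minAlternationDistance <- function(seq) {
  stopifnot(is(seq, "FibrilSequence"))
  n <- length(seq@types)
  refw <- alternatingReferences(n)$w@types
  d_w <- sum(seq@types != refw)
  d_v <- n - d_w
  nearest <- c("w", "v")[c(d_w <= d_v, d_v <= d_w)]
  list(distance = min(d_w, d_v), nearest = nearest, d_w = d_w, d_v = d_v)
}

#' Count sequences at a given alternation distance
#'
#' The number of length-`N` type sequences whose minimum Hamming distance to
#' the nearest perfectly alternating reference equals `k`. For `k < N / 2`
#' this is `2 * choose(N, k)` (each reference contributes its own
#' `k`-neighbourhood); at the tie distance `k = N / 2` (even `N`) each
#' sequence is equidistant from both references and is counted once, giving
#' `choose(N, N / 2)`.
#'
#' @param N chain length.
#' @param k distance, `0 <= k <= N`.
#' @return a non-negative count; zero for `k > floor(N / 2)`.
#' @examples
#' countKErrorSequences(12, 0) # 2 perfectly alternating orders
#' countKErrorSequences(12, 1) # 24 one-error sequences
#' @export
countKErrorSequences <- function(N, k) {
  stopifnot(N >= 2, k >= 0, k <= N)
  if (k > N / 2) return(0)
  if (k == N / 2) choose(N, k) else 2 * choose(N, k)
}

# Unnormalised weight mass by distance-to-reference-w, via DP over
# (position, current type, mismatches so far). Columns rescaled per position;
# only the final normalised profile is used. Linear in N * N, no cap.
distanceProfileDP <- function(params, sitePs = numeric(0),
                              siteGammas = numeric(0)) {
  sv <- siteVectors(params, sitePs, siteGammas)
  n <- params@N
  refw <- alternatingReferences(n)$w@types
  # W[sigma + 1, d + 1] = weight mass of prefixes ending in type sigma with
  # d mismatches against the starts-with-w reference.
  W <- matrix(0, nrow = 2L, ncol = n + 1L)
  a1 <- c(sv$ps[1L], 1 - sv$ps[1L])
  W[1L, 1L + (refw[1L] != 0L)] <- a1[1L]
  W[2L, 1L + (refw[1L] != 1L)] <- a1[2L]
  for (i in 2:n) {
    a <- c(sv$ps[i], 1 - sv$ps[i])
    eg <- exp(sv$gs[i - 1L]); emg <- exp(-sv$gs[i - 1L])
    nw <- matrix(0, nrow = 2L, ncol = n + 1L)
    # sigma_i = 0 (wildtype): same-pair bond with previous 0, different with 1
    shift0 <- as.integer(refw[i] != 0L)
    from0 <- a[1L] * (W[1L, ] * eg + W[2L, ] * emg)
    if (shift0) nw[1L, 2:(n + 1L)] <- from0[1:n] else nw[1L, ] <- from0
    # sigma_i = 1 (variant)
    shift1 <- as.integer(refw[i] != 1L)
    from1 <- a[2L] * (W[1L, ] * emg + W[2L, ] * eg)
    if (shift1) nw[2L, 2:(n + 1L)] <- nw[2L, 2:(n + 1L)] + from1[1:n]
    else nw[2L, ] <- nw[2L, ] + from1
    W <- nw / max(nw)
  }
  mass <- colSums(W)
  mass / sum(mass)  # P(d_w = 0..N)
}

#' Fraction of perfectly alternating fibrils
#'
#' Total probability of the two perfectly alternating sequences under the
#' model. For even `N` at wildtype probability `p` this has the closed form
#' `2 * p^(N/2) * (1 - p)^(N/2) * exp(-(N - 1) * gamma) / Z`.
#'
#' @param params a [ModelParams-class].
#' @return a probability in `[0, 1]`.
#' @examples
#' perfectFraction(modelParams(N = 12, p = 0.5, odds = 4)) # ~0.086
#' @export
perfectFraction <- function(params) {
  stopifnot(is(params, "ModelParams"))
  refs <- alternatingReferences(params@N)
  sv <- siteVectors(params)
  lz <- logPartitionTM(sv$ps, sv$gs)
  lw <- drop(logWeightMatrix(rbind(refs$w@types, refs$v@types), sv$ps, sv$gs))
  sum(exp(lw - lz))
}

#' Fraction of fibrils k errors from perfect alternation
#'
#' Total probability of all sequences at minimum alternation distance `k`.
#' `method = "enumeration"` sums over the explicit `2^N` table (capped at
#' [enumerationCap()]); `method = "dp"` uses the dynamic programme of
#' [patternFractionDP()], which has no cap; `"auto"` picks enumeration for
#' `N <= 14` and the DP otherwise. All routes agree to 1e-12.
#'
#' @param params a [ModelParams-class].
#' @param k distance, `0 <= k <= N`.
#' @param method `"auto"`, `"enumeration"` or `"dp"`.
#' @return a probability in `[0, 1]`.
#' @examples
#' mp <- modelParams(N = 12, p = 0.5, odds = 1.5)
#' kErrorFraction(mp, 0) == perfectFraction(mp)
#' @export
kErrorFraction <- function(params, k, method = c("auto", "enumeration", "dp")) {
  stopifnot(is(params, "ModelParams"), k >= 0, k <= params@N)
  method <- match.arg(method)
  if (method == "auto")
    method <- if (params@N <= 14L) "enumeration" else "dp"
  if (method == "dp") return(patternFractionDP(params, k))
  checkCap(params@N)
  n <- params@N
  bits <- allSequenceBits(n)
  d_w <- as.vector(bits %*% (1 - alternatingReferences(n)$w@types) +
                     (1 - bits) %*% alternatingReferences(n)$w@types)
  mind <- pmin(d_w, n - d_w)
  sum(probabilities(enumerateDistribution(params))[mind == k])
}

#' @rdname kErrorFraction
#' @details `patternFractionDP` aggregates weight mass over
#'   (position, current type, mismatch count against the starts-with-wildtype
#'   reference); because the distances to the two references sum to `N`,
#'   folding the mismatch profile at `N / 2` gives the minimum-distance law
#'   without double counting. Cost is `O(N^2)`, so chains far beyond the
#'   enumeration cap are fine.
#' @export
patternFractionDP <- function(params, k) {
  stopifnot(is(params, "ModelParams"), k >= 0, k <= params@N)
  n <- params@N
  profile <- distanceProfileDP(params)  # P(d_w = 0..N)
  d <- 0:n
  sum(profile[pmin(d, n - d) == k])
}

#' Enrichment of perfect alternation over the random reference
#'
#' The perfect-alternation fraction divided by its value in the fully random
#' reference state (coupling 0, `p = 0.5`, same `N`), which is `2 / 2^N`.
#' `roundSigfigs` optionally rounds each alternating sequence's probability
#' to that many significant figures before forming the ratio, matching the
#' convention of quoting per-sequence probabilities at 2 significant figures
#' (at odds 1.5, N = 12 this gives 7.37 versus the unrounded 7.43).
#'
#' @param params a [ModelParams-class].
#' @param roundSigfigs `NULL` (exact) or a number of significant figures
#'   applied to each per-sequence probability first.
#' @return a positive fold change; 1 in the reference state.
#' @examples
#' enrichment(modelParams(N = 12, p = 0.5, odds = 1.5))               # 7.43
#' enrichment(modelParams(N = 12, p = 0.5, odds = 1.5), roundSigfigs = 2) # 7.37
#' @export
enrichment <- function(params, roundSigfigs = NULL) {
  stopifnot(is(params, "ModelParams"))
  ref <- 2 / 2^params@N
  if (is.null(roundSigfigs)) return(perfectFraction(params) / ref)
  refs <- alternatingReferences(params@N)
  pr <- vapply(refs, sequenceProbability, 0, params = params)
  sum(signif(pr, roundSigfigs)) / ref
}

sweepRow <- function(params) {
  c(perfect_fraction = perfectFraction(params),
    one_error_fraction = kErrorFraction(params, 1L),
    enrichment = enrichment(params))
}

#' Sweep pattern fractions over the binding odds ratio
#'
#' For each odds value, derives the coupling via [oddsToGamma()] and
#' tabulates the perfect-alternation fraction, the one-error fraction and
#' the enrichment fold at fixed wildtype probability `p` and chain length
#' `N`. At `p = 0.5` the perfect fraction rises steeply with the odds.
#'
#' @param oddsGrid strictly increasing vector of positive odds ratios.
#' @param p wildtype selection probability.
#' @param N chain length.
#' @return a [SweepTable-class] with axis `"odds"`.
#' @examples
#' sweepOdds(c(1, 1.5, 4, 10))
#' @export
sweepOdds <- function(oddsGrid, p = 0.5, N = 12) {
  if (any(!is.finite(oddsGrid)) || any(oddsGrid <= 0))
    stop("odds values must be positive and finite")
  rows <- t(vapply(oddsGrid, function(o)
    sweepRow(modelParams(N = N, p = p, odds = o)), numeric(3)))
  tb <- data.frame(axis_value = oddsGrid, gamma = oddsToGamma(oddsGrid), rows)
  new("SweepTable", axis = "odds", table = tb, N = as.integer(N))
}

#' Sweep pattern fractions over the variant:wildtype ratio
#'
#' The concentration ratio `r = [v] : [wt]` maps to the wildtype selection
#' probability as `p = 1 / (1 + r)`. For each ratio on the grid, the perfect
#' and one-error fractions and the enrichment are tabulated at a fixed odds
#' ratio. `r = 0` (no variant available) is allowed and yields zero for both
#' pattern fractions; the table is symmetric under `r <-> 1/r` because
#' swapping the two molecule types relabels but does not change the model.
#'
#' @param ratioGrid strictly increasing vector of non-negative ratios.
#' @param odds positive odds ratio, fixed across the sweep.
#' @param N chain length.
#' @return a [SweepTable-class] with axis `"ratio"`.
#' @examples
#' sweepRatio(c(0, 0.5, 1, 2), odds = 4)
#' @export
sweepRatio <- function(ratioGrid, odds = 4, N = 12) {
  if (any(!is.finite(ratioGrid)) || any(ratioGrid < 0))
    stop("ratios must be non-negative and finite")
  gam <- oddsToGamma(odds)
  rows <- t(vapply(ratioGrid, function(r) {
    if (r == 0)  # only the all-wildtype sequence can form
      return(c(perfect_fraction = 0, one_error_fraction = 0, enrichment = 0))
    sweepRow(modelParams(N = N, p = 1 / (1 + r), gamma = gam))
  }, numeric(3)))
  tb <- data.frame(axis_value = ratioGrid, gamma = gam, rows)
  new("SweepTable", axis = "ratio", table = tb, N = as.integer(N))
}

#' @rdname sweepOdds
#' @param object a [SweepTable-class].
#' @aliases sweepFrame
#' @export
setMethod("sweepFrame", "SweepTable", function(object) object@table)

setMethod("show", "SweepTable", function(object) {
  cat(sprintf("SweepTable over %s (N = %d), %d grid points\n",
              object@axis, object@N, nrow(object@table)))
  print(utils::head(object@table))
  if (nrow(object@table) > 6L) cat("...\n")
})

#' Full probability spectrum over sequence indices
#'
#' The enumerated per-index probability of every length-`N` sequence, with
#' its string rendering and the flat random-reference level `1 / 2^N`
#' (the no-selectivity line) as a constant column. The spikes of this table
#' at negative coupling sit at the two perfectly alternating sequences.
#'
#' @param params a [ModelParams-class] with `N <= enumerationCap()`.
#' @return a data.frame with columns `index`, `sequence`, `probability`,
#'   `reference_level`, ordered by ascending index.
#' @examples
#' sp <- spectrum(modelParams(N = 6, p = 0.5, odds = 1.5))
#' sp[which.max(sp$probability), ]
#' @export
spectrum <- function(params) {
  stopifnot(is(params, "ModelParams"))
  checkCap(params@N)
  n <- params@N
  d <- enumerateDistribution(params)
  bits <- allSequenceBits(n)
  seqs <- apply(bits, 1L, function(b)
    paste(c("w", "v")[b + 1L], collapse = ""))
  data.frame(index = 0:(2^n - 1), sequence = seqs,
             probability = probabilities(d), reference_level = 1 / 2^n)
}

#' Probability of fibrils tiling a repeating motif
#'
#' Total probability of the sequences formed by tiling a motif cyclically
#' along the chain, counting every phase shift of the motif and removing
#' duplicate sequences. Motif `"wv"` recovers the two perfectly alternating
#' sequences; a single-letter motif gives one homogeneous sequence.
#'
#' @param params a [ModelParams-class].
#' @param motif nonempty string over `w`/`v`.
#' @return a probability in `[0, 1]`.
#' @examples
#' mp <- modelParams(N = 12, p = 0.5, odds = 1.5)
#' motifFraction(mp, "wv") == perfectFraction(mp)
#' @export
motifFraction <- function(params, motif) {
  stopifnot(is(params, "ModelParams"), is.character(motif),
            length(motif) == 1L, nchar(motif) >= 1L)
  ch <- strsplit(motif, "", fixed = TRUE)[[1L]]
  if (!all(ch %in% c("w", "v")))
    stop("motif may only contain 'w' and 'v'")
  n <- params@N
  L <- length(ch)
  tilings <- unique(vapply(0:(L - 1L), function(shift)
    paste(ch[(((seq_len(n) - 1L) + shift) %% L) + 1L], collapse = ""), ""))
  sum(vapply(tilings, function(s)
    sequenceProbability(fibrilSequence(s), params), 0))
}
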