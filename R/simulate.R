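#' Configure a stochastic fibril growth run
#'
#' @param params a [ModelParams-class].
#' @param mode growth mode; see [GrowthConfig-class]. Default
#'   `"gibbs_exact"`, the mode whose ensembles follow the globally
#'   normalised sequence distribution for every `p` (the local modes agree
#'   with it at `p = 0.5` but not in general; see [compareToExact()]).
#' @param siteGammas optional per-bond couplings, length `N - 1`
#'   (tissue-templated extension); empty to use the homogeneous coupling.
#' @param sitePs optional per-position wildtype selection probabilities,
#'   length `N`; empty to use the homogeneous `p`.
#' @param seed integer root seed.
#' @param count ensemble size.
#' @return a [GrowthConfig-class].
#' @examples
#' growthConfig(modelParams(N = 12, p = 0.5, odds = 4), count = 1000)
#' @export
growthConfig <- function(params, mode = c("gibbs_exact", "local_conditional",
                                          "local_rejection"),
                         siteGammas = numeric(0), sitePs = numeric(0),
                         seed = 1L, count = 10000L) {
  mode <- match.arg(mode)
  new("GrowthConfig", params = params, mode = mode,
      siteGammas = as.numeric(siteGammas), sitePs = as.numeric(sitePs),
      seed = as.integer(seed), count = as.integer(count))
}

setMethod("show", "GrowthConfig", function(object) {
  cat(sprintf("GrowthConfig: mode = %s, count = %d, seed = %d\n",
              object@mode, object@count, object@seed))
  show(object@params)
  if (length(object@siteGammas) || length(object@sitePs))
    cat("  with position-dependent (tissue-templated) overrides\n")
})

# Vectorised local growth: each fibril is grown molecule by molecule; the
# next type is drawn from the conditional implied by the selection
# probability and the bond to the current end molecule. Draw order is
# position-major. Returns a count x N 0/1 matrix.
growLocalMatrix <- function(count, ps, gs, rejection = FALSE) {
  n <- length(ps)
  out <- matrix(0L, nrow = count, ncol = n)
  out[, 1L] <- as.integer(stats::runif(count) >= ps[1L])
  for (i in 2:n) {
    s_prev <- 1 - 2 * out[, i - 1L]
    g <- gs[i - 1L]
    if (!rejection) {
      w0 <- ps[i] * exp(g * s_prev)
      w1 <- (1 - ps[i]) * exp(-g * s_prev)
      out[, i] <- as.integer(stats::runif(count) < w1 / (w0 + w1))
    } else {
      # propose from the selection probability, accept with
      # exp(g * s_new * s_prev) / exp(|g|)  (always <= 1), retry on reject
      pending <- seq_len(count)
      while (length(pending)) {
        prop <- as.integer(stats::runif(length(pending)) >= ps[i])
        s_new <- 1 - 2 * prop
        acc <- stats::runif(length(pending)) <
          exp(g * s_new * s_prev[pending] - abs(g))
        out[pending[acc], i] <- prop[acc]
        pending <- pending[!acc]
      }
    }
  }
  out
}

growBitsMatrix <- function(config) {
  sv <- siteVectors(config@params, config@sitePs, config@siteGammas)
  switch(config@mode,
    gibbs_exact = sampleGibbsMatrix(config@count, sv$ps, sv$gs),
    local_conditional = growLocalMatrix(config@count, sv$ps, sv$gs),
    local_rejection = growLocalMatrix(config@count, sv$ps, sv$gs,
                                      rejection = TRUE))
}

#' Grow a single fibril
#'
#' Draws one fibril sequence under the configuration's growth mode, using
#' (and advancing) R's current random number stream — seed the stream
#' yourself, or use [simulateEnsemble()] for seeded ensembles. Growth starts
#' from a single molecule drawn from the selection probability; each
#' subsequent molecule is drawn given the current end molecule
#' (local modes) or from the exact Gibbs conditionals (`gibbs_exact`).
#'
#' @param config a [GrowthConfig-class] (`count` is ignored here).
#' @return a [FibrilSequence-class].
#' @examples
#' set.seed(7)
#' growFibril(growthConfig(modelParams(N = 12, p = 0.5, odds = 4)))
#' @export
growFibril <- function(config) {
  stopifnot(is(config, "GrowthConfig"))
  one <- initialize(config, count = 1L)
  new("FibrilSequence", types = growBitsMatrix(one)[1L, ])
}

#' Simulate a seeded ensemble of fibrils
#'
#' Grows `count` independent fibrils under the configuration, seeded from
#' `config@seed`, and tabulates the empirical frequency of each observed
#' sequence index together with binomial summaries of the perfect and
#' one-error pattern classes. Identical (seed, config) pairs reproduce the
#' result bit for bit.
#'
#' @param config a [GrowthConfig-class].
#' @return a [SimulationResult-class].
#' @examples
#' res <- simulateEnsemble(
#'   growthConfig(modelParams(N = 12, p = 0.5, odds = 4),
#'                seed = 1, count = 5000))
#' res@summary$perfect_fraction
#' @export
simulateEnsemble <- function(config) {
  stopifnot(is(config, "GrowthConfig"))
  set.seed(config@seed)
  bits <- growBitsMatrix(config)
  n <- config@params@N
  idx <- drop(bits %*% 2^(0:(n - 1L)))
  tab <- table(idx)
  counts <- data.frame(index = as.numeric(names(tab)),
                       count = as.integer(tab))
  counts <- counts[order(counts$index), , drop = FALSE]
  rownames(counts) <- NULL
  refw <- alternatingReferences(n)$w@types
  d_w <- drop(bits %*% (1L - refw) + (1L - bits) %*% refw)
  mind <- pmin(d_w, n - d_w)
  m <- config@count
  pf <- mean(mind == 0); of <- mean(mind == 1)
  new("SimulationResult", config = config, counts = counts,
      summary = list(perfect_fraction = pf,
                     perfect_se = sqrt(pf * (1 - pf) / m),
                     one_error_fraction = of,
                     one_error_se = sqrt(of * (1 - of) / m)))
}

#' @rdname simulateEnsemble
#' @param object a [SimulationResult-class].
#' @return `empiricalFrequencies`: data.frame of `index`, `count`,
#'   `frequency` over the observed sequence indices.
#' @aliases empiricalFrequencies
#' @export
setMethod("empiricalFrequencies", "SimulationResult", function(object) {
  cbind(object@counts, frequency = object@counts$count / object@config@count)
})

setMethod("show", "SimulationResult", function(object) {
  s <- object@summary
  cat(sprintf(
    "SimulationResult: %d fibrils (mode %s, seed %d)\n",
    object@config@count, object@config@mode, object@config@seed))
  cat(sprintf("  perfect fraction  %.5f (se %.5f)\n",
              s$perfect_fraction, s$perfect_se))
  cat(sprintf("  one-error fraction %.5f (se %.5f)\n",
              s$one_error_fraction, s$one_error_se))
})

#' Compare an ensemble with the exact sequence distribution
#'
#' Quantifies how far an empirical ensemble sits from an exact enumerated
#' distribution: total-variation distance over all `2^N` sequences, a
#' chi-square goodness-of-fit statistic against the model's expected counts
#' (degrees of freedom `2^N - 1`), and a per-pattern-class z-score for every
#' alternation distance class. The local growth modes match the exact Gibbs
#' law at `p = 0.5` but drift from it at other `p` — this report is how that
#' drift is surfaced rather than hidden.
#'
#' `result` may also be a second [SequenceDistribution-class], in which case
#' only the analytic total-variation distance is reported (chi-square is not
#' applicable without sampling noise).
#'
#' @param result a [SimulationResult-class] (or a second
#'   [SequenceDistribution-class]).
#' @param dist a [SequenceDistribution-class] with the same `N`.
#' @return a list: `tv` (total variation), `chisq`
#'   (list `statistic`, `df`, `p_value`; `NULL` for analytic comparisons),
#'   `classes` (data.frame of distance class, expected and observed
#'   fractions, z-score).
#' @export
compareToExact <- function(result, dist) {
  stopifnot(is(dist, "SequenceDistribution"))
  n <- dist@params@N
  exact <- probabilities(dist)
  refw <- alternatingReferences(n)$w@types
  bits <- allSequenceBits(n)
  d_w <- as.vector(bits %*% (1L - refw) + (1L - bits) %*% refw)
  mind <- pmin(d_w, n - d_w)
  exact_class <- vapply(0:floor(n / 2), function(k)
    sum(exact[mind == k]), 0)

  if (is(result, "SequenceDistribution")) {
    if (result@params@N != n) stop("chain lengths differ")
    other <- probabilities(result)
    other_class <- vapply(0:floor(n / 2), function(k)
      sum(other[mind == k]), 0)
    return(list(
      tv = sum(abs(other - exact)) / 2, chisq = NULL,
      classes = data.frame(distance = 0:floor(n / 2),
                           expected = exact_class, observed = other_class,
                           z = NA_real_)))
  }

  stopifnot(is(result, "SimulationResult"))
  if (result@config@params@N != n) stop("chain lengths differ")
  m <- result@config@count
  emp <- numeric(2^n)
  emp[result@counts$index + 1] <- result@counts$count / m
  obs_class <- vapply(0:floor(n / 2), function(k)
    sum(emp[mind == k]), 0)
  z <- (obs_class - exact_class) /
    sqrt(exact_class * (1 - exact_class) / m)
  stat <- sum((emp * m - exact * m)^2 / (exact * m))
  df <- 2^n - 1
  list(
    tv = sum(abs(emp - exact)) / 2,
    chisq = list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
    classes = data.frame(distance = 0:floor(n / 2),
                         expected = exact_class, observed = obs_class, z = z))
}
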