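#' @import methods
NULL

#' FibrilSequence: an ordered binary sequence of molecule types
#'
#' Represents the order in which wildtype (wt) and variant (v) molecules were
#' deposited in a proto-fibril. Position 1 is the first molecule deposited.
#' Internally each position holds an indicator: 0 for wildtype, 1 for variant.
#' The string rendering uses the alphabet `w`/`v` with the leftmost character
#' at position 1.
#'
#' @slot types integer vector of 0/1 indicators, one per molecule.
#' @seealso [fibrilSequence()], [sequenceToIndex()], [indexToSequence()]
#' @export
setClass("FibrilSequence", representation(types = "integer"))

setValidity("FibrilSequence", function(object) {
  t <- object@types
  if (length(t) < 2L)
    return("a fibril sequence needs at least 2 molecules")
  if (anyNA(t) || !all(t %in% c(0L, 1L)))
    return("type indicators must all be 0 (wildtype) or 1 (variant)")
  TRUE
})

#' ModelParams: parameters of the fibril stacking model
#'
#' Bundles the chain length `N` (number of molecules in the proto-fibril),
#' the wildtype selection probability `p` (proportional to the wt:v
#' concentration ratio), the nearest-neighbour coupling `gamma`
#' (dimensionless; `gamma < 0` favours alternation of the two types), and an
#' absolute temperature in kelvin used only by the thermodynamic conversions.
#' The binding odds ratio is `exp(-2 * gamma)`: odds greater than 1 mean a
#' different-type attachment is favoured over a same-type one.
#'
#' @slot N integer chain length, at least 2.
#' @slot p wildtype selection probability, strictly between 0 and 1.
#' @slot gamma same-pair/different-pair coupling (dimensionless).
#' @slot temperature kelvin, strictly positive.
#' @seealso [modelParams()], [oddsRatio()], [oddsToGamma()]
#' @export
setClass("ModelParams", representation(
  N = "integer", p = "numeric", gamma = "numeric", temperature = "numeric"
))

setValidity("ModelParams", function(object) {
  msgs <- character()
  if (length(object@N) != 1L || is.na(object@N) || object@N < 2L)
    msgs <- c(msgs, "N must be a single integer >= 2")
  if (length(object@p) != 1L || is.na(object@p) ||
      object@p <= 0 || object@p >= 1)
    msgs <- c(msgs, "p must satisfy 0 < p < 1")
  if (length(object@gamma) != 1L || is.na(object@gamma) ||
      !is.finite(object@gamma))
    msgs <- c(msgs, "gamma must be a single finite number")
  if (length(object@temperature) != 1L || is.na(object@temperature) ||
      object@temperature <= 0)
    msgs <- c(msgs, "temperature must be positive (kelvin)")
  if (length(msgs)) msgs else TRUE
})

#' SequenceDistribution: the exact Gibbs law over all 2^N sequences
#'
#' Holds the normalised probability of every length-`N` type sequence,
#' indexed by the integer whose binary representation the sequence is
#' (see [sequenceToIndex()]), together with the partition constant `Z`
#' (the reciprocal of the model's proportionality constant).
#'
#' @slot params the [ModelParams-class] the distribution was enumerated under.
#' @slot prob numeric vector of length `2^N`; `prob[m + 1]` is the probability
#'   of the sequence with index `m`.
#' @slot Z the partition constant (sum of unnormalised sequence weights).
#' @seealso [enumerateDistribution()], [spectrum()]
#' @export
setClass("SequenceDistribution", representation(
  params = "ModelParams", prob = "numeric", Z = "numeric"
))

setValidity("SequenceDistribution", function(object) {
  n <- object@params@N
  if (length(object@prob) != 2^n)
    return(sprintf("probability vector must have length 2^N = %d", 2^n))
  if (any(object@prob < 0))
    return("probabilities must be non-negative")
  if (abs(sum(object@prob) - 1) > 1e-12)
    return("probabilities must sum to 1 within 1e-12")
  if (length(object@Z) != 1L || object@Z <= 0)
    return("Z must be a single positive number")
  TRUE
})

#' SweepTable: pattern fractions along a parameter grid
#'
#' One row per grid point of either the binding odds ratio or the
#' variant:wildtype concentration ratio, carrying the fraction of fibrils
#' that are perfectly alternating, the fraction one error away from
#' alternation, and the enrichment fold over the random reference
#' (p = 0.5, coupling 0).
#'
#' @slot axis `"odds"` or `"ratio"` — the swept quantity.
#' @slot table data.frame with columns `axis_value`, `gamma`,
#'   `perfect_fraction`, `one_error_fraction`, `enrichment`.
#' @slot N chain length used for every row.
#' @seealso [sweepOdds()], [sweepRatio()]
#' @export
setClass("SweepTable", representation(
  axis = "character", table = "data.frame", N = "integer"
))

setValidity("SweepTable", function(object) {
  if (!object@axis %in% c("odds", "ratio"))
    return("axis must be 'odds' or 'ratio'")
  need <- c("axis_value", "gamma", "perfect_fraction",
            "one_error_fraction", "enrichment")
  if (!all(need %in% names(object@table)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  tb <- object@table
  if (is.unsorted(tb$axis_value, strictly = TRUE))
    return("grid values must be strictly increasing")
  fr <- c(tb$perfect_fraction, tb$one_error_fraction)
  if (any(fr < -1e-15 | fr > 1 + 1e-15))
    return("fractions must lie in [0, 1]")
  TRUE
})

#' GrowthConfig: configuration of a stochastic growth run
#'
#' Describes a seeded ensemble of fibril growth simulations: the model
#' parameters, the growth mode, the ensemble size, and optional
#' position-dependent overrides representing a tissue-templated surface
#' (per-bond couplings and per-position selection probabilities).
#'
#' Modes: `"local_conditional"` draws each added molecule from the
#' conditional implied by the selection probability and the bond to the
#' current end molecule; `"local_rejection"` proposes from the selection
#' probability and accepts with a bond-dependent probability, re-sampling on
#' rejection (the two are the same law); `"gibbs_exact"` samples the full
#' globally-normalised Gibbs distribution by backward transfer-matrix
#' conditionals.
#'
#' @slot params the [ModelParams-class].
#' @slot mode one of `"local_conditional"`, `"local_rejection"`,
#'   `"gibbs_exact"`.
#' @slot siteGammas numeric of length `N - 1` (per-bond couplings) or
#'   length 0 to use the homogeneous `gamma`.
#' @slot sitePs numeric of length `N` (per-position wildtype selection
#'   probabilities) or length 0 to use the homogeneous `p`.
#' @slot seed integer root seed.
#' @slot count ensemble size, at least 1.
#' @seealso [growthConfig()], [simulateEnsemble()]
#' @export
setClass("GrowthConfig", representation(
  params = "ModelParams", mode = "character", siteGammas = "numeric",
  sitePs = "numeric", seed = "integer", count = "integer"
))

setValidity("GrowthConfig", function(object) {
  n <- object@params@N
  if (!object@mode %in% c("local_conditional", "local_rejection",
                          "gibbs_exact"))
    return("mode must be local_conditional, local_rejection or gibbs_exact")
  if (length(object@siteGammas) && length(object@siteGammas) != n - 1L)
    return(sprintf("siteGammas must have length N - 1 = %d", n - 1L))
  if (length(object@sitePs)) {
    if (length(object@sitePs) != n)
      return(sprintf("sitePs must have length N = %d", n))
    if (any(object@sitePs <= 0 | object@sitePs >= 1))
      return("sitePs must all satisfy 0 < p < 1")
  }
  if (length(object@count) != 1L || is.na(object@count) || object@count < 1L)
    return("count must be a single integer >= 1")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed must be a single integer")
  TRUE
})

#' SimulationResult: a seeded Monte Carlo ensemble summary
#'
#' Empirical sequence-index frequencies from an ensemble of simulated
#' fibrils, with the configuration that produced them and binomial summary
#' statistics for the perfectly alternating and one-error pattern classes.
#'
#' @slot config the [GrowthConfig-class] used.
#' @slot counts data.frame with columns `index` (integer sequence index) and
#'   `count` (number of fibrils observed at that index); indices ascending.
#' @slot summary named list: `perfect_fraction`, `perfect_se`,
#'   `one_error_fraction`, `one_error_se`.
#' @seealso [simulateEnsemble()], [compareToExact()]
#' @export
setClass("SimulationResult", representation(
  config = "GrowthConfig", counts = "data.frame", summary = "list"
))

setValidity("SimulationResult", function(object) {
  cts <- object@counts
  if (!all(c("index", "count") %in% names(cts)))
    return("counts must have columns index, count")
  if (sum(cts$count) != object@config@count)
    return("counts must sum to the ensemble size")
  if (is.unsorted(cts$index, strictly = TRUE))
    return("indices must be strictly increasing")
  TRUE
})
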