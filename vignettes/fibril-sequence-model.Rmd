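---
title: "A nearest-neighbour sequence model of amyloid proto-fibril assembly"
author: "fibrilseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A nearest-neighbour sequence model of amyloid proto-fibril assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilseq)
```

## The model

Transthyretin (TTR) amyloid fibrils are stacks of misfolded, cross-β-sheet
protein molecules. When both wildtype (wt) and variant (v) molecules
circulate, the *order* in which the two types stack determines the array of
side chains presented on the fibril surface, and with it which tissues the
fibril can bind. `fibrilseq` models that order directly.

A proto-fibril of `N` molecules is a binary sequence
$\sigma = (\sigma_1, \dots, \sigma_N)$ with $\sigma_i = 0$ for wildtype and
$1$ for variant, position 1 being the first molecule deposited. The model
assigns each sequence the Gibbs weight

$$
w(\sigma) \;=\;
p^{1-\sigma_1}(1-p)^{\sigma_1}
\prod_{i=2}^{N} p^{1-\sigma_i}(1-p)^{\sigma_i}\,
e^{\gamma\,s_i s_{i-1}},
\qquad s_i = 1 - 2\sigma_i \in \{+1, -1\},
$$

and the probability $w(\sigma) / Z$ with $Z = \sum_\sigma w(\sigma)$. This
is a one-dimensional Ising chain with field set by the selection
probability `p` (proportional to the wt:v concentration ratio) and
nearest-neighbour coupling `gamma`: each same-type adjacency is reweighted
by $e^{\gamma}$ and each different-type adjacency by $e^{-\gamma}$, so
$\gamma < 0$ favours strict alternation of the two types. The *odds ratio*
of a different-type over a same-type attachment is
$e^{-\gamma}/e^{\gamma} = e^{-2\gamma}$; odds of 1 mean no selectivity.

Sequences are identified with integers by reading the indicators as binary
digits, $m = \sum_i \sigma_i 2^{i-1}$, so the all-wildtype sequence is
index 0, the all-variant sequence is $2^N - 1$, and for $N = 12$ the two
perfectly alternating sequences sit at 1365 (variant first) and 2730
(wildtype first). Spectra plotted over this index make structured fibrils
visible as isolated spikes.

### Assumptions

* Exactly two molecule types. Proteolytic fragments or other co-aggregating
  species would have to be treated as one of the two types; the package
  does not model a third.
* Interactions are nearest-neighbour along the stack; no 2D sheet lattices.
* Selection is stationary: `p` and `gamma` do not change as the fibril
  grows, except through the explicit tissue-templated overrides
  (`sitePs`, `siteGammas`), which make the field position-dependent but
  still nearest-neighbour.
* The thermodynamic layer treats the odds ratio as the equilibrium constant
  of the end-molecule exchange reaction with fibril phases at unit
  activity, giving $\Delta G^\circ = -RT \ln(\text{odds})$.

## Parameters

| parameter | meaning | units | default |
|---|---|---|---|
| `N` | molecules per proto-fibril | count | 12 |
| `p` | wildtype selection probability | — | 0.5 |
| `gamma` | same/different-pair coupling | — | 0 |
| `odds` | $e^{-2\gamma}$, alternative to `gamma` | — | — |
| `temperature` | used only by energy conversions | K | 310.15 |

`N = 12` is the worked default: it is in the size range of a circulating
proto-fibril (large enough to present a recognisable surface, small enough
to circulate) and keeps exhaustive enumeration of all $2^N$ sequences
instant. The variant:wildtype concentration ratio `r` enters as
`p = 1 / (1 + r)`; `sweepRatio()` applies this mapping. The temperature
default is physiological (310.15 K); the Gibbs-energy line
$-RT\ln(\text{odds})$ is configurable in `T`, and the familiar reference
point — odds of 2 corresponding to roughly 2 kJ/mol, about one weak
hydrogen bond — holds at one significant figure anywhere between 273 and
320 K.

## Exact machinery

Three routes to the same distribution are implemented and cross-checked:

* **Enumeration** (`enumerateDistribution`, `spectrum`): explicit
  tabulation of all $2^N$ probabilities, capped at `N <= 22` where the
  table itself becomes the memory cost.
* **Transfer matrix** (`partitionFunction`, `sequenceProbability`): $Z$ as
  a product of $2\times2$ matrices, linear in `N`, no cap. At `p = 0.5` it
  collapses to the closed form $Z = 2\,(2\cosh\gamma)^{N-1}/2^N$, which the
  test suite verifies to relative $10^{-12}$.
* **Dynamic programme** (`patternFractionDP`): pattern-class masses for
  arbitrary `N` by propagating weight over (position, current type,
  mismatches against the starts-with-wildtype alternating reference).
  Because the Hamming distances to the two alternating references sum to
  `N`, folding that profile at `N/2` yields the minimum-distance law with
  no double counting, including the tie class at distance `N/2` for even
  `N`, which is counted once.

Numerical choices: weights are computed in log space; enumeration
normalises through a log-sum-exp; the transfer matrix and the DP rescale
at every position and so run at any `N` without overflow. All exactness
claims in the tests are asserted at $10^{-12}$ relative tolerance;
Monte Carlo claims at four binomial standard errors.

## Pattern statistics

A fibril's distance from perfect alternation is the minimum Hamming
distance to the two alternating references (`minAlternationDistance`).
There are always exactly two perfect sequences, $2\binom{N}{k}$ sequences
at distance $k < N/2$, and $\binom{N}{N/2}$ at the tie distance. The
quantitative surfaces are:

* `perfectFraction` — total mass of the two perfect sequences. At
  `N = 12`, `p = 0.5` it is 2/4096 ≈ 0.00049 with no selectivity, ≈ 0.0036
  at odds 1.5, ≈ 0.086 at odds 4 and ≈ 0.35 at odds 10: modest pairwise
  selectivity concentrates a macroscopic share of all fibrils onto two
  sequences out of 4096.
* `kErrorFraction` / `patternFractionDP` — mass of each distance class.
  One-error fibrils split into end flips (probability $e^{2\gamma}$ times a
  perfect sequence — one bond changed) and interior flips ($e^{4\gamma}$ —
  two bonds changed); the class totals report both together, and the
  per-sequence probabilities expose the split.
* `enrichment` — perfect fraction over the no-selectivity reference
  $2/2^N$ at `p = 0.5`, the flat line a spectrum is judged against. The
  reference stays fixed at (`gamma = 0`, `p = 0.5`) even when the query `p`
  differs, so enrichment always answers "how much more likely than blind
  chance". Quoting intermediate probabilities at two significant figures
  before taking the ratio gives 7.37 at odds 1.5; the unrounded ratio is
  7.43. `enrichment(..., roundSigfigs = 2)` reproduces the former
  convention, the default the latter, and both are reported side by side
  where it matters.
* `sweepOdds`, `sweepRatio` — the two one-parameter families. The ratio
  sweep is symmetric under $r \leftrightarrow 1/r$ (relabelling the types)
  and peaks at $r = 1$; at odds 4 that peak is 0.086. `r = 0` is the
  degenerate no-variant limit and returns zero for both pattern classes.
* `motifFraction` — mass of all cyclic tilings of a longer repeat such as
  `wwv`, since alternation is not the only orderable surface.

## The growth simulator

The stacking story — seed with one molecule, then repeatedly select a type
(Bernoulli in `p`) and attach it with a bond-dependent likelihood — is a
*local* Markov process. Its stationary conditionals
$P(\sigma_i \mid \sigma_{i-1}) \propto a(\sigma_i)\,e^{\gamma s_i s_{i-1}}$
coincide with the exact conditionals of the global Gibbs law at
`p = 0.5`, but not at other `p`, where the global law also feels the field
through the backward messages. The package therefore ships both and never
silently substitutes one for the other:

* `local_conditional` — draw each added type from the local conditional.
* `local_rejection` — propose from `p`, accept with
  $e^{\gamma s s'}/e^{|\gamma|}$ (always ≤ 1), re-sample on rejection.
  Rejection re-samples the molecule type rather than aborting growth, the
  reading under which the scheme normalises to exactly the
  `local_conditional` law — the two modes are one distribution, which the
  suite checks by chi-square.
* `gibbs_exact` — backward transfer-matrix conditionals; i.i.d. exact
  draws from the global law for any `N`, homogeneous or tissue-templated.
  This is the default and the mode used wherever results are validated
  against exact numbers.

`compareToExact` reports total-variation distance, a chi-square
goodness-of-fit statistic and per-distance-class z-scores, so the drift of
the local modes away from the global law off the symmetric point is
measured and surfaced rather than hidden.

**Randomness.** An ensemble is seeded once (`seed` in `growthConfig`) and
drawn position-major: all first molecules, then all second molecules, and
so on, vectorised across the ensemble. Identical (seed, config) pairs
reproduce results bit for bit, which is the reproducibility contract the
package makes; per-fibril independent streams were considered and set
aside because the position-major order makes the ensemble a single
vectorised computation at no cost to that contract.

**Tissue templating.** A fibril growing *in situ* on a tissue surface is
selected by the tissue site as well as by its end molecule. The minimal
faithful extension is a position-dependent field: per-position selection
probabilities (`sitePs`, length `N`) and per-bond couplings (`siteGammas`,
length `N - 1`). Constant overrides reproduce the homogeneous model
exactly; no specific functional form for tissue affinity is assumed beyond
that.

## What the simulations do and do not show

The generator draws from the model itself, so passing tests demonstrate
internal correctness — that the samplers, the enumeration, the transfer
matrix and the DP are one distribution — and that the printed quantitative
claims follow from the model. They cannot show that real fibril ensembles
obey a nearest-neighbour law: no fibril fragmentation, secondary
nucleation, growth kinetics, spatial diffusion, more than two molecule
types, or fitting of (`p`, `gamma`) to measured fibril compositions is
modelled. Problem sizes used throughout the suite — exhaustive checks at
`N ≤ 14`, DP spot checks at `N = 30` and `50`, Monte Carlo ensembles of
$2\times10^5$ fibrils — were chosen so every exact claim is checked
against an independent route and every stochastic claim sits well inside
four standard errors.

## Known limitations

* Two types only; co-aggregating fragments must be mapped onto one of them.
* The local growth modes are *not* the global Gibbs law away from
  `p = 0.5`; quantitative claims validated here use `gibbs_exact`, and
  `compareToExact` exists precisely to quantify the gap.
* Enumeration-backed operations stop at `N = 22`; beyond that only
  transfer-matrix, DP and sampling paths are available.
* The energy map is a pure $-RT\ln(\text{odds})$ conversion; it does not
  decompose the effective bond into specific interaction types.
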