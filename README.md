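# fibrilseq

Statistical modelling of the order in which wildtype (wt) and variant (v)
protein molecules stack into amyloid proto-fibrils.

## The problem

Transthyretin (TTR) amyloidosis is driven by fibrils of misfolded,
cross-β-sheet TTR molecules. When a destabilising mutation puts both
wildtype and variant molecules in circulation, the *sequence* in which the
two types stack fixes the array of amino-acid side chains on the fibril
surface — and with it the fibril's complementarity to particular tissue
surfaces. The question this package makes quantitative is: how easily does
plain stacking, with a modest pairwise preference for wt–v contacts,
produce *structured* (e.g. strictly alternating) fibrils rather than random
ones?

`fibrilseq` is for structural bioinformaticians and modellers who want the
exact machinery behind that question: the sequence distribution, its
pattern statistics, the thermodynamic scale of the preference, and a
stochastic growth simulator.

## The model

A proto-fibril of `N` molecules is a binary sequence
σ = (σ₁, …, σ_N), σᵢ ∈ {0 (wt), 1 (v)}, with Gibbs probability

    Prob(σ) = c · p^(1−σ₁)(1−p)^(σ₁) · ∏_{i=2..N} p^(1−σᵢ)(1−p)^(σᵢ) · exp(γ sᵢ sᵢ₋₁),

where sᵢ = 1 − 2σᵢ, `p` is the wildtype selection probability
(proportional to the wt:v concentration ratio), and `γ` is a
nearest-neighbour coupling — a 1D Ising chain over molecule types. A
same-type contact is reweighted by e^γ and a different-type contact by
e^(−γ), so the *odds ratio* of a correct (alternating) over an incorrect
attachment is `odds = exp(−2γ)`; `γ < 0` favours alternation. The odds
double as an equilibrium constant for the end-molecule exchange reaction,
giving the energy scale ΔG° = −RT ln(odds).

Sequences map to integers by reading σ as binary digits
(index = Σ σᵢ 2^(i−1)), so a probability spectrum over 0…2^N − 1 shows
structured fibrils as spikes: for N = 12 the two perfectly alternating
sequences sit at indices 1365 and 2730.

Everything is computed three mutually cross-checked ways: exhaustive
enumeration (N ≤ 22), a transfer matrix (any N), and a dynamic programme
over alternation-distance classes (any N). A seeded simulator grows fibril
ensembles molecule by molecule, either by the local stacking conditionals
or by exact global-Gibbs sampling, and `compareToExact()` measures the
difference.

## Worked example

```r
library(fibrilseq)

mp <- modelParams(N = 12, p = 0.5, odds = 1.5)
mp
#> ModelParams: N = 12, p(wt) = 0.5, gamma = -0.202733 (odds ratio 1.5), T = 310.15 K

alt <- fibrilSequence("vwvwvwvwvwvw")   # variant-first alternating 12-mer
sequenceToIndex(alt)
#> [1] 1365
sequenceProbability(alt, mp)
#> [1] 0.001814
```

With odds of only 1.5 — a wt–v contact just 50% likelier than wt–wt or
v–v — each perfectly alternating sequence already carries probability
0.0018, against a no-selectivity baseline of 1/4096 ≈ 0.00024 per
sequence (0.00049 for the pair):

```r
perfectFraction(mp)                     # both alternating orders together
#> [1] 0.003628
enrichment(mp)                          # fold over the random reference
#> [1] 7.43
enrichment(mp, roundSigfigs = 2)        # quoting 2-s.f. intermediates
#> [1] 7.37
```

Sweeping the odds shows how fast stacking selectivity concentrates mass
onto two sequences out of 4096 — 8.6% of all fibrils at odds 4, 35% at
odds 10 — while the energy scale stays within about one hydrogen bond:

```r
sweepFrame(sweepOdds(c(1, 1.5, 4, 10)))
#>   axis_value  gamma perfect_fraction one_error_fraction enrichment
#> 1        1.0  0.000         0.000488            0.00586       1.00
#> 2        1.5 -0.203         0.003628            0.02096       7.43
#> 3        4.0 -0.693         0.085899            0.09664     175.92
#> 4       10.0 -1.151         0.350494            0.10515     717.81

energyMap(c(1, 1.5, 2, 4), temperature = 310)[, c("odds", "gamma", "delta_G_kJ_per_mol")]
#>   odds      gamma delta_G_kJ_per_mol
#> 1  1.0  0.0000000           0.000000
#> 2  1.5 -0.2027326          -1.045021
#> 3  2.0 -0.3465736          -1.786476
#> 4  4.0 -0.6931472          -3.572952
```

A seeded Monte Carlo ensemble agrees with the exact law:

```r
simulateEnsemble(growthConfig(modelParams(N = 12, p = 0.5, odds = 4),
                              seed = 1, count = 200000))
#> SimulationResult: 200000 fibrils (mode gibbs_exact, seed 1)
#>   perfect fraction  0.08640 (se 0.00063)
#>   one-error fraction 0.09706 (se 0.00066)
```

A command-line wrapper over the same functions ships at
`system.file("scripts", "fibrilseq", package = "fibrilseq")`, with
subcommands `enumerate`, `sweep-odds`, `sweep-ratio`, `thermo` and
`simulate`; every table comes with a JSON sidecar recording the full
configuration and seed.

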