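test_that("alternation distance classifies sequences as expected", {
  expect_equal(minAlternationDistance(fibrilSequence("vwvwvwvwvwvw"))$distance,
               0)
  expect_equal(minAlternationDistance(fibrilSequence("wvwvwvwvwvwv"))$distance,
               0)
  # one interior flip of an alternating 12-mer
  flipped <- c(1L, 0L, 1L, 1L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L)
  expect_equal(minAlternationDistance(fibrilSequence(flipped))$distance, 1)
  # all-wildtype: six mismatches to each reference, tied
  allw <- minAlternationDistance(fibrilSequence(rep(0, 12)))
  expect_equal(allw$distance, 6)
  expect_setequal(allw$nearest, c("w", "v"))

  # distances to the two references always sum to N
  set.seed(5)
  for (i in 1:20) {
    n <- sample(2:16, 1)
    cl <- minAlternationDistance(fibrilSequence(sample(0:1, n, TRUE)))
    expect_equal(cl$d_w + cl$d_v, n)
    expect_lte(cl$distance, floor(n / 2))
  }
})

test_that("k-error sequence counts match brute-force enumeration", {
  expect_equal(countKErrorSequences(12, 0), 2)
  expect_equal(countKErrorSequences(12, 1), 24)
  # ties at distance N/2 are counted once: all 16 words of length 4
  expect_equal(countKErrorSequences(4, 2), 6)
  expect_equal(sum(vapply(0:4, function(k) bruteMinDistance(k, 4) == 2,
                          NA)), 2) # sanity on the oracle itself
  for (n in c(2:8, 12, 14)) {
    counted <- vapply(0:n, function(k) countKErrorSequences(n, k), 0)
    brute <- table(factor(vapply(0:(2^n - 1), bruteMinDistance, 0, N = n),
                          levels = 0:n))
    expect_equal(counted, as.numeric(brute))
    expect_equal(sum(counted), 2^n)
  }
})

test_that("perfect-alternation fraction reproduces the printed sweep points", {
  expect_equal(perfectFraction(modelParams(N = 12, p = 0.5, gamma = 0)),
               2 / 4096, tolerance = 1e-12)
  expect_equal(perfectFraction(modelParams(N = 12, p = 0.5, odds = 4)),
               0.086, tolerance = 5e-3)
  pf10 <- perfectFraction(modelParams(N = 12, p = 0.5, odds = 10))
  expect_gt(pf10, 0.30)
  expect_equal(pf10, 2 * 10^5.5 / (2 * (2 * cosh(log(10) / 2))^11),
               tolerance = 1e-12)
  # closed form for even N at general p
  mp <- modelParams(N = 10, p = 0.35, gamma = -0.3)
  expect_equal(perfectFraction(mp),
               2 * 0.35^5 * 0.65^5 * exp(9 * 0.3) / partitionFunction(mp),
               tolerance = 1e-12)
  # invariance under p <-> 1 - p
  expect_equal(perfectFraction(modelParams(N = 12, p = 0.2, gamma = -0.5)),
               perfectFraction(modelParams(N = 12, p = 0.8, gamma = -0.5)),
               tolerance = 1e-12)
})

test_that("k-error fractions sum to one and match per-sequence arithmetic", {
  mp <- modelParams(N = 12, p = 0.5, odds = 1.5)
  expect_equal(kErrorFraction(mp, 0), perfectFraction(mp), tolerance = 1e-12)
  total <- sum(vapply(0:12, function(k) kErrorFraction(mp, k), 0))
  expect_equal(total, 1, tolerance = 1e-12)
  # uniform law: the 24 one-error words carry 24/4096
  expect_equal(kErrorFraction(modelParams(N = 12, p = 0.5, gamma = 0), 1),
               24 / 4096, tolerance = 1e-12)

  # an end flip costs one bond sign: e^(2 gamma) times the perfect sequence;
  # an interior flip costs two bonds: e^(4 gamma)
  g <- -log(1.5) / 2
  alt <- fibrilSequence("vwvwvwvwvwvw")
  endflip <- fibrilSequence("wwvwvwvwvwvw")
  intflip <- fibrilSequence("vwwwvwvwvwvw")
  p_alt <- sequenceProbability(alt, mp)
  expect_equal(sequenceProbability(endflip, mp), p_alt * exp(2 * g),
               tolerance = 1e-12)
  expect_equal(sequenceProbability(endflip, mp), 0.00121, tolerance = 5e-3)
  expect_equal(sequenceProbability(intflip, mp), p_alt * exp(4 * g),
               tolerance = 1e-12)
})

test_that("the DP fraction path agrees with enumeration and closed forms", {
  for (r in seq_len(nrow(paramGrid))) {
    mp <- modelParams(N = paramGrid$N[r], p = paramGrid$p[r],
                      gamma = paramGrid$gamma[r])
    for (k in 0:min(2, floor(paramGrid$N[r] / 2)))
      expect_equal(patternFractionDP(mp, k),
                   kErrorFraction(mp, k, "enumeration"), tolerance = 1e-12)
  }
  expect_equal(patternFractionDP(modelParams(N = 50, p = 0.5, gamma = 0), 0),
               2 / 2^50, tolerance = 1e-12)
  mp30 <- modelParams(N = 30, p = 0.5, gamma = -log(4) / 2)
  expect_equal(patternFractionDP(mp30, 0),
               2 * exp(29 * log(4) / 2) * 0.5^30 / partitionFunction(mp30),
               tolerance = 1e-12)
})

test_that("enrichment over the random reference matches both conventions", {
  expect_equal(enrichment(modelParams(N = 12, p = 0.5, gamma = 0)), 1,
               tolerance = 1e-12)
  mp <- modelParams(N = 12, p = 0.5, odds = 1.5)
  expect_equal(enrichment(mp, roundSigfigs = 2), 7.37, tolerance = 1e-2)
  expect_equal(enrichment(mp), 7.43, tolerance = 1e-2)
  expect_gte(enrichment(modelParams(N = 12, p = 0.5, odds = 4)), 175)
})

test_that("odds sweeps rise monotonically from the random baseline", {
  sw <- sweepFrame(sweepOdds(c(1, 1.5, 4, 10, 20)))
  expect_equal(sw$perfect_fraction[1], 2 / 4096, tolerance = 1e-12)
  expect_gt(sw$perfect_fraction[sw$axis_value == 10], 0.30)
  expect_true(all(diff(sw$perfect_fraction) > 0))
  sw2 <- sweepFrame(sweepOdds(1:20))
  expect_true(all(diff(sw2$perfect_fraction) > 0))
  expect_error(sweepOdds(c(-1, 2)), "positive")
})

test_that("ratio sweeps handle the no-variant limit and type symmetry", {
  sw <- sweepFrame(sweepRatio(c(0, 0.25, 0.5, 1, 2, 4), odds = 4))
  expect_equal(sw$perfect_fraction[sw$axis_value == 0], 0)
  expect_equal(sw$perfect_fraction[sw$axis_value == 1], 0.086,
               tolerance = 5e-3)
  # r and 1/r describe the same model with the labels swapped
  expect_equal(sw$perfect_fraction[sw$axis_value == 0.25],
               sw$perfect_fraction[sw$axis_value == 4], tolerance = 1e-12)
  expect_equal(sw$perfect_fraction[sw$axis_value == 0.5],
               sw$perfect_fraction[sw$axis_value == 2], tolerance = 1e-12)
})

test_that("the spectrum table is a normalised, reference-lined distribution", {
  sp <- spectrum(modelParams(N = 12, p = 0.5, odds = 1.5))
  expect_equal(nrow(sp), 4096)
  expect_equal(sum(sp$probability), 1, tolerance = 1e-12)
  expect_true(all(sp$reference_level == 1 / 4096))
  expect_setequal(sp$index[rank(-sp$probability) <= 2], c(1365, 2730))
  flat <- spectrum(modelParams(N = 8, p = 0.5, gamma = 0))
  expect_equal(flat$probability, rep(1 / 256, 256), tolerance = 1e-12)
  # string column round-trips through the index
  i <- c(1, 100, 256)
  expect_equal(vapply(flat$sequence[i], function(s)
    sequenceToIndex(fibrilSequence(s)), 0, USE.NAMES = FALSE),
    flat$index[i])
})

test_that("motif tilings aggregate the right sequences", {
  mp <- modelParams(N = 12, p = 0.5, odds = 1.5)
  expect_equal(motifFraction(mp, "wv"), perfectFraction(mp),
               tolerance = 1e-12)
  expect_equal(motifFraction(mp, "w"),
               sequenceProbability(fibrilSequence(rep(0, 12)), mp),
               tolerance = 1e-12)
  expect_error(motifFraction(mp, "wx"), "may only contain")

  # period-3 motif against a brute-force sum over enumerated sequences
  sp <- spectrum(mp)
  tile <- function(motif, shift) {
    ch <- strsplit(motif, "")[[1]]
    paste(ch[((0:11 + shift) %% 3) + 1], collapse = "")
  }
  targets <- unique(vapply(0:2, function(s) tile("wwv", s), ""))
  expect_equal(motifFraction(mp, "wwv"),
               sum(sp$probability[sp$sequence %in% targets]),
               tolerance = 1e-12)
})
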