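# Synthetic polysomnography generator: Markov hypnograms, stage-dependent
# spectra, the scalp-to-ear shift, and cohort structure.

test_that("transition model validity is enforced", {
  P <- matrix(0.2, 5, 5)
  expect_silent(new("TransitionModel", initial = c(1, 0, 0, 0, 0),
                    transition = P))
  P[1, 1] <- 0.5
  expect_error(new("TransitionModel", initial = c(1, 0, 0, 0, 0),
                   transition = P), "sum to 1")
  expect_error(new("TransitionModel", initial = c(2, 0, 0, 0, 0),
                   transition = matrix(0.2, 5, 5)), "sum to 1")
})

test_that("hypnogram generation follows the chain and is seed-deterministic", {
  absorbing <- new("TransitionModel", initial = c(1, 0, 0, 0, 0),
                   transition = diag(5))
  h <- generateHypnogram(10, absorbing, seed = 1)
  expect_identical(as.character(stages(h)), rep("W", 10))

  h1 <- generateHypnogram(200, seed = 42)
  h2 <- generateHypnogram(200, seed = 42)
  expect_identical(stages(h1), stages(h2))
  expect_false(identical(stages(h1), stages(generateHypnogram(200, seed = 43))))
})

test_that("empirical one-step transition frequencies match the model", {
  # Monte-Carlo check of the default preset: pooled transition counts across
  # many seeded nights stay within 3 binomial s.e. of the specified rows
  model <- defaultTransitionModel()
  nEp <- 400; nSeeds <- 60
  counts <- matrix(0, 5, 5)
  for (s in seq_len(nSeeds)) {
    codes <- stageCodes(stages(generateHypnogram(nEp, model, seed = s))) + 1
    for (i in seq_len(nEp - 1))
      counts[codes[i], codes[i + 1]] <- counts[codes[i], codes[i + 1]] + 1
  }
  rowN <- rowSums(counts)
  for (i in 1:5) {
    phat <- counts[i, ] / rowN[i]
    se <- sqrt(model@transition[i, ] * (1 - model@transition[i, ]) / rowN[i])
    expect_true(all(abs(phat - model@transition[i, ]) <= 3 * se + 1e-12),
                info = sprintf("row %d", i))
  }
})

test_that("epoch generator is seeded, stage-checked and respects null weights", {
  expect_error(generateEpochSignal("XX"), "unknown stage")
  x1 <- generateEpochSignal("N2", fs = 128, seed = 7)
  x2 <- generateEpochSignal("N2", fs = 128, seed = 7)
  expect_identical(x1, x2)
  expect_length(x1, 30 * 128)

  nullProfile <- new("StageSpectralProfile",
                     bandWeights = setNames(rep(0, 6), bandDefinitions()$name),
                     spindleFreq = 13.5, spindleDur = 1, spindleRate = 0,
                     spindleAmp = 0, slowWaveScale = 1, weightJitter = 0,
                     noiseFloor = 0)
  z <- generateEpochSignal("W", nullProfile, scalpShift(), fs = 128, seed = 1)
  expect_identical(z, rep(0, 30 * 128))
})

test_that("stage-conditional delta power ranks N3 > N2 > {N1, REM} > W", {
  relDelta <- function(stage, shift, seeds) {
    vapply(seeds, function(s) {
      f <- spectralFeatures(generateEpochSignal(stage, shift = shift,
                                                fs = 128, seed = s), 128)
      f[["sdelta"]] + f[["fdelta"]]
    }, numeric(1))
  }
  seeds <- 1:120
  m <- vapply(stageLevels(), function(st)
    mean(relDelta(st, scalpShift(), seeds)), numeric(1))
  expect_gt(m[["N3"]], m[["N2"]])
  expect_gt(m[["N2"]], max(m[["N1"]], m[["REM"]]))
  expect_gt(min(m[["N1"]], m[["REM"]]), m[["W"]])

  # alpha+beta relative power is maximal in wake
  relAB <- vapply(stageLevels(), function(st) {
    mean(vapply(seeds[1:60], function(s) {
      f <- spectralFeatures(generateEpochSignal(st, fs = 128, seed = s), 128)
      f[["alpha"]] + f[["beta"]]
    }, numeric(1)))
  }, numeric(1))
  expect_identical(names(which.max(relAB)), "W")

  # the designed domain shift: ear N3 epochs carry less relative delta
  earDelta <- relDelta("N3", earShift(), seeds)
  scalpDelta <- relDelta("N3", scalpShift(), seeds)
  expect_lt(median(earDelta), median(scalpDelta))
})

test_that("cohort generation is reproducible with consistent structure", {
  co <- generateCohort(3, 40, seed = 21)
  expect_length(co, 3)
  for (s in co) {
    expect_length(s$hypnogram, 40)
    expect_named(s$recordings, c("scalp", "ear"))
    expect_length(samples(s$recordings$scalp), 40 * 30 * 256)
  }
  expect_identical(vapply(co, `[[`, character(1), "subjectId"),
                   c("s01", "s02", "s03"))

  co2 <- generateCohort(3, 40, seed = 21)
  expect_identical(samples(co[[2]]$recordings$ear),
                   samples(co2[[2]]$recordings$ear))
  expect_identical(stages(co[[3]]$hypnogram), stages(co2[[3]]$hypnogram))

  scalpOnly <- generateCohort(2, 10, modalities = "scalp", seed = 1)
  expect_named(scalpOnly[[1]]$recordings, "scalp")
})
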