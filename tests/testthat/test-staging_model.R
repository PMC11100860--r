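# Gradient-boosted stager: config validation, separable-oracle training,
# append-only fine-tuning, prediction contracts, LOSO mechanics.

test_that("staging config validates its fields", {
  cfg <- stagingConfig()
  expect_equal(cfg$nEstimators, 500L)
  expect_equal(cfg$maxDepth, 5L)
  expect_equal(cfg$numLeaves, 90L)
  expect_equal(cfg$featureFraction, 0.60)
  expect_equal(unname(cfg$classWeights),
               c(1, 2.2, 1, 1.2, 1.4))
  expect_error(stagingConfig(featureFraction = 0), "featureFraction")
  expect_error(stagingConfig(classWeights = c(W = 1, N1 = -1, N2 = 1,
                                              N3 = 1, REM = 1)), "positive")
})

test_that("training on separable features reaches perfect training accuracy", {
  sep <- separableFixture()
  pred <- predictStages(sep$model, sep$features)
  expect_identical(as.character(stages(pred$hypnogram)),
                   stageLevels()[sep$codes + 1])
  expect_equal(rowSums(pred$probabilities), rep(1, length(sep$codes)),
               tolerance = 1e-9)
})

test_that("training rejects malformed inputs and is seed-deterministic", {
  sep <- separableFixture()
  shortHyp <- Hypnogram(rep("W", 10))
  expect_error(pretrainStager(list(sep$features), list(shortHyp),
                              stagingConfig(nEstimators = 2L)), "mismatch")

  cfg <- stagingConfig(nEstimators = 10L, seed = 4L)
  m1 <- pretrainStager(list(sep$features), list(sep$hyp), cfg)
  m2 <- pretrainStager(list(sep$features), list(sep$hyp), cfg)
  expect_identical(dumpTrees(m1), dumpTrees(m2))
})

test_that("globally rescaling class weights leaves the model unchanged", {
  sep <- separableFixture()
  base <- stagingConfig(nEstimators = 8L, seed = 6L)
  doubled <- stagingConfig(nEstimators = 8L, seed = 6L,
                           classWeights = 2 * base$classWeights)
  m1 <- pretrainStager(list(sep$features), list(sep$hyp), base)
  m2 <- pretrainStager(list(sep$features), list(sep$hyp), doubled)
  expect_identical(dumpTrees(m1), dumpTrees(m2))
  expect_identical(predictStages(m1, sep$features)$probabilities,
                   predictStages(m2, sep$features)$probabilities)
})

test_that("fine-tuning is append-only and 0 rounds is a no-op", {
  fx <- smallCohortFeatures()
  cfg <- stagingConfig(nEstimators = 12L, finetuneRounds = 6L, seed = 1L)
  pre <- pretrainStager(fx$scalp[1:3], fx$hyps[1:3], cfg)

  noop <- finetuneStager(pre, fx$ear[1:3], fx$hyps[1:3],
                         stagingConfig(nEstimators = 12L, finetuneRounds = 0L))
  expect_identical(predictStages(noop, fx$ear[[4]])$probabilities,
                   predictStages(pre, fx$ear[[4]])$probabilities)

  fine <- finetuneStager(pre, fx$ear[1:3], fx$hyps[1:3], cfg)
  expect_equal(fine@nAppendedRounds, 6L)
  expect_equal(fine@nPretrainedRounds, 12L)
  # serialized pretrained tree section byte-identical after fine-tuning
  expect_identical(dumpTrees(fine, nRounds = 12L), dumpTrees(pre))
  # appended weight is a small fraction of the pretrained ensemble's
  expect_lt(fine@appendedWeightFraction, 1)
  expect_gt(fine@appendedWeightFraction, 0)

  # manifest mismatch is rejected with the offending names
  renamed <- FeatureTable({
    m <- featureMatrix(fx$ear[[1]]); colnames(m)[1] <- "bogus"; m
  })
  expect_error(finetuneStager(pre, list(renamed), fx$hyps[1],
                              cfg), "bogus")
})

test_that("prediction is row-wise, tie-stable and manifest-checked", {
  sep <- separableFixture()
  perm <- withr::with_seed(20, sample(nrow(featureMatrix(sep$features))))
  permuted <- FeatureTable(featureMatrix(sep$features)[perm, ])
  p1 <- predictStages(sep$model, sep$features)
  p2 <- predictStages(sep$model, permuted)
  expect_identical(p2$probabilities, p1$probabilities[perm, ])
  expect_identical(as.character(stages(p2$hypnogram)),
                   as.character(stages(p1$hypnogram))[perm])

  onecol <- FeatureTable(matrix(1, 3, 1, dimnames = list(NULL, "code")))
  expect_error(predictStages(sep$model, onecol), "missing")
})

test_that("LOSO produces one report pair per subject and flags tiny subjects", {
  fx <- smallCohortFeatures()
  cfg <- stagingConfig(nEstimators = 15L, finetuneRounds = 5L, seed = 2L)
  pre <- pretrainStager(fx$scalp, fx$hyps, cfg)
  lo <- losoEvaluate(fx$ear, fx$hyps, pre, cfg)
  expect_length(lo$reports, 4)
  expect_equal(nrow(lo$summary), 4)
  expect_true(all(c("accuracy_pre", "kappa_pre", "accuracy_fine",
                    "kappa_fine") %in% colnames(lo$summary)))
  expect_equal(lo$pairedTest$n, 4)

  tiny <- list(FeatureTable(featureMatrix(fx$ear[[1]])[1:5, ]), fx$ear[[2]],
               fx$ear[[3]])
  tinyHyp <- list(Hypnogram(as.character(stages(fx$hyps[[1]]))[1:5]),
                  fx$hyps[[2]], fx$hyps[[3]])
  expect_warning(lo2 <- losoEvaluate(tiny, tinyHyp, pre, cfg), "excluded")
  expect_length(lo2$reports, 2)
})

test_that("model serialization round-trips predictions and metadata", {
  sep <- separableFixture()
  path <- tempfile(fileext = ".json")
  writeStager(sep$model, path)
  back <- readStager(path)
  expect_equal(back@nPretrainedRounds, sep$model@nPretrainedRounds)
  expect_identical(back@featureManifest, sep$model@featureManifest)
  expect_equal(predictStages(back, sep$features)$probabilities,
               predictStages(sep$model, sep$features)$probabilities,
               tolerance = 1e-7)
})
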