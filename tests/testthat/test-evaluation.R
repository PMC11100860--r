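# Confusion/kappa oracles, degenerate branches, paired test behaviour and
# rendering.

test_that("confusion matrix and rates match the hand-counted example", {
  ref <- Hypnogram(c("W", "W", "N2", "N2"))
  pred <- Hypnogram(c("W", "N2", "N2", "N2"))
  r <- confusionAndRates(ref, pred)
  expect_equal(accuracy(r), 0.75)
  expect_equal(sensitivity(r)[["W"]], 0.5)
  expect_equal(precision(r)[["N2"]], 2 / 3)
  expect_equal(sum(confusionMatrix(r)), 4)
  expect_true(is.nan(sensitivity(r)[["N3"]]))  # absent stage: NaN, not 0

  perfect <- confusionAndRates(ref, ref)
  expect_equal(accuracy(perfect), 1)
  expect_equal(unname(sensitivity(perfect)[c("W", "N2")]), c(1, 1))

  wrong <- confusionAndRates(Hypnogram(rep("W", 3)), Hypnogram(rep("N1", 3)))
  expect_equal(accuracy(wrong), 0)

  expect_error(confusionAndRates(ref, Hypnogram(c("W", "W"))), "length")
})

test_that("Cohen's kappa matches hand computation and degenerate rules", {
  expect_equal(cohenKappa(c("W", "W", "N2", "N2"), c("W", "N2", "N2", "N2")),
               0.5)
  expect_equal(cohenKappa(c("W", "N1", "N2"), c("W", "N1", "N2")), 1)
  expect_equal(cohenKappa(rep("W", 5), rep("W", 5)), 1)  # p_e = 1, p_o = 1
  # disjoint constant sequences: p_e = 0, kappa 0 without ceremony
  expect_equal(cohenKappa(rep("W", 4), rep("N1", 4)), 0)

  # permutation null: kappa ~ 0
  hyp <- generateHypnogram(10000, seed = 16)
  shuf <- withr::with_seed(17, sample(as.character(stages(hyp))))
  expect_lt(abs(cohenKappa(hyp, Hypnogram(shuf))), 0.03)

  # invariance under consistent stage relabeling
  set.seed(18)
  a <- sample(stageLevels(), 500, replace = TRUE)
  b <- sample(stageLevels(), 500, replace = TRUE)
  mapping <- setNames(c("N3", "REM", "W", "N1", "N2"), stageLevels())
  expect_equal(cohenKappa(a, b), cohenKappa(mapping[a], mapping[b]),
               tolerance = 1e-12)
})

test_that("paired kappa test handles regular and degenerate branches", {
  same <- pairedKappaTest(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(same$p, 1)
  expect_equal(same$nImproved, 0L)

  expect_warning(
    const <- pairedKappaTest(c(0.5, 0.4, 0.6), c(0.6, 0.5, 0.7)),
    "constant nonzero")
  expect_equal(const$meanDifference, 0.1)
  expect_equal(const$p, 0)
  expect_equal(const$nImproved, 3L)

  reg <- pairedKappaTest(c(0.50, 0.42, 0.61, 0.55), c(0.60, 0.49, 0.70, 0.68))
  expect_equal(reg$p,
               t.test(c(0.60, 0.49, 0.70, 0.68) - c(0.50, 0.42, 0.61, 0.55))$p.value)
})

test_that("paired test power matches a reference t implementation", {
  # true shift 0.05, s.d. 0.02, n = 13: rejection rate at alpha 0.05 > 0.99
  set.seed(19)
  rej <- replicate(1000, {
    pre <- rnorm(13, 0.6, 0.05)
    fine <- pre + rnorm(13, 0.05, 0.02)
    pairedKappaTest(pre, fine)$p < 0.05
  })
  expect_gt(mean(rej), 0.99)
})

test_that("pooled accuracy equals the epoch-weighted mean of per-subject accuracy", {
  sep <- separableFixture()
  # simulate three subjects of different lengths from one prediction set
  pred <- predictStages(sep$model, sep$features)$hypnogram
  cuts <- list(1:100, 101:180, 181:300)
  reps <- lapply(cuts, function(idx)
    confusionAndRates(Hypnogram(as.character(stages(sep$hyp))[idx]),
                      Hypnogram(as.character(stages(pred))[idx])))
  pooled <- Reduce(`+`, lapply(reps, confusionMatrix))
  accPooled <- sum(diag(pooled)) / sum(pooled)
  accWeighted <- sum(vapply(seq_along(reps), function(i)
    accuracy(reps[[i]]) * length(cuts[[i]]), numeric(1))) / 300
  expect_equal(accPooled, accWeighted, tolerance = 1e-12)
})

test_that("night rendering writes a figure and rejects empty hypnograms", {
  co <- generateCohort(2, 6, modalities = "scalp", seed = 30)
  rec <- co[[1]]$recordings$scalp
  f1 <- tempfile(fileext = ".png")
  renderSummary(rec, co[[1]]$hypnogram, f1)
  expect_true(file.exists(f1) && file.size(f1) > 1000)

  emptyHyp <- new("Hypnogram", stages = factor(character(),
                                               levels = stageLevels()),
                  epochLength = 30)
  expect_error(renderSummary(rec, emptyHyp, tempfile()), "empty")

  # deterministic bytes given identical inputs and device settings
  f2 <- tempfile(fileext = ".png")
  renderSummary(rec, co[[1]]$hypnogram, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
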