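# Per-epoch feature set: closed forms, degenerate conventions, smoothing and
# the 65-column layout.

test_that("time-domain features match conventions and symmetries", {
  expect_identical(unname(timeDomainFeatures(rep(3, 10))), rep(0, 4))

  set.seed(1); x <- rnorm(500)^3  # skewed
  f <- timeDomainFeatures(x); fn <- timeDomainFeatures(-x)
  expect_equal(f[["std"]], fn[["std"]])
  expect_equal(f[["iqr"]], fn[["iqr"]])
  expect_equal(f[["kurt"]], fn[["kurt"]])
  expect_equal(f[["skew"]], -fn[["skew"]])

  set.seed(2); g <- rnorm(3000)
  fg <- timeDomainFeatures(g)
  expect_lt(abs(fg[["std"]] - 1), 0.1)
  expect_lt(abs(fg[["kurt"]]), 0.3)
})

test_that("non-linear features match closed forms", {
  fs <- 100; t <- (0:2999) / fs
  s <- sin(2 * pi * 1 * t)
  f <- nonlinearFeatures(s)
  expect_equal(f[["hmob"]], 2 * sin(pi * 1 / fs), tolerance = 1e-3)
  expect_equal(f[["hcomp"]], 1, tolerance = 1e-2)

  expect_equal(nonlinearFeatures(seq_len(200))[["perm"]], 0)
  expect_equal(nonlinearFeatures(seq(0, 1, length.out = 3000))[["higuchi"]],
               1, tolerance = 0.01)

  set.seed(3); wn <- rnorm(5000)
  fw <- nonlinearFeatures(wn)
  expect_equal(fw[["perm"]], 1, tolerance = 0.05)
  expect_equal(fw[["higuchi"]], 2, tolerance = 0.05)
  expect_true(fw[["petrosian"]] > 1 && fw[["petrosian"]] < 1.2)

  expect_warning(z <- nonlinearFeatures(rep(1, 200)), "zero-variance")
  expect_equal(z[["hmob"]], 0)
})

test_that("zero crossings use the carried-sign rule", {
  zc <- get(".zeroCrossings", asNamespace("earstage"))
  expect_equal(zc(c(1, -1, 1, -1)), 3)
  expect_equal(zc(c(1, 0, 1, -1)), 1)   # touch without crossing not counted
  expect_equal(zc(c(1, 0, -1)), 1)
  expect_equal(zc(rep(1, 5)), 0)
})

test_that("spectral features concentrate, normalize and scale correctly", {
  fs <- 100; t <- (0:2999) / fs
  f <- spectralFeatures(sin(2 * pi * 2 * t), fs)
  expect_gt(f[["fdelta"]], 0.95)
  expect_true(all(f[c("sdelta", "theta", "alpha", "sigma", "beta")] < 0.05))

  set.seed(4); x <- rnorm(3000)
  fx <- spectralFeatures(x, fs)
  expect_equal(sum(fx[bandDefinitions()$name]), 1, tolerance = 1e-9)

  f2 <- spectralFeatures(2 * x, fs)
  expect_equal(f2[bandDefinitions()$name], fx[bandDefinitions()$name])
  expect_equal(f2[["abspow"]], 4 * fx[["abspow"]], tolerance = 1e-9)
  expect_equal(f2[["dbratio"]], fx[["dbratio"]], tolerance = 1e-9)

  expect_warning(fz <- spectralFeatures(rep(0, 3000), fs), "all-zero")
  expect_equal(unname(fz[bandDefinitions()$name]), rep(1 / 6, 6))
})

test_that("smoothing appends kernel-correct normalized variants", {
  const <- FeatureTable(matrix(5, 40, 1, dimnames = list(NULL, "a")))
  sm <- smoothAndNormalize(const)
  expect_equal(unname(featureMatrix(sm)[, "a_roll2min_norm"]), rep(0, 40))
  expect_equal(unname(featureMatrix(sm)[, "a_tri7.5min_norm"]), rep(0, 40))
  expect_equal(unname(featureMatrix(sm)[, "a"]), rep(5, 40))

  # unit impulse under the centered triangular window: proportional to the
  # 15-tap triangular kernel (z-scoring is affine, so correlation is exact)
  imp <- numeric(41); imp[21] <- 1
  smI <- smoothAndNormalize(FeatureTable(matrix(imp, 41, 1,
                                                dimnames = list(NULL, "a"))))
  tri <- featureMatrix(smI)[, "a_tri7.5min_norm"]
  kern <- c(rep(0, 13), 1:8, 7:1, rep(0, 13)) / 64
  expect_equal(cor(tri, kern), 1, tolerance = 1e-9)
  expect_equal(tri[1:13], rep(min(tri), 13), tolerance = 1e-9)

  # trailing rolling mean is causal: value at t uses epochs <= t only
  xr <- c(rep(0, 10), rep(1, 10))
  smr <- smoothAndNormalize(FeatureTable(matrix(xr, 20, 1,
                                                dimnames = list(NULL, "a"))))
  roll <- featureMatrix(smr)[, "a_roll2min_norm"]
  expect_equal(roll[10], min(roll))  # unaffected by the later step

  # z-score contract per recording
  set.seed(5)
  ft <- smoothAndNormalize(FeatureTable(matrix(rnorm(200), 100, 2,
                                               dimnames = list(NULL, c("a", "b")))))
  m <- featureMatrix(ft)
  for (cc in grep("_norm$", colnames(m), value = TRUE)) {
    expect_equal(mean(m[, cc]), 0, tolerance = 1e-9)
    expect_equal(sd(m[, cc]), 1, tolerance = 1e-9)
  }
})

test_that("extractFeatures yields the 65-column table with pure base features", {
  set.seed(6)
  rec <- Recording(rnorm(100 * 30 * 12), fs = 100)
  ep <- epochRecording(rec)
  ft <- extractFeatures(ep)
  expect_equal(ncol(featureMatrix(ft)), 65)
  expect_equal(nrow(featureMatrix(ft)), 12)
  expect_false(anyDuplicated(featureNames(ft)) > 0)
  expect_false(any(!is.finite(featureMatrix(ft))))

  # raw base features are epoch-local: permuting epochs permutes rows
  perm <- c(5, 3, 12, 1, 7, 2, 9, 11, 4, 10, 8, 6)
  ep2 <- ep; ep2@epochs <- ep@epochs[perm, ]
  raw <- extractFeatures(ep, smooth = FALSE)
  raw2 <- extractFeatures(ep2, smooth = FALSE)
  base <- setdiff(featureNames(raw), c("epoch_index", "time_norm"))
  expect_equal(featureMatrix(raw2)[, base], featureMatrix(raw)[perm, base])
})

test_that("relative delta power separates stages on synthetic data", {
  # one-way stage ANOVA on epoch-level relative delta power
  perStage <- 110
  stagesV <- rep(stageLevels(), each = perStage)
  vals <- vapply(seq_along(stagesV), function(i) {
    f <- spectralFeatures(generateEpochSignal(stagesV[i], fs = 128, seed = i),
                          128)
    f[["sdelta"]] + f[["fdelta"]]
  }, numeric(1))
  p <- summary(aov(vals ~ factor(stagesV)))[[1]][["Pr(>F)"]][1]
  expect_lt(p, 0.01)
})
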