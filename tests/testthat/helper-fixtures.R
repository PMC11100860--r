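# Shared fixtures built in code. Model-backed fixtures are cached per session
# because several test files probe the same small cohort.

fixtureEnv <- new.env()

# a tiny preprocessed cohort with both modalities (nSubjects x nEpochs)
smallCohortFeatures <- function(nSubjects = 4, nEpochs = 120, seed = 11) {
  key <- sprintf("cohort_%d_%d_%d", nSubjects, nEpochs, seed)
  if (!is.null(fixtureEnv[[key]])) return(fixtureEnv[[key]])
  cohort <- generateCohort(nSubjects, nEpochs, seed = seed)
  out <- list(
    hyps = lapply(cohort, `[[`, "hypnogram"),
    scalp = lapply(cohort, function(s)
      extractFeatures(preprocessRecording(s$recordings$scalp))),
    ear = lapply(cohort, function(s)
      extractFeatures(preprocessRecording(s$recordings$ear))))
  fixtureEnv[[key]] <- out
  out
}

# separable toy staging problem: one feature equals the stage code
separableFixture <- function(n = 300, seed = 5) {
  key <- sprintf("sep_%d_%d", n, seed)
  if (!is.null(fixtureEnv[[key]])) return(fixtureEnv[[key]])
  codes <- withr::with_seed(seed, sample(0:4, n, replace = TRUE))
  X <- withr::with_seed(seed + 1,
    cbind(code = codes + rnorm(n, sd = 0.01), junk = rnorm(n)))
  ft <- FeatureTable(X)
  hyp <- Hypnogram(stageLevels()[codes + 1])
  model <- pretrainStager(list(ft), list(hyp),
                          stagingConfig(nEstimators = 30L, seed = 3L))
  out <- list(features = ft, hyp = hyp, model = model, codes = codes)
  fixtureEnv[[key]] <- out
  out
}

# small random multiclass model over few features, for SHAP oracle checks
tinyModel <- function(p = 4, nTrees = 3, n = 150, seed = 9) {
  key <- sprintf("tiny_%d_%d_%d_%d", p, nTrees, n, seed)
  if (!is.null(fixtureEnv[[key]])) return(fixtureEnv[[key]])
  X <- withr::with_seed(seed, matrix(rnorm(n * p), n, p,
                                     dimnames = list(NULL, paste0("f", 1:p))))
  y <- withr::with_seed(seed + 1, sample(0:4, n, replace = TRUE))
  ft <- FeatureTable(X)
  hyp <- Hypnogram(stageLevels()[y + 1])
  model <- pretrainStager(list(ft), list(hyp),
                          stagingConfig(nEstimators = nTrees, maxDepth = 3L,
                                        featureFraction = 1, seed = 2L))
  out <- list(features = ft, hyp = hyp, model = model)
  fixtureEnv[[key]] <- out
  out
}
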