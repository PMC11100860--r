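# End-to-end experiment: simulate -> preprocess -> features -> pretrain ->
# LOSO fine-tuning evaluation -> MI comparison -> SHAP rankings, fully
# reproducible from (config, seed).

#' Experiment configuration
#'
#' All knobs of [runExperiment()] in one serializable list. The defaults
#' describe the study conditions: a 13-subject evaluation cohort with
#' 10-hour nights (1200 epochs), a disjoint 13-subject scalp pretraining
#' cohort, both modalities, and a scaled-down tree budget (100 pretraining
#' rounds, 20 fine-tuning rounds) that keeps a desk-scale run tractable.
#'
#' @param nSubjects evaluation-cohort size.
#' @param epochsPerSubject epochs per night.
#' @param nPretrainSubjects pretraining-cohort size (scalp only).
#' @param modalities modalities to evaluate.
#' @param nEstimators,finetuneRounds,learningRate boosting budget.
#' @param seed global seed; every stage derives its own stream from it.
#' @param fs native generation rate, Hz.
#' @return a named list of class `runConfig`.
#' @export
runConfig <- function(nSubjects = 13L, epochsPerSubject = 1200L,
                      nPretrainSubjects = 13L,
                      modalities = c("scalp", "ear"),
                      nEstimators = 100L, finetuneRounds = 20L,
                      learningRate = 0.1, seed = 1L, fs = 256L) {
  structure(list(nSubjects = as.integer(nSubjects),
                 epochsPerSubject = as.integer(epochsPerSubject),
                 nPretrainSubjects = as.integer(nPretrainSubjects),
                 modalities = match.arg(modalities, c("scalp", "ear"),
                                        several.ok = TRUE),
                 nEstimators = as.integer(nEstimators),
                 finetuneRounds = as.integer(finetuneRounds),
                 learningRate = learningRate,
                 seed = as.integer(seed), fs = as.integer(fs)),
            class = "runConfig")
}

# preprocess + extract features for one cohort; returns per-subject lists
.cohortFeatures <- function(cohort, modality) {
  lapply(cohort, function(subj) {
    rec <- subj$recordings[[modality]]
    ep <- preprocessRecording(rec)
    extractFeatures(ep)
  })
}

#' Run the full transfer-learning experiment
#'
#' Generates a synthetic scalp pretraining cohort and a separate evaluation
#' cohort (scalp + shifted ear), pretrains the stager on scalp data, then
#' for each requested modality runs the leave-one-subject-out
#' pretrained-vs-fine-tuned comparison. When both modalities are present it
#' also computes the per-feature scalp-vs-ear mutual-information comparison
#' and the N3 top-feature SHAP rankings of the pretrained and ear-fine-tuned
#' models. All outputs are written under `outDir` and are identical across
#' runs with the same config.
#'
#' @param config a [runConfig()].
#' @param outDir output directory (created if missing).
#' @return invisibly, a list with the LOSO results per modality, the MI
#'   table, the SHAP rankings and the summary list written to
#'   `summary.json`.
#' @export
runExperiment <- function(config = runConfig(), outDir = tempfile("earstage_run")) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outDir, "reports"), showWarnings = FALSE)
  dir.create(file.path(outDir, "models"), showWarnings = FALSE)
  logFile <- file.path(outDir, "log.txt")
  logMsg <- function(...) cat(sprintf(...), "\n", sep = "", file = logFile,
                              append = TRUE)
  writeRunConfig(unclass(config), file.path(outDir, "config.yaml"))

  t0 <- proc.time()[["elapsed"]]
  step <- function(what, code) {
    s <- proc.time()[["elapsed"]]
    res <- force(code)
    logMsg("%-28s %8.1fs", what, proc.time()[["elapsed"]] - s)
    res
  }

  preCohort <- step("simulate pretraining cohort",
    generateCohort(config$nPretrainSubjects, config$epochsPerSubject,
                   modalities = "scalp", seed = deriveSeed(config$seed, 11L),
                   fs = config$fs))
  evalCohort <- step("simulate evaluation cohort",
    generateCohort(config$nSubjects, config$epochsPerSubject,
                   modalities = config$modalities,
                   seed = deriveSeed(config$seed, 12L), fs = config$fs))

  preFeats <- step("features: pretraining cohort",
                   .cohortFeatures(preCohort, "scalp"))
  preHyps <- lapply(preCohort, `[[`, "hypnogram")
  evalFeats <- lapply(config$modalities, function(m)
    step(paste0("features: evaluation ", m), .cohortFeatures(evalCohort, m)))
  names(evalFeats) <- config$modalities
  evalHyps <- lapply(evalCohort, `[[`, "hypnogram")

  cfg <- stagingConfig(nEstimators = config$nEstimators,
                       finetuneRounds = config$finetuneRounds,
                       learningRate = config$learningRate,
                       seed = deriveSeed(config$seed, 13L))
  pretrained <- step("pretrain", pretrainStager(preFeats, preHyps, cfg))
  writeStager(pretrained, file.path(outDir, "models", "pretrained.json"))

  loso <- list(); summary <- list(seed = config$seed)
  for (m in config$modalities) {
    loso[[m]] <- step(paste0("LOSO ", m),
                      losoEvaluate(evalFeats[[m]], evalHyps, pretrained, cfg))
    utils::write.csv(loso[[m]]$summary,
                     file.path(outDir, "reports", paste0("loso_", m, ".csv")),
                     row.names = FALSE)
    pooledPre <- pooledReport(loso[[m]], "pre")
    pooledFine <- pooledReport(loso[[m]], "fine")
    summary[[m]] <- list(
      accuracy_pre_pooled = accuracy(pooledPre),
      accuracy_fine_pooled = accuracy(pooledFine),
      kappa_pre_mean = mean(loso[[m]]$summary$kappa_pre),
      kappa_fine_mean = mean(loso[[m]]$summary$kappa_fine),
      n3_sensitivity_pre = sensitivity(pooledPre)[["N3"]],
      n3_sensitivity_fine = sensitivity(pooledFine)[["N3"]],
      n_improved = loso[[m]]$pairedTest$nImproved,
      p_value = loso[[m]]$pairedTest$p,
      finetuning_improves = loso[[m]]$pairedTest$meanDifference > 0)
  }

  mi <- NULL; rankings <- NULL
  if (all(c("scalp", "ear") %in% config$modalities)) {
    mi <- step("MI comparison",
               compareModalities(evalFeats$scalp, evalFeats$ear, evalHyps))
    utils::write.csv(mi, file.path(outDir, "reports", "mi_comparison.csv"),
                     row.names = FALSE)
    summary$mi <- list(n_features = attr(mi, "nFeatures"),
                       n_scalp_greater = attr(mi, "nScalpGreater"))

    # SHAP N3 rankings on pooled ear epochs, pretrained vs ear-fine-tuned
    earFine <- step("finetune on all ear data",
                    finetuneStager(pretrained, evalFeats$ear, evalHyps, cfg))
    writeStager(earFine, file.path(outDir, "models", "finetuned_ear.json"))
    allEar <- FeatureTable(do.call(rbind, lapply(evalFeats$ear, featureMatrix)),
                           subjectId = "pooled", modality = "ear")
    allRef <- Hypnogram(unlist(lapply(evalHyps, function(h)
      as.character(h@stages))))
    rankings <- step("SHAP N3 rankings", {
      rbind(
        cbind(model = "pretrained",
              topFeatures(shapValues(pretrained, allEar), allRef, "N3", 5L)),
        cbind(model = "finetuned",
              topFeatures(shapValues(earFine, allEar), allRef, "N3", 5L)))
    })
    utils::write.csv(rankings,
                     file.path(outDir, "reports", "shap_n3_top5.csv"),
                     row.names = FALSE)
  }

  jsonlite::write_json(summary, file.path(outDir, "reports", "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logMsg("total %31.1fs", proc.time()[["elapsed"]] - t0)
  invisible(list(loso = loso, mi = mi, shapRankings = rankings,
                 summary = summary, outDir = outDir))
}
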