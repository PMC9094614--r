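# Cross-validation and external evaluation.

#' Event-stratified fold assignment
#'
#' Subjects are shuffled within event strata and dealt round-robin, so every
#' fold receives its share of events; splits are fixed by the seed and can be
#' serialized so they stay consistent across all evaluated methods.
#'
#' @param event 0/1 event indicators
#' @param nFolds number of folds (>= 2)
#' @param seed RNG seed
#' @return integer fold label (1..nFolds) per subject
#' @export
makeFolds <- function(event, nFolds = 5L, seed = 1L) {
  n <- length(event)
  if (nFolds < 2L) stop("nFolds must be >= 2")
  if (n < nFolds) stop("fewer subjects than folds")
  set.seed(seed)
  fold <- integer(n)
  for (e in unique(event)) {
    idx <- sample(which(event == e))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  if (any(tapply(event, fold, sum) == 0))
    stop("a fold has zero events even after stratified splitting; ",
         "reduce nFolds")
  fold
}

#' Cross-validated evaluation of the spherical risk pipeline
#'
#' Subject-level, event-stratified folds fixed by the seed; for each fold a
#' model is trained on the remaining folds (with its own internal validation
#' split) and scored on the held-out fold.
#'
#' @param maps list of \linkS4class{SphericalMap}
#' @param cohort matching \linkS4class{SurvivalCohort}
#' @param config network architecture
#' @param nFolds number of folds
#' @param seed RNG seed controlling both the split and the training runs
#' @param ... further arguments to \code{\link{trainRiskModel}}
#' @return list: \code{fold} (assignment vector), \code{perFold} (test
#'   C-index per fold), \code{mean}, \code{sd}, \code{scores} (test-fold risk
#'   score per subject)
#' @export
crossValidate <- function(maps, cohort, config = networkConfig(),
                          nFolds = 5L, seed = 1L, ...) {
  n <- length(maps)
  event <- eventIndicators(cohort); time <- survivalTimes(cohort)
  fold <- makeFolds(event, nFolds, seed)
  perFold <- numeric(nFolds)
  scores <- numeric(n)
  for (f in seq_len(nFolds)) {
    te <- which(fold == f); tr <- which(fold != f)
    fit <- trainRiskModel(maps[tr], subsetCohort(cohort, tr), config,
                          seed = seed + f, ...)
    s <- predictRiskAll(fit$model, maps[te])
    scores[te] <- s
    perFold[f] <- concordanceIndex(s, subsetCohort(cohort, te))
  }
  list(fold = fold, perFold = perFold, mean = mean(perFold),
       sd = stats::sd(perFold), scores = scores)
}

#' Subset a cohort by index
#' @param cohort a \linkS4class{SurvivalCohort}
#' @param idx subject indices
#' @return the restricted \linkS4class{SurvivalCohort}
#' @export
subsetCohort <- function(cohort, idx) {
  covs <- covariateMatrix(cohort)
  new("SurvivalCohort",
      subjectId = cohort@subjectId[idx],
      time = survivalTimes(cohort)[idx],
      event = eventIndicators(cohort)[idx],
      covariates = if (nrow(covs)) covs[idx, , drop = FALSE] else covs,
      risk = if (length(riskScores(cohort))) riskScores(cohort)[idx]
             else numeric(0))
}

#' Evaluate a trained model on an external cohort
#'
#' Applies the model's stored training-split normalization (no re-fitting),
#' computes the C-index, stratifies by the median of the predicted scores on
#' the external cohort, and estimates Kaplan-Meier curves per risk group.
#'
#' @param model trained \linkS4class{RiskModel}
#' @param maps external subjects' \linkS4class{SphericalMap}s
#' @param cohort external \linkS4class{SurvivalCohort}
#' @return list: \code{cIndex}, \code{scores}, \code{groups} (low/high
#'   factor), \code{kmLow}, \code{kmHigh} (\linkS4class{KMEstimate})
#' @export
evaluateExternal <- function(model, maps, cohort) {
  scores <- predictRiskAll(model, maps)
  ci <- concordanceIndex(scores, cohort)
  groups <- stratifyByMedian(scores)
  list(cIndex = ci, scores = scores, groups = groups,
       kmLow = kaplanMeier(subsetCohort(cohort, which(groups == "low"))),
       kmHigh = kaplanMeier(subsetCohort(cohort, which(groups == "high"))))
}

#' Compute spherical maps for a whole phantom cohort
#'
#' @param subjects the \code{subjects} element of \code{\link{generateCohort}}
#' @param config input configuration (\code{sphcnn1} / \code{sphcnn2})
#' @param bandwidth grid bandwidth
#' @param ... passed to \code{\link{makeInput}}
#' @return list of \linkS4class{SphericalMap}
#' @export
mapCohort <- function(subjects, config = "sphcnn1", bandwidth = 16L, ...) {
  grid <- sphericalGrid(bandwidth)
  lapply(subjects, function(s) makeInput(config, s$image, s$mask, grid, ...))
}
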