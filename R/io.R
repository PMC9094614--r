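# File formats: NIfTI volumes (RNifti), CSV cohorts/curves/scores, JSON
# configs and metrics, RDS for maps and model checkpoints.

#' Write a volume as NIfTI
#' @param vol a \linkS4class{VoxelVolume}
#' @param path output path (.nii or .nii.gz)
#' @export
writeVoxelVolume <- function(vol, path) {
  img <- RNifti::asNifti(voxelData(vol))
  RNifti::pixdim(img) <- voxelSpacing(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#' @param path input path
#' @return a \linkS4class{VoxelVolume} (origin at 0, spacing from the header)
#' @export
readVoxelVolume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  new("VoxelVolume", values = array(as.numeric(img), dim(img)[1:3]),
      spacing = as.numeric(sp), origin = c(0, 0, 0))
}

#' Write a survival cohort as CSV
#'
#' Columns: subject_id, time, event, optionally true_log_risk and
#' covariate_<name>, optionally risk.
#' @param cohort a \linkS4class{SurvivalCohort}
#' @param path output path
#' @param trueLogRisk optional vector written as \code{true_log_risk}
#' @export
writeCohortCsv <- function(cohort, path, trueLogRisk = NULL) {
  df <- data.frame(subject_id = cohort@subjectId,
                   time = survivalTimes(cohort),
                   event = eventIndicators(cohort))
  if (!is.null(trueLogRisk)) df$true_log_risk <- trueLogRisk
  covs <- covariateMatrix(cohort)
  if (nrow(covs) > 0) {
    cn <- colnames(covs)
    if (is.null(cn)) cn <- paste0("x", seq_len(ncol(covs)))
    for (j in seq_len(ncol(covs))) df[[paste0("covariate_", cn[j])]] <- covs[, j]
  }
  if (length(riskScores(cohort)) > 0) df$risk <- riskScores(cohort)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a survival cohort from CSV
#' @param path CSV written by \code{\link{writeCohortCsv}} (or matching its
#'   column convention)
#' @return a \linkS4class{SurvivalCohort}
#' @export
readCohortCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  covCols <- grep("^covariate_", names(df), value = TRUE)
  covs <- if (length(covCols)) {
    m <- as.matrix(df[covCols])
    colnames(m) <- sub("^covariate_", "", covCols)
    m
  } else NULL
  survivalCohort(df$time, df$event, covariates = covs,
                 risk = if ("risk" %in% names(df)) df$risk else numeric(0),
                 subjectId = df$subject_id)
}

#' Write a Kaplan-Meier estimate as CSV
#' @param km a \linkS4class{KMEstimate}
#' @param path output path; columns time, survival, n_risk, n_event
#' @export
writeKmCsv <- function(km, path) {
  utils::write.csv(data.frame(time = km@time, survival = km@surv,
                              n_risk = km@nRisk, n_event = km@nEvent),
                   path, row.names = FALSE)
  invisible(path)
}

#' Save / load a risk model
#'
#' The checkpoint stores the architecture config, all parameter arrays and
#' the training-split normalization statistics; predictions are reproduced
#' exactly after a round trip.
#' @param model a \linkS4class{RiskModel}
#' @param path checkpoint path (.rds)
#' @export
saveRiskModel <- function(model, path) {
  saveRDS(list(config = model@config, params = model@params,
               normStats = model@normStats), path)
  invisible(path)
}

#' @rdname saveRiskModel
#' @return \code{loadRiskModel}: the restored \linkS4class{RiskModel}
#' @export
loadRiskModel <- function(path) {
  x <- readRDS(path)
  new("RiskModel", config = x$config, params = x$params,
      normStats = x$normStats)
}

#' Save / load spherical maps
#' @param maps list of \linkS4class{SphericalMap}
#' @param path .rds path
#' @export
saveSphericalMaps <- function(maps, path) {
  saveRDS(maps, path)
  invisible(path)
}

#' @rdname saveSphericalMaps
#' @export
readSphericalMaps <- function(path) readRDS(path)

#' Experiment configuration with exact JSON round trip
#'
#' @param inputConfig,bandwidth,c1,c2 network architecture
#' @param epochs,learningRate,weightDecay,batchSize,valFraction optimizer
#' @param nFolds cross-validation folds
#' @param seed mandatory RNG seed (no silent nondeterminism)
#' @return named list of class \code{experimentConfig}
#' @export
experimentConfig <- function(inputConfig = "sphcnn1", bandwidth = 16L,
                             c1 = 4L, c2 = 8L, epochs = 40L,
                             learningRate = 3e-3, weightDecay = 1e-4,
                             batchSize = 64L, valFraction = 0.2,
                             nFolds = 5L, seed = 1L) {
  if (is.null(seed)) stop("seed is mandatory")
  if (nFolds < 2L) stop("nFolds must be >= 2")
  out <- list(inputConfig = inputConfig, bandwidth = as.integer(bandwidth),
              c1 = as.integer(c1), c2 = as.integer(c2),
              epochs = as.integer(epochs), learningRate = learningRate,
              weightDecay = weightDecay, batchSize = as.integer(batchSize),
              valFraction = valFraction, nFolds = as.integer(nFolds),
              seed = as.integer(seed))
  class(out) <- "experimentConfig"
  out
}

#' @rdname experimentConfig
#' @param cfg an \code{experimentConfig}
#' @param path JSON path
#' @export
writeExperimentConfig <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname experimentConfig
#' @export
readExperimentConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(experimentConfig, x)
}
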