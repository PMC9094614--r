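#' @rdname SphericalGrid-class
#' @param object,x an object
#' @export
setGeneric("bandwidth", function(x) standardGeneric("bandwidth"))
#' @rdname SphericalGrid-class
#' @export
setGeneric("colatitudes", function(x) standardGeneric("colatitudes"))
#' @rdname SphericalGrid-class
#' @export
setGeneric("longitudes", function(x) standardGeneric("longitudes"))
#' @rdname SphericalGrid-class
#' @export
setGeneric("quadratureWeights", function(x) standardGeneric("quadratureWeights"))

#' @rdname VoxelVolume-class
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname VoxelVolume-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname VoxelVolume-class
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))

#' @rdname SphericalMap-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname SphericalMap-class
#' @param channel channel name
#' @export
setGeneric("mapChannel", function(x, channel) standardGeneric("mapChannel"))
#' @rdname SphericalMap-class
#' @export
setGeneric("mapCentroid", function(x) standardGeneric("mapCentroid"))
#' @rdname SphericalMap-class
#' @export
setGeneric("enclosingRadiusOf", function(x) standardGeneric("enclosingRadiusOf"))

#' @rdname SurvivalCohort-class
#' @export
setGeneric("survivalTimes", function(x) standardGeneric("survivalTimes"))
#' @rdname SurvivalCohort-class
#' @export
setGeneric("eventIndicators", function(x) standardGeneric("eventIndicators"))
#' @rdname SurvivalCohort-class
#' @export
setGeneric("covariateMatrix", function(x) standardGeneric("covariateMatrix"))
#' @rdname SurvivalCohort-class
#' @export
setGeneric("riskScores", function(x) standardGeneric("riskScores"))
#' @rdname SurvivalCohort-class
#' @param value replacement value
#' @export
setGeneric("riskScores<-", function(x, value) standardGeneric("riskScores<-"))
#' @rdname SurvivalCohort-class
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

setMethod("bandwidth", "SphericalGrid", function(x) x@bandwidth)
setMethod("colatitudes", "SphericalGrid", function(x) x@theta)
setMethod("longitudes", "SphericalGrid", function(x) x@phi)
setMethod("quadratureWeights", "SphericalGrid", function(x) x@weights)
setMethod("bandwidth", "SphericalMap", function(x) x@grid@bandwidth)

setMethod("voxelData", "VoxelVolume", function(x) x@values)
setMethod("voxelSpacing", "VoxelVolume", function(x) x@spacing)
setMethod("voxelOrigin", "VoxelVolume", function(x) x@origin)

setMethod("channelNames", "SphericalMap", function(x) x@channels)
setMethod("mapChannel", "SphericalMap", function(x, channel) {
  i <- match(channel, x@channels)
  if (is.na(i)) stop("no channel named '", channel, "'")
  x@values[i, , ]
})
setMethod("mapCentroid", "SphericalMap", function(x) x@centroid)
setMethod("enclosingRadiusOf", "SphericalMap", function(x) x@radius)

setMethod("survivalTimes", "SurvivalCohort", function(x) x@time)
setMethod("eventIndicators", "SurvivalCohort", function(x) x@event)
setMethod("covariateMatrix", "SurvivalCohort", function(x) x@covariates)
setMethod("riskScores", "SurvivalCohort", function(x) x@risk)
setMethod("riskScores<-", "SurvivalCohort", function(x, value) {
  x@risk <- as.numeric(value)
  validObject(x)
  x
})
setMethod("nSubjects", "SurvivalCohort", function(x) length(x@time))

setMethod("show", "SphericalGrid", function(object) {
  cat("SphericalGrid: bandwidth", object@bandwidth, "(",
      2 * object@bandwidth, "x", 2 * object@bandwidth, "equiangular samples )\n")
})
setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@values)
  cat("VoxelVolume:", paste(d, collapse = " x "), "voxels, spacing",
      paste(signif(object@spacing, 4), collapse = " x "), "mm\n")
  v <- object@values
  if (all(v %in% c(0, 1))) {
    cat("  binary mask,", sum(v), "foreground voxels\n")
  } else {
    cat("  intensity range [", signif(min(v), 4), ",", signif(max(v), 4), "]\n")
  }
})
setMethod("show", "SphericalMap", function(object) {
  cat("SphericalMap: channels {", paste(object@channels, collapse = ", "),
      "} at bandwidth", object@grid@bandwidth, "\n")
  cat("  centroid (mm):", paste(signif(object@centroid, 4), collapse = ", "),
      " enclosing radius:", signif(object@radius, 4), "mm\n")
})
setMethod("show", "SurvivalCohort", function(object) {
  cat("SurvivalCohort:", length(object@time), "subjects,",
      sum(object@event), "events (",
      round(100 * mean(object@event)), "% )\n")
  if (ncol(object@covariates) > 0)
    cat("  covariates:", paste(colnames(object@covariates), collapse = ", "), "\n")
  if (length(object@risk) > 0)
    cat("  risk scores present\n")
})
setMethod("show", "KMEstimate", function(object) {
  cat("KMEstimate:", length(object@time), "event times; final S(t) =",
      if (length(object@surv)) signif(object@surv[length(object@surv)], 4) else 1, "\n")
})
setMethod("show", "RiskModel", function(object) {
  cfg <- object@config
  cat("RiskModel (", cfg$inputConfig, "): bandwidths", cfg$bandwidth, "->",
      cfg$l1, "->", cfg$l2, ", channels", cfg$channelsIn, "->", cfg$c1, "->",
      cfg$c2, "-> dense", cfg$dense, "-> 1\n")
})
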