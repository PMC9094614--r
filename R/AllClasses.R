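#' @import methods
NULL

#' Equiangular sampling grid on the unit sphere
#'
#' A 2B x 2B equiangular grid with colatitudes \eqn{\theta_j = \pi(2j+1)/(4B)},
#' longitudes \eqn{\phi_k = \pi k / B} and per-row quadrature weights that
#' integrate band-limited functions exactly. Note that this convention
#' oversamples the polar caps relative to the equator; the quadrature weights
#' compensate so integrals are unbiased, but grid-cell areas are not uniform.
#'
#' @slot bandwidth maximum represented spherical-harmonic degree (exclusive)
#' @slot theta colatitude nodes, length 2B
#' @slot phi longitude nodes, length 2B
#' @slot weights per-row quadrature weights; \code{sum(weights) == 2} so that
#'   \code{sum(weights) * pi/B * 2B == 4*pi}
#' @export
setClass("SphericalGrid",
  representation(bandwidth = "integer", theta = "numeric",
                 phi = "numeric", weights = "numeric"),
  validity = function(object) {
    B <- object@bandwidth
    if (length(B) != 1L || B < 2L) return("bandwidth must be a single integer >= 2")
    if (length(object@theta) != 2L * B) return("theta must have length 2B")
    if (length(object@phi) != 2L * B) return("phi must have length 2B")
    if (length(object@weights) != 2L * B) return("weights must have length 2B")
    if (abs(sum(object@weights) * pi / B * 2 * B - 4 * pi) > 1e-10)
      return("quadrature weights must integrate the constant 1 to 4*pi")
    TRUE
  })

#' Scalar 3D image with physical voxel geometry
#'
#' Houses a CT image or (as a binary special case) a tumor mask. Voxel index
#' (i,j,k) (1-based in R) has physical center
#' \code{origin + (c(i,j,k) - 0.5) * spacing}, all in millimetres.
#'
#' @slot values 3D numeric array
#' @slot spacing voxel spacing in mm, length 3, strictly positive
#' @slot origin physical position of the corner of voxel (1,1,1), mm
#' @export
setClass("VoxelVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(dim(object@values)) != 3L) return("values must be a 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive numbers")
    if (length(object@origin) != 3L) return("origin must have length 3")
    if (any(!is.finite(object@values))) return("values must be finite")
    TRUE
  })

#' Multi-channel real-valued signal on the sphere
#'
#' The pipeline's intermediate representation: one or more of the channels
#' \code{egi}, \code{depth}, \code{intensity} sampled on a
#' \linkS4class{SphericalGrid}, together with the geometry they were computed
#' under (tumor centroid and enclosing-sphere radius, mm).
#'
#' @slot grid the sampling grid
#' @slot values array of shape channels x 2B x 2B
#' @slot channels channel names, in slice order
#' @slot centroid tumor center of mass, mm
#' @slot radius enclosing-sphere radius R, mm
#' @slot normalized TRUE if the depth channel was divided by R
#' @export
setClass("SphericalMap",
  representation(grid = "SphericalGrid", values = "array",
                 channels = "character", centroid = "numeric",
                 radius = "numeric", normalized = "logical"),
  validity = function(object) {
    d <- dim(object@values)
    B <- object@grid@bandwidth
    if (length(d) != 3L) return("values must be channels x 2B x 2B")
    if (d[1] != length(object@channels)) return("channel count mismatch")
    if (d[2] != 2L * B || d[3] != 2L * B) return("grid size mismatch")
    if (any(!is.finite(object@values))) return("values must be finite")
    if ("egi" %in% object@channels &&
        min(object@values[match("egi", object@channels), , ]) < -1e-9)
      return("egi channel must be nonnegative")
    TRUE
  })

#' Right-censored survival records
#'
#' Per-subject observation time T (months), event indicator E (1 = event
#' observed at T, 0 = right-censored at T), optional covariates and optional
#' risk scores.
#'
#' @slot subjectId subject identifiers
#' @slot time observation times, strictly positive
#' @slot event 0/1 event indicators
#' @slot covariates numeric matrix (subjects x covariates); may have 0 columns
#' @slot risk per-subject risk scores (log-risk scale); may be empty
#' @export
setClass("SurvivalCohort",
  representation(subjectId = "character", time = "numeric",
                 event = "integer", covariates = "matrix", risk = "numeric"),
  validity = function(object) {
    n <- length(object@time)
    if (length(object@subjectId) != n) return("subjectId length mismatch")
    if (length(object@event) != n) return("event length mismatch")
    if (any(object@time <= 0)) return("all times must be > 0")
    if (!all(object@event %in% c(0L, 1L))) return("event must be 0/1")
    if (nrow(object@covariates) != n && nrow(object@covariates) != 0L)
      return("covariates row count mismatch")
    if (length(object@risk) != 0L && length(object@risk) != n)
      return("risk length mismatch")
    TRUE
  })

#' Kaplan-Meier survivor-function estimate
#'
#' Step function dropping only at observed event times; S(0) = 1.
#'
#' @slot time distinct event times, ascending
#' @slot surv estimated survival probability just after each event time
#' @slot nRisk number at risk just before each event time
#' @slot nEvent number of events at each event time
#' @export
setClass("KMEstimate",
  representation(time = "numeric", surv = "numeric",
                 nRisk = "numeric", nEvent = "numeric"),
  validity = function(object) {
    k <- length(object@time)
    if (length(object@surv) != k || length(object@nRisk) != k ||
        length(object@nEvent) != k) return("slot length mismatch")
    if (is.unsorted(object@time, strictly = TRUE)) return("times must be strictly ascending")
    if (k > 0 && (any(object@surv < 0) || any(object@surv > 1)))
      return("survival probabilities must lie in [0,1]")
    if (k > 1 && any(diff(object@surv) > 1e-12)) return("survival must be non-increasing")
    TRUE
  })

#' Spherical-network risk model
#'
#' Parameters of the spherical convolutional network approximating the
#' log-risk h(x) of a generalized Cox proportional hazards model, together
#' with its architecture configuration and the per-channel normalization
#' statistics estimated on the training split.
#'
#' @slot config named list: bandwidth, layer bandwidths, channel widths,
#'   input configuration, readout and head options
#' @slot params named list of numeric/complex parameter arrays
#' @slot normStats per-channel means and sds used to standardize inputs
#' @export
setClass("RiskModel",
  representation(config = "list", params = "list", normStats = "list"),
  validity = function(object) {
    cfg <- object@config
    need <- c("bandwidth", "channelsIn", "c1", "c2", "l1", "l2", "dense")
    if (!all(need %in% names(cfg)))
      return(paste("config must contain:", paste(need, collapse = ", ")))
    if (cfg$dense != 40L) return("dense layer width is fixed at 40 features")
    TRUE
  })
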