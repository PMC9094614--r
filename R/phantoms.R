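# Synthetic tumor phantoms with known ground truth.
#
# Tumors are star-shaped solids about their center: the boundary is
# r(w) = r0 * (1 + sum_{l<=L,m} a_lm S_lm(w)) with real spherical harmonics
# S_lm, so the centroid-based depth projection has the closed form r(w) --
# the analytic oracle the mapping tests rely on. Interiors get a textured
# intensity (base HU + smooth random blobs + i.i.d. noise); survival times
# follow a proportional-hazards law with constant baseline hazard
# lambda(t|x) = lambda0 * exp(beta' x), drawn exactly by inverse transform,
# with uniform independent censoring on [0, cMax].

# real orthonormal spherical harmonics up to degree L at given directions:
# columns ordered (l,m) with m = -l..l; m<0 -> sqrt2*Im(Y_l|m|),
# m=0 -> Y_l0, m>0 -> sqrt2*Re(Y_lm)
realSphericalHarmonics <- function(L, theta, phi) {
  Ph <- legendreNormalized(L, theta)
  idxh <- function(l, m) l * (l + 1) / 2 + m + 1
  out <- matrix(0, length(theta), (L + 1)^2)
  for (l in 0:L) for (m in (-l):l) {
    fi <- l^2 + l + m + 1
    if (m == 0) {
      out[, fi] <- Ph[, idxh(l, 0)]
    } else if (m > 0) {
      out[, fi] <- sqrt(2) * Ph[, idxh(l, m)] * cos(m * phi)
    } else {
      out[, fi] <- sqrt(2) * Ph[, idxh(l, -m)] * sin(-m * phi)
    }
  }
  out
}

#' Specification of a phantom cohort
#'
#' Defaults define the simulated study conditions: ~1 mm CT-like voxels,
#' base radii 6-12 mm, mild boundary perturbations band-limited at degree 4
#' (below the mapping bandwidth, so phantoms are representable without
#' aliasing), soft-tissue interior around 40 HU on an air background,
#' a constant baseline hazard of 0.05 events/month (mean survival 20 months
#' at the baseline risk) and uniform censoring over 5 years, giving roughly
#' a third censored records.
#'
#' @param nSubjects number of subjects (>= 2)
#' @param gridShape voxel grid dimensions
#' @param spacing voxel spacing, mm
#' @param r0Range base-radius range, mm
#' @param perturbScale scale of the radial perturbation coefficients
#' @param perturbDegree band limit L of the perturbation
#' @param baseHU,blobCount,blobAmp,noiseSd interior texture parameters
#' @param betaTrue true risk coefficients for the shape covariates
#'   (standardized log volume, asphericity)
#' @param lambda0 constant baseline hazard, events/month (> 0)
#' @param cMax censoring horizon, months (> 0)
#' @param seed RNG seed; identical spec + seed gives a bit-identical cohort
#' @return named list of class \code{phantomCohortSpec}
#' @export
phantomCohortSpec <- function(nSubjects = 50L,
                              gridShape = c(48L, 48L, 48L),
                              spacing = c(1, 1, 1),
                              r0Range = c(6, 12),
                              perturbScale = 0.12,
                              perturbDegree = 4L,
                              baseHU = 40, blobCount = 6L, blobAmp = 25,
                              noiseSd = 20,
                              betaTrue = c(volume = 1.0, asphericity = 0.5),
                              lambda0 = 0.05, cMax = 60,
                              seed = 1L) {
  if (nSubjects < 2L) stop("nSubjects must be >= 2")
  if (lambda0 <= 0) stop("lambda0 must be > 0")
  if (cMax <= 0) stop("cMax must be > 0")
  spec <- list(nSubjects = as.integer(nSubjects), gridShape = as.integer(gridShape),
               spacing = as.numeric(spacing), r0Range = r0Range,
               perturbScale = perturbScale, perturbDegree = as.integer(perturbDegree),
               baseHU = baseHU, blobCount = as.integer(blobCount),
               blobAmp = blobAmp, noiseSd = noiseSd,
               betaTrue = betaTrue, lambda0 = lambda0, cMax = cMax,
               seed = as.integer(seed))
  class(spec) <- "phantomCohortSpec"
  spec
}

# deterministic per-subject seed, kept well below 2^31
subjectSeed <- function(spec, subjectIndex, stream = 0L) {
  (spec$seed %% 19997L) * 100003L + subjectIndex * 13L + stream
}

# draw the analytic star-shaped solid for one subject
drawSolid <- function(spec, subjectIndex) {
  set.seed(subjectSeed(spec, subjectIndex, 0L))
  r0 <- stats::runif(1, spec$r0Range[1], spec$r0Range[2])
  L <- spec$perturbDegree
  nlm <- (L + 1)^2
  coef <- stats::rnorm(nlm, sd = spec$perturbScale / (1 + floor(sqrt(0:(nlm - 1)))))
  coef[1] <- 0  # degree 0 would only rescale r0
  # clamp so r(w) stays positive: check on a dense direction set
  chk <- sphericalGrid(16L)
  S <- realSphericalHarmonics(L, rep(chk@theta, each = 32), rep(chk@phi, 32))
  pert <- as.vector(S %*% coef)
  if (min(1 + pert) < 0.25) coef <- coef * (0.75 / max(-min(pert), 1e-9))
  # place the center on a voxel center so degenerate (sub-voxel) solids
  # voxelize to the single central voxel
  center <- (floor(spec$gridShape / 2) + 0.5) * spec$spacing
  list(center = center, r0 = r0, coef = coef, degree = L)
}

#' Analytic radial function of a star-shaped solid
#'
#' @param solid as returned in the \code{solid} element of
#'   \code{\link{generateMask}}
#' @param theta,phi directions from the solid's center
#' @return radii r(w), mm
#' @export
radialFunction <- function(solid, theta, phi) {
  S <- realSphericalHarmonics(solid$degree, theta, phi)
  solid$r0 * (1 + as.vector(S %*% solid$coef))
}

# physical voxel-center coordinates along each axis
voxelCenters <- function(shape, spacing, origin = c(0, 0, 0)) {
  lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 0.5) * spacing[a])
}

#' Generate the binary tumor mask of one phantom subject
#'
#' A voxel is foreground iff its center lies inside the subject's star-shaped
#' solid. The analytic solid parameters are returned alongside the mask so
#' tests can compare projections against the closed-form boundary.
#'
#' @param spec a \code{\link{phantomCohortSpec}}
#' @param subjectIndex subject number (1-based)
#' @return list with elements \code{mask} (\linkS4class{VoxelVolume}, binary)
#'   and \code{solid} (center mm, base radius r0, perturbation coefficients)
#' @export
generateMask <- function(spec, subjectIndex) {
  solid <- drawSolid(spec, subjectIndex)
  rmax <- solid$r0 * (1 + maxPerturbation(solid))
  if (any(rmax + 2 * spec$spacing > spec$gridShape * spec$spacing / 2))
    stop("subject ", subjectIndex, ": solid (max radius ~", round(rmax, 1),
         " mm) exceeds grid bounds; need a grid of at least ",
         ceiling(2 * (rmax + 2 * max(spec$spacing))), " mm per side")
  cen <- voxelCenters(spec$gridShape, spec$spacing)
  dx <- cen[[1]] - solid$center[1]
  dy <- cen[[2]] - solid$center[2]
  dz <- cen[[3]] - solid$center[3]
  D2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
  # only voxels that could possibly be inside need the angular evaluation
  cand <- which(D2 <= (solid$r0 * (1 + maxPerturbation(solid)))^2)
  vals <- array(0, spec$gridShape)
  if (length(cand)) {
    ijk <- arrayInd(cand, spec$gridShape)
    px <- cen[[1]][ijk[, 1]] - solid$center[1]
    py <- cen[[2]][ijk[, 2]] - solid$center[2]
    pz <- cen[[3]][ijk[, 3]] - solid$center[3]
    rr <- sqrt(px^2 + py^2 + pz^2)
    th <- acos(pmin(1, pmax(-1, ifelse(rr > 0, pz / pmax(rr, 1e-12), 1))))
    ph <- atan2(py, px)
    inside <- rr <= radialFunction(solid, th, ph)
    inside[rr == 0] <- TRUE
    vals[cand[inside]] <- 1
  }
  if (sum(vals) == 0)
    stop("subject ", subjectIndex, ": empty mask (solid smaller than a voxel?)")
  list(mask = new("VoxelVolume", values = vals, spacing = spec$spacing,
                  origin = c(0, 0, 0)),
       solid = solid)
}

maxPerturbation <- function(solid) {
  # conservative bound via dense evaluation (cached scale of the draw)
  chk <- sphericalGrid(16L)
  S <- realSphericalHarmonics(solid$degree, rep(chk@theta, each = 32),
                              rep(chk@phi, 32))
  max(abs(as.vector(S %*% solid$coef)))
}

#' Textured interior intensities for a phantom mask
#'
#' Inside the mask: \code{baseHU} plus smooth Gaussian blobs plus i.i.d.
#' noise. Outside: air at -1000 HU.
#'
#' @param mask binary \linkS4class{VoxelVolume}
#' @param baseHU,blobCount,blobAmp,noiseSd texture parameters
#' @param seed RNG seed
#' @return \linkS4class{VoxelVolume} of intensities (HU)
#' @export
generateIntensity <- function(mask, baseHU = 40, blobCount = 6L, blobAmp = 25,
                              noiseSd = 20, seed = 1L) {
  m <- voxelData(mask)
  if (sum(m) == 0) stop("mask is empty")
  set.seed(seed)
  shape <- dim(m)
  cen <- voxelCenters(shape, voxelSpacing(mask), voxelOrigin(mask))
  vals <- array(0, shape)
  idx <- which(m >= 0.5)
  ijk <- arrayInd(idx, shape)
  px <- cen[[1]][ijk[, 1]]; py <- cen[[2]][ijk[, 2]]; pz <- cen[[3]][ijk[, 3]]
  tex <- rep(baseHU, length(idx))
  if (blobCount > 0) {
    lo <- c(min(px), min(py), min(pz)); hi <- c(max(px), max(py), max(pz))
    for (b in seq_len(blobCount)) {
      bc <- stats::runif(3, lo, hi)
      amp <- stats::rnorm(1, 0, blobAmp)
      w <- stats::runif(1, 2, 5) * mean(voxelSpacing(mask))
      d2 <- (px - bc[1])^2 + (py - bc[2])^2 + (pz - bc[3])^2
      tex <- tex + amp * exp(-d2 / (2 * w^2))
    }
  }
  if (noiseSd > 0) tex <- tex + stats::rnorm(length(idx), 0, noiseSd)
  vals[] <- -1000
  vals[idx] <- tex
  new("VoxelVolume", values = vals, spacing = voxelSpacing(mask),
      origin = voxelOrigin(mask))
}

#' Simulate right-censored survival under a proportional-hazards law
#'
#' Latent event times are exponential with rate \code{lambda0 * exp(beta'x)}
#' (constant baseline hazard), drawn exactly by inverse transform
#' T* = -log(U) / (lambda0 exp(h)); censoring times are uniform on
#' [0, cMax], independent of the covariates.
#'
#' @param spec a \code{\link{phantomCohortSpec}} (supplies betaTrue, lambda0,
#'   cMax, seed)
#' @param covariates numeric matrix, one row per subject
#' @return \linkS4class{SurvivalCohort} with the true log-risk in the
#'   \code{risk} slot
#' @export
simulateSurvival <- function(spec, covariates) {
  covariates <- as.matrix(covariates)
  if (any(!is.finite(covariates))) stop("covariates must be finite")
  if (spec$lambda0 <= 0) stop("lambda0 must be > 0")
  n <- nrow(covariates)
  beta <- spec$betaTrue[seq_len(ncol(covariates))]
  h <- as.vector(covariates %*% beta)
  set.seed(subjectSeed(spec, 0L, 1L))
  U <- stats::runif(n)
  tstar <- -log(U) / (spec$lambda0 * exp(h))
  cens <- stats::runif(n, 0, spec$cMax)
  time <- pmin(tstar, cens)
  event <- as.integer(tstar <= cens)
  # guard: observation times must stay positive
  time <- pmax(time, 1e-6)
  survivalCohort(time, event, covariates = covariates, risk = h)
}

#' Generate a full phantom cohort
#'
#' Composes the mask, intensity and survival generators. The default
#' covariates are the standardized log tumor volume and the standardized
#' perturbation-magnitude ("asphericity") score, so that risk is a pure
#' function of shape and is learnable from the spherical projections.
#'
#' @param spec a \code{\link{phantomCohortSpec}}
#' @return list: \code{subjects} (per subject: \code{image}, \code{mask},
#'   \code{solid}), \code{cohort} (\linkS4class{SurvivalCohort}),
#'   \code{covariatesRaw} (unstandardized log volume / asphericity)
#' @export
generateCohort <- function(spec) {
  subjects <- vector("list", spec$nSubjects)
  logvol <- numeric(spec$nSubjects)
  asph <- numeric(spec$nSubjects)
  for (i in seq_len(spec$nSubjects)) {
    gm <- generateMask(spec, i)
    img <- generateIntensity(gm$mask, spec$baseHU, spec$blobCount,
                             spec$blobAmp, spec$noiseSd,
                             seed = subjectSeed(spec, i, 2L))
    subjects[[i]] <- list(image = img, mask = gm$mask, solid = gm$solid)
    logvol[i] <- log(sum(voxelData(gm$mask)) * prod(voxelSpacing(gm$mask)))
    asph[i] <- sqrt(sum(gm$solid$coef^2))
  }
  raw <- cbind(volume = logvol, asphericity = asph)
  std <- apply(raw, 2, function(v) {
    s <- stats::sd(v)
    if (s < 1e-12) rep(0, length(v)) else (v - mean(v)) / s
  })
  covs <- cbind(volume = std[, 1], asphericity = std[, 2])
  cohort <- simulateSurvival(spec, covs)
  list(subjects = subjects, cohort = cohort, covariatesRaw = raw)
}
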