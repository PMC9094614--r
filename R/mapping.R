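# Spherical projections of a segmented tumor.
#
# All three mappings are built relative to the tumor's center of mass and
# its enclosing sphere: depth and intensity by casting one ray per grid
# direction from the sphere surface to the centroid, the EGI by binning
# surface-normal directions of the triangulated mask boundary. Everything is
# computed in physical millimetres; voxel index (i,j,k) has its center at
# origin + (i-1/2, j-1/2, k-1/2) * spacing.

#' Center of mass of a binary mask
#'
#' Unweighted mean of the physical centers of foreground voxels.
#'
#' @param mask a binary \linkS4class{VoxelVolume}
#' @return 3-vector, mm
#' @export
centerOfMass <- function(mask) {
  m <- voxelData(mask)
  idx <- which(m >= 0.5)
  if (length(idx) == 0L) stop("mask is empty: center of mass undefined")
  ijk <- arrayInd(idx, dim(m))
  colMeans(sweep(sweep(ijk - 0.5, 2, voxelSpacing(mask), "*"), 2,
                 voxelOrigin(mask), "+"))
}

#' Radius of the enclosing sphere
#'
#' Maximum distance from \code{center} to any foreground voxel center plus a
#' one-voxel-diagonal margin, so every mask voxel lies strictly inside the
#' sphere.
#'
#' @param mask binary \linkS4class{VoxelVolume}
#' @param center sphere center, mm (defaults to the center of mass)
#' @return radius, mm
#' @export
enclosingRadius <- function(mask, center = centerOfMass(mask)) {
  m <- voxelData(mask)
  idx <- which(m >= 0.5)
  if (length(idx) == 0L) stop("mask is empty: enclosing radius undefined")
  ijk <- arrayInd(idx, dim(m))
  pos <- sweep(sweep(ijk - 0.5, 2, voxelSpacing(mask), "*"), 2,
               voxelOrigin(mask), "+")
  d <- sqrt(rowSums(sweep(pos, 2, center, "-")^2))
  max(d) + sqrt(sum(voxelSpacing(mask)^2))
}

# trilinear interpolation at physical points; outside the volume -> fill
trilinearInterpolate <- function(vol, pts, fill = 0) {
  v <- voxelData(vol)
  dims <- dim(v)
  sp <- voxelSpacing(vol); o <- voxelOrigin(vol)
  # continuous voxel coordinate: voxel center i at u = i (1-based)
  u <- sweep(sweep(pts, 2, o, "-"), 2, sp, "/") + 0.5
  i0 <- floor(u)
  fr <- u - i0
  out <- rep(fill, nrow(pts))
  ok <- i0[, 1] >= 1 & i0[, 1] < dims[1] &
        i0[, 2] >= 1 & i0[, 2] < dims[2] &
        i0[, 3] >= 1 & i0[, 3] < dims[3]
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]; fr <- fr[ok, , drop = FALSE]
  acc <- numeric(sum(ok))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    acc <- acc + w * v[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  out[ok] <- acc
  out
}

# unit direction vectors of every grid node, as a (4B^2) x 3 matrix in
# column-major (theta fastest) order matching matrix[j, k] vectorization
gridDirections <- function(grid) {
  th <- colatitudes(grid); ph <- longitudes(grid)
  n <- length(th)
  cbind(c(outer(sin(th), cos(ph))),
        c(outer(sin(th), sin(ph))),
        c(outer(cos(th), rep(1, n))))
}

# shared ray-marching: sample values of `vol` along rays from the sphere
# surface toward the centroid; returns values matrix (nsteps x ndirs) and the
# distances from the sphere surface
marchRays <- function(vol, center, radius, grid, step) {
  dirs <- gridDirections(grid)
  tt <- seq(0, radius, by = step)
  ndir <- nrow(dirs)
  pts <- matrix(0, ndir * length(tt), 3)
  for (a in 1:3) {
    pts[, a] <- center[a] + rep(dirs[, a], times = length(tt)) *
      rep(radius - tt, each = ndir)
  }
  vals <- trilinearInterpolate(vol, pts)
  list(values = matrix(vals, ndir, length(tt)), t = tt, ndir = ndir)
}

#' Depth-based spherical projection of a tumor mask
#'
#' For each grid direction a ray is cast from the enclosing sphere's surface
#' toward the centroid, marching in steps of half the minimum voxel spacing
#' and interpolating the mask trilinearly; the first sample at or above 0.5,
#' at distance d from the sphere, defines the radial extent
#' depth = R - d (mm) of the tumor along that direction. The crossing is
#' refined by linear interpolation between the bracketing samples. Rays that
#' never intersect the mask map to 0. Values are stored in mm (tumor size is
#' preserved); set \code{normalize} to divide by R.
#'
#' @param mask binary \linkS4class{VoxelVolume} (values in [0, 1])
#' @param grid a \linkS4class{SphericalGrid}
#' @param center,radius optionally precomputed centroid / enclosing radius
#' @param normalize divide depths by R
#' @return \linkS4class{SphericalMap} with channel \code{depth}
#' @export
depthProjection <- function(mask, grid, center = centerOfMass(mask),
                            radius = enclosingRadius(mask, center),
                            normalize = FALSE) {
  v <- voxelData(mask)
  if (min(v) < -1e-9 || max(v) > 1 + 1e-9)
    stop("mask values must lie in [0, 1] (binary or resampled binary)")
  step <- min(voxelSpacing(mask)) / 2
  mr <- marchRays(mask, center, radius, grid, step)
  B2 <- 2 * bandwidth(grid)
  depth <- numeric(mr$ndir)
  hit <- mr$values >= 0.5
  first <- apply(hit, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  has <- !is.na(first)
  if (any(has)) {
    i1 <- first[has]
    d <- mr$t[i1]
    refine <- i1 > 1
    if (any(refine)) {
      rows <- which(has)[refine]
      va <- mr$values[cbind(rows, i1[refine] - 1L)]
      vb <- mr$values[cbind(rows, i1[refine])]
      frac <- (0.5 - va) / (vb - va)
      d[refine] <- mr$t[i1[refine] - 1L] + frac * step
    }
    depth[has] <- radius - d
  }
  vals <- array(0, c(1, B2, B2))
  vals[1, , ] <- matrix(depth, B2, B2)
  if (normalize) vals <- vals / radius
  new("SphericalMap", grid = grid, values = vals, channels = "depth",
      centroid = as.numeric(center), radius = radius, normalized = normalize)
}

#' Affine CT intensity windowing
#'
#' Maps HU values in \code{window} linearly to [0, 1], clamping outside.
#' @param v intensities (HU)
#' @param window lower/upper HU bounds
#' @return windowed values in [0, 1]
#' @export
windowIntensity <- function(v, window = c(-1000, 400)) {
  out <- pmin(1, pmax(0, (v - window[1]) / (window[2] - window[1])))
  if (!is.null(dim(v))) dim(out) <- dim(v)
  out
}

#' Intensity-based spherical projection
#'
#' Accumulates the (windowed) image intensity within the tumor along every
#' ray from the sphere surface to the centroid: a line integral approximated
#' as sample sum times step length, in units of (windowed HU) x mm.
#'
#' @param image \linkS4class{VoxelVolume} of intensities (HU)
#' @param mask binary \linkS4class{VoxelVolume}, same geometry
#' @param grid a \linkS4class{SphericalGrid}
#' @param window HU window applied before accumulation
#' @param center,radius optionally precomputed geometry
#' @return \linkS4class{SphericalMap} with channel \code{intensity}
#' @export
intensityProjection <- function(image, mask, grid, window = c(-1000, 400),
                                center = centerOfMass(mask),
                                radius = enclosingRadius(mask, center)) {
  if (!identical(dim(voxelData(image)), dim(voxelData(mask))) ||
      max(abs(voxelSpacing(image) - voxelSpacing(mask))) > 1e-9 ||
      max(abs(voxelOrigin(image) - voxelOrigin(mask))) > 1e-9)
    stop("image and mask geometry differ")
  step <- min(voxelSpacing(mask)) / 2
  win <- new("VoxelVolume", values = windowIntensity(voxelData(image), window),
             spacing = voxelSpacing(image), origin = voxelOrigin(image))
  mrI <- marchRays(win, center, radius, grid, step)
  mrM <- marchRays(mask, center, radius, grid, step)
  acc <- rowSums(mrI$values * (mrM$values >= 0.5)) * step
  B2 <- 2 * bandwidth(grid)
  vals <- array(0, c(1, B2, B2))
  vals[1, , ] <- matrix(acc, B2, B2)
  new("SphericalMap", grid = grid, values = vals, channels = "intensity",
      centroid = as.numeric(center), radius = radius, normalized = FALSE)
}

# separable Gaussian smoothing in voxel units
gaussianSmooth3D <- function(v, sigma) {
  if (sigma <= 0) return(v)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  sm1 <- function(x, dimAlong) {
    d <- dim(x)
    perm <- switch(dimAlong, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    m <- matrix(xp, dp[1], dp[2] * dp[3])
    n <- dp[1]
    out <- matrix(0, n, ncol(m))
    for (o in (-r):r) {
      src <- pmin(pmax(seq_len(n) + o, 1L), n)   # replicate-pad
      out <- out + k[o + r + 1] * m[src, , drop = FALSE]
    }
    xp <- array(out, dp)
    aperm(xp, order(perm))
  }
  sm1(sm1(sm1(v, 1), 2), 3)
}

padVolume <- function(vol, pad = 2L, fill = 0) {
  v <- voxelData(vol)
  d <- dim(v)
  out <- array(fill, d + 2L * pad)
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- v
  new("VoxelVolume", values = out, spacing = voxelSpacing(vol),
      origin = voxelOrigin(vol) - pad * voxelSpacing(vol))
}

#' Extended Gaussian image of a tumor mask
#'
#' The orientation distribution of outward surface normals: the 0.5
#' isosurface of the (optionally Gaussian-smoothed) mask is triangulated by
#' marching tetrahedra; each triangle adds its area (mm^2) to the grid cell
#' containing its outward unit normal, and cell masses are divided by the
#' cell solid angle, giving a density on the sphere whose total integrated
#' mass equals the triangulated surface area. Masks touching the volume
#' border are zero-padded by 2 voxels before extraction.
#'
#' @param mask binary \linkS4class{VoxelVolume}
#' @param grid a \linkS4class{SphericalGrid}
#' @param sigma smoothing in voxels before surface extraction; 0 keeps the
#'   raw voxel isosurface (normals then collapse toward few directions)
#' @param center,radius optionally precomputed geometry (metadata only)
#' @return \linkS4class{SphericalMap} with channel \code{egi} plus attribute-free
#'   access to total mass via \code{\link{egiTotalMass}}
#' @export
egi <- function(mask, grid, sigma = 1,
                center = centerOfMass(mask),
                radius = enclosingRadius(mask, center)) {
  vol <- padVolume(mask, 2L)
  sm <- gaussianSmooth3D(voxelData(vol), sigma)
  tris <- tryCatch(
    marchingTetrahedra(sm, voxelSpacing(vol), voxelOrigin(vol), 0.5),
    error = function(e) stop("surface extraction failed (", conditionMessage(e),
                             "); if the mask touches the volume border, pad it"))
  smVol <- new("VoxelVolume", values = sm, spacing = voxelSpacing(vol),
               origin = voxelOrigin(vol))
  # outward orientation from the negative smoothed-mask gradient
  gradRef <- function(p) {
    eps <- min(voxelSpacing(vol)) / 2
    g <- sapply(1:3, function(a) {
      dp <- p; dm <- p
      dp[, a] <- dp[, a] + eps; dm[, a] <- dm[, a] - eps
      (trilinearInterpolate(smVol, dp) - trilinearInterpolate(smVol, dm)) / (2 * eps)
    })
    -matrix(g, nrow(p), 3)
  }
  geom <- triangleGeometry(tris, gradRef)
  B <- bandwidth(grid); B2 <- 2L * B
  th <- acos(pmin(1, pmax(-1, geom$normal[, 3])))
  ph <- atan2(geom$normal[, 2], geom$normal[, 1]) %% (2 * pi)
  jrow <- pmin(B2, pmax(1L, ceiling(th / (pi / B2))))
  kcol <- (floor((ph + pi / B2) / (pi / B)) %% B2) + 1L
  mass <- matrix(0, B2, B2)
  cell <- jrow + (kcol - 1L) * B2
  agg <- rowsum(geom$area, cell)
  mass[as.integer(rownames(agg))] <- agg[, 1]
  omega <- cellSolidAngles(grid)
  vals <- array(0, c(1, B2, B2))
  vals[1, , ] <- mass / omega
  out <- new("SphericalMap", grid = grid, values = vals, channels = "egi",
             centroid = as.numeric(center), radius = radius, normalized = FALSE)
  out
}

#' Solid angles of the grid cells
#'
#' Cell (j, k) spans colatitudes [pi j/(2B), pi (j+1)/(2B)) and a longitude
#' band of width pi/B centered on phi_k.
#' @param grid a \linkS4class{SphericalGrid}
#' @return 2B x 2B matrix of solid angles, summing to 4 pi
#' @export
cellSolidAngles <- function(grid) {
  B <- bandwidth(grid); B2 <- 2L * B
  edges <- pi * (0:B2) / B2
  band <- (cos(edges[-(B2 + 1)]) - cos(edges[-1])) * (pi / B)
  matrix(band, B2, B2)
}

#' Total mass of an EGI map
#'
#' Sum of cell density times exact cell solid angle; equals the triangulated
#' surface area by construction.
#' @param map SphericalMap with an \code{egi} channel
#' @return total surface area, mm^2
#' @export
egiTotalMass <- function(map) {
  sum(mapChannel(map, "egi") * cellSolidAngles(map@grid))
}

#' Assemble the network input channels
#'
#' \code{sphcnn1} uses only the mask's depth projection; \code{sphcnn2} uses
#' the EGI and the image's intensity projection. Channel standardization is
#' not applied here: it uses training-split statistics stored in the model
#' (see \code{\link{trainRiskModel}}).
#'
#' @param config \code{"sphcnn1"} or \code{"sphcnn2"}
#' @param image \linkS4class{VoxelVolume} (HU); unused by sphcnn1
#' @param mask binary \linkS4class{VoxelVolume}
#' @param grid a \linkS4class{SphericalGrid}
#' @param window HU window for the intensity projection
#' @param sigma EGI smoothing (voxels)
#' @return \linkS4class{SphericalMap} with 1 (sphcnn1) or 2 (sphcnn2) channels
#' @export
makeInput <- function(config = c("sphcnn1", "sphcnn2"), image, mask, grid,
                      window = c(-1000, 400), sigma = 1) {
  config <- match.arg(config)
  center <- centerOfMass(mask)
  radius <- enclosingRadius(mask, center)
  if (config == "sphcnn1") {
    return(depthProjection(mask, grid, center, radius))
  }
  e <- egi(mask, grid, sigma, center, radius)
  it <- intensityProjection(image, mask, grid, window, center, radius)
  B2 <- 2L * bandwidth(grid)
  vals <- array(0, c(2, B2, B2))
  vals[1, , ] <- mapChannel(e, "egi")
  vals[2, , ] <- mapChannel(it, "intensity")
  new("SphericalMap", grid = grid, values = vals,
      channels = c("egi", "intensity"), centroid = center, radius = radius,
      normalized = FALSE)
}

#' Resample a volume under a rotation about a fixed point
#'
#' Used to probe rotation invariance: values are pulled back through the
#' rotation with trilinear interpolation, so a binary mask becomes a
#' continuous [0, 1] field with the rotated shape.
#'
#' @param vol a \linkS4class{VoxelVolume}
#' @param R 3x3 rotation matrix
#' @param center rotation center, mm
#' @param fill value outside the original volume
#' @return rotated \linkS4class{VoxelVolume}
#' @export
rotateVolume <- function(vol, R, center, fill = 0) {
  d <- dim(voxelData(vol))
  cen <- voxelCenters(d, voxelSpacing(vol), voxelOrigin(vol))
  pts <- cbind(rep(cen[[1]], times = d[2] * d[3]),
               rep(rep(cen[[2]], each = d[1]), times = d[3]),
               rep(cen[[3]], each = d[1] * d[2]))
  q <- sweep(sweep(pts, 2, center, "-") %*% R, 2, center, "+")
  vals <- array(trilinearInterpolate(vol, q, fill = fill), d)
  new("VoxelVolume", values = vals, spacing = voxelSpacing(vol),
      origin = voxelOrigin(vol))
}
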