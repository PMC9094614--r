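# Spherical projections: geometry, depth/intensity oracles, EGI, inputs.

mkVolume <- function(vals, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("VoxelVolume", values = vals, spacing = spacing, origin = origin)
}

test_that("center of mass follows the center-of-voxel convention", {
  v <- array(0, c(8, 8, 8)); v[4, 5, 6] <- 1
  expect_equal(centerOfMass(mkVolume(v)), c(3.5, 4.5, 5.5))
  v2 <- array(0, c(8, 8, 8)); v2[1, 1, 1] <- 1; v2[1, 1, 3] <- 1
  expect_equal(centerOfMass(mkVolume(v2)), c(0.5, 0.5, 1.5))
  expect_error(centerOfMass(mkVolume(array(0, c(4, 4, 4)))), "empty")
})

test_that("digitized ball centroid lies within half a voxel of the solid center", {
  spec <- phantomCohortSpec(nSubjects = 2, r0Range = c(8, 8),
                            perturbScale = 0, seed = 3)
  gm <- generateMask(spec, 1)
  expect_lt(max(abs(centerOfMass(gm$mask) - gm$solid$center)), 0.5)
})

test_that("enclosing radius bounds the ball with the one-diagonal margin", {
  spec <- phantomCohortSpec(nSubjects = 2, r0Range = c(8, 8),
                            perturbScale = 0, seed = 3)
  gm <- generateMask(spec, 1)
  R <- enclosingRadius(gm$mask)
  expect_gte(R, 8)
  expect_lte(R, 8 + sqrt(3) + 0.5)
  # single voxel: margin only
  v <- array(0, c(6, 6, 6)); v[3, 3, 3] <- 1
  expect_equal(enclosingRadius(mkVolume(v)), sqrt(3))
  # 90-degree rotation about a grid axis is an isometry
  m <- voxelData(gm$mask)
  rot <- aperm(m, c(2, 1, 3))[dim(m)[2]:1, , ]
  expect_equal(enclosingRadius(mkVolume(rot)), R, tolerance = 1e-9)
})

test_that("depth projection recovers the ball radius everywhere", {
  spec <- phantomCohortSpec(nSubjects = 2, r0Range = c(8, 8),
                            perturbScale = 0, seed = 3)
  gm <- generateMask(spec, 1)
  d <- mapChannel(depthProjection(gm$mask, sphericalGrid(16)), "depth")
  expect_lt(max(abs(d - 8)), halfVoxelDiagonal())
})

test_that("depth projection matches the analytic star-shaped radial function", {
  g <- sphericalGrid(16)
  th <- rep(colatitudes(g), times = 32)
  ph <- rep(longitudes(g), each = 32)
  fx <- phantomFixture()
  for (i in 1:5) {
    gm <- fx$subjects[[i]]
    dp <- depthProjection(gm$mask, g, center = gm$solid$center)
    d <- as.vector(mapChannel(dp, "depth"))
    ra <- radialFunction(gm$solid, th, ph)
    expect_lt(max(abs(d - ra)), halfVoxelDiagonal())
  }
})

test_that("rays that miss the mask record zero depth", {
  v <- array(0, c(20, 20, 20)); v[3:5, 3:5, 3:5] <- 1   # off-center blob
  vol <- mkVolume(v)
  # cast rays about a far-away center: directions opposite the blob miss it
  d <- mapChannel(depthProjection(vol, sphericalGrid(8),
                                  center = c(15, 15, 15), radius = 25), "depth")
  expect_true(any(d == 0))
  expect_true(any(d > 0))
})

test_that("intensity projection integrates windowed intensity along rays", {
  spec <- phantomCohortSpec(nSubjects = 2, r0Range = c(8, 8),
                            perturbScale = 0, seed = 3)
  gm <- generateMask(spec, 1)
  # image with windowed value 1 inside the mask (400 HU -> 1)
  img <- mkVolume(array(400, dim(voxelData(gm$mask))))
  it <- intensityProjection(img, gm$mask, sphericalGrid(16))
  v <- mapChannel(it, "intensity")
  expect_lt(max(abs(v - 8)), 2 * halfVoxelDiagonal())

  # zero (after windowing) image -> all-zero map
  img0 <- mkVolume(array(-1000, dim(voxelData(gm$mask))))
  expect_equal(max(abs(mapChannel(
    intensityProjection(img0, gm$mask, sphericalGrid(16)), "intensity"))), 0)

  # windowed intensity 0.25 vs 0.5: exact linearity of the accumulation
  imgA <- mkVolume(array(-650, dim(voxelData(gm$mask))))   # windowed 0.25
  imgB <- mkVolume(array(-300, dim(voxelData(gm$mask))))   # windowed 0.50
  vA <- mapChannel(intensityProjection(imgA, gm$mask, sphericalGrid(16)),
                   "intensity")
  vB <- mapChannel(intensityProjection(imgB, gm$mask, sphericalGrid(16)),
                   "intensity")
  expect_equal(2 * vA, vB, tolerance = 1e-12)

  expect_error(intensityProjection(mkVolume(array(0, c(4, 4, 4))), gm$mask,
                                   sphericalGrid(8)), "geometry")
})

test_that("EGI mass is conserved exactly and matches analytic areas", {
  spec <- phantomCohortSpec(nSubjects = 2, r0Range = c(8, 8),
                            perturbScale = 0, seed = 3)
  gm <- generateMask(spec, 1)
  g <- sphericalGrid(16)
  e <- egi(gm$mask, g, sigma = 1)
  expect_gte(min(mapChannel(e, "egi")), 0)

  # conservation: binned mass equals the triangulated surface area
  vol <- sphsurv:::padVolume(gm$mask, 2L)
  sm <- sphsurv:::gaussianSmooth3D(voxelData(vol), 1)
  tris <- sphsurv:::marchingTetrahedra(sm, voxelSpacing(vol), voxelOrigin(vol))
  e1 <- tris$v2 - tris$v1; e2 <- tris$v3 - tris$v1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  areaSum <- sum(sqrt(rowSums(cr^2)) / 2)
  expect_lt(abs(egiTotalMass(e) - areaSum) / areaSum, 1e-6)

  # ball: total mass within 10% of 4*pi*r^2
  expect_lt(abs(egiTotalMass(e) - 4 * pi * 64) / (4 * pi * 64), 0.10)
})

test_that("cube EGI concentrates >= 90% of its mass in six 15-degree caps", {
  v <- array(0, c(24, 24, 24)); v[5:20, 5:20, 5:20] <- 1
  g <- sphericalGrid(16)
  e <- egi(mkVolume(v), g, sigma = 0)
  mass <- mapChannel(e, "egi") * cellSolidAngles(g)
  th <- rep(colatitudes(g), times = 32)
  ph <- rep(longitudes(g), each = 32)
  dirs <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  axes <- rbind(diag(3), -diag(3))
  inCap <- apply(dirs %*% t(axes), 1, max) >= cos(15 * pi / 180)
  expect_gte(sum(mass[matrix(inCap, 32, 32)]) / sum(mass), 0.90)
  # each face cap carries roughly one sixth of the mass
  for (a in 1:6) {
    cap <- dirs %*% axes[a, ] >= cos(15 * pi / 180)
    expect_lt(abs(sum(mass[matrix(cap, 32, 32)]) / sum(mass) - 1 / 6), 0.05)
  }
})

test_that("cell solid angles tile the sphere", {
  expect_equal(sum(cellSolidAngles(sphericalGrid(12))), 4 * pi,
               tolerance = 1e-10)
})

test_that("input assembly matches the two published channel configurations", {
  fx <- phantomFixture()
  gm <- fx$subjects[[1]]
  img <- generateIntensity(gm$mask, seed = 2)
  g <- sphericalGrid(8)
  m1 <- makeInput("sphcnn1", img, gm$mask, g)
  expect_identical(channelNames(m1), "depth")
  m2 <- makeInput("sphcnn2", img, gm$mask, g)
  expect_identical(channelNames(m2), c("egi", "intensity"))
  expect_error(makeInput("sphcnn3", img, gm$mask, g))
})

test_that("training-split standardization gives mean 0 and sd 1", {
  fx <- phantomFixture()
  g <- sphericalGrid(8)
  maps <- lapply(fx$subjects, function(s) depthProjection(s$mask, g))
  cfg <- networkConfig(8, "sphcnn1", c1 = 2, c2 = 2, l1 = 4, l2 = 2)
  model <- newRiskModel(cfg, 1)
  model@normStats <- sphsurv:::computeNormStats(maps, 1:3)
  std <- unlist(lapply(1:3, function(i)
    sphsurv:::standardizeInput(model, maps[[i]])))
  expect_lt(abs(mean(std)), 1e-9)
  expect_lt(abs(sd(std) - 1), 1e-3)   # sd vs population-sd convention
})

test_that("projections are invariant to integer-voxel translations", {
  spec <- phantomCohortSpec(nSubjects = 2, seed = 13,
                            gridShape = c(56L, 56L, 56L))
  gm <- generateMask(spec, 1)
  m <- voxelData(gm$mask)
  shifted <- array(0, dim(m))
  shifted[4:56, 1:54, 2:56] <- m[1:53, 3:56, 1:55]
  g <- sphericalGrid(8)
  d0 <- mapChannel(depthProjection(gm$mask, g), "depth")
  d1 <- mapChannel(depthProjection(mkVolume(shifted), g), "depth")
  expect_equal(d0, d1, tolerance = 1e-9)
})

test_that("a quarter turn about the polar axis shifts the depth map by B columns", {
  fx <- phantomFixture()
  gm <- fx$subjects[[2]]
  m <- voxelData(gm$mask)
  # 90-degree rotation in the xy-plane about the grid center
  rot <- aperm(m, c(2, 1, 3))[dim(m)[2]:1, , ]
  g <- sphericalGrid(16)
  d0 <- mapChannel(depthProjection(gm$mask, g), "depth")
  d1 <- mapChannel(depthProjection(mkVolume(rot), g), "depth")
  # 90 degrees = B/2 longitude steps of pi/B; this array transform rotates
  # clockwise in the longitude indexing, so the cyclic shift is 3B/2
  shift <- 24
  expect_lt(max(abs(d1 - d0[, c((shift + 1):32, 1:shift)])),
            halfVoxelDiagonal())
})
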