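# Spectral convolutions against brute-force integration of their definitions,
# equivariance, pooling and the invariant readout.

# quadrature evaluation of (psi star f)(R) = int f(w) conj(psi(R^-1 w)) dw
directS2Correlation <- function(fh, ph, R, Bq = 16) {
  g <- sphericalGrid(Bq)
  th <- rep(colatitudes(g), times = 2 * Bq)
  phl <- rep(longitudes(g), each = 2 * Bq)
  dirs <- cbind(sin(th) * cos(phl), sin(th) * sin(phl), cos(th))
  wts <- rep(quadratureWeights(g), times = 2 * Bq) * pi / Bq
  fv <- shtEvaluate(fh, th, phl)
  rw <- dirs %*% R
  pv <- shtEvaluate(ph, acos(pmin(1, pmax(-1, rw[, 3]))), atan2(rw[, 2], rw[, 1]))
  sum(wts * fv * pv)
}

test_that("s2 correlation agrees with direct numerical integration", {
  B <- 8
  set.seed(21)
  fh <- randomRealCoefficients(B)
  ph <- randomRealCoefficients(B)
  blocks <- s2Conv(matrix(fh, ncol = 1),
                   array(ph, c(B^2, 1, 1)))
  gout <- so3Synthesize(blocks)
  sb <- sphsurv:::so3Basis(B)
  for (tc in list(c(1, 1, 1), c(3, 5, 2), c(7, 2, 6), c(12, 9, 15))) {
    R <- rotationZYZ(sb$ang[tc[1]], sb$beta[tc[2]], sb$ang[tc[3]])
    direct <- directS2Correlation(fh, ph, R)
    spec <- gout[tc[1], tc[2], tc[3], 1]
    expect_lt(abs(direct - spec) / max(abs(direct), 1e-6), 1e-5)
  }
})

test_that("constant signal and filter correlate to the constant c*d*4*pi", {
  B <- 8
  fh <- rep(0 + 0i, B^2); fh[1] <- 3 * sqrt(4 * pi)    # constant 3
  ph <- rep(0 + 0i, B^2); ph[1] <- 2 * sqrt(4 * pi)    # constant 2
  gout <- so3Synthesize(s2Conv(matrix(fh, ncol = 1), array(ph, c(B^2, 1, 1))))
  expect_equal(range(gout), rep(3 * 2 * 4 * pi, 2), tolerance = 1e-10)
})

test_that("zero filters and zero signals give zero outputs", {
  B <- 4
  fh <- randomBandLimited(B, 22)$fh
  zero <- array(0 + 0i, c(B^2, 1, 1))
  expect_equal(max(abs(so3Synthesize(s2Conv(matrix(fh, ncol = 1), zero)))), 0)
  blocks <- sphsurv:::emptyBlocks(B, 1L)
  chih <- lapply(0:(B - 1), function(l)
    array(1 + 1i, c(2 * l + 1, 2 * l + 1, 1, 2)))
  out <- so3Conv(blocks, chih)
  expect_equal(max(vapply(out, function(b) max(abs(b)), numeric(1))), 0)
})

test_that("s2 correlation is equivariant under polar grid rotations", {
  B <- 8
  set.seed(23)
  fh <- randomRealCoefficients(B)
  ph <- randomRealCoefficients(B)
  psih <- array(ph, c(B^2, 1, 1))
  g0 <- so3Synthesize(s2Conv(matrix(fh, ncol = 1), psih))
  k <- 5                                  # rotate input by alpha = pi*k/B
  fhRot <- rotateCoefficients(fh, pi * k / B, 0, 0)
  g1 <- so3Synthesize(s2Conv(matrix(fhRot, ncol = 1), psih))
  # output is left-translated: alpha index shifts by k
  shift <- function(g, k) g[c((k + 1):(2 * B), 1:k), , , , drop = FALSE]
  expect_lt(max(abs(g1 - shift(g0, 2 * B - k))), 1e-6)
})

test_that("so3 correlation agrees with direct group-integral evaluation", {
  B <- 4
  set.seed(24)
  sig <- symmetrizeSO3(lapply(0:(B - 1), function(l) {
    n <- (2 * l + 1)^2
    array(complex(real = rnorm(n), imaginary = rnorm(n)),
          c(2 * l + 1, 2 * l + 1, 1))
  }))
  chi <- lapply(0:(B - 1), function(l) {
    n <- (2 * l + 1)^2
    array(complex(real = rnorm(n), imaginary = rnorm(n)),
          c(2 * l + 1, 2 * l + 1, 1, 1))
  })
  out <- so3Conv(sig, chi)
  ogrid <- so3Synthesize(out)
  # direct: int g(Q) conj(chi(R^-1 Q)) dQ on a finer exact quadrature grid
  Lq <- 6
  sbq <- sphsurv:::so3Basis(Lq)
  sigPad <- c(sig, lapply(B:(Lq - 1), function(l)
    array(0 + 0i, c(2 * l + 1, 2 * l + 1, 1))))
  gq <- so3Synthesize(sigPad)
  chiBlocks <- lapply(chi, function(a) array(a[, , 1, 1], c(dim(a)[1], dim(a)[2], 1)))
  sb <- sphsurv:::so3Basis(B)
  for (tc in list(c(3, 5, 2), c(1, 2, 7))) {
    R <- rotationZYZ(sb$ang[tc[1]], sb$beta[tc[2]], sb$ang[tc[3]])
    direct <- 0
    for (a in 1:(2 * Lq)) for (j in 1:(2 * Lq)) for (cc in 1:(2 * Lq)) {
      Q <- rotationZYZ(sbq$ang[a], sbq$beta[j], sbq$ang[cc])
      direct <- direct + sbq$wq[j] * gq[a, j, cc, 1] *
        sphsurv:::so3Evaluate(chiBlocks, t(R) %*% Q)
    }
    spec <- ogrid[tc[1], tc[2], tc[3], 1]
    expect_lt(abs(direct - spec) / max(abs(direct), 1e-6), 1e-5)
  }
})

test_that("scaled-identity so3 filters rescale the spectrum blockwise", {
  B <- 4
  set.seed(25)
  sig <- symmetrizeSO3(lapply(0:(B - 1), function(l) {
    n <- (2 * l + 1)^2
    array(complex(real = rnorm(n), imaginary = rnorm(n)),
          c(2 * l + 1, 2 * l + 1, 1))
  }))
  chi <- lapply(0:(B - 1), function(l)
    array(diag(2 * l + 1) * 0.5 + 0i, c(2 * l + 1, 2 * l + 1, 1, 1)))
  out <- so3Conv(sig, chi)
  for (l in 0:(B - 1)) {
    s <- 8 * pi^2 / (2 * l + 1)
    expect_equal(out[[l + 1]], sig[[l + 1]] * (0.5 * s), tolerance = 1e-10)
  }
})

test_that("so3 correlation is left-translation equivariant on the alpha grid", {
  L <- 4
  set.seed(26)
  sig <- symmetrizeSO3(lapply(0:(L - 1), function(l) {
    n <- (2 * l + 1)^2
    array(complex(real = rnorm(n), imaginary = rnorm(n)),
          c(2 * l + 1, 2 * l + 1, 1))
  }))
  chi <- lapply(0:(L - 1), function(l) {
    n <- (2 * l + 1)^2
    array(complex(real = rnorm(n), imaginary = rnorm(n)),
          c(2 * l + 1, 2 * l + 1, 1, 1))
  })
  g0 <- so3Synthesize(so3Conv(sig, chi))
  # left translation by Rz(alpha_k): row phases e^{-i m alpha} on the spectra
  k <- 3
  alpha <- pi * k / L
  translate <- function(blocks) lapply(0:(L - 1), function(l)
    blocks[[l + 1]] * exp(-1i * ((-l):l) * alpha))
  shift <- function(g, s) g[c((s + 1):(2 * L), 1:s), , , , drop = FALSE]
  # confirm the phase convention translates the grid as expected ...
  gS <- so3Synthesize(translate(sig))
  expect_lt(max(abs(gS - shift(so3Synthesize(sig), 2 * L - k))), 1e-8)
  # ... then equivariance: convolving the translated signal translates the output
  g1 <- so3Synthesize(so3Conv(translate(sig), chi))
  expect_lt(max(abs(g1 - shift(g0, 2 * L - k))), 1e-6)
})

test_that("spherical pooling preserves constants and never raises energy", {
  L <- 8
  bl <- sphsurv:::emptyBlocks(L, 1L)
  bl[[1]][1, 1, 1] <- 1.7
  g <- so3Synthesize(bl)
  p <- sphericalPool(g, 2)
  expect_equal(range(p), c(1.7, 1.7), tolerance = 1e-10)

  set.seed(27)
  g2 <- array(rnorm((2 * L)^3), c(2 * L, 2 * L, 2 * L, 1))
  p2 <- sphericalPool(g2, 2)
  sbL <- sphsurv:::so3Basis(L)
  sb2 <- sphsurv:::so3Basis(L / 2)
  eIn <- sum(sweep(g2, 2, sbL$wq, "*") * g2)
  eOut <- sum(sweep(p2, 2, sb2$wq, "*") * p2)
  expect_lte(eOut, eIn + 1e-9)
  expect_error(sphericalPool(g2, 3), "divisible")
})

test_that("pooling is exact resampling for signals below the cutoff", {
  L <- 8
  set.seed(28)
  blLow <- symmetrizeSO3(lapply(0:(L / 2 - 1), function(l) {
    n <- (2 * l + 1)^2
    array(complex(real = rnorm(n), imaginary = rnorm(n)),
          c(2 * l + 1, 2 * l + 1, 1))
  }))
  blFull <- c(blLow, lapply((L / 2):(L - 1), function(l)
    array(0 + 0i, c(2 * l + 1, 2 * l + 1, 1))))
  g <- so3Synthesize(blFull)
  expect_lt(max(abs(sphericalPool(g, 2) - so3Synthesize(blLow))), 1e-8)
})

test_that("invariant readout integrates constants to c*8*pi^2 and is rotation invariant", {
  L <- 4
  bl <- sphsurv:::emptyBlocks(L, 1L)
  bl[[1]][1, 1, 1] <- 2
  g <- so3Synthesize(bl)
  feat <- invariantReadout(g)
  expect_equal(feat[1], 2 * 8 * pi^2, tolerance = 1e-9)
  expect_equal(invariantReadout(array(0, c(8, 8, 8, 2))), rep(0, 4))

  set.seed(29)
  sig <- symmetrizeSO3(lapply(0:(L - 1), function(l) {
    n <- (2 * l + 1)^2
    array(complex(real = rnorm(n), imaginary = rnorm(n)),
          c(2 * l + 1, 2 * l + 1, 1))
  }))
  g1 <- so3Synthesize(sig)
  k <- 2
  sigT <- lapply(0:(L - 1), function(l)
    sig[[l + 1]] * exp(1i * ((-l):l) * pi * k / L))
  g2 <- so3Synthesize(sigT)
  expect_lt(max(abs(invariantReadout(g1) - invariantReadout(g2))), 1e-6)
})
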