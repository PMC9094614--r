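# The spherical risk network.
#
# Topology (three layers, fixed per the shallow-is-better finding):
#   S2 conv (spectral filters, Cin -> C1) -> bias -> ReLU on the SO(3) grid
#   -> spherical pool (bandwidth l1 -> l2)
#   -> SO(3) conv (Wigner-block filters, C1 -> C2) -> bias -> ReLU
#   -> spherical pool (l2 -> l3)
#   -> rotation-invariant readout (integral + L2 norm per channel)
#   -> dense layer with 40 features (+ ReLU) -> linear scalar output h.
#
# The scalar output approximates the log-risk h_theta(x) of the generalized
# proportional-hazards model; rotation invariance holds because every layer
# before the readout is rotation-equivariant and the readout integrates over
# the group. Filters are parameterized directly by their (unconstrained)
# spectral coefficients and projected onto the real-signal subspace in the
# forward pass; gradients are hand-derived and checked against central
# differences in the tests.

#' Architecture configuration for the risk network
#'
#' @param bandwidth input grid bandwidth B (input maps are 2B x 2B)
#' @param inputConfig \code{"sphcnn1"} (single depth channel) or
#'   \code{"sphcnn2"} (EGI + intensity channels)
#' @param c1,c2 channel widths of the two convolutional layers
#' @param l1,l2 bandwidths after the first/second layer (defaults B/2, B/4)
#' @param useL2Stat include the L2-norm readout statistic alongside the mean
#' @param reluDense apply ReLU after the 40-feature dense layer
#' @return named list, the \code{config} slot of a \linkS4class{RiskModel}
#' @export
networkConfig <- function(bandwidth = 16L, inputConfig = c("sphcnn1", "sphcnn2"),
                          c1 = 8L, c2 = 16L,
                          l1 = bandwidth / 2L, l2 = bandwidth / 4L,
                          useL2Stat = TRUE, reluDense = TRUE) {
  inputConfig <- match.arg(inputConfig)
  channelsIn <- if (inputConfig == "sphcnn1") 1L else 2L
  l1 <- as.integer(l1); l2 <- as.integer(l2)
  if (l1 > bandwidth || l2 > l1 || l2 < 2L || l2 %% 2L != 0L)
    stop("layer bandwidths must satisfy B >= l1 >= l2 >= 2 with l2 even")
  list(bandwidth = as.integer(bandwidth), inputConfig = inputConfig,
       channelsIn = channelsIn, c1 = as.integer(c1), c2 = as.integer(c2),
       l1 = l1, l2 = l2, l3 = as.integer(l2 / 2L), dense = 40L,
       useL2Stat = useL2Stat, reluDense = reluDense)
}

# He-style spectral initialization: coefficient variance scaled by fan-in
initParams <- function(cfg) {
  nlm1 <- cfg$l1^2
  psi <- array(complex(real = stats::rnorm(nlm1 * cfg$channelsIn * cfg$c1),
                       imaginary = stats::rnorm(nlm1 * cfg$channelsIn * cfg$c1)),
               c(nlm1, cfg$channelsIn, cfg$c1)) *
    sqrt(1 / (cfg$channelsIn * nlm1))
  chi <- lapply(0:(cfg$l2 - 1), function(l) {
    K <- 2 * l + 1
    n <- K * K * cfg$c1 * cfg$c2
    array(complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)),
          c(K, K, cfg$c1, cfg$c2)) *
      sqrt(1 / (cfg$c1 * cfg$l2^2)) / (8 * pi^2 / (2 * l + 1))
  })
  nfeat <- cfg$c2 * (if (cfg$useL2Stat) 2L else 1L)
  list(psi = psi, bias1 = rep(0, cfg$c1),
       chi = chi, bias2 = rep(0, cfg$c2),
       W1 = matrix(stats::rnorm(cfg$dense * nfeat, sd = sqrt(2 / nfeat)),
                   cfg$dense, nfeat),
       bd1 = rep(0, cfg$dense),
       W2 = matrix(stats::rnorm(cfg$dense, sd = sqrt(2 / cfg$dense)), 1, cfg$dense),
       bd2 = 0)
}

#' Create an untrained risk model
#'
#' @param config from \code{\link{networkConfig}}
#' @param seed RNG seed for the parameter initialization
#' @return a \linkS4class{RiskModel}
#' @export
newRiskModel <- function(config = networkConfig(), seed = 1L) {
  set.seed(seed)
  new("RiskModel", config = config, params = initParams(config),
      normStats = list())
}

# batched forward pass: X is (S, Cin, 2B, 2B), already standardized.
# Samples ride along the channel dimension of every SO(3) grid (channel
# order: filter output fastest, then sample). Returns the h vector and, if
# keepCache, every intermediate the backward pass needs.
riskForwardBatch <- function(params, cfg, X, keepCache = FALSE) {
  S <- dim(X)[1]; Cin <- cfg$channelsIn
  fh1 <- array(0 + 0i, c(cfg$l1^2, Cin, S))
  for (s in seq_len(S)) for (cc in seq_len(Cin))
    fh1[, cc, s] <- truncateCoefficients(shtForward(X[s, cc, , ]), cfg$l1)

  psiS <- params$psi
  for (ci in seq_len(Cin)) for (co in seq_len(cfg$c1))
    psiS[, ci, co] <- symmetrizeS2(psiS[, ci, co])

  bl1 <- s2ConvBatch(fh1, psiS)
  z1 <- so3Synthesize(bl1, cfg$l1)
  z1 <- sweep(z1, 4, rep(params$bias1, times = S), "+")
  a1 <- relu(z1)
  g1p <- sphericalPool(a1, cfg$l1 / cfg$l2)

  sig2 <- so3Analyze(g1p, cfg$l2)
  chiS <- lapply(params$chi, function(a) {
    d <- dim(a)
    array(symmetrizeSO3Block(array(a, c(d[1], d[2], d[3] * d[4]))), d)
  })
  bl2 <- so3ConvBatch(sig2, chiS, S)
  z2 <- so3Synthesize(bl2, cfg$l2)
  z2 <- sweep(z2, 4, rep(params$bias2, times = S), "+")
  a2 <- relu(z2)
  g2p <- sphericalPool(a2, cfg$l2 / cfg$l3)

  featFlat <- invariantReadout(g2p, cfg$useL2Stat)   # (C2*S) or (2*C2*S)
  C2 <- cfg$c2
  feat <- if (cfg$useL2Stat) {
    rbind(matrix(featFlat[seq_len(C2 * S)], C2, S),
          matrix(featFlat[C2 * S + seq_len(C2 * S)], C2, S))
  } else matrix(featFlat, C2, S)
  pre1 <- sweep(params$W1 %*% feat, 1, params$bd1, "+")
  act1 <- if (cfg$reluDense) relu(pre1) else pre1
  h <- as.vector(params$W2 %*% act1) + params$bd2

  if (!keepCache) return(list(h = h))
  list(h = h, S = S, fh1 = fh1, psiS = psiS, z1 = z1, g1p = g1p,
       sig2 = sig2, chiS = chiS, z2 = z2, g2p = g2p,
       feat = feat, pre1 = pre1, act1 = act1)
}

# batched backward: gradH is the vector dLoss/dh; returns parameter
# gradients summed over the batch
riskBackwardBatch <- function(params, cfg, cache, gradH) {
  S <- cache$S; C2 <- cfg$c2
  g <- list()
  gH <- matrix(gradH, 1, S)
  g$W2 <- gH %*% t(cache$act1)
  g$bd2 <- sum(gradH)
  gAct1 <- t(params$W2) %*% gH                      # (dense x S)
  gPre1 <- if (cfg$reluDense) gAct1 * (cache$pre1 > 0) else gAct1
  g$W1 <- gPre1 %*% t(cache$feat)
  g$bd1 <- rowSums(gPre1)
  gFeat <- t(params$W1) %*% gPre1                   # (nfeat x S)

  gFeatFlat <- if (cfg$useL2Stat) {
    c(as.vector(gFeat[seq_len(C2), , drop = FALSE]),
      as.vector(gFeat[C2 + seq_len(C2), , drop = FALSE]))
  } else as.vector(gFeat)
  gG2p <- invariantReadoutBackward(gFeatFlat, cache$g2p, cfg$useL2Stat)
  gA2 <- sphericalPoolAdjoint(gG2p, cfg$l2, cfg$l2 / cfg$l3)
  gZ2 <- gA2 * (cache$z2 > 0)
  g$bias2 <- rowSums(matrix(apply(gZ2, 4, sum), C2, S))
  gBl2 <- so3SynthesizeAdjoint(gZ2, cfg$l2)
  cb <- so3ConvBatchBackward(gBl2, cache$sig2, cache$chiS, S)
  g$chi <- lapply(cb$filter, function(a) {
    d <- dim(a)
    array(symmetrizeSO3Block(array(a, c(d[1], d[2], d[3] * d[4]))), d)
  })
  gG1p <- so3AnalyzeAdjoint(cb$signal, cfg$l2)
  gA1 <- sphericalPoolAdjoint(gG1p, cfg$l1, cfg$l1 / cfg$l2)
  gZ1 <- gA1 * (cache$z1 > 0)
  g$bias1 <- rowSums(matrix(apply(gZ1, 4, sum), cfg$c1, S))
  gBl1 <- so3SynthesizeAdjoint(gZ1, cfg$l1)
  sb <- s2ConvBatchBackward(gBl1, cache$fh1, cache$psiS)
  gPsi <- sb$filter
  for (ci in seq_len(cfg$channelsIn)) for (co in seq_len(cfg$c1))
    gPsi[, ci, co] <- symmetrizeS2(gPsi[, ci, co])
  g$psi <- gPsi
  g
}

# single-sample wrappers (used by prediction and the gradient-check tests)
riskForwardOne <- function(params, cfg, x, keepCache = FALSE) {
  X <- array(0, c(1, dim(x)))
  X[1, , , ] <- x
  out <- riskForwardBatch(params, cfg, X, keepCache)
  out$h <- out$h[1]
  out
}

riskBackwardOne <- function(params, cfg, cache, gradH = 1) {
  riskBackwardBatch(params, cfg, cache, gradH)
}

#' Network log-risk for one spherical map
#'
#' Standardizes the map with the model's stored training-split statistics and
#' evaluates the network. The result is invariant to rotations of the tumor
#' (up to grid tolerance) by construction.
#'
#' @param model a \linkS4class{RiskModel}
#' @param map a \linkS4class{SphericalMap} whose channels match the model's
#'   input configuration
#' @return scalar log-risk h
#' @export
predictRisk <- function(model, map) {
  x <- standardizeInput(model, map)
  riskForwardOne(model@params, model@config, x)$h
}

# apply stored normalization; validates channel compatibility
standardizeInput <- function(model, map) {
  cfg <- model@config
  wanted <- if (cfg$inputConfig == "sphcnn1") "depth" else c("egi", "intensity")
  if (!all(wanted %in% channelNames(map)))
    stop("map channels {", paste(channelNames(map), collapse = ","),
         "} do not provide the model's input config ", cfg$inputConfig)
  if (bandwidth(map) != cfg$bandwidth)
    stop("map bandwidth ", bandwidth(map), " != model bandwidth ", cfg$bandwidth)
  x <- array(0, c(length(wanted), 2 * cfg$bandwidth, 2 * cfg$bandwidth))
  for (i in seq_along(wanted)) {
    ch <- mapChannel(map, wanted[i])
    if (length(model@normStats) > 0) {
      st <- model@normStats[[wanted[i]]]
      ch <- (ch - st$mean) / st$sd
    }
    x[i, , ] <- ch
  }
  x
}

# ---- parameter flattening (optimizer / finite-difference checks) ----

paramsToVec <- function(params) {
  unlist(lapply(params, function(p) {
    if (is.list(p)) {
      unlist(lapply(p, function(q) c(Re(q), Im(q))))
    } else if (is.complex(p)) {
      c(Re(p), Im(p))
    } else as.numeric(p)
  }), use.names = FALSE)
}

vecToParams <- function(v, skeleton) {
  pos <- 0L
  take <- function(n) {
    out <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
  rebuild <- function(p) {
    if (is.list(p)) return(lapply(p, rebuild))
    if (is.complex(p)) {
      n <- length(p)
      re <- take(n); im <- take(n)
      out <- complex(real = re, imaginary = im)
      dim(out) <- dim(p)
      out
    } else {
      out <- take(length(p))
      dim(out) <- dim(p)
      out
    }
  }
  out <- lapply(skeleton, rebuild)
  names(out) <- names(skeleton)
  out
}
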