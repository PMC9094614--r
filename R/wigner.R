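# Wigner-d matrices and the SO(3) Fourier transform.
#
# Rotations are parameterized by ZYZ Euler angles (alpha, beta, gamma) with
# R = Rz(alpha) Ry(beta) Rz(gamma); the rotation operator on sphere signals is
# (Lambda(R) f)(w) = f(R^-1 w) and acts on coefficients per degree as
# fh' = D^l(R) fh with D^l_mn = exp(-i m alpha) d^l_mn(beta) exp(-i n gamma).
# d^l(beta) = expm(beta K) is evaluated through the eigendecomposition of the
# tridiagonal angular-momentum generator K = -i J_y, which is exact and stable
# for the moderate degrees (< 64) used here.
#
# SO(3) signals are sampled on a 2L x 2L x 2L ZYZ grid: alpha_a = pi a / L,
# beta_j on the equiangular colatitude nodes (with their quadrature weights),
# gamma_c = pi c / L. Spectra are stored per degree l as complex arrays
# [m, n, channel] of dim (2l+1, 2l+1, C); synthesis is
#   g(R) = sum_lmn gh^l_mn conj(D^l_mn(R)),
# analysis gh^l_mn = (2l+1)/(8 pi^2) * int g D^l_mn dR.

# eigendecomposition-based d^l(beta) evaluator, cached per degree
wignerdFactory <- function(l) {
  key <- paste0("wd_", l)
  if (!is.null(.sphsurvCache[[key]])) return(.sphsurvCache[[key]])
  K <- matrix(0, 2 * l + 1, 2 * l + 1)
  if (l > 0) {
    ms <- (-l):(l - 1)
    cm <- sqrt(l * (l + 1) - ms * (ms + 1))
    for (i in seq_along(ms)) {
      K[i + 1, i] <- -cm[i] / 2
      K[i, i + 1] <- cm[i] / 2
    }
  }
  ei <- eigen(1i * K, symmetric = TRUE)
  V <- ei$vectors; lam <- ei$values
  fn <- function(beta) Re(V %*% (exp(-1i * beta * lam) * Conj(t(V))))
  .sphsurvCache[[key]] <- fn
  fn
}

# full Wigner-D matrix for one degree, rows/cols indexed m,n = -l..l
wignerD <- function(l, alpha, beta, gamma) {
  d <- wignerdFactory(l)(beta)
  m <- (-l):l
  exp(-1i * alpha * m) * d * rep(exp(-1i * gamma * m), each = 2 * l + 1)
}

#' Rotation matrix from ZYZ Euler angles
#' @param alpha,beta,gamma Euler angles (radians), R = Rz(alpha) Ry(beta) Rz(gamma)
#' @return 3 x 3 rotation matrix
#' @export
rotationZYZ <- function(alpha, beta, gamma) {
  Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- function(b) matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz(alpha) %*% Ry(beta) %*% Rz(gamma)
}

# ZYZ Euler angles of a rotation matrix (beta in [0, pi])
eulerZYZ <- function(R) {
  beta <- acos(min(1, max(-1, R[3, 3])))
  if (abs(sin(beta)) < 1e-12) {
    alpha <- atan2(R[2, 1], R[1, 1])
    if (R[3, 3] < 0) alpha <- -alpha
    gamma <- 0
  } else {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  }
  c(alpha, beta, gamma)
}

#' Rotate spherical-harmonic coefficients
#'
#' Applies the coefficient-space action of the rotation
#' \code{rotationZYZ(alpha, beta, gamma)}: the result represents
#' \code{f(R^-1 w)}.
#'
#' @param fh complex coefficients, length B^2
#' @param alpha,beta,gamma ZYZ Euler angles
#' @return rotated coefficients
#' @export
rotateCoefficients <- function(fh, alpha, beta, gamma) {
  B <- as.integer(round(sqrt(length(fh))))
  out <- fh
  for (l in 0:(B - 1)) {
    sel <- (l^2 + 1):((l + 1)^2)
    out[sel] <- wignerD(l, alpha, beta, gamma) %*% fh[sel]
  }
  out
}

# cached tables for the SO(3) grid of bandwidth L
so3Basis <- function(L) {
  key <- paste0("so3_", L)
  if (!is.null(.sphsurvCache[[key]])) return(.sphsurvCache[[key]])
  q <- dhQuadrature(L)
  nm <- 2 * L - 1
  dflat <- vector("list", L)     # [j, k] k = flat (m,n), col-major m fastest
  scat <- vector("list", L)      # flat position of block entries in nm x nm plane
  for (l in 0:(L - 1)) {
    K <- 2 * l + 1
    fac <- wignerdFactory(l)
    D <- matrix(0, 2 * L, K * K)
    for (j in 1:(2 * L)) D[j, ] <- as.vector(fac(q$theta[j]))
    dflat[[l + 1]] <- D
    pos <- (L - 1) + ((-l):l) + 1
    scat[[l + 1]] <- as.vector(outer(pos, pos, function(mi, ni) mi + (ni - 1) * nm))
  }
  ang <- pi * (0:(2 * L - 1)) / L
  mcols <- (-(L - 1)):(L - 1)
  E <- exp(1i * outer(ang, mcols))
  # reality-symmetry sign tables (-1)^(m-n) per degree
  sgn <- lapply(0:(L - 1), function(l) {
    m <- (-l):l
    outer(m, m, function(a, b) (-1)^(a - b))
  })
  basis <- list(L = L, beta = q$theta, w = q$w, ang = ang, nm = nm,
                dflat = dflat, scat = scat, E = E, Et = t(E),
                EH = Conj(t(E)), Ec = Conj(E), sgn = sgn,
                wq = (pi / L)^2 * q$w)
  .sphsurvCache[[key]] <- basis
  basis
}

emptyBlocks <- function(L, C = 1L) {
  lapply(0:(L - 1), function(l) array(0 + 0i, c(2 * l + 1, 2 * l + 1, C)))
}

blockChannels <- function(blocks) dim(blocks[[1]])[3]

#' Synthesize an SO(3) signal from its Wigner spectra
#'
#' Evaluates \code{g(R) = sum_lmn gh^l_mn conj(D^l_mn(R))} on the 2L x 2L x 2L
#' ZYZ Euler grid. The two Fourier sums over alpha and gamma are batched into
#' single complex matrix products across all (beta, channel) slices.
#'
#' @param blocks spectra: list over degrees l of complex arrays
#'   (2l+1) x (2l+1) x C indexed \code{[m, n, channel]}
#' @param L bandwidth (defaults to \code{length(blocks)})
#' @return real array (2L, 2L, 2L, C) indexed \code{[alpha, beta, gamma, channel]}
#' @export
so3Synthesize <- function(blocks, L = length(blocks)) {
  sb <- so3Basis(L)
  C <- blockChannels(blocks)
  nm <- sb$nm; n2 <- nm^2; nb <- 2 * L
  Tarr <- array(0 + 0i, c(nb, n2 * C))     # [j, (m,n,C)]
  for (l in 0:(L - 1)) {
    K2 <- (2 * l + 1)^2
    D <- sb$dflat[[l + 1]]
    blv <- matrix(blocks[[l + 1]], K2, C)
    cols <- as.vector(outer(sb$scat[[l + 1]], (0:(C - 1)) * n2, "+"))
    contrib <- D[, rep(seq_len(K2), C), drop = FALSE] *
      rep(as.vector(blv), each = nb)
    Tarr[, cols] <- Tarr[, cols] + contrib
  }
  dim(Tarr) <- c(nb, nm, nm, C)            # [j, m, n, C]
  # gamma sum: rows (j, m, C) x cols n
  M <- matrix(aperm(Tarr, c(1, 2, 4, 3)), ncol = nm) %*% sb$Et  # [(j,m,C), a_g]
  dim(M) <- c(nb, nm, C, nb)               # [j, m, C, g]
  # alpha sum: rows m x cols (j, C, g)
  A <- sb$E %*% matrix(aperm(M, c(2, 1, 3, 4)), nrow = nm)      # [a, (j,C,g)]
  dim(A) <- c(nb, nb, C, nb)               # [a, j, C, g]
  aperm(array(Re(A), dim(A)), c(1, 2, 4, 3))
}

# core contraction shared by analysis and the synthesis adjoint
.so3GridContract <- function(g, L, jweight, lscale) {
  sb <- so3Basis(L)
  C <- dim(g)[4]
  nm <- sb$nm; nb <- 2 * L
  blocks <- emptyBlocks(L, C)
  # alpha sum: EH [m, a] x g [a, (j,g,C)]
  P1 <- sb$EH %*% matrix(g, nb)                      # [m, (j,g,C)]
  dim(P1) <- c(nm, nb, nb, C)                        # [m, j, g, C]
  # gamma sum: rows (m, j, C) x cols g
  P2 <- matrix(aperm(P1, c(1, 2, 4, 3)), ncol = nb) %*% sb$Ec  # [(m,j,C), n]
  dim(P2) <- c(nm, nb, C, nm)
  P <- aperm(P2, c(2, 1, 4, 3))                      # [j, m, n, C]
  dim(P) <- c(nb, nm * nm * C)
  n2 <- nm^2
  for (l in 0:(L - 1)) {
    K <- 2 * l + 1
    D <- sb$dflat[[l + 1]] * jweight                 # [j, k]
    K2 <- K * K
    cols <- as.vector(outer(sb$scat[[l + 1]], (0:(C - 1)) * n2, "+"))
    acc <- colSums(D[, rep(seq_len(K2), C), drop = FALSE] *
                     P[, cols, drop = FALSE])
    blocks[[l + 1]] <- array(lscale[l + 1] * acc, c(K, K, C))
  }
  blocks
}

#' Analyze an SO(3) grid signal into Wigner spectra
#'
#' Quadrature evaluation of \code{gh^l_mn = (2l+1)/(8 pi^2) int g D^l_mn dR};
#' exact for signals band-limited below L, so it inverts
#' \code{\link{so3Synthesize}}.
#'
#' @param g real array (2L, 2L, 2L, C) on the Euler grid
#' @param L bandwidth
#' @return spectra as in \code{\link{so3Synthesize}}
#' @export
so3Analyze <- function(g, L = dim(g)[1] / 2) {
  sb <- so3Basis(L)
  lscale <- (2 * (0:(L - 1)) + 1) / (8 * pi^2)
  .so3GridContract(g, L, sb$wq, lscale)
}

# adjoint of so3Synthesize as a real-linear map (grid cograd -> block grads)
so3SynthesizeAdjoint <- function(G, L = dim(G)[1] / 2) {
  .so3GridContract(G, L, rep(1, 2 * L), rep(1, L))
}

# adjoint of so3Analyze (block cograds -> grid grad): synthesis with the
# quadrature weights and (2l+1)/(8 pi^2) factors attached
so3AnalyzeAdjoint <- function(gradBlocks, L = length(gradBlocks)) {
  sb <- so3Basis(L)
  scaled <- lapply(0:(L - 1), function(l)
    gradBlocks[[l + 1]] * ((2 * l + 1) / (8 * pi^2)))
  g <- so3Synthesize(scaled, L)
  sweep(g, 2, sb$wq, "*")
}

#' Project SO(3) spectra onto the real-signal subspace
#'
#' Enforces \code{gh^l_{-m,-n} = (-1)^(m-n) conj(gh^l_mn)} by orthogonal
#' projection (its own adjoint under the real inner product).
#' @param blocks spectra as in \code{\link{so3Synthesize}}
#' @return symmetrized spectra
#' @export
symmetrizeSO3 <- function(blocks) {
  for (l in 0:(length(blocks) - 1))
    blocks[[l + 1]] <- symmetrizeSO3Block(blocks[[l + 1]])
  blocks
}

# same projection for a single degree-l block array (2l+1, 2l+1, C)
symmetrizeSO3Block <- function(bl) {
  K <- dim(bl)[1]
  l <- (K - 1) / 2
  m <- (-l):l
  sgn <- outer(m, m, function(a, b) (-1)^(a - b))
  fl <- bl[K:1, K:1, , drop = FALSE]
  (bl + Conj(fl) * as.vector(sgn)) / 2
}

# evaluate band-limited SO(3) spectra at an arbitrary rotation matrix;
# returns one value per channel
so3Evaluate <- function(blocks, R) {
  ang <- eulerZYZ(R)
  C <- blockChannels(blocks)
  tot <- rep(0 + 0i, C)
  for (l in 0:(length(blocks) - 1)) {
    Dl <- wignerD(l, ang[1], ang[2], ang[3])
    tot <- tot + vapply(seq_len(C), function(cc)
      sum(blocks[[l + 1]][, , cc] * Conj(Dl)), complex(1))
  }
  Re(tot)
}
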