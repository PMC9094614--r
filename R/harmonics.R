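# Spherical harmonic analysis on the equiangular 2B x 2B grid.
#
# Conventions (fixed package-wide):
#  - orthonormal complex harmonics Y_lm with Condon-Shortley phase,
#    Y_{l,-m} = (-1)^m conj(Y_lm);
#  - colatitude nodes theta_j = pi(2j+1)/(4B), longitudes phi_k = pi k/B;
#  - analysis  fhat_lm = (pi/B) sum_jk w_j f(theta_j,phi_k) conj(Y_lm),
#    exact for signals band-limited below B;
#  - flat coefficient index fi(l,m) = l^2 + l + m + 1, l = 0..B-1, |m| <= l.

.sphsurvCache <- new.env(parent = emptyenv())

# Driscoll-Healy quadrature weights for the colatitude rows; sum(w) = 2.
dhQuadrature <- function(B) {
  j <- 0:(2 * B - 1)
  theta <- pi * (2 * j + 1) / (4 * B)
  k <- 0:(B - 1)
  w <- vapply(theta, function(th)
    (2 / B) * sin(th) * sum(sin((2 * k + 1) * th) / (2 * k + 1)), numeric(1))
  list(theta = theta, w = w)
}

# Fully normalized associated Legendre functions (including sqrt(1/(4pi)) and
# the Condon-Shortley phase) for m >= 0, evaluated at arbitrary colatitudes.
# Standard three-term recursion, stable for the moderate degrees used here.
legendreNormalized <- function(lmax, theta) {
  ct <- cos(theta); st <- sin(theta)
  n <- length(theta)
  nlm <- (lmax + 1) * (lmax + 2) / 2
  P <- matrix(0, n, nlm)
  idx <- function(l, m) l * (l + 1) / 2 + m + 1
  P[, idx(0, 0)] <- sqrt(1 / (4 * pi))
  if (lmax >= 1) {
    for (m in 1:lmax)
      P[, idx(m, m)] <- -sqrt((2 * m + 1) / (2 * m)) * st * P[, idx(m - 1, m - 1)]
    for (m in 0:(lmax - 1))
      P[, idx(m + 1, m)] <- sqrt(2 * m + 3) * ct * P[, idx(m, m)]
    if (lmax >= 2) {
      for (l in 2:lmax) for (m in 0:(l - 2)) {
        a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        b <- sqrt(((2 * l + 1) * (l - 1 + m) * (l - 1 - m)) /
                    ((2 * l - 3) * (l^2 - m^2)))
        P[, idx(l, m)] <- a * ct * P[, idx(l - 1, m)] - b * P[, idx(l - 2, m)]
      }
    }
  }
  P
}

# Cached per-bandwidth transform tables.
shBasis <- function(B) {
  key <- paste0("s2_", B)
  if (!is.null(.sphsurvCache[[key]])) return(.sphsurvCache[[key]])
  q <- dhQuadrature(B)
  lmax <- B - 1
  Ph <- legendreNormalized(lmax, q$theta)
  nlm <- B^2
  lv <- integer(nlm); mv <- integer(nlm)
  for (l in 0:lmax) for (m in (-l):l) {
    fi <- l^2 + l + m + 1; lv[fi] <- l; mv[fi] <- m
  }
  idxh <- function(l, m) l * (l + 1) / 2 + m + 1
  Pfull <- matrix(0, 2 * B, nlm)
  for (fi in seq_len(nlm)) {
    l <- lv[fi]; m <- mv[fi]
    Pfull[, fi] <- if (m >= 0) Ph[, idxh(l, m)] else (-1)^m * Ph[, idxh(l, -m)]
  }
  phi <- pi * (0:(2 * B - 1)) / B
  mcols <- (-(B - 1)):(B - 1)
  Ephi <- exp(1i * outer(phi, mcols))
  mcolOf <- match(mv, mcols)
  mSel <- lapply(seq_along(mcols), function(mc) which(mcolOf == mc))
  basis <- list(B = B, theta = q$theta, w = q$w, phi = phi, Pfull = Pfull,
                wP = q$w * Pfull, Ephi = Ephi, lv = lv, mv = mv,
                mcols = mcols, mcolOf = mcolOf, mSel = mSel)
  .sphsurvCache[[key]] <- basis
  basis
}

#' Construct an equiangular spherical grid
#'
#' Builds the 2B x 2B Driscoll-Healy-style grid with exact quadrature weights.
#' Regions close to the poles are oversampled compared to the equator under
#' this convention; the weights account for that in all integrals.
#'
#' @param B bandwidth (maximum harmonic degree, exclusive)
#' @return a \linkS4class{SphericalGrid}
#' @examples
#' g <- sphericalGrid(8)
#' sum(quadratureWeights(g)) * pi / 8 * 16  # 4*pi
#' @export
sphericalGrid <- function(B) {
  B <- as.integer(B)
  q <- dhQuadrature(B)
  new("SphericalGrid", bandwidth = B, theta = q$theta,
      phi = pi * (0:(2 * B - 1)) / B, weights = q$w)
}

#' Forward spherical harmonic transform
#'
#' Analysis of a real signal sampled on the equiangular grid. Exact (to float
#' precision) for signals band-limited below B.
#'
#' @param f 2B x 2B real matrix, rows indexed by colatitude
#' @param B bandwidth; defaults to \code{nrow(f)/2}
#' @return complex coefficient vector of length B^2, flat index
#'   \code{l^2 + l + m + 1}
#' @export
shtForward <- function(f, B = nrow(f) / 2) {
  bs <- shBasis(B)
  if (!is.matrix(f) || nrow(f) != 2 * B || ncol(f) != 2 * B)
    stop("f must be a 2B x 2B matrix matching the grid")
  Fm <- f %*% Conj(bs$Ephi)
  (pi / B) * colSums(bs$wP * Fm[, bs$mcolOf, drop = FALSE])
}

#' Inverse spherical harmonic transform
#'
#' Synthesis at the grid nodes. \code{shtInverse(shtForward(f))} is the
#' identity for band-limited f.
#'
#' @param fh complex coefficients, length B^2
#' @param real return the real part (TRUE for signals with conjugate symmetry)
#' @return 2B x 2B matrix
#' @export
shtInverse <- function(fh, real = TRUE) {
  B <- as.integer(round(sqrt(length(fh))))
  if (B * B != length(fh)) stop("coefficient vector length must be a square")
  bs <- shBasis(B)
  A <- matrix(0 + 0i, 2 * B, length(bs$mcols))
  for (mc in seq_along(bs$mcols)) {
    sel <- bs$mSel[[mc]]
    if (length(sel)) A[, mc] <- bs$Pfull[, sel, drop = FALSE] %*% fh[sel]
  }
  out <- A %*% t(bs$Ephi)
  if (real) Re(out) else out
}

# Adjoint of shtInverse as a real-linear map grid -> coefficients: used in
# backpropagation. For real grid gradients G, grad_fh = sum_jk G conj(Y_lm).
shtInverseAdjoint <- function(G, B = nrow(G) / 2) {
  bs <- shBasis(B)
  Fm <- G %*% Conj(bs$Ephi)
  colSums(bs$Pfull * Fm[, bs$mcolOf, drop = FALSE])
}

# Adjoint of shtForward: coefficients gradient -> grid gradient.
# shtForward is fh = (pi/B) t(wP) (f Ephi*): adjoint is
# grad_f = Re( (pi/B) wP gradfh-scattered Ephi^T ).
shtForwardAdjoint <- function(gh, B) {
  bs <- shBasis(B)
  A <- matrix(0 + 0i, 2 * B, length(bs$mcols))
  for (mc in seq_along(bs$mcols)) {
    sel <- bs$mSel[[mc]]
    if (length(sel)) A[, mc] <- bs$wP[, sel, drop = FALSE] %*% gh[sel]
  }
  Re((pi / B) * A %*% t(bs$Ephi))
}

#' Evaluate a band-limited spherical signal at arbitrary directions
#'
#' Synthesis of the harmonic expansion at given (colatitude, longitude) pairs;
#' used by the phantom oracle and by resampled-rotation tests.
#'
#' @param fh complex coefficients, length B^2
#' @param theta,phi directions (radians), equal lengths
#' @param real return real part
#' @return numeric (or complex) vector of values
#' @export
shtEvaluate <- function(fh, theta, phi, real = TRUE) {
  B <- as.integer(round(sqrt(length(fh))))
  lmax <- B - 1
  Ph <- legendreNormalized(lmax, theta)
  idxh <- function(l, m) l * (l + 1) / 2 + m + 1
  out <- rep(0 + 0i, length(theta))
  for (l in 0:lmax) for (m in (-l):l) {
    fi <- l^2 + l + m + 1
    if (fh[fi] == 0) next
    Pv <- if (m >= 0) Ph[, idxh(l, m)] else (-1)^m * Ph[, idxh(l, -m)]
    out <- out + fh[fi] * Pv * exp(1i * m * phi)
  }
  if (real) Re(out) else out
}

# Impose the real-signal conjugate symmetry fh_{l,-m} = (-1)^m conj(fh_{lm})
# by averaging a free complex vector with its reflected conjugate. Linear and
# self-adjoint, so it is its own gradient backrule.
symmetrizeS2 <- function(fh) {
  B <- as.integer(round(sqrt(length(fh))))
  out <- fh
  for (l in 0:(B - 1)) {
    base <- l^2 + l + 1
    out[base] <- complex(real = Re(fh[base]))
    if (l > 0) for (m in 1:l) {
      a <- fh[base + m]; b <- fh[base - m]
      s <- (a + (-1)^m * Conj(b)) / 2
      out[base + m] <- s
      out[base - m] <- (-1)^m * Conj(s)
    }
  }
  out
}

#' Random real band-limited coefficient vector
#'
#' Gaussian coefficients projected onto the real-signal subspace; used for
#' property tests and filter initialization.
#' @param B bandwidth
#' @param scale coefficient standard deviation
#' @return complex vector of length B^2 with conjugate symmetry
#' @export
randomRealCoefficients <- function(B, scale = 1) {
  fh <- complex(real = stats::rnorm(B^2, sd = scale),
                imaginary = stats::rnorm(B^2, sd = scale))
  symmetrizeS2(fh)
}
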