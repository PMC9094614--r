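# Spectral convolution layers.
#
# S2 correlation of a spherical signal f with a filter psi produces a function
# on the rotation group,
#   (psi star f)(R) = int_{S2} f(w) conj(psi(R^-1 w)) dw,
# whose Wigner coefficients factorize degree-wise as
#   gh^l_mn = fh_lm conj(psih_ln).
# SO(3) correlation acts blockwise, oh^l = 8 pi^2/(2l+1) gh^l (chih^l)^H.
# Both identities are verified against direct numerical integration of the
# definitions in the test suite.

# truncate a flat S2 coefficient vector/matrix to degrees < L
truncateCoefficients <- function(fh, L) {
  if (is.matrix(fh)) fh[seq_len(L^2), , drop = FALSE] else fh[seq_len(L^2)]
}

#' S2 spectral correlation lifting sphere signals onto SO(3)
#'
#' Computes the Wigner spectrum of the correlation of a multi-channel
#' spherical signal with a bank of spherical filters, summed over input
#' channels.
#'
#' @param fh complex coefficient matrix (L^2 x Cin), flat degree index
#' @param psih complex coefficient array (L^2 x Cin x Cout)
#' @return SO(3) spectra: list over degrees l = 0..L-1 of complex arrays
#'   (2l+1) x (2l+1) x Cout indexed [m, n, channel]
#' @export
s2Conv <- function(fh, psih) {
  if (is.null(dim(fh))) fh <- matrix(fh, ncol = 1)
  L <- as.integer(round(sqrt(nrow(fh))))
  if (L^2 != nrow(fh) || dim(psih)[1] != nrow(fh))
    stop("signal/filter bandwidth mismatch")
  if (dim(psih)[2] != ncol(fh)) stop("input channel count mismatch")
  O <- dim(psih)[3]
  Cin <- ncol(fh)
  blocks <- emptyBlocks(L, O)
  for (l in 0:(L - 1)) {
    sel <- (l^2 + 1):((l + 1)^2)
    K <- length(sel)
    Fl <- fh[sel, , drop = FALSE]                       # [m, c]
    Pl <- Conj(aperm(array(psih[sel, , , drop = FALSE],
                           c(K, Cin, O)), c(2, 1, 3)))  # [c, n, o]
    blocks[[l + 1]] <- array(Fl %*% matrix(Pl, Cin), c(K, K, O))
  }
  blocks
}

# backward: cograds on output blocks -> (grad fh, grad psih)
s2ConvBackward <- function(gradBlocks, fh, psih) {
  if (is.null(dim(fh))) fh <- matrix(fh, ncol = 1)
  L <- length(gradBlocks)
  Cin <- ncol(fh); O <- dim(psih)[3]
  gFh <- matrix(0 + 0i, nrow(fh), Cin)
  gPsi <- array(0 + 0i, dim(psih))
  for (l in 0:(L - 1)) {
    sel <- (l^2 + 1):((l + 1)^2)
    K <- length(sel)
    Fl <- fh[sel, , drop = FALSE]
    Gl <- array(gradBlocks[[l + 1]], c(K, K, O))
    # grad_f[m,c] = sum_{n,o} G[m,n,o] psi[n,c,o]
    Pl <- array(psih[sel, , , drop = FALSE], c(K, Cin, O))
    Pno <- matrix(aperm(Pl, c(1, 3, 2)), K * O, Cin)    # [(n,o), c]
    gFh[sel, ] <- gFh[sel, ] + matrix(Gl, K) %*% Pno
    # grad_psi[n,c,o] = sum_m conj(G[m,n,o]) F[m,c]
    Gm <- Conj(t(matrix(Gl, K)))                        # [(n,o), m]
    gPsi[sel, , ] <- aperm(array(Gm %*% Fl, c(K, O, Cin)), c(1, 3, 2))
  }
  list(signal = gFh, filter = gPsi)
}

#' SO(3) group correlation in the Wigner spectral domain
#'
#' @param blocks signal spectra, list over l of (2l+1) x (2l+1) x Cin arrays
#' @param chih filter spectra, list over l of (2l+1) x (2l+1) x Cin x Cout
#' @return output spectra, list over l of (2l+1) x (2l+1) x Cout
#' @export
so3Conv <- function(blocks, chih) {
  L <- length(blocks)
  if (length(chih) != L) stop("signal/filter bandwidth mismatch")
  Cin <- blockChannels(blocks); O <- dim(chih[[1]])[4]
  if (dim(chih[[1]])[3] != Cin) stop("channel count mismatch")
  out <- emptyBlocks(L, O)
  for (l in 0:(L - 1)) {
    s <- 8 * pi^2 / (2 * l + 1)
    K <- 2 * l + 1
    Smat <- matrix(blocks[[l + 1]], K)                      # [m, (n,c)]
    Xmat <- Conj(matrix(aperm(chih[[l + 1]], c(2, 3, 1, 4)), K * Cin))
    out[[l + 1]] <- array(s * (Smat %*% Xmat), c(K, K, O))  # [m, (n',o)]
  }
  out
}

so3ConvBackward <- function(gradBlocks, blocks, chih) {
  L <- length(blocks)
  Cin <- blockChannels(blocks); O <- dim(chih[[1]])[4]
  gS <- emptyBlocks(L, Cin)
  gX <- lapply(chih, function(a) array(0 + 0i, dim(a)))
  for (l in 0:(L - 1)) {
    s <- 8 * pi^2 / (2 * l + 1)
    K <- 2 * l + 1
    Gmat <- matrix(gradBlocks[[l + 1]], K)                  # [m, (n',o)]
    Smat <- matrix(blocks[[l + 1]], K)                      # [m, (n,c)]
    X2 <- matrix(aperm(chih[[l + 1]], c(1, 4, 2, 3)), K * O)
    gS[[l + 1]] <- array(s * (Gmat %*% X2), c(K, K, Cin))
    GH <- Conj(t(Gmat))                                     # [(n',o), m]
    gX[[l + 1]] <- aperm(array(s * (GH %*% Smat), c(K, O, K, Cin)),
                         c(1, 3, 4, 2))
  }
  list(signal = gS, filter = gX)
}

#' Spherical pooling on SO(3) signals
#'
#' Halves the bandwidth by spectral truncation and resamples on the coarser
#' grid. Constants pass through unchanged and the weighted L2 norm never
#' increases (truncation property).
#'
#' @param g real array (2L, 2L, 2L, C) on the SO(3) grid
#' @param factor bandwidth reduction factor (must divide the grid)
#' @return real array (2L/factor, 2L/factor, 2L/factor, C)
#' @export
sphericalPool <- function(g, factor = 2L) {
  L <- dim(g)[1] / 2
  if (L %% factor != 0) stop("grid size not divisible by pooling factor")
  L2 <- as.integer(L / factor)
  blocks <- so3Analyze(g, L)
  so3Synthesize(blocks[seq_len(L2)], L2)
}

sphericalPoolAdjoint <- function(gradOut, L, factor = 2L) {
  L2 <- as.integer(L / factor)
  gb <- so3SynthesizeAdjoint(gradOut, L2)
  C <- dim(gradOut)[4]
  full <- emptyBlocks(L, C)
  full[seq_len(L2)] <- gb
  so3AnalyzeAdjoint(full, L)
}

#' Rotation-invariant readout of an SO(3) signal
#'
#' Per channel, the integral of the signal over the rotation group (with
#' quadrature weights) and, optionally, its weighted L2 norm. Both statistics
#' are invariant to rotations of the network input.
#'
#' @param g real array (2L, 2L, 2L, C)
#' @param useL2 include the L2-norm statistic
#' @return numeric feature vector, length C (or 2C with \code{useL2})
#' @export
invariantReadout <- function(g, useL2 = TRUE) {
  L <- dim(g)[1] / 2
  sb <- so3Basis(L)
  wg <- sweep(g, 2, sb$wq, "*")
  ints <- apply(wg, 4, sum)
  if (!useL2) return(ints)
  nrm <- sqrt(pmax(apply(wg * g, 4, sum), 0))
  c(ints, nrm)
}

invariantReadoutBackward <- function(gradFeat, g, useL2 = TRUE) {
  L <- dim(g)[1] / 2
  sb <- so3Basis(L)
  C <- dim(g)[4]
  wqArr <- array(rep(sb$wq, each = 2 * L), dim(g)[1:3])
  gi <- gradFeat[seq_len(C)]
  grad <- sweep(array(wqArr, dim(g)), 4, gi, "*")
  if (useL2) {
    nrm <- sqrt(pmax(apply(sweep(g, 2, sb$wq, "*") * g, 4, sum), 0))
    gn <- ifelse(nrm > 1e-12, gradFeat[C + seq_len(C)] / pmax(nrm, 1e-12), 0)
    grad <- grad + array(wqArr, dim(g)) * sweep(g, 4, gn, "*")
  }
  grad
}

relu <- function(x) pmax(x, 0)

# ---- batched variants: samples ride along the channel dimension ----
# Channel order in batched block arrays is (filter output o fastest, then
# sample s); filters are shared across samples, so the convolutions stay
# single matrix products per degree.

s2ConvBatch <- function(fh3, psih) {
  L <- as.integer(round(sqrt(dim(fh3)[1])))
  Cin <- dim(fh3)[2]; S <- dim(fh3)[3]; O <- dim(psih)[3]
  blocks <- emptyBlocks(L, O * S)
  for (l in 0:(L - 1)) {
    sel <- (l^2 + 1):((l + 1)^2)
    K <- length(sel)
    F2 <- matrix(aperm(array(fh3[sel, , , drop = FALSE], c(K, Cin, S)),
                       c(1, 3, 2)), K * S, Cin)
    Pmat <- Conj(matrix(aperm(array(psih[sel, , , drop = FALSE], c(K, Cin, O)),
                              c(2, 1, 3)), Cin, K * O))
    out <- array(F2 %*% Pmat, c(K, S, K, O))
    blocks[[l + 1]] <- array(aperm(out, c(1, 3, 4, 2)), c(K, K, O * S))
  }
  blocks
}

s2ConvBatchBackward <- function(gradBlocks, fh3, psih) {
  L <- length(gradBlocks)
  Cin <- dim(fh3)[2]; S <- dim(fh3)[3]; O <- dim(psih)[3]
  gFh <- array(0 + 0i, dim(fh3))
  gPsi <- array(0 + 0i, dim(psih))
  for (l in 0:(L - 1)) {
    sel <- (l^2 + 1):((l + 1)^2)
    K <- length(sel)
    Gl <- array(gradBlocks[[l + 1]], c(K, K, O, S))
    Gmat <- matrix(aperm(Gl, c(1, 4, 2, 3)), K * S, K * O)   # [(m,s),(n,o)]
    F2 <- matrix(aperm(array(fh3[sel, , , drop = FALSE], c(K, Cin, S)),
                       c(1, 3, 2)), K * S, Cin)
    gPsi[sel, , ] <- aperm(array(Conj(t(Gmat)) %*% F2, c(K, O, Cin)),
                           c(1, 3, 2))
    Pno <- matrix(aperm(array(psih[sel, , , drop = FALSE], c(K, Cin, O)),
                        c(1, 3, 2)), K * O, Cin)             # [(n,o), c]
    gFh[sel, , ] <- aperm(array(Gmat %*% Pno, c(K, S, Cin)), c(1, 3, 2))
  }
  list(signal = gFh, filter = gPsi)
}

so3ConvBatch <- function(blocks, chih, S) {
  L <- length(blocks)
  Cin <- dim(chih[[1]])[3]; O <- dim(chih[[1]])[4]
  out <- emptyBlocks(L, O * S)
  for (l in 0:(L - 1)) {
    s <- 8 * pi^2 / (2 * l + 1)
    K <- 2 * l + 1
    S4 <- array(blocks[[l + 1]], c(K, K, Cin, S))
    S2 <- matrix(aperm(S4, c(1, 4, 2, 3)), K * S)            # [(m,s),(n,c)]
    Xmat <- Conj(matrix(aperm(chih[[l + 1]], c(2, 3, 1, 4)), K * Cin))
    out[[l + 1]] <- array(aperm(array(s * (S2 %*% Xmat), c(K, S, K, O)),
                                c(1, 3, 4, 2)), c(K, K, O * S))
  }
  out
}

so3ConvBatchBackward <- function(gradBlocks, blocks, chih, S) {
  L <- length(blocks)
  Cin <- dim(chih[[1]])[3]; O <- dim(chih[[1]])[4]
  gS <- emptyBlocks(L, Cin * S)
  gX <- lapply(chih, function(a) array(0 + 0i, dim(a)))
  for (l in 0:(L - 1)) {
    s <- 8 * pi^2 / (2 * l + 1)
    K <- 2 * l + 1
    Gmat <- matrix(aperm(array(gradBlocks[[l + 1]], c(K, K, O, S)),
                         c(1, 4, 2, 3)), K * S)              # [(m,s),(n',o)]
    S2 <- matrix(aperm(array(blocks[[l + 1]], c(K, K, Cin, S)),
                       c(1, 4, 2, 3)), K * S)                # [(m,s),(n,c)]
    X2 <- matrix(aperm(chih[[l + 1]], c(1, 4, 2, 3)), K * O) # [(n',o),(n,c)]
    gS[[l + 1]] <- array(aperm(array(s * (Gmat %*% X2), c(K, S, K, Cin)),
                               c(1, 3, 4, 2)), c(K, K, Cin * S))
    gX[[l + 1]] <- aperm(array(s * (Conj(t(Gmat)) %*% S2), c(K, O, K, Cin)),
                         c(1, 3, 4, 2))
  }
  list(signal = gS, filter = gX)
}
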