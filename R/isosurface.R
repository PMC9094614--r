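# Isosurface triangulation by marching tetrahedra.
#
# Each cell of 8 neighbouring voxel centers is split into the 6 Kuhn
# tetrahedra sharing the main diagonal; each tetrahedron crossing the level
# set contributes one or two triangles with vertices linearly interpolated
# along crossing edges. Simpler than marching cubes (no ambiguous cases) and
# watertight on shared faces, which is what the extended Gaussian image
# needs: triangle areas are binned exactly, so total EGI mass equals total
# triangulated area by construction.

# Kuhn subdivision: vertex offset paths 000 -> e_s1 -> e_s1+e_s2 -> 111
.tetPaths <- local({
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(perms, function(p) {
    o <- matrix(0, 4, 3)
    o[2, p[1]] <- 1
    o[3, p[1]] <- 1; o[3, p[2]] <- 1
    o[4, ] <- 1
    o
  })
})

# triangle vertex-edge table per above-pattern (bits v1..v4); each row of a
# case entry is one triangle given as three edges, an edge being a pair of
# local vertex indices with opposite sign
.tetCases <- local({
  E <- function(a, b) c(a, b)
  tab <- vector("list", 16)
  one <- function(v, rest) list(rbind(c(E(v, rest[1]), E(v, rest[2]), E(v, rest[3]))))
  two <- function(a, b, c, d) list(rbind(
    c(E(a, c), E(a, d), E(b, d)),
    c(E(a, c), E(b, d), E(b, c))))
  for (code in 0:15) {
    above <- which(bitwAnd(code, c(1L, 2L, 4L, 8L)) > 0)
    below <- setdiff(1:4, above)
    tab[[code + 1]] <- switch(as.character(length(above)),
      "0" = list(), "4" = list(),
      "1" = one(above, below),
      "3" = one(below, above),
      "2" = two(above[1], above[2], below[1], below[2]))
  }
  tab
})

# volume values (3D array), physical geometry -> triangle soup
# returns list(v1, v2, v3): N x 3 matrices of triangle vertices (mm)
marchingTetrahedra <- function(vals, spacing, origin = c(0, 0, 0), level = 0.5) {
  dims <- dim(vals)
  if (any(dims < 2)) stop("volume too small for surface extraction")
  nc <- dims - 1L
  cellIdx <- arrayInd(seq_len(prod(nc)), nc)   # lower corner of each cell
  # voxel-center coordinates of the 8 corners, computed lazily per offset
  cornerVal <- function(off) {
    vals[cbind(cellIdx[, 1] + off[1], cellIdx[, 2] + off[2], cellIdx[, 3] + off[3])]
  }
  cornerPos <- function(off) {
    cbind(origin[1] + (cellIdx[, 1] + off[1] - 0.5) * spacing[1],
          origin[2] + (cellIdx[, 2] + off[2] - 0.5) * spacing[2],
          origin[3] + (cellIdx[, 3] + off[3] - 0.5) * spacing[3])
  }
  V1 <- NULL; V2 <- NULL; V3 <- NULL
  for (tet in .tetPaths) {
    tv <- lapply(1:4, function(k) cornerVal(tet[k, ]))
    code <- (tv[[1]] >= level) + 2L * (tv[[2]] >= level) +
      4L * (tv[[3]] >= level) + 8L * (tv[[4]] >= level)
    active <- which(code > 0L & code < 15L)
    if (!length(active)) next
    tp <- NULL
    for (cs in sort(unique(code[active]))) {
      rows <- active[code[active] == cs]
      tris <- .tetCases[[cs + 1]]
      if (!length(tris)) next
      if (is.null(tp)) tp <- lapply(1:4, function(k) cornerPos(tet[k, ]))
      for (mat in tris) for (r in seq_len(nrow(mat))) {
        eg <- mat[r, ]
        pts <- lapply(c(1, 3, 5), function(q) {
          a <- eg[q]; b <- eg[q + 1]
          va <- tv[[a]][rows]; vb <- tv[[b]][rows]
          t <- (level - va) / (vb - va)
          tp[[a]][rows, , drop = FALSE] +
            t * (tp[[b]][rows, , drop = FALSE] - tp[[a]][rows, , drop = FALSE])
        })
        V1 <- rbind(V1, pts[[1]]); V2 <- rbind(V2, pts[[2]]); V3 <- rbind(V3, pts[[3]])
      }
    }
  }
  if (is.null(V1)) stop("no isosurface found at level ", level)
  list(v1 = V1, v2 = V2, v3 = V3)
}

# areas (mm^2) and unit normals of a triangle soup; normals oriented along
# the provided reference field evaluated at triangle centroids
triangleGeometry <- function(tris, orientRef) {
  e1 <- tris$v2 - tris$v1
  e2 <- tris$v3 - tris$v1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- sqrt(rowSums(cr^2))
  keep <- nrm > 1e-12
  area <- nrm[keep] / 2
  normal <- cr[keep, , drop = FALSE] / nrm[keep]
  centroid <- (tris$v1[keep, , drop = FALSE] + tris$v2[keep, , drop = FALSE] +
                 tris$v3[keep, , drop = FALSE]) / 3
  ref <- orientRef(centroid)
  flip <- rowSums(normal * ref) < 0
  normal[flip, ] <- -normal[flip, ]
  list(area = area, normal = normal, centroid = centroid)
}
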