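# Isosurface extraction by marching tetrahedra.
#
# Each grid cube is split into six tetrahedra sharing the main diagonal;
# every tetrahedron with a sign change contributes one or two triangles with
# vertices linearly interpolated along crossing edges. Unlike the classic
# 256-case cube lookup, the tetrahedral split has no ambiguous cases, so the
# extracted surface is always closed and consistently oriented (normals
# point out of the >= isovalue region). Vertices are deduplicated by the
# grid edge they sit on, which makes Euler-characteristic bookkeeping exact.

# cube corner offsets, corner index b = dx + 2 dy + 4 dz (0-based)
.mt_corners <- cbind(dx = c(0, 1, 0, 1, 0, 1, 0, 1),
                     dy = c(0, 0, 1, 1, 0, 0, 1, 1),
                     dz = c(0, 0, 0, 0, 1, 1, 1, 1))

# six tetrahedra around the 0-7 diagonal (1-based corner ids)
.mt_tets <- list(c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
                 c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8))

# case table: for each inside-mask 1..14, a list of triangles; a triangle is
# a 3 x 2 matrix of (inside, outside) local vertex index pairs (1..4)
.mt_case_table <- local({
  tab <- vector("list", 14)
  for (mask in 1:14) {
    ins <- which(bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L)
    out <- setdiff(1:4, ins)
    tris <- list()
    if (length(ins) == 1) {
      tris[[1]] <- cbind(rep(ins, 3), out)
    } else if (length(ins) == 3) {
      tris[[1]] <- cbind(ins, rep(out, 3))
    } else {                           # two in, two out -> quad -> 2 triangles
      i1 <- ins[1]; i2 <- ins[2]; o1 <- out[1]; o2 <- out[2]
      tris[[1]] <- rbind(c(i1, o1), c(i1, o2), c(i2, o2))
      tris[[2]] <- rbind(c(i1, o1), c(i2, o2), c(i2, o1))
    }
    tab[[mask]] <- tris
  }
  tab
})

# Core extractor on a 3D array. Returns vertices in voxel-index units
# (1-based grid coordinates) and faces, outward-oriented w.r.t. the
# >= iso region. Empty surface -> NULL.
marching_tetrahedra <- function(vol, iso) {
  dm <- dim(vol)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  inside <- vol >= iso
  # active cells: any corner sign differs
  cs <- array(0L, dm - 1L)
  for (b in 1:8) {
    o <- .mt_corners[b, ]
    cs <- cs + inside[(1 + o[1]):(nx - 1 + o[1]),
                      (1 + o[2]):(ny - 1 + o[2]),
                      (1 + o[3]):(nz - 1 + o[3])]
  }
  act <- which(cs > 0L & cs < 8L, arr.ind = TRUE)
  if (nrow(act) == 0) return(NULL)
  nxy <- nx * ny
  corner_lin <- sapply(1:8, function(b) {
    o <- .mt_corners[b, ]
    (act[, 1] + o[1]) + (act[, 2] + o[2] - 1) * nx + (act[, 3] + o[3] - 1) * nxy
  })
  if (is.null(dim(corner_lin))) corner_lin <- matrix(corner_lin, nrow = 1)
  V8 <- matrix(vol[corner_lin], ncol = 8)
  I8 <- matrix(inside[corner_lin], ncol = 8)

  pts <- list(); keys <- list(); refs <- list(); np <- 0L
  lin_to_xyz <- function(lin) {
    k <- (lin - 1) %/% nxy
    r <- (lin - 1) %% nxy
    cbind(r %% nx + 1, r %/% nx + 1, k + 1)
  }
  for (tet in .mt_tets) {
    mask <- I8[, tet[1]] + 2L * I8[, tet[2]] + 4L * I8[, tet[3]] +
      8L * I8[, tet[4]]
    for (m in 1:14) {
      rows <- which(mask == m)
      if (length(rows) == 0) next
      for (tri in .mt_case_table[[m]]) {
        tri_pts <- vector("list", 3)
        tri_keys <- matrix(0, length(rows), 3)
        for (e in 1:3) {
          a <- tet[tri[e, 1]]; b <- tet[tri[e, 2]]
          la <- corner_lin[rows, a]; lb <- corner_lin[rows, b]
          va <- V8[rows, a]; vb <- V8[rows, b]
          tt <- (iso - va) / (vb - va)
          tt[!is.finite(tt)] <- 0.5
          tt <- pmin(pmax(tt, 0), 1)
          pa <- lin_to_xyz(la); pb <- lin_to_xyz(lb)
          tri_pts[[e]] <- pa + tt * (pb - pa)
          tri_keys[, e] <- pmin(la, lb) * (nxy * nz + 1) + pmax(la, lb)
        }
        # reference inside-corner position for orientation
        ref <- lin_to_xyz(corner_lin[rows, tet[tri[1, 1]]])
        np <- np + 1L
        pts[[np]] <- list(p = tri_pts, k = tri_keys, ref = ref)
      }
    }
  }
  P1 <- do.call(rbind, lapply(pts, function(z) z$p[[1]]))
  P2 <- do.call(rbind, lapply(pts, function(z) z$p[[2]]))
  P3 <- do.call(rbind, lapply(pts, function(z) z$p[[3]]))
  K <- do.call(rbind, lapply(pts, function(z) z$k))
  REF <- do.call(rbind, lapply(pts, function(z) z$ref))

  allk <- c(K[, 1], K[, 2], K[, 3])
  uk <- unique(allk)
  id <- match(allk, uk)
  ntri <- nrow(K)
  f1 <- id[seq_len(ntri)]
  f2 <- id[ntri + seq_len(ntri)]
  f3 <- id[2 * ntri + seq_len(ntri)]
  verts <- matrix(NA_real_, length(uk), 3)
  allp <- rbind(P1, P2, P3)
  verts[id, ] <- allp          # last write wins; identical up to rounding

  # orient: normal should point from the inside corner toward the triangle
  e1 <- P2 - P1; e2 <- P3 - P1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  cen <- (P1 + P2 + P3) / 3
  flip <- rowSums(nrm * (cen - REF)) < 0
  faces <- cbind(f1, ifelse(flip, f3, f2), ifelse(flip, f2, f3))
  # drop degenerate (zero-length edge) triangles
  good <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  faces <- faces[good, , drop = FALSE]
  if (nrow(faces) == 0) return(NULL)
  list(vertices = verts, faces = faces)
}
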